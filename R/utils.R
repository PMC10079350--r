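# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

.stop_typed <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "isoformGO_error")))
}

.ASPECTS <- c(molecular_function = "MF",
              biological_process = "BP",
              cellular_component = "CC")

#' Map a GO namespace or GAF aspect code to the short subontology label
#'
#' @param x character vector of namespaces (`molecular_function`, ...),
#'   GAF aspect codes (`F`/`P`/`C`) or already-short labels (`MF`/`BP`/`CC`).
#' @return character vector in `MF`/`BP`/`CC`.
#' @keywords internal
.as_aspect <- function(x) {
  out <- ifelse(x %in% c("MF", "BP", "CC"), x,
         ifelse(x == "F" | x == "molecular_function", "MF",
         ifelse(x == "P" | x == "biological_process", "BP",
         ifelse(x == "C" | x == "cellular_component", "CC", NA_character_))))
  out
}

.check_go_id <- function(x, what = "GO id") {
  bad <- x[!grepl("^GO:\\d{7}$", x)]
  if (length(bad)) {
    .stop_typed("isoformGO_parse_error", "malformed %s: '%s'", what, bad[[1L]])
  }
  invisible(x)
}

.check_ipr_id <- function(x) {
  bad <- x[!grepl("^IPR\\d{6}$", x)]
  if (length(bad)) {
    .stop_typed("isoformGO_parse_error",
                "malformed InterPro accession: '%s'", bad[[1L]])
  }
  invisible(x)
}

# Strip a trailing transcript/gene version suffix (".N").
.strip_version <- function(x) sub("\\.\\d+$", "", x)

# Draw a sub-seed from the active RNG stream; keeps nested set.seed() calls
# reproducible under a single top-level seed (R seeds are 32-bit).
.draw_seed <- function() sample.int(.Machine$integer.max - 1L, 1L)
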