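# Smith-Waterman protein similarity and its normalization into the
# standardized score S used by the quadratic model. Raw scores come
# from Biostrings' local pairwiseAlignment with BLOSUM62 (gap open 10,
# extend 4, i.e. a gap of length L costs open + L * extend); they are
# log10-transformed and z-scored within each scoring batch.

.blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      mat <<- env$BLOSUM62
    }
    mat
  }
})

.sub_matrix <- function(name) {
  if (identical(name, "BLOSUM62")) return(.blosum62())
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  env[[name]]
}

#' Smith-Waterman local alignment score of two protein sequences
#'
#' Maximal local alignment score under an affine gap model (a gap of
#' length L costs `gap_open + L * gap_extend`). Selenocysteine (`U`) is
#' scored as `X` since BLOSUM62 has no U row.
#'
#' @param seq_a,seq_b non-empty amino-acid strings.
#' @param substitution substitution matrix name (default `BLOSUM62`).
#' @param gap_open,gap_extend gap penalties (defaults 10 and 4).
#' @return non-negative numeric score, symmetric in its arguments.
#' @export
sw_score <- function(seq_a, seq_b, substitution = "BLOSUM62",
                     gap_open = 10, gap_extend = 4) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    .stop_typed("isoformGO_alignment_error", "empty sequence in sw_score")
  }
  seq_a <- chartr("U", "X", seq_a)
  seq_b <- chartr("U", "X", seq_b)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "local", substitutionMatrix = .sub_matrix(substitution),
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
  as.numeric(pa)
}

#' Log-transform and standardize a batch of alignment scores
#'
#' Scores are mapped through `y = log10(x + a)` with offset `a = 0`
#' when all scores are positive and `a = 1e-6 - min(x)` otherwise, then
#' z-scored with the sample standard deviation. The transform is
#' monotone, so rank order is preserved.
#'
#' @param raw numeric vector of raw scores (length >= 2, non-constant
#'   after transform).
#' @return list with `std` (standardized scores) and `meta`
#'   (list: `offset`, `base`, `mean`, `sd` of the log scores).
#' @export
normalize_scores <- function(raw) {
  if (length(raw) < 2L) {
    .stop_typed("isoformGO_alignment_error",
                "need >= 2 scores to standardize (got %d)", length(raw))
  }
  offset <- if (min(raw) > 0) 0 else 1e-6 - min(raw)
  y <- log10(raw + offset)
  mu <- mean(y)
  sdv <- stats::sd(y)
  if (!is.finite(sdv) || sdv == 0) {
    .stop_typed("isoformGO_alignment_error",
                "constant scores: zero variance after log transform")
  }
  list(std = (y - mu) / sdv,
       meta = list(offset = offset, base = 10, mean = mu, sd = sdv))
}

#' Create a raw-alignment cache
#'
#' Raw Smith-Waterman scores are keyed by unordered isoform pair, so
#' repeated partitions never recompute an alignment.
#'
#' @return an environment usable as the `cache` argument of
#'   [score_subset()].
#' @export
alignment_cache <- function() new.env(parent = emptyenv())

#' Align and standardize the eligible pairs of one isoform subset
#'
#' Computes (or fetches from `cache`) the raw Smith-Waterman score of
#' each requested pair, then standardizes the scores within the batch:
#' the objective only ever compares scores inside one mini-batch
#' subset, so standardization is per subset.
#'
#' @param subset character vector of isoform ids in the batch.
#' @param sequences named character vector of protein sequences.
#' @param pairs data.frame with columns `a`, `b` (isoform ids), all
#'   within `subset`.
#' @param params list of alignment parameters (`substitution`,
#'   `gap_open`, `gap_extend`), defaulting to [sw_score()]'s defaults.
#' @param cache optional [alignment_cache()].
#' @return a `pair_score_table` data.frame (`a`, `b`, `raw`, `std`)
#'   with the normalization metadata attached as attribute
#'   `normalization`.
#' @export
score_subset <- function(subset, sequences, pairs, params = list(),
                         cache = NULL) {
  stopifnot(is.data.frame(pairs), all(c("a", "b") %in% names(pairs)))
  ids <- unique(c(pairs$a, pairs$b))
  if (!all(ids %in% subset)) {
    .stop_typed("isoformGO_alignment_error", "pair outside subset: %s",
                setdiff(ids, subset)[[1L]])
  }
  missing <- setdiff(ids, names(sequences))
  if (length(missing)) {
    .stop_typed("isoformGO_alignment_error",
                "missing sequence for isoform %s", missing[[1L]])
  }
  sub <- params$substitution %||% "BLOSUM62"
  go <- params$gap_open %||% 10
  ge <- params$gap_extend %||% 4
  raw <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    key <- paste(sort(c(pairs$a[[k]], pairs$b[[k]])), collapse = "\r")
    if (!is.null(cache) && !is.null(cache[[key]])) {
      raw[[k]] <- cache[[key]]
    } else {
      raw[[k]] <- sw_score(sequences[[pairs$a[[k]]]],
                           sequences[[pairs$b[[k]]]],
                           substitution = sub, gap_open = go,
                           gap_extend = ge)
      if (!is.null(cache)) cache[[key]] <- raw[[k]]
    }
  }
  nz <- normalize_scores(raw)
  out <- data.frame(a = pairs$a, b = pairs$b, raw = raw, std = nz$std,
                    stringsAsFactors = FALSE)
  attr(out, "normalization") <- nz$meta
  class(out) <- c("pair_score_table", "data.frame")
  out
}
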