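# Readers and writers for every on-disk format the pipeline touches:
# GAF 2.x gene annotations, OBO 1.2 term stanzas, protein FASTA,
# external2go (InterPro2GO) mappings, and the bespoke TSVs (isoform
# domains, gene-isoform map, curated labels, output annotations).
# No algorithmic logic lives here.

#' Read gene-level GO annotations from a GAF 2.x file
#'
#' Parses a Gene Association File and collapses it to a
#' [gene_annotation_map()]: one row per distinct (gene, GO term,
#' subontology) triple. Genes are keyed on GAF column 2 (DB Object ID),
#' which is stable across releases, not on the gene symbol. Rows whose
#' qualifier (column 4) contains `NOT` are negative statements and are
#' excluded; duplicate (gene, term) rows are collapsed.
#'
#' @param gaf_path path to a GAF 2.x file. Comment lines start with `!`;
#'   data lines are tab-separated with at least 15 columns.
#' @return a [gene_annotation_map()] with columns `gene_id`, `go_id`,
#'   `aspect` (`MF`/`BP`/`CC`, mapped from GAF aspect codes F/P/C).
#' @export
read_gene_annotations <- function(gaf_path) {
  if (!file.exists(gaf_path)) {
    .stop_typed("isoformGO_io_error", "file not found: %s", gaf_path)
  }
  lines <- readLines(gaf_path)
  keep <- !startsWith(lines, "!") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(gene_annotation_map(data.frame(gene_id = character(),
                                          go_id = character(),
                                          aspect = character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 15L)) {
    i <- which(nf < 15L)[[1L]]
    .stop_typed("isoformGO_parse_error",
                "GAF line %d has %d columns (>= 15 required)",
                lineno[[i]], nf[[i]])
  }
  gene <- vapply(fields, `[[`, "", 2L)
  qualifier <- vapply(fields, `[[`, "", 4L)
  go_id <- vapply(fields, `[[`, "", 5L)
  aspect_code <- vapply(fields, `[[`, "", 9L)
  aspect <- .as_aspect(aspect_code)
  if (anyNA(aspect)) {
    i <- which(is.na(aspect))[[1L]]
    .stop_typed("isoformGO_parse_error",
                "GAF line %d has unknown aspect code '%s'",
                lineno[[i]], aspect_code[[i]])
  }
  .check_go_id(go_id, "GO id in GAF column 5")
  not_row <- vapply(strsplit(qualifier, "|", fixed = TRUE),
                    function(q) "NOT" %in% q, logical(1L))
  df <- data.frame(gene_id = gene, go_id = go_id, aspect = aspect,
                   stringsAsFactors = FALSE)[!not_row, , drop = FALSE]
  gene_annotation_map(df)
}

#' Read GO term namespaces and is_a parents from an OBO 1.2 file
#'
#' A minimal reader for `[Term]` stanzas: it captures the term id, its
#' namespace and its `is_a` parents, and drops obsolete terms. The
#' pipeline only needs namespace lookups (and, optionally, the is_a
#' graph for information-content propagation), so the many other OBO
#' tags are ignored.
#'
#' @param obo_path path to an OBO 1.2 flat file.
#' @return an object of class `go_ontology`: a list with `namespace`
#'   (named character vector, values `molecular_function` /
#'   `biological_process` / `cellular_component`) and `parents`
#'   (named list of character vectors of is_a parent ids).
#' @export
read_ontology <- function(obo_path) {
  if (!file.exists(obo_path)) {
    .stop_typed("isoformGO_io_error", "file not found: %s", obo_path)
  }
  lines <- readLines(obo_path)
  starts <- which(lines == "[Term]")
  ns <- character()
  parents <- list()
  bounds <- c(starts, length(lines) + 1L)
  for (k in seq_along(starts)) {
    stanza <- lines[(bounds[[k]] + 1L):(bounds[[k + 1L]] - 1L)]
    stanza <- stanza[!startsWith(stanza, "[")]  # stop at next stanza header
    get <- function(tag) {
      hit <- stanza[startsWith(stanza, paste0(tag, ":"))]
      trimws(sub(paste0("^", tag, ":"), "", hit))
    }
    id <- get("id")
    if (!length(id)) {
      .stop_typed("isoformGO_parse_error",
                  "OBO [Term] stanza starting at line %d has no id",
                  starts[[k]])
    }
    id <- id[[1L]]
    if (any(get("is_obsolete") == "true")) next
    namespace <- get("namespace")
    if (!length(namespace) || is.na(.as_aspect(namespace[[1L]]))) {
      .stop_typed("isoformGO_parse_error",
                  "OBO term %s has missing or unknown namespace", id)
    }
    isa <- trimws(sub("!.*$", "", get("is_a")))
    ns[[id]] <- namespace[[1L]]
    parents[[id]] <- isa
  }
  structure(list(namespace = ns, parents = parents), class = "go_ontology")
}

#' Read protein sequences of isoforms from a FASTA file
#'
#' Sequence records are keyed by the first whitespace-delimited token of
#' the header with any transcript version suffix (`.N`) stripped.
#' Sequences are uppercased, a single trailing stop (`*`) is removed,
#' and only the 20 standard residues plus `X`, `U` and internal `*` are
#' permitted.
#'
#' @param path path to a protein FASTA file.
#' @return named character vector, isoform accession to amino-acid
#'   sequence.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) {
    .stop_typed("isoformGO_io_error", "file not found: %s", path)
  }
  set <- Biostrings::readAAStringSet(path)
  ids <- .strip_version(vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L))
  if (anyDuplicated(ids)) {
    .stop_typed("isoformGO_io_error", "duplicate isoform accession: %s",
                ids[duplicated(ids)][[1L]])
  }
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYXU*]", seqs)
  if (any(bad)) {
    .stop_typed("isoformGO_io_error",
                "record %s contains an illegal residue character",
                ids[bad][[1L]])
  }
  names(seqs) <- ids
  seqs
}

#' Read an InterPro-to-GO mapping in external2go format
#'
#' Lines look like
#' `InterPro:IPR001095 Acetyl-CoA carboxylase alpha > GO:... ; GO:0003989`;
#' `!` comment lines are skipped. One InterPro entry may map to several
#' GO terms.
#'
#' @param path path to an external2go text file.
#' @return named list, InterPro accession to character vector of GO ids.
#' @export
read_interpro2go <- function(path) {
  if (!file.exists(path)) {
    .stop_typed("isoformGO_io_error", "file not found: %s", path)
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) return(structure(list(), names = character()))
  pat <- "^InterPro:(IPR\\d{6})\\s.*>\\s*GO:.*;\\s*(GO:\\d{7})\\s*$"
  ok <- grepl(pat, lines)
  if (any(!ok)) {
    .stop_typed("isoformGO_parse_error",
                "line not in external2go format: '%s'", lines[!ok][[1L]])
  }
  ipr <- sub(pat, "\\1", lines)
  go <- sub(pat, "\\2", lines)
  out <- lapply(split(go, ipr), unique)
  out[order(names(out))]
}

#' Read an isoform-to-InterPro-domain table
#'
#' A two-column TSV (`isoform_id`, InterPro accession); a header row is
#' detected and skipped when the second field is not an `IPRxxxxxx`
#' accession. Isoforms absent from the file simply have no domains.
#'
#' @param path path to the TSV.
#' @return named list, isoform accession to character vector of unique
#'   InterPro accessions.
#' @export
read_isoform_domains <- function(path) {
  if (!file.exists(path)) {
    .stop_typed("isoformGO_io_error", "file not found: %s", path)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(structure(list(), names = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    .stop_typed("isoformGO_parse_error",
                "domain table line %d has fewer than 2 columns",
                which(lengths(fields) < 2L)[[1L]])
  }
  iso <- .strip_version(vapply(fields, `[[`, "", 1L))
  ipr <- vapply(fields, `[[`, "", 2L)
  if (identical(iso[[1L]], "isoform_id")) {  # header row
    iso <- iso[-1L]
    ipr <- ipr[-1L]
  }
  if (!length(iso)) return(structure(list(), names = character()))
  .check_ipr_id(ipr)
  lapply(split(ipr, iso), unique)
}

#' Read a gene-to-isoform membership table
#'
#' Two-column TSV (`gene_id`, `isoform_id`), header optional (detected
#' when the first line equals the documented column names). Version
#' suffixes are stripped from both columns.
#'
#' @param path path to the TSV.
#' @return a [gene_records()] collection.
#' @export
read_gene_isoforms <- function(path) {
  if (!file.exists(path)) {
    .stop_typed("isoformGO_io_error", "file not found: %s", path)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[[1L]], "gene_id")) lines <- lines[-1L]
  if (!length(lines)) {
    .stop_typed("isoformGO_io_error", "empty gene-isoform table: %s", path)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    .stop_typed("isoformGO_parse_error",
                "gene-isoform line %d has fewer than 2 columns",
                which(lengths(fields) < 2L)[[1L]])
  }
  gene <- .strip_version(vapply(fields, `[[`, "", 1L))
  iso <- .strip_version(vapply(fields, `[[`, "", 2L))
  gene_records(split(iso, factor(gene, levels = unique(gene))))
}

#' Read curated isoform-function labels
#'
#' TSV with header columns `isoform_id`, `go_id`, `label` and optional
#' `source`. Labels accept `1`/`0`, `true`/`false` or `TRUE`/`FALSE`
#' and are normalized to logical.
#'
#' @param path path to the curation TSV.
#' @return data.frame with columns `isoform_id`, `go_id`, `label`
#'   (logical) and `source`, preserving file order.
#' @export
read_curation <- function(path) {
  if (!file.exists(path)) {
    .stop_typed("isoformGO_io_error", "file not found: %s", path)
  }
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (!nrow(df)) {
    return(data.frame(isoform_id = character(), go_id = character(),
                      label = logical(), source = character()))
  }
  need <- c("isoform_id", "go_id", "label")
  if (!all(need %in% names(df))) {
    .stop_typed("isoformGO_parse_error",
                "curation file must have columns %s",
                paste(need, collapse = ", "))
  }
  .check_go_id(df$go_id, "GO id in curation file")
  tok <- tolower(df$label)
  ok_true <- tok %in% c("1", "true")
  ok_false <- tok %in% c("0", "false")
  if (any(!(ok_true | ok_false))) {
    .stop_typed("isoformGO_parse_error",
                "curation label '%s' not recognized; accepted tokens: 1, 0, true, false",
                df$label[!(ok_true | ok_false)][[1L]])
  }
  data.frame(isoform_id = .strip_version(df$isoform_id),
             go_id = df$go_id,
             label = ok_true,
             source = df$source %||% rep(NA_character_, nrow(df)),
             stringsAsFactors = FALSE)
}

#' Write isoform-level GO annotations to a TSV
#'
#' One row per set bit of the assignment matrix (frozen surrogate bits
#' from another subontology are excluded), in deterministic order
#' (isoform accession, then GO id). The `origin` column records whether
#' the bit was part of the InterPro-derived seed or added by the EM
#' search.
#'
#' @param assignment an [assignment_matrix()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_isoform_annotations <- function(assignment, path) {
  stopifnot(inherits(assignment, "assignment_matrix"))
  keep <- assignment$bits & !assignment$frozen
  idx <- which(keep, arr.ind = TRUE)
  if (!nrow(idx)) {
    utils::write.table(
      data.frame(isoform_id = character(), gene_id = character(),
                 go_id = character(), subontology = character(),
                 origin = character()),
      path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
    return(invisible(path))
  }
  df <- data.frame(
    isoform_id = assignment$isoforms[idx[, 1L]],
    gene_id = unname(assignment$gene_of[assignment$isoforms[idx[, 1L]]]),
    go_id = assignment$terms[idx[, 2L]],
    subontology = assignment$subontology,
    origin = ifelse(assignment$seed[idx], "interpro_seed", "em_assigned"),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$isoform_id, df$go_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back an annotation TSV written by [write_isoform_annotations()]
#'
#' @param path path to the TSV.
#' @return data.frame with the written columns.
#' @export
read_isoform_annotations <- function(path) {
  utils::read.delim(path, header = TRUE, colClasses = "character")
}

#' Rebuild the bit matrix of an assignment from an annotation TSV
#'
#' Applies the rows of a read-back annotation table to a skeleton
#' assignment (typically the candidate structure the run started from),
#' so that a write/read round trip reproduces the exact bit matrix.
#'
#' @param df data.frame from [read_isoform_annotations()].
#' @param skeleton an [assignment_matrix()] providing the index maps.
#' @return the skeleton with `bits` set from `df`.
#' @export
annotations_to_matrix <- function(df, skeleton) {
  stopifnot(inherits(skeleton, "assignment_matrix"))
  bits <- skeleton$bits & FALSE
  i <- match(df$isoform_id, skeleton$isoforms)
  j <- match(df$go_id, skeleton$terms)
  if (anyNA(i) || anyNA(j)) {
    .stop_typed("isoformGO_io_error",
                "annotation row references an isoform or term absent from the skeleton")
  }
  bits[cbind(i, j)] <- TRUE
  skeleton$bits <- bits
  skeleton$seed <- skeleton$seed & bits
  skeleton
}
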