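# Core containers: genes with their isoform sets, the gene-level GO
# annotation map (psi / TG), the binary isoform-by-term assignment
# matrix (phi / TI) with its candidate and frozen masks, and the
# shared-term matrix T = TI %*% t(TI).

#' Construct a collection of gene records
#'
#' @param x either a named list (gene id to character vector of isoform
#'   accessions) or a data.frame with columns `gene_id`, `isoform_id`.
#' @return object of class `gene_records`: a named list of isoform-id
#'   vectors. Every gene has at least one isoform; isoform ids are
#'   globally unique.
#' @export
gene_records <- function(x) {
  if (is.data.frame(x)) {
    x <- split(x$isoform_id, factor(x$gene_id, levels = unique(x$gene_id)))
  }
  x <- lapply(x, as.character)
  if (!length(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    .stop_typed("isoformGO_model_error", "gene records need gene ids")
  }
  if (any(lengths(x) < 1L)) {
    .stop_typed("isoformGO_model_error", "every gene needs >= 1 isoform")
  }
  iso <- unlist(x, use.names = FALSE)
  if (anyDuplicated(iso)) {
    .stop_typed("isoformGO_model_error", "duplicate isoform id: %s",
                iso[duplicated(iso)][[1L]])
  }
  structure(x, class = "gene_records")
}

#' Map each isoform to its gene
#'
#' @param genes a [gene_records()] collection.
#' @return named character vector, isoform id to gene id.
#' @export
isoform_genes <- function(genes) {
  iso <- unlist(unclass(genes), use.names = FALSE)
  g <- rep(names(genes), lengths(genes))
  stats::setNames(g, iso)
}

#' Construct a gene-level GO annotation map (psi)
#'
#' @param df data.frame with columns `gene_id`, `go_id`, `aspect`
#'   (`MF`/`BP`/`CC`). Duplicate rows are collapsed.
#' @return object of class `gene_annotation_map` (a data.frame).
#' @export
gene_annotation_map <- function(df) {
  stopifnot(all(c("gene_id", "go_id", "aspect") %in% names(df)))
  df <- unique(df[, c("gene_id", "go_id", "aspect")])
  rownames(df) <- NULL
  class(df) <- c("gene_annotation_map", "data.frame")
  df
}

#' Gene term sets of an annotation map
#'
#' @param tg a [gene_annotation_map()].
#' @param aspect optional subontology label (`MF`/`BP`/`CC`) to restrict
#'   to.
#' @return named list, gene id to character vector of GO term ids.
#' @export
gene_term_sets <- function(tg, aspect = NULL) {
  stopifnot(inherits(tg, "gene_annotation_map"))
  df <- as.data.frame(tg)
  if (!is.null(aspect)) df <- df[df$aspect == aspect, , drop = FALSE]
  lapply(split(df$go_id, df$gene_id), unique)
}

#' Keep GO terms that annotate fewer than a fraction of genes
#'
#' A term is "specific" when the number of genes annotated to it,
#' divided by the total number of genes in the map, is strictly below
#' `threshold` (default 10%). Only specific terms are ever assigned to
#' isoforms; a term at exactly the threshold is excluded.
#'
#' @param tg a [gene_annotation_map()].
#' @param threshold fraction in (0, 1].
#' @return character vector of specific GO term ids.
#' @export
filter_specific_terms <- function(tg, threshold = 0.10) {
  stopifnot(inherits(tg, "gene_annotation_map"))
  if (!nrow(tg)) {
    .stop_typed("isoformGO_model_error",
                "cannot filter specific terms of an empty annotation map")
  }
  stopifnot(threshold > 0, threshold <= 1)
  n_genes <- length(unique(tg$gene_id))
  counts <- vapply(split(tg$gene_id, tg$go_id),
                   function(g) length(unique(g)), integer(1L))
  sort(names(counts)[counts / n_genes < threshold])
}

#' Construct an isoform-by-term assignment matrix
#'
#' @param isoforms character vector of isoform accessions (rows).
#' @param terms character vector of GO term ids (columns).
#' @param gene_of named character vector mapping each isoform to its
#'   gene.
#' @param subontology subontology label of the matrix columns.
#' @param bits,candidate,frozen,seed logical p-by-m matrices; `bits`
#'   must lie within `candidate`, and `frozen` cells are excluded from
#'   E-step mutation while still contributing to shared-term counts.
#' @return object of class `assignment_matrix`.
#' @export
assignment_matrix <- function(isoforms, terms, gene_of, subontology,
                              bits = NULL, candidate = NULL,
                              frozen = NULL, seed = NULL) {
  p <- length(isoforms)
  m <- length(terms)
  blank <- matrix(FALSE, p, m, dimnames = list(isoforms, terms))
  obj <- structure(list(
    isoforms = isoforms,
    terms = terms,
    gene_of = gene_of[isoforms],
    subontology = subontology,
    bits = bits %||% blank,
    candidate = candidate %||% blank,
    frozen = frozen %||% blank,
    seed = seed %||% blank
  ), class = "assignment_matrix")
  validate_assignment_matrix(obj)
}

#' @rdname assignment_matrix
#' @param x an object to validate.
#' @export
validate_assignment_matrix <- function(x) {
  stopifnot(inherits(x, "assignment_matrix"))
  p <- length(x$isoforms)
  m <- length(x$terms)
  for (f in c("bits", "candidate", "frozen", "seed")) {
    if (!is.logical(x[[f]]) || !all(dim(x[[f]]) == c(p, m))) {
      .stop_typed("isoformGO_model_error", "field '%s' must be a %dx%d logical matrix",
                  f, p, m)
    }
  }
  if (any(x$bits & !(x$candidate | x$frozen))) {
    .stop_typed("isoformGO_model_error",
                "assignment bits outside the candidate mask")
  }
  if (anyNA(x$gene_of)) {
    .stop_typed("isoformGO_model_error", "isoform with unknown gene")
  }
  x
}

#' @export
print.assignment_matrix <- function(x, ...) {
  cat(sprintf("assignment_matrix [%s]: %d isoforms x %d terms, %d bits set (%d candidate, %d frozen)\n",
              x$subontology, length(x$isoforms), length(x$terms),
              sum(x$bits), sum(x$candidate), sum(x$frozen)))
  invisible(x)
}

#' Combine gene-level annotations with InterPro-domain-derived terms
#'
#' Any GO term reachable from an isoform's InterPro domains through the
#' InterPro2GO mapping, but absent from the isoform's gene annotation
#' set, is added to the gene's term set (the gene map and the domain
#' mapping are combined at gene level before candidate construction).
#' Terms whose subontology cannot be resolved from the map or the
#' ontology are dropped with a warning.
#'
#' @param tg a [gene_annotation_map()].
#' @param genes a [gene_records()] collection.
#' @param domains named list, isoform id to InterPro accessions.
#' @param ipr2go named list, InterPro accession to GO term ids.
#' @param ontology optional `go_ontology` used to resolve the namespace
#'   of terms not yet present in `tg`.
#' @return the augmented [gene_annotation_map()].
#' @export
augment_gene_annotations <- function(tg, genes, domains, ipr2go,
                                     ontology = NULL) {
  aspect_of <- local({
    known <- tapply(tg$aspect, tg$go_id, `[[`, 1L)
    function(term) {
      if (term %in% names(known)) return(known[[term]])
      ns <- ontology$namespace[[term]] %||% NULL
      if (is.null(ns)) NA_character_ else .as_aspect(ns)
    }
  })
  extra <- list()
  for (g in names(genes)) {
    dts <- unique(unlist(ipr2go[unlist(domains[genes[[g]]], use.names = FALSE)],
                         use.names = FALSE))
    if (!length(dts)) next
    asp <- vapply(dts, aspect_of, character(1L))
    if (anyNA(asp)) {
      warning(sprintf("dropping %d domain-derived term(s) of gene %s with unresolvable namespace",
                      sum(is.na(asp)), g))
    }
    keep <- !is.na(asp)
    if (any(keep)) {
      extra[[g]] <- data.frame(gene_id = g, go_id = dts[keep],
                               aspect = unname(asp[keep]),
                               stringsAsFactors = FALSE)
    }
  }
  gene_annotation_map(rbind(as.data.frame(tg), do.call(rbind, extra)))
}

#' Build the candidate structure and InterPro seed for one subontology
#'
#' The candidate mask marks cell (i, t) assignable when term t belongs
#' to the (domain-augmented) annotation set of isoform i's gene, is
#' specific, and lies in the active subontology; isoform functions are
#' thus always a subset of gene functions. The seed sets a bit where
#' the term is additionally derivable from the isoform's own InterPro
#' domains; all other candidate cells start unassigned and are left for
#' the EM search.
#'
#' @param genes a [gene_records()] collection.
#' @param tg a [gene_annotation_map()] (pre-augmentation; domain-derived
#'   terms are merged in here).
#' @param domains named list, isoform id to InterPro accessions;
#'   isoforms absent from the list have no domains.
#' @param ipr2go named list, InterPro accession to GO term ids.
#' @param specific character vector of specific term ids (see
#'   [filter_specific_terms()]); only these are assignable.
#' @param subontology `MF`, `BP` or `CC`.
#' @param ontology optional `go_ontology` for namespace resolution of
#'   domain-derived terms.
#' @return an [assignment_matrix()] with `bits` = seed and the
#'   augmented gene map attached as field `tg`.
#' @export
build_candidates <- function(genes, tg, domains, ipr2go, specific,
                             subontology, ontology = NULL) {
  stopifnot(inherits(genes, "gene_records"), subontology %in% c("MF", "BP", "CC"))
  tg2 <- augment_gene_annotations(tg, genes, domains, ipr2go, ontology)
  gene_of <- isoform_genes(genes)
  isoforms <- names(gene_of)
  psets <- gene_term_sets(tg2, aspect = subontology)
  cand_terms <- lapply(psets, function(ts) sort(intersect(ts, specific)))
  terms <- sort(unique(unlist(cand_terms, use.names = FALSE)))
  p <- length(isoforms)
  m <- length(terms)
  cand <- matrix(FALSE, p, m, dimnames = list(isoforms, terms))
  seedm <- cand
  for (i in seq_len(p)) {
    g <- gene_of[[i]]
    ct <- cand_terms[[g]]
    if (is.null(ct) || !length(ct)) next
    cand[i, ct] <- TRUE
    dts <- unique(unlist(ipr2go[unlist(domains[[isoforms[[i]]]], use.names = FALSE)],
                         use.names = FALSE))
    st <- intersect(ct, dts)
    if (length(st)) seedm[i, st] <- TRUE
  }
  am <- assignment_matrix(isoforms, terms, gene_of, subontology,
                          bits = seedm, candidate = cand, seed = seedm)
  am$tg <- tg2
  am
}

#' Shared-term counts between isoform pairs
#'
#' Multiplies the binary assignment matrix by its transpose: cell (i, j)
#' is the number of GO terms isoforms i and j are both assigned to, and
#' the diagonal is each isoform's annotation count.
#'
#' @param ti an [assignment_matrix()].
#' @return symmetric integer matrix of class `shared_term_matrix`.
#' @export
shared_term_counts <- function(ti) {
  stopifnot(inherits(ti, "assignment_matrix"))
  b <- ti$bits
  storage.mode(b) <- "integer"
  out <- tcrossprod(b)
  storage.mode(out) <- "integer"
  structure(out, class = c("shared_term_matrix", "matrix"))
}

#' Hamming accuracy of an assignment against a reference
#'
#' Fraction of candidate-mask cells on which two assignments agree;
#' used to compare recovered assignments with a planted truth.
#'
#' @param am,ref [assignment_matrix()] objects over the same index maps.
#' @return fraction in `[0, 1]`.
#' @export
assignment_accuracy <- function(am, ref) {
  stopifnot(identical(am$isoforms, ref$isoforms))
  mask <- am$candidate & !am$frozen
  common <- intersect(am$terms, ref$terms)
  a <- am$bits[, common, drop = FALSE]
  r <- ref$bits[, common, drop = FALSE]
  k <- mask[, common, drop = FALSE]
  if (!sum(k)) return(NA_real_)
  sum((a == r)[k]) / sum(k)
}
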