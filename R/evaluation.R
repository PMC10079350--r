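# Evaluation utilities: confusion metrics against a curated
# gold-standard, GO-term information content, and the two trend
# analyses relating shared GO terms to expression correlation and to
# InterPro domain sharing.

#' Confusion summary of an assignment against curated labels
#'
#' A curated record is predicted positive when the corresponding bit of
#' the assignment matrix is set. Records whose isoform is absent from
#' the matrix row index are skipped (listed in `skipped`); a record
#' whose GO term is absent from the column index counts as predicted
#' negative.
#'
#' @param assignment an [assignment_matrix()].
#' @param records data.frame from [read_curation()].
#' @return object of class `confusion_summary`: list with `tp`, `fp`,
#'   `tn`, `fn`, `tp_rate` (= TP/(TP+FN)), `fp_rate` (= FP/(FP+TN)) and
#'   `skipped` (row indices of skipped records).
#' @export
confusion_vs_curation <- function(assignment, records) {
  stopifnot(inherits(assignment, "assignment_matrix"),
            all(c("isoform_id", "go_id", "label") %in% names(records)))
  i <- match(records$isoform_id, assignment$isoforms)
  skipped <- which(is.na(i))
  keep <- !is.na(i)
  j <- match(records$go_id, assignment$terms)
  pred <- logical(nrow(records))
  ok <- keep & !is.na(j)
  pred[ok] <- assignment$bits[cbind(i[ok], j[ok])]
  pred <- pred[keep]
  lab <- records$label[keep]
  tp <- sum(pred & lab)
  fp <- sum(pred & !lab)
  tn <- sum(!pred & !lab)
  fn <- sum(!pred & lab)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 tp_rate = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 fp_rate = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
                 skipped = skipped),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("confusion_summary: TP=%d FP=%d TN=%d FN=%d  TP rate=%.3f FP rate=%.3f (%d skipped)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp_rate, x$fp_rate,
              length(x$skipped)))
  invisible(x)
}

.term_gene_counts <- function(tg, ontology = NULL, propagate = FALSE) {
  df <- unique(as.data.frame(tg)[, c("gene_id", "go_id")])
  if (propagate) {
    if (is.null(ontology)) {
      .stop_typed("isoformGO_model_error",
                  "ancestor propagation requires an ontology")
    }
    anc <- function(t) {
      out <- character()
      frontier <- t
      while (length(frontier)) {
        out <- union(out, frontier)
        frontier <- setdiff(unique(unlist(ontology$parents[frontier],
                                          use.names = FALSE)), out)
      }
      out
    }
    ext <- lapply(seq_len(nrow(df)), function(r) {
      data.frame(gene_id = df$gene_id[[r]], go_id = anc(df$go_id[[r]]),
                 stringsAsFactors = FALSE)
    })
    df <- unique(do.call(rbind, ext))
  }
  vapply(split(df$gene_id, df$go_id), function(g) length(unique(g)),
         integer(1L))
}

#' Information content of a GO term
#'
#' `IC = -ln(n_t / N)` in nats, where `n_t` is the number of genes
#' annotated to the term (optionally propagated through is_a ancestors)
#' and `N` the total number of genes in the map. Higher IC means a
#' more specific term.
#'
#' @param term GO term id (must annotate at least one gene).
#' @param tg a [gene_annotation_map()].
#' @param ontology optional `go_ontology`, required when
#'   `propagate = TRUE`.
#' @param propagate count a gene as annotated to `term` when it is
#'   annotated to any is_a descendant of it.
#' @return IC in nats.
#' @export
information_content <- function(term, tg, ontology = NULL,
                                propagate = FALSE) {
  counts <- .term_gene_counts(tg, ontology, propagate)
  if (!term %in% names(counts)) {
    .stop_typed("isoformGO_model_error",
                "term %s annotates no gene in the map", term)
  }
  n <- length(unique(tg$gene_id))
  -log(counts[[term]] / n)
}

#' Mean information content of a set of annotations
#'
#' @param assignment an [assignment_matrix()]; each distinct assigned
#'   term contributes once to the unweighted mean, and once per set bit
#'   to the annotation-weighted mean.
#' @inheritParams information_content
#' @return list with `mean_ic` (over distinct assigned terms) and
#'   `weighted_mean_ic` (weighted by annotation count).
#' @export
mean_information_content <- function(assignment, tg, ontology = NULL,
                                     propagate = FALSE) {
  counts <- .term_gene_counts(tg, ontology, propagate)
  n <- length(unique(tg$gene_id))
  used <- colSums(assignment$bits & !assignment$frozen)
  terms <- assignment$terms[used > 0L]
  terms <- terms[terms %in% names(counts)]
  if (!length(terms)) return(list(mean_ic = NA_real_,
                                  weighted_mean_ic = NA_real_))
  ic <- -log(counts[terms] / n)
  w <- used[terms]
  list(mean_ic = mean(ic), weighted_mean_ic = sum(ic * w) / sum(w))
}

.shared_counts_for_pairs <- function(pairs_i, pairs_j, sets) {
  vapply(seq_along(pairs_i), function(k) {
    length(intersect(sets[[pairs_i[[k]]]], sets[[pairs_j[[k]]]]))
  }, integer(1L))
}

#' Expression correlation as a function of shared GO terms
#'
#' Filters isoforms to those with nonzero expression in more than half
#' of the samples and a standard deviation at or above the 90th
#' percentile of the filtered sd distribution, samples isoform pairs so
#' that for every shared-term count `i` in `bins` at least
#' `min_bin_frac` of the pairs share at least `i` terms
#' (cumulative-quantile rejection sampling), computes the Pearson
#' correlation of each pair, and bins the correlations by the
#' isoform-level shared-term count (from the assignment) and by the
#' gene-level count (every isoform inheriting all of its gene's
#' terms). A two-sided Mann-Whitney U test compares the two binnings
#' at each count.
#'
#' @param expr numeric matrix, isoform rows by sample columns (>= 4
#'   samples).
#' @param assignment an [assignment_matrix()].
#' @param tg a [gene_annotation_map()].
#' @param n_pairs number of pairs to sample.
#' @param seed integer seed.
#' @param bins shared-term counts whose cumulative quota is enforced
#'   (default `1:10`).
#' @param min_bin_frac cumulative quota per bin (default 0.1).
#' @param sd_quantile sd percentile filter (default 0.9).
#' @param log_transform apply `log1p` to the expression values before
#'   correlating.
#' @return list with `pairs` (data.frame: `a`, `b`, `cor`,
#'   `shared_isoform`, `shared_gene`) and `tests` (data.frame per bin:
#'   shared count, n in each binning, median correlations, Mann-Whitney
#'   p-value).
#' @export
correlation_by_shared_terms <- function(expr, assignment, tg,
                                        n_pairs = 1000L, seed = 1L,
                                        bins = 1:10, min_bin_frac = 0.1,
                                        sd_quantile = 0.9,
                                        log_transform = FALSE) {
  stopifnot(is.matrix(expr), ncol(expr) >= 4L)
  if (log_transform) expr <- log1p(expr)
  nonzero <- rowSums(expr != 0) > ncol(expr) / 2
  expr <- expr[nonzero, , drop = FALSE]
  sds <- apply(expr, 1L, stats::sd)
  expr <- expr[sds >= stats::quantile(sds, sd_quantile), , drop = FALSE]
  ids <- intersect(rownames(expr), assignment$isoforms)
  if (length(ids) < 4L) {
    .stop_typed("isoformGO_evaluation_error",
                "only %d isoforms pass the expression filters", length(ids))
  }
  iso_sets <- apply(assignment$bits[ids, , drop = FALSE], 1L, function(b) {
    assignment$terms[b]
  }, simplify = FALSE)
  gsets <- gene_term_sets(tg)
  gene_sets <- lapply(assignment$gene_of[ids], function(g) {
    gsets[[g]] %||% character()
  })
  names(gene_sets) <- ids
  all_pairs <- utils::combn(ids, 2L)
  shared_iso_all <- .shared_counts_for_pairs(all_pairs[1L, ], all_pairs[2L, ],
                                             iso_sets)
  # cumulative quota: for each i in bins, >= min_bin_frac of the sample
  # must share at least i terms
  set.seed(seed)
  quota <- ceiling(min_bin_frac * n_pairs)
  chosen <- integer()
  avail <- seq_len(ncol(all_pairs))
  for (i in sort(bins, decreasing = TRUE)) {
    need <- quota - sum(shared_iso_all[chosen] >= i)
    if (need <= 0) next
    cand <- setdiff(avail[shared_iso_all[avail] >= i], chosen)
    if (length(cand) < need) {
      census <- table(factor(pmin(shared_iso_all, max(bins)),
                             levels = 0:max(bins)))
      .stop_typed("isoformGO_evaluation_error",
                  "cannot fill the shared>=%d quota (need %d more); pair census by shared count: %s",
                  i, need, paste(sprintf("%s:%d", names(census), census),
                                 collapse = " "))
    }
    chosen <- c(chosen, sample(cand, need))
  }
  rest <- setdiff(avail, chosen)
  extra <- min(length(rest), n_pairs - length(chosen))
  if (extra > 0) chosen <- c(chosen, sample(rest, extra))
  pa <- all_pairs[1L, chosen]
  pb <- all_pairs[2L, chosen]
  cors <- vapply(seq_along(pa), function(k) {
    stats::cor(expr[pa[[k]], ], expr[pb[[k]], ])
  }, numeric(1L))
  out <- data.frame(a = pa, b = pb, cor = cors,
                    shared_isoform = shared_iso_all[chosen],
                    shared_gene = .shared_counts_for_pairs(pa, pb, gene_sets),
                    stringsAsFactors = FALSE)
  tests <- do.call(rbind, lapply(sort(unique(bins)), function(i) {
    x <- out$cor[out$shared_isoform == i]
    y <- out$cor[out$shared_gene == i]
    p <- if (length(x) && length(y)) {
      suppressWarnings(stats::wilcox.test(x, y)$p.value)
    } else {
      NA_real_
    }
    data.frame(shared = i, n_isoform = length(x), n_gene = length(y),
               median_isoform = stats::median(x),
               median_gene = stats::median(y), p_value = p)
  }))
  list(pairs = out, tests = tests)
}

#' Domain sharing as a function of shared GO terms
#'
#' Restricts to isoform pairs sharing at least one InterPro domain and
#' relates their shared-domain count to the number of GO terms they
#' share — once with isoform-level assignments, once with gene-level
#' annotation (every isoform carrying all of its gene's terms) —
#' reporting Kendall's tau for each. A degenerate input (constant
#' shared-domain or shared-term counts) returns tau 0 with
#' `degenerate = TRUE`.
#'
#' @param domains named list, isoform id to InterPro accessions.
#' @param assignment an [assignment_matrix()].
#' @param tg a [gene_annotation_map()].
#' @param max_shared cap on the shared-term counts reported per bin
#'   (default 10).
#' @return list with `pairs` (data.frame: `a`, `b`, `shared_domains`,
#'   `shared_isoform`, `shared_gene`), `tau_isoform`, `tau_gene`, and
#'   `degenerate` flags.
#' @export
domain_sharing_by_shared_terms <- function(domains, assignment, tg,
                                           max_shared = 10L) {
  ids <- intersect(names(domains)[lengths(domains) > 0L],
                   assignment$isoforms)
  if (length(ids) < 2L) {
    .stop_typed("isoformGO_evaluation_error",
                "need >= 2 isoforms with domains (got %d)", length(ids))
  }
  pr <- utils::combn(ids, 2L)
  sd_count <- .shared_counts_for_pairs(pr[1L, ], pr[2L, ], domains)
  keep <- sd_count >= 1L
  pa <- pr[1L, keep]
  pb <- pr[2L, keep]
  sd_count <- sd_count[keep]
  iso_sets <- apply(assignment$bits[, , drop = FALSE], 1L, function(b) {
    assignment$terms[b]
  }, simplify = FALSE)
  names(iso_sets) <- assignment$isoforms
  gsets <- gene_term_sets(tg)
  gene_sets <- lapply(assignment$gene_of, function(g) gsets[[g]] %||% character())
  names(gene_sets) <- assignment$isoforms
  si <- pmin(.shared_counts_for_pairs(pa, pb, iso_sets), max_shared)
  sg <- pmin(.shared_counts_for_pairs(pa, pb, gene_sets), max_shared)
  tau_of <- function(x) {
    if (length(unique(x)) < 2L || length(unique(sd_count)) < 2L) {
      list(tau = 0, degenerate = TRUE)
    } else {
      list(tau = stats::cor(x, sd_count, method = "kendall"),
           degenerate = FALSE)
    }
  }
  ti <- tau_of(si)
  tg_ <- tau_of(sg)
  list(pairs = data.frame(a = pa, b = pb, shared_domains = sd_count,
                          shared_isoform = si, shared_gene = sg,
                          stringsAsFactors = FALSE),
       tau_isoform = ti$tau, tau_gene = tg_$tau,
       degenerate = ti$degenerate || tg_$degenerate)
}
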