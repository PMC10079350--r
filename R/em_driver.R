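# Mini-batch EM orchestration: random partition of the isoforms into
# subsets, eligible-pair construction, the per-iteration accumulator
# sigma_i = sum over subsets of (subset log-likelihood / subset pair
# count), the windowed convergence rule, the outer E/M cycle, and the
# MF -> BP -> CC subontology schedule with frozen BP surrogate bits in
# the CC run.

#' EM configuration
#'
#' @param subsets number of mini-batch subsets K (default 200).
#' @param window convergence window: number of E-iterations over which
#'   the cumulative change of the sigma trace is measured (default 25).
#' @param threshold convergence threshold on that cumulative change
#'   (default 1/3).
#' @param convergence_mode `"signed"` (default; the cumulative change
#'   is the telescoped difference `sigma_last - sigma_(last-window)`)
#'   or `"absolute"` (its absolute value).
#' @param max_e_iterations cap on E-iterations per cycle.
#' @param max_cycles cap on outer E/M cycles (default 10); 0 returns
#'   the seed assignment unchanged.
#' @param outer_tol outer-loop stop: relative coefficient change
#'   `max |delta beta| / (1 + |beta|)` below this ends the run.
#' @param ga a [ga_params()] object for the E-step searches.
#' @param init_subset_size subset size for [initialize_beta()]
#'   (`NULL` = its default).
#' @param seed master integer seed; every random draw of the run
#'   derives from it.
#' @param freeze_bp_surrogates logical; when `TRUE` (default) the CC
#'   run carries the finished BP assignment as frozen bits that raise
#'   shared-term counts but are excluded from the GA search.
#' @return object of class `em_config`.
#' @export
em_config <- function(subsets = 200L, window = 25L, threshold = 1 / 3,
                      convergence_mode = c("signed", "absolute"),
                      max_e_iterations = 200L, max_cycles = 10L,
                      outer_tol = 1e-4, ga = ga_params(),
                      init_subset_size = NULL, seed = 1L,
                      freeze_bp_surrogates = TRUE) {
  convergence_mode <- match.arg(convergence_mode)
  stopifnot(subsets >= 1L, window >= 1L, threshold > 0, max_cycles >= 0L)
  structure(list(subsets = as.integer(subsets), window = as.integer(window),
                 threshold = threshold, convergence_mode = convergence_mode,
                 max_e_iterations = as.integer(max_e_iterations),
                 max_cycles = as.integer(max_cycles), outer_tol = outer_tol,
                 ga = ga, init_subset_size = init_subset_size,
                 seed = as.integer(seed),
                 freeze_bp_surrogates = freeze_bp_surrogates),
            class = "em_config")
}

#' Randomly partition isoforms into mini-batch subsets
#'
#' Each isoform independently receives a label drawn uniformly from
#' `1..K`; subset sizes are deliberately not equalized.
#'
#' @param isoforms character vector of isoform ids.
#' @param K number of subsets.
#' @param seed integer seed.
#' @return named integer vector of labels in `1..K`.
#' @export
partition <- function(isoforms, K = 200L, seed = 1L) {
  stopifnot(K >= 1L)
  set.seed(seed)
  stats::setNames(sample.int(K, length(isoforms), replace = TRUE), isoforms)
}

#' Eligible isoform pairs within a subset
#'
#' All unordered pairs of distinct subset isoforms whose genes share at
#' least one GO term (same-gene pairs qualify whenever the gene has any
#' term); no self-pairs.
#'
#' @param subset character vector of isoform ids.
#' @param gene_of named character vector mapping isoform to gene.
#' @param tg a [gene_annotation_map()] used for the sharing test.
#' @return data.frame with columns `a`, `b` (subset order, `a` before
#'   `b`).
#' @export
eligible_pairs <- function(subset, gene_of, tg) {
  n <- length(subset)
  empty <- data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  genes <- gene_of[subset]
  if (anyNA(genes)) {
    .stop_typed("isoformGO_model_error", "isoform with unknown gene: %s",
                subset[is.na(genes)][[1L]])
  }
  tsets <- gene_term_sets(tg)
  ug <- unique(genes)
  terms <- unique(unlist(tsets[ug], use.names = FALSE))
  share <- matrix(FALSE, length(ug), length(ug), dimnames = list(ug, ug))
  if (length(terms)) {
    inc <- matrix(0L, length(ug), length(terms), dimnames = list(ug, terms))
    for (g in ug) inc[g, tsets[[g]] %||% character()] <- 1L
    share <- tcrossprod(inc) > 0L
  }
  idx <- utils::combn(n, 2L)
  ok <- share[cbind(genes[idx[1L, ]], genes[idx[2L, ]])]
  data.frame(a = subset[idx[1L, ok]], b = subset[idx[2L, ok]],
             stringsAsFactors = FALSE)
}

#' Score provider backed by a precomputed pair score table
#'
#' Looks standardized scores up by unordered pair; used with
#' model-derived synthetic scores where no alignment is involved.
#'
#' @param table data.frame with columns `a`, `b`, `std` (and optionally
#'   `raw`).
#' @return function `(subset, pairs) -> pair_score_table`, erroring on
#'   a pair absent from the table.
#' @export
make_table_scorer <- function(table) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  std <- stats::setNames(table$std, key(table$a, table$b))
  function(subset, pairs) {
    if (!nrow(pairs)) return(NULL)
    k <- key(pairs$a, pairs$b)
    if (anyNA(std[k])) {
      .stop_typed("isoformGO_model_error",
                  "no precomputed score for pair %s",
                  gsub("\r", " / ", k[is.na(std[k])][[1L]]))
    }
    out <- data.frame(a = pairs$a, b = pairs$b, raw = NA_real_,
                      std = unname(std[k]), stringsAsFactors = FALSE)
    class(out) <- c("pair_score_table", "data.frame")
    out
  }
}

#' Score provider that aligns sequences on demand
#'
#' Wraps [score_subset()] with a shared raw-score cache. Subsets whose
#' eligible pairs cannot be standardized (fewer than two pairs, or
#' constant scores) yield `NULL` and are skipped by the driver.
#'
#' @param sequences named character vector of protein sequences.
#' @param params alignment parameter list (see [score_subset()]).
#' @param cache an [alignment_cache()]; defaults to a fresh one.
#' @return function `(subset, pairs) -> pair_score_table` or `NULL`.
#' @export
make_sequence_scorer <- function(sequences, params = list(),
                                 cache = alignment_cache()) {
  function(subset, pairs) {
    if (nrow(pairs) < 2L) return(NULL)
    tryCatch(score_subset(subset, sequences, pairs, params, cache),
             isoformGO_alignment_error = function(e) {
               if (grepl("missing sequence", conditionMessage(e))) stop(e)
               NULL
             })
  }
}

#' Windowed convergence rule on the sigma trace
#'
#' `FALSE` until the trace has `window + 1` entries; afterwards the
#' cumulative change over the last `window` iterations — the telescoped
#' difference `sigma_last - sigma_(last-window)` (or its absolute value
#' in `"absolute"` mode) — is compared against `threshold`.
#'
#' @param trace numeric vector of sigma values.
#' @param window window length (default 25).
#' @param threshold threshold (default 1/3).
#' @param mode `"signed"` or `"absolute"`.
#' @return logical.
#' @export
check_convergence <- function(trace, window = 25L, threshold = 1 / 3,
                              mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  n <- length(trace)
  if (n < window + 1L) return(FALSE)
  d <- trace[[n]] - trace[[n - window]]
  if (mode == "absolute") d <- abs(d)
  d < threshold
}

.sigma_over_partition <- function(state, labels, run_ga, config) {
  am <- state$am
  sigma <- 0
  last <- list()
  for (k in sort(unique(labels))) {
    ids <- names(labels)[labels == k]
    if (length(ids) < 2L) next
    pairs <- eligible_pairs(ids, am$gene_of, state$tg)
    if (!nrow(pairs)) next
    tab <- state$scorer(ids, pairs)
    if (is.null(tab)) next
    if (run_ga) {
      prob <- subset_problem(am, ids, tab, state$model)
      if (nrow(prob$mut) > 0L) {
        ga <- config$ga
        ga$seed <- .draw_seed()
        res <- evolve(prob, ga, init = encode(am, prob))
        am$bits[match(ids, am$isoforms), prob$terms] <-
          decode_bits(res$bits, prob)
      }
    }
    taus <- pair_taus(am, tab)
    ll <- log_likelihood(tab, taus, state$model)
    sigma <- sigma + ll$total / ll$n_terms
    last[[length(last) + 1L]] <- list(ids = ids, tab = tab, taus = taus)
  }
  state$am <- am
  state$last_pass <- last
  state$last_sigma <- sigma
  state
}

#' One E-step iteration of the mini-batch EM
#'
#' Draws a fresh partition; in each subset builds the eligible pairs,
#' fetches scores, runs the GA from the current bits and replaces them
#' by the GA result; then accumulates
#' `sigma_i = sum_subsets lambda / lambda*` where `lambda` is the
#' subset log-likelihood under the current model and `lambda*` its pair
#' count. Subsets with fewer than two isoforms or no scorable pairs
#' contribute 0.
#'
#' @param state an EM state list (fields `am`, `model`, `tg`, `scorer`,
#'   `sigma_trace`, `iter`).
#' @param config an [em_config()].
#' @return the updated state; the new sigma is appended to
#'   `sigma_trace` and the change from the previous entry is in
#'   `delta`.
#' @export
estep_iteration <- function(state, config) {
  labels <- partition(state$am$isoforms, config$subsets, seed = .draw_seed())
  prev <- if (length(state$sigma_trace)) {
    state$sigma_trace[[length(state$sigma_trace)]]
  } else {
    NA_real_
  }
  state <- .sigma_over_partition(state, labels, run_ga = TRUE, config = config)
  state$sigma_trace <- c(state$sigma_trace, state$last_sigma)
  state$iter <- (state$iter %||% 0L) + 1L
  state$delta <- state$last_sigma - prev
  state
}

# M-step with graceful degradation: full quadratic when three
# shared-term counts are distinguishable in the pass, otherwise a
# linear refit (quadratic coefficient 0), otherwise the previous
# model. A pass whose counts collapsed to one or two values can still
# correct the slope, which is what lets a later E-step re-diversify
# the counts.
.fit_highest_degree <- function(s, taus, prev) {
  full <- tryCatch(fit_quadratic(s, taus),
                   isoformGO_rank_deficient = function(e) NULL)
  if (!is.null(full)) return(full)
  if (length(s) >= 2L && length(unique(taus)) >= 2L) {
    co <- unname(stats::lm.fit(cbind(1, taus), s)$coefficients)
    return(quadratic_model(co[[1L]], co[[2L]], 0))
  }
  prev
}

.has_eligible_pairs <- function(genes, tg) {
  tsets <- gene_term_sets(tg)
  multi <- names(genes)[lengths(genes) >= 2L]
  if (any(lengths(tsets[multi]) > 0L)) return(TRUE)
  counts <- table(unique(as.data.frame(tg)[, c("gene_id", "go_id")])$go_id)
  any(counts >= 2L)
}

#' Run the full EM for one subontology
#'
#' Initializes the model coefficients from a random subset of the seed
#' assignment, then cycles: E (GA iterations until the windowed sigma
#' convergence rule fires or the iteration cap is hit) and M (ordinary
#' least squares on the pairs of the last E pass), stopping when the
#' relative coefficient change falls below `outer_tol` or after
#' `max_cycles` cycles. With `max_cycles = 0` the seed assignment is
#' returned unchanged.
#'
#' @param assignment an [assignment_matrix()] from [build_candidates()]
#'   (its `tg` field provides pair eligibility), possibly extended with
#'   frozen surrogate bits.
#' @param scorer a score provider ([make_sequence_scorer()] or
#'   [make_table_scorer()]).
#' @param config an [em_config()].
#' @param model optional starting [quadratic_model()]; default is
#'   [initialize_beta()] on the seed assignment.
#' @return list with `assignment` (final matrix), `model`,
#'   `sigma_trace`, `sigma_log` (data.frame: cycle, iteration, sigma),
#'   `cycles`, and `last_pass` (per-subset pairs/taus of the final E
#'   pass).
#' @export
run_subontology <- function(assignment, scorer, config = em_config(),
                            model = NULL) {
  stopifnot(inherits(assignment, "assignment_matrix"))
  tg <- assignment$tg
  if (is.null(tg)) {
    .stop_typed("isoformGO_model_error",
                "assignment lacks its gene annotation map (field 'tg')")
  }
  state <- list(am = assignment, tg = tg, scorer = scorer, model = model,
                sigma_trace = numeric(), iter = 0L)
  if (config$max_cycles == 0L) {
    return(list(assignment = assignment, model = model,
                sigma_trace = numeric(),
                sigma_log = data.frame(cycle = integer(),
                                       iteration = integer(),
                                       sigma = numeric()),
                cycles = 0L, last_pass = list()))
  }
  genes <- split(assignment$isoforms, assignment$gene_of)
  if (!.has_eligible_pairs(genes, tg)) {
    .stop_typed("isoformGO_degenerate_corpus",
                "no eligible isoform pair exists in the corpus")
  }
  set.seed(config$seed)
  if (is.null(state$model)) {
    state$model <- initialize_beta(assignment, scorer, tg,
                                   subset_size = config$init_subset_size,
                                   seed = .draw_seed())
  }
  # sigma_0 baseline on the seed assignment over one initial partition
  labels <- partition(assignment$isoforms, config$subsets, seed = .draw_seed())
  state <- .sigma_over_partition(state, labels, run_ga = FALSE, config = config)
  state$sigma_trace <- state$last_sigma
  sigma_log <- data.frame(cycle = 0L, iteration = 0L,
                          sigma = state$last_sigma)
  cycles_run <- 0L
  for (cycle in seq_len(config$max_cycles)) {
    cycles_run <- cycle
    cycle_trace <- state$sigma_trace[[length(state$sigma_trace)]]
    for (it in seq_len(config$max_e_iterations)) {
      state <- estep_iteration(state, config)
      cycle_trace <- c(cycle_trace, state$last_sigma)
      sigma_log <- rbind(sigma_log,
                         data.frame(cycle = cycle, iteration = state$iter,
                                    sigma = state$last_sigma))
      if (check_convergence(cycle_trace, config$window, config$threshold,
                            config$convergence_mode)) break
    }
    tab_all <- do.call(rbind, lapply(state$last_pass, function(x) {
      data.frame(std = x$tab$std, tau = x$taus)
    }))
    new_model <- .fit_highest_degree(tab_all$std, tab_all$tau, state$model)
    rel <- max(abs(new_model$beta - state$model$beta) /
                 (1 + abs(state$model$beta)))
    state$model <- new_model
    if (rel < config$outer_tol) break
  }
  list(assignment = state$am, model = state$model,
       sigma_trace = state$sigma_trace, sigma_log = sigma_log,
       cycles = cycles_run, last_pass = state$last_pass)
}

#' Attach frozen surrogate bits from another subontology's result
#'
#' Appends the donor's assigned terms as frozen columns of the
#' receiving matrix: the bits raise shared-term counts during the GA
#' search but are never searched, and [write_isoform_annotations()]
#' excludes them from output.
#'
#' @param am receiving [assignment_matrix()] (e.g. the CC candidates).
#' @param donor finished [assignment_matrix()] (e.g. the BP result).
#' @return the extended matrix.
#' @export
add_frozen_surrogates <- function(am, donor) {
  used <- donor$terms[colSums(donor$bits) > 0L]
  new_terms <- setdiff(used, am$terms)
  if (!length(new_terms)) return(am)
  common <- intersect(am$isoforms, donor$isoforms)
  ext <- function(mat, fill) {
    add <- matrix(fill, length(am$isoforms), length(new_terms),
                  dimnames = list(am$isoforms, new_terms))
    cbind(mat, add)
  }
  bits <- ext(am$bits, FALSE)
  frozen <- ext(am$frozen, FALSE)
  donor_bits <- donor$bits[common, intersect(new_terms, donor$terms),
                           drop = FALSE]
  bits[common, colnames(donor_bits)] <- donor_bits
  frozen[common, colnames(donor_bits)] <- donor_bits
  assignment_matrix(am$isoforms, c(am$terms, new_terms), am$gene_of,
                    am$subontology,
                    bits = bits, candidate = ext(am$candidate, FALSE),
                    frozen = frozen, seed = ext(am$seed, FALSE)) -> out
  out$tg <- am$tg
  out
}

#' Drop frozen surrogate columns from an assignment
#'
#' @param am an [assignment_matrix()].
#' @return the matrix restricted to columns holding no frozen bit.
#' @export
strip_frozen <- function(am) {
  keep <- which(colSums(am$frozen) == 0L)
  out <- assignment_matrix(am$isoforms, am$terms[keep], am$gene_of,
                           am$subontology,
                           bits = am$bits[, keep, drop = FALSE],
                           candidate = am$candidate[, keep, drop = FALSE],
                           frozen = am$frozen[, keep, drop = FALSE],
                           seed = am$seed[, keep, drop = FALSE])
  out$tg <- am$tg
  out
}

#' Run the EM for all three subontologies (MF, BP, CC)
#'
#' Runs MF, then BP, then CC. When `freeze_bp_surrogates` is on, the
#' CC run starts from the CC InterPro seed plus the BP terms assigned
#' by the finished BP run as frozen bits — similar sequences share MF
#' and BP terms more readily than CC terms, so the BP assignment acts
#' as a surrogate that sharpens pair similarity during the CC search;
#' the surrogate bits are stripped from the CC output.
#'
#' @param genes a [gene_records()] collection.
#' @param tg gene-level [gene_annotation_map()] (all aspects).
#' @param domains named list, isoform id to InterPro accessions.
#' @param ipr2go named list, InterPro accession to GO term ids.
#' @param ontology optional `go_ontology`.
#' @param sequences named character vector of protein sequences (used
#'   when no `scorers` are given).
#' @param scorers optional named list (`MF`/`BP`/`CC`) of score
#'   providers overriding sequence alignment.
#' @param config an [em_config()]; per-aspect runs derive their seeds
#'   from `config$seed`.
#' @param specific_threshold fraction for [filter_specific_terms()].
#' @param out_dir optional directory; per-aspect annotation TSVs
#'   (`isoform_annotations_<aspect>.tsv`) and sigma traces
#'   (`sigma_trace_<aspect>.tsv`) are written there.
#' @return named list (`MF`, `BP`, `CC`) of [run_subontology()] results
#'   (CC stripped of surrogate columns); aspects with no candidate
#'   terms yield `NULL`.
#' @export
run_full <- function(genes, tg, domains, ipr2go, ontology = NULL,
                     sequences = NULL, scorers = NULL,
                     config = em_config(), specific_threshold = 0.10,
                     out_dir = NULL) {
  tg_comb <- augment_gene_annotations(tg, genes, domains, ipr2go, ontology)
  specific <- filter_specific_terms(tg_comb, specific_threshold)
  cache <- alignment_cache()
  results <- list(MF = NULL, BP = NULL, CC = NULL)
  for (aspect in c("MF", "BP", "CC")) {
    am <- build_candidates(genes, tg, domains, ipr2go, specific, aspect,
                           ontology)
    if (!length(am$terms)) next
    if (aspect == "CC" && config$freeze_bp_surrogates &&
        !is.null(results$BP)) {
      am <- add_frozen_surrogates(am, results$BP$assignment)
    }
    scorer <- scorers[[aspect]] %||%
      make_sequence_scorer(sequences, cache = cache)
    cfg <- config
    cfg$seed <- config$seed + match(aspect, c("MF", "BP", "CC")) - 1L
    res <- run_subontology(am, scorer, cfg)
    if (aspect == "CC") res$assignment <- strip_frozen(res$assignment)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_isoform_annotations(
        res$assignment,
        file.path(out_dir, sprintf("isoform_annotations_%s.tsv", aspect)))
      utils::write.table(
        res$sigma_log,
        file.path(out_dir, sprintf("sigma_trace_%s.tsv", aspect)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    results[[aspect]] <- res
  }
  results
}

#' Report gene terms not covered by any isoform of the gene
#'
#' The model treats every gene term as the function of at least one
#' isoform, but coverage is not enforced during the search; this
#' post-run report lists the (gene, term) pairs left uncovered.
#'
#' @param am an [assignment_matrix()].
#' @return data.frame with columns `gene_id`, `go_id`.
#' @export
uncovered_gene_terms <- function(am) {
  out <- list()
  for (g in unique(am$gene_of)) {
    rows <- which(am$gene_of == g)
    cand <- which(colSums(am$candidate[rows, , drop = FALSE]) > 0L)
    cov <- colSums(am$bits[rows, cand, drop = FALSE]) > 0L
    if (any(!cov)) {
      out[[g]] <- data.frame(gene_id = g, go_id = am$terms[cand][!cov],
                             stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(), go_id = character()))
  }
  rn <- do.call(rbind, out)
  rownames(rn) <- NULL
  rn
}
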