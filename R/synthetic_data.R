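# Fully synthetic corpora with planted ground truth. Two score
# pathways are provided so the alignment stage and the EM stage can be
# tested independently: model-derived scores (quadratic mean of the
# planted shared-term count plus Gaussian noise) and sequence-derived
# scores (per-term motifs concatenated into isoform sequences so that
# alignment scores rise with the number of shared terms).

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Simulate a gene/isoform/GO universe with a planted assignment
#'
#' Gene term sets are drawn uniformly from the term pool; each gene
#' term is planted on each of the gene's isoforms with probability
#' `assign_prob`, then repaired so that every gene term covers at least
#' one isoform (in the planted truth, every gene function is the
#' function of some isoform).
#'
#' @param n_genes,isoforms_per_gene,n_terms,terms_per_gene counts
#'   (all >= 1).
#' @param assign_prob probability in (0, 1] that a gene term is planted
#'   on a given isoform.
#' @param seed integer seed.
#' @param namespace GO namespace of all simulated terms.
#' @param unique_gene_terms when `TRUE`, gene term sets are drawn
#'   disjointly: `min(n_terms, n_genes * terms_per_gene)` shuffled
#'   terms are partitioned across the genes as evenly as possible, so
#'   every term annotates exactly one gene (hence, with 10 or more
#'   genes, every term is specific). Requires `n_terms >= n_genes`.
#' @return object of class `synthetic_truth`: list with `genes`
#'   ([gene_records()]), `tg` ([gene_annotation_map()]), `assignment`
#'   (planted [assignment_matrix()], candidates = gene term sets),
#'   `namespace`, `aspect`, and `seed`.
#' @export
simulate_universe <- function(n_genes, isoforms_per_gene, n_terms,
                              terms_per_gene, assign_prob = 0.5,
                              seed = 1L,
                              namespace = "molecular_function",
                              unique_gene_terms = FALSE) {
  stopifnot(n_genes >= 1L, isoforms_per_gene >= 1L, n_terms >= 1L,
            terms_per_gene >= 1L, terms_per_gene <= n_terms,
            assign_prob > 0, assign_prob <= 1)
  aspect <- .as_aspect(namespace)
  stopifnot(!is.na(aspect))
  set.seed(seed)
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  iso_of <- lapply(seq_len(n_genes), function(g) {
    sprintf("T%04d%02d", g, seq_len(isoforms_per_gene))
  })
  names(iso_of) <- gene_ids
  genes <- gene_records(iso_of)
  if (unique_gene_terms) {
    stopifnot(n_terms >= n_genes)
    n_used <- min(n_terms, n_genes * terms_per_gene)
    pool <- sample(terms, n_used)
    sizes <- rep(floor(n_used / n_genes), n_genes)
    extra <- n_used - sum(sizes)
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    tsets <- split(pool, rep(gene_ids, sizes))[gene_ids]
  } else {
    tsets <- lapply(gene_ids, function(g) sample(terms, terms_per_gene))
    names(tsets) <- gene_ids
  }
  tg <- gene_annotation_map(data.frame(
    gene_id = rep(gene_ids, lengths(tsets)),
    go_id = unlist(tsets, use.names = FALSE),
    aspect = aspect, stringsAsFactors = FALSE))
  gene_of <- isoform_genes(genes)
  isoforms <- names(gene_of)
  used_terms <- sort(unique(unlist(tsets, use.names = FALSE)))
  cand <- matrix(FALSE, length(isoforms), length(used_terms),
                 dimnames = list(isoforms, used_terms))
  bits <- cand
  for (g in gene_ids) {
    rows <- match(iso_of[[g]], isoforms)
    for (t in tsets[[g]]) {
      cand[rows, t] <- TRUE
      on <- stats::runif(length(rows)) < assign_prob
      if (!any(on)) on[sample.int(length(rows), 1L)] <- TRUE  # coverage repair
      bits[rows[on], t] <- TRUE
    }
  }
  am <- assignment_matrix(isoforms, used_terms, gene_of, aspect,
                          bits = bits, candidate = cand)
  am$tg <- tg
  structure(list(genes = genes, tg = tg, assignment = am,
                 namespace = namespace, aspect = aspect, seed = seed),
            class = "synthetic_truth")
}

#' Simulate standardized similarity scores from the quadratic model
#'
#' One score per eligible pair (genes sharing at least one term):
#' `std = beta2 tau^2 + beta1 tau + beta0 + noise_sd * N(0, 1)` with
#' tau taken from the planted assignment. `noise_sd = 0` gives the
#' noiseless pathway.
#'
#' @param truth a [simulate_universe()] result.
#' @param beta numeric length-3 vector `(beta0, beta1, beta2)`.
#' @param seed integer seed.
#' @param noise_sd residual standard deviation (default 1, the model's
#'   assumption).
#' @return a `pair_score_table` data.frame (`a`, `b`, `raw = NA`,
#'   `std`) with attributes `beta` and `tau`.
#' @export
simulate_scores <- function(truth, beta, seed = 1L, noise_sd = 1) {
  stopifnot(inherits(truth, "synthetic_truth"), length(beta) == 3L,
            all(is.finite(beta)))
  set.seed(seed)
  am <- truth$assignment
  pairs <- eligible_pairs(am$isoforms, am$gene_of, truth$tg)
  tau <- pair_taus(am, pairs)
  mu <- beta[[3L]] * tau^2 + beta[[2L]] * tau + beta[[1L]]
  std <- mu + if (noise_sd > 0) stats::rnorm(length(mu), 0, noise_sd) else 0
  out <- data.frame(a = pairs$a, b = pairs$b, raw = NA_real_, std = std,
                    stringsAsFactors = FALSE)
  attr(out, "beta") <- beta
  attr(out, "tau") <- tau
  class(out) <- c("pair_score_table", "data.frame")
  out
}

#' Simulate protein sequences realizing the planted assignment
#'
#' Every term receives a fixed random motif; an isoform's sequence is
#' the concatenation of the motifs of its planted terms (in GO-id
#' order) interleaved with per-isoform random filler, so the raw
#' Smith-Waterman score of a pair rises with their shared-term count.
#'
#' @param truth a [simulate_universe()] result.
#' @param motif_len motif length (>= 5).
#' @param filler_len filler segment length.
#' @param seed integer seed.
#' @return named character vector of sequences with the per-term motifs
#'   attached as attribute `motifs`.
#' @export
simulate_sequences <- function(truth, motif_len = 12L, filler_len = 8L,
                               seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), motif_len >= 5L,
            filler_len >= 0L)
  set.seed(seed)
  am <- truth$assignment
  motifs <- vapply(am$terms, function(t) {
    paste(sample(.AA20, motif_len, replace = TRUE), collapse = "")
  }, character(1L))
  filler <- function(n) {
    if (n == 0L) "" else paste(sample(.AA20, n, replace = TRUE), collapse = "")
  }
  seqs <- vapply(seq_along(am$isoforms), function(i) {
    ts <- am$terms[am$bits[i, ]]  # terms ascend, so GO-id order
    parts <- character(0)
    for (t in ts) parts <- c(parts, motifs[[t]], filler(filler_len))
    s <- paste0(filler(filler_len), paste(parts, collapse = ""))
    if (!nzchar(s)) s <- filler(max(filler_len, motif_len))
    s
  }, character(1L))
  names(seqs) <- am$isoforms
  attr(seqs, "motifs") <- motifs
  seqs
}

#' Write a synthetic corpus to disk in the pipeline's input formats
#'
#' Emits a GAF, an OBO stub (term ids and namespaces only), a protein
#' FASTA, a gene-isoform table, an isoform-domain TSV and an
#' InterPro2GO mapping. One synthetic InterPro accession is created
#' per GO term; an isoform carries the accession of a planted term
#' with probability `seed_fraction`, so the InterPro seed recovered by
#' [build_candidates()] marks (on average) that fraction of the
#' planted bits.
#'
#' @param truth a [simulate_universe()] result.
#' @param out_dir output directory (created if needed).
#' @param seed_fraction fraction in `[0, 1]` of planted bits made
#'   domain-derivable.
#' @param seed integer seed for the domain draw.
#' @param sequences optional sequences (default
#'   `simulate_sequences(truth, seed = seed)`).
#' @return named list of file paths (`gaf`, `obo`, `fasta`,
#'   `gene_isoforms`, `domains`, `ipr2go`).
#' @export
emit_corpus <- function(truth, out_dir, seed_fraction = 0.3, seed = 1L,
                        sequences = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"),
            seed_fraction >= 0, seed_fraction <= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  am <- truth$assignment
  paths <- list(gaf = file.path(out_dir, "corpus.gaf"),
                obo = file.path(out_dir, "ontology.obo"),
                fasta = file.path(out_dir, "proteins.fa"),
                gene_isoforms = file.path(out_dir, "gene_isoforms.tsv"),
                domains = file.path(out_dir, "domains.tsv"),
                ipr2go = file.path(out_dir, "interpro2go.txt"))
  aspect_code <- c(MF = "F", BP = "P", CC = "C")[[truth$aspect]]
  tgdf <- as.data.frame(truth$tg)
  gaf <- c("!gaf-version: 2.2",
           vapply(seq_len(nrow(tgdf)), function(r) {
             paste(c("SYN", tgdf$gene_id[[r]], tgdf$gene_id[[r]], "",
                     tgdf$go_id[[r]], "SYN_REF:0000001", "IEA", "",
                     aspect_code, tgdf$gene_id[[r]], "", "gene", "taxon:0000",
                     "20260101", "SYN", "", ""), collapse = "\t")
           }, character(1L)))
  writeLines(gaf, paths$gaf)
  obo <- c("format-version: 1.2", "")
  for (t in am$terms) {
    obo <- c(obo, "[Term]", paste0("id: ", t),
             paste0("name: synthetic term ", sub("GO:0*", "", t)),
             paste0("namespace: ", truth$namespace), "")
  }
  writeLines(obo, paths$obo)
  sequences <- sequences %||% simulate_sequences(truth, seed = seed)
  writeLines(as.vector(rbind(paste0(">", names(sequences)),
                             unname(sequences))), paths$fasta)
  gi <- data.frame(gene_id = unname(am$gene_of), isoform_id = am$isoforms)
  utils::write.table(gi[, c("gene_id", "isoform_id")], paths$gene_isoforms,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ipr_of <- stats::setNames(sprintf("IPR%06d", seq_along(am$terms)),
                            am$terms)
  set.seed(seed)
  dom <- c("isoform_id\tinterpro_id")
  for (i in seq_along(am$isoforms)) {
    ts <- am$terms[am$bits[i, ]]
    keep <- ts[stats::runif(length(ts)) < seed_fraction]
    for (t in keep) {
      dom <- c(dom, paste(am$isoforms[[i]], ipr_of[[t]], sep = "\t"))
    }
  }
  writeLines(dom, paths$domains)
  i2g <- c("!date: 2026/01/01",
           sprintf("InterPro:%s synthetic motif %d > GO:synthetic term %d ; %s",
                   ipr_of, seq_along(am$terms), seq_along(am$terms),
                   am$terms))
  writeLines(i2g, paths$ipr2go)
  paths
}
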