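# Independent oracles and in-code fixtures shared by the test files.

# Reference Smith-Waterman: textbook affine-gap dynamic programme
# (gap of length L costs open + L * ext), written independently of the
# alignment backend the package delegates to.
sw_reference <- function(a, b, mat, open = 10, ext = 4) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  n <- length(A)
  m <- length(B)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)
  F <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - open - ext, E[i, j - 1L] - ext)
      F[i, j] <- max(H[i - 1L, j] - open - ext, F[i - 1L, j] - ext)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + mat[A[[i - 1L]], B[[j - 1L]]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

blosum62_matrix <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

random_peptide <- function(len) {
  paste(sample(rownames(blosum62_matrix)[1:20], len, replace = TRUE),
        collapse = "")
}

# Small single-gene assignment + random scored pairs, used by the GA
# and EM tests.
random_subset_fixture <- function(seed, n_iso = 4L, n_terms = 3L,
                                  bit_prob = 0.3,
                                  beta = c(0.5, 0.2, 0.05)) {
  set.seed(seed)
  iso <- paste0("I", seq_len(n_iso))
  gene_of <- stats::setNames(rep("G1", n_iso), iso)
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  cand <- matrix(TRUE, n_iso, n_terms, dimnames = list(iso, terms))
  bits <- matrix(stats::runif(n_iso * n_terms) < bit_prob, n_iso, n_terms,
                 dimnames = list(iso, terms))
  am <- assignment_matrix(iso, terms, gene_of, "MF",
                          bits = bits, candidate = cand)
  pr <- t(utils::combn(iso, 2L))
  tab <- data.frame(a = pr[, 1L], b = pr[, 2L],
                    std = stats::rnorm(nrow(pr), 0.7, 0.5),
                    stringsAsFactors = FALSE)
  model <- quadratic_model(beta[[1L]], beta[[2L]], beta[[3L]])
  list(am = am, tab = tab, model = model,
       problem = subset_problem(am, iso, tab, model))
}

# Noiseless planted variant: scores generated exactly from the planted
# bits through the quadratic model, so the planted chromosome has
# subset ssr 0.
planted_subset_fixture <- function(seed, n_iso = 4L, n_terms = 3L,
                                   beta = c(0.5, 0.2, 0.05)) {
  fx <- random_subset_fixture(seed, n_iso, n_terms)
  taus <- pair_taus(fx$am, fx$tab)
  fx$tab$std <- beta[[3L]] * taus^2 + beta[[2L]] * taus + beta[[1L]]
  fx$problem <- subset_problem(fx$am, fx$am$isoforms, fx$tab, fx$model)
  fx$planted_taus <- taus
  fx
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Three-line GAF fixture: two ordinary rows and one NOT-qualified row.
gaf_fixture_lines <- function() {
  row <- function(gene, qual, go, aspect) {
    paste(c("UniProtKB", gene, gene, qual, go, "PMID:1", "IDA", "",
            aspect, gene, "", "protein", "taxon:9606", "20260101",
            "UniProt", "", ""), collapse = "\t")
  }
  c("!gaf-version: 2.2",
    row("GX", "enables", "GO:0003989", "F"),
    row("GX", "involved_in", "GO:0008150", "P"),
    row("GY", "NOT|enables", "GO:0003989", "F"))
}

obo_fixture_lines <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: GO:0000003", "name: c", "namespace: molecular_function", "",
    "[Term]", "id: GO:0000002", "name: b", "namespace: molecular_function",
    "is_a: GO:0000003 ! c", "",
    "[Term]", "id: GO:0000001", "name: a", "namespace: molecular_function",
    "is_a: GO:0000002 ! b", "",
    "[Term]", "id: GO:0000009", "name: gone",
    "namespace: biological_process", "is_obsolete: true", "")
}
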