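test_that("the simulated universe is reproducible and honors coverage", {
  a <- simulate_universe(20, 4, 30, 2, assign_prob = 0.5, seed = 17)
  b <- simulate_universe(20, 4, 30, 2, assign_prob = 0.5, seed = 17)
  expect_identical(a$assignment$bits, b$assignment$bits)
  expect_identical(as.data.frame(a$tg), as.data.frame(b$tg))
  # every gene term covers at least one isoform (planted truth honors
  # the gene-function coverage assumption)
  tsets <- gene_term_sets(a$tg)
  for (g in names(a$genes)) {
    rows <- match(a$genes[[g]], a$assignment$isoforms)
    for (t in tsets[[g]]) {
      expect_gte(sum(a$assignment$bits[rows, t]), 1L)
    }
  }
  # assign_prob = 1: isoform rows equal their gene term sets
  full <- simulate_universe(5, 3, 20, 3, assign_prob = 1, seed = 2)
  fsets <- gene_term_sets(full$tg)
  for (i in seq_along(full$assignment$isoforms)) {
    g <- full$assignment$gene_of[[i]]
    expect_setequal(full$assignment$terms[full$assignment$bits[i, ]],
                    fsets[[g]])
  }
  # unique mode: every term annotates exactly one gene
  u <- simulate_universe(20, 4, 30, 2, seed = 3, unique_gene_terms = TRUE)
  expect_identical(max(table(as.data.frame(u$tg)$go_id)), 1L)
  expect_identical(length(unique(u$tg$go_id)), 30L)
})

test_that("model-derived scores follow the quadratic with unit noise", {
  beta <- c(0.5, 0.2, 0.05)
  tr <- simulate_universe(10, 4, 30, 3, assign_prob = 0.7, seed = 21)
  s0 <- simulate_scores(tr, beta, seed = 22, noise_sd = 0)
  taus <- attr(s0, "tau")
  expect_equal(s0$std,
               beta[[3]] * taus^2 + beta[[2]] * taus + beta[[1]],
               tolerance = 1e-12)
  expect_true(any(taus == 3))
  expect_equal(s0$std[match(3, taus)], 0.5 + 0.6 + 0.45,
               tolerance = 1e-12)

  big <- simulate_universe(60, 6, 30, 3, assign_prob = 0.7, seed = 23)
  s1 <- simulate_scores(big, beta, seed = 24, noise_sd = 1)
  res <- s1$std - predict_similarity(attr(s1, "tau"),
                                     quadratic_model(beta[1], beta[2], beta[3]))
  expect_gt(length(res), 10000)
  expect_gt(stats::sd(res), 0.97)
  expect_lt(stats::sd(res), 1.03)
  expect_identical(simulate_scores(tr, beta, seed = 22)$std,
                   simulate_scores(tr, beta, seed = 22)$std)
})

test_that("motif sequences make alignment rise with shared terms", {
  tr <- simulate_universe(12, 3, 20, 3, assign_prob = 0.6, seed = 25)
  seqs <- simulate_sequences(tr, motif_len = 12, filler_len = 0, seed = 26)
  expect_identical(seqs, simulate_sequences(tr, motif_len = 12,
                                            filler_len = 0, seed = 26))
  am <- tr$assignment
  # two isoforms with identical planted terms and no filler share the
  # whole sequence: score equals the self-score
  sets <- apply(am$bits, 1L, function(b) paste(which(b), collapse = ","))
  twin <- which(duplicated(sets) | duplicated(sets, fromLast = TRUE))
  twin <- twin[sets[twin] != ""]
  expect_gte(length(twin), 2L)
  i <- twin[[1L]]
  j <- twin[sets[twin] == sets[[i]]][[2L]]
  expect_identical(sw_score(seqs[[i]], seqs[[j]]),
                   sw_score(seqs[[i]], seqs[[i]]))
  # mean score with zero shared terms is below one-shared-term mean
  T_ <- shared_term_counts(am)
  seqs2 <- simulate_sequences(tr, motif_len = 12, filler_len = 6, seed = 27)
  pool0 <- which(T_ == 0 & upper.tri(T_), arr.ind = TRUE)
  pool1 <- which(T_ == 1 & upper.tri(T_), arr.ind = TRUE)
  set.seed(28)
  pool0 <- pool0[sample(nrow(pool0), min(100, nrow(pool0))), , drop = FALSE]
  pool1 <- pool1[sample(nrow(pool1), min(100, nrow(pool1))), , drop = FALSE]
  m0 <- mean(apply(pool0, 1, function(p) sw_score(seqs2[[p[1]]], seqs2[[p[2]]])))
  m1 <- mean(apply(pool1, 1, function(p) sw_score(seqs2[[p[1]]], seqs2[[p[2]]])))
  expect_lt(m0, m1)
})

test_that("an emitted corpus round-trips and seeds the requested fraction", {
  tr <- simulate_universe(20, 3, 30, 2, assign_prob = 0.6, seed = 31,
                          unique_gene_terms = TRUE)
  d <- tempfile()
  paths <- emit_corpus(tr, d, seed_fraction = 1, seed = 32)
  tg <- read_gene_annotations(paths$gaf)
  expect_identical(as.data.frame(tg)[order(tg$gene_id, tg$go_id), ],
                   as.data.frame(tr$tg)[order(tr$tg$gene_id, tr$tg$go_id), ],
                   ignore_attr = TRUE)
  genes <- read_gene_isoforms(paths$gene_isoforms)
  expect_identical(isoform_genes(genes), tr$assignment$gene_of)
  onto <- read_ontology(paths$obo)
  expect_setequal(names(onto$namespace), tr$assignment$terms)
  spec <- filter_specific_terms(tg, 0.10)
  am1 <- build_candidates(genes, tg, read_isoform_domains(paths$domains),
                          read_interpro2go(paths$ipr2go), spec,
                          tr$aspect, onto)
  # seed fraction 1: the InterPro seed recovers the planted bits
  expect_identical(am1$bits[, sort(tr$assignment$terms)],
                   tr$assignment$bits[, sort(tr$assignment$terms)])
  # seed fraction 0: empty seed, same candidates
  paths0 <- emit_corpus(tr, tempfile(), seed_fraction = 0, seed = 32)
  am0 <- build_candidates(genes, tg, read_isoform_domains(paths0$domains),
                          read_interpro2go(paths0$ipr2go), spec,
                          tr$aspect, onto)
  expect_identical(sum(am0$bits), 0L)
  expect_identical(am0$candidate, am1$candidate)
})
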