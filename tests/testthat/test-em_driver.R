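test_that("partitions are uniform, deterministic and label everything", {
  ids <- sprintf("T%05d", 1:10000)
  p <- partition(ids, K = 200L, seed = 13L)
  expect_identical(names(p), ids)
  expect_true(all(p %in% 1:200))
  expect_identical(p, partition(ids, K = 200L, seed = 13L))
  chi <- stats::chisq.test(table(factor(p, levels = 1:200)))
  expect_gt(chi$p.value, 0.001)
  expect_true(all(partition(ids[1:40], K = 1L, seed = 1L) == 1L))
})

test_that("pair eligibility requires a shared gene-level term", {
  tg <- gene_annotation_map(data.frame(
    gene_id = c("G1", "G1", "G2", "G3"),
    go_id = c("GO:0000001", "GO:0000002", "GO:0000002", "GO:0000003"),
    aspect = "MF"))
  gene_of <- c(A1 = "G1", A2 = "G1", B1 = "G2", C1 = "G3")
  # two isoforms of one annotated gene: one pair
  expect_identical(nrow(eligible_pairs(c("A1", "A2"), gene_of, tg)), 1L)
  # disjoint gene annotations: no pair
  expect_identical(nrow(eligible_pairs(c("B1", "C1"), gene_of, tg)), 0L)
  # mixed subset matches a brute-force double loop
  subset <- c("A1", "A2", "B1", "C1")
  got <- eligible_pairs(subset, gene_of, tg)
  tsets <- gene_term_sets(tg)
  want <- 0L
  for (i in 1:3) {
    for (j in (i + 1):4) {
      if (length(intersect(tsets[[gene_of[[subset[i]]]]],
                           tsets[[gene_of[[subset[j]]]]]))) {
        want <- want + 1L
      }
    }
  }
  expect_identical(nrow(got), want)
  expect_true(all(got$a != got$b))
})

test_that("the convergence rule telescopes the sigma window", {
  expect_true(check_convergence(seq(0, by = 0.01, length.out = 26)))
  expect_false(check_convergence(seq(0, by = 0.02, length.out = 26)))
  expect_false(check_convergence(seq(0, by = 0.01, length.out = 10)))
  # signed mode: a large drop converges; absolute mode does not
  drop <- c(rep(1, 10), seq(1, by = -0.1, length.out = 26))
  expect_true(check_convergence(drop, mode = "signed"))
  expect_false(check_convergence(drop, mode = "absolute"))
})

test_that("an E-step iteration reproduces the hand-computed sigma", {
  tr <- simulate_universe(6, 3, 20, 2, assign_prob = 0.7, seed = 8)
  truth_beta <- c(0.5, 0.2, 0.05)
  sc <- simulate_scores(tr, truth_beta, seed = 9, noise_sd = 0)
  model <- quadratic_model(truth_beta[1], truth_beta[2], truth_beta[3])
  state <- list(am = tr$assignment, tg = tr$tg,
                scorer = make_table_scorer(sc), model = model,
                sigma_trace = numeric(), iter = 0L)
  cfg <- em_config(subsets = 1L, ga = ga_params(10L, 5L, seed = 2L),
                   seed = 1L)
  set.seed(42)
  st2 <- estep_iteration(state, cfg)
  expect_length(st2$sigma_trace, 1L)
  # K = 1: sigma is the mean pair log-likelihood of the full pair set
  pairs <- eligible_pairs(tr$assignment$isoforms, tr$assignment$gene_of,
                          tr$tg)
  taus <- pair_taus(st2$am, data.frame(a = pairs$a, b = pairs$b))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  std <- stats::setNames(sc$std, key(sc$a, sc$b))[key(pairs$a, pairs$b)]
  hand <- sum(-(predict_similarity(taus, model) - std)^2 / 2 -
                log(2 * pi) / 2) / nrow(pairs)
  expect_equal(st2$sigma_trace[[1L]], hand, tolerance = 1e-9)
  # noiseless data scored with the true model from the planted truth:
  # sigma can only improve toward the ceiling
  expect_lte(st2$sigma_trace[[1L]], -log(2 * pi) / 2 + 1e-9)
})

test_that("frozen surrogate bits raise shared-term counts but are not searched", {
  # two genes, two isoforms each; a BP run assigned term b1 to A1 and A2
  gene_of <- c(A1 = "G1", A2 = "G1", B1 = "G2", B2 = "G2")
  iso <- names(gene_of)
  cc_terms <- c("GO:0000011", "GO:0000012")
  cand <- matrix(c(TRUE, TRUE, FALSE, FALSE,
                   FALSE, FALSE, TRUE, TRUE), 4, 2,
                 dimnames = list(iso, cc_terms))
  cc <- assignment_matrix(iso, cc_terms, gene_of, "CC", candidate = cand)
  bp_bits <- matrix(c(TRUE, TRUE, FALSE, FALSE), 4, 1,
                    dimnames = list(iso, "GO:0000099"))
  bp <- assignment_matrix(iso, "GO:0000099", gene_of, "BP",
                          bits = bp_bits, candidate = bp_bits)
  ext <- add_frozen_surrogates(cc, bp)
  expect_true("GO:0000099" %in% ext$terms)
  expect_identical(sum(ext$frozen), 2L)
  # tau(A1, A2) now counts the shared BP surrogate
  taus <- pair_taus(ext, data.frame(a = c("A1", "B1"), b = c("A2", "B2")))
  expect_identical(taus, c(1, 0))
  # the surrogate cells are not part of any chromosome
  tab <- data.frame(a = "A1", b = "A2", std = 0.5)
  prob <- subset_problem(ext, c("A1", "A2"), tab, quadratic_model(0, 0, 0))
  expect_false(any(prob$terms[prob$mut[, "col"]] == "GO:0000099"))
  # and stripping removes the surrogate column but keeps CC bits intact
  back <- strip_frozen(ext)
  expect_identical(sort(back$terms), sort(cc_terms))
})

test_that("a full subontology run on noiseless planted data beats its seed", {
  tr <- simulate_universe(12, 3, 24, 2, assign_prob = 0.5, seed = 31,
                          unique_gene_terms = TRUE)
  sc <- simulate_scores(tr, c(0.5, 0.2, 0.05), seed = 32, noise_sd = 0)
  spec <- filter_specific_terms(tr$tg, 0.10)
  d <- tempfile()
  paths <- emit_corpus(tr, d, seed_fraction = 0.3, seed = 33)
  am <- build_candidates(read_gene_isoforms(paths$gene_isoforms),
                         read_gene_annotations(paths$gaf),
                         read_isoform_domains(paths$domains),
                         read_interpro2go(paths$ipr2go),
                         spec, "MF", read_ontology(paths$obo))
  cfg <- em_config(subsets = 6L, window = 10L, max_e_iterations = 15L,
                   max_cycles = 3L, ga = ga_params(40L, 40L), seed = 41L,
                   init_subset_size = 30L)
  res <- suppressMessages(run_subontology(am, make_table_scorer(sc), cfg))
  expect_gt(assignment_accuracy(res$assignment, tr$assignment),
            assignment_accuracy(am, tr$assignment))
  expect_true(all(res$assignment$bits <= res$assignment$candidate))
  # max_cycles = 0 returns the seed untouched
  res0 <- run_subontology(am, make_table_scorer(sc),
                          em_config(max_cycles = 0L))
  expect_identical(res0$assignment$bits, am$bits)
})

test_that("full runs are bitwise reproducible under a fixed seed", {
  tr <- simulate_universe(8, 3, 16, 2, assign_prob = 0.5, seed = 51,
                          unique_gene_terms = TRUE)
  d <- tempfile()
  paths <- emit_corpus(tr, d, seed_fraction = 0.4, seed = 52)
  inputs <- list(genes = read_gene_isoforms(paths$gene_isoforms),
                 tg = read_gene_annotations(paths$gaf),
                 domains = read_isoform_domains(paths$domains),
                 ipr2go = read_interpro2go(paths$ipr2go),
                 ontology = read_ontology(paths$obo),
                 sequences = read_protein_fasta(paths$fasta))
  cfg <- em_config(subsets = 4L, window = 3L, max_e_iterations = 4L,
                   max_cycles = 1L, ga = ga_params(15L, 8L), seed = 61L,
                   init_subset_size = 24L)
  run_once <- function(dir) {
    suppressMessages(run_full(inputs$genes, inputs$tg, inputs$domains,
                              inputs$ipr2go, inputs$ontology,
                              sequences = inputs$sequences, config = cfg,
                              out_dir = dir))
  }
  d1 <- tempfile()
  d2 <- tempfile()
  run_once(d1)
  run_once(d2)
  f1 <- list.files(d1)
  expect_identical(f1, list.files(d2))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("a corpus with no eligible pair is rejected", {
  gene_of <- c(A = "G1", B = "G2")
  tg <- gene_annotation_map(data.frame(
    gene_id = c("G1", "G2"), go_id = c("GO:0000001", "GO:0000002"),
    aspect = "MF"))
  cand <- matrix(TRUE, 2, 2,
                 dimnames = list(c("A", "B"),
                                 c("GO:0000001", "GO:0000002")))
  cand["A", "GO:0000002"] <- FALSE
  cand["B", "GO:0000001"] <- FALSE
  am <- assignment_matrix(c("A", "B"), c("GO:0000001", "GO:0000002"),
                          gene_of, "MF", candidate = cand)
  am$tg <- tg
  expect_error(
    run_subontology(am, make_table_scorer(
      data.frame(a = character(), b = character(), std = numeric()))),
    class = "isoformGO_degenerate_corpus")
})
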