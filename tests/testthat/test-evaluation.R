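make_assignment <- function(bits) {
  iso <- rownames(bits)
  assignment_matrix(iso, colnames(bits),
                    stats::setNames(paste0("g_", iso), iso), "MF",
                    bits = bits, candidate = bits | TRUE)
}

test_that("confusion counts match a hand-filled table and ignore order", {
  bits <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2,
                 dimnames = list(c("T1", "T2"),
                                 c("GO:0000001", "GO:0000002")))
  am <- make_assignment(bits)
  rec <- data.frame(
    isoform_id = c("T1", "T2", "T1", "T2", "TX"),
    go_id = c("GO:0000001", "GO:0000001", "GO:0000002", "GO:0000002",
              "GO:0000001"),
    label = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  cs <- confusion_vs_curation(am, rec)
  # hand count: T1/t1 TP, T2/t1 TP, T1/t2 FN, T2/t2 TN, TX skipped
  expect_identical(c(cs$tp, cs$fp, cs$tn, cs$fn), c(2L, 0L, 1L, 1L))
  expect_identical(cs$tp_rate, 2 / 3)
  expect_identical(cs$fp_rate, 0)
  expect_identical(cs$skipped, 5L)
  perm <- rec[c(3, 5, 1, 4, 2), ]
  cs2 <- confusion_vs_curation(am, perm)
  expect_identical(c(cs2$tp, cs2$fp, cs2$tn, cs2$fn),
                   c(cs$tp, cs$fp, cs$tn, cs$fn))
  # all-zero assignment predicts nothing
  am0 <- make_assignment(bits & FALSE)
  cs0 <- confusion_vs_curation(am0, rec)
  expect_identical(c(cs0$tp, cs0$fp), c(0L, 0L))
})

test_that("information content follows -ln(frequency) and decreases with use", {
  genes <- sprintf("G%03d", 1:100)
  tg <- gene_annotation_map(data.frame(
    gene_id = c(genes, genes[1], genes[1:10]),
    go_id = c(rep("GO:0000001", 100), "GO:0000002",
              rep("GO:0000003", 10)),
    aspect = "MF"))
  expect_identical(information_content("GO:0000001", tg), 0)
  expect_equal(information_content("GO:0000002", tg), -log(0.01),
               tolerance = 1e-12)
  expect_gt(information_content("GO:0000002", tg),
            information_content("GO:0000003", tg))
  expect_error(information_content("GO:0009999", tg),
               class = "isoformGO_model_error")

  # mean and weighted mean match a direct loop
  bits <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2,
                 dimnames = list(c("T1", "T2"),
                                 c("GO:0000002", "GO:0000003")))
  am <- make_assignment(bits)
  got <- mean_information_content(am, tg)
  ic2 <- information_content("GO:0000002", tg)
  ic3 <- information_content("GO:0000003", tg)
  expect_equal(got$mean_ic, mean(c(ic2, ic3)), tolerance = 1e-12)
  expect_equal(got$weighted_mean_ic, (2 * ic2 + 1 * ic3) / 3,
               tolerance = 1e-12)

  # ancestor propagation pools descendant annotations
  onto <- read_ontology(write_tmp(obo_fixture_lines(), ".obo"))
  tg2 <- gene_annotation_map(data.frame(
    gene_id = c("G1", "G2"), go_id = c("GO:0000001", "GO:0000002"),
    aspect = "MF"))
  expect_equal(information_content("GO:0000002", tg2, onto,
                                   propagate = TRUE),
               -log(1), tolerance = 1e-12)
})

test_that("expression correlations separate by construction and bin sanely", {
  # planted corpus where expression noise shrinks with shared-term count
  tr <- simulate_universe(12, 4, 24, 2, assign_prob = 0.8, seed = 61)
  am <- tr$assignment
  n_samp <- 30L
  set.seed(62)
  base <- matrix(stats::rnorm(length(am$terms) * n_samp, 5, 2),
                 length(am$terms))
  expr <- t(vapply(seq_along(am$isoforms), function(i) {
    ts <- which(am$bits[i, ])
    profile <- if (length(ts)) colMeans(base[ts, , drop = FALSE]) else
      stats::rnorm(n_samp, 5, 2)
    abs(profile + stats::rnorm(n_samp, 0, 0.2)) + 0.1
  }, numeric(n_samp)))
  rownames(expr) <- am$isoforms
  out <- correlation_by_shared_terms(expr, am, tr$tg, n_pairs = 100,
                                     seed = 63, bins = 1:2,
                                     sd_quantile = 0)
  expect_true(all(out$pairs$cor >= -1 & out$pairs$cor <= 1))
  expect_gte(mean(out$pairs$shared_isoform >= 1), 0.1)
  expect_gte(mean(out$pairs$shared_isoform >= 2), 0.1)
  med <- tapply(out$pairs$cor, pmin(out$pairs$shared_isoform, 2), stats::median)
  expect_lt(med[["0"]], med[["2"]])

  # identical rows correlate at exactly 1
  twin <- expr
  twin[2, ] <- twin[1, ]
  out2 <- correlation_by_shared_terms(twin, am, tr$tg, n_pairs = 100,
                                      seed = 64, bins = 1,
                                      sd_quantile = 0)
  pair12 <- out2$pairs[out2$pairs$a == am$isoforms[1] &
                         out2$pairs$b == am$isoforms[2], ]
  if (nrow(pair12)) expect_equal(pair12$cor, 1, tolerance = 1e-9)

  # independent rows: mean correlation near zero
  set.seed(65)
  rnd <- matrix(abs(stats::rnorm(48 * 40, 10, 3)), 48,
                dimnames = list(am$isoforms, NULL))
  out3 <- correlation_by_shared_terms(rnd, am, tr$tg, n_pairs = 500,
                                      seed = 66, bins = 1,
                                      sd_quantile = 0)
  expect_lt(abs(mean(out3$pairs$cor)), 0.1)

  # an unfillable quota errors with a census
  empty_am <- am
  empty_am$bits <- empty_am$bits & FALSE
  expect_error(
    correlation_by_shared_terms(rnd, empty_am, tr$tg, n_pairs = 100,
                                seed = 67, bins = 1, sd_quantile = 0),
    "census", class = "isoformGO_evaluation_error")
})

test_that("domain sharing trends favor isoform-level assignments on planted data", {
  tr <- simulate_universe(12, 4, 24, 2, assign_prob = 0.6, seed = 71)
  am <- tr$assignment
  # domains mirror the planted terms exactly (domains = term motifs)
  ipr_of <- stats::setNames(sprintf("IPR%06d", seq_along(am$terms)),
                            am$terms)
  domains <- lapply(seq_along(am$isoforms), function(i) {
    unname(ipr_of[am$terms[am$bits[i, ]]])
  })
  names(domains) <- am$isoforms
  out <- domain_sharing_by_shared_terms(domains, am, tr$tg)
  expect_false(out$degenerate)
  expect_gt(out$tau_isoform, out$tau_gene)
  # counts match a brute-force loop
  for (k in sample(nrow(out$pairs), 10)) {
    a <- out$pairs$a[[k]]
    b <- out$pairs$b[[k]]
    expect_identical(out$pairs$shared_domains[[k]],
                     length(intersect(domains[[a]], domains[[b]])))
  }
  # degenerate guard: all pairs share exactly one identical domain
  dom1 <- stats::setNames(rep(list("IPR000001"), 4), am$isoforms[1:4])
  out1 <- domain_sharing_by_shared_terms(dom1, am, tr$tg)
  expect_true(out1$degenerate)
  expect_identical(out1$tau_isoform, 0)
})
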