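# Group-vs-rest rank tests, BH adjustment, drug correlations, hallmark
# overlap, DEG attribution and drug-class enrichment.

sd_pop_assoc <- function(x) sqrt(mean((x - mean(x))^2))
zscore_pop_assoc <- function(x) (x - mean(x)) / sd_pop_assoc(x)

test_that("rank-sum test is exact for small tie-free samples", {
  v <- stats::setNames(c(1, 2, 3, 4, 5, 6), paste0("s", 1:6))
  res <- group_vs_rest_wilcoxon(v, paste0("s", 1:3))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, oracle_ranksum_p(c(1, 2, 3), c(4, 5, 6)))

  # identical distributions on both sides give p = 1
  v2 <- stats::setNames(c(1, 2, 3, 1, 2, 3), paste0("s", 1:6))
  expect_equal(group_vs_rest_wilcoxon(v2, paste0("s", 1:3))$p_value, 1)

  # rank statistic is invariant to strictly monotone transforms
  v3 <- stats::setNames(rnorm(12), paste0("s", 1:12))
  grp <- paste0("s", 1:5)
  expect_equal(group_vs_rest_wilcoxon(v3, grp)$p_value,
               group_vs_rest_wilcoxon(exp(v3), grp)$p_value)

  expect_error(group_vs_rest_wilcoxon(v, character(0)), "at least one")
})

test_that("exact rank-sum matches full enumeration on all small instances", {
  set.seed(19)
  for (i in 1:30) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    vals <- sample(1:50, n + m)   # distinct -> tie-free
    v <- stats::setNames(as.numeric(vals), paste0("s", seq_len(n + m)))
    p_pkg <- group_vs_rest_wilcoxon(v, paste0("s", seq_len(n)))$p_value
    p_or <- oracle_ranksum_p(vals[seq_len(n)], vals[-seq_len(n)])
    expect_equal(p_pkg, p_or, tolerance = 1e-12)
  }
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.4), 0.4)
  set.seed(3)
  p <- runif(50)
  adj <- adjust_bh(p)
  expect_true(all(adj <= 1))
  expect_true(all(adj >= p))
  # rejection set at alpha matches the classic step-up rule
  alpha <- 0.1
  ps <- sort(p)
  k <- max(c(0, which(ps <= alpha * seq_along(ps) / length(ps))))
  expect_equal(sum(adj <= alpha), k)
})

test_that("identity-drug correlation recovers exact linear relations", {
  z <- stats::setNames(rnorm(20), paste0("s", 1:20))
  res <- identity_drug_correlation(z, 2 * z + 1)
  expect_equal(res$pcc, 1)
  expect_equal(res$slope, 2, tolerance = 1e-10)
  expect_equal(res$intercept, 1, tolerance = 1e-10)
  expect_equal(identity_drug_correlation(z, -z)$pcc, -1)

  # PCC equals the covariance formula on random data
  set.seed(8)
  a <- stats::setNames(rnorm(30), paste0("s", 1:30))
  b <- stats::setNames(rnorm(30), paste0("s", 1:30))
  got <- identity_drug_correlation(a, b)$pcc
  want <- mean((a - mean(a)) * (b - mean(b))) / (sd_pop_assoc(a) * sd_pop_assoc(b))
  expect_equal(got, want, tolerance = 1e-12)

  # degenerate input is flagged, not an error
  flat <- stats::setNames(rep(1, 10), paste0("s", 1:10))
  expect_true(identity_drug_correlation(flat, a[1:10])$degenerate)
  expect_error(identity_drug_correlation(z[1:2], z[1:2]), "fewer than 3")
})

test_that("designated synthetic drug correlates with its planted factor", {
  b <- simulate_bulk(n_samples = 30, seed = 14)
  planted_pcc <- with(b$truth$drug_effect,
                      slope / sqrt(slope^2 + noise_sd^2))
  hits <- vapply(1:20, function(s) {
    d <- simulate_drug_auc(b$truth, n_drugs = 3, seed = s)
    z <- stats::setNames(zscore_pop_assoc(b$truth$sample_weights["F0", ]),
                         colnames(b$truth$sample_weights))
    abs(identity_drug_correlation(z, d$auc["D001", ])$pcc - planted_pcc) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("hallmark overlap fractions follow the set definitions", {
  sets <- list(H1 = c("A", "B", "X"), H2 = letters, H3 = c("A", "B", "C", "D"))
  ids <- c("A", "B", "C", "D")
  ov <- hallmark_overlap(ids, sets)
  expect_equal(ov$overlap_fraction[ov$set == "H1"], 0.5)
  expect_equal(ov$overlap_fraction[ov$set == "H2"], 0)
  expect_equal(ov$overlap_fraction[ov$set == "H3"], 1)
  expect_error(hallmark_overlap(character(0), sets), "empty")
})

test_that("DEG attribution splits by direction and sums to one", {
  groups <- c(g1 = "F2", g2 = "F2", g3 = "F1")
  degs <- tibble::tibble(gene = c("g1", "g2", "g3", "zz", "g1"),
                         direction = c("up", "up", "up", "down", "down"))
  attr_ <- deg_identity_attribution(degs, groups)
  up <- attr_[attr_$direction == "up", ]
  expect_equal(up$proportion[up$identity == "F2"], 2 / 3)
  expect_equal(up$proportion[up$identity == "F1"], 1 / 3)
  down <- attr_[attr_$direction == "down", ]
  expect_equal(down$proportion[down$identity == "other"], 0.5)
  expect_equal(sum(up$proportion), 1)
  expect_equal(sum(down$proportion), 1)
  expect_warning(deg_identity_attribution(degs[0, ], groups), "empty")
})

test_that("drug-class enrichment flags the loaded class and degrades gracefully", {
  set.seed(26)
  samples <- paste0("s", 1:40)
  tnbc <- samples[1:20]
  n_drugs <- 24
  auc <- matrix(rnorm(n_drugs * 40), n_drugs, 40,
                dimnames = list(paste0("d", 1:n_drugs), samples))
  classes <- stats::setNames(rep(c("hit", "bg1", "bg2"), each = 8),
                             rownames(auc))
  # drugs of class "hit" respond strongly in the TNBC group
  auc[classes == "hit", 1:20] <- auc[classes == "hit", 1:20] + 3
  res <- drug_class_enrichment(auc, classes, tnbc)
  expect_true(all(res$drugs$differential[res$drugs$class == "hit"]))
  top <- res$classes[which.min(res$classes$p_adjusted), ]
  expect_equal(top$class, "hit")
  expect_lt(top$p_adjusted, 0.05)

  # with no differential drug at all, every class chi2 is 0
  auc0 <- matrix(rnorm(n_drugs * 40), n_drugs, 40,
                 dimnames = dimnames(auc))
  res0 <- drug_class_enrichment(auc0, classes, tnbc)
  expect_true(all(res0$classes$chi2 == 0))
  expect_true(all(res0$classes$p_value == 1))

  # classes with fewer than 2 drugs are skipped with a warning
  cls2 <- classes; cls2["d1"] <- "solo"
  expect_warning(res2 <- drug_class_enrichment(auc, cls2, tnbc), "solo")
  expect_false("solo" %in% res2$classes$class)
})

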