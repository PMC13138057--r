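# The synthetic-data generators: determinism, planted structure in the
# noiseless limits, and the statistical properties of the noisy defaults.

test_that("bulk generator is deterministic and plants a rank-k_true signal", {
  a <- simulate_bulk(seed = 3)
  b <- simulate_bulk(seed = 3)
  expect_identical(a$expr, b$expr)
  expect_identical(a$truth$W_true, b$truth$W_true)
  c <- simulate_bulk(seed = 4)
  expect_false(identical(a$expr, c$expr))

  # noiseless matrix has numerical rank exactly k_true
  nl <- simulate_bulk(n_genes = 80, n_samples = 20, k_true = 4, noise_sd = 0,
                      seed = 1)
  sv <- svd(nl$expr)$d
  expect_equal(sum(sv > 1e-8 * sv[1]), 4L)
  # and equals W_true %*% weights exactly (clipping never triggers without noise)
  expect_equal(nl$expr, nl$truth$W_true %*% nl$truth$sample_weights,
               ignore_attr = FALSE)

  expect_error(simulate_bulk(k_true = 1), "k_true")
  expect_error(simulate_bulk(n_genes = 10, k_true = 4), "n_genes")
})

test_that("condition compositions are normalized and shifted as planted", {
  b <- simulate_bulk(k_true = 4, shift_delta = 0.15, shift_identity = "F0")
  comps <- b$truth$condition_compositions
  expect_equal(sum(comps$control), 1, tolerance = 1e-9)
  expect_equal(sum(comps$treated), 1, tolerance = 1e-9)
  expect_equal(comps$treated[["F0"]] - comps$control[["F0"]], 0.15)
})

test_that("single-cell generator respects composition and purity limits", {
  b <- simulate_bulk(n_genes = 80, n_samples = 20, k_true = 3, seed = 2)
  sc <- simulate_single_cells(b$truth, c(control = 30, treated = 30), seed = 9)
  expect_identical(dim(sc$counts), c(nrow(b$truth$W_true), 60L))
  expect_identical(sc$cell_meta$cluster, sc$cell_meta$identity_true)
  expect_identical(sc$counts,
                   simulate_single_cells(b$truth, c(control = 30, treated = 30),
                                         seed = 9)$counts)

  # single-identity composition labels every cell with that identity
  t2 <- b$truth
  t2$condition_compositions$pure <- c(F0 = 1, F1 = 0, F2 = 0)
  scp <- simulate_single_cells(t2, c(pure = 25), seed = 1)
  expect_true(all(scp$cell_meta$identity_true == "F0"))

  # near-infinite concentration and depth: profile proportional to W column
  sc_inf <- simulate_single_cells(t2, c(pure = 5), mixture_alpha = 1e6,
                                  depth = 2e6, seed = 1)
  p_hat <- sc_inf$counts[, 1] / sum(sc_inf$counts[, 1])
  p_true <- t2$W_true[, "F0"] / sum(t2$W_true[, "F0"])
  expect_lt(max(abs(p_hat - p_true)), 5e-3)

  expect_error(simulate_single_cells(b$truth, c(control = 10), depth = 0),
               "depth")
  expect_error(simulate_single_cells(b$truth, c(nosuch = 10)), "nosuch")
})

test_that("per-condition identity frequencies track the planted composition", {
  b <- simulate_bulk(seed = 1)
  sc <- simulate_single_cells(b$truth, c(control = 500, treated = 500), seed = 1)
  for (cond in c("control", "treated")) {
    comp <- b$truth$condition_compositions[[cond]]
    obs <- table(factor(sc$cell_meta$identity_true[sc$cell_meta$condition == cond],
                        levels = names(comp))) / 500
    expect_lt(max(abs(as.numeric(obs) - comp)), 0.06)
  }
})

test_that("drug generator couples exactly one drug to the planted factor", {
  b <- simulate_bulk(n_genes = 80, n_samples = 30, k_true = 3, seed = 6)
  # noiseless coupling gives |PCC| = 1
  t0 <- b$truth
  t0$drug_effect$noise_sd <- 0
  d0 <- simulate_drug_auc(t0, n_drugs = 5, seed = 2)
  z <- t0$sample_weights["F0", ]
  expect_equal(abs(cor(d0$auc["D001", ], z)), 1, tolerance = 1e-12)

  # a zero-slope drug stays within the null PCC band at n = 30:
  # critical |r| at alpha = 0.05 is sqrt(t^2 / (t^2 + n - 2))
  t0$drug_effect$slope <- 0
  t0$drug_effect$noise_sd <- 1
  n <- ncol(t0$sample_weights)
  tcrit <- stats::qt(0.975, n - 2)
  rcrit <- sqrt(tcrit^2 / (tcrit^2 + n - 2))
  hits <- vapply(1:40, function(s) {
    d <- simulate_drug_auc(t0, n_drugs = 2, seed = s)
    abs(cor(d$auc["D001", ], z)) < rcrit
  }, logical(1))
  expect_gte(mean(hits), 0.85)

  expect_identical(simulate_drug_auc(b$truth, seed = 7)$auc,
                   simulate_drug_auc(b$truth, seed = 7)$auc)
})

test_that("multiome generator plants the designed accessibility-expression coupling", {
  b <- simulate_bulk(n_genes = 80, n_samples = 20, k_true = 3, seed = 2)
  # noiseless slope: R^2 = 1 in the treated condition
  t0 <- b$truth
  t0$tf_effect$treated <- list(slope = 1, noise_sd = 0, accessibility_mean = 1)
  mo <- simulate_tf_multiome(t0, n_cells = c(control = 50, treated = 50),
                             n_targets = 1, seed = 4)
  trt <- mo$cell_meta$cell_id[mo$cell_meta$condition == "treated"]
  sc <- colMeans(mo$expr[mo$targets[[mo$planted_tf]], , drop = FALSE])
  r2 <- tf_target_r2(mo$accessibility[mo$planted_tf, ], sc, cells = trt)
  expect_gt(r2, 0.995)  # only the sd-0.05 per-gene jitter remains

  # zero slope everywhere: R^2 stays near zero at n = 2000
  t0$tf_effect$treated <- list(slope = 0, noise_sd = 1, accessibility_mean = 1)
  mo0 <- simulate_tf_multiome(t0, n_cells = c(treated = 2000), seed = 5)
  sc0 <- colMeans(mo0$expr[mo0$targets[[mo0$planted_tf]], , drop = FALSE])
  r20 <- tf_target_r2(mo0$accessibility[mo0$planted_tf, ], sc0)
  expect_lt(r20, 0.05)

  expect_error(simulate_tf_multiome(b$truth, n_cells = c(nope = 5)), "nope")
})

test_that("fixture bundle writes a complete, reloadable directory", {
  d <- withr::local_tempdir()
  res <- simulate_fixture_bundle(file.path(d, "fx"), seed = 2,
                                 n_genes = 60, n_samples = 16, k_true = 3)
  expect_true(all(file.exists(file.path(d, "fx",
    c("bulk.tsv", "drug_auc.tsv", "accessibility.tsv", "multiome_expr.tsv",
      "cell_meta.tsv", "tf_targets.gmt", "truth.json",
      "sc/matrix.mtx", "sc/features.tsv", "sc/barcodes.tsv")))))
  bulk <- read_expression_tsv(file.path(d, "fx", "bulk.tsv"))
  expect_equal(bulk, res$bulk$expr, tolerance = 1e-12)
  counts <- read_mtx_bundle(file.path(d, "fx", "sc/matrix.mtx"),
                            file.path(d, "fx", "sc/features.tsv"),
                            file.path(d, "fx", "sc/barcodes.tsv"))
  expect_equal(as.matrix(counts), res$sc$counts)
})
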