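# Contingency tables, chi-squared residual scores, cluster contributions.

make_profiles <- function(identity, condition, cluster = "c0") {
  structure(tibble::tibble(cell_id = sprintf("c%04d", seq_along(identity)),
                           condition = condition, cluster = cluster,
                           assigned_identity = identity),
            class = c("cell_profiles", class(tibble::tibble())))
}

test_that("identity contingency counts, drops unassigned and empty rows", {
  prof <- make_profiles(
    identity = c(rep("F0", 10), rep("F1", 5), rep("F0", 10), "unassigned"),
    condition = c(rep("pre", 15), rep("post", 11)))
  expect_message(tab <- identity_contingency(prof, "pre", "post"), "unassigned")
  expect_equal(tab["F0", ], c(pre = 10, post = 10))
  expect_equal(tab["F1", ], c(pre = 5, post = 0))
  expect_equal(sum(tab), 25)

  prof0 <- make_profiles(rep("F0", 4), rep("pre", 4))
  expect_error(identity_contingency(prof0, "pre", "post"), "no assigned cells")
})

test_that("chi-squared residuals match the hand-worked example", {
  tab <- matrix(c(60, 40, 40, 60), 2, 2,
                dimnames = list(c("F0", "F1"), c("pre", "post")))
  sr <- chisq_residuals(tab)
  expect_equal(sr$chi2, 8)
  expect_equal(sr$dof, 1L)
  expect_equal(unname(sr$residuals), matrix(c(sqrt(2), -sqrt(2), -sqrt(2), sqrt(2)), 2, 2))
  expect_equal(unname(sr$residual_scores), c(-sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(sr$most_expanded, "F1")
  expect_equal(sr$p_value, stats::pchisq(8, 1, lower.tail = FALSE))

  # observed == expected gives a null result
  t0 <- matrix(50, 2, 2, dimnames = list(c("F0", "F1"), c("pre", "post")))
  s0 <- chisq_residuals(t0)
  expect_equal(s0$chi2, 0)
  expect_true(all(s0$residuals == 0))

  # doubling counts doubles chi2 and scales residuals by sqrt(2)
  s2 <- chisq_residuals(2 * tab)
  expect_equal(s2$chi2, 2 * sr$chi2)
  expect_equal(s2$residuals, sqrt(2) * sr$residuals, tolerance = 1e-12)

  # empty margin is refused with the margin named
  bad <- matrix(c(5, 0, 7, 0), 2, 2,
                dimnames = list(c("F0", "F1"), c("pre", "post")))
  expect_error(chisq_residuals(bad), "row 'F1'")
})

test_that("chisq_residuals agrees with the textbook oracle on random tables", {
  set.seed(17)
  for (i in 1:300) {
    r <- sample(2:5, 1); c <- sample(2:4, 1)
    tab <- matrix(sample(1:100, r * c, replace = TRUE), r, c,
                  dimnames = list(paste0("I", 1:r), paste0("C", 1:c)))
    got <- chisq_residuals(tab)
    want <- oracle_chisq(tab)
    expect_equal(got$chi2, want$chi2, tolerance = 1e-10)
    expect_equal(got$dof, want$dof)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
    expect_equal(got$residuals, want$residuals, tolerance = 1e-10)
  }
})

test_that("row and column deviations from expectation sum to zero", {
  set.seed(23)
  tab <- matrix(sample(5:50, 12), 4, 3,
                dimnames = list(paste0("I", 1:4), paste0("C", 1:3)))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(rowSums(tab - E), rep(0, 4), ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(colSums(tab - E), rep(0, 3), ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("cluster contributions localize an expansion to the driving cluster", {
  # identity F0: cluster A carries the whole post-treatment gain
  prof <- make_profiles(
    identity = rep("F0", 100),
    condition = c(rep("pre", 40), rep("post", 60)),
    cluster = c(rep(c("A", "B"), each = 20), rep("A", 50), rep("B", 10)))
  contrib <- cluster_contributions(prof, "F0", "pre", "post")
  expect_equal(contrib$cluster[which.max(contrib$residual_score)], "A")
  expect_gt(max(contrib$residual_score), 0)
  expect_lt(min(contrib$residual_score), 0)

  # proportional scaling leaves residuals at zero
  prop <- make_profiles(
    identity = rep("F0", 90),
    condition = c(rep("pre", 30), rep("post", 60)),
    cluster = c(rep(c("A", "B", "C"), each = 10), rep(c("A", "B", "C"), each = 20)))
  c2 <- cluster_contributions(prop, "F0", "pre", "post")
  expect_equal(c2$residual_score, rep(0, 3), tolerance = 1e-12)

  # relabeling clusters permutes rows but not residual values
  relab <- make_profiles(
    identity = rep("F0", 100),
    condition = c(rep("pre", 40), rep("post", 60)),
    cluster = c(rep(c("Z", "Y"), each = 20), rep("Z", 50), rep("Y", 10)))
  c3 <- cluster_contributions(relab, "F0", "pre", "post")
  expect_equal(sort(c3$residual_score), sort(contrib$residual_score))

  one <- make_profiles(rep("F0", 10), rep(c("pre", "post"), 5), cluster = "A")
  expect_error(cluster_contributions(one, "F0", "pre", "post"), "fewer than 2")
})

test_that("planted composition shifts are detected end to end", {
  b <- simulate_bulk(n_genes = 200, n_samples = 32, seed = 31)
  sal <- select_salient_genes(b$expr, gene_selection_config("cell_line"))
  m <- fit_identity_model(b$expr, genes = sal, k_grid = 2:7, seed = 3)
  sc <- simulate_single_cells(b$truth, c(control = 400, treated = 400), seed = 5)
  cells <- map_cells(normalize_cells(sc$counts), m, cell_meta = sc$cell_meta)
  sr <- identity_shift(cells, "control", "treated")
  map <- match_identities(cells$assigned_identity,
                          sc$cell_meta$identity_true)$map
  expect_equal(unname(map[sr$most_expanded]), "F0")
  expect_lt(sr$p_value, 0.05)
  expect_equal(sum(sr$table), sum(cells$assigned_identity != "unassigned"))
})
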