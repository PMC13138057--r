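# Anchor-paired DBSCAN gene selection.

test_that("expression prefilter applies strict 'lower than' semantics", {
  expr <- rbind(
    low_max   = c(0, 2.9, 1, 1),
    boundary  = c(0.0, 3.0, 1, 2),
    low_range = c(5, 6, 5.5, 5.2),
    keeper    = c(0, 5, 1, 4),
    MYC       = c(0, 6, 1, 5))
  colnames(expr) <- paste0("s", 1:4)
  cfg <- gene_selection_config("cell_line")
  kept <- prefilter_genes(expr, cfg)
  expect_setequal(kept, c("boundary", "keeper", "MYC"))

  # the anchor itself must survive
  cfg2 <- gene_selection_config("cell_line", anchor_gene = "low_range")
  expect_error(prefilter_genes(expr, cfg2), "anchor")
})

test_that("dbscan_pair reproduces the defining cases", {
  # two tight blobs, well separated
  g <- c(rnorm(5, 0, 0.05), rnorm(5, 10, 0.05))
  a <- c(rnorm(5, 0, 0.05), rnorm(5, 10, 0.05))
  lab <- dbscan_pair(g, a, eps = 0.5, min_samples = 3)
  expect_equal(sort(unique(lab)), c(0L, 1L))
  expect_equal(unname(table(lab)), c(5L, 5L), ignore_attr = TRUE)

  # all identical points: one cluster, no noise
  lab1 <- dbscan_pair(rep(1, 8), rep(2, 8), eps = 0.5, min_samples = 3)
  expect_equal(lab1, rep(0L, 8))

  # 12 collinear points at spacing 1 with eps 0.5: everything is noise
  lab2 <- dbscan_pair(1:12, rep(0, 12), eps = 0.5, min_samples = 3)
  expect_equal(lab2, rep(-1L, 12))
})

test_that("dbscan_pair agrees with a brute-force oracle on random instances", {
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(5:50, 1)
    # mixture of blobs and uniform scatter to exercise border/noise cases
    cx <- runif(3, 0, 8); cy <- runif(3, 0, 8)
    which_b <- sample(1:3, n, replace = TRUE)
    g <- cx[which_b] + rnorm(n, 0, runif(1, 0.1, 1.5))
    a <- cy[which_b] + rnorm(n, 0, runif(1, 0.1, 1.5))
    eps <- runif(1, 0.2, 1.5)
    ms <- sample(2:5, 1)
    got <- dbscan_pair(g, a, eps, ms)
    want <- oracle_dbscan(g, a, eps, ms)
    expect_equal(canonical_labels(got), canonical_labels(want))
  }
})

test_that("evaluate_gene applies the size/distance/separation thresholds", {
  cfg <- gene_selection_config("cell_line")
  expect_length(cfg$eps_grid, 112)

  blob <- function(n, gx, gy, s = 0.05) {
    cbind(rnorm(n, gx, s), rnorm(n, gy, s))
  }
  set.seed(2)
  # two blobs of 5, centroids 5 apart on the gene axis, gap > 1: accepted
  pts <- rbind(blob(5, 0, 0), blob(5, 5, 0))
  ev <- evaluate_gene(pts[, 1], pts[, 2], cfg)
  expect_false(is.null(ev))
  expect_equal(ev$centroid_dist, 5, tolerance = 0.2)
  expect_equal(c(ev$size_small, ev$size_large), c(5L, 5L))

  # two blobs of exactly 3 each: "more than 3" is strict, so rejected
  pts3 <- rbind(blob(3, 0, 0), blob(3, 5, 0))
  expect_null(evaluate_gene(pts3[, 1], pts3[, 2], cfg))

  # centroid distance below 3: rejected
  near <- rbind(blob(5, 0, 0), blob(5, 2, 0))
  expect_null(evaluate_gene(near[, 1], near[, 2], cfg))
})

test_that("selection keeps planted markers, rejects noise genes, and is order-invariant", {
  b <- simulate_bulk(n_genes = 150, n_samples = 30, k_true = 3, seed = 8)
  cfg <- gene_selection_config("cell_line")
  sal <- select_salient_genes(b$expr, cfg)
  markers <- unlist(b$truth$marker_blocks)
  noise_genes <- setdiff(rownames(b$expr), markers)
  expect_gte(mean(markers %in% sal$gene), 0.95)
  expect_gte(mean(!noise_genes %in% sal$gene), 0.95)
  # anchor is included first, without evidence
  expect_equal(sal$gene[1], "MYC")
  expect_true(is.na(sal$best_eps[1]))
  # evaluated genes are ordered by descending centroid distance
  expect_false(is.unsorted(rev(sal$centroid_dist[-1])))

  # permuting samples and genes leaves the selected set unchanged
  set.seed(1)
  perm <- b$expr[sample(nrow(b$expr)), sample(ncol(b$expr))]
  sal2 <- select_salient_genes(perm, cfg)
  expect_setequal(sal$gene, sal2$gene)

  # impossible thresholds leave only the anchor -> error
  cfg_inf <- gene_selection_config("cell_line", min_centroid_dist = 1e6)
  expect_error(select_salient_genes(b$expr, cfg_inf), "no gene passed")
})

test_that("raising the centroid-distance threshold never grows the selection", {
  b <- simulate_bulk(n_genes = 100, n_samples = 24, k_true = 3, seed = 12)
  sel <- function(d) {
    select_salient_genes(b$expr,
                         gene_selection_config("cell_line",
                                               min_centroid_dist = d))$gene
  }
  s3 <- sel(3); s4 <- sel(4); s5 <- sel(5)
  expect_true(all(s4 %in% s3))
  expect_true(all(s5 %in% s4))
})

test_that("tumor two-round mode counts basal samples non-strictly", {
  # 36 samples: 20 basal, 16 non-basal. One gene splits all samples into
  # two clusters with >= 10 basal each; a second gene has a cluster with
  # only 7 basal members and must fail round 2 (needs >= 8).
  set.seed(30)
  n_b <- 20; n_o <- 16
  samples <- c(sprintf("B%02d", 1:n_b), sprintf("O%02d", 1:n_o))
  anchor <- c(rnorm(n_b, 6, 0.2), rnorm(n_o, 6, 0.2))
  strong <- c(rnorm(10, 2, 0.2), rnorm(10, 9, 0.2),   # basal: 10 low, 10 high
              rnorm(8, 2, 0.2), rnorm(8, 9, 0.2))     # others split too
  weak <- c(rnorm(7, 2, 0.2), rnorm(13, 9, 0.2),      # only 7 basal low
            rnorm(8, 2, 0.2), rnorm(8, 9, 0.2))
  expr <- rbind(STRONG = strong, WEAK = weak, MYC = anchor)
  colnames(expr) <- samples
  cfg <- gene_selection_config("tumor_two_round")
  sal <- select_salient_genes(expr, cfg, basal_samples = samples[1:n_b])
  expect_true("STRONG" %in% sal$gene)
  expect_false("WEAK" %in% sal$gene)
  expect_error(select_salient_genes(expr, cfg), "basal_samples")
})
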