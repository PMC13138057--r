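# Anchor-paired DBSCAN selection of "salient" high-variance genes. Each
# candidate gene is clustered against the anchor gene (MYC by default) in
# the 2-D space of raw log-scale expression, over a grid of DBSCAN eps
# values; a gene is kept when some eps yields a well-separated pair of
# sufficiently large clusters.

#' Configuration for salient-gene selection
#'
#' Thresholds operate on raw log-scale expression units (the absolute
#' distance cut-offs assume log2(TPM+1)-like values; the 2-D points are
#' deliberately not standardized). Two modes exist:
#' `cell_line` (one DBSCAN round with expression prefilters; cluster sizes
#' must *exceed* `min_cluster_size`, centroid distance must exceed
#' `min_centroid_dist`, and single-linkage separation must exceed
#' `min_separation`) and `tumor_two_round` (round 1 on all samples, round 2
#' on the basal subset; sizes are counted over basal samples and compared
#' non-strictly, separation is not used).
#'
#' @param mode `"cell_line"` or `"tumor_two_round"`.
#' @param anchor_gene Anchor gene id (default `"MYC"`).
#' @param eps_grid DBSCAN radius grid; default `seq(0.1, 1.21, by = 0.01)`
#'   (112 values).
#' @param min_samples DBSCAN core-point threshold (neighborhood includes
#'   the point itself).
#' @param min_max_expr,min_range Cell-line prefilters: a gene is kept iff
#'   its max expression and its range are not lower than these values.
#' @param min_cluster_size Cell-line mode: clusters must have *more than*
#'   this many samples (strict). For tumor mode see `round1_min_size` /
#'   `round2_min_size`.
#' @param min_centroid_dist Minimum centroid Euclidean distance between an
#'   accepting cluster pair (strict in both modes).
#' @param min_separation Cell-line mode: minimum single-linkage gap
#'   between the pair (strict).
#' @param round1_min_size,round2_min_size Tumor mode: minimum basal-sample
#'   count per cluster (non-strict, "at least").
#' @return A `gene_selection_config` list.
#' @export
gene_selection_config <- function(mode = c("cell_line", "tumor_two_round"),
                                  anchor_gene = "MYC",
                                  eps_grid = seq(0.1, 1.21, by = 0.01),
                                  min_samples = 3,
                                  min_max_expr = 3, min_range = 3,
                                  min_cluster_size = 3,
                                  min_centroid_dist = NULL,
                                  min_separation = 1,
                                  round1_min_size = 10, round2_min_size = 8) {
  mode <- match.arg(mode)
  min_centroid_dist <- min_centroid_dist %||% if (mode == "cell_line") 3 else 4
  stopifnot(length(eps_grid) >= 1, all(diff(eps_grid) > 0), all(eps_grid > 0),
            min_samples >= 1)
  structure(list(mode = mode, anchor_gene = anchor_gene, eps_grid = eps_grid,
                 min_samples = as.integer(min_samples),
                 min_max_expr = min_max_expr, min_range = min_range,
                 min_cluster_size = min_cluster_size,
                 min_centroid_dist = min_centroid_dist,
                 min_separation = min_separation,
                 round1_min_size = round1_min_size,
                 round2_min_size = round2_min_size),
            class = "gene_selection_config")
}

#' Prefilter genes on expression level and range
#'
#' Cell-line mode only: genes whose maximum expression is lower than
#' `min_max_expr` or whose range (max - min) is lower than `min_range` are
#' removed. "Lower than" is strict, so boundary values are kept.
#'
#' @param expr Genes-by-samples matrix.
#' @param cfg A [gene_selection_config()].
#' @return Character vector of surviving gene ids.
#' @export
prefilter_genes <- function(expr, cfg) {
  validate_expression_matrix(expr)
  mx <- apply(expr, 1, max)
  rg <- mx - apply(expr, 1, min)
  keep <- !(mx < cfg$min_max_expr) & !(rg < cfg$min_range)
  genes <- rownames(expr)[keep]
  if (!cfg$anchor_gene %in% genes) {
    abort(sprintf("anchor gene '%s' does not survive the expression prefilter",
                  cfg$anchor_gene))
  }
  genes
}

#' DBSCAN on a gene/anchor expression pair
#'
#' Runs classic DBSCAN on the 2-D points `(gene_vec[i], anchor_vec[i])`
#' with the Euclidean metric on raw (unscaled) values. A core point has at
#' least `min_samples` neighbors within `eps` (neighborhood includes the
#' point itself, boundary distance inclusive). Returns per-sample labels:
#' -1 for noise, clusters numbered 0, 1, ...
#'
#' @param gene_vec,anchor_vec Equal-length numeric vectors.
#' @param eps Neighborhood radius.
#' @param min_samples Core-point threshold.
#' @return Integer vector of labels.
#' @export
dbscan_pair <- function(gene_vec, anchor_vec, eps, min_samples) {
  stopifnot(length(gene_vec) == length(anchor_vec), eps > 0, min_samples >= 1)
  .dbscan_pair_cpp(as.numeric(gene_vec), as.numeric(anchor_vec),
                   as.numeric(eps), as.integer(min_samples))
}

#' Evaluate one gene against the anchor over the eps grid
#'
#' For every eps in the grid, clusters the (gene, anchor) scatter and
#' inspects every unordered pair of non-noise clusters: the gene is
#' accepted if any pair passes the size, centroid-distance and (cell-line
#' mode) separation thresholds. Evidence records the accepting pair with
#' the largest centroid distance.
#'
#' @param gene_vec,anchor_vec Numeric vectors of expression.
#' @param cfg A [gene_selection_config()].
#' @param count_mask Logical vector: which samples count toward cluster
#'   size (tumor mode counts basal samples only). Default: all.
#' @param min_size,strict_size,use_separation Overrides used internally by
#'   the tumor two-round procedure; default from `cfg`.
#' @return One-row tibble (gene evidence) if accepted, otherwise `NULL`.
#' @export
evaluate_gene <- function(gene_vec, anchor_vec, cfg, count_mask = NULL,
                          min_size = NULL, strict_size = NULL,
                          use_separation = NULL) {
  n <- length(gene_vec)
  count_mask <- count_mask %||% rep(TRUE, n)
  cell_line <- cfg$mode == "cell_line"
  res <- .evaluate_gene_cpp(
    as.numeric(gene_vec), as.numeric(anchor_vec), as.numeric(cfg$eps_grid),
    cfg$min_samples,
    as.numeric(min_size %||% cfg$min_cluster_size),
    strict_size %||% cell_line,
    cfg$min_centroid_dist,
    cfg$min_separation,
    use_separation %||% cell_line,
    as.logical(count_mask))
  if (!res$accepted) return(NULL)
  tibble(best_eps = res$best_eps, centroid_dist = res$centroid_dist,
         size_small = res$size_small, size_large = res$size_large,
         separation = res$separation)
}

#' Select salient genes by anchor-paired DBSCAN
#'
#' Cell-line mode: prefilters genes on expression level and range, then
#' accepts genes via [evaluate_gene()]. Tumor mode: round 1 clusters all
#' samples and requires cluster pairs with centroid distance above the
#' threshold and at least `round1_min_size` basal samples per cluster;
#' survivors enter round 2, which clusters basal samples only and requires
#' at least `round2_min_size` basal samples per cluster. The anchor gene
#' is always included, without evaluation.
#'
#' @param expr Genes-by-samples matrix of log-scale expression.
#' @param cfg A [gene_selection_config()].
#' @param basal_samples Character vector of basal-subset sample ids
#'   (required in tumor mode).
#' @return A `salient_genes` tibble (gene, best_eps, centroid_dist,
#'   size_small, size_large, separation), anchor first, evaluated genes in
#'   descending centroid distance then lexicographic order. The anchor
#'   gene id is stored in `attr(, "anchor_gene")`.
#' @export
select_salient_genes <- function(expr, cfg, basal_samples = NULL) {
  validate_expression_matrix(expr)
  if (!cfg$anchor_gene %in% rownames(expr)) {
    abort(sprintf("anchor gene '%s' not present in the matrix", cfg$anchor_gene))
  }
  anchor_vec <- expr[cfg$anchor_gene, ]

  if (cfg$mode == "cell_line") {
    genes <- setdiff(prefilter_genes(expr, cfg), cfg$anchor_gene)
    rows <- lapply(genes, function(g) {
      ev <- evaluate_gene(expr[g, ], anchor_vec, cfg)
      if (is.null(ev)) NULL else dplyr::mutate(ev, gene = g, .before = 1)
    })
    out <- dplyr::bind_rows(rows)
  } else {
    if (is.null(basal_samples)) {
      abort("tumor_two_round mode requires `basal_samples`")
    }
    basal_samples <- intersect(basal_samples, colnames(expr))
    if (length(basal_samples) == 0) abort("no basal samples found in the matrix")
    mask_all <- colnames(expr) %in% basal_samples
    genes <- setdiff(rownames(expr), cfg$anchor_gene)
    round1 <- genes[vapply(genes, function(g) {
      !is.null(evaluate_gene(expr[g, ], anchor_vec, cfg, count_mask = mask_all,
                             min_size = cfg$round1_min_size,
                             strict_size = FALSE, use_separation = FALSE))
    }, logical(1))]
    expr2 <- expr[, basal_samples, drop = FALSE]
    anchor2 <- expr2[cfg$anchor_gene, ]
    rows <- lapply(round1, function(g) {
      ev <- evaluate_gene(expr2[g, ], anchor2, cfg,
                          min_size = cfg$round2_min_size,
                          strict_size = FALSE, use_separation = FALSE)
      if (is.null(ev)) NULL else dplyr::mutate(ev, gene = g, .before = 1)
    })
    out <- dplyr::bind_rows(rows)
  }

  if (nrow(out) == 0) {
    abort("no gene passed selection (anchor alone is not a valid set); review the thresholds")
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$centroid_dist), .data$gene)
  anchor_row <- tibble(gene = cfg$anchor_gene, best_eps = NA_real_,
                       centroid_dist = NA_real_, size_small = NA_integer_,
                       size_large = NA_integer_, separation = NA_real_)
  out <- dplyr::bind_rows(anchor_row, out)
  attr(out, "anchor_gene") <- cfg$anchor_gene
  class(out) <- c("salient_genes", class(out))
  out
}
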