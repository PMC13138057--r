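# "Reverse NMF": project single cells onto the bulk-derived W matrix by
# non-negative least squares, assign each cell the identity of its
# dominant factor, and z-score the per-cell weights into identity scores.

#' Normalize single-cell counts to log1p(CP10k)
#'
#' Per cell: counts are scaled to counts-per-10,000 and log1p-transformed.
#' Cells with zero total counts are dropped with a warning. This produces
#' the non-negative log-scale representation fed to the NNLS projection.
#'
#' @param counts Genes-by-cells matrix (dense or sparse) of non-negative
#'   counts with dimnames.
#' @return Dense genes-by-cells matrix of log1p(CP10k) values.
#' @export
normalize_cells <- function(counts) {
  m <- as.matrix(counts)
  if (any(m < 0)) abort("counts must be non-negative")
  tot <- colSums(m)
  if (any(tot == 0)) {
    warn(sprintf("dropping %d cell(s) with zero total counts", sum(tot == 0)))
    m <- m[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  log1p(sweep(m, 2, tot, "/") * 1e4)
}

#' Restrict W and a single-cell matrix to their common genes
#'
#' Gene identifiers are matched after [normalize_gene_ids()]. Both
#' matrices are restricted to the intersection, in the same order. An
#' intersection below 50% of the W genes is an error (the projection would
#' be unreliable); below 100% a warning reports the fraction.
#'
#' @param W Genes-by-k factor matrix.
#' @param sc_expr Genes-by-cells matrix.
#' @return List with `W`, `sc_expr` (row-aligned) and
#'   `intersection_fraction`.
#' @export
harmonize_genes <- function(W, sc_expr) {
  w_ids <- normalize_gene_ids(rownames(W))
  s_ids <- normalize_gene_ids(rownames(sc_expr))
  common <- intersect(w_ids, s_ids)
  frac <- length(common) / nrow(W)
  if (frac < 0.5) {
    abort(sprintf("only %.1f%% of the model genes are present in the single-cell matrix; projection would be unreliable",
                  100 * frac))
  }
  if (frac < 1) {
    warn(sprintf("%.1f%% of the model genes found in the single-cell matrix",
                 100 * frac))
  }
  Wm <- W[match(common, w_ids), , drop = FALSE]
  Sm <- sc_expr[match(common, s_ids), , drop = FALSE]
  rownames(Wm) <- common
  rownames(Sm) <- common
  list(W = Wm, sc_expr = Sm, intersection_fraction = frac)
}

#' Non-negative least squares projection of one cell
#'
#' Solves `min ||x - W h||_2` subject to `h >= 0` (Lawson-Hanson active
#' set, via [pracma::lsqnonneg()]). The solution satisfies the KKT
#' conditions: the gradient `t(W) %*% (W h - x)` is non-negative, and zero
#' on the support of h.
#'
#' @param x Numeric vector (one cell's expression over the model genes).
#' @param W Genes-by-k matrix.
#' @return Non-negative numeric vector of length k.
#' @export
nnls_project <- function(x, W) {
  stopifnot(length(x) == nrow(W))
  if (all(x == 0)) return(stats::setNames(rep(0, ncol(W)), colnames(W)))
  h <- pracma::lsqnonneg(W, as.numeric(x))$x
  stats::setNames(pmax(h, 0), colnames(W))
}

#' Map single cells onto bulk-derived identities
#'
#' Per cell, solves the NNLS problem against the model's W (after gene
#' harmonization), assigns the identity of the largest weight (ties to the
#' lowest factor index; all-zero weight vectors become `"unassigned"`),
#' and z-scores each factor's weights across all cells pooled, so that
#' conditions share one score scale.
#'
#' @param sc_expr Genes-by-cells matrix of normalized (non-negative,
#'   log-scale) expression, e.g. from [normalize_cells()].
#' @param model An `identity_model`.
#' @param cell_meta Optional tibble/data.frame with columns `cell_id` and
#'   any of `condition`, `cluster`; joined onto the output.
#' @return A `cell_profiles` tibble: cell_id, condition, cluster,
#'   `h_<factor>` weight columns, `score_<factor>` z-score columns,
#'   assigned_identity.
#' @export
map_cells <- function(sc_expr, model, cell_meta = NULL) {
  stopifnot(inherits(model, "identity_model"))
  harm <- harmonize_genes(model$W, sc_expr)
  W <- harm$W
  X <- as.matrix(harm$sc_expr)
  k <- ncol(W)
  H <- matrix(0, k, ncol(X), dimnames = list(colnames(W), colnames(X)))
  for (i in seq_len(ncol(X))) {
    H[, i] <- nnls_project(X[, i], W)
  }
  assigned <- apply(H, 2, function(h) {
    if (max(h) == 0) "unassigned" else rownames(H)[which.max(h)]
  })
  scores <- t(apply(H, 1, zscore_pop))
  out <- tibble(cell_id = colnames(X))
  if (!is.null(cell_meta)) {
    out <- dplyr::left_join(out, tibble::as_tibble(cell_meta), by = "cell_id")
  }
  if (!"condition" %in% names(out)) out$condition <- NA_character_
  if (!"cluster" %in% names(out)) out$cluster <- NA_character_
  hw <- tibble::as_tibble(t(H), .name_repair = ~ paste0("h_", rownames(H)))
  sw <- tibble::as_tibble(t(scores), .name_repair = ~ paste0("score_", rownames(H)))
  out <- dplyr::bind_cols(out, hw, sw)
  out$assigned_identity <- unname(assigned)
  attr(out, "identities") <- rownames(H)
  class(out) <- c("cell_profiles", class(out))
  out
}
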