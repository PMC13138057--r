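# Identity discovery: NMF on the salient-gene matrix, rank choice by the
# elbow rule on reconstruction error, sample identities by Ward
# hierarchical clustering of H columns, gene groups by the dominant W
# factor, and per-factor H z-scores for downstream correlation analyses.

new_identity_model <- function(W, H, k, recon_err_by_k, sample_labels,
                               gene_groups, H_zscores) {
  structure(list(W = W, H = H, k = k, recon_err_by_k = recon_err_by_k,
                 sample_labels = sample_labels, gene_groups = gene_groups,
                 H_zscores = H_zscores),
            class = "identity_model")
}

#' Non-negative matrix factorization (Frobenius, multiplicative updates)
#'
#' Minimizes `||X - W H||_F` with Lee-Seung multiplicative updates, taking
#' the best of `n_restarts` deterministic random initializations (restart
#' `i` is seeded with `seed + i`). W columns are rescaled to unit L2 norm
#' with the scale absorbed into H.
#'
#' @param x Non-negative genes-by-samples matrix.
#' @param k Factorization rank (`k < min(dim(x))`).
#' @param n_restarts Random restarts.
#' @param seed Integer seed.
#' @param max_iter,tol Update iterations and relative-error convergence
#'   tolerance.
#' @return List with `W` (genes x k, unit-norm columns), `H` (k x samples),
#'   and `recon_err` (Frobenius reconstruction error).
#' @export
run_nmf <- function(x, k, n_restarts = 10, seed = 1, max_iter = 1000,
                    tol = 1e-7) {
  stopifnot(is.matrix(x), all(x >= 0))
  if (k >= min(dim(x))) {
    abort(sprintf("k = %d must be smaller than min(dim(x)) = %d", k, min(dim(x))))
  }
  scale0 <- sqrt(mean(x) / k)
  best <- NULL
  for (i in seq_len(n_restarts)) {
    fit <- withr::with_seed(seed + i, {
      W0 <- matrix(runif(nrow(x) * k, 0.1, 1), nrow(x), k) * scale0
      H0 <- matrix(runif(k * ncol(x), 0.1, 1), k, ncol(x)) * scale0
      .nmf_mu_cpp(x, W0, H0, as.integer(max_iter), tol)
    })
    if (is.null(best) || fit$recon_err < best$recon_err) best <- fit
  }
  W <- best$W
  H <- best$H
  nrm <- sqrt(colSums(W^2))
  pos <- nrm > 0
  W[, pos] <- sweep(W[, pos, drop = FALSE], 2, nrm[pos], "/")
  H[pos, ] <- sweep(H[pos, , drop = FALSE], 1, nrm[pos], "*")
  dimnames(W) <- list(rownames(x), NULL)
  dimnames(H) <- list(NULL, colnames(x))
  list(W = W, H = H, recon_err = best$recon_err)
}

#' Choose the NMF rank by the elbow rule
#'
#' Formalizes the elbow as the point of maximum discrete curvature of
#' reconstruction error versus k: with drops `d_k = err(k-1) - err(k)`,
#' `k* = argmax_k (d_k - d_{k+1})` over interior grid points; ties go to
#' the smallest k. Monotone-increasing error curves degenerate to the
#' first grid point with a warning.
#'
#' @param recon_err_by_k Named numeric vector of reconstruction errors over
#'   a contiguous integer grid (names are the k values; >= 3 points).
#' @return The chosen integer rank.
#' @export
choose_k_elbow <- function(recon_err_by_k) {
  ks <- as.integer(names(recon_err_by_k))
  if (length(ks) < 3) abort("elbow rule needs at least 3 grid points")
  if (any(diff(ks) != 1)) abort("k grid must be contiguous")
  err <- as.numeric(recon_err_by_k)
  if (all(diff(err) >= 0)) {
    warn("reconstruction error is non-decreasing in k; returning the first grid point")
    return(ks[1])
  }
  d <- -diff(err)                      # d[i] = err(k_{i}) - err(k_{i+1}) drop into ks[i+1]
  curv <- d[-length(d)] - d[-1]        # curvature at interior ks[2..n-1]
  interior <- ks[2:(length(ks) - 1)]
  interior[which.max(curv)]            # which.max takes the first (smallest k) on ties
}

#' Assign sample identities from H by hierarchical clustering
#'
#' Columns of H are L1-normalized, clustered by Ward-linkage (`ward.D2`)
#' hierarchical clustering on Euclidean distances, and cut into k
#' clusters. Each cluster is labeled by the factor with the highest mean
#' normalized weight among its samples; when the top two factor means are
#' within `mixture_margin` (relative to the top mean), the cluster is
#' labeled `"mixture:Fi+Fj"`. All-zero columns are labeled
#' `"unassigned"` with a warning.
#'
#' @param H k-by-samples non-negative matrix with factor rownames and
#'   sample colnames.
#' @param mixture_margin Relative margin below which the two top factors
#'   are reported as a mixture.
#' @return Named character vector, sample -> identity label.
#' @export
assign_sample_identities <- function(H, mixture_margin = 0.10) {
  stopifnot(is.matrix(H), !is.null(rownames(H)), !is.null(colnames(H)))
  k <- nrow(H)
  labels <- stats::setNames(rep(NA_character_, ncol(H)), colnames(H))
  tot <- colSums(H)
  if (any(tot == 0)) {
    warn(sprintf("%d sample(s) have an all-zero H column; labeled 'unassigned'",
                 sum(tot == 0)))
    labels[tot == 0] <- "unassigned"
  }
  ok <- which(tot > 0)
  Hn <- sweep(H[, ok, drop = FALSE], 2, tot[ok], "/")
  if (length(ok) <= k) {
    cl <- seq_along(ok)
  } else {
    hc <- stats::hclust(stats::dist(t(Hn)), method = "ward.D2")
    cl <- stats::cutree(hc, k = k)
  }
  for (c_id in unique(cl)) {
    members <- ok[cl == c_id]
    mw <- rowMeans(Hn[, cl == c_id, drop = FALSE])
    ord <- order(-mw)
    top <- ord[1]; second <- ord[2]
    lab <- rownames(H)[top]
    if (k >= 2 && mw[top] > 0 &&
        (mw[top] - mw[second]) / mw[top] < mixture_margin) {
      pair <- sort(rownames(H)[c(top, second)])
      lab <- sprintf("mixture:%s+%s", pair[1], pair[2])
    }
    labels[members] <- lab
  }
  labels
}

#' Group genes by their dominant identity factor
#'
#' Assigns each gene to the factor with the largest W weight; ties go to
#' the lowest factor index, all-zero rows to `"unassigned"`.
#'
#' @param W Genes-by-k non-negative matrix with gene rownames and factor
#'   colnames.
#' @return Named character vector, gene -> identity name.
#' @export
group_genes_by_identity <- function(W) {
  stopifnot(is.matrix(W), !is.null(rownames(W)), !is.null(colnames(W)))
  idx <- apply(W, 1, which.max)   # which.max: lowest index on ties
  out <- colnames(W)[idx]
  out[rowSums(W) == 0] <- "unassigned"
  stats::setNames(out, rownames(W))
}

#' Per-factor z-scores of H across samples
#'
#' Each row of H is centered and scaled by its population (ddof = 0)
#' standard deviation across samples; constant rows become zeros with a
#' warning.
#'
#' @param H k-by-samples matrix.
#' @return Matrix of the same shape.
#' @export
compute_h_zscores <- function(H) {
  stopifnot(is.matrix(H), ncol(H) >= 2)
  out <- t(apply(H, 1, function(r) {
    if (sd_pop(r) == 0) {
      warn("constant H row; z-scores set to 0")
      rep(0, length(r))
    } else zscore_pop(r)
  }))
  dimnames(out) <- dimnames(H)
  out
}

#' Fit an identity model: NMF over a k grid + elbow + labeling
#'
#' Runs [run_nmf()] for every rank in `k_grid` on the salient-gene
#' submatrix, picks the rank with [choose_k_elbow()], canonicalizes factor
#' order by descending total factor mass (row sums of H, i.e. the W-column
#' mass absorbed into H by the unit-norm convention), names factors
#' `F0..F(k-1)`, and derives sample identity labels, gene groups and H
#' z-scores.
#'
#' @param expr Genes-by-samples matrix.
#' @param genes Character vector of salient genes (or a `salient_genes`
#'   tibble); default all rows.
#' @param k_grid Contiguous integer grid of candidate ranks.
#' @param n_restarts,seed,mixture_margin See [run_nmf()] and
#'   [assign_sample_identities()].
#' @return An `identity_model` with elements `W`, `H`, `k`,
#'   `recon_err_by_k`, `sample_labels`, `gene_groups`, `H_zscores`.
#' @export
fit_identity_model <- function(expr, genes = NULL, k_grid = 4:9,
                               n_restarts = 10, seed = 1,
                               mixture_margin = 0.10) {
  validate_expression_matrix(expr)
  if (inherits(genes, "salient_genes")) genes <- genes$gene
  genes <- genes %||% rownames(expr)
  missing_g <- setdiff(genes, rownames(expr))
  if (length(missing_g)) {
    abort(sprintf("%d selected gene(s) absent from the matrix (first: '%s')",
                  length(missing_g), missing_g[1]))
  }
  x <- expr[genes, , drop = FALSE]
  fits <- lapply(k_grid, function(k) {
    run_nmf(x, k, n_restarts = n_restarts, seed = seed + 1000L * k)
  })
  errs <- stats::setNames(vapply(fits, `[[`, numeric(1), "recon_err"),
                          as.character(k_grid))
  k_star <- choose_k_elbow(errs)
  fit <- fits[[match(k_star, k_grid)]]
  ord <- order(-rowSums(fit$H))
  W <- fit$W[, ord, drop = FALSE]
  H <- fit$H[ord, , drop = FALSE]
  fnames <- paste0("F", seq_len(k_star) - 1)
  colnames(W) <- fnames
  rownames(H) <- fnames
  new_identity_model(
    W = W, H = H, k = as.integer(k_star), recon_err_by_k = errs,
    sample_labels = assign_sample_identities(H, mixture_margin),
    gene_groups = group_genes_by_identity(W),
    H_zscores = compute_h_zscores(H))
}

#' @export
print.identity_model <- function(x, ...) {
  cat(sprintf("<identity_model> k = %d, %d genes x %d samples\n",
              x$k, nrow(x$W), ncol(x$H)))
  cat("identity sizes:\n")
  print(table(x$sample_labels))
  invisible(x)
}

#' Tidy an identity model
#'
#' @param x An `identity_model`.
#' @param matrix `"samples"` (per-sample factor weights, z-scores and
#'   labels, long) or `"genes"` (per-gene factor weights and groups, long).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy identity_model
#' @export
tidy.identity_model <- function(x, matrix = c("samples", "genes"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "samples") {
    tibble(sample = rep(colnames(x$H), each = x$k),
           factor = rep(rownames(x$H), times = ncol(x$H)),
           weight = as.vector(x$H),
           zscore = as.vector(x$H_zscores),
           identity = rep(unname(x$sample_labels[colnames(x$H)]), each = x$k))
  } else {
    tibble(gene = rep(rownames(x$W), times = x$k),
           factor = rep(colnames(x$W), each = nrow(x$W)),
           weight = as.vector(x$W),
           group = rep(unname(x$gene_groups[rownames(x$W)]), times = x$k))
  }
}

#' One-row summary of an identity model
#'
#' @param x An `identity_model`.
#' @param ... Unused.
#' @return A tibble with k, dimensions, reconstruction error and label
#'   counts.
#' @method glance identity_model
#' @export
glance.identity_model <- function(x, ...) {
  tibble(k = x$k, n_genes = nrow(x$W), n_samples = ncol(x$H),
         recon_err = unname(x$recon_err_by_k[as.character(x$k)]),
         n_mixture = sum(startsWith(x$sample_labels, "mixture:")),
         n_unassigned = sum(x$sample_labels == "unassigned"))
}
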