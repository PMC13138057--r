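# Link TF motif accessibility to target gene-set expression: per-cell
# module scores against expression-bin-matched control genes, per-
# condition OLS R^2 of target score on accessibility, delta R^2 across
# treatments, and the TF relevance table.

#' Per-cell gene-set module score
#'
#' Scores each cell as the mean expression of the set genes minus the
#' mean expression of a bin-matched control gene pool: genes are binned
#' into `n_bins` by average expression across cells, and for each set gene
#' up to `n_ctrl` control genes are sampled (seeded, without replacement)
#' from the non-set genes of its bin; the union of sampled genes forms the
#' control pool. Set genes are excluded from the pool so that the set's
#' own signal cannot cancel itself. Supplying `control_genes` bypasses the
#' sampling entirely (e.g. the self-control configuration
#' `control_genes = gene_set` gives a score of exactly zero).
#'
#' @param expr Genes-by-cells matrix.
#' @param gene_set Character vector of set genes; absent genes are dropped
#'   with a message.
#' @param n_bins Expression bins.
#' @param n_ctrl Control genes sampled per set gene.
#' @param seed Integer seed for control sampling.
#' @param control_genes Optional explicit control pool overriding the
#'   bin-matched sampling.
#' @return Named numeric vector, cell -> score.
#' @export
module_score <- function(expr, gene_set, n_bins = 24, n_ctrl = 100, seed = 1,
                         control_genes = NULL) {
  stopifnot(is.matrix(expr) || methods::is(expr, "Matrix"))
  present <- intersect(gene_set, rownames(expr))
  if (length(present) == 0) abort("no gene of the set is present in the matrix")
  if (length(present) < length(gene_set)) {
    inform(sprintf("dropping %d set gene(s) absent from the matrix",
                   length(gene_set) - length(present)))
  }
  if (is.null(control_genes)) {
    avg <- rowMeans(expr)
    n_bins_eff <- min(n_bins, length(avg))
    bins <- dplyr::ntile(avg, n_bins_eff)
    names(bins) <- rownames(expr)
    ctrl <- withr::with_seed(seed, {
      unique(unlist(lapply(present, function(g) {
        pool <- setdiff(names(bins)[bins == bins[g]], present)
        sample(pool, min(n_ctrl, length(pool)))
      })))
    })
    if (length(ctrl) == 0) {
      abort("no control gene available outside the set; supply `control_genes`")
    }
  } else {
    ctrl <- intersect(control_genes, rownames(expr))
    if (length(ctrl) == 0) abort("none of `control_genes` is in the matrix")
  }
  set_mean <- colMeans(expr[present, , drop = FALSE])
  ctrl_mean <- colMeans(expr[ctrl, , drop = FALSE])
  set_mean - ctrl_mean
}

#' R-squared of target score on motif accessibility
#'
#' Ordinary least squares of the per-cell target gene-set score on the
#' per-cell motif accessibility, within one condition;
#' `R^2 = 1 - SS_res/SS_tot`. Zero-variance accessibility is flagged as
#' undefined (NA) rather than an error.
#'
#' @param accessibility Named numeric vector, cell -> motif accessibility.
#' @param target_scores Named numeric vector, cell -> target-set score.
#' @param cells Optional character vector restricting to a condition's
#'   cells.
#' @return A single R-squared value (NA if undefined).
#' @export
tf_target_r2 <- function(accessibility, target_scores, cells = NULL) {
  if (!is.null(cells)) {
    accessibility <- accessibility[cells]
    target_scores <- target_scores[cells]
  } else if (!is.null(names(accessibility)) && !is.null(names(target_scores))) {
    common <- intersect(names(accessibility), names(target_scores))
    accessibility <- accessibility[common]
    target_scores <- target_scores[common]
  }
  if (length(accessibility) < 3) abort("need at least 3 cells")
  if (sd_pop(accessibility) == 0) return(NA_real_)
  fit <- stats::lm(target_scores ~ accessibility)
  ss_tot <- sum((target_scores - mean(target_scores))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum(stats::residuals(fit)^2) / ss_tot
}

#' Treatment-induced change in R-squared
#'
#' `delta R^2(t) = R^2(t) - R^2(control)` for every non-control condition.
#'
#' @param r2_by_condition Named numeric vector, condition -> R^2.
#' @param control Name of the control condition.
#' @return Named numeric vector over the non-control conditions.
#' @export
delta_r2 <- function(r2_by_condition, control) {
  if (!control %in% names(r2_by_condition)) {
    abort(sprintf("control condition '%s' missing from r2_by_condition", control))
  }
  treatments <- setdiff(names(r2_by_condition), control)
  stats::setNames(r2_by_condition[treatments] - r2_by_condition[[control]],
                  treatments)
}

#' TF relevance table: accessibility shift, target upregulation, R-squared linkage
#'
#' Per TF and treatment: the mean difference in motif accessibility
#' (treated minus control); a one-sided (greater) rank-sum p-value testing
#' whether target module scores are higher under treatment, over all
#' targets (`broad_p`) and over targets intersected with a pathway set
#' (`pathway_p`, NA when the intersection is empty); per-condition R^2
#' between accessibility and target score; and the delta R^2 versus
#' control. p-values are BH-adjusted across TFs within each treatment and
#' column.
#'
#' @param accessibility TF-by-cells numeric matrix of motif accessibility.
#' @param expr Genes-by-cells matrix of normalized expression.
#' @param targets Named list, TF -> target gene ids (e.g. from
#'   [read_gmt()]); every TF must have at least one target in `expr`.
#' @param pathway_genes Character vector of pathway gene ids.
#' @param cell_meta Tibble with `cell_id` and `condition`.
#' @param control Control condition name.
#' @param treatments Treatment condition names; default all non-control
#'   conditions present.
#' @param n_bins,n_ctrl,seed Passed to [module_score()].
#' @return A `tf_linkage` tibble, one row per TF x treatment: tf,
#'   treatment, accessibility_diff, broad_p, broad_p_adj, pathway_p,
#'   pathway_p_adj, r2_control, r2_treated, delta_r2.
#' @export
tf_relevance_table <- function(accessibility, expr, targets, pathway_genes,
                               cell_meta, control, treatments = NULL,
                               n_bins = 24, n_ctrl = 100, seed = 1) {
  stopifnot(is.matrix(accessibility), !is.null(rownames(accessibility)))
  meta <- tibble::as_tibble(cell_meta)
  cells <- intersect(colnames(accessibility), meta$cell_id)
  cells <- intersect(cells, colnames(expr))
  meta <- meta[match(cells, meta$cell_id), ]
  treatments <- treatments %||% setdiff(unique(meta$condition), control)
  if (!control %in% meta$condition) {
    abort(sprintf("control condition '%s' has no cells", control))
  }
  cond_cells <- split(meta$cell_id, meta$condition)

  tfs <- intersect(rownames(accessibility), names(targets))
  if (length(tfs) == 0) abort("no TF shared between accessibility and targets")

  rows <- purrr::map_dfr(tfs, function(tf) {
    tgt <- targets[[tf]]
    if (length(intersect(tgt, rownames(expr))) == 0) {
      abort(sprintf("TF '%s' has no target gene in the expression matrix", tf))
    }
    sc_all <- module_score(expr[, cells, drop = FALSE], tgt,
                           n_bins = n_bins, n_ctrl = n_ctrl,
                           seed = derive_seed(seed, tf))
    path_tgt <- intersect(tgt, pathway_genes)
    sc_path <- if (length(intersect(path_tgt, rownames(expr))) > 0) {
      module_score(expr[, cells, drop = FALSE], path_tgt,
                   n_bins = n_bins, n_ctrl = n_ctrl,
                   seed = derive_seed(seed, paste0(tf, ":pathway")))
    } else NULL
    acc <- accessibility[tf, cells]
    r2 <- vapply(c(control, treatments), function(cond) {
      tf_target_r2(acc, sc_all, cells = cond_cells[[cond]])
    }, numeric(1))
    dr2 <- delta_r2(r2, control)
    purrr::map_dfr(treatments, function(tr) {
      tr_cells <- cond_cells[[tr]]
      ct_cells <- cond_cells[[control]]
      one_sided <- function(sc) {
        suppressWarnings(stats::wilcox.test(
          sc[tr_cells], sc[ct_cells], alternative = "greater",
          exact = FALSE, correct = FALSE))$p.value
      }
      tibble(tf = tf, treatment = tr,
             accessibility_diff = mean(acc[tr_cells]) - mean(acc[ct_cells]),
             broad_p = one_sided(sc_all),
             pathway_p = if (is.null(sc_path)) NA_real_ else one_sided(sc_path),
             r2_control = unname(r2[control]),
             r2_treated = unname(r2[tr]),
             delta_r2 = unname(dr2[tr]))
    })
  })
  rows <- rows |>
    dplyr::group_by(.data$treatment) |>
    dplyr::mutate(broad_p_adj = adjust_bh(.data$broad_p),
                  pathway_p_adj = adjust_bh(.data$pathway_p)) |>
    dplyr::ungroup() |>
    dplyr::relocate("broad_p_adj", .after = "broad_p") |>
    dplyr::relocate("pathway_p_adj", .after = "pathway_p")
  class(rows) <- c("tf_linkage", class(rows))
  rows
}
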