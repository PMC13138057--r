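# Quantify identity expansion/shrinkage after treatment: identity-by-
# condition contingency tables, chi-squared tests without continuity
# correction, and Pearson residual scores in the treated column.

#' Build an identity-by-condition contingency table
#'
#' Counts assigned cells per identity for a control/treated condition
#' pair. Unassigned cells are excluded (reported), identities with zero
#' total count are dropped (reported); a condition with no assigned cells
#' is an error.
#'
#' @param profiles A `cell_profiles` tibble from [map_cells()].
#' @param control,treated Condition labels; the table columns are ordered
#'   (control, treated).
#' @return Integer matrix, identities x 2 conditions.
#' @export
identity_contingency <- function(profiles, control, treated) {
  df <- dplyr::filter(profiles, .data$condition %in% c(control, treated))
  n_un <- sum(df$assigned_identity == "unassigned")
  if (n_un > 0) {
    inform(sprintf("excluding %d unassigned cell(s)", n_un))
    df <- dplyr::filter(df, .data$assigned_identity != "unassigned")
  }
  for (cond in c(control, treated)) {
    if (!any(df$condition == cond)) {
      abort(sprintf("condition '%s' has no assigned cells", cond))
    }
  }
  ids <- sort(unique(df$assigned_identity))
  tab <- table(factor(df$assigned_identity, levels = ids),
               factor(df$condition, levels = c(control, treated)))
  tab <- matrix(as.integer(tab), nrow = length(ids),
                dimnames = list(ids, c(control, treated)))
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    inform(sprintf("dropping %d identit(ies) with zero counts", sum(empty)))
    tab <- tab[!empty, , drop = FALSE]
  }
  tab
}

#' Chi-squared test with Pearson residual scores
#'
#' Runs the chi-squared test of independence (no continuity correction by
#' default) on an identities-by-conditions count table and returns the
#' Pearson residuals `(O - E)/sqrt(E)` with `E = row * col / N`. The
#' residual score of an identity is its residual in the treated (last)
#' column; positive means expansion under treatment, negative shrinkage.
#'
#' @param table Integer count matrix (>= 2 rows, >= 2 columns), treated
#'   condition in the last column.
#' @param correct Apply Yates continuity correction to the test statistic
#'   (2x2 tables only); residuals are always uncorrected.
#' @return A `shift_result` list: `table`, `chi2`, `dof`, `p_value`,
#'   `residuals`, `residual_scores` (treated column, named by identity),
#'   `most_expanded`.
#' @export
chisq_residuals <- function(table, correct = FALSE) {
  stopifnot(is.matrix(table), nrow(table) >= 2, ncol(table) >= 2,
            all(table >= 0))
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(E == 0)) {
    zr <- which(rowSums(table) == 0)
    zc <- which(colSums(table) == 0)
    what <- if (length(zr)) sprintf("row '%s'", rownames(table)[zr[1]])
            else sprintf("column '%s'", colnames(table)[zc[1]])
    abort(sprintf("expected count of zero: margin %s is empty", what))
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  res <- (table - E) / sqrt(E)
  scores <- res[, ncol(res)]
  structure(list(
    table = table,
    chi2 = unname(ct$statistic),
    dof = unname(ct$parameter),
    p_value = unname(ct$p.value),
    residuals = res,
    residual_scores = scores,
    most_expanded = rownames(table)[which.max(scores)]
  ), class = "shift_result")
}

#' Identity shift between two conditions
#'
#' Convenience wrapper: [identity_contingency()] followed by
#' [chisq_residuals()].
#'
#' @inheritParams identity_contingency
#' @inheritParams chisq_residuals
#' @return A `shift_result`.
#' @export
identity_shift <- function(profiles, control, treated, correct = FALSE) {
  chisq_residuals(identity_contingency(profiles, control, treated),
                  correct = correct)
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf("<shift_result> chi2 = %.4g, dof = %d, p = %.3g\n",
              x$chi2, x$dof, x$p_value))
  cat(sprintf("most expanded identity: %s (residual %.3f)\n",
              x$most_expanded, x$residual_scores[x$most_expanded]))
  invisible(x)
}

#' Tidy a shift result
#'
#' @param x A `shift_result`.
#' @param ... Unused.
#' @return Tibble: identity, counts per condition, residuals per
#'   condition, residual_score, expanded flag.
#' @method tidy shift_result
#' @export
tidy.shift_result <- function(x, ...) {
  conds <- colnames(x$table)
  out <- tibble(identity = rownames(x$table))
  for (j in seq_along(conds)) {
    out[[paste0("n_", conds[j])]] <- unname(x$table[, j])
  }
  out$residual_score <- unname(x$residual_scores)
  out$expanded <- out$identity == x$most_expanded
  out
}

#' @method glance shift_result
#' @export
glance.shift_result <- function(x, ...) {
  tibble(chi2 = x$chi2, dof = x$dof, p_value = x$p_value,
         n_cells = sum(x$table), most_expanded = x$most_expanded)
}

#' Per-cluster contributions to an identity expansion
#'
#' Restricts to cells assigned the expanded identity, builds a cluster-by-
#' condition count table, and returns each cluster's treated-column
#' Pearson residual: positive residuals mark clusters driving the
#' expansion, negative ones clusters resisting it.
#'
#' @param profiles A `cell_profiles` tibble (must carry `cluster` labels).
#' @param expanded_identity Identity to decompose (typically
#'   `most_expanded` of [identity_shift()]).
#' @param control,treated Condition labels.
#' @return Tibble: cluster, counts per condition, residual_score; the
#'   test's chi2/dof/p are in attributes `chi2`, `dof`, `p_value`.
#' @export
cluster_contributions <- function(profiles, expanded_identity, control, treated) {
  df <- dplyr::filter(profiles,
                      .data$assigned_identity == expanded_identity,
                      .data$condition %in% c(control, treated))
  if (nrow(df) == 0) {
    abort(sprintf("no cells assigned identity '%s'", expanded_identity))
  }
  clusters <- sort(unique(df$cluster))
  tab <- table(factor(df$cluster, levels = clusters),
               factor(df$condition, levels = c(control, treated)))
  tab <- matrix(as.integer(tab), nrow = length(clusters),
                dimnames = list(clusters, c(control, treated)))
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2) {
    abort("fewer than 2 clusters with nonzero counts for this identity")
  }
  sr <- chisq_residuals(tab)
  out <- tidy(sr)
  names(out)[1] <- "cluster"
  attr(out, "chi2") <- sr$chi2
  attr(out, "dof") <- sr$dof
  attr(out, "p_value") <- sr$p_value
  out
}
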