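# ggplot2 visualizations for the main result types.

#' Elbow plot of NMF reconstruction error
#'
#' @param object An `identity_model`.
#' @param ... Unused.
#' @return A ggplot: reconstruction error versus rank, chosen k marked.
#' @method autoplot identity_model
#' @export
autoplot.identity_model <- function(object, ...) {
  df <- tibble(k = as.integer(names(object$recon_err_by_k)),
               recon_err = unname(object$recon_err_by_k))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$recon_err)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed",
                        color = "firebrick") +
    ggplot2::scale_x_continuous(breaks = df$k) +
    ggplot2::labs(x = "rank k", y = "Frobenius reconstruction error",
                  title = sprintf("Elbow rank selection (k* = %d)", object$k)) +
    ggplot2::theme_minimal()
}

#' Residual-score bar chart of an identity shift
#'
#' @param object A `shift_result`.
#' @param ... Unused.
#' @return A ggplot: treated-column Pearson residual per identity;
#'   positive bars mark expansion under treatment.
#' @method autoplot shift_result
#' @export
autoplot.shift_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$identity, .data$residual_score),
                                   y = .data$residual_score,
                                   fill = .data$residual_score > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "steelblue")) +
    ggplot2::labs(x = NULL, y = "residual score (treated column)",
                  title = sprintf("Identity shift: chi2 = %.1f, p = %.2g",
                                  object$chi2, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Identity composition of mapped cells by condition
#'
#' @param object A `cell_profiles` tibble from [map_cells()].
#' @param ... Unused.
#' @return A ggplot: per-condition stacked composition over assigned
#'   identities.
#' @method autoplot cell_profiles
#' @export
autoplot.cell_profiles <- function(object, ...) {
  df <- dplyr::count(tibble::as_tibble(object), .data$condition,
                     .data$assigned_identity)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$n,
                                   fill = .data$assigned_identity)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(x = NULL, y = "fraction of cells", fill = "identity") +
    ggplot2::theme_minimal()
}

#' Delta R-squared scatter of TF linkage results
#'
#' @param object A `tf_linkage` tibble from [tf_relevance_table()]. With
#'   two treatments, plots one against the other; with one, delta R^2
#'   versus accessibility shift.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tf_linkage
#' @export
autoplot.tf_linkage <- function(object, ...) {
  df <- tibble::as_tibble(object)
  trs <- unique(df$treatment)
  if (length(trs) >= 2) {
    wide <- tidyr::pivot_wider(df[, c("tf", "treatment", "delta_r2")],
                               names_from = "treatment",
                               values_from = "delta_r2")
    ggplot2::ggplot(wide, ggplot2::aes(x = .data[[trs[1]]], y = .data[[trs[2]]])) +
      ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
      ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
      ggplot2::labs(x = sprintf("delta R2 (%s)", trs[1]),
                    y = sprintf("delta R2 (%s)", trs[2]),
                    title = "Treatment-induced change in TF-target linkage") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$accessibility_diff,
                                     y = .data$delta_r2)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "motif accessibility difference",
                    y = sprintf("delta R2 (%s)", trs[1])) +
      ggplot2::theme_minimal()
  }
}
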