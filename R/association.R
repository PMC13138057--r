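# Orthogonal validation of identities: group-vs-rest rank tests on
# expression / CRISPR dependency / drug AUC, identity-weight vs drug-AUC
# correlations, hallmark overlap fractions, DEG identity attribution, and
# drug-class enrichment.

#' Two-sided group-vs-rest Wilcoxon rank-sum test
#'
#' Compares the values of a sample group against all remaining samples
#' with the two-sided Mann-Whitney rank-sum test: exact null enumeration
#' when both sides have at most 8 observations and there are no ties,
#' otherwise the normal approximation with tie correction (no continuity
#' correction).
#'
#' @param values Named numeric vector (sample -> value), or unnamed with
#'   `group` logical.
#' @param group Character vector of in-group sample names, or a logical
#'   vector along `values`.
#' @return Tibble: statistic (rank-sum W for the group), p_value,
#'   median_diff (group median minus rest median).
#' @export
group_vs_rest_wilcoxon <- function(values, group) {
  if (is.logical(group)) {
    stopifnot(length(group) == length(values))
    in_grp <- group
  } else {
    stopifnot(!is.null(names(values)))
    in_grp <- names(values) %in% group
  }
  x <- values[in_grp]
  y <- values[!in_grp]
  if (length(x) == 0 || length(y) == 0) {
    abort("both the group and the rest must contain at least one sample")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 8 && length(y) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = FALSE))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         median_diff = stats::median(x) - stats::median(y))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' a thin wrapper over [stats::p.adjust()] kept as the package's single
#' place to change the multiplicity method.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Correlate identity weights with drug response
#'
#' Pearson correlation (with two-sided t-test p-value) and OLS
#' slope/intercept between a factor's H z-scores and per-sample drug AUC,
#' on the overlapping samples. Zero variance on either side yields a
#' flagged row with NA statistics rather than an error.
#'
#' @param zscores Named numeric vector (sample -> factor z-score), e.g. a
#'   row of `model$H_zscores`.
#' @param auc Named numeric vector (sample -> AUC).
#' @return Tibble: n, pcc, p_value, slope, intercept, degenerate.
#' @export
identity_drug_correlation <- function(zscores, auc) {
  common <- intersect(names(zscores), names(auc))
  if (length(common) < 3) abort("fewer than 3 overlapping samples")
  z <- zscores[common]
  a <- auc[common]
  if (sd_pop(z) == 0 || sd_pop(a) == 0) {
    return(tibble(n = length(common), pcc = NA_real_, p_value = NA_real_,
                  slope = NA_real_, intercept = NA_real_, degenerate = TRUE))
  }
  ct <- stats::cor.test(z, a, method = "pearson")
  fit <- stats::lm(a ~ z)
  tibble(n = length(common), pcc = unname(ct$estimate),
         p_value = ct$p.value, slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]), degenerate = FALSE)
}

#' Overlap of identity genes with hallmark gene sets
#'
#' For each set, the fraction of the identity's genes it contains:
#' `|identity genes intersect set| / |identity genes|`.
#'
#' @param identity_genes Character vector of an identity's defining genes.
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @return Tibble: set, n_overlap, overlap_fraction; descending fraction.
#' @export
hallmark_overlap <- function(identity_genes, collection) {
  identity_genes <- unique(identity_genes)
  if (length(identity_genes) == 0) abort("identity gene set is empty")
  out <- purrr::imap(collection, function(genes, nm) {
    n <- length(intersect(identity_genes, genes))
    tibble(set = nm, n_overlap = n,
           overlap_fraction = n / length(identity_genes))
  })
  dplyr::arrange(dplyr::bind_rows(out), dplyr::desc(.data$overlap_fraction),
                 .data$set)
}

#' Attribute differentially expressed genes to identities
#'
#' Splits a DEG list by direction and reports, per direction, the
#' proportion of genes falling into each identity's gene group; DEGs
#' outside the salient gene set count as `"other"`. Proportions sum to 1
#' within each direction.
#'
#' @param degs Tibble/data.frame with columns `gene` and `direction`
#'   (`"up"`/`"down"`).
#' @param gene_groups Named character vector, gene -> identity (from an
#'   `identity_model`).
#' @return Tibble: direction, identity, n, proportion.
#' @export
deg_identity_attribution <- function(degs, gene_groups) {
  degs <- tibble::as_tibble(degs)
  if (nrow(degs) == 0) {
    warn("empty DEG list")
    return(tibble(direction = character(), identity = character(),
                  n = integer(), proportion = numeric()))
  }
  degs$identity <- dplyr::coalesce(unname(gene_groups[degs$gene]), "other")
  degs |>
    dplyr::count(.data$direction, .data$identity, name = "n") |>
    dplyr::group_by(.data$direction) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Drug-class enrichment among differential drugs
#'
#' Flags each drug as "differential" when its BH-adjusted two-sided
#' rank-sum p-value (target samples vs the rest) falls below `alpha`,
#' then tests each drug class for enrichment of differential drugs with a
#' 2x2 chi-squared test (class membership x differential status, no
#' continuity correction), BH-adjusted across classes. Degenerate 2x2
#' tables with an empty margin (e.g. no differential drug at all) are
#' reported as chi2 = 0, p = 1.
#'
#' @param auc Drugs-by-samples numeric matrix.
#' @param drug_classes Named character vector, drug -> class.
#' @param target_samples Character vector of the sample group of interest
#'   (e.g. TNBC lines).
#' @param alpha Significance threshold on BH-adjusted drug p-values.
#' @return List with `drugs` (per-drug tibble: drug, class, statistic,
#'   p_value, p_adjusted, differential) and `classes` (per-class tibble:
#'   class, n_drugs, n_differential, chi2, p_value, p_adjusted).
#' @export
drug_class_enrichment <- function(auc, drug_classes, target_samples,
                                  alpha = 0.05) {
  stopifnot(is.matrix(auc), !is.null(rownames(auc)), !is.null(colnames(auc)))
  in_grp <- colnames(auc) %in% target_samples
  if (!any(in_grp) || all(in_grp)) {
    abort("both the target group and the rest must be nonempty")
  }
  drugs <- purrr::map_dfr(rownames(auc), function(d) {
    wt <- group_vs_rest_wilcoxon(auc[d, ], in_grp)
    tibble(drug = d, class = unname(drug_classes[d]),
           statistic = wt$statistic, p_value = wt$p_value)
  })
  drugs$p_adjusted <- adjust_bh(drugs$p_value)
  drugs$differential <- drugs$p_adjusted < alpha

  classes <- unique(stats::na.omit(drugs$class))
  small <- classes[vapply(classes, function(cl) sum(drugs$class == cl, na.rm = TRUE) < 2,
                          logical(1))]
  if (length(small)) {
    warn(sprintf("skipping class(es) with fewer than 2 drugs: %s",
                 paste(small, collapse = ", ")))
    classes <- setdiff(classes, small)
  }
  cls <- purrr::map_dfr(classes, function(cl) {
    in_cl <- !is.na(drugs$class) & drugs$class == cl
    tab <- matrix(c(sum(in_cl & drugs$differential),
                    sum(in_cl & !drugs$differential),
                    sum(!in_cl & drugs$differential),
                    sum(!in_cl & !drugs$differential)), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      chi2 <- 0; p <- 1
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      chi2 <- unname(ct$statistic); p <- unname(ct$p.value)
    }
    tibble(class = cl, n_drugs = sum(in_cl),
           n_differential = sum(in_cl & drugs$differential),
           chi2 = chi2, p_value = p)
  })
  cls$p_adjusted <- adjust_bh(cls$p_value)
  list(drugs = drugs, classes = dplyr::arrange(cls, .data$p_adjusted))
}
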