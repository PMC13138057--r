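# Internal helpers shared across modules.

# Validate a genes-x-columns expression matrix: numeric, finite,
# non-negative, unique dimnames.
validate_expression_matrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("%s must be a numeric matrix (genes in rows)", what))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort(sprintf("%s must carry rownames (genes) and colnames", what))
  }
  if (anyDuplicated(rownames(x))) abort(sprintf("%s has duplicate gene ids", what))
  if (anyDuplicated(colnames(x))) abort(sprintf("%s has duplicate column ids", what))
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1, ]
    abort(sprintf("%s has a missing value at gene '%s', column '%s'",
                  what, rownames(x)[idx[1]], colnames(x)[idx[2]]))
  }
  if (any(x < 0)) {
    idx <- which(x < 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "%s has a negative value (%.4g) at gene '%s', column '%s'; expression must be log-transformed and non-negative",
      what, x[idx[1], idx[2]], rownames(x)[idx[1]], colnames(x)[idx[2]]))
  }
  invisible(x)
}

#' Normalize gene identifiers for cross-dataset matching
#'
#' Uppercases identifiers and strips trailing version suffixes
#' (e.g. `ENSG00000136997.12` -> `ENSG00000136997`), the convention used when
#' harmonizing bulk-derived factor matrices with single-cell gene lists.
#'
#' @param ids Character vector of gene identifiers.
#' @return Character vector of normalized identifiers.
#' @export
#' @examples
#' normalize_gene_ids(c("myc", "ENSG00000136997.12"))
normalize_gene_ids <- function(ids) {
  sub("\\.[0-9]+$", "", toupper(ids))
}

# Population (ddof = 0) standard deviation.
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# z-score with population sd; constant vectors map to all zeros.
zscore_pop <- function(x) {
  s <- sd_pop(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Derive a 32-bit sub-seed from a base seed and a stage/op name, so one
# global seed fans out deterministically across pipeline stages.
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
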