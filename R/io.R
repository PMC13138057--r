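# Readers and writers for the external formats the pipeline touches:
# TSV/CSV expression tables, MatrixMarket single-cell bundles, GMT gene
# sets, and the JSON serialization of fitted identity models.

#' Read a bulk expression table (TSV or CSV)
#'
#' Reads a delimited genes-by-samples table of log-scale expression values
#' (e.g. log2(TPM+1)). The first column (or row, depending on
#' `orientation`) holds gene identifiers. Values must be non-negative with
#' no missing cells. Duplicate gene ids are collapsed by keeping the row
#' with the highest mean expression (reported via a message).
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` (comma) file with a
#'   header row.
#' @param orientation `"genes_in_rows"` (default) or `"genes_in_columns"`;
#'   the returned matrix always has genes in rows.
#' @return Numeric matrix, genes in rows, with dimnames.
#' @export
read_expression_tsv <- function(path,
                                orientation = c("genes_in_rows", "genes_in_columns")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, locale = readr::locale(decimal_mark = "."))
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (orientation == "genes_in_columns") {
    m <- t(m)
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort(sprintf("missing value at gene '%s', sample '%s' in %s",
                  rownames(m)[idx[1]], colnames(m)[idx[2]], path))
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative value at gene '%s', sample '%s' in %s; expected log-transformed non-negative expression",
                  rownames(m)[idx[1]], colnames(m)[idx[2]], path))
  }
  if (anyDuplicated(rownames(m))) {
    first_seen <- unique(rownames(m))
    ord <- order(-rowMeans(m))
    m2 <- m[ord, , drop = FALSE]
    m2 <- m2[!duplicated(rownames(m2)), , drop = FALSE]
    m <- m2[match(first_seen, rownames(m2)), , drop = FALSE]
    inform(sprintf("collapsed duplicate gene ids in %s by keeping the highest-mean row", path))
  }
  validate_expression_matrix(m)
  m
}

#' Write an expression matrix as TSV
#'
#' @param x Genes-by-columns numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Name for the gene-id column.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path, id_col = "gene") {
  df <- tibble::as_tibble(x, rownames = id_col)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a MatrixMarket single-cell bundle
#'
#' Reads the standard single-cell triplet export: a MatrixMarket coordinate
#' file plus a features file (gene ids in the first column) and a barcodes
#' file (one barcode per line). Zero entries are implicit.
#'
#' @param matrix_path Path to the `.mtx` file.
#' @param features_path Path to `features.tsv` (first column = gene id).
#' @param barcodes_path Path to `barcodes.tsv`.
#' @return A sparse `dgCMatrix`, genes in rows, cells in columns.
#' @export
read_mtx_bundle <- function(matrix_path, features_path, barcodes_path) {
  m <- Matrix::readMM(matrix_path)
  feats <- readr::read_tsv(features_path, col_names = FALSE,
                           show_col_types = FALSE, progress = FALSE)[[1]]
  bcs <- readr::read_tsv(barcodes_path, col_names = FALSE,
                         show_col_types = FALSE, progress = FALSE)[[1]]
  if (nrow(m) != length(feats)) {
    abort(sprintf("matrix has %d rows but features file lists %d genes",
                  nrow(m), length(feats)))
  }
  if (ncol(m) != length(bcs)) {
    abort(sprintf("matrix has %d columns but barcodes file lists %d cells",
                  ncol(m), length(bcs)))
  }
  m <- methods::as(methods::as(m, "CsparseMatrix"), "dMatrix")
  dimnames(m) <- list(as.character(feats), as.character(bcs))
  m
}

#' Write a MatrixMarket single-cell bundle
#'
#' @param x Genes-by-cells matrix (dense or sparse) with dimnames.
#' @param dir Output directory (created if missing); writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`.
#' @return The directory path, invisibly.
#' @export
write_mtx_bundle <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sm <- methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(sm, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x), file.path(dir, "features.tsv"))
  writeLines(colnames(x), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a GMT gene-set file
#'
#' Each line holds: set name, description (discarded), then one gene per
#' field. Duplicate genes within a set are deduplicated; duplicate set
#' names are an error.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors (gene ids per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    abort(sprintf("GMT line %d has fewer than 3 tab-separated fields", bad[1]))
  }
  names_ <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names_)) {
    abort(sprintf("duplicate gene-set name '%s' in %s",
                  names_[duplicated(names_)][1], path))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- names_
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("sets must be a uniquely named list")
  }
  desc <- descriptions %||% rep("na", length(sets))
  lines <- mapply(function(nm, d, genes) {
    paste(c(nm, d, genes), collapse = "\t")
  }, names(sets), desc, sets)
  writeLines(lines, path)
  invisible(path)
}

MODEL_SCHEMA_VERSION <- "1.0"

#' Serialize a fitted identity model to JSON
#'
#' Writes the factor matrices and derived labels of an [identity_model] as
#' a single JSON document with full float precision, so that
#' `read_identity_model(write_identity_model(m, p))` restores the model
#' bit-comparably.
#'
#' @param model An `identity_model` (see [fit_identity_model()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_identity_model <- function(model, path) {
  stopifnot(inherits(model, "identity_model"))
  if (nrow(model$W) == 0) abort("refusing to serialize a model with 0 genes")
  doc <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    k = model$k,
    genes = rownames(model$W),
    samples = colnames(model$H),
    factors = colnames(model$W),
    W = unname(model$W),
    H = unname(model$H),
    recon_err_by_k = as.list(model$recon_err_by_k),
    sample_labels = as.list(model$sample_labels),
    gene_groups = as.list(model$gene_groups),
    H_zscores = unname(model$H_zscores)
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a fitted identity model from JSON
#'
#' @param path Path written by [write_identity_model()].
#' @return An `identity_model`.
#' @export
read_identity_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema_version, MODEL_SCHEMA_VERSION)) {
    abort(sprintf("model schema version '%s' does not match expected '%s'",
                  doc$schema_version %||% "<missing>", MODEL_SCHEMA_VERSION))
  }
  as_mat <- function(obj, nr, dn) {
    m <- if (is.matrix(obj)) obj else matrix(unlist(obj), nrow = nr, byrow = TRUE)
    dimnames(m) <- dn
    m
  }
  W <- as_mat(doc$W, length(doc$genes), list(doc$genes, doc$factors))
  H <- as_mat(doc$H, doc$k, list(doc$factors, doc$samples))
  Hz <- as_mat(doc$H_zscores, doc$k, list(doc$factors, doc$samples))
  new_identity_model(
    W = W, H = H, k = as.integer(doc$k),
    recon_err_by_k = unlist(doc$recon_err_by_k),
    sample_labels = unlist(doc$sample_labels),
    gene_groups = unlist(doc$gene_groups),
    H_zscores = Hz
  )
}
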