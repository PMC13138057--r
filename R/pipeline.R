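# End-to-end orchestration: a single validated configuration drives
# select-genes -> fit -> map -> shift -> associate -> tf-link, with
# deterministic per-stage seeding and provenance JSON next to every
# output.

PIPELINE_STAGES <- c("select", "fit", "map", "shift", "associate", "tf_link")

CONFIG_KEYS <- c(
  "seed", "outdir", "stages",
  "bulk_expr", "orientation", "anchor_gene", "selection_mode",
  "basal_samples", "min_samples",
  "k_grid", "n_restarts", "mixture_margin",
  "sc_matrix", "sc_features", "sc_barcodes", "cell_meta",
  "control", "treated",
  "drug_auc", "hallmark_gmt",
  "tf_accessibility", "tf_expr", "tf_cell_meta", "tf_targets_gmt",
  "pathway_genes", "tf_treatments"
)

#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or a named list; checks that every key is
#' known, that requested stages exist, and that the inputs required by
#' each enabled stage are present, before any computation starts.
#'
#' @param config Path to a YAML file or a named list.
#' @return The validated config list (with defaults filled in).
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), CONFIG_KEYS)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$outdir <- config$outdir %||% "idmapr_run"
  config$stages <- config$stages %||% PIPELINE_STAGES
  bad <- setdiff(config$stages, PIPELINE_STAGES)
  if (length(bad)) {
    abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  config$orientation <- config$orientation %||% "genes_in_rows"
  config$anchor_gene <- config$anchor_gene %||% "MYC"
  config$selection_mode <- config$selection_mode %||% "cell_line"
  config$k_grid <- config$k_grid %||% c(4L, 9L)
  config$n_restarts <- config$n_restarts %||% 10L
  config$mixture_margin <- config$mixture_margin %||% 0.10

  need <- function(keys, stage) {
    miss <- keys[vapply(keys, function(k) is.null(config[[k]]), logical(1))]
    if (length(miss)) {
      abort(sprintf("stage '%s' requires config key(s): %s", stage,
                    paste(miss, collapse = ", ")))
    }
  }
  if ("select" %in% config$stages) need("bulk_expr", "select")
  if ("fit" %in% config$stages) need("bulk_expr", "fit")
  if ("map" %in% config$stages) {
    need(c("sc_matrix", "sc_features", "sc_barcodes"), "map")
  }
  if ("shift" %in% config$stages) need(c("control", "treated"), "shift")
  if ("associate" %in% config$stages) need("drug_auc", "associate")
  if ("tf_link" %in% config$stages) {
    need(c("tf_accessibility", "tf_expr", "tf_cell_meta", "tf_targets_gmt",
           "control"), "tf_link")
  }
  config
}

write_provenance <- function(dir, stage, config, seed) {
  prov <- list(
    stage = stage,
    seed = seed,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("idmapr")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(prov, file.path(dir, sprintf("%s.provenance.json", stage)),
                       auto_unbox = TRUE)
}

#' Run the identity pipeline end to end
#'
#' Executes the enabled stages in order, writing TSV outputs and a
#' provenance JSON per stage under `config$outdir`. Later stages consume
#' earlier stages' in-memory results when run together, or reload them
#' from the output directory when resumed. Any stage error aborts with
#' the stage name.
#'
#' @param config Path to a YAML file or a named list; see
#'   [validate_run_config()].
#' @return Invisibly, a list of stage results (`salient`, `model`,
#'   `cells`, `shift`, `associations`, `tf_table`).
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  stage <- function(name, fn) {
    if (!name %in% config$stages) return(NULL)
    inform(sprintf("[%s] starting", name))
    out <- tryCatch(fn(derive_seed(config$seed, name)), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    write_provenance(config$outdir, name, config, derive_seed(config$seed, name))
    inform(sprintf("[%s] done", name))
    out
  }

  bulk <- NULL
  get_bulk <- function() {
    if (is.null(bulk)) {
      bulk <<- read_expression_tsv(config$bulk_expr, config$orientation)
    }
    bulk
  }

  res$salient <- stage("select", function(seed) {
    cfg <- gene_selection_config(mode = config$selection_mode,
                                 anchor_gene = config$anchor_gene,
                                 min_samples = config$min_samples %||% 3)
    sal <- select_salient_genes(get_bulk(), cfg,
                                basal_samples = config$basal_samples)
    readr::write_tsv(sal, file.path(config$outdir, "salient_genes.tsv"),
                     progress = FALSE)
    sal
  })

  res$model <- stage("fit", function(seed) {
    genes <- if (!is.null(res$salient)) res$salient$gene else NULL
    kg <- config$k_grid
    model <- fit_identity_model(get_bulk(), genes = genes,
                                k_grid = seq(kg[1], kg[2]),
                                n_restarts = config$n_restarts,
                                seed = seed,
                                mixture_margin = config$mixture_margin)
    write_identity_model(model, file.path(config$outdir, "model.json"))
    readr::write_tsv(tidy(model, "samples"),
                     file.path(config$outdir, "sample_labels.tsv"),
                     progress = FALSE)
    readr::write_tsv(tidy(model, "genes"),
                     file.path(config$outdir, "gene_groups.tsv"),
                     progress = FALSE)
    readr::write_tsv(tibble(k = names(model$recon_err_by_k),
                            recon_err = unname(model$recon_err_by_k)),
                     file.path(config$outdir, "recon_err.tsv"),
                     progress = FALSE)
    model
  })

  get_model <- function() {
    res$model %||% read_identity_model(file.path(config$outdir, "model.json"))
  }

  res$cells <- stage("map", function(seed) {
    counts <- read_mtx_bundle(config$sc_matrix, config$sc_features,
                              config$sc_barcodes)
    meta <- if (!is.null(config$cell_meta)) {
      readr::read_tsv(config$cell_meta, show_col_types = FALSE, progress = FALSE)
    } else NULL
    cells <- map_cells(normalize_cells(counts), get_model(), cell_meta = meta)
    readr::write_tsv(cells, file.path(config$outdir, "cells.tsv"),
                     progress = FALSE)
    cells
  })

  get_cells <- function() {
    res$cells %||% {
      cells <- readr::read_tsv(file.path(config$outdir, "cells.tsv"),
                               show_col_types = FALSE, progress = FALSE)
      class(cells) <- c("cell_profiles", class(cells))
      cells
    }
  }

  res$shift <- stage("shift", function(seed) {
    cells <- get_cells()
    sr <- identity_shift(cells, config$control, config$treated)
    readr::write_tsv(tidy(sr), file.path(config$outdir, "shift.tsv"),
                     progress = FALSE)
    jsonlite::write_json(glance(sr), file.path(config$outdir, "shift_stats.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    contrib <- tryCatch(
      cluster_contributions(cells, sr$most_expanded, config$control,
                            config$treated),
      error = function(e) {
        inform(sprintf("cluster contributions skipped: %s", conditionMessage(e)))
        NULL
      })
    if (!is.null(contrib)) {
      readr::write_tsv(contrib, file.path(config$outdir, "cluster_shift.tsv"),
                       progress = FALSE)
    }
    sr
  })

  res$associations <- stage("associate", function(seed) {
    model <- get_model()
    auc_df <- readr::read_tsv(config$drug_auc, show_col_types = FALSE,
                              progress = FALSE)
    auc <- as.matrix(auc_df[, -1])
    rownames(auc) <- auc_df[[1]]
    out <- purrr::map_dfr(rownames(auc), function(d) {
      purrr::map_dfr(rownames(model$H_zscores), function(f) {
        r <- identity_drug_correlation(model$H_zscores[f, ], auc[d, ])
        dplyr::mutate(r, kind = "auc_correlation", feature = d, factor = f,
                      .before = 1)
      })
    })
    out <- out |>
      dplyr::group_by(.data$factor) |>
      dplyr::mutate(p_adjusted = adjust_bh(.data$p_value)) |>
      dplyr::ungroup()
    if (!is.null(config$hallmark_gmt)) {
      hm <- read_gmt(config$hallmark_gmt)
      groups <- split(names(model$gene_groups), model$gene_groups)
      ov <- purrr::imap_dfr(groups, function(genes, id) {
        dplyr::mutate(hallmark_overlap(genes, hm), kind = "overlap",
                      factor = id, .before = 1)
      })
      readr::write_tsv(ov, file.path(config$outdir, "hallmark_overlap.tsv"),
                       progress = FALSE)
    }
    readr::write_tsv(out, file.path(config$outdir, "associations.tsv"),
                     progress = FALSE)
    out
  })

  res$tf_table <- stage("tf_link", function(seed) {
    acc_df <- readr::read_tsv(config$tf_accessibility, show_col_types = FALSE,
                              progress = FALSE)
    acc <- as.matrix(acc_df[, -1])
    rownames(acc) <- acc_df[[1]]
    targets <- read_gmt(config$tf_targets_gmt)
    pathway <- config$pathway_genes %||% unique(unlist(targets))
    meta <- readr::read_tsv(config$tf_cell_meta, show_col_types = FALSE,
                            progress = FALSE)
    expr <- read_expression_tsv(config$tf_expr)
    tab <- tf_relevance_table(acc, expr, targets, pathway,
                              meta, control = config$control,
                              treatments = config$tf_treatments, seed = seed)
    readr::write_tsv(tab, file.path(config$outdir, "tf_table.tsv"),
                     progress = FALSE)
    tab
  })

  invisible(res)
}
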