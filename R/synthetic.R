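# Seeded synthetic-data generators. They plant the statistical structure
# the pipeline assumes -- bulk samples as non-negative mixtures of k latent
# gene programs, single cells as noisy mixtures with condition-dependent
# composition, drug AUC linearly coupled to one program, and per-cell motif
# accessibility linearly coupled to target gene-set expression -- so every
# downstream stage has a parameter-recovery test surface.

#' Simulate bulk expression with planted gene programs
#'
#' Builds a non-negative gene-program matrix `W_true` in which each of
#' `k_true` programs owns a disjoint block of marker genes (log-scale
#' on-levels drawn from U(4, 8) over a U(0, 0.3) baseline, so markers clear
#' the absolute distance thresholds used in salient-gene selection the way
#' strong markers do in real log2(TPM+1) data), plus a pool of flat
#' "noise" genes with no program structure. A fraction `program_overlap` of
#' each block is shared with the next program at half weight. Samples carry
#' a planted identity (balanced across programs); expression is
#' `pmax(W_true %*% weights + N(0, noise_sd), 0)`. The anchor gene is
#' inserted as an extra marker of the heaviest program, making it bimodal
#' across samples. Programs are named `F0..F(k-1)` by descending total
#' marker-block weight.
#'
#' The returned truth object also fixes the study conditions used by the
#' companion generators: two conditions (`control` with a uniform identity
#' composition, `treated` with `shift_delta` extra mass on
#' `shift_identity`), a designated drug coupled to program F0, and a
#' TF whose motif accessibility predicts target expression under the
#' treated condition only.
#'
#' @param n_genes Total genes (>= 10 * k_true).
#' @param n_samples Bulk samples.
#' @param k_true Number of planted programs (>= 2).
#' @param program_overlap Fraction of each marker block shared with the
#'   next program.
#' @param noise_sd Gaussian noise SD on the log scale.
#' @param anchor_gene Name given to the anchor marker gene.
#' @param shift_delta Extra composition mass on `shift_identity` in the
#'   treated condition.
#' @param shift_identity Identity receiving the planted expansion.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A list with `expr` (genes x samples matrix) and `truth`
#'   (a `synthetic_truth` list: `k_true`, `W_true`, `sample_weights`,
#'   `sample_identities`, `marker_blocks`, `condition_compositions`,
#'   `anchor_gene`, `drug_effect`, `tf_effect`, `seed`).
#' @export
simulate_bulk <- function(n_genes = 400, n_samples = 40, k_true = 4,
                          program_overlap = 0.1, noise_sd = 0.3,
                          anchor_gene = "MYC", shift_delta = 0.15,
                          shift_identity = "F0", seed = 1) {
  if (k_true < 2) abort("k_true must be >= 2")
  if (n_genes < 10 * k_true) abort("n_genes must be at least 10 * k_true")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  withr::with_seed(derive_seed(seed, "bulk"), {
    block_size <- floor(n_genes * 0.5 / k_true)
    gene_ids <- sprintf("G%04d", seq_len(n_genes))
    W <- matrix(runif(n_genes * k_true, 0, 0.3), n_genes, k_true)
    blocks <- vector("list", k_true)
    for (j in seq_len(k_true)) {
      rows <- (j - 1) * block_size + seq_len(block_size)
      blocks[[j]] <- rows
      W[rows, j] <- runif(block_size, 4, 8)
      n_shared <- round(program_overlap * block_size)
      if (n_shared > 0) {
        nxt <- if (j == k_true) 1L else j + 1L
        W[rows[seq_len(n_shared)], nxt] <- W[rows[seq_len(n_shared)], j] * 0.5
      }
    }
    # canonical program order: descending total marker-block weight
    block_mass <- vapply(seq_len(k_true), function(j) sum(W[blocks[[j]], j]),
                         numeric(1))
    ord <- order(-block_mass)
    W <- W[, ord, drop = FALSE]
    blocks <- blocks[ord]
    factor_names <- paste0("F", seq_len(k_true) - 1)
    colnames(W) <- factor_names

    # anchor gene: an extra strong marker of F0
    anchor_row <- matrix(runif(k_true, 0, 0.3), 1, k_true)
    anchor_row[1, 1] <- runif(1, 6, 8)
    W <- rbind(W, anchor_row)
    gene_ids <- c(gene_ids, anchor_gene)
    rownames(W) <- gene_ids
    blocks <- lapply(blocks, function(b) gene_ids[b])
    blocks[[1]] <- c(blocks[[1]], anchor_gene)
    names(blocks) <- factor_names

    sample_ids <- sprintf("S%03d", seq_len(n_samples))
    sample_identities <- factor_names[(seq_len(n_samples) - 1) %% k_true + 1]
    names(sample_identities) <- sample_ids
    S <- matrix(runif(k_true * n_samples, 0, 0.05), k_true, n_samples,
                dimnames = list(factor_names, sample_ids))
    for (i in seq_len(n_samples)) {
      S[sample_identities[i], i] <- runif(1, 0.9, 1.1)
    }
    X <- W %*% S + matrix(rnorm(length(W %*% S), 0, noise_sd),
                          nrow(W), n_samples)
    X <- pmax(X, 0)
    dimnames(X) <- list(gene_ids, sample_ids)

    if (!shift_identity %in% factor_names) {
      abort(sprintf("shift_identity '%s' is not one of %s", shift_identity,
                    paste(factor_names, collapse = ", ")))
    }
    comp_control <- stats::setNames(rep(1 / k_true, k_true), factor_names)
    comp_treated <- comp_control - shift_delta / (k_true - 1)
    comp_treated[shift_identity] <- comp_control[shift_identity] + shift_delta
    truth <- structure(list(
      k_true = as.integer(k_true),
      W_true = W,
      sample_weights = S,
      sample_identities = sample_identities,
      marker_blocks = blocks,
      condition_compositions = list(control = comp_control,
                                    treated = comp_treated),
      anchor_gene = anchor_gene,
      drug_effect = list(factor = "F0", slope = -1, noise_sd = 0.5,
                         intercept = 10),
      tf_effect = list(control = list(slope = 0, noise_sd = 1,
                                      accessibility_mean = 0),
                       treated = list(slope = 1, noise_sd = 1,
                                      accessibility_mean = 1)),
      seed = as.integer(seed)
    ), class = "synthetic_truth")
    list(expr = X, truth = truth)
  })
}

#' Simulate single cells as mixtures of planted programs
#'
#' Each cell draws its identity from its condition's composition
#' (recorded in `truth$condition_compositions`), perturbs the identity's
#' normalized `W_true` column with a Dirichlet draw (per-gene concentration
#' `mixture_alpha`, so larger values give tighter cells), scales to `depth`
#' expected counts, Poisson-samples, and is returned as raw counts together
#' with per-cell metadata. The planted identity string doubles as the
#' cluster label.
#'
#' @param truth A `synthetic_truth` from [simulate_bulk()].
#' @param n_cells_per_condition Named integer vector, condition -> cells.
#' @param mixture_alpha Dirichlet concentration per gene (larger = purer).
#' @param depth Expected total counts per cell.
#' @param seed Integer seed.
#' @return List with `counts` (genes x cells matrix) and `cell_meta`
#'   (tibble: cell_id, condition, cluster, identity_true).
#' @export
simulate_single_cells <- function(truth,
                                  n_cells_per_condition = c(control = 500, treated = 500),
                                  mixture_alpha = 50, depth = 2000, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (depth <= 0) abort("depth must be > 0")
  conds <- names(n_cells_per_condition)
  unknown <- setdiff(conds, names(truth$condition_compositions))
  if (length(unknown)) {
    abort(sprintf("condition '%s' has no composition in truth", unknown[1]))
  }
  withr::with_seed(derive_seed(seed, "cells"), {
    W <- truth$W_true
    G <- nrow(W)
    P <- apply(W, 2, function(w) w / sum(w))
    counts_list <- list()
    meta_list <- list()
    for (cond in conds) {
      n <- n_cells_per_condition[[cond]]
      comp <- truth$condition_compositions[[cond]]
      ids <- sample(names(comp), n, replace = TRUE, prob = comp)
      cc <- matrix(0L, G, n)
      for (i in seq_len(n)) {
        conc <- mixture_alpha * G * P[, ids[i]]
        g <- rgamma(G, shape = conc, rate = 1)
        p <- if (sum(g) > 0) g / sum(g) else P[, ids[i]]
        cc[, i] <- rpois(G, depth * p)
      }
      colnames(cc) <- sprintf("%s_c%04d", cond, seq_len(n))
      counts_list[[cond]] <- cc
      meta_list[[cond]] <- tibble(cell_id = colnames(cc), condition = cond,
                                  cluster = ids, identity_true = ids)
    }
    counts <- do.call(cbind, counts_list)
    rownames(counts) <- rownames(W)
    list(counts = counts, cell_meta = dplyr::bind_rows(meta_list))
  })
}

#' Simulate a drug-response AUC table
#'
#' One designated drug's AUC is linearly coupled to the z-scored planted
#' weight of the program named in `truth$drug_effect$factor`
#' (`AUC = intercept + slope * z + N(0, noise_sd)`); all other drugs are
#' pure noise on the same scale.
#'
#' @param truth A `synthetic_truth`.
#' @param n_drugs Total drugs, including the designated one (`D001`).
#' @param seed Integer seed.
#' @return List with `auc` (drugs x samples matrix) and `designated_drug`.
#' @export
simulate_drug_auc <- function(truth, n_drugs = 30, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  eff <- truth$drug_effect
  withr::with_seed(derive_seed(seed, "drugs"), {
    samples <- colnames(truth$sample_weights)
    n <- length(samples)
    z <- zscore_pop(truth$sample_weights[eff$factor, ])
    auc <- matrix(rnorm(n_drugs * n, eff$intercept, 1), n_drugs, n,
                  dimnames = list(sprintf("D%03d", seq_len(n_drugs)), samples))
    auc[1, ] <- eff$intercept + eff$slope * z + rnorm(n, 0, eff$noise_sd)
    list(auc = auc, designated_drug = "D001")
  })
}

#' Simulate paired motif-accessibility / target-expression single cells
#'
#' One planted TF and `n_decoys` decoy TFs get per-cell motif
#' accessibility `a ~ N(condition mean, 1)`. Each TF owns `n_targets`
#' target genes whose expression is `baseline + slope_cond * a + e + jitter`,
#' where `e ~ N(0, noise_sd)` is shared across the TF's targets within a
#' cell (pathway-level noise) and the per-gene jitter SD is 0.05. The
#' shared-noise design keeps the closed form
#' `R^2 = slope^2 var(a) / (slope^2 var(a) + noise_sd^2)` exact for the
#' target-set mean. Decoy TFs have slope 0 in every condition. Background
#' genes with flat expression are included so module scoring has a control
#' pool.
#'
#' @param truth A `synthetic_truth` (uses `truth$tf_effect`, a per-condition
#'   list of `slope`, `noise_sd`, `accessibility_mean` for the planted TF).
#' @param n_cells Named integer vector, condition -> cells.
#' @param n_decoys Number of decoy TFs.
#' @param n_targets Target genes per TF.
#' @param n_background Flat background genes.
#' @param baseline Baseline log-scale expression of target genes.
#' @param seed Integer seed.
#' @return List with `accessibility` (TF x cells matrix), `expr` (genes x
#'   cells matrix, non-negative), `cell_meta` (tibble: cell_id, condition),
#'   `targets` (named list TF -> target genes), `pathway_genes` (the planted
#'   TF's targets) and `planted_tf`.
#' @export
simulate_tf_multiome <- function(truth,
                                 n_cells = c(control = 5000, treated = 5000),
                                 n_decoys = 20, n_targets = 3,
                                 n_background = 60, baseline = 10,
                                 seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  conds <- names(n_cells)
  missing_c <- setdiff(conds, names(truth$tf_effect))
  if (length(missing_c)) {
    abort(sprintf("condition '%s' missing from truth$tf_effect", missing_c[1]))
  }
  withr::with_seed(derive_seed(seed, "multiome"), {
    tfs <- c("TF_PLANTED", sprintf("TF_DECOY%02d", seq_len(n_decoys)))
    targets <- lapply(tfs, function(tf) sprintf("TG_%s_%d", tf, seq_len(n_targets)))
    names(targets) <- tfs
    cell_ids <- unlist(lapply(conds, function(cond) {
      sprintf("%s_m%05d", cond, seq_len(n_cells[[cond]]))
    }))
    cond_of <- rep(conds, times = n_cells[conds])
    n_total <- length(cell_ids)

    acc <- matrix(rnorm(length(tfs) * n_total), length(tfs), n_total,
                  dimnames = list(tfs, cell_ids))
    genes <- c(unlist(targets), sprintf("BG%03d", seq_len(n_background)))
    expr <- matrix(0, length(genes), n_total, dimnames = list(genes, cell_ids))
    expr[grep("^BG", genes), ] <- baseline +
      rnorm(n_background * n_total, 0, 0.1)

    for (cond in conds) {
      eff <- truth$tf_effect[[cond]]
      idx <- which(cond_of == cond)
      acc["TF_PLANTED", idx] <- acc["TF_PLANTED", idx] + eff$accessibility_mean
      for (tf in tfs) {
        slope <- if (tf == "TF_PLANTED") eff$slope else 0
        shared <- rnorm(length(idx), 0, eff$noise_sd)
        for (g in targets[[tf]]) {
          expr[g, idx] <- baseline + slope * acc[tf, idx] + shared +
            rnorm(length(idx), 0, 0.05)
        }
      }
    }
    expr <- pmax(expr, 0)
    list(accessibility = acc, expr = expr,
         cell_meta = tibble(cell_id = cell_ids, condition = cond_of),
         targets = targets, pathway_genes = targets[["TF_PLANTED"]],
         planted_tf = "TF_PLANTED")
  })
}

#' Write a complete synthetic fixture bundle to a directory
#'
#' Generates the bulk matrix, the single-cell MTX bundle, the drug AUC
#' table, the motif-accessibility table and the ground-truth JSON with one
#' call, for use as pipeline input.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param ... Passed to [simulate_bulk()].
#' @return Invisibly, a list of the generated objects.
#' @export
simulate_fixture_bundle <- function(dir, seed = 1, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bulk <- simulate_bulk(seed = seed, ...)
  sc <- simulate_single_cells(bulk$truth, seed = seed)
  drugs <- simulate_drug_auc(bulk$truth, seed = seed)
  mo <- simulate_tf_multiome(bulk$truth,
                             n_cells = c(control = 1000, treated = 1000),
                             seed = seed)
  write_expression_tsv(bulk$expr, file.path(dir, "bulk.tsv"))
  write_mtx_bundle(sc$counts, file.path(dir, "sc"))
  readr::write_tsv(sc$cell_meta, file.path(dir, "cell_meta.tsv"), progress = FALSE)
  readr::write_tsv(tibble::as_tibble(drugs$auc, rownames = "drug"),
                   file.path(dir, "drug_auc.tsv"), progress = FALSE)
  # motif accessibility is a signed deviation score, not expression
  readr::write_tsv(tibble::as_tibble(mo$accessibility, rownames = "tf"),
                   file.path(dir, "accessibility.tsv"), progress = FALSE)
  write_expression_tsv(mo$expr, file.path(dir, "multiome_expr.tsv"))
  readr::write_tsv(mo$cell_meta, file.path(dir, "multiome_cell_meta.tsv"),
                   progress = FALSE)
  write_gmt(mo$targets, file.path(dir, "tf_targets.gmt"))
  truth <- bulk$truth
  jsonlite::write_json(
    list(seed = seed, k_true = truth$k_true,
         sample_identities = as.list(truth$sample_identities),
         condition_compositions = truth$condition_compositions,
         anchor_gene = truth$anchor_gene),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(list(bulk = bulk, sc = sc, drugs = drugs, multiome = mo))
}
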