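#' Pipeline configuration
#'
#' Per-stage parameter blocks for [run_pipeline()].  Defaults follow the
#' pipeline's standard settings: support thresholds 10 cells / 10 reads;
#' 10 partitions at 70% training; factorization rank 500 with at most 15
#' active modules per cell and dictionary penalty 0.1; screening at
#' adjusted p < 0.01 with 1000 permutations and a 0.1 correlation gate;
#' core-gene cap 1000 (Z from 1.0 in steps of 0.05); stability at 0.80
#' recurrence with a 0.75 fallback below 5 stable modules.
#'
#' @param ... named overrides of the nested defaults, e.g.
#'   `smaf = list(d = 30)` (unnamed entries of a block fall back to the
#'   defaults).
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    celltype_col = "cell_type", label_col = "diagnosis",
    donor_col = "donor", seed = 1,
    siteqc = list(min_cells = 10, min_reads = 10),
    smaf = list(n_repeats = 10, train_fraction = 0.7, d = 500, k = 15,
                lambda_u = 0.1, max_iter = 100, tol = 1e-5),
    screen = list(alpha = 0.01, n_perm = 1000, rho_min = 0.1),
    refine = list(z_init = 1.0, step = 0.05, max_genes = 1000,
                  threshold = 0.80, fallback = 0.75,
                  fallback_min_modules = 5),
    enrich = list(alpha = 0.05, sets = NULL),
    diffapa = list(alpha = 0.05, run = TRUE),
    predict = list(run = TRUE, ratio = 0.7))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(defaults[[nm]]) && is.list(over[[nm]]))
      defaults[[nm]] <- utils::modifyList(defaults[[nm]], over[[nm]])
    else defaults[[nm]] <- over[[nm]]
  }
  structure(defaults, class = "pipeline_config")
}

sanitize_celltype <- function(x) gsub("[/ ]", "-", x)

derive_seed <- function(seed, ...) {
  s <- seed
  for (o in list(...)) s <- (s * 31L + as.integer(o)) %% 2147480017L
  as.integer(s)
}

#' Run the module-discovery pipeline per cell type
#'
#' Chains the stages for every cell type found in the cell metadata:
#' RUD matrix construction from the (already QC'd) site table, repeated
#' 70/30 partitioning, sparse module-activity factorization per
#' training set, combined phenotype screening of module activities,
#' core-gene selection for passing modules, cross-partition stability
#' filtering, optional enrichment gating against supplied gene sets,
#' differential APA within stable modules, and a donor-aware boosted
#' classifier on the union of stable core genes.  Module ids follow the
#' `celltype_partition_module` convention ("L2-3_1_4" = module 4 of
#' partition 1 in cell type L2/3; "/" is sanitized to "-" in ids and
#' file names, with the mapping recorded in the manifest).
#'
#' All randomness derives from `config$seed`, so a rerun with the same
#' configuration reproduces identical module gene sets and accuracies.
#'
#' @param sites a QC'd `site_table` (see [site_qc()]); cell metadata
#'   must contain the configured cell-type, label and donor columns.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; stage outputs (TSV / GMT)
#'   and a JSON provenance manifest are written there.
#' @return named list per cell type: `screen` (per-partition screen
#'   results), `records` (stability table), `stable_sets`,
#'   `enrichment`, `diffapa`, `prediction`, plus a top-level `manifest`.
#' @export
run_pipeline <- function(sites, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(sites, "site_table"),
            inherits(config, "pipeline_config"))
  for (col in c(config$celltype_col, config$label_col, config$donor_col))
    if (!col %in% names(sites$cells))
      stop("run_pipeline: metadata column '", col, "' not found")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  rud <- stage("rud", build_rud_matrix(sites))
  celltypes <- sort(unique(sites$cells[[config$celltype_col]]))
  results <- list()
  manifest <- list(tool = "apamod",
                   version = as.character(utils::packageVersion("apamod")),
                   seed = config$seed,
                   param_hash = param_hash(unclass(config)),
                   celltype_map = stats::setNames(
                     sanitize_celltype(celltypes), celltypes),
                   stages = character(0))

  for (ct in celltypes) {
    ct_id <- sanitize_celltype(ct)
    log_msg("pipeline", "INFO", "cell type ", ct, ": start")
    cells_ct <- sites$cells[sites$cells[[config$celltype_col]] == ct, ,
                            drop = FALSE]
    X_ct <- rud$values[, cells_ct$cell_id, drop = FALSE]
    X_ct <- X_ct[rowSums(!is.na(X_ct)) > 0, , drop = FALSE]
    labels_ct <- stats::setNames(cells_ct[[config$label_col]],
                                 cells_ct$cell_id)

    parts <- stage("partition", make_partitions(
      cells_ct, config$smaf$n_repeats, config$smaf$train_fraction,
      seed = derive_seed(config$seed, match(ct, celltypes))))

    screens <- list()
    mods_by_block <- vector("list", length(parts))
    u_cols <- list()
    for (i in seq_along(parts)) {
      tr <- parts[[i]]$train
      Xtr <- X_ct[, tr, drop = FALSE]
      Xtr <- Xtr[rowSums(!is.na(Xtr)) > 0, , drop = FALSE]
      keep_cells <- colSums(!is.na(Xtr)) > 0
      Xtr <- Xtr[, keep_cells, drop = FALSE]
      fit <- stage("smaf", fit_smaf(
        Xtr, d = min(config$smaf$d, nrow(Xtr), ncol(Xtr)),
        k = config$smaf$k, lambda_u = config$smaf$lambda_u,
        max_iter = config$smaf$max_iter, tol = config$smaf$tol,
        seed = derive_seed(config$seed, match(ct, celltypes), i)))
      scr <- stage("screen", combined_screen(
        fit$W, labels_ct[colnames(Xtr)], alpha = config$screen$alpha,
        n_perm = config$screen$n_perm, rho_min = config$screen$rho_min,
        seed = derive_seed(config$seed, match(ct, celltypes), i, 2L)))
      scr$partition <- i
      screens[[i]] <- scr
      passing <- scr$module_id[scr$passed]
      block_mods <- list()
      for (m in passing) {
        core <- stage("refine", select_core_genes(
          fit$U[, m], z_init = config$refine$z_init,
          step = config$refine$step, max_genes = config$refine$max_genes))
        if (length(core$genes) == 0) next
        id <- sprintf("%s_%d_%s", ct_id, i, sub("^m", "", m))
        block_mods[[id]] <- core$genes
        u_cols[[id]] <- fit$U[, m]
      }
      mods_by_block[[i]] <- block_mods
    }
    screen_all <- do.call(rbind, screens)

    n_mod_blocks <- sum(vapply(mods_by_block, length, 0L) > 0)
    records <- NULL
    stable_sets <- list()
    if (n_mod_blocks >= 2) {
      records <- stage("stability", stability_filter(
        mods_by_block, threshold = config$refine$threshold,
        fallback = config$refine$fallback,
        fallback_min_modules = config$refine$fallback_min_modules))
      stable_sets <- attr(records, "stable_sets")
    } else {
      log_msg("pipeline", "WARN", ct,
              ": fewer than 2 partitions yielded modules; no stability")
    }

    enr <- NULL
    if (!is.null(config$enrich$sets) && length(stable_sets) > 0) {
      enr <- stage("enrich", enrich_modules(
        stable_sets, config$enrich$sets, universe = rownames(X_ct),
        alpha = config$enrich$alpha))
      flags <- attr(enr, "flags")
      gated <- flags$module_id[flags$any_significant]
      stable_sets <- stable_sets[names(stable_sets) %in% gated]
    }

    dres <- NULL
    if (isTRUE(config$diffapa$run) && length(stable_sets) > 0) {
      genes <- unique(unlist(stable_sets))
      dres <- stage("diffapa", diff_apa(
        X_ct[intersect(rownames(X_ct), genes), , drop = FALSE],
        labels_ct, alpha = config$diffapa$alpha))
    }

    pred <- NULL
    if (isTRUE(config$predict$run) && length(stable_sets) > 0 &&
        length(unique(labels_ct)) == 2) {
      genes <- intersect(unique(unlist(stable_sets)), rownames(X_ct))
      sp <- stage("predict", donor_split(
        data.frame(cell_id = cells_ct$cell_id,
                   donor = cells_ct[[config$donor_col]],
                   diagnosis = labels_ct,
                   stringsAsFactors = FALSE),
        ratio = config$predict$ratio,
        seed = derive_seed(config$seed, match(ct, celltypes), 99L)))
      feats <- t(X_ct[genes, , drop = FALSE])
      # impute with train-cell means only (no test leakage)
      mu <- colMeans(feats[sp$train, , drop = FALSE], na.rm = TRUE)
      mu[is.na(mu)] <- 0
      for (j in seq_along(mu)) feats[is.na(feats[, j]), j] <- mu[j]
      pred <- stage("predict", train_boosted(
        feats[sp$train, , drop = FALSE], labels_ct[sp$train],
        boost_config(seed = derive_seed(config$seed, 7L)),
        feats[sp$test, , drop = FALSE], labels_ct[sp$test]))
    }

    results[[ct]] <- list(screen = screen_all, records = records,
                          stable_sets = stable_sets, enrichment = enr,
                          diffapa = dres, prediction = pred)
    manifest$stages <- c(manifest$stages, paste0(ct_id, ":complete"))

    if (!is.null(out_dir)) {
      write_tsv_file(screen_all,
                     file.path(out_dir, paste0(ct_id, "_screen.tsv")),
                     seed = config$seed, params = unclass(config))
      if (!is.null(records))
        write_tsv_file(as.data.frame(records),
                       file.path(out_dir, paste0(ct_id, "_modules.tsv")),
                       seed = config$seed, params = unclass(config))
      if (length(stable_sets) > 0)
        write_gmt(stable_sets,
                  file.path(out_dir, paste0(ct_id, "_stable_modules.gmt")))
      if (!is.null(dres))
        write_tsv_file(dres,
                       file.path(out_dir, paste0(ct_id, "_diffapa.tsv")),
                       seed = config$seed, params = unclass(config))
    }
  }
  if (!is.null(out_dir))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
               file.path(out_dir, "manifest.json"))
  results$manifest <- manifest
  results
}
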