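#' Adaptive Z-score core-gene selection for one module
#'
#' Z-scores a module's dictionary weights against the column's own
#' weight distribution, then raises the selection threshold from
#' `z_init` in increments of `step` until fewer than `max_genes` genes
#' remain above it.  The surviving genes are the module's core genes: a
#' concise, highly specific representation used for enrichment and
#' stability analysis.
#'
#' @param u_col named numeric vector of gene weights (one dictionary
#'   column; needs at least one nonzero weight to be meaningful).
#' @param z_init initial Z threshold (default 1.0).
#' @param step threshold increment (default 0.05).
#' @param max_genes selection cap: the threshold is raised until the
#'   selected count is below this (default 1000).
#' @return list: `genes` (character vector), `threshold` (final Z
#'   threshold), `z` (the Z-scores).
#' @export
select_core_genes <- function(u_col, z_init = 1.0, step = 0.05,
                              max_genes = 1000) {
  stopifnot(length(u_col) >= 1, z_init >= 0, step > 0, max_genes >= 1)
  if (is.null(names(u_col))) names(u_col) <- as.character(seq_along(u_col))
  s <- sd(u_col)
  if (is.na(s) || s == 0) {
    warning("select_core_genes: constant weights; empty core set")
    return(list(genes = character(0), threshold = z_init,
                z = setNames(rep(0, length(u_col)), names(u_col))))
  }
  z <- (u_col - mean(u_col)) / s
  th <- z_init
  while (sum(z >= th) >= max_genes) th <- th + step
  list(genes = names(u_col)[z >= th], threshold = th, z = z)
}

#' Cross-partition recurrence rate of a module
#'
#' Containment of the query module's gene set in the best-matching
#' module of another data block: `max_j |M ∩ M_oj| / |M|`, where `M` is
#' the query gene set and `M_oj` ranges over the other block's modules.
#' The denominator is always the query module's size, so the measure is
#' asymmetric (a containment, not a Jaccard index).
#'
#' @param module character vector of the query module's genes (non-empty).
#' @param other_block_modules list of gene sets from another block (may
#'   be empty, giving 0).
#' @return recurrence rate in [0, 1].
#' @export
recurrence_rate <- function(module, other_block_modules) {
  if (length(module) == 0) stop("recurrence_rate: empty query module")
  if (length(other_block_modules) == 0) return(0)
  best <- max(vapply(other_block_modules,
                     function(o) length(intersect(module, o)), 0L))
  best / length(module)
}

#' Stability filtering of modules across data partitions
#'
#' For every module of every block (partition), computes the recurrence
#' rate against each other block and aggregates (mean by default) into a
#' single stability score.  Modules at or above `threshold` are stable;
#' if fewer than `fallback_min_modules` modules pass, retention is
#' re-run at the relaxed `fallback` threshold (the relaxation used for
#' cell types yielding few stable modules).
#'
#' @param modules_by_block list over blocks; each element a named list
#'   of gene sets (module core genes) from that block.
#' @param threshold stability threshold (default 0.80).
#' @param fallback relaxed threshold (default 0.75).
#' @param fallback_min_modules minimum stable-module count before the
#'   fallback applies (default 5).
#' @param aggregate how to combine per-block recurrence rates: "mean"
#'   (default), "min" or "median".
#' @return data frame of class `module_record`: module_id, block,
#'   size, recurrence, stable, threshold_used; the retained gene sets
#'   are in `attr(, "stable_sets")`.
#' @export
stability_filter <- function(modules_by_block, threshold = 0.80,
                             fallback = 0.75, fallback_min_modules = 5,
                             aggregate = c("mean", "min", "median")) {
  aggregate <- match.arg(aggregate)
  n_blocks <- length(modules_by_block)
  if (n_blocks < 2)
    stop("stability_filter: stability is undefined with a single block")
  agg_fun <- switch(aggregate, mean = mean, min = min, median = stats::median)
  rows <- list()
  sets <- list()
  for (b in seq_len(n_blocks)) {
    mods <- modules_by_block[[b]]
    if (length(mods) == 0) next
    ids <- names(mods)
    if (is.null(ids)) ids <- sprintf("m%d", seq_along(mods))
    for (i in seq_along(mods)) {
      if (length(mods[[i]]) == 0) next
      rr <- vapply(setdiff(seq_len(n_blocks), b), function(o)
        recurrence_rate(mods[[i]], modules_by_block[[o]]), 0)
      id <- if (grepl("_", ids[i])) ids[i] else sprintf("%d_%s", b, ids[i])
      rows[[id]] <- data.frame(module_id = id, block = b,
                               size = length(mods[[i]]),
                               recurrence = agg_fun(rr),
                               stringsAsFactors = FALSE)
      sets[[id]] <- mods[[i]]
    }
  }
  rec <- do.call(rbind, rows)
  if (is.null(rec))
    stop("stability_filter: no non-empty modules in any block")
  rownames(rec) <- NULL
  used <- threshold
  stable <- rec$recurrence >= used
  if (sum(stable) < fallback_min_modules) {
    used <- fallback
    stable <- rec$recurrence >= used
  }
  rec$stable <- stable
  rec$threshold_used <- used
  class(rec) <- c("module_record", "data.frame")
  attr(rec, "stable_sets") <- sets[rec$module_id[stable]]
  rec
}

#' Collapse near-duplicate stable modules for reporting
#'
#' Stable modules recur across partitions almost by construction, so the
#' per-partition view contains near-identical gene sets.  This greedy
#' clustering merges sets whose containment in an already-kept
#' representative is at least `containment`, keeping the largest set of
#' each cluster as representative.  Both views (per-partition and
#' collapsed) are useful; this produces the collapsed one.
#'
#' @param sets named list of gene sets.
#' @param containment merge threshold (default 0.8).
#' @return named list of representative gene sets with a `members`
#'   attribute mapping representatives to merged module ids.
#' @export
collapse_modules <- function(sets, containment = 0.8) {
  if (length(sets) == 0) return(sets)
  ord <- order(-lengths(sets))
  reps <- list()
  members <- list()
  for (i in ord) {
    placed <- FALSE
    for (r in names(reps)) {
      if (length(intersect(sets[[i]], reps[[r]])) / length(sets[[i]]) >=
          containment) {
        members[[r]] <- c(members[[r]], names(sets)[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps[[names(sets)[i]]] <- sets[[i]]
      members[[names(sets)[i]]] <- names(sets)[i]
    }
  }
  attr(reps, "members") <- members
  reps
}
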