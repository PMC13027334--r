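#' Hypergeometric enrichment of a module against a gene set
#'
#' Upper-tail hypergeometric test of the overlap between a module's core
#' genes and a target set (cell-type markers, risk genes), conditioned
#' on a background universe: `p = P(overlap >= k)` drawing
#' `n = |module|` genes from a universe of `N` containing
#' `K = |target|` successes.  Fold enrichment is `(k/n) / (K/N)`.
#'
#' @param module_genes character vector, subset of `universe`.
#' @param target_set character vector, subset of `universe`.
#' @param universe background gene ids (non-empty).
#' @return list: p, overlap, fold, n_module, n_target, n_universe.
#' @export
hypergeom_enrich <- function(module_genes, target_set, universe) {
  if (length(universe) == 0) stop("hypergeom_enrich: empty universe")
  if (length(module_genes) == 0) stop("hypergeom_enrich: empty module")
  module_genes <- unique(module_genes); target_set <- unique(target_set)
  universe <- unique(universe)
  if (!all(module_genes %in% universe))
    stop("hypergeom_enrich: module genes outside the universe")
  if (!all(target_set %in% universe))
    stop("hypergeom_enrich: target set outside the universe")
  N <- length(universe); K <- length(target_set); n <- length(module_genes)
  k <- length(intersect(module_genes, target_set))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (K == 0) NA_real_ else (k / n) / (K / N)
  list(p = p, overlap = k, fold = fold,
       n_module = n, n_target = K, n_universe = N)
}

#' Enrichment report for a collection of modules against gene-set families
#'
#' Tests every module against every set and BH-adjusts p-values within
#' each set family (e.g. all marker sets form one family, the risk list
#' another), so the correction matches how a set family is interrogated.
#' Flags summarize, per module, significance against any marker set
#' ("cell-type specific") and against any risk set ("risk enriched").
#'
#' @param modules named list of core-gene sets.
#' @param collection named list of target gene sets.
#' @param universe background gene ids; sets are intersected with it.
#' @param family optional character vector (same names as `collection`)
#'   assigning each set to a family; default: one family per set name
#'   prefix up to the first "_", or the set name itself.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return data frame: module_id, set, family, overlap, fold, p, p_adj,
#'   significant; with per-module flags in `attr(, "flags")`.
#' @export
enrich_modules <- function(modules, collection, universe, family = NULL,
                           alpha = 0.05) {
  stopifnot(length(modules) > 0, length(collection) > 0)
  collection <- lapply(collection, intersect, y = universe)
  modules <- lapply(modules, intersect, y = universe)
  if (is.null(family)) {
    family <- ifelse(grepl("_", names(collection)),
                     sub("_.*$", "", names(collection)), names(collection))
    names(family) <- names(collection)
  }
  grid <- expand.grid(module_id = names(modules), set = names(collection),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    h <- hypergeom_enrich(modules[[grid$module_id[i]]],
                          collection[[grid$set[i]]], universe)
    data.frame(module_id = grid$module_id[i], set = grid$set[i],
               family = unname(family[grid$set[i]]),
               overlap = h$overlap, fold = h$fold, p = h$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  for (fam in unique(out$family)) {
    sel <- out$family == fam
    out$p_adj[sel] <- p.adjust(out$p[sel], "BH")
  }
  out$significant <- out$p_adj < alpha
  flags <- do.call(rbind, lapply(names(modules), function(m) {
    sub <- out[out$module_id == m, ]
    data.frame(module_id = m,
               celltype_specific = any(sub$significant &
                 grepl("marker", sub$family, ignore.case = TRUE)),
               risk_enriched = any(sub$significant &
                 grepl("risk|sfari", sub$family, ignore.case = TRUE)),
               any_significant = any(sub$significant),
               stringsAsFactors = FALSE)
  }))
  attr(out, "flags") <- flags
  out
}
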