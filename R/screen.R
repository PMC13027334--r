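## label utilities: screens expect a two-level grouping encoded +1 / -1
encode_labels <- function(labels, positive = NULL) {
  if (is.numeric(labels) && all(labels %in% c(-1, 1)))
    return(list(y = as.numeric(labels),
                positive = "+1", negative = "-1"))
  f <- factor(labels)
  if (nlevels(f) != 2)
    stop("labels must have exactly 2 levels, got ", nlevels(f))
  lev <- levels(f)
  pos <- if (!is.null(positive)) positive
         else if ("ASD" %in% lev) "ASD" else lev[1]
  if (!pos %in% lev) stop("positive level '", pos, "' not in labels")
  list(y = ifelse(f == pos, 1, -1), positive = pos,
       negative = setdiff(lev, pos))
}

#' Wilcoxon rank-sum screen of module activities against a phenotype
#'
#' Tests, per module, whether activity differs between the two phenotype
#' groups (two-sided rank-sum test with average ranks for ties);
#' p-values are Benjamini-Hochberg adjusted across the modules of the
#' screening unit (one cell type, one partition).
#'
#' @param W modules x cells activity matrix (rownames = module ids).
#' @param labels two-level phenotype per cell (e.g. ASD / Control).
#' @param alpha adjusted-p threshold for the retain flag (default 0.01).
#' @param positive which level is encoded +1 (default "ASD" if present).
#' @return data frame: module_id, p_wilcoxon, p_wilcoxon_adj, w_pass.
#' @export
wilcoxon_screen <- function(W, labels, alpha = 0.01, positive = NULL) {
  enc <- encode_labels(labels, positive)
  g1 <- enc$y > 0; g2 <- !g1
  if (!any(g1) || !any(g2)) stop("wilcoxon_screen: a group is empty")
  small <- sum(g1) < 3 || sum(g2) < 3
  if (small)
    warning("wilcoxon_screen: a group has < 3 cells; p-values set to 1")
  p <- apply(W, 1, function(w) {
    if (small || sd(w) == 0) return(1)
    suppressWarnings(wilcox.test(w[g1], w[g2], exact = FALSE)$p.value)
  })
  p[is.na(p)] <- 1
  padj <- p.adjust(p, "BH")
  data.frame(module_id = rownames(W), p_wilcoxon = p,
             p_wilcoxon_adj = padj, w_pass = padj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman + permutation screen of module activities
#'
#' Computes the Spearman correlation `rho` between each module's
#' activity and the +1/-1 phenotype encoding, with an empirical
#' two-sided permutation p-value: `p = (b + 1) / (n_perm + 1)` where `b`
#' counts label permutations with `|rho|` at least the observed value
#' (the add-one rule keeps p-values valid).  BH adjustment is applied
#' across modules; passing requires both `rho > rho_min` (a minimal
#' effect size) and adjusted p below `alpha`.
#'
#' @param W modules x cells activity matrix.
#' @param labels two-level phenotype per cell.
#' @param n_perm number of permutations (default 1000).
#' @param rho_min effect-size gate on rho (default 0.1).
#' @param alpha adjusted-p threshold (default 0.01).
#' @param positive level encoded +1.
#' @param seed seed for the permutations.
#' @return data frame: module_id, rho, p_perm, p_perm_adj, s_pass,
#'   reason (NA or "constant_activity").
#' @export
spearman_perm_screen <- function(W, labels, n_perm = 1000, rho_min = 0.1,
                                 alpha = 0.01, positive = NULL, seed = 1) {
  enc <- encode_labels(labels, positive)
  y <- enc$y
  n <- length(y)
  stopifnot(ncol(W) == n)
  ry <- rank(y)
  ry_c <- ry - mean(ry)
  ry_s <- ry_c / sqrt(sum(ry_c^2))
  rw <- t(apply(W, 1, rank))            # average ranks for ties
  rw_c <- rw - rowMeans(rw)
  rw_norm <- sqrt(rowSums(rw_c^2))
  constant <- rw_norm < 1e-12
  rw_s <- rw_c / ifelse(constant, 1, rw_norm)
  rho <- as.numeric(rw_s %*% ry_s)
  rho[constant] <- NA

  set.seed(seed)
  perm <- replicate(n_perm, ry_s[sample.int(n)])
  rho_perm <- abs(rw_s %*% perm)        # modules x n_perm
  b <- rowSums(rho_perm >= abs(rho) - 1e-12)
  p <- (b + 1) / (n_perm + 1)
  p[constant] <- 1
  padj <- p.adjust(p, "BH")
  data.frame(module_id = rownames(W), rho = rho, p_perm = p,
             p_perm_adj = padj,
             s_pass = !constant & !is.na(rho) & rho > rho_min & padj < alpha,
             reason = ifelse(constant, "constant_activity", NA_character_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Combined two-step module screen
#'
#' A module is phenotype-associated only if it passes both the Wilcoxon
#' rank-sum criterion (adjusted p below `alpha`) and the
#' Spearman-permutation criterion (`rho > rho_min` and adjusted p below
#' `alpha`).  The conjunction enforces significance and a minimal effect
#' size jointly, guarding against hits driven solely by sample size.
#'
#' @inheritParams spearman_perm_screen
#' @return data frame of class `screen_result` with all component
#'   statistics (columns Pw/Pr report -log10 adjusted p-values, R the
#'   correlation) and the conjunction flag `passed`.
#' @export
combined_screen <- function(W, labels, alpha = 0.01, n_perm = 1000,
                            rho_min = 0.1, positive = NULL, seed = 1) {
  wres <- wilcoxon_screen(W, labels, alpha, positive)
  sres <- spearman_perm_screen(W, labels, n_perm, rho_min, alpha,
                               positive, seed)
  out <- merge(wres, sres, by = "module_id", sort = FALSE)
  out$passed <- out$w_pass & out$s_pass
  out$Pw <- -log10(out$p_wilcoxon_adj)
  out$Pr <- -log10(out$p_perm_adj)
  out$R <- out$rho
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Module-covariate association with FCA-style scores
#'
#' Runs the combined screen with a two-level covariate (sex or brain
#' region) as the label, and additionally reports a factor-covariate
#' association (FCA) surrogate score per covariate level: the area under
#' the ROC curve of the module activity against the covariate, rescaled
#' to [0, 1] and split by direction, so a module whose activity is high
#' in level L scores near 1 for L and 0 for the other level.  This is a
#' documented surrogate for ensemble-classifier FCA scoring, not a
#' reimplementation of it.
#'
#' @param W modules x cells activity matrix.
#' @param covariate two-level covariate per cell (error on > 2 levels).
#' @param ... passed to [combined_screen()].
#' @return data frame: screen columns plus `fca_<level>` score columns.
#' @export
covariate_assoc <- function(W, covariate, ...) {
  f <- factor(covariate)
  if (nlevels(f) != 2)
    stop("covariate_assoc: covariate must have exactly 2 levels, got ",
         nlevels(f))
  lev <- levels(f)
  res <- combined_screen(W, covariate, positive = lev[2], ...)
  n2 <- sum(f == lev[2]); n1 <- sum(f == lev[1])
  auc <- apply(W, 1, function(w) {
    # rank-sum AUC: P(activity in level2 > activity in level1)
    r <- rank(w)
    (sum(r[f == lev[2]]) - n2 * (n2 + 1) / 2) / (n1 * n2)
  })
  auc_df <- data.frame(module_id = rownames(W),
                       a = pmax(0, 1 - 2 * auc),  # enriched in level 1
                       b = pmax(0, 2 * auc - 1),  # enriched in level 2
                       stringsAsFactors = FALSE)
  names(auc_df)[2:3] <- paste0("fca_", lev)
  merge(res, auc_df, by = "module_id", sort = FALSE)
}
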