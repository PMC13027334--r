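#' Differential APA between two conditions on a RUD matrix
#'
#' Per-gene two-group comparison of RUD values with empirical-Bayes
#' variance moderation: the per-gene pooled variance is shrunk toward a
#' prior estimated from all genes (via [limma::squeezeVar()]), and the
#' moderated t uses the augmented degrees of freedom.  Masked (`NA`)
#' entries are excluded; genes observed in fewer than `min_cells` cells
#' in either group are skipped, as are genes constant in both groups
#' with equal means (t undefined).  `delta_rud` is mean(group1) -
#' mean(group2), so with group1 = disease a positive significant value
#' is a 3' UTR lengthening event (higher RUD = longer 3' UTR).
#'
#' @param rud genes x cells matrix of RUD values with `NA` masking, or a
#'   `rud_matrix`.
#' @param groups two-level condition per cell; `positive` names the
#'   level treated as group1 (default "ASD" when present, else the first
#'   level).
#' @param alpha BH-adjusted significance threshold for the calls
#'   (default 0.05).
#' @param min_cells minimum observed cells per group per gene (default 3).
#' @param positive level used as group1.
#' @return data frame of class `diff_apa`: gene_id, delta_rud, t_mod,
#'   df_total, p, p_adj, call ("lengthening", "shortening", "ns"), and
#'   skipped genes with a `reason`.
#' @export
diff_apa <- function(rud, groups, alpha = 0.05, min_cells = 3,
                     positive = NULL) {
  if (inherits(rud, "rud_matrix")) rud <- rud$values
  stopifnot(is.matrix(rud), ncol(rud) == length(groups))
  enc <- encode_labels(groups, positive)
  g1 <- enc$y > 0; g2 <- !g1
  X1 <- rud[, g1, drop = FALSE]; X2 <- rud[, g2, drop = FALSE]
  n1 <- rowSums(!is.na(X1)); n2 <- rowSums(!is.na(X2))
  m1 <- rowMeans(X1, na.rm = TRUE); m2 <- rowMeans(X2, na.rm = TRUE)
  v1 <- apply(X1, 1, var, na.rm = TRUE)
  v2 <- apply(X2, 1, var, na.rm = TRUE)
  delta <- m1 - m2
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df

  ok <- n1 >= min_cells & n2 >= min_cells
  reason <- rep(NA_character_, nrow(rud))
  reason[!ok] <- "insufficient_cells"
  constant <- ok & !is.na(s2) & s2 == 0 & delta == 0
  reason[constant] <- "constant"
  test <- ok & !constant

  out <- data.frame(gene_id = rownames(rud), delta_rud = delta,
                    t_mod = NA_real_, df_total = NA_real_,
                    p = NA_real_, p_adj = NA_real_,
                    call = NA_character_, reason = reason,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (any(test)) {
    sq <- suppressWarnings(limma::squeezeVar(s2[test], df = df[test]))
    df_tot <- df[test] + sq$df.prior
    se <- sqrt(sq$var.post * (1 / n1[test] + 1 / n2[test]))
    t_mod <- delta[test] / se
    p <- 2 * pt(-abs(t_mod), df = df_tot)
    out$t_mod[test] <- t_mod
    out$df_total[test] <- df_tot
    out$p[test] <- p
    out$p_adj[test] <- p.adjust(p, "BH")
    out$call[test] <- ifelse(out$p_adj[test] < alpha,
                             ifelse(out$delta_rud[test] > 0,
                                    "lengthening", "shortening"), "ns")
    attr(out, "df_prior") <- sq$df.prior
    attr(out, "var_prior") <- sq$var.prior
  }
  class(out) <- c("diff_apa", "data.frame")
  out
}

#' Count 3' UTR lengthening and shortening events
#'
#' Counts significant differential-APA genes by the sign of the RUD
#' shift: positive (toward distal usage) is lengthening, negative is
#' shortening.
#'
#' @param results a `diff_apa` data frame.
#' @param alpha significance threshold on the adjusted p (default: the
#'   calls already present in `results`).
#' @return named integer vector `c(lengthening = , shortening = )`.
#' @export
count_utr_shifts <- function(results, alpha = NULL) {
  if (is.null(results) || nrow(results) == 0)
    return(c(lengthening = 0L, shortening = 0L))
  if (is.null(alpha)) {
    lon <- sum(results$call == "lengthening", na.rm = TRUE)
    sho <- sum(results$call == "shortening", na.rm = TRUE)
  } else {
    sig <- !is.na(results$p_adj) & results$p_adj < alpha
    lon <- sum(sig & results$delta_rud > 0)
    sho <- sum(sig & results$delta_rud < 0)
  }
  c(lengthening = as.integer(lon), shortening = as.integer(sho))
}

#' Top differential-APA genes
#'
#' Ranks tested genes by adjusted p-value, breaking ties by the absolute
#' RUD shift (largest first).
#'
#' @param results a `diff_apa` data frame.
#' @param n number of genes to report (default 20).
#' @return the top rows of `results`.
#' @export
top_apa_genes <- function(results, n = 20) {
  tested <- results[!is.na(results$p_adj), , drop = FALSE]
  ord <- order(tested$p_adj, -abs(tested$delta_rud))
  utils::head(tested[ord, , drop = FALSE], n)
}
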