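# bounded usage values with a given mean via a scaled beta draw
rud_noise <- function(n, mean, sd = 0.15) {
  pmin(pmax(rnorm(n, mean, sd), 0), 1)
}

test_that("null data give super-uniform p-values and few BH calls", {
  set.seed(51)
  G <- 300; n <- 120
  rud <- matrix(rud_noise(G * n, 0.5), G, n,
                dimnames = list(sprintf("g%d", 1:G), NULL))
  groups <- rep(c("ASD", "Control"), each = n / 2)
  res <- diff_apa(rud, groups)
  p <- res$p[!is.na(res$p)]
  for (t in c(0.05, 0.2))
    expect_lte(mean(p <= t), t + 3 * sqrt(t * (1 - t) / length(p)))
  expect_lte(sum(res$call %in% c("lengthening", "shortening")), 3)
})

test_that("a planted RUD shift is detected with the correct sign", {
  set.seed(52)
  G <- 60; n_per <- 200
  rud <- matrix(rud_noise(G * 2 * n_per, 0.4), G, 2 * n_per,
                dimnames = list(sprintf("g%d", 1:G), NULL))
  groups <- rep(c("ASD", "Control"), each = n_per)
  # plant +0.3 on genes 1-10 (lengthening), -0.3 on 11-20 (shortening)
  rud[1:10, groups == "ASD"] <- rud_noise(10 * n_per, 0.7)
  rud[11:20, groups == "ASD"] <- rud_noise(10 * n_per, 0.1)
  res <- diff_apa(rud, groups)
  expect_true(all(res$call[1:10] == "lengthening"))
  expect_true(all(res$call[11:20] == "shortening"))
  expect_equal(res$delta_rud[1], 0.3, tolerance = 0.06)
  shifts <- count_utr_shifts(res)
  # all 10 planted per direction, allowing a stray BH false positive
  expect_true(abs(shifts["lengthening"] - 10) <= 1)
  expect_true(abs(shifts["shortening"] - 10) <= 1)
})

test_that("degenerate genes are skipped with a reason", {
  rud <- rbind(g_const = rep(0.5, 20),
               g_onegroup = c(rep(0.5, 10), rep(NA, 10)),
               g_ok = c(rud_noise(20, 0.5)))
  groups <- rep(c("ASD", "Control"), each = 10)
  res <- diff_apa(rud, groups)
  expect_identical(res$reason[res$gene_id == "g_const"], "constant")
  expect_identical(res$reason[res$gene_id == "g_onegroup"],
                   "insufficient_cells")
  expect_false(is.na(res$p[res$gene_id == "g_ok"]))
})

test_that("moderated variance lies between per-gene and prior variance", {
  set.seed(53)
  G <- 100; n <- 60
  # heterogeneous gene variances so shrinkage is visible
  sds <- runif(G, 0.05, 0.3)
  rud <- t(sapply(sds, function(s) rud_noise(n, 0.5, s)))
  rownames(rud) <- sprintf("g%d", 1:G)
  groups <- rep(c("ASD", "Control"), each = n / 2)
  res <- diff_apa(rud, groups)
  v_prior <- attr(res, "var_prior")
  # recompute the per-gene pooled variance independently
  g1 <- groups == "ASD"
  s2 <- sapply(seq_len(G), function(g) {
    ((sum(g1) - 1) * var(rud[g, g1]) + (sum(!g1) - 1) * var(rud[g, !g1])) /
      (n - 2)
  })
  d0 <- attr(res, "df_prior")
  s2_post <- (d0 * v_prior + (n - 2) * s2) / (d0 + n - 2)
  # posterior sits between the per-gene and the prior estimate
  lo <- pmin(s2, v_prior); hi <- pmax(s2, v_prior)
  expect_true(all(s2_post >= lo - 1e-12 & s2_post <= hi + 1e-12))
  # and the reported t matches the shrunken scale
  t_chk <- (rowMeans(rud[, g1]) - rowMeans(rud[, !g1])) /
    sqrt(s2_post * (2 / (n / 2)))
  expect_equal(res$t_mod, unname(t_chk), tolerance = 1e-6)
})

test_that("with dispersed variances the moderated t approaches ordinary t", {
  set.seed(54)
  G <- 200; n <- 40
  sds <- exp(runif(G, log(0.02), log(0.45)))   # heavy variance dispersion
  rud <- t(sapply(sds, function(s) rud_noise(n, 0.5, s)))
  rownames(rud) <- sprintf("g%d", 1:G)
  groups <- rep(c("ASD", "Control"), each = n / 2)
  res <- diff_apa(rud, groups)
  t_ord <- sapply(seq_len(G), function(g)
    t.test(rud[g, groups == "ASD"], rud[g, groups == "Control"],
           var.equal = TRUE)$statistic)
  expect_gt(cor(res$t_mod, t_ord), 0.98)
})

test_that("shift counting handles one-sided and empty results", {
  res <- data.frame(gene_id = c("a", "b"), delta_rud = c(0.2, 0.1),
                    p_adj = c(0.001, 0.002),
                    call = c("lengthening", "lengthening"))
  expect_equal(unname(count_utr_shifts(res)), c(2L, 0L))
  expect_equal(unname(count_utr_shifts(res[0, ])), c(0L, 0L))
  # explicit alpha path
  expect_equal(unname(count_utr_shifts(res, alpha = 0.0015)), c(1L, 0L))
})

test_that("top genes rank by adjusted p then effect size", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    delta_rud = c(0.1, -0.4, 0.2, 0.05),
                    p_adj = c(0.01, 0.001, 0.001, NA),
                    call = "ns")
  top <- top_apa_genes(res, n = 3)
  expect_identical(top$gene_id, c("b", "c", "a"))
})
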