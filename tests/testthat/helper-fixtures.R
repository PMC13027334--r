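# fixtures built in code: small site tables, genomes and label vectors

# a hand-sized site table: `per_gene` sites for each of `n_genes` genes,
# counts supplied or drawn reproducibly
toy_site_table <- function(counts, positions, strands, genes,
                           cells = NULL) {
  n_sites <- nrow(counts)
  if (is.null(cells))
    cells <- data.frame(cell_id = sprintf("c%02d", seq_len(ncol(counts))),
                        stringsAsFactors = FALSE)
  sites <- data.frame(
    site_id = sprintf("s%02d", seq_len(n_sites)),
    chrom = "chr1",
    position = positions,
    strand = strands,
    gene_id = genes,
    stringsAsFactors = FALSE)
  site_table(sites, Matrix::Matrix(counts, sparse = TRUE), cells)
}

# two-site gene table from a gene x cell RUD target: distal counts are
# round(depth * rud), proximal the remainder (exact ratios)
rud_site_table <- function(rud_target, depth = 10, strand = "+") {
  G <- nrow(rud_target); N <- ncol(rud_target)
  counts <- matrix(0, 2 * G, N)
  positions <- integer(2 * G)
  genes <- character(2 * G)
  for (g in seq_len(G)) {
    distal <- round(depth * rud_target[g, ])
    counts[2 * g - 1, ] <- depth - distal
    counts[2 * g, ] <- distal
    base <- g * 1000L
    positions[c(2 * g - 1, 2 * g)] <-
      if (strand == "+") c(base, base + 500L) else c(base + 500L, base)
    genes[c(2 * g - 1, 2 * g)] <- sprintf("g%03d", g)
  }
  toy_site_table(counts, positions, rep(strand, 2 * G), genes)
}

# synthetic activity matrix with a planted two-group location shift on
# the first `n_planted` modules (shift in pooled-SD units)
planted_activity <- function(n_modules, n_planted, n_per_group,
                             shift = 1, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  labels <- rep(c("ASD", "Control"), each = n_per_group)
  W <- matrix(rnorm(n_modules * n), n_modules, n,
              dimnames = list(sprintf("m%d", seq_len(n_modules)), NULL))
  if (n_planted > 0)
    W[seq_len(n_planted), labels == "ASD"] <-
      W[seq_len(n_planted), labels == "ASD"] + shift
  list(W = W, labels = labels, planted = sprintf("m%d", seq_len(n_planted)))
}

# small cached synthetic dataset shared across test files
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_site_counts(synth_config(
        n_genes = 150, n_cells = 500, n_modules_planted = 2,
        module_size = 30, group_effect = 0.3, n_donors = 8, seed = 42))
    cache
  }
})
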