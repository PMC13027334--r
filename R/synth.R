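#' Configuration for the synthetic poly(A)-site count generator
#'
#' Describes a synthetic single-nucleus APA dataset: a gene universe with
#' ordered 3' UTR poly(A) sites, planted gene modules whose distal-site
#' usage co-varies across cells, a diagnosis contrast (case vs control)
#' realized as a module-activity shift, optional sex / brain-region
#' covariate effects, donor structure, and sparse counts.
#'
#' Effects are placed on the distal-usage probability scale: a
#' group-associated module shifts the mean distal usage of its member
#' genes by `group_effect` between diagnosis groups (values clipped to
#' [0.02, 0.98] to avoid degenerate all-or-nothing genes).  Donor effects
#' are small random intercepts on the usage logit.  Per-cell library
#' sizes are negative binomial and per-gene counts are allocated to sites
#' multinomially given the cell's usage probabilities.
#'
#' @param n_genes,n_cells gene and cell universe sizes.
#' @param n_sites_per_gene ordered poly(A) sites per gene (>= 2).
#' @param n_modules_planted,module_size number and size of planted modules
#'   (disjoint gene sets).
#' @param group_effect distal-usage (RUD) shift between diagnosis groups
#'   for genes in group-associated modules; 0 gives a null dataset.
#' @param covariate_effect RUD shift attached to sex (module 1) and brain
#'   region (module 2) when positive.
#' @param n_donors number of donors; each donor carries one diagnosis.
#' @param dropout_rate probability that a (gene, cell) observation is
#'   zeroed (no coverage), in [0, 1).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param n_cell_types optional number of cell-type labels to assign.
#' @param mean_reads expected reads per gene per cell before dropout.
#' @param nb_size negative-binomial size of the per-cell library.
#' @param coherence distal-usage amplitude per unit of latent module
#'   activity (drives within-module RUD correlation).
#' @param noise_sd per-gene, per-cell usage noise (probability scale).
#' @param donor_sd standard deviation of donor intercepts (logit scale).
#' @return an object of class `synth_config` (validated list).
#' @export
synth_config <- function(n_genes = 200, n_cells = 600, n_sites_per_gene = 2,
                         n_modules_planted = 3, module_size = 30,
                         group_effect = 0.3, covariate_effect = 0,
                         n_donors = 10, dropout_rate = 0.2, seed = 1,
                         n_cell_types = 1, mean_reads = 8, nb_size = 10,
                         coherence = 0.12, noise_sd = 0.06, donor_sd = 0.1) {
  cfg <- list(n_genes = n_genes, n_cells = n_cells,
              n_sites_per_gene = n_sites_per_gene,
              n_modules_planted = n_modules_planted, module_size = module_size,
              group_effect = group_effect, covariate_effect = covariate_effect,
              n_donors = n_donors, dropout_rate = dropout_rate, seed = seed,
              n_cell_types = n_cell_types, mean_reads = mean_reads,
              nb_size = nb_size, coherence = coherence, noise_sd = noise_sd,
              donor_sd = donor_sd)
  counts <- c("n_genes", "n_cells", "n_sites_per_gene", "n_modules_planted",
              "module_size", "n_donors", "n_cell_types")
  for (f in counts)
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1 ||
        cfg[[f]] != round(cfg[[f]]))
      stop("synth_config: '", f, "' must be a positive integer")
  if (n_sites_per_gene < 2) stop("synth_config: n_sites_per_gene must be >= 2")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("synth_config: dropout_rate must be in [0, 1)")
  if (n_modules_planted * module_size > n_genes)
    stop("synth_config: planted modules exceed the gene universe")
  if (abs(group_effect) >= 1 || abs(covariate_effect) >= 1)
    stop("synth_config: effects are RUD shifts and must be < 1 in magnitude")
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic poly(A)-site count table with ground truth
#'
#' Produces a `site_table` (site metadata + sparse site-by-cell counts +
#' cell metadata) and a `synth_truth` object recording the planted module
#' gene sets, which modules are diagnosis-associated, covariate-attached
#' modules, per-cell labels and the donor map.
#'
#' Genes are laid out on a toy genome (alternating strands) so that the
#' full site-QC / RUD machinery runs unchanged on synthetic data.  The
#' transcriptionally distal site of a minus-strand gene has the smallest
#' genomic coordinate.
#'
#' @param cfg a [synth_config()].
#' @return list with elements `sites` (a `site_table`) and `truth`
#'   (a `synth_truth`).
#' @export
generate_site_counts <- function(cfg) {
  if (!inherits(cfg, "synth_config")) cfg <- do.call(synth_config, cfg)
  set.seed(cfg$seed)
  G <- cfg$n_genes; N <- cfg$n_cells; S <- cfg$n_sites_per_gene

  ## --- cells, donors, covariates -------------------------------------
  donor_dx <- rep(c("ASD", "Control"), length.out = cfg$n_donors)
  donor_sex <- rep(c("M", "F"), length.out = cfg$n_donors)[sample(cfg$n_donors)]
  donor_of_cell <- sample(cfg$n_donors, N, replace = TRUE)
  cells <- data.frame(
    cell_id = sprintf("cell%04d", seq_len(N)),
    diagnosis = donor_dx[donor_of_cell],
    sex = donor_sex[donor_of_cell],
    region = sample(c("PFC", "ACC"), N, replace = TRUE),
    donor = sprintf("donor%02d", donor_of_cell),
    cell_type = sprintf("CT%d", sample(cfg$n_cell_types, N, replace = TRUE)),
    stringsAsFactors = FALSE)
  is_case <- cells$diagnosis == "ASD"

  ## --- planted modules ------------------------------------------------
  gene_ids <- sprintf("gene%05d", seq_len(G))
  n_mod <- cfg$n_modules_planted
  planted_idx <- split(seq_len(n_mod * cfg$module_size),
                       rep(seq_len(n_mod), each = cfg$module_size))
  planted_genes <- lapply(planted_idx, function(i) gene_ids[i])
  names(planted_genes) <- sprintf("planted%d", seq_len(n_mod))
  module_of_gene <- rep(NA_integer_, G)
  for (m in seq_len(n_mod)) module_of_gene[planted_idx[[m]]] <- m
  group_assoc <- rep(cfg$group_effect != 0, n_mod)
  cov_modules <- c(sex = NA_integer_, region = NA_integer_)
  if (cfg$covariate_effect != 0) {
    cov_modules["sex"] <- 1L
    if (n_mod >= 2) cov_modules["region"] <- 2L
  }

  ## latent module activities (non-negative so usage is elevated when a
  ## module is active; diagnosis/covariate shifts enter through activity)
  act <- matrix(abs(rnorm(n_mod * N)), n_mod, N)
  shift_units <- cfg$group_effect / cfg$coherence
  for (m in seq_len(n_mod)) {
    if (group_assoc[m]) act[m, is_case] <- act[m, is_case] + shift_units
    if (!is.na(cov_modules["sex"]) && cov_modules["sex"] == m)
      act[m, cells$sex == "M"] <- act[m, cells$sex == "M"] +
        cfg$covariate_effect / cfg$coherence
    if (!is.na(cov_modules["region"]) && cov_modules["region"] == m)
      act[m, cells$region == "ACC"] <- act[m, cells$region == "ACC"] +
        cfg$covariate_effect / cfg$coherence
  }

  ## --- per-gene, per-cell distal-usage probabilities -------------------
  ## planted genes start low so an activity-driven gain keeps usage in range
  p0 <- runif(G, 0.25, 0.75)
  p0[!is.na(module_of_gene)] <- runif(sum(!is.na(module_of_gene)), 0.15, 0.45)
  donor_int <- rnorm(cfg$n_donors, 0, cfg$donor_sd)
  dint <- donor_int[donor_of_cell]

  ## --- counts ----------------------------------------------------------
  lib <- rnbinom(N, size = cfg$nb_size, mu = G * cfg$mean_reads)
  gene_w <- rgamma(G, shape = 5, rate = 5)
  gene_w <- gene_w / sum(gene_w)
  keep_prob <- 1 - cfg$dropout_rate

  ## proximal-site relative weights are fixed per gene (transcription order)
  prox_w <- if (S > 2)
    matrix(rgamma(G * (S - 1), 2, 2), G, S - 1) else matrix(1, G, 1)
  prox_w <- prox_w / rowSums(prox_w)

  counts <- matrix(0L, G * S, N)   # rows: gene-major, transcription order
  for (g in seq_len(G)) {
    m <- module_of_gene[g]
    p <- p0[g] + rnorm(N, 0, cfg$noise_sd)
    if (!is.na(m)) p <- p + cfg$coherence * act[m, ]
    p <- pmin(pmax(p, 0.02), 0.98)
    p <- stats::plogis(stats::qlogis(p) + dint)
    reads <- rpois(N, lib * gene_w[g])
    reads <- reads * (runif(N) < keep_prob)
    distal <- rbinom(N, reads, p)
    rest <- reads - distal
    rows <- (g - 1L) * S
    counts[rows + S, ] <- distal            # site S = transcriptionally distal
    if (S == 2) {
      counts[rows + 1L, ] <- rest
    } else {
      remaining_w <- 1
      for (s in seq_len(S - 2L)) {
        pr <- prox_w[g, s] / remaining_w
        cs <- rbinom(N, rest, pr)
        counts[rows + s, ] <- cs
        rest <- rest - cs
        remaining_w <- remaining_w - prox_w[g, s]
      }
      counts[rows + S - 1L, ] <- rest
    }
  }

  ## --- toy genomic layout ---------------------------------------------
  strand_of_gene <- rep(c("+", "-"), length.out = G)
  gene_start <- 10000L + (seq_len(G) - 1L) * 10000L
  site_tx_rank <- rep(seq_len(S), G)         # 1 = most proximal
  gene_of_site <- rep(seq_len(G), each = S)
  # on '+' transcription order follows coordinates; on '-' it is reversed
  offset <- ifelse(strand_of_gene[gene_of_site] == "+",
                   (site_tx_rank - 1L) * 500L,
                   (S - site_tx_rank) * 500L)
  position <- gene_start[gene_of_site] + offset

  sites <- data.frame(
    site_id = sprintf("site_%05d_%d", gene_of_site, site_tx_rank),
    chrom = "chr1",
    position = position,
    strand = strand_of_gene[gene_of_site],
    gene_id = gene_ids[gene_of_site],
    site_rank = site_tx_rank,
    stringsAsFactors = FALSE)
  cmat <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
    "generalMatrix"), "CsparseMatrix")
  dimnames(cmat) <- list(sites$site_id, cells$cell_id)
  st <- site_table(sites, cmat, cells)

  truth <- structure(list(
    planted_module_genes = planted_genes,
    module_group_assoc = group_assoc,
    covariate_modules = cov_modules,
    cell_labels = cells$diagnosis,
    covariates = cells[, c("sex", "region")],
    donor_of_cell = stats::setNames(cells$donor, cells$cell_id),
    module_activity = act), class = "synth_truth")
  list(sites = st, truth = truth)
}

#' Construct a site table
#'
#' Container used throughout the pipeline: site metadata, a sparse
#' site-by-cell count matrix, and cell metadata.  Support columns
#' `n_cells_detected` and `total_reads` are (re)computed from the counts.
#'
#' @param sites data frame with columns site_id, chrom, position, strand,
#'   gene_id (and optionally site_rank, QC flags).
#' @param counts sparse sites x cells count matrix (rows match `sites`).
#' @param cells data frame of cell metadata with a `cell_id` column.
#' @return object of class `site_table`.
#' @export
site_table <- function(sites, counts, cells) {
  stopifnot(nrow(sites) == nrow(counts), nrow(cells) == ncol(counts))
  if (any(counts < 0)) stop("site_table: negative counts")
  sites$n_cells_detected <- Matrix::rowSums(counts > 0)
  sites$total_reads <- Matrix::rowSums(counts)
  structure(list(sites = sites, counts = counts, cells = cells),
            class = "site_table")
}

#' @export
print.site_table <- function(x, ...) {
  cat(sprintf("site_table: %d sites, %d genes, %d cells\n",
              nrow(x$sites), length(unique(x$sites$gene_id)), nrow(x$cells)))
  invisible(x)
}

#' Generate flanking-sequence windows with planted internal-priming truth
#'
#' Emits +/-50 bp windows around simulated cleavage sites (101 bp, the
#' site at the center, transcript orientation).  A truth-flagged artifact
#' window carries one of the internal-priming signatures -- an A-tract of
#' >= 7 adenines, a dense pair of A/T-rich hexamers, or simply no
#' polyadenylation signal (PAS) -- and never a canonical PAS.  Clean
#' windows carry AATAAA 16-35 bp upstream of the site and none of the
#' disqualifying motifs.  Exactly `round(artifact_fraction * n_sites)`
#' windows are flagged.
#'
#' @param n_sites number of windows.
#' @param artifact_fraction fraction of windows planted as artifacts.
#' @param seed integer seed.
#' @return data frame with columns site_id, seq (101-character string),
#'   artifact (logical truth flag), artifact_type ("a_tract",
#'   "at_dense", "no_pas" or NA).
#' @export
generate_flank_sequences <- function(n_sites, artifact_fraction, seed = 1) {
  stopifnot(n_sites >= 1, artifact_fraction >= 0, artifact_fraction <= 1)
  set.seed(seed)
  n_art <- round(artifact_fraction * n_sites)
  width <- 101L
  bases <- c("A", "C", "G", "T")

  rand_seq <- function() paste(sample(bases, width, replace = TRUE,
                                      prob = c(.3, .2, .2, .3)), collapse = "")
  # independent base-R checks (the QC module scans with Biostrings)
  has_atract <- function(s) grepl("AAAAAA", s, fixed = TRUE)
  hex_starts <- function(s, hx) {
    out <- integer(0)
    for (h in hx) {
      g <- gregexpr(h, s, fixed = TRUE)[[1]]
      if (g[1] != -1L) out <- c(out, as.integer(g))
    }
    sort(out)
  }
  has_at_dense <- function(s) {
    st <- hex_starts(s, c("AAAAAT", "TTTTTA"))
    length(st) >= 2 && min(diff(st)) <= 14
  }
  pas_all <- c("AATAAA", "ATTAAA", "TATAAA", "AGTAAA", "AAGAAA", "AATATA",
               "AATACA", "CATAAA", "GATAAA", "AATGAA", "TTTAAA", "ACTAAA")
  has_pas <- function(s) any(vapply(pas_all, grepl, TRUE, x = s, fixed = TRUE))

  draw_background <- function() {   # no PAS, no A-tract, no dense AT pair
    repeat {
      s <- rand_seq()
      if (!has_atract(s) && !has_at_dense(s) && !has_pas(s)) return(s)
    }
  }
  splice <- function(s, at, ins)
    paste0(substr(s, 1, at - 1), ins, substr(s, at + nchar(ins), width))

  make_clean <- function() {
    repeat {
      s <- draw_background()
      d <- sample(16:35, 1)                    # PAS start upstream of center
      s <- splice(s, 51 - d, "AATAAA")
      if (!has_atract(s) && !has_at_dense(s)) return(s)
    }
  }
  make_artifact <- function(type) {
    repeat {
      s <- draw_background()
      if (type == "no_pas") return(s)
      ins <- if (type == "a_tract") "AAAAAAA" else "AAAAATCTTTTTA"
      s2 <- splice(s, sample(20:70, 1), ins)
      ok <- if (type == "a_tract") has_atract(s2) else
        (has_at_dense(s2) && !has_atract(s2))
      if (ok && !has_pas(s2)) return(s2)
    }
  }

  artifact <- rep(FALSE, n_sites)
  if (n_art > 0) artifact[sample(n_sites, n_art)] <- TRUE
  types <- rep(NA_character_, n_sites)
  types[artifact] <- rep(c("a_tract", "at_dense", "no_pas"),
                         length.out = n_art)
  seqs <- character(n_sites)
  for (i in seq_len(n_sites))
    seqs[i] <- if (artifact[i]) make_artifact(types[i]) else make_clean()

  data.frame(site_id = sprintf("fseq%04d", seq_len(n_sites)),
             seq = seqs, artifact = artifact, artifact_type = types,
             stringsAsFactors = FALSE)
}
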