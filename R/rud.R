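#' Index of the transcriptionally most distal poly(A) site
#'
#' The distal site is the one farthest 3' in transcript orientation:
#' largest genomic coordinate on the plus strand, smallest on the minus
#' strand.
#'
#' @param positions genomic positions of the gene's sites (>= 2, unique).
#' @param strand "+" or "-".
#' @return integer index into `positions`.
#' @export
distal_site_index <- function(positions, strand) {
  if (length(positions) < 2)
    stop("distal_site_index: gene must have >= 2 sites")
  if (anyDuplicated(positions))
    stop("distal_site_index: duplicate site coordinates")
  if (!strand %in% c("+", "-"))
    stop("distal_site_index: strand must be '+' or '-'")
  if (strand == "+") which.max(positions) else which.min(positions)
}

#' Relative usage of the distal site for one gene in one cell
#'
#' RUD = reads at the most distal site divided by total reads over all
#' retained 3' UTR sites of the gene.  Zero total coverage gives a
#' missing value (`NA`), not zero: absence of data is not proximal usage.
#'
#' @param counts non-negative per-site read counts for one gene in one
#'   cell.
#' @param distal_index index of the most distal site (see
#'   [distal_site_index()]).
#' @return RUD in [0, 1], or `NA` when the gene has no reads in the cell.
#' @export
compute_rud <- function(counts, distal_index) {
  if (any(counts < 0)) stop("compute_rud: negative counts")
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  counts[distal_index] / tot
}

#' Build the RUD matrix from a QC'd site table
#'
#' For every gene with at least two retained sites, computes RUD per cell
#' (distal reads over total gene reads); cells with zero coverage for the
#' gene are masked as `NA`.  Genes with a single retained site are
#' excluded (their RUD is trivially 1).  A higher value indicates a
#' preference for distal site usage, i.e. a longer 3' UTR.
#'
#' @param sites a QC'd `site_table`.
#' @return object of class `rud_matrix`: list with `values` (genes x
#'   cells matrix, `NA` = masked), `distal_site` (named vector, distal
#'   site id per gene), `n_sites` (retained sites per gene), and `cells`
#'   (cell metadata).  Internally genes x cells; writers emit the
#'   transposed cells x genes form.
#' @export
build_rud_matrix <- function(sites) {
  stopifnot(inherits(sites, "site_table"))
  sdf <- sites$sites
  tab <- table(sdf$gene_id)
  genes <- names(tab)[tab >= 2]
  if (length(genes) == 0)
    stop("build_rud_matrix: no gene has >= 2 retained sites")
  genes <- sort(genes)
  n_cells <- ncol(sites$counts)
  vals <- matrix(NA_real_, length(genes), n_cells,
                 dimnames = list(genes, colnames(sites$counts)))
  distal_site <- character(length(genes))
  n_sites <- integer(length(genes))
  row_of <- split(seq_len(nrow(sdf)), sdf$gene_id)
  for (gi in seq_along(genes)) {
    rows <- row_of[[genes[gi]]]
    di <- distal_site_index(sdf$position[rows], sdf$strand[rows[1]])
    sub <- sites$counts[rows, , drop = FALSE]
    tot <- Matrix::colSums(sub)
    r <- as.numeric(sub[di, ]) / tot
    r[tot == 0] <- NA_real_
    vals[gi, ] <- r
    distal_site[gi] <- sdf$site_id[rows[di]]
    n_sites[gi] <- length(rows)
  }
  structure(list(values = vals,
                 distal_site = stats::setNames(distal_site, genes),
                 n_sites = stats::setNames(n_sites, genes),
                 cells = sites$cells),
            class = "rud_matrix")
}

#' @export
print.rud_matrix <- function(x, ...) {
  cat(sprintf("rud_matrix: %d genes x %d cells (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Write a RUD matrix as TSV (cells x genes)
#'
#' Values are emitted cells x genes with `NA` for masked entries.
#'
#' @param x a `rud_matrix`.
#' @param path output TSV path.
#' @param seed,params provenance recorded in the header comment.
#' @export
write_rud_matrix <- function(x, path, seed = NA, params = list()) {
  df <- data.frame(cell_id = colnames(x$values), t(x$values),
                   check.names = FALSE)
  write_tsv_file(df, path, seed = seed, params = params)
}
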