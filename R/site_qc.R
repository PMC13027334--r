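#' Internal-priming detection rule
#'
#' Parameters of the sequence scan around each candidate cleavage site.
#' A site is flagged as a putative internal-priming artifact when, within
#' a window of `window_bp` on each side (transcript orientation), any of
#' the following holds: (a) an uninterrupted run of at least
#' `a_tract_len` adenines; (b) a dense A/T-rich region, operationalized
#' as two or more occurrences of any listed hexamer inside a 20-bp
#' subwindow; (c) no polyadenylation signal (PAS) hexamer anywhere in the
#' window.
#'
#' @param window_bp half-window size in bp (default 50).
#' @param a_tract_len minimum A-run length (default 6).
#' @param at_rich_hexamers A/T-rich hexamer list for rule (b).
#' @param at_dense_window subwindow (bp) within which two hexamer hits
#'   count as dense.
#' @param pas_motifs PAS hexamer list for rule (c): AATAAA and common
#'   variants (configurable; defaults follow the commonly used variant
#'   set).
#' @param rescue_tolerance_bp maximum distance to a database site for
#'   rescue (default 10).
#' @return object of class `ip_rule`.
#' @export
ip_rule <- function(window_bp = 50, a_tract_len = 6,
                    at_rich_hexamers = c("AAAAAT", "TTTTTA"),
                    at_dense_window = 20,
                    pas_motifs = c("AATAAA", "ATTAAA", "TATAAA", "AGTAAA",
                                   "AAGAAA", "AATATA", "AATACA", "CATAAA",
                                   "GATAAA", "AATGAA", "TTTAAA", "ACTAAA"),
                    rescue_tolerance_bp = 10) {
  stopifnot(window_bp > 0, a_tract_len >= 2, rescue_tolerance_bp >= 0,
            at_dense_window >= 6)
  structure(list(window_bp = window_bp, a_tract_len = a_tract_len,
                 at_rich_hexamers = toupper(at_rich_hexamers),
                 at_dense_window = at_dense_window,
                 pas_motifs = toupper(pas_motifs),
                 rescue_tolerance_bp = rescue_tolerance_bp),
            class = "ip_rule")
}

#' Support filter for candidate poly(A) sites
#'
#' Retains sites detected in at least `min_cells` cells and supported by
#' at least `min_reads` reads in total (both thresholds inclusive).
#' Row order is preserved.
#'
#' @param sites a `site_table`.
#' @param min_cells,min_reads inclusive support thresholds.
#' @return filtered `site_table`.
#' @export
filter_candidates <- function(sites, min_cells = 10, min_reads = 10) {
  stopifnot(inherits(sites, "site_table"))
  if (any(sites$counts < 0)) stop("filter_candidates: negative counts")
  keep <- sites$sites$n_cells_detected >= min_cells &
          sites$sites$total_reads >= min_reads
  subset_site_table(sites, keep)
}

subset_site_table <- function(st, keep) {
  out <- st
  out$sites <- st$sites[keep, , drop = FALSE]
  rownames(out$sites) <- NULL
  out$counts <- st$counts[keep, , drop = FALSE]
  out
}

# window extraction + motif scan for one oriented window sequence
ip_scan_window <- function(dna, rule) {
  reasons <- character(0)
  atract <- paste(rep("A", rule$a_tract_len), collapse = "")
  if (length(Biostrings::matchPattern(atract, dna)) > 0)
    reasons <- c(reasons, "a")
  starts <- sort(unlist(lapply(rule$at_rich_hexamers, function(h)
    Biostrings::start(Biostrings::matchPattern(h, dna)))))
  if (length(starts) >= 2 &&
      min(diff(starts)) <= rule$at_dense_window - 6L)
    reasons <- c(reasons, "b")
  n_pas <- sum(vapply(rule$pas_motifs, function(h)
    length(Biostrings::matchPattern(h, dna)), 0L))
  if (n_pas == 0) reasons <- c(reasons, "c")
  reasons
}

#' Flag internal-priming artifacts by genomic sequence scan
#'
#' Scans the +/- `window_bp` genomic window around each site and applies
#' the three-part rule of [ip_rule()].  Scanning is strand-aware: for a
#' minus-strand site the reverse complement is scanned so that motifs are
#' read in transcript orientation.  Windows running off a contig end are
#' truncated with a warning.
#'
#' @param sites a `site_table`, or a data frame with columns chrom,
#'   position, strand.  Alternatively pass `seqs` directly.
#' @param genome a `DNAStringSet` (names = chromosomes) or path to a
#'   FASTA file.  Ignored when `seqs` is given.
#' @param rule an [ip_rule()].
#' @param seqs optional character vector / `DNAStringSet` of
#'   pre-extracted windows in transcript orientation (one per site),
#'   e.g. from [generate_flank_sequences()].
#' @return logical flag vector with attribute `reasons` (list of reason
#'   codes "a"/"b"/"c" per site).  When `sites` is a `site_table` the
#'   table is returned with columns `ip_flag` and `ip_reasons` added.
#' @export
flag_internal_priming <- function(sites, genome = NULL, rule = ip_rule(),
                                  seqs = NULL) {
  st <- NULL
  if (inherits(sites, "site_table")) { st <- sites; sdf <- sites$sites }
  else sdf <- sites
  if (is.null(seqs)) {
    if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
    # FASTA headers may carry descriptions; key on the first word
    names(genome) <- sub("\\s.*$", "", names(genome))
    n <- nrow(sdf)
    seqs <- character(n)
    truncated <- FALSE
    for (i in seq_len(n)) {
      chr <- sdf$chrom[i]
      if (!chr %in% names(genome))
        stop("flag_internal_priming: chromosome not in genome: ", chr)
      len <- Biostrings::width(genome[chr])
      lo <- sdf$position[i] - rule$window_bp
      hi <- sdf$position[i] + rule$window_bp
      if (lo < 1 || hi > len) { truncated <- TRUE }
      win <- Biostrings::subseq(genome[[chr]], max(1L, lo), min(len, hi))
      if (identical(sdf$strand[i], "-"))
        win <- Biostrings::reverseComplement(win)
      seqs[i] <- as.character(win)
    }
    if (truncated)
      warning("flag_internal_priming: window truncated at contig end")
  } else {
    seqs <- as.character(seqs)
  }
  reasons <- lapply(seqs, function(s)
    ip_scan_window(Biostrings::DNAString(s), rule))
  flag <- lengths(reasons) > 0
  if (!is.null(st)) {
    st$sites$ip_flag <- flag
    st$sites$ip_reasons <- vapply(reasons, paste, "", collapse = ",")
    return(st)
  }
  attr(flag, "reasons") <- reasons
  flag
}

#' Rescue flagged sites against reference poly(A)-site databases
#'
#' A site flagged as a putative internal-priming artifact is reclassified
#' as a validated true site when a reference site on the same chromosome
#' and strand lies within `tol_bp` (inclusive).  The retained set is the
#' union of non-flagged and rescued sites.
#'
#' @param sites a `site_table` with an `ip_flag` column (see
#'   [flag_internal_priming()]).
#' @param reference_sites data frame with columns chrom, position, strand
#'   (1-based), or a BED file path (see [read_bed()]; the BED `start` is
#'   used as the site position after 1-based conversion).
#' @param tol_bp inclusive distance tolerance in bp.
#' @return `site_table` of retained sites with columns `rescued` added;
#'   flagged, unrescued sites are removed.
#' @export
rescue_flagged <- function(sites, reference_sites, tol_bp = 10) {
  stopifnot(inherits(sites, "site_table"),
            "ip_flag" %in% names(sites$sites))
  if (is.character(reference_sites)) {
    bed <- read_bed(reference_sites)
    reference_sites <- data.frame(chrom = bed$chrom, position = bed$start,
                                  strand = bed$strand)
  }
  sdf <- sites$sites
  rescued <- rep(FALSE, nrow(sdf))
  if (!is.null(reference_sites) && nrow(reference_sites) > 0) {
    key <- paste(reference_sites$chrom, reference_sites$strand)
    refs <- split(reference_sites$position, key)
    skey <- paste(sdf$chrom, sdf$strand)
    idx <- which(sdf$ip_flag)
    for (i in idx) {
      r <- refs[[skey[i]]]
      if (!is.null(r) && min(abs(r - sdf$position[i])) <= tol_bp)
        rescued[i] <- TRUE
    }
  }
  sites$sites$rescued <- rescued
  subset_site_table(sites, !sdf$ip_flag | rescued)
}

#' Restrict sites to 3' UTRs of protein-coding genes
#'
#' Keeps sites whose position falls inside a 3' UTR interval of a
#' protein-coding gene on the same strand, and reassigns the site's
#' `gene_id` to that gene.  Sites matching 3' UTRs of two or more genes
#' are dropped with a warning.
#'
#' @param sites a `site_table`.
#' @param annotation data frame of 3' UTR intervals with columns chrom,
#'   start, end (1-based inclusive), strand, gene_id, biotype; or a
#'   `GRanges` with `gene_id`/`biotype` metadata columns.
#' @return `site_table` restricted to 3' UTR sites, with `region_class`
#'   set to "3UTR".
#' @export
restrict_to_3utr <- function(sites, annotation) {
  stopifnot(inherits(sites, "site_table"))
  if (is(annotation, "GRanges")) {
    ann <- data.frame(chrom = as.character(GenomicRanges::seqnames(annotation)),
                      start = GenomicRanges::start(annotation),
                      end = GenomicRanges::end(annotation),
                      strand = as.character(GenomicRanges::strand(annotation)),
                      gene_id = annotation$gene_id,
                      biotype = annotation$biotype,
                      stringsAsFactors = FALSE)
  } else ann <- annotation
  ann <- ann[ann$biotype == "protein_coding", , drop = FALSE]
  sdf <- sites$sites
  if (nrow(ann) == 0) return(subset_site_table(sites, rep(FALSE, nrow(sdf))))
  site_gr <- GenomicRanges::GRanges(sdf$chrom,
               IRanges::IRanges(sdf$position, sdf$position),
               strand = sdf$strand)
  ann_gr <- GenomicRanges::GRanges(ann$chrom,
              IRanges::IRanges(ann$start, ann$end), strand = ann$strand)
  ov <- GenomicRanges::findOverlaps(site_gr, ann_gr)  # strand-aware
  hit_genes <- split(ann$gene_id[S4Vectors::subjectHits(ov)],
                     S4Vectors::queryHits(ov))
  n_genes <- vapply(hit_genes, function(g) length(unique(g)), 0L)
  ambiguous <- as.integer(names(n_genes)[n_genes > 1])
  if (length(ambiguous))
    warning("restrict_to_3utr: dropped ", length(ambiguous),
            " site(s) overlapping 3' UTRs of multiple genes")
  assigned <- as.integer(names(n_genes)[n_genes == 1])
  keep <- logical(nrow(sdf))
  keep[assigned] <- TRUE
  sdf$gene_id[assigned] <- vapply(hit_genes[as.character(assigned)],
                                  function(g) unique(g)[1], "")
  sdf$region_class <- ifelse(keep, "3UTR", "other")
  sites$sites <- sdf
  subset_site_table(sites, keep)
}

#' Full site-QC pipeline
#'
#' Composes the QC stages in order: support filter, internal-priming
#' flagging, database rescue, 3' UTR restriction.  Stage order matters:
#' rescue can never resurrect a site removed by the support filter.
#'
#' @param sites a `site_table`.
#' @param genome genome sequence for [flag_internal_priming()] (or NULL
#'   with `seqs`).
#' @param reference_sites reference poly(A)-site list for
#'   [rescue_flagged()] (NULL = no rescue database, zero rescues).
#' @param annotation 3' UTR annotation for [restrict_to_3utr()]
#'   (NULL = skip restriction).
#' @param min_cells,min_reads support thresholds.
#' @param rule an [ip_rule()].
#' @param seqs optional pre-extracted windows (see
#'   [flag_internal_priming()]).
#' @return QC'd `site_table`.
#' @export
site_qc <- function(sites, genome = NULL, reference_sites = NULL,
                    annotation = NULL, min_cells = 10, min_reads = 10,
                    rule = ip_rule(), seqs = NULL) {
  st <- filter_candidates(sites, min_cells, min_reads)
  if (!is.null(genome) || !is.null(seqs)) {
    st <- flag_internal_priming(st, genome, rule, seqs = seqs)
    st <- rescue_flagged(st,
      if (is.null(reference_sites)) data.frame(chrom = character(0),
        position = numeric(0), strand = character(0)) else reference_sites,
      tol_bp = rule$rescue_tolerance_bp)
  }
  if (!is.null(annotation)) st <- restrict_to_3utr(st, annotation)
  st
}
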