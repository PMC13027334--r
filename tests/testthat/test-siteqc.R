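test_that("support filter keeps exactly the sites meeting both thresholds", {
  # 6 sites; rows engineered around the 10-cell / 10-read boundaries
  counts <- rbind(
    c(rep(1, 10), rep(0, 10)),      # 10 cells, 10 reads -> kept (boundary)
    c(rep(5, 9),  rep(0, 11)),      # 9 cells, 45 reads -> below cell cutoff
    c(rep(1, 9),  rep(0, 11)),      # 9 cells, 9 reads -> out
    c(rep(1, 12), rep(0, 8)),       # 12 cells, 12 reads -> kept
    c(9, rep(0, 19)),               # 1 cell, 9 reads -> out
    c(rep(2, 10), rep(0, 10)))      # 10 cells, 20 reads -> kept
  st <- toy_site_table(counts, positions = 1:6 * 100,
                       strands = rep("+", 6),
                       genes = rep(c("gA", "gB", "gC"), each = 2))
  out <- filter_candidates(st, min_cells = 10, min_reads = 10)
  expect_identical(out$sites$site_id, c("s01", "s04", "s06"))
})

test_that("negative counts are rejected at construction", {
  counts <- matrix(c(-1, 2, 3, 4), 2, 2)
  expect_error(toy_site_table(counts, c(100, 200), c("+", "+"),
                              c("g", "g")), "negative")
})

test_that("internal-priming rules fire with the documented reason codes", {
  rule <- ip_rule()
  pad <- function(core) {
    left <- paste(rep("CGCGC", 20), collapse = "")
    s <- paste0(substr(left, 1, 50 - nchar(core)), core,
                paste(rep("GC", 30), collapse = ""))
    substr(s, 1, 101)
  }
  # (a) A-tract; PAS absent as well, so reason c fires too
  f <- flag_internal_priming(data.frame(chrom = "x", position = 1,
                                        strand = "+"),
                             seqs = pad("AAAAAA"), rule = rule)
  expect_true(f[1])
  expect_true("a" %in% attr(f, "reasons")[[1]])
  # clean: PAS upstream, no A-tract, no dense AT
  clean <- pad("AATAAA")
  f <- flag_internal_priming(data.frame(chrom = "x", position = 1,
                                        strand = "+"),
                             seqs = clean, rule = rule)
  expect_false(f[1])
  # all-N window: no signal of any kind -> reason (c) only
  f <- flag_internal_priming(data.frame(chrom = "x", position = 1,
                                        strand = "+"),
                             seqs = strrep("N", 101), rule = rule)
  expect_true(f[1])
  expect_identical(attr(f, "reasons")[[1]], "c")
  # dense A/T-rich hexamers within a 20-bp subwindow -> reason (b)
  f <- flag_internal_priming(data.frame(chrom = "x", position = 1,
                                        strand = "+"),
                             seqs = pad("AAAAATCTTTTTA"), rule = rule)
  expect_true(f[1])
  expect_true("b" %in% attr(f, "reasons")[[1]])
})

test_that("genomic scan is strand-aware and truncates at contig ends", {
  # genome with TTTTTT at positions 61-66: reverse complement has an
  # A-tract, so a minus-strand site over it must be flagged via (a)
  g <- paste0(strrep("C", 60), "TTTTTT", strrep("G", 60))
  genome <- Biostrings::DNAStringSet(c(chrZ = g))
  sdf <- data.frame(chrom = "chrZ", position = 63,
                    strand = c("-", "+"), stringsAsFactors = FALSE)
  f <- flag_internal_priming(sdf, genome)
  expect_true("a" %in% attr(f, "reasons")[[1]])   # minus strand sees A-tract
  expect_false("a" %in% attr(f, "reasons")[[2]])  # plus strand sees T-tract
  # off-end window warns, does not error
  expect_warning(
    flag_internal_priming(data.frame(chrom = "chrZ", position = 5,
                                     strand = "+"), genome),
    "truncated")
})

test_that("rescue respects the +/-10 bp tolerance inclusively", {
  counts <- matrix(rep(c(5, 5), each = 12), 2, 12, byrow = TRUE)
  st <- toy_site_table(rbind(counts, counts),
                       positions = c(1000, 2000, 3000, 4000),
                       strands = rep("+", 4),
                       genes = rep("gA", 4))
  st$sites$ip_flag <- c(TRUE, TRUE, TRUE, FALSE)
  refs <- data.frame(chrom = "chr1", position = c(1005, 2011, 3010),
                     strand = "+")
  out <- rescue_flagged(st, refs, tol_bp = 10)
  # 1000 rescued (|5| <= 10); 2000 not (11 > 10); 3000 rescued (boundary);
  # 4000 never flagged
  expect_identical(out$sites$position, c(1000, 3000, 4000))
  expect_identical(out$sites$rescued, c(TRUE, TRUE, FALSE))
  # empty reference list: valid, zero rescues
  st2 <- rescue_flagged(st, data.frame(chrom = character(0),
                                       position = numeric(0),
                                       strand = character(0)))
  expect_identical(st2$sites$position, 4000)
  # wrong strand does not rescue
  st3 <- rescue_flagged(st, data.frame(chrom = "chr1", position = 1005,
                                       strand = "-"))
  expect_identical(st3$sites$position, 4000)
})

test_that("3' UTR restriction keeps protein-coding 3' UTR sites only", {
  counts <- matrix(5, 4, 12)
  st <- toy_site_table(counts,
                       positions = c(150, 650, 1150, 1650),
                       strands = rep("+", 4),
                       genes = rep("unknown", 4))
  ann <- data.frame(
    chrom = "chr1",
    start = c(100, 600, 1100),
    end = c(200, 700, 1200),
    strand = "+",
    gene_id = c("coding1", "noncoding1", "coding2"),
    biotype = c("protein_coding", "lincRNA", "protein_coding"),
    stringsAsFactors = FALSE)
  out <- restrict_to_3utr(st, ann)
  # s1 in coding1 3'UTR; s2 in non-coding -> dropped; s3 in coding2;
  # s4 outside all intervals (intron-like) -> dropped
  expect_identical(out$sites$position, c(150, 1150))
  expect_identical(out$sites$gene_id, c("coding1", "coding2"))
  expect_true(all(out$sites$region_class == "3UTR"))
})

test_that("ambiguous multi-gene 3' UTR overlap drops the site with a warning", {
  counts <- matrix(5, 1, 6)
  st <- toy_site_table(counts, positions = 150, strands = "+",
                       genes = "unknown")
  ann <- data.frame(chrom = "chr1", start = c(100, 120), end = c(200, 180),
                    strand = "+", gene_id = c("gX", "gY"),
                    biotype = "protein_coding", stringsAsFactors = FALSE)
  expect_warning(out <- restrict_to_3utr(st, ann), "multiple genes")
  expect_identical(nrow(out$sites), 0L)
})

test_that("QC composition is idempotent and rescue cannot resurrect
           support-filtered sites", {
  seqs <- generate_flank_sequences(40, 0.5, seed = 6)
  # site 1 fails support (few reads); give it an artifact sequence plus a
  # matching reference site: it must still be gone after the pipeline
  n_cells <- 20
  counts <- matrix(0, 40, n_cells)
  counts[1, 1] <- 1                       # below both support thresholds
  counts[2:40, ] <- 5
  st <- toy_site_table(counts, positions = 1:40 * 1000,
                       strands = rep("+", 40),
                       genes = rep(sprintf("g%02d", 1:20), each = 2))
  refs <- data.frame(chrom = "chr1", position = 1:40 * 1000, strand = "+")
  run_qc <- function(x) {
    out <- filter_candidates(x, 10, 5)
    out <- flag_internal_priming(out, seqs = seqs$seq[match(out$sites$site_id,
                                                     sprintf("s%02d", 1:40))])
    rescue_flagged(out, refs, tol_bp = 10)
  }
  once <- run_qc(st)
  expect_false("s01" %in% once$sites$site_id)
  # idempotence: re-running the composition on its own output is stable
  twice <- run_qc(once)
  expect_identical(once$sites$site_id, twice$sites$site_id)
})

test_that("sequence-based flags agree with planted truth", {
  seqs <- generate_flank_sequences(60, 0.4, seed = 13)
  flags <- flag_internal_priming(
    data.frame(chrom = "x", position = seq_len(60), strand = "+"),
    seqs = seqs$seq)
  expect_identical(as.logical(flags), seqs$artifact)
})
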