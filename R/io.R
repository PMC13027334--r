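#' Read / write a sparse matrix as MatrixMarket triplets with name files
#'
#' The matrix is stored as `<path>` (MTX triplet), `<path>.rownames` and
#' `<path>.colnames` (one name per line).  Round trips are bit-exact for
#' integer matrices and exact to double precision for reals.
#'
#' @param x a matrix or Matrix to write.
#' @param path file path of the `.mtx` file.
#' @return `read_mtx` returns a `dgCMatrix` with dimnames.
#' @export
write_mtx <- function(x, path) {
  m <- methods::as(methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE),
    "dMatrix"), "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, path)
  writeLines(if (is.null(rownames(x))) as.character(seq_len(nrow(x))) else rownames(x),
             paste0(path, ".rownames"))
  writeLines(if (is.null(colnames(x))) as.character(seq_len(ncol(x))) else colnames(x),
             paste0(path, ".colnames"))
  invisible(path)
}

#' @rdname write_mtx
#' @export
read_mtx <- function(path) {
  m <- methods::as(methods::as(methods::as(Matrix::readMM(path), "dMatrix"),
    "generalMatrix"), "CsparseMatrix")
  rn <- paste0(path, ".rownames"); cn <- paste0(path, ".colnames")
  if (file.exists(rn)) rownames(m) <- readLines(rn)
  if (file.exists(cn)) colnames(m) <- readLines(cn)
  m
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate set names are an error on read.
#'
#' @param path GMT file path.
#' @param sets named list of character vectors.
#' @param description optional per-set description column (recycled).
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed GMT at line ", bad[1L], ": fewer than 3 fields")
  nms <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nms))
    stop("duplicate gene-set name in GMT: ", nms[duplicated(nms)][1L])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nms
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names")
  desc <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write genomic intervals in BED format
#'
#' BED is 0-based half-open on disk; in memory intervals are 1-based
#' inclusive (`start`, `end`), the convention used throughout the package.
#'
#' @param path BED file path.
#' @param df data frame with columns chrom, start, end and optionally
#'   name, score, strand (1-based inclusive coordinates).
#' @return `read_bed` returns a data frame with 1-based inclusive
#'   `start`/`end` plus any name/score/strand columns present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  df
}

#' @rdname read_bed
#' @export
write_bed <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  gr <- GenomicRanges::GRanges(df$chrom,
          IRanges::IRanges(df$start, df$end),
          strand = if ("strand" %in% names(df)) df$strand else "*")
  if ("name" %in% names(df)) gr$name <- df$name
  if ("score" %in% names(df)) gr$score <- df$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a data frame as TSV with a provenance header comment
#'
#' The first line is a `#` comment recording package version, seed and a
#' parameter hash so outputs are traceable; `read_tsv_file` skips it.
#'
#' @param df data frame.
#' @param path file path.
#' @param seed integer seed to record (NA if not applicable).
#' @param params list of parameters folded into the provenance hash.
#' @return `read_tsv_file` returns a data frame.
#' @export
write_tsv_file <- function(df, path, seed = NA, params = list()) {
  hash <- param_hash(params)
  header <- sprintf("# apamod %s | seed=%s | params=%s",
                    as.character(utils::packageVersion("apamod")),
                    as.character(seed), hash)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_file
#' @export
read_tsv_file <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# short deterministic hash of a parameter list (djb2 over its deparse)
param_hash <- function(params) {
  if (!is.null(names(params))) params <- params[order(names(params))]
  s <- paste(deparse(params), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with per-stage parameter blocks.
#' @return named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

# internal: structured log line "stage | level | message"
log_msg <- function(stage, level, ...) {
  message(sprintf("[%s] %s | %s", stage, level, paste0(...)))
}
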