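#' Genomic intervals
#'
#' All internal coordinates in methylannot are 0-based half-open
#' (BED convention): a base at 1-based position `p` is the interval
#' `[p - 1, p)`. Manifest MAPINFO and SNP/gene table coordinates are
#' converted on ingest; BED output needs no conversion.
#'
#' @param chrom Chromosome name (non-empty character).
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `start < end`.
#' @param strand One of `"+"`, `"-"`, `"*"` (unspecified).
#' @return A data.frame of class `genomic_interval` with columns
#'   `chrom`, `start`, `end`, `strand`. Vectorised over its arguments.
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  n <- max(length(chrom), length(start), length(end), length(strand))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  strand <- rep_len(as.character(strand), n)
  if (any(is.na(chrom) | !nzchar(chrom))) {
    stop("genomic_interval: 'chrom' must be non-empty")
  }
  if (any(!strand %in% c("+", "-", "*"))) {
    stop("genomic_interval: 'strand' must be one of '+', '-', '*'")
  }
  bad <- which(!(start >= 0 & start < end))
  if (length(bad)) {
    stop(sprintf(
      "genomic_interval: need 0 <= start < end (first offender: [%s, %s))",
      start[bad[1]], end[bad[1]]
    ))
  }
  structure(
    data.frame(
      chrom = chrom, start = start, end = end, strand = strand,
      stringsAsFactors = FALSE
    ),
    class = c("genomic_interval", "data.frame")
  )
}

#' @export
#' @rdname genomic_interval
interval_length <- function(x) x$end - x$start

#' Pairwise interval overlap width
#'
#' @param a,b `genomic_interval` rows, recycled to common length.
#' @return Integer vector of overlap widths (0 if disjoint or on
#'   different chromosomes).
#' @export
interval_overlap <- function(a, b) {
  same <- a$chrom == b$chrom
  w <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  ifelse(same, w, 0)
}

#' Gap between two intervals on the same chromosome
#'
#' 0 when overlapping or directly abutting; positive gap otherwise;
#' NA across chromosomes.
#' @param a,b `genomic_interval` rows.
#' @export
interval_gap <- function(a, b) {
  g <- pmax(0, pmax(a$start, b$start) - pmin(a$end, b$end))
  ifelse(a$chrom == b$chrom, g, NA_real_)
}

#' Read and write BED6
#'
#' BED records are 0-based half-open, matching the internal convention.
#'
#' @param x A data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param path File path.
#' @return `read_bed` returns a data.frame with BED6 columns.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) {
    file.create(path)
    return(invisible(path))
  }
  out <- data.frame(
    chrom = x$chrom,
    start = format(x$start, scientific = FALSE, trim = TRUE),
    end = format(x$end, scientific = FALSE, trim = TRUE),
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("score" %in% names(x)) x$score else 0L,
    strand = if ("strand" %in% names(x)) ifelse(x$strand == "*", ".", x$strand) else ".",
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  empty <- data.frame(
    chrom = character(), start = numeric(), end = numeric(),
    name = character(), score = numeric(), strand = character(),
    stringsAsFactors = FALSE
  )
  if (file.size(path) == 0) {
    return(empty)
  }
  x <- utils::read.delim(path,
    header = FALSE, stringsAsFactors = FALSE,
    colClasses = c("character", "numeric", "numeric", "character", "numeric", "character"),
    col.names = cols, encoding = "UTF-8"
  )
  if (nrow(x) == 0) {
    return(empty)
  }
  x$strand[x$strand == "."] <- "*"
  x
}
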