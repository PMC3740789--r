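#' Reverse complement of a nucleotide string
#'
#' Case is preserved (soft-masked lowercase bases stay lowercase).
#' The degenerate code R (A/G) occurs only in probe space and is never
#' complemented; it is rejected here.
#'
#' @param seq Character vector of sequences over `{A,C,G,T,N,a,c,g,t,n}`.
#' @return Character vector of the reverse complements.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  vapply(seq, function(s) {
    if (is.na(s)) {
      return(NA_character_)
    }
    if (grepl("[^ACGTNacgtn]", s)) {
      stop(
        "reverse_complement: sequence contains characters outside ",
        "{A,C,G,T,N,a,c,g,t,n}"
      )
    }
    chartr("ACGTNacgtn", "TGCANtgcan", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Read a FASTA file into a case-preserving genome store
#'
#' Lowercase bases carry RepeatMasker-style soft masking, so the store keeps
#' case exactly as written. The store is a named character vector, one element
#' per record.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm)) {
    stop("read_fasta: duplicate record names in ", path)
  }
  out <- as.character(x)
  names(out) <- nm
  out
}

#' @rdname read_fasta
#' @param genome Named character vector as returned by `read_fasta`.
#' @export
write_fasta <- function(genome, path) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  x <- Biostrings::BStringSet(genome)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Fetch a 0-based half-open slice of a chromosome
#'
#' @param genome Genome store (named character vector).
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open coordinates. Out-of-bounds requests
#'   raise an error unless `clip = TRUE`, which truncates at the bounds.
#' @param clip Truncate instead of erroring on out-of-bounds coordinates.
#' @export
genome_fetch <- function(genome, chrom, start, end, clip = FALSE) {
  if (!chrom %in% names(genome)) {
    stop("genome_fetch: chromosome not in genome: ", chrom)
  }
  len <- nchar(genome[[chrom]])
  if (clip) {
    start <- max(0, start)
    end <- min(len, end)
    if (start >= end) {
      return("")
    }
  } else if (start < 0 || end > len || start >= end) {
    stop(sprintf(
      "genome_fetch: [%s, %s) out of bounds for %s (length %d)",
      start, end, chrom, len
    ))
  }
  substr(genome[[chrom]], start + 1, end)
}

#' @rdname genome_fetch
#' @export
chrom_lengths <- function(genome) {
  vapply(genome, nchar, integer(1))
}
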