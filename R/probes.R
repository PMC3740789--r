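# Probe-coordinate arithmetic.
#
# MAPINFO gives the 1-based position of the C in the target CpG; c0 below is
# its 0-based position. The probe footprint decision table (fixed by making
# the sequence round-trip validate on fixtures for all four type x strand
# combinations):
#
#   type I,  F:  [c0-49, c0+1)   C at the genomic-right probe terminus
#   type II, F:  [c0-50, c0)     50 bases left-adjacent to the C
#   type I,  R:  [c0+1,  c0+51)  G at the genomic-left probe terminus
#   type II, R:  [c0+2,  c0+52)  50 bases right-adjacent to the G
#
# F-design probes are complementary to the bisulfite-converted minus strand
# (their sequence is the plus strand with convertible minus-strand Cs, i.e.
# plus-strand Gs, read out as A/G/R); R-design probes are the reverse
# complement of the converted plus strand.

.PROBE_OFFSETS <- list(
  I_F = c(-49L, 1L), II_F = c(-50L, 0L),
  I_R = c(1L, 51L), II_R = c(2L, 52L)
)

#' Read a GenomeStudio-style probe manifest
#'
#' Required columns (matched case-insensitively): `IlmnID` or `Name`,
#' `Infinium_Design_Type`, `Strand`, `CHR`, `MAPINFO`, `AlleleA_ProbeSeq`,
#' `AlleleB_ProbeSeq`. The probe category (`cg`, `ch`, `rs`) is taken from the
#' id prefix; `rs` rows are parsed but flagged for exclusion from annotation.
#'
#' @param path Delimited text file with header (tab or comma separated).
#' @return data.frame with columns `probe_id`, `assay_type`, `design_strand`,
#'   `chrom`, `mapinfo` (1-based), `probe_seq_A`, `probe_seq_B`, `category`.
#' @export
read_manifest <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  lc <- tolower(names(raw))
  pick <- function(...) {
    for (cand in c(...)) {
      i <- match(tolower(cand), lc)
      if (!is.na(i)) {
        return(raw[[i]])
      }
    }
    stop("read_manifest: missing required column (one of ", paste(c(...), collapse = "/"), ")")
  }
  probes <- data.frame(
    probe_id = as.character(pick("IlmnID", "Name")),
    assay_type = toupper(as.character(pick("Infinium_Design_Type"))),
    design_strand = toupper(as.character(pick("Strand"))),
    chrom = as.character(pick("CHR")),
    mapinfo = as.integer(pick("MAPINFO")),
    probe_seq_A = toupper(as.character(pick("AlleleA_ProbeSeq"))),
    probe_seq_B = toupper(as.character(pick("AlleleB_ProbeSeq"))),
    stringsAsFactors = FALSE
  )
  probes$probe_seq_B[!nzchar(probes$probe_seq_B) | is.na(probes$probe_seq_B)] <- NA_character_
  probes$category <- substr(probes$probe_id, 1, 2)
  validate_probe_records(probes)
  probes
}

#' Validate probe records against the manifest invariants
#'
#' Checks assay/strand codes, 50-nt sequence lengths, R only in type II
#' sequences, and allele-B presence for type I probes.
#'
#' @param probes data.frame as returned by [read_manifest()].
#' @return Invisibly `probes`; errors name the offending probe.
#' @export
validate_probe_records <- function(probes) {
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i)) {
      stop(sprintf("probe %s: %s", probes$probe_id[i[1]], what))
    }
  }
  bad(!probes$assay_type %in% c("I", "II"), "unknown assay type (need I or II)")
  bad(!probes$design_strand %in% c("F", "R"), "unknown design strand (need F or R)")
  bad(nchar(probes$probe_seq_A) != 50L, "AlleleA probe sequence is not 50 nt")
  bad(probes$assay_type == "I" & is.na(probes$probe_seq_B), "type I probe lacks AlleleB sequence")
  bad(probes$assay_type == "II" & !is.na(probes$probe_seq_B), "type II probe carries AlleleB sequence")
  bad(!is.na(probes$probe_seq_B) & nchar(probes$probe_seq_B) != 50L, "AlleleB probe sequence is not 50 nt")
  bad(probes$assay_type == "I" & grepl("R", probes$probe_seq_A, fixed = TRUE), "degenerate R in a type I sequence")
  bad(!grepl("^[ACGTR]+$", probes$probe_seq_A), "AlleleA sequence outside {A,C,G,T,R}")
  bad(probes$mapinfo < 1L, "MAPINFO must be >= 1")
  invisible(probes)
}

#' Derive the three genomic intervals of a probe
#'
#' For every manifest row, computes (0-based half-open): the target CpG
#' (always the 2 bp spanning MAPINFO and MAPINFO+1), the 50-bp entire-probe
#' footprint, and the probe-without-CpG interval (footprint minus any target
#' CpG base: 49 bp for type I, 50 bp for type II).
#'
#' @param probes data.frame of probe records (see [read_manifest()]).
#' @return data.frame keyed by `probe_id` with columns `chrom`, `cpg_start`,
#'   `cpg_end`, `probe_start`, `probe_end`, `wo_start`, `wo_end`.
#' @export
compute_probe_intervals <- function(probes) {
  validate_probe_records(probes)
  c0 <- probes$mapinfo - 1L
  key <- paste(probes$assay_type, probes$design_strand, sep = "_")
  off <- do.call(rbind, .PROBE_OFFSETS[key])
  probe_start <- c0 + off[, 1]
  probe_end <- c0 + off[, 2]
  # type I footprints contain exactly one target-CpG base at a terminus;
  # probe_wo_cpg drops it from the corresponding end
  wo_start <- ifelse(probes$assay_type == "I" & probes$design_strand == "R",
    probe_start + 1L, probe_start
  )
  wo_end <- ifelse(probes$assay_type == "I" & probes$design_strand == "F",
    probe_end - 1L, probe_end
  )
  data.frame(
    probe_id = probes$probe_id,
    chrom = probes$chrom,
    cpg_start = c0, cpg_end = c0 + 2L,
    probe_start = probe_start, probe_end = probe_end,
    wo_start = wo_start, wo_end = wo_end,
    stringsAsFactors = FALSE
  )
}

# reverse complement that tolerates the degenerate codes R/Y (probe space)
rc_deg <- function(s) {
  chartr(
    "ACGTNRYacgtn",
    "TGCANYRtgcan",
    vapply(strsplit(s, "", fixed = TRUE), function(ch) paste(rev(ch), collapse = ""), character(1))
  )
}

#' Derive a probe sequence from the genome
#'
#' Reconstructs the probe sequence a manifest should carry for a given
#' footprint, applying strand complementation and in-silico bisulfite
#' transformation. `mode` selects the methylation assumption: `"A"` is the
#' type I unmethylated (allele A) probe with every convertible C read as T;
#' `"B"` the type I methylated probe retaining CpG-context Cs; `"II"` the
#' type II probe with CpG-context Cs read out as the degenerate base R.
#'
#' @param genome Genome store from [read_fasta()].
#' @param chrom,start,end Footprint (0-based half-open).
#' @param design_strand `"F"` or `"R"`.
#' @param mode `"A"`, `"B"` or `"II"`.
#' @return Uppercase 50-nt probe sequence.
#' @export
probe_from_genome <- function(genome, chrom, start, end, design_strand, mode = c("A", "B", "II")) {
  mode <- match.arg(mode)
  fp <- toupper(genome_fetch(genome, chrom, start, end))
  n <- nchar(fp)
  ch <- strsplit(fp, "", fixed = TRUE)[[1]]
  if (design_strand == "F") {
    # convertible bases are minus-strand Cs = plus-strand Gs; CpG context
    # means the plus base immediately left is a C
    left <- toupper(genome_fetch(genome, chrom, start - 1, start, clip = TRUE))
    prev <- c(if (nzchar(left)) left else "N", ch[-n])
    is_g <- ch == "G"
    cpg <- is_g & prev == "C"
    out <- ch
    out[is_g & !cpg] <- "A"
    out[cpg] <- switch(mode, A = "A", B = "G", II = "R")
    paste(out, collapse = "")
  } else {
    # convertible bases are plus-strand Cs; CpG context = next plus base is G
    right <- toupper(genome_fetch(genome, chrom, end, end + 1, clip = TRUE))
    nxt <- c(ch[-1], if (nzchar(right)) right else "N")
    is_c <- ch == "C"
    cpg <- is_c & nxt == "G"
    conv <- ch
    conv[is_c & !cpg] <- "T"
    conv[cpg] <- switch(mode, A = "T", B = "C", II = "Y")
    rc_deg(paste(conv, collapse = ""))
  }
}

#' Check manifest probe sequences against the genome
#'
#' For each probe, rebuilds the expected allele A (and, for type I, allele B)
#' sequence from the genome under the probe's footprint and compares it with
#' the stored sequence. The degenerate base R matches A, G or R.
#'
#' @param probes Probe records.
#' @param genome Genome store.
#' @return data.frame with `probe_id`, `valid` (logical), `n_mismatch_A`,
#'   `n_mismatch_B` and `unvalidatable` (footprint out of chromosome bounds).
#' @export
validate_probe_against_genome <- function(probes, genome) {
  iv <- compute_probe_intervals(probes)
  n <- nrow(probes)
  res <- data.frame(
    probe_id = probes$probe_id,
    valid = FALSE,
    n_mismatch_A = NA_integer_,
    n_mismatch_B = NA_integer_,
    unvalidatable = FALSE,
    stringsAsFactors = FALSE
  )
  mism <- function(expected, stored) {
    e <- strsplit(expected, "", fixed = TRUE)[[1]]
    s <- strsplit(stored, "", fixed = TRUE)[[1]]
    ok <- e == s | (e == "R" & s %in% c("A", "G", "R")) | (s == "R" & e %in% c("A", "G", "R"))
    sum(!ok)
  }
  for (i in seq_len(n)) {
    chrom <- probes$chrom[i]
    if (!chrom %in% names(genome) ||
      iv$probe_start[i] < 0 || iv$probe_end[i] > nchar(genome[[chrom]])) {
      res$unvalidatable[i] <- TRUE
      next
    }
    mode_a <- if (probes$assay_type[i] == "II") "II" else "A"
    exp_a <- probe_from_genome(
      genome, chrom, iv$probe_start[i], iv$probe_end[i],
      probes$design_strand[i], mode_a
    )
    res$n_mismatch_A[i] <- mism(exp_a, probes$probe_seq_A[i])
    ok <- res$n_mismatch_A[i] == 0L
    if (probes$assay_type[i] == "I") {
      exp_b <- probe_from_genome(
        genome, chrom, iv$probe_start[i], iv$probe_end[i],
        probes$design_strand[i], "B"
      )
      res$n_mismatch_B[i] <- mism(exp_b, probes$probe_seq_B[i])
      ok <- ok && res$n_mismatch_B[i] == 0L
    }
    res$valid[i] <- ok
  }
  res
}

#' Write a BED track of target Cs
#'
#' One 1-bp record per probe at the 0-based position of the target C.
#'
#' @param probes Probe records.
#' @param path Output BED path.
#' @export
write_target_track <- function(probes, path) {
  write_bed(data.frame(
    chrom = probes$chrom,
    start = probes$mapinfo - 1L,
    end = probes$mapinfo,
    name = probes$probe_id,
    score = 0L,
    strand = ifelse(probes$design_strand == "F", "+", "-"),
    stringsAsFactors = FALSE
  ), path)
}
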