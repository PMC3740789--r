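# In-silico bisulfite cross-hybridization screen.
#
# Probes are aligned, ungapped and end-to-end, against four converted genome
# variants: fully unmethylated (all C->T) and fully methylated (only non-CpG
# C->T) conversions of the forward sequence, and the same two conversions of
# the reverse complement. Candidate placements come from exact seed matches;
# the acceptance filter is: identity >= 90% over the aligned region, >= 40/50
# matching bases, no gaps, and the probe's 50th (3'-terminal) base aligned.

.BS_VARIANTS <- c("unmeth_fwd", "meth_fwd", "unmeth_rev", "meth_rev")

#' In-silico bisulfite conversion of a genome
#'
#' `unmeth_*`: every C becomes T. `meth_*`: C is retained only in CpG
#' context. `*_rev` variants apply the conversion to the reverse complement.
#' Case (soft masking) is preserved; conversion is idempotent.
#'
#' @param genome Genome store (named character vector) or a single sequence.
#' @param variant One of `"unmeth_fwd"`, `"meth_fwd"`, `"unmeth_rev"`,
#'   `"meth_rev"`.
#' @return Converted store of the same shape.
#' @export
bisulfite_convert <- function(genome, variant = .BS_VARIANTS) {
  variant <- match.arg(variant)
  s <- genome
  if (grepl("rev", variant, fixed = TRUE)) s <- reverse_complement(s)
  out <- if (grepl("unmeth", variant, fixed = TRUE)) {
    chartr("Cc", "Tt", s)
  } else {
    s <- gsub("C(?![Gg])", "T", s, perl = TRUE)
    gsub("c(?![Gg])", "t", s, perl = TRUE)
  }
  names(out) <- names(genome)
  out
}

#' Build all four bisulfite genome variants
#'
#' @param genome Genome store.
#' @return Named list of four converted stores.
#' @export
bisulfite_variants <- function(genome) {
  stats::setNames(lapply(.BS_VARIANTS, function(v) bisulfite_convert(genome, v)), .BS_VARIANTS)
}

#' Expand a degenerate type II probe sequence
#'
#' A sequence with R (CpG-context readout) yields exactly two concrete
#' sequences: all Rs replaced by A, and all Rs replaced by G. Mixed
#' substitutions are not enumerated.
#'
#' @param probe_seq Probe sequence, possibly containing R.
#' @param assay_type `"I"` or `"II"`; R in a type I sequence is rejected.
#' @return Named character vector (`none`, or `R2A`/`R2G`).
#' @export
expand_degenerate <- function(probe_seq, assay_type = "II") {
  has_r <- grepl("R", probe_seq, fixed = TRUE)
  if (has_r && assay_type == "I") {
    stop("expand_degenerate: degenerate R in a type I sequence")
  }
  if (!has_r) {
    return(c(none = probe_seq))
  }
  c(
    R2A = gsub("R", "A", probe_seq, fixed = TRUE),
    R2G = gsub("R", "G", probe_seq, fixed = TRUE)
  )
}

# score an ungapped placement of `qry` (probe written in the variant's
# forward reading direction) at variant coordinate `start` (0-based).
# Terminal mismatch runs are trimmed from the aligned region (local
# ungapped alignment, BLAT-style): the aligned region runs from the first
# to the last matching base; internal mismatches stay inside it. Returns
# NULL when nothing matches. `q50` is the query index holding the probe's
# 50th (3'-terminal) base; it is "aligned" iff it falls inside the trimmed
# region.
.score_placement <- function(var_seq_upper, var_len, qry_ch, start, q50) {
  idx <- start + seq_along(qry_ch) # 1-based positions in variant
  inb <- which(idx >= 1 & idx <= var_len)
  if (!length(inb)) {
    return(NULL)
  }
  g <- strsplit(substr(var_seq_upper, max(1, start + 1), min(var_len, start + length(qry_ch))), "", fixed = TRUE)[[1]]
  eq <- g == qry_ch[inb]
  if (!any(eq)) {
    return(NULL)
  }
  first <- inb[which.max(eq)]
  last <- inb[length(eq) + 1L - which.max(rev(eq))]
  list(
    matches = sum(eq),
    aligned = last - first + 1L,
    pos50 = q50 >= first && q50 <= last
  )
}

#' Find candidate alignment hits for probes
#'
#' Every genomic placement sharing at least one exact seed with a probe
#' sequence (either orientation, any of the four variants) is scored by
#' ungapped end-to-end comparison; the intended target placement is always
#' scored even if no seed matches it. Seeds are taken at regular offsets plus
#' the 3'-terminal seed so placements with an aligned 50th base are always
#' generated.
#'
#' @param probes Probe records (see [read_manifest()]).
#' @param genome Genome store (soft-masked case allowed).
#' @param variants Optional precomputed [bisulfite_variants()] output.
#' @param seed_len Exact seed length (default 12).
#' @param max_candidates Per-probe candidate cap; overflow flags the probe
#'   as saturated and truncates.
#' @return data.frame of hits: `probe_id`, `allele`, `degenerate_version`,
#'   `variant`, `chrom`, `start`, `end` (genomic plus-strand footprint),
#'   `matches`, `aligned_length`, `gaps`, `pos50_aligned`,
#'   `is_intended_target`, `saturated`.
#' @export
find_candidate_hits <- function(probes, genome, variants = NULL, seed_len = 12L,
                                max_candidates = 10000L) {
  if (is.null(variants)) variants <- bisulfite_variants(genome)
  glens <- chrom_lengths(genome)
  iv <- compute_probe_intervals(probes)
  # uppercase variant DNAStringSets for seed matching
  var_upper <- lapply(variants, function(v) lapply(v, toupper))
  hits <- list()
  for (i in seq_len(nrow(probes))) {
    pid <- probes$probe_id[i]
    alleles <- list(A = probes$probe_seq_A[i])
    if (probes$assay_type[i] == "I") alleles$B <- probes$probe_seq_B[i]
    intended <- c(iv$probe_start[i], iv$probe_end[i])
    n_cand <- 0L
    saturated <- FALSE
    seen <- character(0)
    for (al in names(alleles)) {
      degs <- expand_degenerate(alleles[[al]], probes$assay_type[i])
      for (dg in names(degs)) {
        sq <- degs[[dg]]
        L <- nchar(sq)
        for (orient in c("fwd", "rev")) {
          # qry: probe written in the variant's forward reading direction;
          # pos50 is the last query base for orient=fwd, the first for rev
          qry <- if (orient == "fwd") sq else rc_deg(sq)
          qry_ch <- strsplit(qry, "", fixed = TRUE)[[1]]
          pos50_q <- if (orient == "fwd") L else 1L
          seed_offs <- unique(c(seq(1L, L - seed_len + 1L, by = seed_len), L - seed_len + 1L))
          for (vn in .BS_VARIANTS) {
            for (chrom in names(genome)) {
              vseq <- var_upper[[vn]][[chrom]]
              vlen <- glens[[chrom]]
              cand_starts <- integer(0)
              for (so in seed_offs) {
                seed <- substr(qry, so, so + seed_len - 1L)
                m <- gregexpr(seed, vseq, fixed = TRUE)[[1]]
                if (m[1] == -1L) next
                cand_starts <- c(cand_starts, as.integer(m) - so) # 0-based placement start
              }
              cand_starts <- unique(cand_starts)
              if (length(cand_starts) > max_candidates - n_cand) {
                saturated <- TRUE
                cand_starts <- cand_starts[seq_len(max(0L, max_candidates - n_cand))]
              }
              n_cand <- n_cand + length(cand_starts)
              # always score the intended placement on this combo
              int_start <- if (grepl("rev", vn, fixed = TRUE)) vlen - intended[2] else intended[1]
              if (probes$chrom[i] == chrom) cand_starts <- unique(c(cand_starts, int_start))
              for (cs in cand_starts) {
                sc <- .score_placement(vseq, vlen, qry_ch, cs, pos50_q)
                if (is.null(sc)) next
                # map variant coordinates back to the plus strand
                if (grepl("rev", vn, fixed = TRUE)) {
                  g_start <- vlen - (cs + L)
                  g_end <- vlen - cs
                } else {
                  g_start <- cs
                  g_end <- cs + L
                }
                key <- paste(al, dg, orient, vn, chrom, cs)
                if (key %in% seen) next
                seen <- c(seen, key)
                hits[[length(hits) + 1L]] <- data.frame(
                  probe_id = pid, allele = al, degenerate_version = dg,
                  variant = vn, orientation = orient, chrom = chrom,
                  start = g_start, end = g_end,
                  matches = sc$matches, aligned_length = sc$aligned, gaps = 0L,
                  pos50_aligned = sc$pos50,
                  is_intended_target = chrom == probes$chrom[i] &&
                    g_start == intended[1] && g_end == intended[2],
                  saturated = saturated,
                  stringsAsFactors = FALSE
                )
              }
            }
          }
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(
      probe_id = character(), allele = character(), degenerate_version = character(),
      variant = character(), orientation = character(), chrom = character(),
      start = integer(), end = integer(), matches = integer(),
      aligned_length = integer(), gaps = integer(), pos50_aligned = logical(),
      is_intended_target = logical(), saturated = logical(), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, hits)
}

#' Apply the hit-acceptance filter
#'
#' Keep a hit iff identity (`matches / aligned_length`) is at least
#' `min_identity`, `matches >= min_matches`, no gaps, and the 50th
#' nucleotide aligned.
#'
#' @param hits data.frame from [find_candidate_hits()] (or equivalent
#'   bookkeeping, e.g. ingested external alignments).
#' @param min_identity Identity threshold (default 0.90).
#' @param min_matches Matching-base threshold (default 40).
#' @return The accepted subset of `hits`.
#' @export
filter_hits <- function(hits, min_identity = 0.90, min_matches = 40L) {
  keep <- hits$matches / hits$aligned_length >= min_identity &
    hits$matches >= min_matches &
    hits$gaps == 0L &
    hits$pos50_aligned
  hits[keep, , drop = FALSE]
}

#' Summarize accepted hits per probe
#'
#' Hits are collapsed to distinct genomic loci by footprint
#' (`chrom`, `start`, `end`) across variants, orientations and degenerate
#' versions. A probe is non-specific when it has more than one distinct
#' accepted locus.
#'
#' @param accepted Accepted hits from [filter_hits()].
#' @param probes Probe records (for intended chromosome and no-hit flags).
#' @param sex_chroms Sex chromosome names (default `c("chrX", "chrY")`).
#' @return data.frame per probe: `AlleleA_Hits`, `AlleleB_Hits`, `XY_Hits`,
#'   `Autosomal_Hits`, `n_loci`, `non_specific`, `no_hit`,
#'   `intended_sex` (probe targets a sex chromosome), `cross_hyb_sex` /
#'   `cross_hyb_auto` (a non-intended locus on a sex / autosomal chromosome).
#' @export
summarize_specificity <- function(accepted, probes, sex_chroms = c("chrX", "chrY")) {
  out <- data.frame(
    probe_id = probes$probe_id,
    AlleleA_Hits = 0L, AlleleB_Hits = 0L,
    XY_Hits = 0L, Autosomal_Hits = 0L,
    n_loci = 0L, non_specific = FALSE, no_hit = TRUE,
    intended_sex = probes$chrom %in% sex_chroms,
    cross_hyb_sex = FALSE, cross_hyb_auto = FALSE,
    saturated = FALSE,
    stringsAsFactors = FALSE
  )
  if (!nrow(accepted)) {
    return(out)
  }
  for (i in seq_len(nrow(probes))) {
    h <- accepted[accepted$probe_id == probes$probe_id[i], , drop = FALSE]
    if (!nrow(h)) next
    loci <- unique(h[, c("chrom", "start", "end")])
    locus_key <- paste(loci$chrom, loci$start, loci$end)
    hit_key <- paste(h$chrom, h$start, h$end)
    out$no_hit[i] <- FALSE
    out$n_loci[i] <- nrow(loci)
    out$non_specific[i] <- nrow(loci) > 1L
    out$AlleleA_Hits[i] <- length(unique(hit_key[h$allele == "A"]))
    out$AlleleB_Hits[i] <- length(unique(hit_key[h$allele == "B"]))
    on_sex <- loci$chrom %in% sex_chroms
    out$XY_Hits[i] <- sum(on_sex)
    out$Autosomal_Hits[i] <- sum(!on_sex)
    out$saturated[i] <- any(h$saturated)
    intended <- h$is_intended_target
    non_int <- !(locus_key %in% paste(
      h$chrom[intended], h$start[intended], h$end[intended]
    ))
    out$cross_hyb_sex[i] <- any(on_sex & non_int)
    out$cross_hyb_auto[i] <- any(!on_sex & non_int)
  }
  out
}

#' Cross-classification of non-specific probes by chromosome class
#'
#' Counts non-specific probes by intended target (autosomal vs sex
#' chromosome) against where their cross-hybridization loci fall.
#'
#' @param summary Output of [summarize_specificity()].
#' @return data.frame cross-tabulation.
#' @export
specificity_crosstab <- function(summary) {
  ns <- summary[summary$non_specific, , drop = FALSE]
  cell <- function(int_sex, sex, auto) {
    sum(ns$intended_sex == int_sex & ns$cross_hyb_sex == sex & ns$cross_hyb_auto == auto)
  }
  data.frame(
    row = c(
      "cross-hybridize only to auto chrs", "cross-hybridize only to sex chrs",
      "cross-hybridize to auto and sex chrs", "total"
    ),
    intended_auto = c(
      cell(FALSE, FALSE, TRUE), cell(FALSE, TRUE, FALSE),
      cell(FALSE, TRUE, TRUE), sum(!ns$intended_sex)
    ),
    intended_sex = c(
      cell(TRUE, FALSE, TRUE), cell(TRUE, TRUE, FALSE),
      cell(TRUE, TRUE, TRUE), sum(ns$intended_sex)
    ),
    stringsAsFactors = FALSE
  )
}

#' Count repetitive (soft-masked) bases under probe footprints
#'
#' @param probe_intervals Output of [compute_probe_intervals()].
#' @param genome Soft-masked genome store.
#' @param specificity Optional [summarize_specificity()] output; when given,
#'   the `specific_repetitive` flag (fully repetitive and specific) is filled.
#' @return data.frame with `probe_id`, `n_bp_repetitive` (0-50), `repetitive`
#'   (> 25 bp) and `specific_repetitive` (= 50 bp and not non-specific).
#' @export
count_repetitive_bp <- function(probe_intervals, genome, specificity = NULL) {
  n <- vapply(seq_len(nrow(probe_intervals)), function(i) {
    s <- genome_fetch(
      genome, probe_intervals$chrom[i],
      probe_intervals$probe_start[i], probe_intervals$probe_end[i],
      clip = TRUE
    )
    sum(strsplit(s, "", fixed = TRUE)[[1]] %in% c("a", "c", "g", "t", "n"))
  }, integer(1))
  out <- data.frame(
    probe_id = probe_intervals$probe_id,
    n_bp_repetitive = n,
    repetitive = n > 25L,
    specific_repetitive = NA,
    stringsAsFactors = FALSE
  )
  if (!is.null(specificity)) {
    m <- match(out$probe_id, specificity$probe_id)
    out$specific_repetitive <- n == 50L & !specificity$non_specific[m]
  }
  out
}
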