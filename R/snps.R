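# Target-CpG SNP annotation and SNP-proximity classes.
#
# A SNP annotates a probe's target CpG iff its (1-based) position equals the
# C (MAPINFO) or the G (MAPINFO + 1) of the target CpG — even when the probe
# footprint itself excludes the G. Proximity classes follow the annotation
# columns: SNP <10 bp (within 10 bases of the target CpG, inside the probe
# footprint) and SNP >10 bp (elsewhere in the footprint); probes with a
# target-CpG SNP are removed from the <10 bp class for analyses.
#
# The fast route uses IRanges interval overlap; tests check it against a
# quadratic probe x SNP scan.

#' Annotate SNPs at the target CpG
#'
#' @param probes Probe records; only `cg`-category probes are annotated.
#' @param snps Filtered SNP table from [read_snp_table()] (1 bp, weight 1,
#'   at most one record per genomic base).
#' @return data.frame with `probe_id`, `target_cpg_snps` (comma-joined rs
#'   ids, NA when none), `n_target_cpg_snp` and `max_het` (NA when no SNP is
#'   documented as variable).
#' @export
annotate_target_cpg_snps <- function(probes, snps) {
  key_snp <- paste(snps$chrom, snps$pos)
  hit_c <- match(paste(probes$chrom, probes$mapinfo), key_snp)
  hit_g <- match(paste(probes$chrom, probes$mapinfo + 1L), key_snp)
  cg <- probes$category == "cg"
  hit_c[!cg] <- NA
  hit_g[!cg] <- NA
  n <- (!is.na(hit_c)) + (!is.na(hit_g))
  join2 <- function(a, b) {
    ifelse(is.na(a), b, ifelse(is.na(b), a, paste(pmin(a, b), pmax(a, b), sep = ",")))
  }
  ids <- join2(snps$rs_id[hit_c], snps$rs_id[hit_g])
  het <- pmax(snps$het[hit_c], snps$het[hit_g], na.rm = TRUE)
  het[is.na(hit_c) & is.na(hit_g)] <- NA_real_
  data.frame(
    probe_id = probes$probe_id,
    target_cpg_snps = ids,
    n_target_cpg_snp = as.integer(n),
    max_het = het,
    stringsAsFactors = FALSE
  )
}

#' Classify SNP proximity to the target CpG
#'
#' @param probes Probe records.
#' @param snps Filtered SNP table.
#' @param probe_intervals Output of [compute_probe_intervals()].
#' @param near_bp Window defining the "<10 bp" class, measured inclusively
#'   from the nearest base of the target CpG (default 10).
#' @return data.frame with logical `snp_lt10bp`, `snp_gt10bp` and
#'   `snp_lt10bp_analysis` (the `<10 bp` class with target-CpG-SNP probes
#'   removed, as used in the variability analyses).
#' @export
classify_snp_proximity <- function(probes, snps, probe_intervals = NULL, near_bp = 10L) {
  if (is.null(probe_intervals)) probe_intervals <- compute_probe_intervals(probes)
  target <- annotate_target_cpg_snps(probes, snps)
  lt <- logical(nrow(probes))
  gt <- logical(nrow(probes))
  for (chrom in unique(probe_intervals$chrom)) {
    pi_idx <- which(probe_intervals$chrom == chrom)
    s <- snps[snps$chrom == chrom, , drop = FALSE]
    if (!nrow(s) || !length(pi_idx)) next
    iv <- probe_intervals[pi_idx, ]
    ir_probe <- IRanges::IRanges(start = iv$probe_start + 1L, end = iv$probe_end)
    ir_snp <- IRanges::IRanges(start = s$pos, width = 1L)
    ov <- IRanges::findOverlaps(ir_probe, ir_snp)
    if (!length(ov)) next
    qi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    p0 <- s$pos[si] - 1L
    cpg_s <- iv$cpg_start[qi]
    cpg_e <- iv$cpg_end[qi]
    at_target <- p0 >= cpg_s & p0 < cpg_e
    d <- pmax(0L, pmax(cpg_s - p0, p0 - (cpg_e - 1L)))
    near <- !at_target & d <= near_bp
    far <- !at_target & d > near_bp
    lt[pi_idx] <- lt[pi_idx] | tabulate(qi[near], nbins = length(pi_idx)) > 0
    gt[pi_idx] <- gt[pi_idx] | tabulate(qi[far], nbins = length(pi_idx)) > 0
  }
  data.frame(
    probe_id = probes$probe_id,
    has_target_snp = target$n_target_cpg_snp > 0L,
    snp_lt10bp = lt,
    snp_gt10bp = gt,
    snp_lt10bp_analysis = lt & target$n_target_cpg_snp == 0L,
    stringsAsFactors = FALSE
  )
}

#' Heterozygosity bins of target-CpG-SNP probes
#'
#' Bins probes carrying a target CpG SNP by their maximum documented
#' heterozygosity: `not_documented` (no heterozygosity value or 0),
#' `le_0.1` (0 < het <= 0.1) and `gt_0.1` (het > 0.1).
#'
#' @param annotations Output of [annotate_target_cpg_snps()].
#' @return data.frame with bin counts and fractions (summing to 1 over
#'   annotated probes).
#' @export
heterozygosity_summary <- function(annotations) {
  ann <- annotations[annotations$n_target_cpg_snp > 0L, , drop = FALSE]
  het <- ann$max_het
  counts <- c(
    not_documented = sum(is.na(het) | het == 0),
    le_0.1 = sum(!is.na(het) & het > 0 & het <= 0.1),
    gt_0.1 = sum(!is.na(het) & het > 0.1)
  )
  data.frame(
    bin = names(counts),
    count = as.integer(counts),
    fraction = if (sum(counts)) as.numeric(counts / sum(counts)) else rep(NA_real_, 3),
    stringsAsFactors = FALSE
  )
}
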