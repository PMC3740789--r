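# End-to-end expanded annotation: merges probe intervals, SNP flags,
# specificity counts, repetitive-bp counts, HIL and UCSC CpG classes, gene
# features and closest-TSS columns into one per-probe table.

#' Run the full expanded annotation
#'
#' `rs`-category probes are parsed but excluded from annotation. SNP and
#' gene tables are optional: their sections are skipped with a warning and
#' the corresponding columns left empty.
#'
#' @param probes Probe records (see [read_manifest()]).
#' @param genome Genome store.
#' @param snps Optional filtered SNP table.
#' @param gene_models Optional gene-model data.frame.
#' @param tss_models Optional separate table for closest-TSS annotation
#'   (defaults to `gene_models`).
#' @param sex_chroms Sex chromosome names.
#' @param seed_len Seed length for the specificity search.
#' @return List: `table` (the merged per-probe annotation data.frame),
#'   `islands` (merged HIL islands), `ucsc_islands`, `summary` (class counts
#'   and the HIL x UCSC cross-tabulation), `specificity` (per-probe detail).
#' @export
annotate_all <- function(probes, genome, snps = NULL, gene_models = NULL,
                         tss_models = gene_models,
                         sex_chroms = c("chrX", "chrY"), seed_len = 12L) {
  ann_probes <- probes[probes$category != "rs", , drop = FALSE]
  iv <- compute_probe_intervals(ann_probes)
  tab <- data.frame(
    probe_id = ann_probes$probe_id,
    CHR = ann_probes$chrom,
    MAPINFO = ann_probes$mapinfo,
    stringsAsFactors = FALSE
  )

  # SNPs (cg probes only)
  if (!is.null(snps)) {
    sa <- annotate_target_cpg_snps(ann_probes, snps)
    tab[["target CpG SNP"]] <- sa$target_cpg_snps
    tab[["n_target CpG SNP"]] <- sa$n_target_cpg_snp
  } else {
    warning("annotate_all: no SNP table; target CpG SNP columns skipped")
  }

  # specificity screen
  variants <- bisulfite_variants(genome)
  hits <- find_candidate_hits(ann_probes, genome, variants, seed_len = seed_len)
  accepted <- filter_hits(hits)
  spec <- summarize_specificity(accepted, ann_probes, sex_chroms = sex_chroms)
  tab$AlleleA_Hits <- spec$AlleleA_Hits
  tab$AlleleB_Hits <- spec$AlleleB_Hits
  tab$XY_Hits <- spec$XY_Hits
  tab$Autosomal_Hits <- spec$Autosomal_Hits
  tab$non_specific <- spec$non_specific

  rep_bp <- count_repetitive_bp(iv, genome, spec)
  tab$n_bp_repetitive <- rep_bp$n_bp_repetitive

  # CpG landscape
  hc <- find_islands(genome, "HC")
  ic <- find_islands(genome, "IC")
  merged <- merge_hil(hc, ic)
  hil <- classify_probe_hil(iv, merged)
  tab$HIL_CpG_class <- hil$HIL_CpG_class
  tab$HIL_CpG_Island_Name <- hil$HIL_CpG_Island_Name
  ucsc_islands <- find_islands(genome, "UCSC")
  ucsc <- classify_probe_ucsc(iv, ucsc_islands)
  tab$UCSC_CpG_class <- ucsc$UCSC_CpG_class

  # gene features and TSS
  features <- NULL
  if (!is.null(gene_models)) {
    features <- annotate_probe_features(iv, gene_models)
    tab <- cbind(tab, features$indicator[, -1, drop = FALSE])
    tss <- closest_tss(iv, tss_models)
    tab$Closest_TSS <- tss$Closest_TSS
    tab$Distance_closest_TSS <- tss$Distance_closest_TSS
    tab$Closest_TSS_gene_name <- tss$Closest_TSS_gene_name
    tab$Closest_TSS_Transcript <- tss$Closest_TSS_Transcript
  } else {
    warning("annotate_all: no gene table; gene feature / TSS columns skipped")
  }

  xt <- table(HIL = tab$HIL_CpG_class, UCSC = tab$UCSC_CpG_class)
  list(
    table = tab,
    islands = merged,
    ucsc_islands = ucsc_islands,
    specificity = spec,
    features = features,
    summary = list(
      n_probes = nrow(tab),
      hil_counts = table(tab$HIL_CpG_class),
      ucsc_counts = table(tab$UCSC_CpG_class),
      hil_ucsc_crosstab = xt,
      specificity_crosstab = specificity_crosstab(spec)
    )
  )
}
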