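# Nine-way gene-feature classification and closest-TSS annotation.
#
# Per transcript, every base inside the transcript carries exactly one gene
# component (first exon / exon / intron; "first exon" is the most upstream
# exon in transcription direction, "exon" the remaining exons) and exactly
# one gene region (5'UTR / body / 3'UTR; UTRs from the tx/cds boundaries,
# strand-aware). The nine features are the pairwise intersections.

.GENE_FEATURES <- c(
  "5'UTR first exon", "5'UTR exon", "5'UTR intron",
  "body first exon", "body exon", "body intron",
  "3'UTR first exon", "3'UTR exon", "3'UTR intron"
)

#' Build labeled feature intervals for one transcript
#'
#' @param model One row of a gene-model data.frame (see [read_gene_table()]).
#' @return data.frame of intervals (`start`, `end`, 0-based half-open) with
#'   `component` (first exon/exon/intron), `region` (5'UTR/body/3'UTR) and
#'   `feature` (their combination). Non-coding transcripts
#'   (`cds_start == cds_end`) have all bases labeled `body`.
#' @export
build_feature_intervals <- function(model) {
  es <- model$exon_starts[[1]]
  ee <- model$exon_ends[[1]]
  strand <- model$strand
  n_ex <- length(es)
  first_idx <- if (strand == "+") 1L else n_ex
  comp <- data.frame(
    start = es, end = ee,
    component = ifelse(seq_len(n_ex) == first_idx, "first exon", "exon"),
    stringsAsFactors = FALSE
  )
  if (n_ex > 1) {
    comp <- rbind(comp, data.frame(
      start = ee[-n_ex], end = es[-1], component = "intron",
      stringsAsFactors = FALSE
    ))
  }
  comp <- comp[comp$end > comp$start, , drop = FALSE]
  # gene regions from tx/cds boundaries, strand-aware
  cs <- model$cds_start
  ce <- model$cds_end
  if (model$cds_start == model$cds_end) {
    regions <- data.frame(
      start = model$tx_start, end = model$tx_end, region = "body",
      stringsAsFactors = FALSE
    )
  } else {
    left <- data.frame(
      start = model$tx_start, end = cs,
      region = if (strand == "+") "5'UTR" else "3'UTR", stringsAsFactors = FALSE
    )
    right <- data.frame(
      start = ce, end = model$tx_end,
      region = if (strand == "+") "3'UTR" else "5'UTR", stringsAsFactors = FALSE
    )
    regions <- rbind(
      left,
      data.frame(start = cs, end = ce, region = "body", stringsAsFactors = FALSE),
      right
    )
    regions <- regions[regions$end > regions$start, , drop = FALSE]
  }
  out <- list()
  for (i in seq_len(nrow(comp))) {
    for (j in seq_len(nrow(regions))) {
      s <- max(comp$start[i], regions$start[j])
      e <- min(comp$end[i], regions$end[j])
      if (s < e) {
        out[[length(out) + 1L]] <- data.frame(
          start = s, end = e,
          component = comp$component[i], region = regions$region[j],
          feature = paste(regions$region[j], comp$component[i]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Annotate probes with gene features
#'
#' Labels are collected over every transcript overlapping the target C and
#' de-duplicated by (feature, transcript); a per-gene collapsed view
#' de-duplicates by (feature, gene).
#'
#' @param probe_intervals Output of [compute_probe_intervals()].
#' @param models Gene-model data.frame.
#' @return List with `transcript_level` (one row per probe x transcript x
#'   feature), `gene_level` (deduplicated by gene), and `indicator` (probe x
#'   nine-feature 0/1 matrix as data.frame, first column `probe_id`).
#' @export
annotate_probe_features <- function(probe_intervals, models) {
  feat_iv <- lapply(seq_len(nrow(models)), function(i) build_feature_intervals(models[i, ]))
  rows <- list()
  for (i in seq_len(nrow(probe_intervals))) {
    pos <- probe_intervals$cpg_start[i] # the target C
    for (j in seq_len(nrow(models))) {
      if (models$chrom[j] != probe_intervals$chrom[i]) next
      fi <- feat_iv[[j]]
      hit <- fi[fi$start <= pos & pos < fi$end, , drop = FALSE]
      if (nrow(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          probe_id = probe_intervals$probe_id[i],
          transcript_id = models$transcript_id[j],
          gene_name = models$gene_name[j],
          feature = hit$feature[1],
          noncoding = isTRUE(models$noncoding[j]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  tl <- if (length(rows)) do.call(rbind, rows) else data.frame(
    probe_id = character(), transcript_id = character(), gene_name = character(),
    feature = character(), noncoding = logical(), stringsAsFactors = FALSE
  )
  tl <- tl[!duplicated(tl[, c("probe_id", "transcript_id", "feature")]), , drop = FALSE]
  gl <- tl[!duplicated(tl[, c("probe_id", "gene_name", "feature")]), c("probe_id", "gene_name", "feature")]
  ind <- data.frame(probe_id = probe_intervals$probe_id, stringsAsFactors = FALSE)
  for (f in .GENE_FEATURES) {
    ind[[f]] <- as.integer(probe_intervals$probe_id %in% tl$probe_id[tl$feature == f])
  }
  list(transcript_level = tl, gene_level = gl, indicator = ind)
}

#' Closest transcription start site per probe
#'
#' Distance is measured from the 1-based target C to the strand-aware TSS of
#' every transcript on the probe's chromosome, regardless of gene membership.
#' Ties go to the lexicographically smallest transcript id and are flagged.
#'
#' @param probe_intervals Output of [compute_probe_intervals()].
#' @param models Gene-model data.frame (may be a different table than the one
#'   used for features).
#' @return data.frame with `Closest_TSS` (1-based position),
#'   `Distance_closest_TSS` (unsigned), `signed_distance` (negative = probe
#'   upstream of the TSS in transcription direction),
#'   `Closest_TSS_gene_name`, `Closest_TSS_Transcript`, `tss_tie`.
#' @export
closest_tss <- function(probe_intervals, models) {
  # 0-based TSS base: txStart for +, txEnd-1 for -
  tss0 <- ifelse(models$strand == "+", models$tx_start, models$tx_end - 1L)
  out <- data.frame(
    probe_id = probe_intervals$probe_id,
    Closest_TSS = NA_integer_,
    Distance_closest_TSS = NA_integer_,
    signed_distance = NA_integer_,
    Closest_TSS_gene_name = NA_character_,
    Closest_TSS_Transcript = NA_character_,
    tss_tie = FALSE,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(probe_intervals))) {
    on_chr <- which(models$chrom == probe_intervals$chrom[i])
    if (!length(on_chr)) next
    pos <- probe_intervals$cpg_start[i]
    d <- abs(pos - tss0[on_chr])
    dmin <- min(d)
    cand <- on_chr[d == dmin]
    pick <- cand[order(models$transcript_id[cand])][1]
    out$Closest_TSS[i] <- tss0[pick] + 1L
    out$Distance_closest_TSS[i] <- dmin
    # negative = probe upstream of the TSS in transcription direction
    raw <- pos - tss0[pick]
    out$signed_distance[i] <- if (models$strand[pick] == "+") raw else -raw
    out$Closest_TSS_gene_name[i] <- models$gene_name[pick]
    out$Closest_TSS_Transcript[i] <- models$transcript_id[pick]
    out$tss_tie[i] <- length(cand) > 1L
  }
  out
}
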