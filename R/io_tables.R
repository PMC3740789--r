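# Readers/writers for the delimited tables the pipeline touches. All outputs
# are tab-delimited UTF-8 with a header; coordinates in dbSNP/refGene-style
# dumps follow the UCSC 0-based half-open convention and are kept internal.

#' Read a dbSNP-style table
#'
#' Expects columns (case-insensitive): `chrom`, `chromStart`, `chromEnd`,
#' `name`, `weight`, `avHet` (aliases `start`/`end`/`het` accepted). Records
#' that are not exactly 1 bp long or not of weight 1 are dropped and counted,
#' as are malformed rows.
#'
#' @param path Delimited file.
#' @return data.frame of retained SNPs with columns `rs_id`, `chrom`, `pos`
#'   (1-based single base), `weight`, `het` (NA = not documented as variable);
#'   attribute `dropped` carries the per-rule drop counts.
#' @export
read_snp_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  lc <- tolower(names(raw))
  pick <- function(..., required = TRUE) {
    for (cand in c(...)) {
      i <- match(tolower(cand), lc)
      if (!is.na(i)) {
        return(raw[[i]])
      }
    }
    if (required) stop("read_snp_table: missing column ", ..1)
    NULL
  }
  x <- data.frame(
    rs_id = as.character(pick("name", "rs_id")),
    chrom = as.character(pick("chrom")),
    start = suppressWarnings(as.numeric(pick("chromStart", "start"))),
    end = suppressWarnings(as.numeric(pick("chromEnd", "end"))),
    weight = suppressWarnings(as.numeric(pick("weight"))),
    het = suppressWarnings(as.numeric(pick("avHet", "het", required = FALSE))),
    stringsAsFactors = FALSE
  )
  if (is.null(x$het)) x$het <- NA_real_
  malformed <- is.na(x$start) | is.na(x$end) | is.na(x$weight) | !nzchar(x$rs_id)
  not_1bp <- !malformed & (x$end - x$start) != 1
  bad_weight <- !malformed & !not_1bp & x$weight != 1
  keep <- !(malformed | not_1bp | bad_weight)
  out <- x[keep, , drop = FALSE]
  out$pos <- as.integer(out$start + 1) # 1-based single base
  out <- out[, c("rs_id", "chrom", "pos", "weight", "het")]
  # keep one record per genomic base (rs ids unique per (chrom, pos))
  out <- out[!duplicated(paste(out$chrom, out$pos)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- c(
    malformed = sum(malformed), not_1bp = sum(not_1bp), bad_weight = sum(bad_weight)
  )
  out
}

#' Read a refGene-style gene-model table
#'
#' Expects columns (case-insensitive): `name` (transcript id), `name2`
#' (gene name), `chrom`, `strand`, `txStart`, `txEnd`, `cdsStart`, `cdsEnd`,
#' `exonStarts`, `exonEnds` (comma-joined). Coordinates are UCSC 0-based
#' half-open and kept as such. Records violating the exon invariants are
#' rejected with a diagnostic.
#'
#' @param path Delimited file.
#' @return data.frame with one row per transcript; `exon_starts`/`exon_ends`
#'   are list-columns of integer vectors; `noncoding` flags cdsStart==cdsEnd.
#' @export
read_gene_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  lc <- tolower(names(raw))
  pick <- function(...) {
    for (cand in c(...)) {
      i <- match(tolower(cand), lc)
      if (!is.na(i)) {
        return(raw[[i]])
      }
    }
    stop("read_gene_table: missing column ", ..1)
  }
  parse_csv_ints <- function(v) {
    lapply(strsplit(as.character(v), ",", fixed = TRUE), function(s) as.integer(s[nzchar(s)]))
  }
  x <- data.frame(
    transcript_id = as.character(pick("name", "transcript_id")),
    gene_name = as.character(pick("name2", "gene_name")),
    chrom = as.character(pick("chrom")),
    strand = as.character(pick("strand")),
    tx_start = as.integer(pick("txStart", "tx_start")),
    tx_end = as.integer(pick("txEnd", "tx_end")),
    cds_start = as.integer(pick("cdsStart", "cds_start")),
    cds_end = as.integer(pick("cdsEnd", "cds_end")),
    stringsAsFactors = FALSE
  )
  x$exon_starts <- parse_csv_ints(pick("exonStarts", "exon_starts"))
  x$exon_ends <- parse_csv_ints(pick("exonEnds", "exon_ends"))
  validate_gene_models(x)
  x$noncoding <- x$cds_start == x$cds_end
  x
}

#' @rdname read_gene_table
#' @param models Gene-model data.frame.
#' @export
validate_gene_models <- function(models) {
  for (i in seq_len(nrow(models))) {
    es <- models$exon_starts[[i]]
    ee <- models$exon_ends[[i]]
    id <- models$transcript_id[i]
    if (length(es) != length(ee)) {
      stop("gene model ", id, ": exon start/end count mismatch")
    }
    if (is.unsorted(es, strictly = TRUE) || any(ee <= es) ||
      (length(es) > 1 && any(es[-1] < ee[-length(ee)]))) {
      stop("gene model ", id, ": exons must be sorted and non-overlapping")
    }
    if (!models$strand[i] %in% c("+", "-")) {
      stop("gene model ", id, ": strand must be + or -")
    }
    with_m <- models[i, ]
    if (!(with_m$tx_start <= with_m$cds_start && with_m$cds_start <= with_m$cds_end &&
      with_m$cds_end <= with_m$tx_end)) {
      stop("gene model ", id, ": need txStart <= cdsStart <= cdsEnd <= txEnd")
    }
  }
  invisible(models)
}

# Verbatim column order of the expanded annotation table.
.ANNOT_COLUMNS <- c(
  "probe_id", "CHR", "MAPINFO",
  "target CpG SNP", "n_target CpG SNP",
  "AlleleA_Hits", "AlleleB_Hits", "XY_Hits", "Autosomal_Hits",
  "n_bp_repetitive",
  "HIL_CpG_class", "HIL_CpG_Island_Name", "UCSC_CpG_class",
  "Closest_TSS", "Distance_closest_TSS",
  "Closest_TSS_gene_name", "Closest_TSS_Transcript",
  "5'UTR first exon", "5'UTR exon", "5'UTR intron",
  "body first exon", "body exon", "body intron",
  "3'UTR first exon", "3'UTR exon", "3'UTR intron"
)

#' Write / read the expanded per-probe annotation table
#'
#' Tab-delimited UTF-8 with the expanded-annotation column names emitted
#' verbatim (including the nine gene-feature indicator columns). Reading
#' restores an equal in-memory structure.
#'
#' @param records data.frame containing at least `probe_id`; recognised
#'   annotation columns are written in canonical order, any others appended.
#' @param path File path.
#' @export
write_annotation_table <- function(records, path) {
  if (!"probe_id" %in% names(records) || any(is.na(records$probe_id) | !nzchar(records$probe_id))) {
    stop("write_annotation_table: records must carry non-missing probe ids")
  }
  known <- intersect(.ANNOT_COLUMNS, names(records))
  extra <- setdiff(names(records), .ANNOT_COLUMNS)
  out <- records[, c(known, extra), drop = FALSE]
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_annotation_table
#' @export
read_annotation_table <- function(path) {
  utils::read.delim(path,
    stringsAsFactors = FALSE, check.names = FALSE,
    na.strings = "", encoding = "UTF-8"
  )
}

#' Write / read a beta-value matrix with sample metadata
#'
#' The matrix is written probes x samples as TSV with a `probe_id` first
#' column; sample metadata (`sample_id`, `tissue`, `sex`) go to a sidecar
#' file `<path>.samples.tsv`.
#'
#' @param beta Numeric matrix (probes x samples) with dimnames.
#' @param samples data.frame with `sample_id`, `tissue`, `sex` matching
#'   `colnames(beta)`.
#' @param path Matrix file path.
#' @export
write_beta_matrix <- function(beta, samples, path) {
  stopifnot(is.matrix(beta), identical(colnames(beta), samples$sample_id))
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(samples, paste0(path, ".samples.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_beta_matrix
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  beta <- as.matrix(df[, -1, drop = FALSE])
  rownames(beta) <- df$probe_id
  samples <- utils::read.delim(paste0(path, ".samples.tsv"), stringsAsFactors = FALSE)
  list(beta = beta, samples = samples)
}
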