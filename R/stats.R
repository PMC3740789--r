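# Methylation-matrix statistics: beta/M transforms, variability screens,
# level categories, KS comparisons, tissue differential methylation (tDM),
# relative enrichment, and the sex-difference screen.

#' M value from methylated/unmethylated intensities
#'
#' `M = log2((intensity_m + 1) / (intensity_u + 1))`.
#'
#' @param intensity_m,intensity_u Non-negative intensities (vectorised).
#' @export
m_from_intensities <- function(intensity_m, intensity_u) {
  if (any(intensity_m < 0 | intensity_u < 0)) {
    stop("m_from_intensities: intensities must be >= 0")
  }
  log2((intensity_m + 1) / (intensity_u + 1))
}

#' Convert between beta and M values
#'
#' `beta = 2^M / (2^M + 1)`; the inverse is `M = log2(beta / (1 - beta))`.
#' Betas at exactly 0 or 1 are clamped inward by `clamp` before inversion
#' (logged via a message the first time it happens in a call).
#'
#' @param M,beta Numeric vectors/matrices.
#' @param clamp Clamp width for beta in `{0, 1}` (default `1e-6`).
#' @export
beta_from_m <- function(M) {
  2^M / (2^M + 1)
}

#' @rdname beta_from_m
#' @export
m_from_beta <- function(beta, clamp = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("m_from_beta: beta values must lie in [0, 1]")
  }
  n_clamped <- sum(beta %in% c(0, 1))
  if (n_clamped > 0) {
    message("m_from_beta: clamped ", n_clamped, " boundary beta value(s) by ", clamp)
    beta <- pmin(pmax(beta, clamp), 1 - clamp)
  }
  log2(beta / (1 - beta))
}

#' Per-probe standard deviation within sample groups
#'
#' Sample SD (n-1 denominator) of each probe within each group; groups of
#' one sample are flagged undefined (NA).
#'
#' @param beta Probes x samples matrix.
#' @param groups Group label per column.
#' @return Matrix probes x groups of SDs.
#' @export
within_group_sd <- function(beta, groups) {
  stopifnot(ncol(beta) == length(groups))
  gl <- unique(groups)
  out <- sapply(gl, function(g) {
    cols <- which(groups == g)
    if (length(cols) < 2) {
      return(rep(NA_real_, nrow(beta)))
    }
    sqrt(.row_vars(beta[, cols, drop = FALSE]))
  })
  out <- matrix(out, nrow = nrow(beta), dimnames = list(rownames(beta), gl))
  out
}

# vectorised per-row sample variance (n-1 denominator)
.row_vars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1L)
}

#' Flag highly variable probes
#'
#' @param sds Numeric vector of within-tissue SDs in beta.
#' @param threshold Flag when `SD >= threshold` (default 0.25).
#' @export
flag_highly_variable <- function(sds, threshold = 0.25) {
  !is.na(sds) & sds >= threshold
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' `D = max |ECDF1 - ECDF2|`, with the asymptotic two-sided tail
#' probability. Implemented directly (tests compare against
#' `stats::ks.test`).
#'
#' @param x,y Numeric samples.
#' @return List with `D` and `p`.
#' @export
ks_statistic <- function(x, y) {
  x <- sort(x[!is.na(x)])
  y <- sort(y[!is.na(y)])
  n1 <- length(x)
  n2 <- length(y)
  if (!n1 || !n2) stop("ks_statistic: empty sample")
  all_v <- sort(unique(c(x, y)))
  d <- max(abs(
    findInterval(all_v, x) / n1 - findInterval(all_v, y) / n2
  ))
  ne <- n1 * n2 / (n1 + n2)
  lambda <- sqrt(ne) * d
  k <- 1:100
  p <- min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * lambda^2 * k^2))))
  list(D = d, p = p)
}

#' Compare SD-in-beta distributions of probe classes against all probes
#'
#' Probes with SD below `min_sd` (default 0.10) are removed from every
#' group first; each class's SD distribution is then compared with that of
#' all (retained) probes by the two-sample KS statistic.
#'
#' @param sds Named numeric vector of per-probe SDs (all probes).
#' @param classes Named list of logical vectors (or probe-id vectors)
#'   selecting each class.
#' @param min_sd Removal threshold (default 0.10, strict `<` removal).
#' @return data.frame with class, n, D and p (classes empty after the filter
#'   are reported with NA and skipped).
#' @export
sd_distribution_compare <- function(sds, classes, min_sd = 0.10) {
  keep <- !is.na(sds) & sds >= min_sd
  all_sd <- sds[keep]
  res <- lapply(names(classes), function(cl) {
    sel <- classes[[cl]]
    if (!is.logical(sel)) sel <- names(sds) %in% sel
    v <- sds[keep & sel]
    if (!length(v)) {
      return(data.frame(
        class = cl, n = 0L, D = NA_real_, p = NA_real_,
        stringsAsFactors = FALSE
      ))
    }
    ks <- ks_statistic(v, all_sd)
    data.frame(class = cl, n = length(v), D = ks$D, p = ks$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Three-level methylation category of a mean beta value
#'
#' hypomethylated: 0 to <= 0.2; heterogeneously methylated: > 0.2 to < 0.8;
#' hypermethylated: >= 0.8 to 1.
#'
#' @param mean_beta Numeric vector in `[0, 1]`.
#' @return Character vector over `{"hypo", "hetero", "hyper"}`.
#' @export
methylation_level <- function(mean_beta) {
  ifelse(mean_beta <= 0.2, "hypo", ifelse(mean_beta < 0.8, "hetero", "hyper"))
}

#' Select tissue differentially methylated (tDM) probes
#'
#' Per-tissue means are compared by a z-score,
#' `z = (mu1 - mu2) / sqrt(s1^2/n1 + s2^2/n2)` (Welch form; a pooled-variance
#' alternative is available), with a two-sided normal tail and Bonferroni
#' correction at family-wise level `alpha`.
#'
#' @param beta Probes x samples matrix.
#' @param tissues Tissue label per column.
#' @param pair Length-2 character vector naming the tissues to compare
#'   (defaults to the first two labels).
#' @param alpha Family-wise error level (default 0.05).
#' @param variance `"welch"` (default) or `"pooled"`.
#' @return data.frame per probe: `delta_mean`, `z`, `p`, `significant`.
#' @export
select_tdm <- function(beta, tissues, pair = NULL, alpha = 0.05,
                       variance = c("welch", "pooled")) {
  variance <- match.arg(variance)
  if (is.null(pair)) pair <- unique(tissues)[1:2]
  stopifnot(length(pair) == 2, all(pair %in% tissues))
  c1 <- which(tissues == pair[1])
  c2 <- which(tissues == pair[2])
  if (length(c1) < 2 || length(c2) < 2) {
    stop("select_tdm: need >= 2 samples per tissue")
  }
  m1 <- rowMeans(beta[, c1, drop = FALSE])
  m2 <- rowMeans(beta[, c2, drop = FALSE])
  v1 <- .row_vars(beta[, c1, drop = FALSE])
  v2 <- .row_vars(beta[, c2, drop = FALSE])
  n1 <- length(c1)
  n2 <- length(c2)
  se <- if (variance == "welch") {
    sqrt(v1 / n1 + v2 / n2)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  delta <- m1 - m2
  z <- ifelse(se == 0, ifelse(delta == 0, 0, sign(delta) * Inf), delta / se)
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(
    probe_id = rownames(beta),
    delta_mean = delta, z = z, p = p,
    significant = p < alpha / nrow(beta),
    stringsAsFactors = FALSE
  )
}

#' Percentage relative enrichment of tDM probes per class
#'
#' `PRE = 100 * (f_tDM - f_all) / f_all`, where `f` is the fraction of
#' probes belonging to the class within the tDM set and within all probes.
#' The composition test is a two-sided Fisher's exact test of tDM membership
#' against class membership; significance at `p < 1e-7`.
#'
#' @param tdm_flags Logical vector: probe is tDM.
#' @param class_labels Class label per probe (same length).
#' @param sig_threshold Significance threshold (default `1e-7`).
#' @return data.frame per class: `f_all`, `f_tdm`,
#'   `pct_relative_enrichment`, `p`, `significant`.
#' @export
relative_enrichment <- function(tdm_flags, class_labels, sig_threshold = 1e-7) {
  stopifnot(length(tdm_flags) == length(class_labels))
  classes <- unique(class_labels)
  n_all <- length(class_labels)
  n_tdm <- sum(tdm_flags)
  res <- lapply(classes, function(cl) {
    in_cl <- class_labels == cl
    f_all <- sum(in_cl) / n_all
    if (f_all == 0 || n_tdm == 0) {
      return(data.frame(
        class = cl, f_all = f_all, f_tdm = NA_real_,
        pct_relative_enrichment = NA_real_, p = NA_real_, significant = NA,
        stringsAsFactors = FALSE
      ))
    }
    f_tdm <- sum(in_cl & tdm_flags) / n_tdm
    pre <- 100 * (f_tdm - f_all) / f_all
    tab <- matrix(c(
      sum(in_cl & tdm_flags), sum(!in_cl & tdm_flags),
      sum(in_cl & !tdm_flags), sum(!in_cl & !tdm_flags)
    ), nrow = 2)
    p <- stats::fisher.test(tab)$p.value
    data.frame(
      class = cl, f_all = f_all, f_tdm = f_tdm,
      pct_relative_enrichment = pre, p = p,
      significant = p < sig_threshold, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Screen for sex-differentially methylated probes
#'
#' Moderated two-sample test on M values (limma eBayes; a documented
#' stand-in for SAM) with Benjamini-Hochberg FDR, crossed with a minimum
#' absolute difference in mean beta between the sexes.
#'
#' @param beta Probes x samples matrix of beta values.
#' @param sex Sex label per column (two levels required).
#' @param fdr FDR threshold (default 0.01).
#' @param min_delta Minimum |delta beta| (default 0.10); 0 reduces the
#'   screen to the pure FDR criterion.
#' @return data.frame of all probes with `delta_beta`, `p`, `fdr`,
#'   `selected`; attribute `method` is `"standin"`.
#' @export
sex_differential <- function(beta, sex, fdr = 0.01, min_delta = 0.10) {
  lv <- unique(sex)
  if (length(lv) != 2) stop("sex_differential: need exactly two sexes present")
  M <- m_from_beta(beta)
  design <- stats::model.matrix(~ factor(sex, levels = lv))
  fit <- limma::eBayes(limma::lmFit(M, design))
  p <- fit$p.value[, 2]
  q <- stats::p.adjust(p, method = "BH")
  delta <- abs(
    rowMeans(beta[, sex == lv[1], drop = FALSE]) -
      rowMeans(beta[, sex == lv[2], drop = FALSE])
  )
  out <- data.frame(
    probe_id = rownames(beta),
    delta_beta = delta, p = p, fdr = q,
    selected = q < fdr & delta >= min_delta,
    stringsAsFactors = FALSE
  )
  attr(out, "method") <- "standin"
  out
}

#' Pre-filter a beta matrix for analysis
#'
#' Removes probes with detection p > `detection_p_max` in any sample, probes
#' with any missing beta, all `rs` and `ch` probes, all sex-chromosome
#' probes, and all non-specific probes. Rules whose inputs are absent are
#' skipped and logged.
#'
#' @param beta Probes x samples matrix.
#' @param detection_p Optional matrix of detection p values (same shape).
#' @param annotations Optional data.frame with `probe_id` and any of
#'   `category`, `chrom`, `non_specific`.
#' @param sex_chroms Sex chromosome names.
#' @param detection_p_max Threshold (default 0.01).
#' @return Filtered matrix; attribute `removed` logs counts per rule.
#' @export
prefilter_probes <- function(beta, detection_p = NULL, annotations = NULL,
                             sex_chroms = c("chrX", "chrY"), detection_p_max = 0.01) {
  keep <- rep(TRUE, nrow(beta))
  removed <- c()
  if (!is.null(detection_p)) {
    bad <- apply(detection_p > detection_p_max, 1, any)
    removed["detection_p"] <- sum(bad & keep)
    keep <- keep & !bad
  } else {
    removed["detection_p"] <- NA_integer_
  }
  bad <- apply(is.na(beta), 1, any)
  removed["missing_beta"] <- sum(bad & keep)
  keep <- keep & !bad
  if (!is.null(annotations)) {
    m <- match(rownames(beta), annotations$probe_id)
    if ("category" %in% names(annotations)) {
      bad <- annotations$category[m] %in% c("rs", "ch")
      removed["rs_ch"] <- sum(bad & keep, na.rm = TRUE)
      keep <- keep & !bad
    }
    if ("chrom" %in% names(annotations)) {
      bad <- annotations$chrom[m] %in% sex_chroms
      removed["sex_chrom"] <- sum(bad & keep, na.rm = TRUE)
      keep <- keep & !bad
    }
    if ("non_specific" %in% names(annotations)) {
      bad <- annotations$non_specific[m] %in% TRUE
      removed["non_specific"] <- sum(bad & keep, na.rm = TRUE)
      keep <- keep & !bad
    }
  }
  out <- beta[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}
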