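# beta/M transforms, variability screens, KS, tDM, enrichment, sex screen

test_that("M and beta transforms are exact inverses with the stated anchors", {
  expect_equal(m_from_intensities(3, 1), 1.0)
  expect_equal(m_from_intensities(5, 5), 0)
  expect_equal(m_from_intensities(0, 0), 0)
  expect_error(m_from_intensities(-1, 2), ">= 0")
  expect_equal(beta_from_m(0), 0.5)
  expect_equal(beta_from_m(log2(3)), 0.75)
  b <- seq(0.01, 0.99, by = 0.01)
  expect_lt(max(abs(beta_from_m(m_from_beta(b)) - b)), 1e-12)
  # monotone increasing
  expect_true(all(diff(beta_from_m(seq(-5, 5, by = 0.1))) > 0))
  # boundary clamping is logged
  expect_message(m_from_beta(c(0, 0.5, 1)), "clamped 2")
})

test_that("within-group SD uses the n-1 denominator and flags singletons", {
  m <- matrix(c(0, 0, 1, 1, 0.5, 0.5, 0.5, 0.5), nrow = 2, byrow = TRUE)
  sds <- within_group_sd(m, rep("g", 4))
  expect_equal(unname(sds[1, 1]), sqrt(1 / 3), tolerance = 1e-7)
  expect_equal(unname(sds[2, 1]), 0)
  # permutation invariance
  perm <- within_group_sd(m[, c(3, 1, 4, 2)], rep("g", 4))
  expect_equal(perm, sds)
  # singleton group undefined
  s2 <- within_group_sd(m, c("a", "b", "b", "b"))
  expect_true(all(is.na(s2[, "a"])))
  expect_false(anyNA(s2[, "b"]))
})

test_that("highly-variable flag is >= 0.25 inclusive", {
  expect_true(flag_highly_variable(0.25))
  expect_false(flag_highly_variable(0.249))
  expect_false(flag_highly_variable(NA))
})

test_that("KS statistic and tail match stats::ks.test", {
  set.seed(61)
  for (i in 1:10) {
    x <- rnorm(40 + i)
    y <- rnorm(30 + i, mean = 0.3)
    got <- ks_statistic(x, y)
    ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    expect_equal(got$D, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-6)
  }
  expect_equal(ks_statistic(1:10, 1:10)$D, 0)
  expect_equal(ks_statistic(1:10, 101:110)$D, 1)
})

test_that("SD-distribution comparison filters small SDs and skips empty classes", {
  sds <- c(rep(0.05, 50), seq(0.1, 0.6, length.out = 100))
  names(sds) <- sprintf("cg%03d", seq_along(sds))
  classes <- list(
    all_again = rep(TRUE, length(sds)),
    low_only = c(rep(TRUE, 50), rep(FALSE, 100)),
    upper = c(rep(FALSE, 100), rep(TRUE, 50))
  )
  res <- sd_distribution_compare(sds, classes)
  expect_equal(res$D[res$class == "all_again"], 0)
  expect_equal(res$n[res$class == "low_only"], 0L) # all removed by the SD < 0.10 filter
  expect_true(is.na(res$D[res$class == "low_only"]))
  expect_gt(res$D[res$class == "upper"], 0)
})

test_that("methylation level boundaries sit exactly at 0.2 and 0.8", {
  expect_identical(
    methylation_level(c(0, 0.2, 0.200001, 0.5, 0.799999, 0.8, 1)),
    c("hypo", "hypo", "hetero", "hetero", "hetero", "hyper", "hyper")
  )
})

test_that("tDM z-scores behave on identical and planted inputs", {
  samples <- fixture_samples(tissues = c("blood", "villi"), n_per_tissue = 4)
  # identical tissue distributions -> z = 0
  beta <- matrix(0.4, nrow = 5, ncol = 8, dimnames = list(paste0("cg", 1:5), samples$sample_id))
  td <- select_tdm(beta, samples$tissue)
  expect_true(all(td$z == 0))
  expect_false(any(td$significant))
  # planted differential probes are detected (small-scale power check)
  gb <- gen_beta(400, samples,
    seed = 62, noise_sd = 0.05,
    tissue_diff = data.frame(probe_idx = 1:20, tissue = "villi", mean = 0.98)
  )
  td2 <- select_tdm(gb$beta, samples$tissue)
  expect_gt(mean(td2$significant[1:20]), 0.5)
  # significance respects the Bonferroni bound
  expect_true(all(td2$p[td2$significant] < 0.05 / nrow(gb$beta)))
})

test_that("relative enrichment matches the formula and is duplication-invariant", {
  # equal fractions -> 0; doubled -> +100; halved -> -50
  labels <- rep(c("a", "b"), c(100, 100))
  tdm_eq <- rep(c(TRUE, FALSE, TRUE, FALSE), c(25, 75, 25, 75))
  expect_equal(relative_enrichment(tdm_eq, labels)$pct_relative_enrichment, c(0, 0))
  labels3 <- rep(c("a", "b"), c(50, 150))
  tdm3 <- c(rep(TRUE, 25), rep(FALSE, 25), rep(TRUE, 25), rep(FALSE, 125))
  pre <- relative_enrichment(tdm3, labels3)
  expect_equal(pre$pct_relative_enrichment[pre$class == "a"], 100)
  got <- relative_enrichment(
    c(rep(TRUE, 5), rep(FALSE, 35), rep(TRUE, 35), rep(FALSE, 125)),
    rep(c("a", "b"), c(40, 160))
  )
  expect_equal(got$pct_relative_enrichment[got$class == "a"], -37.5)
  # duplicating every probe leaves PRE unchanged
  dup <- relative_enrichment(rep(tdm3, 2), rep(labels3, 2))
  expect_equal(dup$pct_relative_enrichment, pre$pct_relative_enrichment)
})

test_that("sex screen recovers planted effects and respects min_delta", {
  samples <- fixture_samples(tissues = "blood", n_per_tissue = 40)
  gb <- gen_beta(300, samples,
    seed = 63, noise_sd = 0.03,
    sex_diff = data.frame(probe_idx = 1:15, delta = 0.2)
  )
  res <- sex_differential(gb$beta, samples$sex)
  expect_identical(attr(res, "method"), "standin")
  expect_gte(sum(res$selected[1:15]), 13)
  expect_lte(sum(res$selected[-(1:15)]), 2)
  # min_delta = 0 reduces to a pure FDR screen
  res0 <- sex_differential(gb$beta, samples$sex, min_delta = 0)
  expect_true(all(res0$selected == (res0$fdr < 0.01)))
  # permuted labels on null data -> no discoveries
  gbn <- gen_beta(300, samples, seed = 64, noise_sd = 0.03)
  resn <- sex_differential(gbn$beta, samples$sex)
  expect_equal(sum(resn$selected), 0L)
  expect_error(sex_differential(gb$beta, rep("M", nrow(samples))), "two sexes")
})

test_that("prefilter applies each removal rule and logs counts", {
  samples <- fixture_samples(tissues = "blood", n_per_tissue = 4)
  gb <- gen_beta(10, samples, seed = 65)
  beta <- gb$beta
  rownames(beta) <- sprintf("cg%02d", 1:10)
  rownames(beta)[9] <- "ch01"
  rownames(beta)[10] <- "rs01"
  beta[1, 2] <- NA
  detp <- matrix(0.001, nrow = 10, ncol = ncol(beta), dimnames = dimnames(beta))
  detp[2, 3] <- 0.02
  ann <- data.frame(
    probe_id = rownames(beta),
    category = c(rep("cg", 8), "ch", "rs"),
    chrom = c("chrX", rep("chr1", 9)),
    non_specific = c(FALSE, FALSE, TRUE, rep(FALSE, 7))
  )
  out <- prefilter_probes(beta, detp, ann)
  removed <- attr(out, "removed")
  expect_equal(unname(removed["detection_p"]), 1L) # cg02
  expect_equal(unname(removed["missing_beta"]), 1L) # cg01
  expect_equal(unname(removed["rs_ch"]), 2L)
  expect_equal(unname(removed["sex_chrom"]), 0L) # chrX probe already gone (missing beta)
  expect_equal(unname(removed["non_specific"]), 1L)
  expect_equal(nrow(out), 5L)
})
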