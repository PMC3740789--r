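# bisulfite variants, degenerate expansion, candidate search, hit filter,
# specificity summaries and repetitive-bp counting

test_that("bisulfite conversion follows the four-variant definitions", {
  expect_identical(unname(bisulfite_convert(c(x = "ACGT"), "unmeth_fwd")), "ATGT")
  expect_identical(unname(bisulfite_convert(c(x = "ACGT"), "meth_fwd")), "ACGT")
  expect_identical(unname(bisulfite_convert(c(x = "ACCT"), "meth_fwd")), "ATTT")
  # rev variants convert the reverse complement
  expect_identical(unname(bisulfite_convert(c(x = "ACGT"), "unmeth_rev")), "ATGT")
  expect_identical(unname(bisulfite_convert(c(x = "AACCT"), "unmeth_rev")), "AGGTT")
  # case preserved
  expect_identical(unname(bisulfite_convert(c(x = "acgt"), "unmeth_fwd")), "atgt")
  # idempotence on random sequences
  set.seed(3)
  for (i in 1:10) {
    s <- c(chr = paste(sample(c("A", "C", "G", "T", "a", "c", "g", "t"), 200, TRUE), collapse = ""))
    for (v in c("unmeth_fwd", "meth_fwd")) {
      once <- bisulfite_convert(s, v)
      expect_identical(bisulfite_convert(once, v), once)
    }
  }
  # unmeth variants contain no C; meth variants retain C only in CpG context
  s <- c(chr = "CCGCTACGA")
  expect_false(grepl("C", bisulfite_convert(s, "unmeth_fwd"), ignore.case = TRUE))
  m <- unname(bisulfite_convert(s, "meth_fwd"))
  cpos <- gregexpr("C", m, fixed = TRUE)[[1]]
  expect_true(all(substr(m, cpos + 1, cpos + 1) == "G"))
})

test_that("degenerate expansion yields exactly the all-A and all-G versions", {
  expect_identical(unname(expand_degenerate("AARTT")), c("AAATT", "AAGTT"))
  expect_identical(unname(expand_degenerate("AATTT")), "AATTT")
  expect_identical(unname(expand_degenerate("RRA")), c("AAA", "GGA"))
  expect_length(expand_degenerate("RRA"), 2) # not 4
  expect_error(expand_degenerate("AR", assay_type = "I"), "type I")
})

test_that("hit filter implements the four acceptance rules exactly", {
  mk_hit <- function(matches, aligned, gaps, pos50) {
    data.frame(
      probe_id = "cg1", matches = matches, aligned_length = aligned,
      gaps = gaps, pos50_aligned = pos50
    )
  }
  expect_equal(nrow(filter_hits(mk_hit(50, 50, 0, TRUE))), 1) # pass
  expect_equal(nrow(filter_hits(mk_hit(39, 40, 0, TRUE))), 0) # < 40 matches
  expect_equal(nrow(filter_hits(mk_hit(45, 50, 1, TRUE))), 0) # gap
  expect_equal(nrow(filter_hits(mk_hit(44, 48, 0, FALSE))), 0) # 50th unaligned
  expect_equal(nrow(filter_hits(mk_hit(44, 50, 0, TRUE))), 0) # identity < 90%
  expect_equal(nrow(filter_hits(mk_hit(45, 50, 0, TRUE))), 1) # identity = 90%
})

test_that("every fixture probe finds its intended target as sole locus", {
  fx <- get_default_fixture()
  hits <- find_candidate_hits(fx$probes, fx$genome)
  acc <- filter_hits(hits)
  s <- summarize_specificity(acc, fx$probes)
  expect_false(any(s$no_hit))
  expect_true(all(s$n_loci == 1))
  expect_false(any(s$non_specific))
  expect_true(all(s$AlleleA_Hits == 1))
  # type I probes also carry an allele B hit at the same locus
  typeI <- fx$probes$assay_type == "I"
  expect_true(all(s$AlleleB_Hits[typeI] == 1))
  expect_true(all(s$AlleleB_Hits[!typeI] == 0))
  # intended-target hits achieve 50 matches
  int <- acc[acc$is_intended_target, ]
  expect_true(all(tapply(int$matches, int$probe_id, max) == 50))
})

test_that("decoy at 42/50 with intact terminus flips specificity; 39/50 restores it", {
  gg <- gen_genome(
    seed = 31L, length = 30000L, background_gc = 0.25,
    islands = data.frame(start = 5000L, len = 600L, class = "HC"),
    repeats = data.frame(start = integer(), len = integer())
  )
  probes <- gen_probes(gg$genome, n = 24L, seed = 32L)
  host <- find_decoy_host(gg$genome, probes)
  expect_false(is.na(host))
  g42 <- plant_decoy(gg$genome, probes, host, at = 25000L, n_mismatch = 8L)
  s42 <- summarize_specificity(filter_hits(find_candidate_hits(probes, g42)), probes)
  expect_true(s42$non_specific[s42$probe_id == host])
  expect_equal(s42$n_loci[s42$probe_id == host], 2L)
  g39 <- plant_decoy(gg$genome, probes, host, at = 25000L, n_mismatch = 11L)
  s39 <- summarize_specificity(filter_hits(find_candidate_hits(probes, g39)), probes)
  expect_false(s39$non_specific[s39$probe_id == host])
})

test_that("seeded search equals the exhaustive oracle on a small fixture", {
  gg <- gen_genome(
    seed = 33L, length = 12000L, background_gc = 0.25,
    islands = data.frame(start = 4000L, len = 400L, class = "IC"),
    repeats = data.frame(start = integer(), len = integer())
  )
  probes <- gen_probes(gg$genome, n = 6L, seed = 34L)
  host <- find_decoy_host(gg$genome, probes)
  g2 <- if (is.na(host)) gg$genome else plant_decoy(gg$genome, probes, host, at = 10000L)
  acc <- filter_hits(find_candidate_hits(probes, g2))
  got <- unique(acc[, c("probe_id", "chrom", "start", "end")])
  got <- got[order(got$probe_id, got$start), ]
  oracle <- oracle_specificity_scan(probes, g2)
  oracle <- oracle[order(oracle$probe_id, oracle$start), ]
  rownames(got) <- rownames(oracle) <- NULL
  expect_equal(got, oracle)
})

test_that("degenerate versions reaching one locus collapse to one locus", {
  hits <- data.frame(
    probe_id = "cg1",
    allele = "A", degenerate_version = c("R2A", "R2G"),
    variant = c("unmeth_rev", "meth_rev"), orientation = "rev",
    chrom = "chr1", start = 100L, end = 150L,
    matches = c(50L, 50L), aligned_length = 50L, gaps = 0L,
    pos50_aligned = TRUE, is_intended_target = TRUE, saturated = FALSE,
    stringsAsFactors = FALSE
  )
  probes <- data.frame(
    probe_id = "cg1", chrom = "chr1", assay_type = "II",
    design_strand = "F", mapinfo = 151L, category = "cg",
    probe_seq_A = strrep("A", 50), probe_seq_B = NA, stringsAsFactors = FALSE
  )
  s <- summarize_specificity(hits, probes)
  expect_equal(s$n_loci, 1L)
  expect_false(s$non_specific)
})

test_that("cross-hybridization is classed by intended vs extra chromosome", {
  probes <- data.frame(
    probe_id = c("cg1", "cg2"), chrom = c("chr2", "chrX"),
    assay_type = "II", design_strand = "F", mapinfo = 1000L, category = "cg",
    probe_seq_A = strrep("A", 50), probe_seq_B = NA, stringsAsFactors = FALSE
  )
  mk <- function(pid, chrom, start, intended) {
    data.frame(
      probe_id = pid, allele = "A", degenerate_version = "none",
      variant = "unmeth_fwd", orientation = "fwd", chrom = chrom,
      start = start, end = start + 50L, matches = 50L, aligned_length = 50L,
      gaps = 0L, pos50_aligned = TRUE, is_intended_target = intended,
      saturated = FALSE, stringsAsFactors = FALSE
    )
  }
  hits <- rbind(
    mk("cg1", "chr2", 949L, TRUE), mk("cg1", "chrX", 5000L, FALSE),
    mk("cg2", "chrX", 949L, TRUE), mk("cg2", "chr5", 700L, FALSE)
  )
  s <- summarize_specificity(hits, probes)
  # intended autosomal + cross-hyb to sex
  expect_false(s$intended_sex[1])
  expect_true(s$cross_hyb_sex[1])
  expect_equal(s$XY_Hits[1], 1L)
  expect_equal(s$Autosomal_Hits[1], 1L)
  # intended sex + cross-hyb to autosome
  expect_true(s$intended_sex[2])
  expect_true(s$cross_hyb_auto[2])
  xt <- specificity_crosstab(s)
  expect_equal(xt$intended_auto[xt$row == "cross-hybridize only to sex chrs"], 1L)
  expect_equal(xt$intended_sex[xt$row == "cross-hybridize only to auto chrs"], 1L)
})

test_that("repetitive-bp counting uses lowercase under the footprint", {
  fx <- get_default_fixture()
  iv <- compute_probe_intervals(fx$probes)
  rep_bp <- count_repetitive_bp(iv, fx$genome)
  expect_true(all(rep_bp$n_bp_repetitive >= 0 & rep_bp$n_bp_repetitive <= 50))
  # plant a probe footprint fully inside the lowercase tract
  g <- fx$genome
  # repeat tract is at [32000, 33500); fabricate interval rows
  mk_iv <- function(s) {
    data.frame(
      probe_id = "cgX", chrom = "chr1", cpg_start = s + 50, cpg_end = s + 52,
      probe_start = s, probe_end = s + 50, wo_start = s, wo_end = s + 50
    )
  }
  expect_equal(count_repetitive_bp(mk_iv(32100L), g)$n_bp_repetitive, 50L)
  expect_true(count_repetitive_bp(mk_iv(32100L), g)$repetitive)
  # 26 lowercase bases -> flagged; 25 -> not
  expect_true(count_repetitive_bp(mk_iv(32000L - 24L), g)$repetitive)
  expect_false(count_repetitive_bp(mk_iv(32000L - 25L), g)$repetitive)
  # fully uppercase -> 0
  z <- count_repetitive_bp(mk_iv(2000L), g)
  expect_equal(z$n_bp_repetitive, 0L)
  # specific + fully repetitive flag
  spec <- data.frame(probe_id = "cgX", non_specific = FALSE)
  expect_true(count_repetitive_bp(mk_iv(32100L), g, spec)$specific_repetitive)
})

test_that("opposite-strand designs are reached only via rev variants", {
  fx <- get_default_fixture()
  hits <- find_candidate_hits(fx$probes, fx$genome)
  acc <- filter_hits(hits)
  int <- acc[acc$is_intended_target & acc$matches == 50, ]
  # F-design probes (complementary to the converted minus strand) hit rev
  # variants; R-design probes hit fwd variants
  for (i in seq_len(nrow(fx$probes))) {
    h <- int[int$probe_id == fx$probes$probe_id[i], ]
    vs <- unique(h$variant)
    if (fx$probes$design_strand[i] == "F") {
      expect_true(all(grepl("rev", vs)), info = fx$probes$probe_id[i])
    } else {
      expect_true(all(grepl("fwd", vs)), info = fx$probes$probe_id[i])
    }
  }
})
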