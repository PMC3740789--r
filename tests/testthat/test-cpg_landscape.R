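# CpG density metrics, island scanning, HIL merging, probe classes

test_that("gc_content excludes N and handles edge cases", {
  expect_equal(gc_content("CGCG"), 1.0)
  expect_equal(gc_content("ATCG"), 0.5)
  expect_equal(gc_content("aaTTccGG"), 0.5)
  expect_equal(gc_content("ANCG"), 2 / 3) # N dropped from both counts
  expect_warning(v <- gc_content("NNN"), "all-N")
  expect_true(is.na(v))
})

test_that("obs_exp_cpg follows the (CpG x L)/(C x G) formula", {
  expect_equal(obs_exp_cpg("CGCGCG"), 2.0)
  expect_equal(obs_exp_cpg("ATATAT"), 0.0)
  expect_equal(obs_exp_cpg("CCGG"), 1.0)
  expect_equal(obs_exp_cpg("AAAC"), 0.0) # no G -> 0
  expect_error(obs_exp_cpg(""), "empty")
})

test_that("planted islands are recovered with correct classes and tight bounds", {
  gg <- gen_genome(
    seed = 11L, length = 60000L, background_gc = 0.04, background_cpg = 0,
    islands = data.frame(
      start = c(10000L, 30000L, 45000L, 45600L),
      len = c(600L, 400L, 600L, 800L),
      class = c("HC", "IC", "HC", "IC")
    ),
    repeats = data.frame(start = integer(), len = integer())
  )
  hc <- find_islands(gg$genome, "HC")
  ic <- find_islands(gg$genome, "IC")
  merged <- merge_hil(hc, ic)
  # isolated HC recovered within +-50 bp
  hc1 <- hc[hc$start < 20000, ]
  expect_equal(nrow(hc1), 1)
  expect_lte(abs(hc1$start - 10000), 50)
  expect_lte(abs(hc1$end - 10600), 50)
  # isolated IC recovered within +-50 bp and classed IC after merging
  ic1 <- merged[merged$start > 25000 & merged$start < 35000, ]
  expect_equal(ic1$density_class, "IC")
  expect_lte(abs(ic1$start - 30000), 50)
  expect_lte(abs(ic1$end - 30400), 50)
  # the IC run abutting the second HC becomes ICshore
  shore <- merged[merged$start >= 45600 & merged$start < 46400, ]
  expect_true(all(shore$density_class == "ICshore"))
  expect_gte(nrow(shore), 1)
  # every emitted island re-satisfies its thresholds
  expect_true(island_recomputes_ok(gg$genome, hc))
  expect_true(island_recomputes_ok(gg$genome, ic))
})

test_that("below-minimum-length dense blocks yield no island", {
  gg <- gen_genome(
    seed = 12L, length = 20000L, background_gc = 0.04, background_cpg = 0,
    islands = data.frame(start = 8000L, len = 400L, class = "IC"),
    repeats = data.frame(start = integer(), len = integer())
  )
  # a 400-bp block can never satisfy the >500 bp HC length bound
  expect_equal(nrow(find_islands(gg$genome, "HC")), 0)
})

test_that("scanner matches the all-windows oracle on N-flanked plants", {
  gg <- gen_genome(
    seed = 13L, length = 6000L, background_gc = 0.30, background_cpg = 0.001,
    islands = data.frame(start = c(1500L, 4000L), len = c(600L, 400L), class = c("HC", "IC")),
    repeats = data.frame(start = integer(), len = integer()),
    flank_n = 2L
  )
  seq1 <- gg$genome[["chr1"]]
  for (cls in c("HC", "IC")) {
    p <- island_params(cls)
    got <- find_islands(gg$genome, cls)
    got_bases <- unlist(lapply(seq_len(nrow(got)), function(i) got$start[i]:(got$end[i] - 1)))
    oracle_bases <- oracle_island_bases(seq1, p)
    expect_equal(sort(got_bases), sort(oracle_bases), info = cls)
  }
})

test_that("random 40%-GC sequence yields no HC and recomputable islands", {
  set.seed(21)
  seq1 <- paste(sample(c("A", "T", "C", "G"), 8000, TRUE, prob = c(.3, .3, .2, .2)), collapse = "")
  g <- c(chr1 = seq1)
  hc <- find_islands(g, "HC")
  expect_equal(nrow(hc), 0)
  ic <- find_islands(g, "IC")
  expect_true(island_recomputes_ok(g, ic)) # holds even when islands appear
  # scanner base set is contained in the all-windows union
  if (nrow(ic)) {
    got_bases <- unlist(lapply(seq_len(nrow(ic)), function(i) ic$start[i]:(ic$end[i] - 1)))
    expect_true(all(got_bases %in% oracle_island_bases(seq1, island_params("IC"))))
  }
})

test_that("raising thresholds never adds island bases", {
  bases <- function(isl) {
    if (!nrow(isl)) {
      return(integer(0))
    }
    unlist(lapply(seq_len(nrow(isl)), function(i) isl$start[i]:(isl$end[i] - 1)))
  }
  base_p <- island_params("IC")
  # diffuse boundaries: raising the density thresholds shrinks the call
  gg <- gen_genome(
    seed = 14L, length = 20000L, background_gc = 0.2, background_cpg = 0.001,
    islands = data.frame(start = 8000L, len = 700L, class = "HC"),
    repeats = data.frame(start = integer(), len = integer())
  )
  b0 <- bases(find_islands(gg$genome, params = base_p))
  for (p2 in list(
    modifyList(base_p, list(min_oe = 0.7)),
    modifyList(base_p, list(min_gc = 0.55))
  )) {
    expect_true(all(bases(find_islands(gg$genome, params = p2)) %in% b0))
  }
  # sharp (N-flanked) boundaries: raising the length bound also shrinks
  gg2 <- gen_genome(
    seed = 15L, length = 10000L, background_gc = 0.2, background_cpg = 0.001,
    islands = data.frame(start = c(3000L, 7000L), len = c(700L, 300L), class = c("HC", "IC")),
    repeats = data.frame(start = integer(), len = integer()), flank_n = 2L
  )
  b1 <- bases(find_islands(gg2$genome, params = base_p))
  b2 <- bases(find_islands(gg2$genome, params = modifyList(base_p, list(min_len = 400L))))
  expect_true(all(b2 %in% b1))
  expect_lt(length(b2), length(b1)) # the 300-bp plant drops out
})

test_that("HIL merge precedence and adjacency follow the class rules", {
  hc <- data.frame(
    chrom = "chr1", start = 1000L, end = 2000L,
    density_class = "HC", name = island_name("chr1", 1000L, 2000L, "HC")
  )
  ic <- data.frame(
    chrom = "chr1", start = c(500L, 2000L, 12000L, 1200L),
    end = c(1000L, 2600L, 12400L, 1800L),
    density_class = "IC",
    name = island_name("chr1", c(500L, 2000L, 12000L, 1200L), c(1000L, 2600L, 12400L, 1800L), "IC")
  )
  m <- merge_hil(hc, ic)
  # abutting IC runs -> ICshore on both sides
  expect_equal(m$density_class[m$start == 500], "ICshore")
  expect_equal(m$density_class[m$start == 2000], "ICshore")
  # isolated IC 10 kb away stays IC
  expect_equal(m$density_class[m$start == 12000], "IC")
  # region qualifying as both HC and IC: HC wins (IC inside HC disappears)
  expect_false(any(m$start == 1200))
  expect_equal(m$density_class[m$start == 1000], "HC")
})

test_that("probe HIL and UCSC classes partition and respect boundaries", {
  islands <- data.frame(
    chrom = "chr1", start = 5000L, end = 6000L,
    density_class = "HC", name = island_name("chr1", 5000L, 6000L, "HC")
  )
  mk_iv <- function(pos) {
    data.frame(
      probe_id = paste0("cg", pos), chrom = "chr1",
      cpg_start = pos, cpg_end = pos + 2,
      probe_start = pos - 49, probe_end = pos + 1,
      wo_start = pos - 49, wo_end = pos, stringsAsFactors = FALSE
    )
  }
  # island first base, last base, one bp outside, far away
  hil <- classify_probe_hil(mk_iv(5000L), islands)
  expect_equal(hil$HIL_CpG_class, "HC")
  expect_equal(hil$HIL_CpG_Island_Name, islands$name)
  expect_equal(classify_probe_hil(mk_iv(5999L), islands)$HIL_CpG_class, "HC")
  expect_equal(classify_probe_hil(mk_iv(6000L), islands)$HIL_CpG_class, "LC")
  expect_equal(classify_probe_hil(mk_iv(20000L), islands)$HIL_CpG_class, "LC")
  # UCSC distance boundaries: 1 bp out = shore, 2000 out = shore,
  # 2001 = shelf, 4000 = shelf, 4001 = sea
  ucsc <- function(pos) classify_probe_ucsc(mk_iv(pos), islands)$UCSC_CpG_class
  expect_equal(ucsc(5500L), "island")
  expect_equal(ucsc(6000L), "shore") # first base outside
  expect_equal(ucsc(6000L + 1999L), "shore")
  expect_equal(ucsc(6000L + 2000L), "shelf")
  expect_equal(ucsc(6000L + 3999L), "shelf")
  expect_equal(ucsc(6000L + 4000L), "sea")
  expect_equal(ucsc(4999L), "shore") # upstream side
})

test_that("island track IO keeps canonical names, including empty lists", {
  isl <- data.frame(
    chrom = "chr8", start = 49890017L, end = 49891221L,
    density_class = "IC", name = island_name("chr8", 49890017L, 49891221L, "IC")
  )
  expect_identical(isl$name, "chr8_IC:49890018–49891221")
  path <- withr::local_tempfile(fileext = ".bed")
  write_island_track(isl, path)
  got <- read_island_track(path)
  expect_equal(got$start, isl$start)
  expect_identical(got$name, isl$name)
  expect_identical(got$density_class, "IC")
  write_island_track(isl[0, ], path)
  expect_equal(nrow(read_island_track(path)), 0)
})
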