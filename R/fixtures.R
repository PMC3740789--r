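# Deterministic synthetic-fixture generators. Every generated input ships
# with machine-readable truth so downstream tests never re-derive ground
# truth with the method under test.

# run code with a locally seeded RNG, restoring global state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# token-model sequence with tunable CpG rate and GC content:
# emit "CG" with probability cpg_rate, otherwise a single base with
# P(C) = P(G) = gc/2
.random_seq <- function(len, gc = 0.38, cpg_rate = 0) {
  n_tok <- ceiling(len / (1 + cpg_rate))
  single <- c("A", "T", "C", "G")
  p_single <- c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)
  out <- character(0)
  while (sum(nchar(out)) < len) {
    k <- max(100L, n_tok)
    is_cpg <- stats::runif(k) < cpg_rate
    tok <- ifelse(is_cpg, "CG", sample(single, k, replace = TRUE, prob = p_single))
    out <- c(out, tok)
    n_tok <- ceiling((len - sum(nchar(out))) / (1 + cpg_rate))
  }
  substr(paste(out, collapse = ""), 1, len)
}

#' Generate a fixture genome with planted ground truth
#'
#' Builds one chromosome (plus optional sex chromosomes) of AT-rich
#' background with planted CpG-dense blocks (HC and IC density), soft-masked
#' repeat tracts (lowercase) and room for cross-hybridization decoys. The
#' generator rechecks every planted island against its density thresholds
#' (redrawing a bounded number of times) and fails loudly if the layout is
#' unsatisfiable.
#'
#' @param seed Integer seed; the same seed yields identical bytes.
#' @param length Chromosome length (default 100000).
#' @param chrom Chromosome name (default `"chr1"`).
#' @param islands data.frame with `start`, `len`, `class` (`"HC"`/`"IC"`);
#'   defaults plant an HC, an isolated IC, and an IC abutting a second HC.
#' @param repeats data.frame with `start`, `len` lowercase tracts.
#' @param sex_chrom_len If > 0, adds a `chrX` of background sequence.
#' @param background_gc,background_cpg Background base composition
#'   (defaults emulate a repeat-poor mammalian intergenic landscape; set
#'   `background_gc` near 0 for a hostile AT background with sharp island
#'   boundaries).
#' @param flank_n Number of N bases planted on each side of every island
#'   block (N breaks scanning windows, making planted boundaries exact).
#' @return List: `genome` (store), `truth` (data.frame of planted intervals).
#' @export
gen_genome <- function(seed = 1L, length = 100000L, chrom = "chr1",
                       islands = NULL, repeats = NULL, sex_chrom_len = 0L,
                       background_gc = 0.36, background_cpg = 0.002,
                       flank_n = 0L) {
  if (is.null(islands)) {
    islands <- data.frame(
      start = c(10000L, 30000L, 50000L, 50600L),
      len = c(700L, 400L, 600L, 400L),
      class = c("HC", "IC", "HC", "IC"),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(repeats)) {
    repeats <- data.frame(start = 70000L, len = 2000L)
  }
  stopifnot(all(islands$start + islands$len <= length))
  with_seed(seed, {
    seq <- .random_seq(length, gc = background_gc, cpg_rate = background_cpg)
    truth <- list()
    for (i in seq_len(nrow(islands))) {
      cls <- islands$class[i]
      p <- island_params(cls)
      # token parameters tuned so realized CG content sits in a narrow band
      # just above the class threshold: blocks qualify for their class but
      # cannot drag flanking sequence over the threshold, keeping planted
      # boundaries sharp
      pars <- if (cls == "HC") {
        list(gc = 0.41, cpg = 0.14, band = c(0.003, 0.012))
      } else {
        list(gc = 0.47, cpg = 0.042, band = c(0.003, 0.025))
      }
      ok <- FALSE
      for (try in 1:200) {
        block <- .random_seq(islands$len[i], gc = pars$gc, cpg_rate = pars$cpg)
        gcv <- gc_content(block)
        gc_ok <- gcv > p$min_gc + pars$band[1] && gcv < p$min_gc + pars$band[2] &&
          obs_exp_cpg(block) > p$min_oe
        hc_free <- TRUE
        if (cls == "IC") {
          # an IC-density plant must not itself harbour an HC-density window
          hp <- island_params("HC")
          hc_free <- nrow(.scan_chrom(block, hp)) == 0 &&
            !(gc_content(block) > hp$min_gc && obs_exp_cpg(block) > hp$min_oe)
        }
        # a planted block must be recoverable as one clean island of its
        # own class when scanned embedded in AT flanks
        rec_ok <- FALSE
        if (gc_ok && hc_free) {
          pad <- strrep("A", 300L)
          sc <- .scan_chrom(paste0(pad, block, pad), p)
          rec_ok <- nrow(sc) == 1 &&
            abs(sc$start - 300L) <= 25 &&
            abs(sc$end - (300L + islands$len[i])) <= 25
        }
        if (gc_ok && hc_free && rec_ok) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop(sprintf(
          "gen_genome: could not satisfy planted %s island of length %d",
          cls, islands$len[i]
        ))
      }
      substr(seq, islands$start[i] + 1, islands$start[i] + islands$len[i]) <- block
      if (flank_n > 0) {
        a <- islands$start[i] - flank_n
        b <- islands$start[i] + islands$len[i]
        if (a >= 0) substr(seq, a + 1, a + flank_n) <- strrep("N", flank_n)
        if (b + flank_n <= length) substr(seq, b + 1, b + flank_n) <- strrep("N", flank_n)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = chrom, start = islands$start[i],
        end = islands$start[i] + islands$len[i],
        what = paste0("island_", cls), stringsAsFactors = FALSE
      )
    }
    for (i in seq_len(nrow(repeats))) {
      a <- repeats$start[i] + 1
      b <- repeats$start[i] + repeats$len[i]
      substr(seq, a, b) <- tolower(substr(seq, a, b))
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = chrom, start = repeats$start[i], end = b,
        what = "repeat", stringsAsFactors = FALSE
      )
    }
    genome <- stats::setNames(c(seq), chrom)
    if (sex_chrom_len > 0) {
      genome["chrX"] <- .random_seq(sex_chrom_len, gc = 0.36, cpg_rate = 0.002)
    }
    list(genome = genome, truth = do.call(rbind, truth))
  })
}

#' Generate a probe manifest from a genome
#'
#' Picks CpG sites (plus-strand `CG` dinucleotides with full footprint room),
#' cycles through all four assay-type x design-strand combinations, and
#' derives probe sequences from the genome so that every probe validates by
#' construction. Type II probes read internal CpG-context positions as R.
#'
#' @param genome Genome store.
#' @param n Number of cg probes.
#' @param seed Integer seed (site selection).
#' @param chrom Restrict to one chromosome (default: first).
#' @param region Optional `c(start, end)` 0-based half-open window to pick
#'   sites from.
#' @param n_ch,n_rs Numbers of ch-category (non-CpG cytosine target) and
#'   rs-category filler probes appended (default 0).
#' @return data.frame of probe records (see [read_manifest()]).
#' @export
gen_probes <- function(genome, n = 20L, seed = 1L, chrom = names(genome)[1],
                       region = NULL, n_ch = 0L, n_rs = 0L) {
  seq_u <- toupper(genome[[chrom]])
  len <- nchar(seq_u)
  if (is.null(region)) region <- c(0L, len)
  with_seed(seed, {
    find_sites <- function(pattern, not_cpg = FALSE) {
      m <- gregexpr(pattern, substr(seq_u, region[1] + 1, region[2]), fixed = TRUE)[[1]]
      if (m[1] == -1L) {
        return(integer(0))
      }
      pos <- as.integer(m) - 1L + region[1] # 0-based C position
      if (not_cpg) {
        nxt <- substr(seq_u, pos + 2, pos + 2)
        pos <- pos[nxt != "G"]
      }
      pos[pos >= 52 & pos + 52 <= len]
    }
    mk <- function(sites, n, prefix, cpg_required) {
      if (length(sites) < n) {
        stop(sprintf(
          "gen_probes: only %d usable %s sites for %d probes",
          length(sites), prefix, n
        ))
      }
      sites <- sort(sample(sites, n))
      combos <- expand.grid(type = c("I", "II"), strand = c("F", "R"), stringsAsFactors = FALSE)
      idx <- rep(seq_len(4), length.out = n)
      probes <- data.frame(
        probe_id = sprintf("%s%08d", prefix, seq_len(n) + if (prefix == "cg") 0L else if (prefix == "ch") 4e6 else 8e6),
        assay_type = combos$type[idx],
        design_strand = combos$strand[idx],
        chrom = chrom,
        mapinfo = sites + 1L, # 1-based C
        probe_seq_A = NA_character_,
        probe_seq_B = NA_character_,
        stringsAsFactors = FALSE
      )
      iv <- local({
        probes$probe_seq_A <- strrep("A", 50)
        probes$probe_seq_B <- ifelse(probes$assay_type == "I", strrep("A", 50), NA)
        probes$category <- prefix
        compute_probe_intervals(probes)
      })
      for (i in seq_len(n)) {
        is_I <- probes$assay_type[i] == "I"
        probes$probe_seq_A[i] <- probe_from_genome(
          genome, chrom, iv$probe_start[i], iv$probe_end[i],
          probes$design_strand[i], if (is_I) "A" else "II"
        )
        probes$probe_seq_B[i] <- if (is_I) {
          probe_from_genome(
            genome, chrom, iv$probe_start[i], iv$probe_end[i],
            probes$design_strand[i], "B"
          )
        } else {
          NA_character_
        }
      }
      probes$category <- prefix
      probes
    }
    out <- mk(find_sites("CG"), n, "cg", TRUE)
    if (n_ch > 0) out <- rbind(out, mk(find_sites("C", not_cpg = TRUE), n_ch, "ch", FALSE))
    if (n_rs > 0) out <- rbind(out, mk(find_sites("C", not_cpg = TRUE), n_rs, "rs", FALSE))
    validate_probe_records(out)
    out
  })
}

#' Plant a cross-hybridization decoy for a probe
#'
#' Copies the host probe's genomic footprint (with 1 bp of flanking context)
#' to `at` and plants `n_mismatch` A<->T swaps: the first `front_run` of them
#' as a contiguous run at the probe's 5' terminus (trimmed from the aligned
#' region by local alignment, so the decoy's identity stays high), the rest
#' at internal probe offsets; the 3'-terminal 12-mer stays intact. A/T swaps
#' survive every bisulfite conversion and never touch CpG context, so the
#' decoy scores exactly `50 - n_mismatch` matches over an aligned region of
#' `50 - front_run` bases.
#'
#' With the defaults (8 mismatches, front run 4) the decoy scores 42/50
#' matches at 42/46 = 91.3% identity — an accepted hit; `n_mismatch = 11`
#' degrades it to 39 matches — rejected.
#'
#' @param genome Genome store.
#' @param probes Probe records; `probe_id` selects the host.
#' @param probe_id Host probe; its footprint must carry A/T at the leading
#'   `front_run` probe offsets (pick a suitable host, or see
#'   [find_decoy_host()]).
#' @param at 0-based position to plant the decoy footprint at.
#' @param n_mismatch Total planted mismatches (`front_run`-38).
#' @param front_run Length of the leading contiguous mismatch run.
#' @return Modified genome store.
#' @export
plant_decoy <- function(genome, probes, probe_id, at, n_mismatch = 8L, front_run = 4L) {
  i <- match(probe_id, probes$probe_id)
  stopifnot(!is.na(i), n_mismatch >= front_run)
  iv <- compute_probe_intervals(probes[i, , drop = FALSE])
  chrom <- probes$chrom[i]
  fp <- genome_fetch(genome, chrom, iv$probe_start - 1L, iv$probe_end + 1L)
  ch <- strsplit(fp, "", fixed = TRUE)[[1]]
  # probe offset k (1..50): genomic footprint offset k for F designs,
  # 51 - k for R designs (ch[g + 1] is genomic offset g)
  gpos <- function(k) if (probes$design_strand[i] == "F") k else 51L - k
  is_at <- function(k) ch[gpos(k) + 1L] %in% c("A", "T")
  lead <- seq_len(front_run)
  if (!all(vapply(lead, is_at, logical(1)))) {
    stop("plant_decoy: probe ", probe_id, " lacks A/T at the leading ", front_run, " offsets")
  }
  internal <- (front_run + 2L):38L # leave offset front_run+1 matching
  internal <- internal[vapply(internal, is_at, logical(1))]
  n_internal <- n_mismatch - front_run
  if (length(internal) < n_internal) {
    stop("plant_decoy: footprint lacks enough internal A/T positions")
  }
  swap_k <- c(lead, internal[seq_len(n_internal)])
  gi <- vapply(swap_k, gpos, integer(1)) + 1L
  ch[gi] <- chartr("AT", "TA", ch[gi])
  decoy <- paste(ch, collapse = "")
  s <- genome[[chrom]]
  stopifnot(at + nchar(decoy) <= nchar(s))
  substr(s, at + 1, at + nchar(decoy)) <- decoy
  genome[[chrom]] <- s
  genome
}

#' @rdname plant_decoy
#' @param front_run,n_internal_min Requirements the host footprint must meet.
#' @return `find_decoy_host`: the first probe id whose footprint supports the
#'   requested decoy, or NA.
#' @export
find_decoy_host <- function(genome, probes, front_run = 4L, n_internal_min = 7L) {
  iv <- compute_probe_intervals(probes)
  for (i in seq_len(nrow(probes))) {
    fp <- genome_fetch(genome, probes$chrom[i], iv$probe_start[i], iv$probe_end[i], clip = TRUE)
    if (nchar(fp) != 50L) next
    ch <- strsplit(fp, "", fixed = TRUE)[[1]]
    gpos <- function(k) if (probes$design_strand[i] == "F") k else 51L - k
    kk <- vapply(seq_len(50L), gpos, integer(1))
    at_k <- ch[kk] %in% c("A", "T") # indexed by probe offset
    if (all(at_k[seq_len(front_run)]) &&
      sum(at_k[(front_run + 2L):38L]) >= n_internal_min) {
      return(probes$probe_id[i])
    }
  }
  NA_character_
}

#' Generate a SNP table relative to probes
#'
#' Plants SNPs at chosen offsets from probe target CpGs, plus optional
#' decoy records that must be dropped by the reader (multi-bp interval,
#' weight 2).
#'
#' @param probes Probe records.
#' @param placements data.frame with `probe_idx` (row in `probes`),
#'   `offset` (bp relative to MAPINFO; 0 = the C, 1 = the G) and `het`.
#' @param path Optional path to also write the table (UCSC-style 0-based
#'   columns).
#' @param n_bad Number of appended records the reader must drop.
#' @return data.frame in the on-disk schema (`chrom`, `chromStart`,
#'   `chromEnd`, `name`, `weight`, `avHet`).
#' @export
gen_snp_table <- function(probes, placements, path = NULL, n_bad = 2L) {
  pos1 <- probes$mapinfo[placements$probe_idx] + placements$offset # 1-based
  tab <- data.frame(
    chrom = probes$chrom[placements$probe_idx],
    chromStart = pos1 - 1L,
    chromEnd = pos1,
    name = sprintf("rs%07d", seq_along(pos1)),
    weight = 1L,
    avHet = placements$het,
    stringsAsFactors = FALSE
  )
  if (n_bad > 0) {
    bad <- data.frame(
      chrom = rep(probes$chrom[1], n_bad),
      chromStart = c(10L, 20L)[seq_len(n_bad)],
      chromEnd = c(13L, 21L)[seq_len(n_bad)], # 3-bp interval; weight-2 record
      name = sprintf("rs_bad%02d", seq_len(n_bad)),
      weight = c(1L, 2L)[seq_len(n_bad)],
      avHet = 0.1,
      stringsAsFactors = FALSE
    )
    tab <- rbind(tab, bad)
  }
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tab
}

#' The five-transcript alternative-splicing demonstration gene set
#'
#' A fictional plus-strand gene with five transcripts (A-E) and three probe
#' positions (i, ii, iii) whose feature sets exercise all nine gene-feature
#' groups' edge cases: probe i gets 5'UTR exon + 5'UTR first exon + 5'UTR
#' intron; probe ii gets body exon + 5'UTR intron + body intron + body first
#' exon; probe iii gets 3'UTR exon (x3 transcripts) + 3'UTR intron + 3'UTR
#' first exon.
#'
#' @param chrom Chromosome name.
#' @param offset Added to every coordinate.
#' @return List with `models` (gene-model data.frame) and `probe_pos`
#'   (0-based target C positions named i, ii, iii).
#' @export
altsplice_gene_models <- function(chrom = "chr1", offset = 0L) {
  mk <- function(id, tx, cds, es, ee) {
    data.frame(
      transcript_id = id, gene_name = "DEMO1", chrom = chrom, strand = "+",
      tx_start = tx[1] + offset, tx_end = tx[2] + offset,
      cds_start = cds[1] + offset, cds_end = cds[2] + offset,
      exon_starts = I(list(as.integer(es + offset))),
      exon_ends = I(list(as.integer(ee + offset))),
      stringsAsFactors = FALSE
    )
  }
  models <- rbind(
    mk("TR_A", c(900, 6200), c(2800, 3200), c(900, 2800, 5900), c(1200, 3200, 6200)),
    mk("TR_B", c(500, 6200), c(4000, 4200), c(500, 900, 4000, 5900), c(700, 1100, 4300, 6200)),
    mk("TR_C", c(400, 6200), c(2500, 5100), c(400, 2500, 5000, 5900), c(600, 2700, 5200, 6200)),
    mk("TR_D", c(2900, 6700), c(2950, 5050), c(2900, 5000, 6500), c(3200, 5100, 6700)),
    mk("TR_E", c(5800, 6600), c(5850, 5950), c(5800, 6500), c(6100, 6600))
  )
  models$noncoding <- models$cds_start == models$cds_end
  validate_gene_models(models)
  list(
    models = models,
    probe_pos = c(i = 1000L, ii = 3000L, iii = 6000L) + offset
  )
}

#' Generate a beta-value matrix with planted truth
#'
#' Probe models: `null` (a tissue-common mean with noise), `trimodal`
#' (genotype mixture at declared allele frequency under Hardy-Weinberg with
#' centers for the three genotype classes), `tissue_diff` (per-tissue
#' means), `sex_diff` (sex-offset on a base mean). Noise is truncated-normal
#' via clipping to `[0, 1]`.
#'
#' @param n_probes Number of probes.
#' @param samples data.frame with `sample_id`, `tissue`, `sex`.
#' @param seed Integer seed.
#' @param frac_trimodal Fraction of probes given a genotype-trimodal model.
#' @param trimodal_centers Genotype-class beta centers (default
#'   `c(0.05, 0.5, 0.95)`).
#' @param allele_freq Allele frequency for Hardy-Weinberg genotype draws.
#' @param noise_sd Within-genotype / technical noise SD (default 0.05).
#' @param biological_sd_range Optional length-2 range: each `null` probe
#'   draws its own between-individual SD uniformly from this range
#'   (emulating the spread of within-tissue SDs seen among probes surviving
#'   a low-SD filter); genotype-driven (`trimodal`) and planted-effect
#'   probes keep the technical `noise_sd`.
#' @param tissue_diff data.frame with `probe_idx`, `tissue`, `mean` rows
#'   overriding per-tissue means (planted tDM probes).
#' @param sex_diff data.frame with `probe_idx`, `delta` (added to males).
#' @return List: `beta` (matrix), `samples`, `truth` (per-probe model and
#'   genotype assignments).
#' @export
gen_beta <- function(n_probes, samples, seed = 1L, frac_trimodal = 0,
                     trimodal_centers = c(0.05, 0.5, 0.95), allele_freq = 0.5,
                     noise_sd = 0.05, biological_sd_range = NULL,
                     tissue_diff = NULL, sex_diff = NULL) {
  with_seed(seed, {
    n_s <- nrow(samples)
    probe_ids <- sprintf("cg%08d", seq_len(n_probes))
    model <- rep("null", n_probes)
    n_tri <- round(frac_trimodal * n_probes)
    if (n_tri > 0) model[sample(n_probes, n_tri)] <- "trimodal"
    base_mean <- stats::runif(n_probes, 0.05, 0.95)
    mu <- matrix(base_mean, n_probes, n_s)
    genotype <- matrix(NA_integer_, n_probes, n_s)
    tri_idx <- which(model == "trimodal")
    if (length(tri_idx)) {
      p <- allele_freq
      gprob <- c((1 - p)^2, 2 * p * (1 - p), p^2)
      g <- matrix(
        sample(0:2, length(tri_idx) * n_s, replace = TRUE, prob = gprob),
        nrow = length(tri_idx)
      )
      genotype[tri_idx, ] <- g
      mu[tri_idx, ] <- matrix(trimodal_centers[g + 1L], nrow = length(tri_idx))
    }
    if (!is.null(tissue_diff)) {
      for (k in seq_len(nrow(tissue_diff))) {
        cols <- which(samples$tissue == tissue_diff$tissue[k])
        mu[tissue_diff$probe_idx[k], cols] <- tissue_diff$mean[k]
        model[tissue_diff$probe_idx[k]] <- "tissue_diff"
      }
    }
    if (!is.null(sex_diff)) {
      for (k in seq_len(nrow(sex_diff))) {
        cols <- which(samples$sex == "M")
        i <- sex_diff$probe_idx[k]
        mu[i, cols] <- mu[i, cols] + sex_diff$delta[k]
        model[i] <- "sex_diff"
      }
    }
    sd_per_probe <- rep(noise_sd, n_probes)
    if (!is.null(biological_sd_range)) {
      null_idx <- which(model == "null")
      sd_per_probe[null_idx] <- stats::runif(
        length(null_idx), biological_sd_range[1], biological_sd_range[2]
      )
    }
    beta <- mu + matrix(stats::rnorm(n_probes * n_s, 0, sd_per_probe), n_probes, n_s)
    beta <- pmin(pmax(beta, 0), 1)
    dimnames(beta) <- list(probe_ids, samples$sample_id)
    list(
      beta = beta, samples = samples,
      truth = list(
        model = stats::setNames(model, probe_ids),
        genotype = genotype,
        noise_sd = stats::setNames(sd_per_probe, probe_ids)
      )
    )
  })
}

#' Default sample sheet for fixture beta matrices
#'
#' @param tissues Character vector of tissue labels.
#' @param n_per_tissue Samples per tissue.
#' @param sexes Recycled sex labels.
#' @export
fixture_samples <- function(tissues = c("blood", "buccal", "villi"),
                            n_per_tissue = 4L, sexes = c("M", "F")) {
  tissue <- rep(tissues, each = n_per_tissue)
  data.frame(
    sample_id = sprintf("S%02d", seq_along(tissue)),
    tissue = tissue,
    sex = rep_len(rep(sexes, length.out = n_per_tissue), length(tissue)),
    stringsAsFactors = FALSE
  )
}

#' Write a complete default fixture set to a directory
#'
#' Generates genome FASTA, manifest, SNP table, gene table and a beta
#' matrix, all under one seed, plus truth sidecars.
#'
#' @param dir Output directory (created).
#' @param seed Integer seed.
#' @param preset `"default"`, `"altsplice"` (gene worked example only) or
#'   `"snp-demo"` (trimodal beta fixture emphasis).
#' @return Invisibly, the list of generated file paths.
#' @export
make_fixture_set <- function(dir, seed = 1L, preset = c("default", "altsplice", "snp-demo")) {
  preset <- match.arg(preset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  if (preset == "altsplice") {
    demo <- altsplice_gene_models()
    gt <- demo$models
    gt$exonStarts <- vapply(gt$exon_starts, function(v) paste0(paste(v, collapse = ","), ","), character(1))
    gt$exonEnds <- vapply(gt$exon_ends, function(v) paste0(paste(v, collapse = ","), ","), character(1))
    out <- data.frame(
      name = gt$transcript_id, name2 = gt$gene_name, chrom = gt$chrom,
      strand = gt$strand, txStart = gt$tx_start, txEnd = gt$tx_end,
      cdsStart = gt$cds_start, cdsEnd = gt$cds_end,
      exonStarts = gt$exonStarts, exonEnds = gt$exonEnds,
      stringsAsFactors = FALSE
    )
    paths$genes <- file.path(dir, "genes.tsv")
    utils::write.table(out, paths$genes, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(paths))
  }
  gg <- gen_genome(seed = seed, sex_chrom_len = 20000L)
  probes <- gen_probes(gg$genome, n = 24L, seed = seed + 1L)
  paths$genome <- file.path(dir, "genome.fa")
  write_fasta(gg$genome, paths$genome)
  paths$truth <- file.path(dir, "genome_truth.bed")
  write_bed(
    data.frame(
      chrom = gg$truth$chrom, start = gg$truth$start, end = gg$truth$end,
      name = gg$truth$what
    ),
    paths$truth
  )
  paths$manifest <- file.path(dir, "manifest.tsv")
  man <- data.frame(
    IlmnID = probes$probe_id, Infinium_Design_Type = probes$assay_type,
    Strand = probes$design_strand, CHR = probes$chrom, MAPINFO = probes$mapinfo,
    AlleleA_ProbeSeq = probes$probe_seq_A,
    AlleleB_ProbeSeq = ifelse(is.na(probes$probe_seq_B), "", probes$probe_seq_B),
    stringsAsFactors = FALSE
  )
  utils::write.table(man, paths$manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  placements <- data.frame(
    probe_idx = c(1L, 1L, 2L, 3L),
    offset = c(0L, 1L, 1L, 5L),
    het = c(0.25, NA, 0.05, 0.4)
  )
  paths$snps <- file.path(dir, "snps.tsv")
  gen_snp_table(probes, placements, path = paths$snps)
  demo <- altsplice_gene_models()
  make_fixture_set(file.path(dir), seed = seed, preset = "altsplice") -> gp
  paths$genes <- gp$genes
  samples <- fixture_samples()
  frac_tri <- if (preset == "snp-demo") 0.2 else 0.05
  gb <- gen_beta(nrow(probes), samples, seed = seed + 2L, frac_trimodal = frac_tri)
  rownames(gb$beta) <- probes$probe_id
  paths$beta <- file.path(dir, "beta.tsv")
  write_beta_matrix(gb$beta, samples, paths$beta)
  invisible(paths)
}
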