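# Independent brute-force oracles. These deliberately avoid the package's
# fast code paths: quadratic scans, all-offsets alignment, all-windows
# island enumeration.

# quadratic probe x SNP scan for target-CpG and proximity classes
oracle_snp_scan <- function(probes, snps, near_bp = 10L) {
  iv <- compute_probe_intervals(probes)
  n <- nrow(probes)
  res <- data.frame(
    probe_id = probes$probe_id,
    n_target = 0L, rs = NA_character_,
    lt = FALSE, gt = FALSE, stringsAsFactors = FALSE
  )
  # brute force: every probe against every SNP (vectorised over SNPs)
  for (i in seq_len(n)) {
    same <- snps$chrom == probes$chrom[i]
    p0 <- snps$pos - 1L
    at_target <- same & probes$category[i] == "cg" &
      (p0 == iv$cpg_start[i] | p0 == iv$cpg_start[i] + 1L)
    in_probe <- same & p0 >= iv$probe_start[i] & p0 < iv$probe_end[i]
    in_cpg <- p0 >= iv$cpg_start[i] & p0 < iv$cpg_end[i]
    d <- pmax(iv$cpg_start[i] - p0, p0 - (iv$cpg_end[i] - 1L))
    res$lt[i] <- any(in_probe & !in_cpg & d <= near_bp)
    res$gt[i] <- any(in_probe & !in_cpg & d > near_bp)
    if (any(at_target)) {
      res$n_target[i] <- sum(at_target)
      res$rs[i] <- paste(sort(unique(snps$rs_id[at_target])), collapse = ",")
    }
  }
  res
}

# all-offsets x all-variants x both-orientations exhaustive alignment scan,
# scored with the same local-trim semantics as the acceptance criteria but
# computed by direct vector comparison at every offset
oracle_specificity_scan <- function(probes, genome, min_matches = 40L, min_identity = 0.9) {
  variants <- bisulfite_variants(genome)
  res <- list()
  for (i in seq_len(nrow(probes))) {
    alleles <- list(A = probes$probe_seq_A[i])
    if (probes$assay_type[i] == "I") alleles$B <- probes$probe_seq_B[i]
    for (al in names(alleles)) {
      for (sq in expand_degenerate(alleles[[al]], probes$assay_type[i])) {
        for (orient in c("fwd", "rev")) {
          qry <- if (orient == "fwd") sq else methylannot:::rc_deg(sq)
          qc <- strsplit(qry, "", fixed = TRUE)[[1]]
          L <- length(qc)
          q50 <- if (orient == "fwd") L else 1L
          for (vn in names(variants)) {
            for (chrom in names(genome)) {
              vch <- strsplit(toupper(variants[[vn]][[chrom]]), "", fixed = TRUE)[[1]]
              n <- length(vch)
              # match count at every in-bounds offset via shifted comparison
              matches <- integer(n - L + 1)
              for (k in seq_len(L)) {
                matches <- matches + (vch[k:(n - L + k)] == qc[k])
              }
              cand <- which(matches >= min_matches)
              for (off in cand) {
                eq <- vch[off:(off + L - 1)] == qc
                first <- which.max(eq)
                last <- L + 1L - which.max(rev(eq))
                aligned <- last - first + 1L
                m <- matches[off]
                if (m / aligned >= min_identity && m >= min_matches &&
                  q50 >= first && q50 <= last) {
                  s0 <- off - 1L
                  if (grepl("rev", vn, fixed = TRUE)) {
                    gs <- n - (s0 + L)
                    ge <- n - s0
                  } else {
                    gs <- s0
                    ge <- s0 + L
                  }
                  res[[length(res) + 1L]] <- data.frame(
                    probe_id = probes$probe_id[i], chrom = chrom,
                    start = gs, end = ge, stringsAsFactors = FALSE
                  )
                }
              }
            }
          }
        }
      }
    }
  }
  if (!length(res)) {
    return(data.frame(probe_id = character(), chrom = character(), start = integer(), end = integer()))
  }
  unique(do.call(rbind, res))
}

# union of bases covered by ANY window satisfying the class thresholds
# (O(n^2); keep sequences small)
oracle_island_bases <- function(seq, params) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(ch)
  covered <- logical(n)
  is_c <- ch == "C"
  is_g <- ch == "G"
  is_n <- !(ch %in% c("A", "C", "G", "T"))
  is_cpg <- c(is_c[-n] & is_g[-1], FALSE)
  cC <- cumsum(is_c)
  cG <- cumsum(is_g)
  cN <- cumsum(is_n)
  cCpG <- cumsum(is_cpg)
  at <- function(v, i) if (i == 0) 0 else v[i]
  for (a in 0:(n - params$min_len - 1)) {
    b <- (a + params$min_len + 1):n # vectorised over window ends
    nC <- cC[b] - at(cC, a)
    nG <- cG[b] - at(cG, a)
    nN <- cN[b] - at(cN, a)
    len <- b - a
    ncpg <- cCpG[b - 1] - at(cCpG, a)
    gc <- (nC + nG) / len
    oe <- ifelse(nC > 0 & nG > 0, ncpg * len / (nC * nG), 0)
    pass <- nN == 0 & gc > params$min_gc & oe > params$min_oe
    if (any(pass)) covered[(a + 1):max(b[pass])] <- TRUE
  }
  which(covered) - 1L # 0-based base positions
}

# recompute island thresholds over an emitted extent
island_recomputes_ok <- function(genome, islands) {
  if (!nrow(islands)) {
    return(TRUE)
  }
  all(vapply(seq_len(nrow(islands)), function(i) {
    p <- island_params(islands$density_class[i])
    s <- genome_fetch(genome, islands$chrom[i], islands$start[i], islands$end[i])
    gc_content(s) > p$min_gc && obs_exp_cpg(s) > p$min_oe && nchar(s) > p$min_len
  }, logical(1)))
}

# shared small fixture (built once per test session)
fixture_env <- new.env()
get_default_fixture <- function() {
  if (is.null(fixture_env$fx)) {
    gg <- gen_genome(
      seed = 101L, length = 40000L, sex_chrom_len = 8000L,
      islands = data.frame(
        start = c(6000L, 15000L, 25000L, 25600L),
        len = c(600L, 400L, 600L, 400L),
        class = c("HC", "IC", "HC", "IC")
      ),
      repeats = data.frame(start = 32000L, len = 1500L)
    )
    probes <- gen_probes(gg$genome, n = 20L, seed = 102L)
    fixture_env$fx <- list(genome = gg$genome, truth = gg$truth, probes = probes)
  }
  fixture_env$fx
}
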