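# CpG-density landscape: HC/IC island scanning, HIL merging, and UCSC-style
# island/shore/shelf/sea probe classes.
#
# Threshold semantics are strict inequalities throughout: a region qualifies
# when CG content > min_gc, Obs/Exp CpG > min_oe and length > min_len.

#' CG content of a sequence
#'
#' Case-insensitive; N bases are excluded from both numerator and denominator.
#' Returns NA (with a warning) for an all-N sequence.
#'
#' @param seq Character scalar or vector.
#' @return Fraction in `[0, 1]` (or NA).
#' @export
gc_content <- function(seq) {
  vapply(toupper(seq), function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch <- ch[ch != "N"]
    if (!length(ch)) {
      warning("gc_content: all-N sequence; content undefined")
      return(NA_real_)
    }
    sum(ch %in% c("C", "G")) / length(ch)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Observed/expected CpG ratio (Gardiner-Garden & Frommer)
#'
#' `(#CpG * length) / (#C * #G)`; defined as 0 when the sequence has no C or
#' no G.
#'
#' @param seq Character scalar or vector.
#' @export
obs_exp_cpg <- function(seq) {
  vapply(toupper(seq), function(s) {
    if (!nzchar(s)) stop("obs_exp_cpg: empty sequence")
    n_c <- lengths(regmatches(s, gregexpr("C", s, fixed = TRUE)))
    n_g <- lengths(regmatches(s, gregexpr("G", s, fixed = TRUE)))
    n_cpg <- nchar(s) - nchar(gsub("CG", "", s, fixed = TRUE))
    n_cpg <- n_cpg / 2
    if (n_c == 0 || n_g == 0) {
      return(0)
    }
    (n_cpg * nchar(s)) / (n_c * n_g)
  }, numeric(1), USE.NAMES = FALSE)
}

# built-in class parameter sets
#' Island class threshold parameters
#'
#' `HC`: CG > 0.55, Obs/Exp > 0.75, length > 500 bp. `IC`: CG > 0.50,
#' Obs/Exp > 0.48, length > 200 bp. `UCSC`: CG > 0.50, Obs/Exp > 0.60,
#' length > 200 bp.
#'
#' @param class One of `"HC"`, `"IC"`, `"UCSC"`.
#' @return List with `min_gc`, `min_oe`, `min_len`.
#' @export
island_params <- function(class = c("HC", "IC", "UCSC")) {
  class <- match.arg(class)
  switch(class,
    HC = list(min_gc = 0.55, min_oe = 0.75, min_len = 500L),
    IC = list(min_gc = 0.50, min_oe = 0.48, min_len = 200L),
    UCSC = list(min_gc = 0.50, min_oe = 0.60, min_len = 200L)
  )
}

# per-chromosome scan machinery ------------------------------------------------

# cumulative counts so any window's composition is O(1)
.island_cums <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(ch)
  is_c <- ch == "C"
  is_g <- ch == "G"
  is_n <- !(ch %in% c("A", "C", "G", "T"))
  is_cpg <- c(is_c[-n] & is_g[-1], FALSE)
  list(
    n = n,
    C = cumsum(is_c), G = cumsum(is_g), N = cumsum(is_n), CpG = cumsum(is_cpg)
  )
}

# window [a, b) 0-based; vectorised over a/b
.window_pass <- function(cums, a, b, p) {
  cnt <- function(v, a, b) {
    va <- numeric(length(a))
    pos <- a > 0
    va[pos] <- v[a[pos]]
    v[b] - va
  }
  len <- b - a
  nC <- cnt(cums$C, a, b)
  nG <- cnt(cums$G, a, b)
  nN <- cnt(cums$N, a, b)
  # CpG dinucleotides fully inside the window: positions a .. b-2
  nCpG <- ifelse(len >= 2, cnt(cums$CpG, a, pmax(a, b - 1)), 0)
  gc <- (nC + nG) / len
  oe <- ifelse(nC > 0 & nG > 0, nCpG * len / (nC * nG), 0)
  nN == 0 & len > p$min_len & gc > p$min_gc & oe > p$min_oe
}

.scan_chrom <- function(seq, p) {
  cums <- .island_cums(seq)
  n <- cums$n
  L0 <- p$min_len + 1L
  if (n < L0) {
    return(data.frame(start = integer(), end = integer()))
  }
  starts <- 0:(n - L0)
  pass <- .window_pass(cums, starts, starts + L0, p)
  if (!any(pass)) {
    return(data.frame(start = integer(), end = integer()))
  }
  # merge overlapping/abutting passing seed windows into candidate regions
  s <- starts[pass]
  brk <- c(TRUE, diff(s) > L0)
  grp <- cumsum(brk)
  reg_start <- tapply(s, grp, min)
  reg_end <- tapply(s, grp, max) + L0
  out_s <- integer(0)
  out_e <- integer(0)
  for (k in seq_along(reg_start)) {
    a <- reg_start[[k]]
    b <- reg_end[[k]]
    if (.window_pass(cums, a, b, p)) {
      # greedy 1-bp extension while the region keeps qualifying
      repeat {
        ext <- FALSE
        if (b < n && .window_pass(cums, a, b + 1L, p)) {
          b <- b + 1L
          ext <- TRUE
        }
        if (a > 0 && .window_pass(cums, a - 1L, b, p)) {
          a <- a - 1L
          ext <- TRUE
        }
        if (!ext) break
      }
    } else {
      # trim 1 bp at a time from whichever end scores better until the
      # region qualifies or dies
      ok <- FALSE
      while (b - a > p$min_len) {
        if (.window_pass(cums, a, b, p)) {
          ok <- TRUE
          break
        }
        score <- function(a2, b2) {
          cnt <- function(v) v[b2] - ifelse(a2 == 0, 0, v[a2])
          nC <- cnt(cums$C)
          nG <- cnt(cums$G)
          len <- b2 - a2
          gc <- (nC + nG) / len
          oe <- if (nC > 0 && nG > 0) {
            nCpG <- if (len >= 2) cums$CpG[b2 - 1] - ifelse(a2 == 0, 0, cums$CpG[a2]) else 0
            nCpG * len / (nC * nG)
          } else {
            0
          }
          c(gc, oe)
        }
        sl <- score(a + 1L, b)
        sr <- score(a, b - 1L)
        # prefer the trim with higher CG content, then higher Obs/Exp;
        # tie breaks toward trimming the right end (deterministic)
        if (sl[1] > sr[1] || (sl[1] == sr[1] && sl[2] > sr[2])) {
          a <- a + 1L
        } else {
          b <- b - 1L
        }
      }
      if (!ok) next
    }
    out_s <- c(out_s, a)
    out_e <- c(out_e, b)
  }
  if (!length(out_s)) {
    return(data.frame(start = integer(), end = integer()))
  }
  # extension can make neighbouring regions touch; merge and keep qualifiers
  o <- order(out_s)
  out_s <- out_s[o]
  out_e <- out_e[o]
  ms <- out_s[1]
  me <- out_e[1]
  fs <- integer(0)
  fe <- integer(0)
  if (length(out_s) > 1) {
    for (k in 2:length(out_s)) {
      if (out_s[k] <= me) {
        me <- max(me, out_e[k])
      } else {
        fs <- c(fs, ms)
        fe <- c(fe, me)
        ms <- out_s[k]
        me <- out_e[k]
      }
    }
  }
  fs <- c(fs, ms)
  fe <- c(fe, me)
  keep <- .window_pass(cums, fs, fe, p)
  data.frame(start = as.integer(fs[keep]), end = as.integer(fe[keep]))
}

#' Scan a genome for CpG islands of one density class
#'
#' Seeds every minimum-length window satisfying the class thresholds, merges
#' overlapping seeds, greedily extends qualifying regions and trims failing
#' merged regions base by base. Every emitted island re-satisfies its
#' thresholds when recomputed over its final extent; islands of one class
#' never overlap. Windows containing N never qualify.
#'
#' @param genome Genome store from [read_fasta()].
#' @param class `"HC"`, `"IC"` or `"UCSC"` (ignored if `params` given).
#' @param params Optional list overriding [island_params()].
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `density_class`, `name` (1-based inclusive coordinates in the name).
#' @export
find_islands <- function(genome, class = c("HC", "IC", "UCSC"), params = NULL) {
  class <- match.arg(class)
  p <- if (is.null(params)) island_params(class) else params
  out <- lapply(names(genome), function(chrom) {
    df <- .scan_chrom(genome[[chrom]], p)
    if (!nrow(df)) {
      return(NULL)
    }
    df$chrom <- chrom
    df
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(), chrom = character())
  }
  out$density_class <- rep(class, nrow(out))
  out$name <- island_name(out$chrom, out$start, out$end, class)
  out[, c("chrom", "start", "end", "density_class", "name")]
}

#' Canonical island name
#'
#' `chr_CLASS:start-end` with 1-based inclusive coordinates (an en dash
#' separates start and end), e.g. `chr8_IC:49890018–49891221`.
#'
#' @param chrom,start,end 0-based half-open interval.
#' @param class Class label used in the name.
#' @export
island_name <- function(chrom, start, end, class) {
  if (!length(chrom)) {
    return(character(0))
  }
  sprintf("%s_%s:%d–%d", chrom, class, as.integer(start) + 1L, as.integer(end))
}

#' Merge HC and IC scans into the HIL island set
#'
#' Any base of HC density is HC. IC-density bases not inside an HC are
#' ICshore when their maximal IC-density run overlaps or lies within
#' `gap_tol` bp of an HC region, otherwise IC.
#'
#' @param hc_islands,ic_islands Outputs of [find_islands()].
#' @param gap_tol Adjacency tolerance in bp (default 0 = overlap or direct
#'   abutment).
#' @return data.frame of merged islands (`chrom`, `start`, `end`,
#'   `density_class` in HC/IC/ICshore, `name`).
#' @export
merge_hil <- function(hc_islands, ic_islands, gap_tol = 0) {
  pieces <- list()
  if (nrow(hc_islands)) {
    hc <- hc_islands
    hc$density_class <- "HC"
    hc$name <- island_name(hc$chrom, hc$start, hc$end, "HC")
    pieces[[length(pieces) + 1L]] <- hc[, c("chrom", "start", "end", "density_class", "name")]
  }
  for (i in seq_len(nrow(ic_islands))) {
    chrom <- ic_islands$chrom[i]
    s <- ic_islands$start[i]
    e <- ic_islands$end[i]
    hc_chr <- hc_islands[hc_islands$chrom == chrom, , drop = FALSE]
    touches <- nrow(hc_chr) > 0 &&
      any(pmax(0, pmax(hc_chr$start, s) - pmin(hc_chr$end, e)) <= gap_tol)
    cls <- if (touches) "ICshore" else "IC"
    # subtract HC cover; an HC in the interior splits the IC run
    segs <- data.frame(start = s, end = e)
    for (j in seq_len(nrow(hc_chr))) {
      hs <- hc_chr$start[j]
      he <- hc_chr$end[j]
      new <- list()
      for (k in seq_len(nrow(segs))) {
        a <- segs$start[k]
        b <- segs$end[k]
        if (he <= a || hs >= b) {
          new[[length(new) + 1L]] <- c(a, b)
        } else {
          if (a < hs) new[[length(new) + 1L]] <- c(a, hs)
          if (he < b) new[[length(new) + 1L]] <- c(he, b)
        }
      }
      segs <- if (length(new)) {
        as.data.frame(do.call(rbind, new)) |> stats::setNames(c("start", "end"))
      } else {
        data.frame(start = integer(), end = integer())
      }
    }
    if (nrow(segs)) {
      pieces[[length(pieces) + 1L]] <- data.frame(
        chrom = chrom, start = segs$start, end = segs$end,
        density_class = cls,
        name = island_name(rep(chrom, nrow(segs)), segs$start, segs$end, cls),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(pieces)) {
    return(data.frame(
      chrom = character(), start = integer(), end = integer(),
      density_class = character(), name = character(), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify probes into HIL classes
#'
#' The class of the target C's base: HC/IC/ICshore when the C falls inside a
#' merged island, LC otherwise.
#'
#' @param probe_intervals Output of [compute_probe_intervals()].
#' @param merged_islands Output of [merge_hil()].
#' @return data.frame with `probe_id`, `HIL_CpG_class`, `HIL_CpG_Island_Name`.
#' @export
classify_probe_hil <- function(probe_intervals, merged_islands) {
  cls <- rep("LC", nrow(probe_intervals))
  nm <- rep(NA_character_, nrow(probe_intervals))
  for (i in seq_len(nrow(probe_intervals))) {
    pos <- probe_intervals$cpg_start[i]
    hit <- which(merged_islands$chrom == probe_intervals$chrom[i] &
      merged_islands$start <= pos & pos < merged_islands$end)
    if (length(hit)) {
      hit <- hit[1]
      cls[i] <- merged_islands$density_class[hit]
      nm[i] <- merged_islands$name[hit]
    }
  }
  data.frame(
    probe_id = probe_intervals$probe_id,
    HIL_CpG_class = cls, HIL_CpG_Island_Name = nm,
    stringsAsFactors = FALSE
  )
}

#' Classify probes into UCSC island/shore/shelf/sea classes
#'
#' Distance is measured from the target C to the nearest island edge:
#' 0 = island, 1-2000 bp = shore, 2001-4000 bp = shelf, beyond = sea.
#'
#' @param probe_intervals Output of [compute_probe_intervals()].
#' @param ucsc_islands Islands from [find_islands()] in UCSC mode (or
#'   supplied externally).
#' @param shore_bp,shelf_bp Flank widths (defaults 2000 each).
#' @return data.frame with `probe_id`, `UCSC_CpG_class`.
#' @export
classify_probe_ucsc <- function(probe_intervals, ucsc_islands, shore_bp = 2000, shelf_bp = 2000) {
  cls <- rep("sea", nrow(probe_intervals))
  for (i in seq_len(nrow(probe_intervals))) {
    pos <- probe_intervals$cpg_start[i]
    isl <- ucsc_islands[ucsc_islands$chrom == probe_intervals$chrom[i], , drop = FALSE]
    if (!nrow(isl)) next
    d <- ifelse(pos < isl$start, isl$start - pos,
      ifelse(pos >= isl$end, pos - isl$end + 1, 0)
    )
    dmin <- min(d)
    cls[i] <- if (dmin == 0) {
      "island"
    } else if (dmin <= shore_bp) {
      "shore"
    } else if (dmin <= shore_bp + shelf_bp) {
      "shelf"
    } else {
      "sea"
    }
  }
  data.frame(
    probe_id = probe_intervals$probe_id, UCSC_CpG_class = cls,
    stringsAsFactors = FALSE
  )
}

#' Write / read an island BED track
#'
#' BED6 with the canonical island name in the name field.
#'
#' @param islands Island data.frame.
#' @param path File path.
#' @export
write_island_track <- function(islands, path) {
  write_bed(data.frame(
    chrom = islands$chrom, start = islands$start, end = islands$end,
    name = islands$name, score = rep(0L, nrow(islands)),
    strand = rep("*", nrow(islands)),
    stringsAsFactors = FALSE
  ), path)
}

#' @rdname write_island_track
#' @export
read_island_track <- function(path) {
  x <- read_bed(path)
  cls <- sub("^.*_([A-Za-z]+):.*$", "\\1", x$name)
  data.frame(
    chrom = x$chrom, start = as.integer(x$start), end = as.integer(x$end),
    density_class = ifelse(grepl("_[A-Za-z]+:", x$name), cls, NA_character_),
    name = x$name, stringsAsFactors = FALSE
  )
}
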