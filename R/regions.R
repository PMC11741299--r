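#' Genomic region sets
#'
#' Region sets are plain data frames with columns `chrom`, `start`, `end`
#' (0-based half-open) and an optional `summit` column holding the summit
#' as a bp offset from `start` (narrowPeak convention). `regions()`
#' validates and normalizes such a data frame.
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open interval bounds.
#' @param summit optional summit offset from `start`, or NA.
#' @param genome optional `cutnet_genome` used to bounds-check.
#' @return a data.frame with class `c("cutnet_regions", "data.frame")`.
#' @export
regions <- function(chrom, start, end, summit = NA_integer_, genome = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   summit = as.integer(summit),
                   stringsAsFactors = FALSE)
  if (any(df$start < 0) || any(df$start >= df$end))
    stop("require 0 <= start < end for every region")
  ok <- is.na(df$summit) | (df$summit >= 0 & df$summit < df$end - df$start)
  if (!all(ok)) stop("summit offsets must lie inside their region")
  if (!is.null(genome)) {
    len <- seq_lengths(genome)
    if (!all(df$chrom %in% names(len)))
      stop("unknown chromosome(s): ",
           paste(unique(setdiff(df$chrom, names(len))), collapse = ", "))
    if (any(df$end > len[df$chrom])) stop("region(s) extend past chromosome end")
  }
  class(df) <- c("cutnet_regions", "data.frame")
  df
}

# absolute summit position (bp); falls back to the interval midpoint
region_center <- function(rg) {
  s <- ifelse(is.na(rg$summit), (rg$end - rg$start) %/% 2L, rg$summit)
  rg$start + s
}

as_granges <- function(rg) {
  GenomicRanges::GRanges(rg$chrom,
                         IRanges::IRanges(start = rg$start + 1L, end = rg$end))
}

# logical: does each region in `a` overlap any region in `b` by >= 1 bp
overlaps_any <- function(a, b) {
  if (is.null(b) || nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  IRanges::overlapsAny(as_granges(a), as_granges(b))
}

#' Read regions from a BED file
#'
#' BED3 or more; with >= 10 columns the 10th column is taken as the
#' narrowPeak summit offset (-1 meaning absent).
#'
#' @param path BED file path.
#' @param genome optional `cutnet_genome` for bounds checking.
#' @return a `cutnet_regions` data frame.
#' @export
read_bed <- function(path, genome = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  summit <- NA_integer_
  if (ncol(df) >= 10L) {
    summit <- as.integer(df[[10L]])
    summit[summit < 0L] <- NA_integer_
  }
  regions(df[[1L]], df[[2L]], df[[3L]], summit, genome = genome)
}

#' Write regions to a BED file
#'
#' Written deterministically sorted by (chrom, start, end). When any summit
#' is present a 10-column narrowPeak-style record is written, otherwise
#' BED3.
#'
#' @param rg a `cutnet_regions` data frame.
#' @param path output path.
#' @export
write_bed <- function(rg, path) {
  rg <- rg[order(rg$chrom, rg$start, rg$end), , drop = FALSE]
  if (all(is.na(rg$summit))) {
    out <- rg[, c("chrom", "start", "end")]
  } else {
    out <- data.frame(rg$chrom, rg$start, rg$end, ".", 0L, ".",
                      0, -1, -1,
                      ifelse(is.na(rg$summit), -1L, rg$summit))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Enumerate candidate genome-wide bins
#'
#' Tiles every chromosome with fixed-width windows on a regular stride,
#' keeping only windows fully inside the chromosome. These are the
#' candidate regions from which GC-matched negatives are drawn.
#'
#' @param genome a `cutnet_genome`.
#' @param window window width in bp.
#' @param stride distance between window starts in bp.
#' @return a `cutnet_regions` data frame (summit = window center).
#' @export
tile_genome <- function(genome, window, stride) {
  stopifnot(window >= 1, stride >= 1)
  len <- seq_lengths(genome)
  parts <- lapply(names(len), function(ch) {
    if (len[[ch]] < window) return(NULL)
    starts <- seq.int(0L, len[[ch]] - window, by = stride)
    data.frame(chrom = ch, start = starts, end = starts + window)
  })
  df <- do.call(rbind, parts)
  if (is.null(df)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), summit = integer(0))
    class(out) <- c("cutnet_regions", "data.frame")
    return(out)
  }
  regions(df$chrom, df$start, df$end, summit = window %/% 2L)
}

#' GC content of regions
#'
#' Fraction of G+C among non-N bases over the full region sequence; the N
#' fraction is returned alongside.
#'
#' @param genome a `cutnet_genome`.
#' @param rg a `cutnet_regions` data frame.
#' @return data.frame with columns `gc` and `n_frac`.
#' @export
gc_content <- function(genome, rg) {
  res <- vapply(seq_len(nrow(rg)), function(i) {
    s <- get_seq(genome, rg$chrom[i], rg$start[i], rg$end[i])
    tab <- table(factor(strsplit(s, "", fixed = TRUE)[[1]],
                        levels = c("A", "C", "G", "T", "N")))
    acgt <- sum(tab[c("A", "C", "G", "T")])
    c(gc = if (acgt > 0) sum(tab[c("G", "C")]) / acgt else NA_real_,
      n_frac = tab[["N"]] / nchar(s))
  }, numeric(2))
  data.frame(gc = res[1L, ], n_frac = res[2L, ])
}

#' Select GC-matched background (negative) regions
#'
#' From a candidate bin set, removes bins overlapping peaks or the
#' blacklist by >= 1 bp or containing more than `max_n_frac` N bases, then
#' draws negatives whose per-GC-bin counts are proportional to the peak
#' set's GC distribution, targeting `multiplier` times the number of peaks.
#' A peak GC bin with no remaining candidates borrows from the nearest
#' non-empty bin (recorded in the `borrowed` attribute).
#'
#' @param candidates candidate bins, e.g. from [tile_genome()].
#' @param peaks peak regions.
#' @param blacklist optional excluded regions.
#' @param genome a `cutnet_genome`.
#' @param multiplier negatives per peak (default 2).
#' @param bin_width width of the GC-fraction bins (default 0.01).
#' @param max_n_frac maximum tolerated N fraction in a candidate.
#' @param seed optional RNG seed for the within-bin draws.
#' @return a `cutnet_regions` data frame of selected negatives.
#' @export
gc_match_negatives <- function(candidates, peaks, blacklist = NULL, genome,
                               multiplier = 2, bin_width = 0.01,
                               max_n_frac = 0.05, seed = NULL) {
  stopifnot(multiplier > 0, nrow(peaks) > 0)
  drop <- overlaps_any(candidates, peaks) | overlaps_any(candidates, blacklist)
  cand <- candidates[!drop, , drop = FALSE]
  if (nrow(cand) == 0L) stop("no candidate bins remain after exclusion")
  gc_cand <- gc_content(genome, cand)
  keep <- !is.na(gc_cand$gc) & gc_cand$n_frac <= max_n_frac
  cand <- cand[keep, , drop = FALSE]
  gc_cand <- gc_cand$gc[keep]
  gc_peak <- gc_content(genome, peaks)$gc
  breaks <- seq(0, 1, by = bin_width)
  bin_of <- function(g) pmin(pmax(findInterval(g, breaks, rightmost.closed = TRUE), 1L),
                             length(breaks) - 1L)
  cb <- bin_of(gc_cand)
  pb <- bin_of(gc_peak[!is.na(gc_peak)])
  n_target <- min(round(multiplier * nrow(peaks)), nrow(cand))
  if (n_target < round(multiplier * nrow(peaks)))
    warning("only ", nrow(cand), " candidates available; returning all that match")
  # largest-remainder allocation proportional to the peak GC histogram
  pk_counts <- table(factor(pb, levels = seq_len(length(breaks) - 1L)))
  quota <- as.numeric(pk_counts) / sum(pk_counts) * n_target
  alloc <- floor(quota)
  rem <- n_target - sum(alloc)
  if (rem > 0) {
    ord <- order(quota - alloc, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1L
  }
  avail <- table(factor(cb, levels = seq_len(length(breaks) - 1L)))
  borrowed <- character(0)
  sel <- integer(0)
  with_seed(seed, {
    taken <- rep(FALSE, nrow(cand))
    for (b in which(alloc > 0)) {
      need <- alloc[b]
      pool <- which(cb == b & !taken)
      if (length(pool) < need) {
        # borrow from nearest bins by GC distance
        ord <- order(abs(cb - b))
        extra <- setdiff(ord[cb[ord] != b & !taken[ord]], pool)
        if (length(pool) + length(extra) < need)
          need <- length(pool) + length(extra)
        borrowed <- c(borrowed, sprintf(
          "gc bin %d: needed %d, had %d candidates", b, alloc[b], length(pool)))
        pool <- c(pool, extra[seq_len(need - length(pool))])
        pick <- pool
      } else {
        pick <- pool[sample.int(length(pool), need)]
      }
      taken[pick] <- TRUE
      sel <- c(sel, pick)
    }
  })
  if (length(borrowed) > 0)
    message("gc_match_negatives borrowed from neighbouring bins:\n  ",
            paste(borrowed, collapse = "\n  "))
  out <- cand[sort(sel), , drop = FALSE]
  attr(out, "borrowed") <- borrowed
  out
}

#' Filter peaks for model training
#'
#' Removes (1) peaks whose total counts in a `count_width` window centered
#' on the summit exceed the `q` sample quantile over all peaks
#' (linear-interpolation quantile, `type = 7`), (2) peaks whose `input_len`
#' input window (plus `jitter` slack on both sides) cannot be constructed
#' inside the chromosome, and (3) peaks overlapping the blacklist.
#'
#' @param peaks peak regions with summits.
#' @param track a `cutnet_track` coverage track.
#' @param genome a `cutnet_genome`.
#' @param blacklist optional excluded regions.
#' @param input_len model input window width.
#' @param count_width width of the window used for the count filter.
#' @param q quantile threshold on totals (default 0.99).
#' @param jitter extra margin required on both sides for training jitter.
#' @return filtered `cutnet_regions`; attribute `removed` tabulates reasons.
#' @export
filter_training_peaks <- function(peaks, track, genome, blacklist = NULL,
                                  input_len = 2114L, count_width = 1000L,
                                  q = 0.99, jitter = 0L) {
  totals <- region_counts(track, peaks, width = count_width)
  hi <- totals > stats::quantile(totals, q, type = 7)
  ctr <- region_center(peaks)
  half <- input_len %/% 2L
  len <- seq_lengths(genome)[peaks$chrom]
  edge <- (ctr - half - jitter < 0L) | (ctr + half + jitter > len)
  bl <- overlaps_any(peaks, blacklist)
  keep <- !(hi | edge | bl)
  out <- peaks[keep, , drop = FALSE]
  attr(out, "removed") <- c(high_count = sum(hi), edge = sum(edge & !hi),
                            blacklist = sum(bl & !hi & !edge))
  out
}
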