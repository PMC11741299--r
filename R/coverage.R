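#' Cut sites and coverage tracks
#'
#' Cut sites are data frames with columns `chrom`, `pos` (0-based bp of the
#' aligned 5' read end) and `strand` (`+`/`-`). A coverage track
#' (`cutnet_track`) stores one integer vector of unstranded per-base cut
#' counts per chromosome.
#'
#' @param chrom,pos,strand vectors defining the sites.
#' @return data.frame of cut sites.
#' @export
cut_sites <- function(chrom, pos, strand) {
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  data.frame(chrom = as.character(chrom), pos = as.integer(pos),
             strand = strand, stringsAsFactors = FALSE)
}

#' Enzyme-specific strand shift offsets
#'
#' ATAC-seq: +4 bp on the plus strand and -4 bp on the minus strand, which
#' keeps the Tn5 dimer centers of the two strands aligned (the conventional
#' +4/-5 shift misaligns them by 1 bp). DNase-seq: plus strand unshifted,
#' minus strand +1 bp.
#'
#' @param assay `"ATAC"` or `"DNASE"`.
#' @return named numeric vector `c(plus = ..., minus = ...)`.
#' @export
shift_offsets <- function(assay = c("ATAC", "DNASE")) {
  assay <- match.arg(assay)
  switch(assay,
         ATAC  = c(plus = 4L, minus = -4L),
         DNASE = c(plus = 0L, minus = 1L))
}

#' Apply (or undo) the assay-specific read shift
#'
#' Sites whose shifted position falls outside the chromosome are dropped
#' with a counted warning; the drop count is kept in the `dropped`
#' attribute. Shifting then unshifting restores positions exactly.
#'
#' @param sites cut-site data frame.
#' @param assay `"ATAC"` or `"DNASE"`.
#' @param genome a `cutnet_genome` used for bounds checks.
#' @param reverse undo the shift instead of applying it.
#' @return shifted cut-site data frame (attribute `dropped` = count).
#' @export
shift_cuts <- function(sites, assay = c("ATAC", "DNASE"), genome,
                       reverse = FALSE) {
  off <- shift_offsets(assay)
  if (reverse) off <- -off
  delta <- ifelse(sites$strand == "+", off[["plus"]], off[["minus"]])
  pos <- sites$pos + delta
  len <- seq_lengths(genome)
  if (!all(sites$chrom %in% names(len)))
    stop("unknown chromosome(s): ",
         paste(unique(setdiff(sites$chrom, names(len))), collapse = ", "))
  ok <- pos >= 0L & pos < len[sites$chrom]
  if (any(!ok))
    warning(sum(!ok), " site(s) shifted outside chromosome bounds; dropped")
  out <- sites[ok, , drop = FALSE]
  out$pos <- pos[ok]
  rownames(out) <- NULL
  attr(out, "dropped") <- sum(!ok)
  out
}

#' Build an unstranded coverage track from cut sites
#'
#' Applies the assay shift, then pools both strands into one per-base
#' integer count vector per chromosome. Total counts equal the number of
#' sites minus those dropped at chromosome bounds.
#'
#' @param sites cut-site data frame.
#' @param genome a `cutnet_genome`.
#' @param assay `"ATAC"`, `"DNASE"`, or `NULL` if `sites` are already
#'   shifted.
#' @return a `cutnet_track`.
#' @export
build_coverage <- function(sites, genome, assay = NULL) {
  dropped <- 0L
  if (!is.null(assay)) {
    sites <- shift_cuts(sites, assay, genome)
    dropped <- attr(sites, "dropped")
  }
  len <- seq_lengths(genome)
  if (!all(sites$chrom %in% names(len)))
    stop("unknown chromosome(s): ",
         paste(unique(setdiff(sites$chrom, names(len))), collapse = ", "))
  cov <- lapply(names(len), function(ch) {
    p <- sites$pos[sites$chrom == ch]
    if (any(p < 0L | p >= len[[ch]])) stop("cut position outside ", ch)
    tabulate(p + 1L, nbins = len[[ch]])
  })
  structure(list(counts = stats::setNames(cov, names(len)), lengths = len,
                 dropped = dropped),
            class = "cutnet_track")
}

#' @export
print.cutnet_track <- function(x, ...) {
  cat("cutnet_track:", length(x$counts), "chromosome(s),",
      format(sum(vapply(x$counts, sum, 0)), big.mark = ","), "cut sites\n")
  invisible(x)
}

#' Per-region total counts
#'
#' @param track a `cutnet_track`.
#' @param rg regions.
#' @param width if given, count over a `width` window centered on each
#'   region's summit (clipped at chromosome bounds) instead of the region
#'   itself.
#' @return numeric vector of totals.
#' @export
region_counts <- function(track, rg, width = NULL) {
  len <- track$lengths
  if (is.null(width)) {
    s <- rg$start; e <- rg$end
  } else {
    ctr <- region_center(rg)
    s <- pmax(ctr - width %/% 2L, 0L)
    e <- pmin(s + width, len[rg$chrom])
  }
  vapply(seq_len(nrow(rg)), function(i) {
    sum(track$counts[[rg$chrom[i]]][(s[i] + 1L):e[i]])
  }, numeric(1))
}

# per-base counts over [start, end) on one chromosome
track_slice <- function(track, chrom, start, end) {
  v <- track$counts[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  if (start < 0L || end > length(v)) stop("slice outside chromosome")
  v[(start + 1L):end]
}

#' Read cut sites from BED6
#'
#' Each record must be a single-base interval; the 5' end is the `start`
#' coordinate for both strands (the caller is expected to have placed the
#' 5' read end there, as `bedtools bamtobed` does for the plus strand and
#' single-base records generally).
#'
#' @param path BED6 file.
#' @return cut-site data frame.
#' @export
read_cuts_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("cut-site BED must have 6 columns")
  if (any(df[[3L]] - df[[2L]] != 1L))
    stop("cut-site BED records must be single-base intervals")
  cut_sites(df[[1L]], df[[2L]], df[[6L]])
}

#' Write cut sites as BED6
#' @param sites cut-site data frame.
#' @param path output path.
#' @export
write_cuts_bed <- function(sites, path) {
  sites <- sites[order(sites$chrom, sites$pos, sites$strand), , drop = FALSE]
  out <- data.frame(sites$chrom, sites$pos, sites$pos + 1L, ".", 0L,
                    sites$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

track_to_granges <- function(track) {
  grs <- lapply(names(track$counts), function(ch) {
    r <- S4Vectors::Rle(track$counts[[ch]])
    n <- length(S4Vectors::runLength(r))
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r) + 1L
    keep <- S4Vectors::runValue(r) != 0
    GenomicRanges::GRanges(
      factor(rep(ch, sum(keep)), levels = names(track$counts)),
      IRanges::IRanges(starts[keep], ends[keep]),
      score = S4Vectors::runValue(r)[keep])
  })
  do.call(c, grs)
}

#' Write a coverage track as bedGraph (canonical) or bigWig
#'
#' bedGraph output is deterministically sorted by (chrom, start) with
#' zero-count runs omitted.
#'
#' @param track a `cutnet_track`.
#' @param path output path; format chosen by extension (`.bw`/`.bigwig`
#'   for bigWig, bedGraph otherwise).
#' @export
write_track <- function(track, path) {
  gr <- track_to_granges(track)
  GenomeInfoDb::seqlengths(gr) <- track$lengths[GenomeInfoDb::seqlevels(gr)]
  if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)) {
    rtracklayer::export.bw(gr, path)
  } else {
    rtracklayer::export.bedGraph(sort(gr), path)
  }
  invisible(path)
}

#' Read a coverage track from bedGraph or bigWig
#'
#' @param path input path (`.bw`/`.bigwig` read as bigWig, else bedGraph).
#' @param genome a `cutnet_genome` defining chromosomes and lengths.
#' @return a `cutnet_track`.
#' @export
read_track <- function(path, genome) {
  gr <- if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)) {
    rtracklayer::import.bw(path)
  } else {
    rtracklayer::import.bedGraph(path)
  }
  len <- seq_lengths(genome)
  cov <- lapply(names(len), function(ch) integer(len[[ch]]))
  names(cov) <- names(len)
  ch <- as.character(GenomicRanges::seqnames(gr))
  if (!all(ch %in% names(len)))
    stop("track contains unknown chromosome(s): ",
         paste(unique(setdiff(ch, names(len))), collapse = ", "))
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  sc <- gr$score
  for (i in seq_along(gr)) cov[[ch[i]]][st[i]:en[i]] <- sc[i]
  if (all(vapply(cov, function(v) all(v == floor(v)), TRUE)))
    cov <- lapply(cov, as.integer)
  structure(list(counts = cov, lengths = len, dropped = 0L),
            class = "cutnet_track")
}

#' Bernoulli subsampling of cut sites
#'
#' Each site is kept independently with probability `fraction`;
#' reproducible given `seed`.
#'
#' @param sites cut-site data frame.
#' @param fraction keep probability in `[0, 1]`.
#' @param seed RNG seed (default 1234).
#' @return subsampled cut-site data frame.
#' @export
subsample_cuts <- function(sites, fraction, seed = 1234L) {
  stopifnot(fraction >= 0, fraction <= 1)
  keep <- with_seed(seed, stats::runif(nrow(sites)) < fraction)
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strand-shift PWM alignment check
#'
#' For each candidate (plus, minus) shift pair, builds a k-mer position
#' weight matrix from sequences flanking the shifted plus-strand reads and
#' (reverse-complemented) minus-strand reads, and scores their agreement by
#' Pearson correlation. The recommended shift maximizes agreement; exact
#' ties are reported via the `tie` attribute.
#'
#' @param sites unshifted cut sites.
#' @param genome a `cutnet_genome`.
#' @param k PWM width in bp (even; default 24).
#' @param candidates list of length-2 integer vectors `c(plus, minus)`.
#' @param min_sites minimum sites required per strand.
#' @param max_sites per-strand cap; more sites are subsampled (seeded).
#' @param seed RNG seed for the subsample.
#' @return data.frame of per-candidate agreement with attributes `pwms`
#'   (list of plus/minus PWM pairs), `recommended` and `tie`.
#' @export
strand_shift_check <- function(sites, genome, k = 24L,
                               candidates = list(c(4L, -4L), c(4L, -5L),
                                                 c(0L, 0L), c(0L, 1L)),
                               min_sites = 50L, max_sites = 20000L,
                               seed = 1L) {
  stopifnot(k %% 2L == 0L)
  plus <- sites[sites$strand == "+", , drop = FALSE]
  minus <- sites[sites$strand == "-", , drop = FALSE]
  if (nrow(plus) < min_sites || nrow(minus) < min_sites)
    stop("need at least ", min_sites, " sites on each strand")
  with_seed(seed, {
    if (nrow(plus) > max_sites)
      plus <- plus[sample.int(nrow(plus), max_sites), , drop = FALSE]
    if (nrow(minus) > max_sites)
      minus <- minus[sample.int(nrow(minus), max_sites), , drop = FALSE]
  })
  half <- k %/% 2L
  pwm_of <- function(ss, delta, rc) {
    pos <- ss$pos + delta
    len <- seq_lengths(genome)[ss$chrom]
    ok <- pos - half >= 0L & pos + half <= len
    ss <- ss[ok, , drop = FALSE]; pos <- pos[ok]
    counts <- matrix(0, 4L, k, dimnames = list(.BASES, NULL))
    for (i in seq_len(nrow(ss))) {
      s <- get_seq(genome, ss$chrom[i], pos[i] - half, pos[i] + half)
      if (rc) s <- revcomp(s)
      idx <- match(strsplit(s, "", fixed = TRUE)[[1]], .BASES)
      keep <- which(!is.na(idx))
      counts[cbind(idx[keep], keep)] <- counts[cbind(idx[keep], keep)] + 1
    }
    sweep(counts + 0.25, 2L, colSums(counts + 0.25), "/")
  }
  res <- lapply(candidates, function(sh) {
    pp <- pwm_of(plus, sh[[1L]], rc = FALSE)
    pm <- pwm_of(minus, sh[[2L]], rc = TRUE)
    avg <- (pp + pm) / 2
    # information-content centroid: the enzyme's preference k-mer should
    # straddle the (correctly shifted) cut site, i.e. sit at the window
    # center. Candidate pairs differing only by a common translation have
    # identical strand agreement; the centroid separates them.
    ic <- pmax(colSums(avg * log2(pmax(avg, 1e-9) / 0.25)), 0)
    centroid <- if (sum(ic) > 1e-6) sum(seq_len(k) * ic) / sum(ic)
                else (k + 1) / 2
    list(plus = pp, minus = pm,
         agreement = stats::cor(as.vector(pp), as.vector(pm)),
         center_dist = abs(centroid - (k + 1) / 2))
  })
  agg <- vapply(res, `[[`, numeric(1), "agreement")
  cdist <- vapply(res, `[[`, numeric(1), "center_dist")
  tab <- data.frame(shift_plus = vapply(candidates, `[[`, integer(1), 1L),
                    shift_minus = vapply(candidates, `[[`, integer(1), 2L),
                    agreement = agg, center_dist = cdist)
  near <- which(agg >= max(agg) - 0.01)
  best <- near[cdist[near] <= min(cdist[near]) + 0.25]
  attr(tab, "pwms") <- res
  attr(tab, "recommended") <- tab[best[1L], c("shift_plus", "shift_minus")]
  attr(tab, "tie") <- length(best) > 1L
  tab
}
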