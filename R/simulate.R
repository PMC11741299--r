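#' Ground-truth enzyme bias for simulation
#'
#' A hand-set, Tn5-like additive k-mer preference. The log preference of a
#' k-mer is the sum of per-position, per-base weights from a
#' reverse-complement-palindromic weight matrix, scaled so that the
#' standard deviation of the log preference over all k-mers equals
#' `strength`, and centered so its mean over all k-mers is zero
#' (identifiability). The k-mer anchored at a cut position `p` covers
#' `[p - k/2, p + k/2)`.
#'
#' @param k k-mer order (even; default 6).
#' @param strength standard deviation of the log preference (0 disables
#'   bias).
#' @param assay_shift strand-shift convention the simulated reads follow
#'   (`"ATAC"` or `"DNASE"`).
#' @return an object of class `cutnet_bias_truth` with elements `k`,
#'   `weights` (k x 4 matrix, columns A,C,G,T), `assay_shift`.
#' @export
sim_bias_truth <- function(k = 6L, strength = 1.0, assay_shift = "ATAC") {
  stopifnot(k %% 2L == 0L)
  base_w <- matrix(c(  # palindromic-ish Tn5-like half site, rows = positions
     1.0, -0.5, -0.25, -0.25,   # G-rich start encoded on A,C,G,T columns below
    -0.6, -0.6,  0.4,   0.8,
     0.9, -0.3, -0.3,  -0.3), byrow = TRUE, nrow = 3L,
    dimnames = list(NULL, c("G", "C", "A", "T")))
  half <- base_w[, c("A", "C", "G", "T")]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  full <- matrix(0, k, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  hw <- k %/% 2L
  for (i in seq_len(hw)) {
    row <- half[((i - 1L) %% 3L) + 1L, ]
    full[i, ] <- row
    full[k + 1L - i, comp[names(row)]] <- row   # reverse-complement mirror
  }
  full <- full - rowMeans(full)                 # per-position zero mean
  # independent positions: k-mer variance is the sum of position variances
  v <- sum(apply(full, 1L, function(r) mean(r^2)))
  if (strength > 0 && v > 0) full <- full * (strength / sqrt(v))
  if (strength == 0) full[] <- 0
  structure(list(k = k, weights = full, assay_shift = assay_shift),
            class = "cutnet_bias_truth")
}

#' Log bias preference of k-mer strings
#' @param truth a `cutnet_bias_truth`.
#' @param kmers character vector of k-mers.
#' @return numeric log preferences (mean zero over all k-mers).
#' @export
bias_log_pref <- function(truth, kmers) {
  vapply(kmers, function(s) {
    idx <- match(strsplit(s, "", fixed = TRUE)[[1]], .BASES)
    if (length(idx) != truth$k) stop("k-mer of wrong length: ", s)
    sum(truth$weights[cbind(seq_len(truth$k), idx)], na.rm = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
}

#' The most preferred bias k-mer
#' @param truth a `cutnet_bias_truth`.
#' @return character string of length `k`.
#' @export
bias_top_kmer <- function(truth) {
  paste(.BASES[apply(truth$weights, 1L, which.max)], collapse = "")
}

#' Simulated motif with accessibility and footprint ground truth
#'
#' @param name motif label.
#' @param consensus consensus string; the PWM puts `p_consensus` on the
#'   consensus base and the rest uniformly on the others.
#' @param access_effect multiplicative accessibility gain of one instance.
#' @param depth footprint depth at the motif center in (0, 1]; 1 means no
#'   protection, small values a deep footprint. The per-offset protection
#'   follows a raised-cosine valley across the motif.
#' @param p_consensus consensus base probability.
#' @return list describing the motif, class `cutnet_motif`.
#' @export
sim_motif <- function(name, consensus, access_effect, depth,
                      p_consensus = 0.95) {
  w <- nchar(consensus)
  idx <- match(strsplit(toupper(consensus), "", fixed = TRUE)[[1]], .BASES)
  pwm <- matrix((1 - p_consensus) / 3, 4L, w, dimnames = list(.BASES, NULL))
  pwm[cbind(idx, seq_len(w))] <- p_consensus
  prot <- 1 - (1 - depth) * (0.5 - 0.5 * cos(2 * pi * (seq_len(w) - 0.5) / w))
  lo <- log(pwm / 0.25)
  structure(list(name = name, consensus = toupper(consensus), pwm = pwm,
                 logodds = lo, max_score = sum(apply(lo, 2L, max)),
                 access_effect = access_effect, protection = prot),
            class = "cutnet_motif")
}

#' Default simulated motif library
#'
#' Three motifs with deep, moderate and shallow footprints, emulating TFs
#' whose bound footprints differ in protection depth.
#'
#' @return named list of `cutnet_motif`.
#' @export
default_motifs <- function() {
  list(deep = sim_motif("deep", "TGCATAACGGTC", access_effect = 40,
                        depth = 0.15),
       moderate = sim_motif("moderate", "GATAAGCCAG", access_effect = 30,
                            depth = 0.45),
       shallow = sim_motif("shallow", "CAGCTGTT", access_effect = 20,
                           depth = 0.75))
}

#' Simulation specification
#'
#' Defines the synthetic study conditions: a 2 Mb genome split over six
#' chromosomes (four train, one validation, one test), 400 peaks of 500 bp
#' (testbed density — one peak per 5 kb, denser than genome average so the
#' training stage has enough examples to learn from) each carrying one
#' planted motif instance, a strong 6-mer Tn5-like bias, near-miss decoy
#' motifs in the background (for motif-creating variants), and 2 million
#' multinomially sampled cut sites.
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param gc target G+C fraction.
#' @param n_peaks total number of planted peaks.
#' @param peak_width peak width in bp; the accessibility bump has
#'   `sigma = peak_width / 6` and is truncated at 4 sigma.
#' @param margin minimum distance of a peak center from chromosome ends.
#' @param motifs motif library (see [default_motifs()]).
#' @param bias a `cutnet_bias_truth` (see [sim_bias_truth()]).
#' @param n_decoys near-miss (one-substitution-off) motif plants in
#'   background.
#' @param background_access baseline accessibility (rate units).
#' @param match_frac log-odds match threshold as a fraction of each PWM's
#'   maximum score.
#' @param depth number of sampled cut sites.
#' @param seed master RNG seed; all randomness derives from it.
#' @return list of class `cutnet_sim_spec`.
#' @export
sim_spec <- function(chrom_lengths = c(chr1 = 350000L, chr2 = 350000L,
                                       chr3 = 350000L, chr4 = 350000L,
                                       chr5 = 300000L, chr6 = 300000L),
                     gc = 0.41, n_peaks = 400L, peak_width = 500L,
                     margin = 1600L, motifs = default_motifs(),
                     bias = sim_bias_truth(), n_decoys = 110L,
                     background_access = 1.0, match_frac = 0.85,
                     depth = 2e6, seed = 1L) {
  stopifnot(depth > 0, n_peaks > 0)
  structure(list(chrom_lengths = chrom_lengths, gc = gc, n_peaks = n_peaks,
                 peak_width = peak_width, margin = margin, motifs = motifs,
                 bias = bias, n_decoys = n_decoys,
                 background_access = background_access,
                 match_frac = match_frac, depth = depth, seed = seed),
            class = "cutnet_sim_spec")
}

substream <- function(seed, i) (abs(seed) %% 100000000L) * 10L + i

sample_instance <- function(motif, match_frac, max_tries = 50L) {
  thr <- match_frac * motif$max_score
  for (t in seq_len(max_tries)) {
    idx <- apply(motif$pwm, 2L, function(p) sample.int(4L, 1L, prob = p))
    sc <- sum(motif$logodds[cbind(idx, seq_along(idx))])
    if (sc >= thr) return(paste(.BASES[idx], collapse = ""))
  }
  motif$consensus
}

# consensus with the worst base substituted at the highest-information
# column: scores below the match threshold until a variant restores it
decoy_instance <- function(motif) {
  j <- which.max(apply(motif$pwm, 2L, max))
  idx <- match(strsplit(motif$consensus, "", fixed = TRUE)[[1]], .BASES)
  idx[j] <- which.min(motif$pwm[, j])
  paste(.BASES[idx], collapse = "")
}

#' Generate a synthetic genome with planted peaks and decoys
#'
#' Bases are i.i.d. at the target GC outside plants. Each peak carries one
#' motif instance sampled from its PWM (conditioned on scoring above the
#' match threshold) at the peak center, which becomes the summit. Decoys
#' are near-miss instances planted in background.
#'
#' @param spec a `cutnet_sim_spec`.
#' @return list with `genome` (`cutnet_genome`), `peaks`
#'   (`cutnet_regions`), and `planted` (data.frame of every plant).
#' @export
sim_genome <- function(spec) {
  with_seed(substream(spec$seed, 1L), {
    len <- spec$chrom_lengths
    probs <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2,
               G = spec$gc / 2, T = (1 - spec$gc) / 2)
    seqs <- vapply(len, function(L) {
      paste(sample(.BASES, L, replace = TRUE, prob = probs[.BASES]),
            collapse = "")
    }, character(1))
    # distribute peaks over chromosomes proportionally to length
    n_per <- round(spec$n_peaks * len / sum(len))
    n_per[length(n_per)] <- spec$n_peaks - sum(n_per[-length(n_per)])
    planted <- list()
    for (ci in seq_along(len)) {
      ch <- names(len)[ci]
      n <- n_per[ci]
      if (n <= 0) next
      usable <- len[ci] - 2L * spec$margin
      slot <- usable / n
      centers <- spec$margin +
        floor((seq_len(n) - 0.5) * slot +
              stats::runif(n, -0.25 * slot, 0.25 * slot))
      ids <- sample(names(spec$motifs), n, replace = TRUE)
      for (i in seq_len(n)) {
        m <- spec$motifs[[ids[i]]]
        inst <- sample_instance(m, spec$match_frac)
        w <- nchar(inst)
        s0 <- centers[i] - w %/% 2L
        substr(seqs[[ch]], s0 + 1L, s0 + w) <- inst
        planted[[length(planted) + 1L]] <-
          data.frame(chrom = ch, center = centers[i], motif = ids[i],
                     kind = "peak", stringsAsFactors = FALSE)
      }
    }
    # decoys in background, away from peaks
    pk <- do.call(rbind, planted)
    nd <- spec$n_decoys
    if (nd > 0) {
      per <- round(nd * len / sum(len))
      per[length(per)] <- nd - sum(per[-length(per)])
      for (ci in seq_along(len)) {
        ch <- names(len)[ci]
        got <- 0L
        tries <- 0L
        while (got < per[ci] && tries < 50L * per[ci] + 50L) {
          tries <- tries + 1L
          pos <- floor(stats::runif(1, spec$margin, len[ci] - spec$margin))
          near <- pk$center[pk$chrom == ch]
          if (length(near) > 0 && min(abs(near - pos)) < 2L * spec$peak_width)
            next
          dn <- pk$center[pk$chrom == ch & pk$kind == "decoy"]
          if (length(dn) > 0 && min(abs(dn - pos)) < 2L * spec$peak_width)
            next
          id <- sample(names(spec$motifs), 1L)
          inst <- decoy_instance(spec$motifs[[id]])
          w <- nchar(inst)
          s0 <- pos - w %/% 2L
          substr(seqs[[ch]], s0 + 1L, s0 + w) <- inst
          pk <- rbind(pk, data.frame(chrom = ch, center = pos, motif = id,
                                     kind = "decoy", stringsAsFactors = FALSE))
          got <- got + 1L
        }
      }
    }
    genome <- as_genome(seqs)
    is_pk <- pk$kind == "peak"
    half <- spec$peak_width %/% 2L
    peaks <- regions(pk$chrom[is_pk], pk$center[is_pk] - half,
                     pk$center[is_pk] - half + spec$peak_width,
                     summit = half, genome = genome)
    list(genome = genome, peaks = peaks, planted = pk)
  })
}

#' Scan one chromosome for motif matches
#'
#' Log-odds scan (uniform background) of both strands; a position matches
#' when its score reaches `match_frac` of the PWM's maximum score.
#'
#' @param seq chromosome sequence (character).
#' @param motif a `cutnet_motif`.
#' @param match_frac threshold fraction.
#' @return data.frame with `center` (0-based bp), `strand`, `score`.
#' @export
scan_motif <- function(seq, motif, match_frac = 0.85) {
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1]], .BASES)
  w <- ncol(motif$logodds)
  L <- length(idx)
  if (L < w) return(data.frame(center = integer(0), strand = character(0),
                               score = numeric(0)))
  thr <- match_frac * motif$max_score
  hits <- list()
  for (strand in c("+", "-")) {
    lo <- motif$logodds
    if (strand == "-") lo <- lo[4:1, w:1]   # reverse complement
    sc <- numeric(L - w + 1L)
    for (j in seq_len(w)) {
      v <- lo[, j][idx[j:(j + L - w)]]
      v[is.na(v)] <- -10      # N penalised
      sc <- sc + v
    }
    at <- which(sc >= thr)
    if (length(at) > 0)
      hits[[strand]] <- data.frame(center = at - 1L + w %/% 2L,
                                   strand = strand, score = sc[at],
                                   stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) data.frame(center = integer(0), strand = character(0),
                               score = numeric(0))
  else out[order(out$center), , drop = FALSE]
}

#' Ground-truth per-base cleavage rate field
#'
#' `rate(x) = accessibility(x) * exp(bias log preference at x) *
#' protection(x)`. Accessibility is the background level plus, for every
#' motif match found by scanning the sequence, a Gaussian bump
#' (`sigma = peak_width/6`, truncated at 4 sigma) scaled by the motif's
#' `access_effect`. Protection multiplies the rate across each matched
#' motif by its footprint profile. Because accessibility is driven by
#' sequence matches, substituting a base re-shapes the field, which is how
#' variant ground truth is defined.
#'
#' @param genome a `cutnet_genome`.
#' @param spec a `cutnet_sim_spec`.
#' @return list of class `cutnet_rate` with `rate` (per-chrom numeric
#'   vectors) and `matches` (data.frame).
#' @export
true_cut_rate <- function(genome, spec) {
  sigma <- spec$peak_width / 6
  halfspan <- ceiling(4 * sigma)
  out <- list()
  allm <- list()
  for (ch in names(genome$seq)) {
    s <- genome$seq[[ch]]
    L <- nchar(s)
    access <- rep(spec$background_access, L)
    prot <- rep(1, L)
    for (mid in names(spec$motifs)) {
      m <- spec$motifs[[mid]]
      hits <- scan_motif(s, m, spec$match_frac)
      if (nrow(hits) > 0) {
        allm[[length(allm) + 1L]] <-
          cbind(chrom = ch, motif = mid, hits)
        w <- length(m$protection)
        for (i in seq_len(nrow(hits))) {
          c0 <- hits$center[i]
          lo <- max(0L, c0 - halfspan); hi <- min(L - 1L, c0 + halfspan)
          xs <- lo:hi
          access[xs + 1L] <- access[xs + 1L] +
            m$access_effect * exp(-((xs - c0)^2) / (2 * sigma^2))
          p0 <- c0 - w %/% 2L
          pr <- if (hits$strand[i] == "+") m$protection else rev(m$protection)
          span <- pmax(1L, pmin(L, (p0 + 1L):(p0 + w)))
          prot[span] <- prot[span] * pr[seq_along(span)]
        }
      }
    }
    # additive per-position bias score of the k-mer anchored at each base
    idx <- match(strsplit(s, "", fixed = TRUE)[[1]], .BASES)
    k <- spec$bias$k
    off0 <- -(k %/% 2L)
    bscore <- numeric(L)
    for (j in seq_len(k)) {
      wrow <- spec$bias$weights[j, ]
      shift <- off0 + (j - 1L)
      src <- seq_len(L) + shift
      ok <- src >= 1L & src <= L
      v <- numeric(L)
      vv <- wrow[idx[src[ok]]]
      vv[is.na(vv)] <- 0
      v[ok] <- vv
      bscore <- bscore + v
    }
    out[[ch]] <- access * exp(bscore) * prot
  }
  matches <- if (length(allm) > 0) do.call(rbind, allm) else
    data.frame(chrom = character(0), motif = character(0),
               center = integer(0), strand = character(0),
               score = numeric(0))
  structure(list(rate = out, matches = matches, sigma = sigma,
                 halfspan = halfspan), class = "cutnet_rate")
}

#' Multinomially sample cut sites from a rate field
#'
#' Exactly `depth` reads are drawn multinomially with probabilities
#' proportional to the rate. Strands are assigned uniformly at random and
#' recorded positions follow the bias truth's shift convention, so that
#' [shift_cuts()] with the matching assay re-aligns them to the true cut
#' base.
#'
#' @param rate a `cutnet_rate`.
#' @param depth number of reads.
#' @param assay_shift `"ATAC"` or `"DNASE"` (the recording convention).
#' @param seed RNG seed.
#' @return cut-site data frame.
#' @export
sim_cut_sites <- function(rate, depth, assay_shift = "ATAC", seed = 1L) {
  with_seed(seed, {
    lens <- vapply(rate$rate, length, integer(1))
    # zero sampling probability within 5 bp of chromosome ends so every
    # recorded read stays on-chromosome after the strand shift: the total
    # number of sampled reads then equals `depth` exactly
    edge <- 5L
    clipped <- lapply(rate$rate, function(v) {
      v[seq_len(min(edge, length(v)))] <- 0
      v[seq.int(max(1L, length(v) - edge + 1L), length(v))] <- 0
      v
    })
    all_rate <- unlist(clipped, use.names = FALSE)
    counts <- as.vector(stats::rmultinom(1L, size = depth,
                                         prob = all_rate / sum(all_rate)))
    nz <- which(counts > 0L)
    gpos <- rep(nz - 1L, counts[nz])           # 0-based global position
    ord <- sample.int(length(gpos))            # shuffle before strand draw
    gpos <- gpos[ord]
    bnd <- cumsum(lens)
    ci <- findInterval(gpos, c(0, bnd), rightmost.closed = FALSE)
    chrom <- names(rate$rate)[ci]
    pos <- gpos - c(0, bnd)[ci]
    strand <- ifelse(stats::runif(length(gpos)) < 0.5, "+", "-")
    off <- shift_offsets(assay_shift)
    rec <- ifelse(strand == "+", pos - off[["plus"]], pos - off[["minus"]])
    cut_sites(chrom, rec, strand)
  })
}

#' Simulated variant set with ground-truth effects
#'
#' Emits three variant classes: motif-ablating SNVs (worst-base
#' substitution at the highest-information column of a planted peak
#' instance; label `decrease`), motif-creating SNVs (restoring the
#' consensus at a planted decoy; label `increase`), and background SNVs
#' far from any match (label `null`). The true log fold change is the log
#' ratio of summed true cut rate over a 1 kb window centered on the
#' variant, alternate vs reference; because the accessibility bump is
#' truncated at 4 sigma, the value computed on a padded local slice equals
#' the full-genome recomputation exactly.
#'
#' @param genome a `cutnet_genome`.
#' @param sim output of [sim_genome()] (for the plant table).
#' @param spec the `cutnet_sim_spec`.
#' @param n target number of variants (split roughly equally by class).
#' @param window window (bp) over which the true total rate is compared.
#' @param seed RNG seed.
#' @return data.frame: chrom, pos (1-based, VCF convention), ref, alt,
#'   true_logfc, label.
#' @export
sim_variants <- function(genome, sim, spec, n = 240L, window = 1000L,
                         seed = 1L) {
  with_seed(seed, {
    pl <- sim$planted
    rate_ref <- true_cut_rate(genome, spec)
    rows <- list()
    add_variant <- function(ch, pos0, alt, label) {
      ref <- get_seq(genome, ch, pos0, pos0 + 1L)
      if (ref == alt) return(invisible(NULL))
      lfc <- true_logfc(genome, spec, ch, pos0, alt, window)
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = ch, pos = pos0 + 1L, ref = ref, alt = alt,
        true_logfc = lfc, label = label, stringsAsFactors = FALSE)
    }
    per <- ceiling(n / 3)
    # ablating: planted peak instances
    pk <- pl[pl$kind == "peak", , drop = FALSE]
    take <- pk[sample.int(nrow(pk), min(per, nrow(pk))), , drop = FALSE]
    for (i in seq_len(nrow(take))) {
      m <- spec$motifs[[take$motif[i]]]
      j <- which.max(apply(m$pwm, 2L, max))
      w <- ncol(m$pwm)
      pos0 <- take$center[i] - w %/% 2L + (j - 1L)
      alt <- .BASES[which.min(m$pwm[, j])]
      add_variant(take$chrom[i], pos0, alt, "decrease")
    }
    # creating: decoys; restore the consensus base
    dc <- pl[pl$kind == "decoy", , drop = FALSE]
    take <- dc[sample.int(nrow(dc), min(per, nrow(dc))), , drop = FALSE]
    for (i in seq_len(nrow(take))) {
      m <- spec$motifs[[take$motif[i]]]
      j <- which.max(apply(m$pwm, 2L, max))
      w <- ncol(m$pwm)
      pos0 <- take$center[i] - w %/% 2L + (j - 1L)
      alt <- substr(m$consensus, j, j)
      add_variant(take$chrom[i], pos0, alt, "increase")
    }
    # background: far from any match and any plant
    want <- n - length(rows)
    lens <- seq_lengths(genome)
    guard <- spec$peak_width + rate_ref$halfspan
    tries <- 0L
    while (want > 0L && tries < 200L * n) {
      tries <- tries + 1L
      ch <- sample(names(lens), 1L, prob = as.numeric(lens))
      pos0 <- floor(stats::runif(1, spec$margin, lens[[ch]] - spec$margin))
      mm <- rate_ref$matches
      near_m <- mm$center[mm$chrom == ch]
      if (length(near_m) > 0 && min(abs(near_m - pos0)) < guard) next
      near_p <- pl$center[pl$chrom == ch]
      if (length(near_p) > 0 && min(abs(near_p - pos0)) < guard) next
      ref <- get_seq(genome, ch, pos0, pos0 + 1L)
      alt <- sample(setdiff(.BASES, ref), 1L)
      add_variant(ch, pos0, alt, "null")
      want <- want - 1L
    }
    out <- do.call(rbind, rows)
    # drop the rare plant whose sampled instance already lacked the target
    # base: labels must reflect the recomputed truth
    keep <- (out$label == "decrease" & out$true_logfc < 0) |
            (out$label == "increase" & out$true_logfc > 0) |
            (out$label == "null")
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' True log fold change of a single substitution
#'
#' Log ratio of total true cut rate in a `window` around the variant,
#' alternate over reference. Computed on a padded slice wide enough that,
#' with the 4-sigma bump truncation, it equals a full-genome rebuild.
#'
#' @param genome a `cutnet_genome`.
#' @param spec the `cutnet_sim_spec`.
#' @param chrom,pos0 variant location (0-based).
#' @param alt alternate base.
#' @param window comparison window width (bp).
#' @return scalar log fold change (natural log).
#' @export
true_logfc <- function(genome, spec, chrom, pos0, alt, window = 1000L) {
  sigma <- spec$peak_width / 6
  wmax <- max(vapply(spec$motifs, function(m) ncol(m$pwm), integer(1)))
  pad <- window %/% 2L + ceiling(4 * sigma) + wmax + spec$bias$k
  L <- seq_lengths(genome)[[chrom]]
  lo <- max(0L, pos0 - pad); hi <- min(L, pos0 + pad + 1L)
  sl <- get_seq(genome, chrom, lo, hi)
  at <- pos0 - lo
  sl_alt <- sl
  substr(sl_alt, at + 1L, at + 1L) <- alt
  rate_of <- function(s) {
    g <- as_genome(stats::setNames(s, "slice"))
    true_cut_rate(g, spec)$rate[["slice"]]
  }
  half <- window %/% 2L
  win <- (max(0L, at - half) + 1L):min(nchar(sl), at + half)
  log(sum(rate_of(sl_alt)[win])) - log(sum(rate_of(sl)[win]))
}

#' Run the full simulator
#'
#' Generates the genome, peaks, rate field, sampled cut sites, the shifted
#' coverage track, and (optionally) a labelled variant set.
#'
#' @param spec a `cutnet_sim_spec`.
#' @param variants number of variants to emit (0 to skip).
#' @return list with `spec`, `genome`, `peaks`, `planted`, `rate`,
#'   `sites`, `track`, and `variants`.
#' @export
simulate_experiment <- function(spec = sim_spec(), variants = 0L) {
  sim <- sim_genome(spec)
  rate <- true_cut_rate(sim$genome, spec)
  sites <- sim_cut_sites(rate, spec$depth, spec$bias$assay_shift,
                         seed = substream(spec$seed, 2L))
  track <- build_coverage(sites, sim$genome, assay = spec$bias$assay_shift)
  vars <- NULL
  if (variants > 0L)
    vars <- sim_variants(sim$genome, sim, spec, n = variants,
                         seed = substream(spec$seed, 3L))
  list(spec = spec, genome = sim$genome, peaks = sim$peaks,
       planted = sim$planted, rate = rate, sites = sites, track = track,
       variants = vars)
}
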