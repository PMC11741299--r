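#' Count-head performance: Pearson r of log totals
#'
#' @param obs_totals,pred_totals observed and predicted total counts over
#'   regions (linear scale).
#' @return Pearson correlation of `log1p` totals.
#' @export
count_metric <- function(obs_totals, pred_totals) {
  stats::cor(log1p(obs_totals), log1p(pred_totals))
}

#' Jensen-Shannon distance between two profiles (base 2)
#'
#' KL divergences to the pointwise mean, computed with logarithm base 2,
#' averaged; ranges from 0 (identical) to 1 (disjoint support). This is
#' the profile evaluation metric; variant scoring uses the natural-log
#' divergence separately.
#'
#' @param p,q probability vectors (non-negative; normalized internally).
#' @return JSD in `[0, 1]`.
#' @export
profile_jsd <- function(p, q) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl2 <- function(a, b) {
    i <- a > 0
    sum(a[i] * (log2(a[i]) - log2(b[i])))
  }
  (kl2(p, m) + kl2(q, m)) / 2
}

#' Reference JSD baselines for observed profiles
#'
#' For each region: a pseudoreplicate concordance upper bound (random
#' 50/50 split of the region's reads, JSD between the halves), a
#' mean-profile baseline (JSD of the observed profile to the region-set
#' average profile) and a shuffled-profile baseline (JSD to a random
#' within-region permutation of the observed counts).
#'
#' @param track a `cutnet_track`.
#' @param rg regions.
#' @param width profile window width centered on summits.
#' @param seed RNG seed.
#' @return data.frame with columns pseudorep, mean_baseline, shuffled.
#' @export
jsd_baselines <- function(track, rg, width = 1000L, seed = 1L) {
  profs <- lapply(seq_len(nrow(rg)), function(i) {
    ctr <- region_center(rg)[i]
    track_slice(track, rg$chrom[i], ctr - width %/% 2L,
                ctr - width %/% 2L + width)
  })
  keep <- vapply(profs, sum, 0) > 0
  profs <- profs[keep]
  mean_prof <- Reduce(`+`, lapply(profs, function(k) k / sum(k))) /
    length(profs)
  with_seed(seed, {
    res <- t(vapply(profs, function(k) {
      a <- stats::rbinom(length(k), k, 0.5)
      b <- k - a
      ps <- if (sum(a) > 0 && sum(b) > 0) profile_jsd(a, b) else NA_real_
      c(pseudorep = ps,
        mean_baseline = profile_jsd(k, mean_prof),
        shuffled = profile_jsd(k, sample(k)))
    }, numeric(3)))
    as.data.frame(res)
  })
}

#' Label 100 bp genome bins for classification evaluation
#'
#' Positive bins overlap the (IDR summit +/- 100 bp) positive set by
#' 100%. Ambiguous bins are, in order: bins partially (but not fully)
#' overlapping that positive set; bins overlapping an overlap-peak
#' without being positive; bins overlapping the blacklist; bins with
#' under 50% uniquely mappable positions (rule skipped with a warning
#' when no mappability is supplied). Remaining bins are negative.
#'
#' @param genome a `cutnet_genome`.
#' @param idr_peaks high-confidence peaks with summits.
#' @param overlap_peaks more permissive peak set (may be the same).
#' @param blacklist optional excluded regions.
#' @param mappability optional regions of uniquely mappable positions.
#' @param bin bin width (default 100 bp).
#' @param flank half-width of the positive region around each IDR summit.
#' @return `cutnet_regions` of all bins with extra columns `label`
#'   (positive/negative/ambiguous) and `reason`.
#' @export
label_bins <- function(genome, idr_peaks, overlap_peaks = idr_peaks,
                       blacklist = NULL, mappability = NULL, bin = 100L,
                       flank = 100L) {
  bins <- tile_genome(genome, bin, bin)
  ctr <- region_center(idr_peaks)
  pos_rg <- regions(idr_peaks$chrom, pmax(ctr - flank, 0L), ctr + flank)
  gr_b <- as_granges(bins)
  gr_p <- as_granges(pos_rg)
  ov <- GenomicRanges::findOverlaps(gr_b, gr_p)
  covered <- integer(nrow(bins))
  if (length(ov) > 0) {
    inter <- IRanges::pintersect(gr_b[S4Vectors::queryHits(ov)],
                                 gr_p[S4Vectors::subjectHits(ov)])
    w <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), max)
    covered[as.integer(names(w))] <- as.integer(w)
  }
  full <- covered == bin
  part <- covered > 0L & !full
  label <- ifelse(full, "positive", "negative")
  reason <- ifelse(full, "idr_full", "")
  amb <- function(cond, code) {
    hit <- cond & !full & label != "ambiguous"
    label[hit] <<- "ambiguous"
    reason[hit] <<- code
  }
  amb(part, "idr_partial")
  amb(overlaps_any(bins, overlap_peaks), "overlap_peak")
  amb(overlaps_any(bins, blacklist), "blacklist")
  if (is.null(mappability)) {
    warning("no mappability supplied: mappability rule skipped")
  } else {
    gr_m <- as_granges(mappability)
    ovm <- GenomicRanges::findOverlaps(gr_b, gr_m)
    mapb <- integer(nrow(bins))
    if (length(ovm) > 0) {
      inter <- IRanges::pintersect(gr_b[S4Vectors::queryHits(ovm)],
                                   gr_m[S4Vectors::subjectHits(ovm)])
      w <- tapply(IRanges::width(inter), S4Vectors::queryHits(ovm), sum)
      mapb[as.integer(names(w))] <- as.integer(w)
    }
    amb(mapb < bin / 2, "low_mappability")
  }
  bins$label <- label
  bins$reason <- reason
  bins
}

#' Area under the ROC curve
#' @param labels logical or 0/1 vector.
#' @param scores numeric scores.
#' @return AUROC.
#' @export
auroc <- function(labels, scores) {
  r <- pROC::roc(response = as.integer(labels), predictor = scores,
                 quiet = TRUE, direction = "<", levels = c(0L, 1L))
  as.numeric(pROC::auc(r))
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: sum over ranked positives of precision at
#' each recall step.
#'
#' @param labels logical or 0/1 vector.
#' @param scores numeric scores.
#' @return AUPRC.
#' @export
auprc <- function(labels, scores) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  sum(prec[y == 1L]) / sum(y)
}

#' Genome-wide classification of labelled bins
#'
#' Predicts log counts for windows tiled across each chromosome
#' (`stride` default 250 bp), assigns every bin the maximum (or mean)
#' predicted log count of the windows whose output covers it, and
#' computes AUROC/AUPRC over positive vs negative bins (ambiguous
#' excluded).
#'
#' @param fit a `cutnet_fit` or `cutnet_model`.
#' @param genome a `cutnet_genome`.
#' @param labels output of [label_bins()].
#' @param stride prediction window stride (bp).
#' @param corrected use bias-corrected predictions for a `cutnet_fit`.
#' @param aggregate `"max"` (default) or `"mean"` over covering windows.
#' @return list with `auroc`, `auprc`, `prevalence`, `scores` (per-bin),
#'   `labels` (the evaluated subset).
#' @export
genomewide_classification <- function(fit, genome, labels, stride = 250L,
                                      corrected = TRUE,
                                      aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  fun <- prediction_fun(fit, corrected)
  cfg <- fit$config
  half_in <- cfg$input_len %/% 2L
  half_out <- cfg$output_len %/% 2L
  len <- seq_lengths(genome)
  bins <- labels
  score <- rep(-Inf, nrow(bins))
  nhit <- integer(nrow(bins))
  ssum <- numeric(nrow(bins))
  for (ch in names(len)) {
    centers <- seq.int(half_in, len[[ch]] - half_in, by = stride)
    if (length(centers) == 0L) next
    for (ctr in centers) {
      s <- get_seq(genome, ch, ctr - half_in, ctr - half_in + cfg$input_len)
      lt <- fun(s)$log_total
      sel <- which(bins$chrom == ch & bins$start >= ctr - half_out &
                   bins$end <= ctr + half_out)
      if (length(sel) > 0) {
        score[sel] <- pmax(score[sel], lt)
        ssum[sel] <- ssum[sel] + lt
        nhit[sel] <- nhit[sel] + 1L
      }
    }
  }
  if (aggregate == "mean") score <- ifelse(nhit > 0, ssum / nhit, -Inf)
  use <- bins$label != "ambiguous" & nhit > 0
  y <- bins$label[use] == "positive"
  if (!any(y) || all(y)) stop("need both positive and negative bins")
  list(auroc = auroc(y, score[use]), auprc = auprc(y, score[use]),
       prevalence = mean(y),
       scores = score[use],
       labels = bins[use, , drop = FALSE])
}
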