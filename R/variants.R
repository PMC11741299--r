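#' Read variants from VCF or TSV
#'
#' SNVs only. VCF files (`.vcf`) are parsed for CHROM/POS/REF/ALT;
#' anything else is read as a TSV with columns chrom, pos (1-based), ref,
#' alt (header optional, detected).
#'
#' @param path input file.
#' @return data.frame with chrom, pos (1-based), ref, alt.
#' @export
read_variants <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#")]
    f <- strsplit(ln, "\t", fixed = TRUE)
    df <- data.frame(chrom = vapply(f, `[[`, "", 1L),
                     pos = as.integer(vapply(f, `[[`, "", 2L)),
                     ref = toupper(vapply(f, `[[`, "", 4L)),
                     alt = toupper(vapply(f, `[[`, "", 5L)),
                     stringsAsFactors = FALSE)
  } else {
    first <- utils::read.table(path, sep = "\t", nrows = 1L,
                               stringsAsFactors = FALSE)
    has_header <- is.na(suppressWarnings(as.integer(first[[2L]])))
    df <- utils::read.table(path, sep = "\t", header = has_header,
                            stringsAsFactors = FALSE)
    df <- df[, 1:4]
    names(df) <- c("chrom", "pos", "ref", "alt")
    df$pos <- as.integer(df$pos)
    df$ref <- toupper(df$ref); df$alt <- toupper(df$alt)
  }
  bad <- nchar(df$ref) != 1L | nchar(df$alt) != 1L
  if (any(bad)) {
    warning(sum(bad), " non-SNV record(s) dropped")
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write a variant table as TSV
#' @param df variant (or scored-variant) data frame.
#' @param path output path.
#' @export
write_variants <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  out <- df
  out[num] <- lapply(df[num], function(v) signif(v, 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# allele-centered window pair for a variant; windows are centered on the
# variant base
variant_windows <- function(genome, chrom, pos1, ref, alt, input_len) {
  pos0 <- pos1 - 1L
  half <- input_len %/% 2L
  s <- get_seq(genome, chrom, pos0 - half, pos0 - half + input_len)
  at <- half + 1L
  obs <- substr(s, at, at)
  if (obs != toupper(ref))
    stop(sprintf("reference mismatch at %s:%d — genome has %s, variant says %s",
                 chrom, pos1, obs, ref))
  s_alt <- s
  substr(s_alt, at, at) <- toupper(alt)
  list(ref = s, alt = s_alt)
}

jsd_e <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * (log(a[i]) - log(b[i])))
  }
  (kl(p, m) + kl(q, m)) / 2
}

# per-fold predicted log counts over peak input windows (AAQ percentiles)
peak_count_distributions <- function(models, genome, peaks, corrected) {
  lapply(models, function(fit) {
    fun <- prediction_fun(fit, corrected)
    ctr <- region_center(peaks)
    half <- fit$config$input_len %/% 2L
    len <- seq_lengths(genome)[peaks$chrom]
    ok <- ctr - half >= 0L & ctr - half + fit$config$input_len <= len
    vapply(which(ok), function(i) {
      s <- get_seq(genome, peaks$chrom[i], ctr[i] - half,
                   ctr[i] - half + fit$config$input_len)
      predict_symmetrized(fun, s)$log_total
    }, numeric(1))
  })
}

# cross-fold aggregation of the printed formulas:
# IES = mean(logFC) * mean(JSD); IPS = mean(|logFC|) * |mean(JSD)| *
# mean(AAQ). JSD here is the signed per-fold value; IPS takes the
# magnitude of its mean so that IPS >= 0 (a prioritization score) while
# IES keeps the direction information.
variant_aggregates <- function(logfc, jsd, aaq) {
  c(logfc = mean(logfc), jsd = mean(jsd), aaq = mean(aaq),
    ies = mean(logfc) * mean(jsd),
    ips = mean(abs(logfc)) * abs(mean(jsd)) * mean(aaq))
}

# add-one pseudocount empirical p-value (never exactly zero)
empirical_p <- function(observed, null) {
  (1 + sum(null >= observed)) / (1 + length(null))
}

# strand-symmetrized prediction: average the forward prediction with the
# flipped reverse-complement prediction (probability scale for the
# profile, head output for counts)
predict_symmetrized <- function(fun, s) {
  a <- fun(s)
  b <- fun(revcomp(s))
  list(prob = (softmax(a$logits) + rev(softmax(b$logits))) / 2,
       log_total = (a$log_total + b$log_total) / 2)
}

score_variant_one <- function(models, genome, chrom, pos1, ref, alt,
                              peak_log_counts, corrected = TRUE) {
  nfold <- length(models)
  logfc <- jsd <- aaq <- numeric(nfold)
  for (i in seq_len(nfold)) {
    fit <- models[[i]]
    fun <- prediction_fun(fit, corrected)
    wins <- variant_windows(genome, chrom, pos1, ref, alt,
                            fit$config$input_len)
    p1 <- predict_symmetrized(fun, wins$ref)
    p2 <- predict_symmetrized(fun, wins$alt)
    logfc[i] <- p2$log_total - p1$log_total
    sg <- sign(logfc[i])
    jsd[i] <- jsd_e(p1$prob, p2$prob) * if (sg == 0) 0 else sg
    ec <- stats::ecdf(peak_log_counts[[i]])
    aaq[i] <- max(ec(p1$log_total), ec(p2$log_total))
  }
  variant_aggregates(logfc, jsd, aaq)
}

#' Score variants for predicted effects on accessibility
#'
#' For each variant and model fold, both alleles are inserted at the
#' center of the input window and scored: `logFC` is the difference of
#' predicted log totals (alt minus ref); `JSD` is the Jensen-Shannon
#' divergence (natural log) between the two predicted probability
#' profiles, signed by `sign(logFC)`; `AAQ` is the larger allele's
#' empirical percentile of predicted log counts within the fold's peak
#' distribution. Across folds, `IES = mean(logFC) * mean(JSD)` and
#' `IPS = mean(|logFC|) * |mean(JSD)| * mean(AAQ)` (non-negative).
#'
#' @param models list of `cutnet_fit` (one per fold) or a single fit.
#' @param genome a `cutnet_genome`.
#' @param variants data.frame with chrom, pos (1-based), ref, alt.
#' @param peaks peak regions used for the AAQ percentile distribution.
#' @param track optional `cutnet_track`; unused for scoring but accepted
#'   for interface symmetry.
#' @param corrected use bias-corrected predictions (default TRUE).
#' @return the variant data.frame augmented with logfc, jsd, aaq, ies,
#'   ips columns (per-fold means and aggregates).
#' @export
score_variants <- function(models, genome, variants, peaks,
                           track = NULL, corrected = TRUE) {
  if (inherits(models, "cutnet_fit")) models <- list(models)
  peak_log_counts <- peak_count_distributions(models, genome, peaks,
                                              corrected)
  sc <- t(vapply(seq_len(nrow(variants)), function(v) {
    score_variant_one(models, genome, variants$chrom[v], variants$pos[v],
                      variants$ref[v], variants$alt[v], peak_log_counts,
                      corrected)
  }, numeric(5)))
  cbind(variants, as.data.frame(sc))
}

#' Empirical p-value of an IPS score against a shuffled-sequence null
#'
#' The null is built by dinucleotide-shuffling the variant's reference
#' window, reintroducing both alleles at the center, and recomputing IPS;
#' `p = (1 + #{null >= observed}) / (1 + n_null)` (add-one pseudocount,
#' never exactly zero).
#'
#' @param models list of `cutnet_fit` or a single fit.
#' @param genome a `cutnet_genome`.
#' @param variant one-row data.frame (chrom, pos, ref, alt).
#' @param peaks peak regions for AAQ percentiles.
#' @param n_null null-set size (desk default 10000; scale as needed).
#' @param seed RNG seed.
#' @param corrected use bias-corrected predictions.
#' @return list with `p`, `observed_ips`, `null_ips`.
#' @export
variant_pvalue <- function(models, genome, variant, peaks, n_null = 10000L,
                           seed = 1L, corrected = TRUE) {
  if (inherits(models, "cutnet_fit")) models <- list(models)
  scored <- score_variants(models, genome, variant, peaks,
                           corrected = corrected)
  obs <- scored$ips[[1L]]
  input_len <- models[[1L]]$config$input_len
  wins <- variant_windows(genome, variant$chrom[1L], variant$pos[1L],
                          variant$ref[1L], variant$alt[1L], input_len)
  # the same peak log-count distribution the observed score used
  peak_log_counts <- peak_count_distributions(models, genome, peaks,
                                              corrected)
  at <- input_len %/% 2L + 1L
  shuf <- dinuc_shuffle(wins$ref, n_null, seed)
  null_ips <- vapply(shuf, function(s) {
    s1 <- s; substr(s1, at, at) <- variant$ref[1L]
    s2 <- s; substr(s2, at, at) <- variant$alt[1L]
    lf <- js <- aq <- numeric(length(models))
    for (i in seq_along(models)) {
      fun <- prediction_fun(models[[i]], corrected)
      p1 <- predict_symmetrized(fun, s1)
      p2 <- predict_symmetrized(fun, s2)
      lf[i] <- p2$log_total - p1$log_total
      js[i] <- jsd_e(p1$prob, p2$prob) *
        if (sign(lf[i]) == 0) 0 else sign(lf[i])
      ec <- stats::ecdf(peak_log_counts[[i]])
      aq[i] <- max(ec(p1$log_total), ec(p2$log_total))
    }
    mean(abs(lf)) * abs(mean(js)) * mean(aq)
  }, numeric(1), USE.NAMES = FALSE)
  list(p = empirical_p(obs, null_ips),
       observed_ips = obs, null_ips = null_ips)
}

#' Enrichment of high-scoring variants among fine-mapped variants
#'
#' For every (score threshold t, PIP threshold p) pair:
#' `Observed = #{PIP > p and score > t}`; `Expected` is the background
#' rate of high scores among control variants (`PIP <= pip_null`)
#' multiplied by `#{PIP > p}`; `Enrichment = Observed / Expected`.
#'
#' @param scores numeric variant scores (e.g. IPS).
#' @param pips posterior inclusion probabilities, same length.
#' @param score_thresholds vector of score thresholds t.
#' @param pip_thresholds vector of PIP thresholds p.
#' @param pip_null controls are variants with PIP at or below this value.
#' @return data.frame over the threshold grid with observed, expected and
#'   enrichment columns.
#' @export
enrichment_curve <- function(scores, pips, score_thresholds,
                             pip_thresholds, pip_null = 0.01) {
  stopifnot(length(scores) == length(pips))
  ctrl <- pips <= pip_null
  if (!any(ctrl)) stop("no control variants at PIP <= ", pip_null)
  grid <- expand.grid(score_t = score_thresholds, pip_t = pip_thresholds)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    t <- grid$score_t[i]; p <- grid$pip_t[i]
    fm <- pips > p
    obs <- sum(fm & scores > t)
    bg_rate <- mean(scores[ctrl] > t)
    exp_ <- bg_rate * sum(fm)
    data.frame(score_t = t, pip_t = p, n_fine_mapped = sum(fm),
               observed = obs, expected = exp_,
               enrichment = if (exp_ > 0) obs / exp_ else NA_real_)
  })
  do.call(rbind, res)
}
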