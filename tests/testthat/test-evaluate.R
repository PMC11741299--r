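test_that("count metric is Pearson r on the log scale", {
  x <- c(10, 100, 1000, 5000)
  expect_equal(count_metric(x, x), 1)
  anti <- expm1(5 - log1p(x))
  expect_equal(count_metric(x, anti), -1, tolerance = 1e-12)
  set.seed(40)
  a <- rpois(50, 200); b <- rpois(50, 200)
  la <- log1p(a); lb <- log1p(b)
  hand <- sum((la - mean(la)) * (lb - mean(lb))) /
    sqrt(sum((la - mean(la))^2) * sum((lb - mean(lb))^2))
  expect_equal(count_metric(a, b), hand, tolerance = 1e-9)
})

test_that("profile JSD is the base-2 divergence on [0, 1], symmetric", {
  p <- c(0.2, 0.3, 0.5)
  expect_equal(profile_jsd(p, p), 0)
  expect_equal(profile_jsd(c(1, 0), c(0, 1)), 1)
  set.seed(41)
  for (i in 1:20) {
    a <- runif(30); a <- a / sum(a)
    b <- runif(30); b <- b / sum(b)
    expect_identical(profile_jsd(a, b), profile_jsd(b, a))
    # entropy-form oracle: H(m) - (H(a) + H(b)) / 2 with base-2 logs
    H <- function(v) -sum(ifelse(v > 0, v * log2(v), 0))
    m <- (a + b) / 2
    expect_equal(profile_jsd(a, b), H(m) - (H(a) + H(b)) / 2,
                 tolerance = 1e-9)
    expect_gte(profile_jsd(a, b), 0)
    expect_lte(profile_jsd(a, b), 1)
  }
})

test_that("JSD baselines order as expected on structured profiles", {
  sim <- small_sim()
  bl <- jsd_baselines(sim$track, sim$peaks, width = 500L, seed = 5L)
  # deep profiles: pseudoreplicates agree far better than shuffles
  expect_lt(mean(bl$pseudorep, na.rm = TRUE),
            mean(bl$shuffled, na.rm = TRUE))
  # identical regions make the mean baseline vanish
  g <- as_genome(c(chr1 = random_seq(6000L, 42L)))
  counts <- integer(6000L)
  counts[2000:2100] <- 5L
  counts[4000:4100] <- 5L
  tr <- structure(list(counts = list(chr1 = counts),
                       lengths = seq_lengths(g), dropped = 0L),
                  class = "cutnet_track")
  rg <- regions("chr1", c(1800L, 3800L), c(2300L, 4300L), summit = 250L)
  bl2 <- jsd_baselines(tr, rg, width = 500L, seed = 6L)
  expect_equal(bl2$mean_baseline, c(0, 0), tolerance = 1e-9)
})

test_that("bin labelling triggers each printed ambiguity rule", {
  g <- as_genome(c(chr1 = random_seq(10000L, 43L)))
  idr <- regions("chr1", 950L, 1450L, summit = 100L)   # summit at 1050
  overlap <- rbind(idr, regions("chr1", 3000L, 3400L))
  class(overlap) <- class(idr)
  bl <- regions("chr1", 5000L, 5100L)
  mapp <- regions("chr1", c(0L, 7060L), c(7000L, 10000L))
  bins <- label_bins(g, idr, overlap, bl, mapp, bin = 100L, flank = 100L)
  lab <- function(start) bins$label[bins$start == start]
  rsn <- function(start) bins$reason[bins$start == start]
  expect_equal(lab(1000L), "positive")          # fully inside 950..1150
  expect_equal(lab(900L), "ambiguous")          # 50% overlap with idr set
  expect_equal(rsn(900L), "idr_partial")
  expect_equal(lab(3000L), "ambiguous")
  expect_equal(rsn(3000L), "overlap_peak")
  expect_equal(lab(5000L), "ambiguous")
  expect_equal(rsn(5000L), "blacklist")
  expect_equal(lab(7000L), "ambiguous")         # 40/100 bp mappable
  expect_equal(rsn(7000L), "low_mappability")
  expect_equal(lab(8000L), "negative")
  # partition is complete and unique
  expect_equal(nrow(bins), 100L)
  expect_true(all(bins$label %in% c("positive", "negative", "ambiguous")))
  # without mappability the rule is skipped with a warning
  expect_warning(b2 <- label_bins(g, idr, overlap, bl, NULL), "mappability")
  expect_equal(b2$label[b2$start == 7000L], "negative")
})

test_that("AUROC / AUPRC match oracles and behave at the extremes", {
  y <- c(rep(1L, 20), rep(0L, 80))
  s <- c(runif(20, 2, 3), runif(80, 0, 1))
  expect_equal(auroc(y, s), 1)
  expect_equal(auprc(y, s), 1)
  set.seed(44)
  y2 <- rbinom(2000, 1, 0.3)
  s2 <- rnorm(2000)
  expect_lt(abs(auroc(y2, s2) - 0.5), 0.05)
  # AUPRC against a brute-force precision-at-recall-step oracle
  set.seed(45)
  for (i in 1:5) {
    y3 <- rbinom(200, 1, 0.2)
    s3 <- rnorm(200) + y3
    ord <- order(s3, decreasing = TRUE)
    yo <- y3[ord]
    prec <- cumsum(yo) / seq_along(yo)
    expect_equal(auprc(y3, s3), mean(prec[yo == 1]), tolerance = 1e-12)
    # AUROC equals the Mann-Whitney statistic
    u <- wilcox.test(s3[y3 == 1], s3[y3 == 0], exact = FALSE)$statistic
    expect_equal(auroc(y3, s3), unname(u) / (sum(y3) * sum(1 - y3)),
                 tolerance = 1e-9)
  }
})

test_that("genome-wide classification separates peaks from background", {
  b <- prop_fit_bundle()
  bins <- suppressWarnings(
    label_bins(b$ex$genome, b$ex$peaks, b$ex$peaks, NULL, NULL))
  res <- genomewide_classification(b$fit, b$ex$genome, bins,
                                   stride = 500L)
  expect_gt(res$auroc, 0.6)
  expect_gt(res$auprc, res$prevalence)
})
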