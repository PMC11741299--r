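test_that("fold specification enforces disjoint partitions", {
  expect_error(fold_spec(c("chr1", "chr2"), "chr2", "chr3"), "disjoint")
  folds <- make_folds(paste0("chr", 1:5), n_folds = 5L)
  expect_length(folds, 5L)
  for (f in folds) {
    expect_length(intersect(f$train, c(f$val, f$test)), 0L)
    expect_setequal(c(f$train, f$val, f$test), paste0("chr", 1:5))
  }
})

test_that("background filtering matches a brute-force threshold", {
  sim <- small_sim()
  cand <- tile_genome(sim$genome, 1114L, 1000L)
  neg <- gc_match_negatives(cand, sim$peaks, NULL, sim$genome,
                            multiplier = 2, seed = 4L)
  for (fr in c(0.8, 0.4)) {
    kept <- filter_background(neg, sim$track, sim$peaks, fr)
    thr <- quantile(region_counts(sim$track, sim$peaks, width = 1000L),
                    0.01, type = 7) * fr
    tot <- region_counts(sim$track, neg, width = 1000L)
    expect_equal(kept$start, neg$start[tot <= thr])
    expect_equal(attr(kept, "threshold"), as.numeric(thr))
  }
  none <- filter_background(neg, sim$track, sim$peaks, 1e-9)
  expect_equal(nrow(none), 0L)
})

test_that("jitter is clamped so summits stay inside the output window", {
  b <- prop_fit_bundle()
  fit <- b$fit
  expect_lte(fit$jitter, (fit$config$output_len - 1L) %/% 2L)
  # any jittered center keeps the summit within the output window
  off <- seq(-fit$jitter, fit$jitter)
  half_out <- fit$config$output_len %/% 2L
  expect_true(all(abs(off) <= half_out))
})

test_that("two-stage training is seeded-deterministic with frozen bias", {
  spec <- sim_spec(chrom_lengths = c(chr1 = 50000L, chr2 = 40000L,
                                     chr3 = 40000L),
                   n_peaks = 9L, n_decoys = 0L, depth = 1.5e5, seed = 33L)
  ex <- simulate_experiment(spec)
  fold <- fold_spec("chr1", "chr2", "chr3")
  cfg <- cutnet_config(filters = 8L, n_dilated = 4L, input_len = 414L,
                       output_len = 200L)
  bcfg <- bias_config(filters = 8L, input_len = 414L, output_len = 200L)
  cand <- tile_genome(ex$genome, 414L, 600L)
  neg <- gc_match_negatives(cand, ex$peaks, NULL, ex$genome,
                            multiplier = 2, seed = 1L)
  bf <- suppressWarnings(
    fit_bias(ex$genome, ex$track, ex$peaks, neg, fold, cfg = bcfg,
             max_epochs = 6L, seed = 2L))
  bias_par <- bf$model$par
  run <- function() fit_cutnet(ex$genome, ex$track, ex$peaks, neg, bf,
                               fold, cfg = cfg, max_epochs = 8L, seed = 3L)
  f1 <- run(); f2 <- run()
  expect_identical(f1$best_val_loss, f2$best_val_loss)
  expect_identical(f1$tf$par, f2$tf$par)
  expect_identical(f1$history, f2$history)
  # bias parameters bit-identical before and after residual training
  expect_identical(f1$bias$par, bias_par)
  # early stopping reports the minimum validation loss over epochs
  expect_equal(f1$best_val_loss, min(f1$history$loss))
  expect_equal(f1$best_epoch, which.min(f1$history$loss))
})

test_that("contamination check flags motif-trained models and passes clean ones", {
  b <- prop_fit_bundle()
  ex <- b$ex
  pwms <- lapply(default_motifs(), function(m) m$pwm)
  # the bias model was trained on filtered background: clean
  chk <- contamination_check(b$bias$model, ex$genome, b$ex$peaks, pwms,
                             n_regions = 8L, seed = 4L)
  expect_equal(chk$verdict, "PASS")
  # a model that detects the deep motif by construction (first-layer
  # filter = motif log-odds, identity dilated stack via the skips, heads
  # reading that channel) must be flagged
  cfg <- cutnet_config(filters = 4L, n_dilated = 2L, profile_width = 11L,
                       input_len = 1114L, output_len = 500L)
  det <- init_model(cfg, 0)
  det$par[] <- 0
  lay <- cutnet:::param_layout(cfg)
  off <- c(0L, cumsum(lay$size)); names(off) <- c(lay$name, "end")
  m_deep <- default_motifs()$deep
  W1 <- matrix(0, 4L, 4L * 21L)
  lo <- log(m_deep$pwm / 0.25)
  for (j in seq_len(ncol(lo))) W1[1L, (4L * (j + 3L)) + seq_len(4L)] <- lo[, j]
  det$par[off[["W1"]] + seq_len(lay$size[lay$name == "W1"])] <- as.numeric(W1)
  det$par[off[["Wp"]] + 1L] <- 1        # profile head reads channel 1
  det$par[off[["wc"]] + 1L] <- 1        # count head reads channel 1
  chk2 <- contamination_check(det, ex$genome, b$ex$peaks, pwms,
                              n_regions = 8L, seed = 4L)
  expect_equal(chk2$verdict, "FAIL")
  expect_gt(nrow(chk2$evidence), 0L)
  expect_warning(chk3 <- contamination_check(b$bias$model, ex$genome,
                                             b$ex$peaks, list(),
                                             n_regions = 2L),
                 "trivially")
  expect_equal(chk3$verdict, "PASS")
})

test_that("the fitted model predicts held-out peak counts", {
  b <- prop_fit_bundle()
  test_pk <- b$ex$peaks[b$ex$peaks$chrom %in% b$fold$test, ]
  pr <- predict(b$fit, b$ex$genome, test_pk, type = "corrected")
  obs <- region_counts(b$ex$track, test_pk, width = 500L)
  expect_gt(count_metric(obs, expm1(pr$log_total)), 0.0)
  # probabilities normalize
  expect_equal(colSums(pr$probs), rep(1, ncol(pr$probs)), tolerance = 1e-8)
  # combined and bias heads are also exposed
  prc <- predict(b$fit, b$ex$genome, test_pk, type = "combined")
  prb <- predict(b$fit, b$ex$genome, test_pk, type = "bias")
  expect_equal(prc$logits, pr$logits + prb$logits, tolerance = 1e-9)
})

test_that("fit methods (print, summary, coef, residuals, simulate) work", {
  b <- prop_fit_bundle()
  expect_output(print(b$fit), "bias-factorized")
  expect_output(print(summary(b$fit)), "epochs run")
  co <- coef(b$fit)
  expect_true(all(c("gamma", "lambda") %in% names(co)))
  test_pk <- b$ex$peaks[b$ex$peaks$chrom %in% b$fold$test, ][1:3, ]
  r <- residuals(b$fit, b$ex$genome, b$ex$track, test_pk)
  expect_length(r, 3L)
  sims <- simulate(b$fit, nsim = 2L, seed = 1L, genome = b$ex$genome,
                   regions = test_pk)
  expect_length(sims, 2L)
  expect_equal(dim(sims[[1]]), c(500L, 3L))
  pr <- predict(b$fit, b$ex$genome, test_pk)
  expect_equal(colSums(sims[[1]]), pmax(round(expm1(pr$log_total)), 0))
})

test_that("fit round-trips through its JSON checkpoint", {
  b <- prop_fit_bundle()
  path <- withr::local_tempfile(fileext = ".json")
  write_fit(b$fit, path)
  f2 <- read_fit(path)
  expect_identical(f2$tf$par, b$fit$tf$par)
  expect_identical(f2$bias$par, b$fit$bias$par)
  expect_equal(f2$gamma, b$fit$gamma)
  expect_identical(f2$fold$test, b$fit$fold$test)
  s <- get_seq(b$ex$genome, "chr4", 10000L, 11114L)
  expect_identical(corrected_prediction(f2, s), corrected_prediction(b$fit, s))
})
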