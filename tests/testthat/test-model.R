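test_that("receptive field matches the printed architectures", {
  expect_identical(receptive_field(paper_config()), 1041L)
  expect_identical(receptive_field(bias_config()), 81L)
  expect_identical(
    receptive_field(cutnet_config(filters = 4L, conv_width = 1L,
                                  n_dilated = 0L, profile_width = 1L,
                                  input_len = 20L, output_len = 10L)), 1L)
})

test_that("receptive field equals brute-force gradient support width", {
  # profile head of width 1 so one output logit sees exactly the
  # bottleneck receptive field
  cfg <- cutnet_config(filters = 6L, conv_width = 7L, n_dilated = 2L,
                       profile_width = 1L, input_len = 80L,
                       output_len = 20L)
  m <- tiny_model(3L, cfg)
  rf <- receptive_field(cfg)
  x <- one_hot(random_seq(cfg$input_len, 4L))
  w <- numeric(cfg$output_len); w[10] <- 1
  g <- cutnet:::.cn_input_grad(m$par, unclass(cfg), x, 1L, w)
  support <- which(colSums(abs(g)) > 0)
  expect_equal(max(support) - min(support) + 1L, rf)
})

test_that("mnll matches an independent multinomial log-PMF", {
  expect_equal(mnll_loss(c(1, 1), c(0.5, 0.5)), -log(0.5), tolerance = 1e-12)
  expect_equal(mnll_loss(c(5, 0), c(1, 0)), 0)
  set.seed(7)
  for (i in 1:100) {
    k <- rpois(20, 2)
    p <- runif(20); p <- p / sum(p)
    expect_equal(mnll_loss(k, p), -dmultinom(k, prob = p, log = TRUE),
                 tolerance = 1e-9)
  }
})

test_that("mnll is minimized by the empirical distribution", {
  set.seed(8)
  for (i in 1:20) {
    k <- rpois(15, 3)
    if (sum(k) == 0) next
    p <- runif(15); p <- p / sum(p)
    expect_gte(mnll_loss(k, p), mnll_loss(k, k / sum(k)) - 1e-9)
  }
})

test_that("count loss and combined loss follow the printed formulas", {
  expect_equal(mse_log_counts(10, 10), 0)
  expect_equal(mse_log_counts(exp(1) - 1, 0), 1, tolerance = 1e-12)
  expect_equal(default_lambda(rep(100, 11)), 10)
  set.seed(9)
  k <- rpois(30, 4); p <- runif(30); p <- p / sum(p)
  n_pred <- 90
  lam <- 0.5
  expect_equal(combined_loss(k, p, n_pred, lam),
               mnll_loss(k, p) + lam * (log1p(sum(k)) - log1p(n_pred))^2,
               tolerance = 1e-12)
  expect_equal(combined_loss(k, p, n_pred, 0), mnll_loss(k, p))
})

test_that("gamma estimation follows its closed form", {
  expect_equal(estimate_gamma(log1p(c(10, 20)), c(10, 20)), 1)
  expect_equal(estimate_gamma(log1p(c(50, 70)) - 1, c(50, 70)), exp(-1),
               tolerance = 1e-12)
  set.seed(10)
  b <- runif(40, 2, 8); o <- rpois(40, 100)
  expect_equal(estimate_gamma(b, o), exp(mean(b - log1p(o))),
               tolerance = 1e-12)
})

test_that("logit addition realizes the normalized probability product", {
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(100); b <- rnorm(100)
    prod <- softmax(a) * softmax(b)
    expect_equal(softmax(a + b), prod / sum(prod), tolerance = 1e-9)
  }
  # uniform bias probabilities leave the residual profile unchanged
  tf <- list(logits = rnorm(50), log_total = 3)
  bias <- list(logits = rep(0.7, 50), log_total = 2)
  comb <- combine_predictions(tf, bias, gamma = 0.5)
  expect_equal(softmax(comb$combined$logits), softmax(tf$logits),
               tolerance = 1e-12)
  expect_equal(combine_predictions(tf, bias, 0)$combined$log_total,
               tf$log_total)
  lse <- combine_predictions(tf, bias, 0.5, count_mode = "logsumexp")
  expect_equal(lse$combined$log_total, log(exp(3) + 0.5 * exp(2)))
})

test_that("forward pass is deterministic, validated, and normalizes", {
  cfg <- tiny_cfg()
  m <- tiny_model(2L)
  x <- one_hot(random_seq(cfg$input_len, 5L))
  f1 <- forward(m, x); f2 <- forward(m, x)
  expect_identical(f1, f2)
  expect_length(f1$logits, cfg$output_len)
  expect_equal(sum(softmax(f1$logits)), 1, tolerance = 1e-9)
  expect_error(forward(m, x[, 1:100]), "4 x")
  # zeroed network: uniform profile, count head returns its bias term
  m0 <- m; m0$par[] <- 0; m0$par[length(m0$par)] <- 2.5
  f0 <- forward(m0, x)
  expect_equal(unname(f0$logits), rep(0, cfg$output_len))
  expect_equal(f0$log_total, 2.5)
})

test_that("analytic gradients match finite differences", {
  cfg <- cutnet_config(filters = 5L, conv_width = 5L, n_dilated = 2L,
                       profile_width = 7L, input_len = 70L,
                       output_len = 24L)
  m <- tiny_model(6L, cfg, bias = 0.3)
  x <- one_hot(random_seq(cfg$input_len, 7L))
  set.seed(12); k <- rpois(cfg$output_len, 3)
  g <- cutnet:::.cn_loss_grad_batch(m$par, unclass(cfg), list(x), list(k),
                                    0.8, NULL, numeric(0), 0, 0L, TRUE)$grad
  loss_at <- function(p)
    cutnet:::.cn_loss_grad_batch(p, unclass(cfg), list(x), list(k),
                                 0.8, NULL, numeric(0), 0, 0L, FALSE)$loss
  set.seed(13); idx <- sample(length(m$par), 15)
  eps <- 1e-6
  for (i in idx) {
    p1 <- m$par; p1[i] <- p1[i] + eps
    p2 <- m$par; p2[i] <- p2[i] - eps
    fd <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
    expect_equal(g[i], fd, tolerance = 1e-4)
  }
})

test_that("checkpoints round-trip and validate their config hash", {
  m <- tiny_model(4L)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m2$par, m$par)
  expect_identical(unclass(m2$config), unclass(m$config))
  bad <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad$config$filters <- 99L
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, path2, digits = NA, auto_unbox = TRUE)
  expect_error(read_model(path2), "hash")
})
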