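#' Architecture configuration
#'
#' Defines the convolutional architecture shared by the residual (TF)
#' submodel and the bias submodel: an initial convolution, a stack of
#' dilated convolutions whose dilation rate doubles at each layer starting
#' at `dilation_base`, a transposed-convolution profile head of width
#' `profile_width` center-cropped to `output_len`, and a global average
#' pooling + dense count head predicting `log(1 + total counts)`.
#'
#' The default is a desk-scale configuration (32 filters, 6 dilated
#' layers — a 273 bp receptive field that covers the accessibility bump
#' at desk-scale peak widths — 1114 bp input, 500 bp output). [paper_config()] gives the
#' full-scale residual architecture (512 filters, 8 dilated layers,
#' 2114/1000) and [bias_config()] the background bias architecture.
#'
#' @param filters number of filters in every convolution.
#' @param conv_width width of the initial convolution (bp).
#' @param n_dilated number of dilated convolution layers.
#' @param dilated_width width of each dilated convolution (bp).
#' @param dilation_base dilation rate of the first dilated layer; doubles
#'   at each subsequent layer.
#' @param profile_width width of the transposed-convolution profile head.
#' @param input_len,output_len input window and predicted profile lengths.
#' @param count_mode how factorized count heads combine: `"additive"`
#'   (combined log-count head = tf head + gamma * bias head, the
#'   combination as printed) or `"logsumexp"`
#'   (`log(exp(tf) + gamma * exp(bias))`, the linear-scale alternative).
#' @return an object of class `cutnet_config`.
#' @export
cutnet_config <- function(filters = 32L, conv_width = 21L, n_dilated = 6L,
                          dilated_width = 3L, dilation_base = 2L,
                          profile_width = 75L, input_len = 1114L,
                          output_len = 500L,
                          count_mode = c("additive", "logsumexp")) {
  cfg <- list(filters = as.integer(filters),
              conv_width = as.integer(conv_width),
              n_dilated = as.integer(n_dilated),
              dilated_width = as.integer(dilated_width),
              dilation_base = as.integer(dilation_base),
              profile_width = as.integer(profile_width),
              input_len = as.integer(input_len),
              output_len = as.integer(output_len),
              count_mode = match.arg(count_mode))
  class(cfg) <- "cutnet_config"
  if (cfg$dilated_width %% 2L == 0L)
    stop("dilated_width must be odd (symmetric skip-connection cropping)")
  rf <- receptive_field(cfg)
  if (cfg$input_len < cfg$output_len + rf - 1L)
    stop(sprintf("input_len (%d) must be at least output_len + receptive field - 1 = %d",
                 cfg$input_len, cfg$output_len + rf - 1L))
  cfg
}

#' Full-scale residual architecture (512 filters, 8 dilated layers)
#' @inheritParams cutnet_config
#' @return a `cutnet_config`.
#' @export
paper_config <- function(count_mode = "additive") {
  cutnet_config(filters = 512L, n_dilated = 8L, input_len = 2114L,
                output_len = 1000L, count_mode = count_mode)
}

#' Bias submodel architecture (shallow, 4 dilated layers)
#'
#' The full-scale bias submodel uses 128 filters and 4 dilated layers
#' (81 bp receptive field); the desk-scale default trims the filter count.
#'
#' @param filters number of filters.
#' @param input_len,output_len window lengths.
#' @inheritParams cutnet_config
#' @return a `cutnet_config`.
#' @export
bias_config <- function(filters = 32L, input_len = 1114L, output_len = 500L,
                        count_mode = "additive") {
  cutnet_config(filters = filters, n_dilated = 4L, input_len = input_len,
                output_len = output_len, count_mode = count_mode)
}

#' @export
print.cutnet_config <- function(x, ...) {
  cat(sprintf(paste0("cutnet_config: %d filters, first conv %d bp, ",
                     "%d dilated layers (width %d, rates %s)\n",
                     "  input %d bp -> output %d bp, receptive field %d bp, ",
                     "count_mode=%s\n"),
              x$filters, x$conv_width, x$n_dilated, x$dilated_width,
              paste(dilation_rates(x), collapse = ","),
              x$input_len, x$output_len, receptive_field(x), x$count_mode))
  invisible(x)
}

dilation_rates <- function(cfg) {
  if (cfg$n_dilated == 0L) return(integer(0))
  as.integer(cfg$dilation_base * 2^(seq_len(cfg$n_dilated) - 1L))
}

#' Effective receptive field of an architecture
#'
#' `conv_width + sum_l (dilated_width - 1) * rate_l` where the dilation
#' rate doubles at each layer starting at `dilation_base`. The full-scale
#' residual architecture (width-21 first conv, 8 dilated width-3 layers,
#' rates 2,4,...,256) has a receptive field of 1041 bp; the 4-layer bias
#' architecture has 81 bp.
#'
#' @param cfg a `cutnet_config`.
#' @return receptive field in bp.
#' @export
receptive_field <- function(cfg) {
  as.integer(cfg$conv_width + sum((cfg$dilated_width - 1L) * dilation_rates(cfg)))
}

#' Initialize a model with random weights
#'
#' He-scaled Gaussian weights for the convolutions, zero biases. The two
#' output heads are scaled down by `head_scale` so the initial profile is
#' near-uniform regardless of depth (skip connections let activation
#' variance grow with depth); the count head bias starts at
#' `count_bias_init` (typically `log1p(mean total)` of the training data)
#' so early training is well-scaled. Uses the session RNG: seed upstream
#' for reproducibility.
#'
#' @param cfg a `cutnet_config`.
#' @param count_bias_init initial value for the count-head bias.
#' @param head_scale multiplier on the initial profile/count head weights.
#' @return an object of class `cutnet_model`.
#' @export
init_model <- function(cfg, count_bias_init = 0, head_scale = 0.01) {
  lay <- param_layout(cfg)
  par <- numeric(sum(lay$size))
  off <- 0L
  for (i in seq_len(nrow(lay))) {
    n <- lay$size[i]
    if (lay$kind[i] == "weight") {
      sc <- if (lay$name[i] %in% c("Wp", "wc")) head_scale else 1
      par[off + seq_len(n)] <- stats::rnorm(n, sd = sc * sqrt(2 / lay$fan_in[i]))
    }
    off <- off + n
  }
  par[length(par)] <- count_bias_init
  structure(list(par = par, config = cfg), class = "cutnet_model")
}

# parameter blocks in flat-vector order; mirrors the C++ layout
param_layout <- function(cfg) {
  F <- cfg$filters; wd <- cfg$dilated_width
  blocks <- list(c("W1", "weight", F * 4L * cfg$conv_width, 4L * cfg$conv_width),
                 c("b1", "bias", F, 0))
  for (l in seq_len(cfg$n_dilated)) {
    blocks <- c(blocks, list(c(paste0("Wd", l), "weight", F * F * wd, F * wd),
                             c(paste0("bd", l), "bias", F, 0)))
  }
  blocks <- c(blocks, list(
    c("Wp", "weight", F * cfg$profile_width, F),
    c("bp", "bias", 1, 0),
    c("wc", "weight", F, F),
    c("bc", "bias", 1, 0)))
  data.frame(name = vapply(blocks, `[[`, "", 1L),
             kind = vapply(blocks, `[[`, "", 2L),
             size = as.integer(vapply(blocks, `[[`, "", 3L)),
             fan_in = as.numeric(vapply(blocks, `[[`, "", 4L)))
}

#' @export
print.cutnet_model <- function(x, ...) {
  cat("cutnet_model:", length(x$par), "parameters\n")
  print(x$config)
  invisible(x)
}

#' Forward pass of a single submodel
#'
#' @param model a `cutnet_model`.
#' @param x either a 4 x input_len one-hot matrix, a list of such
#'   matrices, or a character vector of sequences.
#' @return for a single input, a list with `logits` (length output_len)
#'   and `log_total` (predicted `log(1 + total counts)`); for several
#'   inputs, `logits` is an output_len x n matrix and `log_total` a
#'   vector.
#' @export
forward <- function(model, x) {
  xs <- normalize_inputs(x, model$config$input_len)
  if (length(xs) == 1L) {
    r <- .cn_forward(model$par, unclass(model$config), xs[[1L]])
    list(logits = as.numeric(r$logits), log_total = r$log_total)
  } else {
    .cn_forward_batch(model$par, unclass(model$config), xs)
  }
}

normalize_inputs <- function(x, input_len) {
  if (is.character(x)) x <- lapply(x, one_hot)
  if (is.matrix(x)) x <- list(x)
  for (m in x) {
    if (nrow(m) != 4L || ncol(m) != input_len)
      stop("each input must be 4 x ", input_len)
  }
  x
}

#' Multinomial negative log-likelihood of a profile
#'
#' Minus the natural-log multinomial PMF of the observed counts under the
#' predicted probability vector.
#'
#' @param k_obs non-negative observed count vector.
#' @param p predicted probability vector (same length, sums to 1).
#' @return scalar loss (natural log).
#' @export
mnll_loss <- function(k_obs, p) {
  stopifnot(length(k_obs) == length(p), all(k_obs >= 0), all(p >= 0))
  n <- sum(k_obs)
  used <- k_obs > 0
  if (any(p[used] == 0)) return(Inf)
  -(lgamma(n + 1) - sum(lgamma(k_obs + 1)) + sum(k_obs[used] * log(p[used])))
}

#' Squared error between observed and predicted totals on the log1p scale
#'
#' @param n_obs,n_pred observed and predicted total counts (linear scale).
#' @return `(log(1 + n_obs) - log(1 + n_pred))^2`.
#' @export
mse_log_counts <- function(n_obs, n_pred) {
  (log1p(n_obs) - log1p(n_pred))^2
}

#' Combined profile + count training loss
#'
#' `mnll + lambda * mse`, with `lambda` conventionally set to one tenth of
#' the median total counts over the validation regions (see
#' [default_lambda()]).
#'
#' @param k_obs observed counts.
#' @param p predicted probabilities.
#' @param n_pred predicted total counts (linear scale).
#' @param lambda count-loss weight.
#' @return scalar loss.
#' @export
combined_loss <- function(k_obs, p, n_pred, lambda) {
  mnll_loss(k_obs, p) + lambda * mse_log_counts(sum(k_obs), n_pred)
}

#' Count-loss weight from validation totals
#'
#' @param val_totals total counts over validation regions.
#' @return `median(val_totals) / 10`.
#' @export
default_lambda <- function(val_totals) stats::median(val_totals) / 10

#' Bias count scaling factor
#'
#' `gamma = exp(mean(log(n_bias + 1) - log(n_obs + 1)))` over the training
#' and validation regions; it accounts for the difference between the bias
#' submodel's total coverage scale and the observed coverage. Since the
#' count head predicts `log(1 + n)`, the head output is used directly for
#' the bias term.
#'
#' @param bias_log_totals bias count-head outputs, i.e. `log(1 + n_bias)`.
#' @param obs_totals observed total counts (linear scale).
#' @return scalar gamma.
#' @export
estimate_gamma <- function(bias_log_totals, obs_totals) {
  stopifnot(length(bias_log_totals) == length(obs_totals))
  exp(mean(bias_log_totals - log1p(obs_totals)))
}

#' Combine residual and bias submodel outputs
#'
#' Profile: logits add, so the softmax of the sum realizes the normalized
#' elementwise product of the two probability vectors. Counts: by default
#' the log-count heads combine additively
#' (`n_pred = n_tf + gamma * n_bias`, as printed); with
#' `count_mode = "logsumexp"` the combination is
#' `log(exp(n_tf) + gamma * exp(n_bias))`.
#'
#' @param tf_part,bias_part lists with `logits` and `log_total` (outputs
#'   of [forward()]).
#' @param gamma bias count scaling factor.
#' @param count_mode `"additive"` or `"logsumexp"`.
#' @return list with `tf`, `bias`, `gamma` and `combined` (logits,
#'   log_total).
#' @export
combine_predictions <- function(tf_part, bias_part, gamma,
                                count_mode = c("additive", "logsumexp")) {
  count_mode <- match.arg(count_mode)
  logits <- tf_part$logits + bias_part$logits
  log_total <- if (count_mode == "additive") {
    tf_part$log_total + gamma * bias_part$log_total
  } else {
    log(exp(tf_part$log_total) + gamma * exp(bias_part$log_total))
  }
  list(tf = tf_part, bias = bias_part, gamma = gamma,
       combined = list(logits = logits, log_total = log_total))
}

#' Probabilities from logits
#' @param logits numeric vector or matrix (columns are profiles).
#' @return softmax along each profile.
#' @export
softmax <- function(logits) {
  if (is.matrix(logits)) return(apply(logits, 2L, softmax))
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are JSON files holding the architecture config, the flat
#' parameter vector at full precision, and a config hash that is validated
#' on load.
#'
#' @param model a `cutnet_model`.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  cfg <- unclass(model$config)
  # parameters serialized at 17 significant digits: lossless for doubles
  obj <- list(config = cfg,
              config_hash = config_hash(cfg),
              par = sprintf("%.17g", model$par))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @return `read_model()` returns a `cutnet_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  cfg$count_mode <- as.character(cfg$count_mode)
  for (f in setdiff(names(cfg), "count_mode")) cfg[[f]] <- as.integer(cfg[[f]])
  class(cfg) <- "cutnet_config"
  if (!identical(config_hash(unclass(cfg)), obj$config_hash))
    stop("checkpoint config hash mismatch")
  if (length(obj$par) != .cn_n_params(unclass(cfg)))
    stop("checkpoint parameter count does not match its config")
  structure(list(par = as.numeric(obj$par), config = cfg),
            class = "cutnet_model")
}

config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(v, collapse = ","), ""),
             sep = "=", collapse = ";")
  # small deterministic polynomial hash; enough to catch config mix-ups
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
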