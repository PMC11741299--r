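#' Methods for fitted bias-factorized models
#'
#' A `cutnet_fit` bundles the frozen bias submodel, the trained residual
#' (TF) submodel, the count scaling factor gamma and training metadata.
#' `predict()` returns per-region profile logits and log totals for the
#' bias-corrected residual model (default), the combined factorized
#' model, or the bias submodel alone.
#'
#' @param object a `cutnet_fit`.
#' @param genome a `cutnet_genome`.
#' @param regions regions to predict (centered on summits).
#' @param type `"corrected"`, `"combined"` or `"bias"`.
#' @param ... unused.
#' @return list with `logits` (output_len x n matrix), `log_total`
#'   (length n; predicted log(1+total)), and `probs` (softmax of logits).
#' @export
predict.cutnet_fit <- function(object, genome, regions,
                               type = c("corrected", "combined", "bias"),
                               ...) {
  type <- match.arg(type)
  cfg <- object$config
  ctr <- region_center(regions)
  half <- cfg$input_len %/% 2L
  Xs <- lapply(seq_len(nrow(regions)), function(i) {
    one_hot(get_seq(genome, regions$chrom[i], ctr[i] - half,
                    ctr[i] - half + cfg$input_len))
  })
  tf <- .cn_forward_batch(object$tf$par, unclass(cfg), Xs)
  out <- switch(type,
    corrected = tf,
    bias = .cn_forward_batch(object$bias$par,
                             unclass(object$bias$config), Xs),
    combined = {
      b <- .cn_forward_batch(object$bias$par,
                             unclass(object$bias$config), Xs)
      lt <- if (cfg$count_mode == "additive")
        tf$log_total + object$gamma * b$log_total
      else log(exp(tf$log_total) + object$gamma * exp(b$log_total))
      list(logits = tf$logits + b$logits, log_total = lt)
    })
  out$logits <- matrix(out$logits, nrow = cfg$output_len)
  out$probs <- apply(out$logits, 2L, softmax)
  out$log_total <- as.numeric(out$log_total)
  out
}

#' Bias-corrected prediction for a single sequence
#'
#' Disconnects the bias submodel and returns the residual submodel's
#' profile and counts — the bias-corrected prediction.
#'
#' @param fit a `cutnet_fit`.
#' @param seq input sequence (length input_len) or one-hot matrix.
#' @return list with `logits` and `log_total`.
#' @export
corrected_prediction <- function(fit, seq) {
  stopifnot(inherits(fit, "cutnet_fit"))
  forward(fit$tf, seq)
}

#' @export
print.cutnet_fit <- function(x, ...) {
  cat(sprintf(paste0("cutnet_fit (bias-factorized accessibility model)\n",
                     "  gamma %.4f, lambda %.3f, best epoch %d ",
                     "(val loss %.4f)\n  fold: train %s | val %s | test %s\n"),
              x$gamma, x$lambda, x$best_epoch, x$best_val_loss,
              paste(x$fold$train, collapse = ","),
              paste(x$fold$val, collapse = ","),
              paste(x$fold$test, collapse = ",")))
  print(x$config)
  invisible(x)
}

#' @export
summary.cutnet_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.cutnet_fit")
}

#' @export
print.summary.cutnet_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  h <- f$history
  cat(sprintf("  epochs run %d; final train loss %.4f; min val loss %.4f\n",
              nrow(h), h$train_loss[nrow(h)], min(h$loss)))
  cat(sprintf("  training peaks %d, negatives %d, jitter +/-%d bp\n",
              nrow(f$peaks), nrow(f$negatives), f$jitter))
  invisible(x)
}

#' @export
coef.cutnet_fit <- function(object, ...) {
  c(gamma = object$gamma, lambda = object$lambda,
    n_par_residual = length(object$tf$par),
    n_par_bias = length(object$bias$par))
}

#' @export
plot.cutnet_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "validation loss",
                 main = "cutnet training history", ...)
  graphics::lines(h$epoch, h$train_loss, lty = 2)
  graphics::abline(v = x$best_epoch, col = "grey60", lty = 3)
  graphics::legend("topright", c("validation", "train"), lty = c(1, 2),
                   pch = c(16, NA), bty = "n")
  invisible(x)
}

#' @export
plot.cutnet_footprint <- function(x, ...) {
  graphics::plot(seq_along(x$M), x$M, type = "l",
                 xlab = "position in output window", ylab = "M",
                 main = sprintf("marginal footprint: %s", x$motif), ...)
  graphics::abline(v = c(x$rs, x$ls), col = "grey60", lty = 3)
  invisible(x)
}

#' Simulate read counts from a fitted model
#'
#' Draws multinomial cut-site counts for each region from the predicted
#' profile, with totals equal to the predicted total counts.
#'
#' @param object a `cutnet_fit`.
#' @param nsim number of draws per region.
#' @param seed RNG seed.
#' @param genome a `cutnet_genome`.
#' @param regions regions to simulate.
#' @param type prediction head to simulate from.
#' @param ... unused.
#' @return list (length nsim) of output_len x n count matrices.
#' @export
simulate.cutnet_fit <- function(object, nsim = 1L, seed = NULL, genome,
                                regions, type = "corrected", ...) {
  pr <- predict(object, genome, regions, type = type)
  totals <- pmax(round(expm1(pr$log_total)), 0)
  with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      vapply(seq_len(ncol(pr$probs)), function(i) {
        as.vector(stats::rmultinom(1L, totals[i], pr$probs[, i]))
      }, numeric(nrow(pr$probs)))
    })
  })
}

#' Residuals of predicted vs observed log totals
#'
#' @param object a `cutnet_fit`.
#' @param genome a `cutnet_genome`.
#' @param track a `cutnet_track` of observed coverage.
#' @param regions regions to evaluate.
#' @param type prediction head.
#' @param ... unused.
#' @return numeric vector: observed log1p totals minus predicted.
#' @export
residuals.cutnet_fit <- function(object, genome, track, regions,
                                 type = "corrected", ...) {
  pr <- predict(object, genome, regions, type = type)
  obs <- region_counts(track, regions, width = object$config$output_len)
  log1p(obs) - pr$log_total
}
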