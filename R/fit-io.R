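#' Save / load a fitted bias-factorized model
#'
#' The checkpoint is a JSON file bundling both submodels (architecture
#' configs and full-precision parameter vectors), gamma, lambda and the
#' fold; config hashes are validated on load.
#'
#' @param fit a `cutnet_fit`.
#' @param path output path.
#' @export
write_fit <- function(fit, path) {
  obj <- list(
    tf = list(config = unclass(fit$tf$config),
              config_hash = config_hash(unclass(fit$tf$config)),
              par = sprintf("%.17g", fit$tf$par)),
    bias = list(config = unclass(fit$bias$config),
                config_hash = config_hash(unclass(fit$bias$config)),
                par = sprintf("%.17g", fit$bias$par)),
    gamma = fit$gamma, lambda = fit$lambda,
    jitter = fit$jitter, best_epoch = fit$best_epoch,
    best_val_loss = fit$best_val_loss,
    fold = unclass(fit$fold))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fit
#' @return `read_fit()` returns a `cutnet_fit`.
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk_model <- function(m) {
    cfg <- m$config
    cfg$count_mode <- as.character(cfg$count_mode)
    for (f in setdiff(names(cfg), "count_mode")) cfg[[f]] <- as.integer(cfg[[f]])
    class(cfg) <- "cutnet_config"
    if (!identical(config_hash(unclass(cfg)), m$config_hash))
      stop("checkpoint config hash mismatch")
    structure(list(par = as.numeric(m$par), config = cfg),
              class = "cutnet_model")
  }
  tf <- mk_model(obj$tf)
  bias <- mk_model(obj$bias)
  fold <- fold_spec(as.character(obj$fold$train),
                    as.character(obj$fold$val),
                    as.character(obj$fold$test))
  structure(list(tf = tf, bias = bias, gamma = obj$gamma,
                 lambda = obj$lambda, config = tf$config, fold = fold,
                 history = data.frame(), best_epoch = obj$best_epoch,
                 best_val_loss = obj$best_val_loss,
                 peaks = NULL, negatives = NULL, jitter = obj$jitter,
                 seed = NA_integer_),
            class = "cutnet_fit")
}
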