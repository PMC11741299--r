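#' Chromosome fold specification
#'
#' Disjoint train / validation / test chromosome partitions. Training
#' functions subset their inputs by these lists and never touch test
#' chromosomes.
#'
#' @param train,val,test character vectors of chromosome names.
#' @return an object of class `cutnet_fold`.
#' @export
fold_spec <- function(train, val, test = character(0)) {
  all <- c(train, val, test)
  if (anyDuplicated(all))
    stop("fold partitions must be disjoint; duplicated: ",
         paste(unique(all[duplicated(all)]), collapse = ", "))
  structure(list(train = train, val = val, test = test),
            class = "cutnet_fold")
}

#' Rotating chromosome folds for cross-validation
#'
#' Fold i holds out chromosome i (mod n) for testing and the next one for
#' validation, training on the rest.
#'
#' @param chroms chromosome names.
#' @param n_folds number of folds.
#' @return list of `cutnet_fold`.
#' @export
make_folds <- function(chroms, n_folds = 5L) {
  stopifnot(length(chroms) >= 3L)
  lapply(seq_len(n_folds), function(i) {
    ti <- ((i - 1L) %% length(chroms)) + 1L
    vi <- (ti %% length(chroms)) + 1L
    fold_spec(train = chroms[-c(ti, vi)], val = chroms[vi],
              test = chroms[ti])
  })
}

subset_fold <- function(rg, chroms) rg[rg$chrom %in% chroms, , drop = FALSE]

#' Filter background regions for bias-model training
#'
#' Keeps negatives whose total counts in a `count_width` window are at or
#' below `quantile(peak totals, 0.01) * fraction`.
#'
#' @param negatives candidate background regions.
#' @param track a `cutnet_track`.
#' @param peaks peak regions (define the count threshold).
#' @param fraction multiplier < 1 applied to the 0.01 peak-count quantile.
#' @param count_width counting window (bp).
#' @return filtered regions; attribute `threshold` records the cutoff.
#' @export
filter_background <- function(negatives, track, peaks, fraction,
                              count_width = 1000L) {
  q01 <- stats::quantile(region_counts(track, peaks, width = count_width),
                         0.01, type = 7)
  thr <- as.numeric(q01) * fraction
  tot <- region_counts(track, negatives, width = count_width)
  out <- negatives[tot <= thr, , drop = FALSE]
  attr(out, "threshold") <- thr
  out
}

# one training example: one-hot input window and observed count window,
# both centered on `center` (+ jitter offset). With flip = TRUE the
# example is presented as its reverse complement: the one-hot matrix is
# reverse-complemented and the counts are taken from the window shifted
# +1 bp and reversed — cuts sit between bases, so the mirror of cut
# position p is p+1 on the reverse strand (the same off-by-one the
# strand-shift alignment corrects).
make_example <- function(genome, track, chrom, center, input_len,
                         output_len, flip = FALSE) {
  hi <- input_len %/% 2L
  ho <- output_len %/% 2L
  X <- one_hot(get_seq(genome, chrom, center - hi, center - hi + input_len))
  if (flip) {
    X <- X[4:1, ncol(X):1]
    k <- rev(track_slice(track, chrom, center - ho + 1L,
                         center - ho + 1L + output_len))
  } else {
    k <- track_slice(track, chrom, center - ho, center - ho + output_len)
  }
  list(X = X, k = k)
}

adam_new <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(par, grad, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0, lr_scale = 1) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mh <- st$m / (1 - beta1^st$t)
  vh <- st$v / (1 - beta2^st$t)
  # decoupled (AdamW-style) weight decay; lr_scale allows per-block rates
  list(par = par - (lr * lr_scale) * (mh / (sqrt(vh) + eps) +
                                        weight_decay * par),
       state = st)
}

# per-parameter learning-rate scale: the count head (wc, bc) sits behind
# global average pooling, which shrinks its effective gradient by the
# bottleneck length; a higher rate lets it reach its working magnitude in
# a desk-scale step budget
count_head_lr_scale <- function(cfg, mult) {
  lay <- param_layout(cfg)
  rep(ifelse(lay$name %in% c("wc", "bc"), mult, 1), lay$size)
}

# Minibatch training with per-epoch peak re-jittering, early stopping on
# validation combined loss (patience epochs, best-weights restore).
# items: data.frame(chrom, center, jitter); bias_model optional (frozen).
train_loop <- function(par, cfg, genome, track, items, val_items, lambda,
                       bias_model = NULL, gamma = 0,
                       jitter = 0L, lr = 1e-3, patience = 5L,
                       max_epochs = 100L, batch_size = 16L, seed = 1L,
                       augment_rc = FALSE, passes_per_epoch = 1L,
                       weight_decay = 0, dropout = 0, head_lr_mult = 1,
                       verbose = FALSE) {
  cfg_l <- unclass(cfg)
  count_mode <- if (cfg$count_mode == "additive") 0L else 1L
  bias_l <- if (!is.null(bias_model)) unclass(bias_model$config) else NULL
  eval_items <- function(it, centers, flips = NULL) {
    n <- nrow(it)
    Xs <- vector("list", n); ks <- vector("list", n)
    for (i in seq_len(n)) {
      ex <- make_example(genome, track, it$chrom[i], centers[i],
                         cfg$input_len, cfg$output_len,
                         flip = !is.null(flips) && flips[i])
      Xs[[i]] <- ex$X; ks[[i]] <- ex$k
    }
    list(Xs = Xs, ks = ks)
  }
  bias_outputs <- function(Xs) {
    if (is.null(bias_model)) return(NULL)
    b <- .cn_forward_batch(bias_model$par, bias_l, Xs)
    list(logits = lapply(seq_along(Xs), function(i) b$logits[, i]),
         totals = b$log_total)
  }
  val_dat <- eval_items(val_items, val_items$center)
  val_bias <- bias_outputs(val_dat$Xs)
  val_loss <- function(p) {
    r <- .cn_loss_grad_batch(p, cfg_l, val_dat$Xs, val_dat$ks, lambda,
                             val_bias$logits,
                             if (is.null(val_bias)) numeric(0) else val_bias$totals,
                             gamma, count_mode, FALSE)
    c(loss = r$loss / r$n, mnll = r$mnll / r$n, mse = r$mse / r$n)
  }
  st <- adam_new(length(par))
  lr_scale <- count_head_lr_scale(cfg, head_lr_mult)
  best <- list(par = par, loss = Inf, epoch = 0L)
  hist <- list()
  bad <- 0L
  with_seed(seed, {
    base_items <- items
    for (epoch in seq_len(max_epochs)) {
      # an epoch makes `passes_per_epoch` passes over the data, each with
      # independent jitter offsets and orientations
      items <- do.call(rbind, rep(list(base_items), passes_per_epoch))
      offs <- ifelse(items$jitter,
                     sample.int(2L * jitter + 1L, nrow(items),
                                replace = TRUE) - jitter - 1L, 0L)
      flips <- if (augment_rc) stats::runif(nrow(items)) < 0.5
               else rep(FALSE, nrow(items))
      ord <- sample.int(nrow(items))
      tr_loss <- 0; tr_n <- 0L
      for (b0 in seq(1L, length(ord), by = batch_size)) {
        sel <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
        dat <- eval_items(items[sel, , drop = FALSE],
                          items$center[sel] + offs[sel], flips[sel])
        bo <- bias_outputs(dat$Xs)
        r <- .cn_loss_grad_batch(par, cfg_l, dat$Xs, dat$ks, lambda,
                                 bo$logits,
                                 if (is.null(bo)) numeric(0) else bo$totals,
                                 gamma, count_mode, TRUE, dropout)
        upd <- adam_step(par, as.numeric(r$grad) / r$n, st, lr = lr,
                         weight_decay = weight_decay, lr_scale = lr_scale)
        par <- upd$par; st <- upd$state
        tr_loss <- tr_loss + r$loss; tr_n <- tr_n + r$n
      }
      vl <- val_loss(par)
      if (!is.finite(vl[["loss"]]))
        stop(structure(class = c("cutnet_numerical_error", "error",
                                 "condition"),
                       list(message = sprintf(
                         "validation loss not finite at epoch %d", epoch),
                         call = NULL)))
      hist[[epoch]] <- c(epoch = epoch, train_loss = tr_loss / tr_n, vl)
      if (verbose)
        message(sprintf(
          "epoch %3d  train %.4f  val %.4f (mnll %.1f, mse %.3f)", epoch,
          tr_loss / tr_n, vl[["loss"]], vl[["mnll"]], vl[["mse"]]))
      if (vl[["loss"]] < best$loss) {
        best <- list(par = par, loss = vl[["loss"]], epoch = epoch)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= patience) break
      }
    }
  })
  list(par = best$par, best_epoch = best$epoch, best_val_loss = best$loss,
       history = as.data.frame(do.call(rbind, hist)))
}

#' Train the bias submodel with contamination-checked threshold tuning
#'
#' Stage one of the factorized workflow. For each fraction in the schedule
#' (starting at 0.8 and decreasing), negatives are filtered to totals at
#' or below `0.01-quantile(peak totals) * fraction`, a bias model is
#' trained on the filtered training-chromosome negatives, and a
#' contamination check scans its high-attribution subsequences against
#' the supplied TF motif PWMs. The first fraction whose check passes is
#' returned with a per-iteration report.
#'
#' @param genome a `cutnet_genome`.
#' @param track a `cutnet_track`.
#' @param peaks peak regions (threshold definition and contamination
#'   check).
#' @param negatives GC-matched background regions.
#' @param fold a `cutnet_fold`.
#' @param cfg a `cutnet_config` (default [bias_config()]).
#' @param fractions decreasing fraction schedule.
#' @param motif_pwms named list of 4-row probability matrices of known TF
#'   motifs for the contamination check (empty list: check passes
#'   trivially, with a warning).
#' @param count_width counting window for the threshold (bp).
#' @param lr,patience,max_epochs,batch_size training hyperparameters.
#' @param seed RNG seed.
#' @param check_regions number of peak regions sampled for the
#'   contamination check.
#' @param verbose print per-epoch losses.
#' @return object of class `cutnet_bias_fit`: `model` (a `cutnet_model`),
#'   `fraction`, `report` (one row per attempted fraction), `history`.
#' @export
fit_bias <- function(genome, track, peaks, negatives, fold,
                     cfg = bias_config(),
                     fractions = c(0.8, 0.6, 0.4, 0.2, 0.1),
                     motif_pwms = list(), count_width = 1000L, lr = 1e-3,
                     patience = 5L, max_epochs = 100L, batch_size = 16L,
                     seed = 1L, check_regions = 20L, verbose = FALSE) {
  stopifnot(all(diff(fractions) < 0), all(fractions < 1), all(fractions > 0))
  report <- list()
  for (fr in fractions) {
    kept <- filter_background(negatives, track, peaks, fr, count_width)
    tr <- subset_fold(kept, fold$train)
    va <- subset_fold(kept, fold$val)
    if (nrow(tr) == 0L || nrow(va) == 0L)
      stop("no background regions left after filtering at fraction ", fr)
    lambda <- default_lambda(region_counts(track, va, width = cfg$output_len))
    items <- data.frame(chrom = tr$chrom, center = region_center(tr),
                        jitter = FALSE)
    vit <- data.frame(chrom = va$chrom, center = region_center(va),
                      jitter = FALSE)
    init_total <- mean(log1p(region_counts(track, tr, width = cfg$output_len)))
    model <- with_seed(seed, init_model(cfg, count_bias_init = init_total))
    res <- train_loop(model$par, cfg, genome, track, items, vit, lambda,
                      jitter = 0L, lr = lr, patience = patience,
                      max_epochs = max_epochs, batch_size = batch_size,
                      seed = seed + 1L, verbose = verbose)
    model$par <- res$par
    chk <- contamination_check(model, genome,
                               subset_fold(peaks, c(fold$train, fold$val)),
                               motif_pwms, n_regions = check_regions,
                               seed = seed + 2L)
    report[[length(report) + 1L]] <- data.frame(
      fraction = fr, threshold = attr(kept, "threshold"),
      n_background = nrow(kept), val_loss = res$best_val_loss,
      contamination = chk$verdict)
    if (chk$verdict == "PASS") {
      return(structure(list(model = model, fraction = fr,
                            threshold = attr(kept, "threshold"),
                            lambda = lambda,
                            report = do.call(rbind, report),
                            check = chk, history = res$history,
                            best_epoch = res$best_epoch,
                            best_val_loss = res$best_val_loss),
                       class = "cutnet_bias_fit"))
    }
  }
  stop("no fraction in the schedule passed the contamination check; ",
       "report:\n", paste(utils::capture.output(
         print(do.call(rbind, report))), collapse = "\n"))
}

#' @export
print.cutnet_bias_fit <- function(x, ...) {
  cat(sprintf("cutnet_bias_fit: fraction %.2f (threshold %.1f), val loss %.4f, contamination %s\n",
              x$fraction, x$threshold, x$best_val_loss, x$check$verdict))
  invisible(x)
}

#' Scan a bias model's attributions for TF motif contamination
#'
#' Computes count- and profile-head contribution scores over sampled
#' regions, takes each region's highest-|score| subsequence per motif
#' width, and log-odds scans those subsequences (both strands) against the
#' supplied TF PWMs. The verdict is FAIL if any subsequence scores at or
#' above `threshold_frac` of a PWM's maximum log-odds.
#'
#' @param model a `cutnet_model` (the bias model).
#' @param genome a `cutnet_genome`.
#' @param rg regions to attribute (typically peaks).
#' @param motif_pwms named list of 4-row probability matrices; empty list
#'   passes trivially with a warning.
#' @param n_regions number of regions sampled.
#' @param threshold_frac match threshold as fraction of max log-odds.
#' @param n_refs shuffled references per attribution.
#' @param seed RNG seed.
#' @return list with `verdict` ("PASS"/"FAIL") and `evidence` data.frame.
#' @export
contamination_check <- function(model, genome, rg, motif_pwms,
                                n_regions = 20L, threshold_frac = 0.7,
                                n_refs = 5L, seed = 1L) {
  if (length(motif_pwms) == 0L) {
    warning("empty motif library: contamination check passes trivially")
    return(list(verdict = "PASS",
                evidence = data.frame(motif = character(0))))
  }
  cfg <- model$config
  ev <- list()
  with_seed(seed, {
    idx <- sample.int(nrow(rg), min(n_regions, nrow(rg)))
    for (i in idx) {
      ctr <- region_center(rg)[i]
      s <- get_seq(genome, rg$chrom[i], ctr - cfg$input_len %/% 2L,
                   ctr - cfg$input_len %/% 2L + cfg$input_len)
      for (head in c("count", "profile")) {
        att <- attribute(model, s, head = head, n_refs = n_refs,
                         seed = seed + i)
        proj <- att$projected
        for (mn in names(motif_pwms)) {
          pwm <- motif_pwms[[mn]]
          w <- ncol(pwm)
          sums <- abs(stats::filter(proj, rep(1, w), sides = 1))
          j <- which.max(sums)                     # window ends at j
          sub <- substr(s, j - w + 1L, j)
          lo <- log(pmax(pwm, 1e-6) / 0.25)
          best <- max(pwm_score(sub, lo), pwm_score(revcomp(sub), lo))
          mx <- sum(apply(lo, 2L, max))
          if (is.finite(best) && best >= threshold_frac * mx) {
            ev[[length(ev) + 1L]] <- data.frame(
              region = i, head = head, motif = mn, subseq = sub,
              score = best, max_score = mx, stringsAsFactors = FALSE)
          }
        }
      }
    }
  })
  evidence <- if (length(ev) > 0) do.call(rbind, ev) else
    data.frame(motif = character(0))
  list(verdict = if (length(ev) > 0) "FAIL" else "PASS",
       evidence = evidence)
}

pwm_score <- function(sub, lo) {
  idx <- match(strsplit(sub, "", fixed = TRUE)[[1]], .BASES)
  if (length(idx) != ncol(lo) || anyNA(idx)) return(-Inf)
  sum(lo[cbind(idx, seq_along(idx))])
}

#' Fit the bias-factorized accessibility model
#'
#' Stage two: trains the residual (TF) submodel on peaks plus a 1:10
#' capped subset of GC-matched negatives with the bias submodel frozen.
#' The bias count scaling factor gamma is estimated first from the bias
#' model's predictions over the training and validation examples. Peaks
#' are re-jittered every epoch (uniform offset up to `jitter` bp);
#' negatives stay fixed. Early stopping monitors validation combined loss
#' with the given patience and restores the best weights.
#'
#' @param genome a `cutnet_genome`.
#' @param track a `cutnet_track`.
#' @param peaks peak regions with summits.
#' @param negatives GC-matched background regions.
#' @param bias a `cutnet_bias_fit` or frozen bias `cutnet_model`.
#' @param fold a `cutnet_fold`.
#' @param cfg residual architecture (default [cutnet_config()]).
#' @param neg_ratio negatives per peak used each epoch (default 0.1,
#'   the 1:10 non-peak:peak ratio).
#' @param jitter maximum jitter in bp (clamped so the summit stays inside
#'   the output window).
#' @param augment_rc present each training window in a random orientation
#'   (reverse complement with flipped counts) every epoch.
#' @param passes_per_epoch number of independently re-jittered,
#'   re-oriented passes over the training set per epoch (early stopping
#'   counts epochs, so this sets how much optimization one epoch holds).
#' @param dropout channel dropout rate applied to every convolution's
#'   ReLU branch during training (inverted dropout; prediction is
#'   dropout-free). The desk-scale default is what lets a model
#'   generalize from a few hundred training regions.
#' @param head_lr_mult learning-rate multiplier for the count head, which
#'   sits behind global average pooling and otherwise cannot reach its
#'   working weight magnitude within a desk-scale step budget.
#' @param blacklist optional excluded regions (peak filtering).
#' @param lr,patience,max_epochs,batch_size training hyperparameters.
#' @param seed RNG seed.
#' @param verbose print per-epoch losses.
#' @return an object of class `cutnet_fit` (see Details) with the frozen
#'   bias model, the trained residual model, `gamma`, `lambda`, the
#'   training history and fold bookkeeping.
#' @export
fit_cutnet <- function(genome, track, peaks, negatives, bias, fold,
                       cfg = cutnet_config(), neg_ratio = 0.1,
                       jitter = 200L, blacklist = NULL, lr = 1e-3,
                       patience = 5L, max_epochs = 100L, batch_size = 16L,
                       seed = 1L, augment_rc = TRUE, passes_per_epoch = 4L,
                       dropout = 0.3, head_lr_mult = 50, verbose = FALSE) {
  bias_model <- if (inherits(bias, "cutnet_bias_fit")) bias$model else bias
  stopifnot(inherits(bias_model, "cutnet_model"))
  if (bias_model$config$input_len != cfg$input_len ||
      bias_model$config$output_len != cfg$output_len)
    stop("bias model window lengths must match the residual config")
  jitter <- min(jitter, (cfg$output_len - 1L) %/% 2L)
  peaks_f <- filter_training_peaks(peaks, track, genome,
                                   blacklist = blacklist,
                                   input_len = cfg$input_len, jitter = jitter)
  tr_pk <- subset_fold(peaks_f, fold$train)
  va_pk <- subset_fold(peaks_f, fold$val)
  tr_ng <- subset_fold(negatives, fold$train)
  va_ng <- subset_fold(negatives, fold$val)
  if (nrow(tr_pk) == 0L || nrow(va_pk) == 0L)
    stop("no peaks on the training or validation chromosomes")
  n_neg <- min(nrow(tr_ng), ceiling(neg_ratio * nrow(tr_pk)))
  n_neg_va <- min(nrow(va_ng), ceiling(neg_ratio * nrow(va_pk)))
  with_seed(seed, {
    tr_ng <- tr_ng[sample.int(nrow(tr_ng), n_neg), , drop = FALSE]
    if (n_neg_va > 0L)
      va_ng <- va_ng[sample.int(nrow(va_ng), n_neg_va), , drop = FALSE]
    else va_ng <- va_ng[0L, , drop = FALSE]
  })
  items <- data.frame(
    chrom = c(tr_pk$chrom, tr_ng$chrom),
    center = c(region_center(tr_pk), region_center(tr_ng)),
    jitter = c(rep(TRUE, nrow(tr_pk)), rep(FALSE, nrow(tr_ng))))
  vit <- data.frame(
    chrom = c(va_pk$chrom, va_ng$chrom),
    center = c(region_center(va_pk), region_center(va_ng)),
    jitter = FALSE)
  # stage 1: fit-and-scale — gamma from bias predictions on train + val
  gdat <- rbind(items[c("chrom", "center")], vit[c("chrom", "center")])
  obs_tot <- numeric(nrow(gdat))
  bias_tot <- numeric(nrow(gdat))
  bl <- unclass(bias_model$config)
  for (b0 in seq(1L, nrow(gdat), by = 64L)) {
    sel <- b0:min(b0 + 63L, nrow(gdat))
    Xs <- vector("list", length(sel))
    for (j in seq_along(sel)) {
      ex <- make_example(genome, track, gdat$chrom[sel[j]],
                         gdat$center[sel[j]], cfg$input_len, cfg$output_len)
      Xs[[j]] <- ex$X
      obs_tot[sel[j]] <- sum(ex$k)
    }
    bias_tot[sel] <- .cn_forward_batch(bias_model$par, bl, Xs)$log_total
  }
  gamma <- estimate_gamma(bias_tot, obs_tot)
  lambda <- default_lambda(obs_tot[(nrow(items) + 1L):nrow(gdat)])
  init_total <- mean(log1p(obs_tot[seq_len(nrow(items))]))
  bias_par_before <- bias_model$par
  tf <- with_seed(seed + 10L, init_model(cfg, count_bias_init = init_total))
  res <- train_loop(tf$par, cfg, genome, track, items, vit, lambda,
                    bias_model = bias_model, gamma = gamma,
                    jitter = jitter, lr = lr, patience = patience,
                    max_epochs = max_epochs, batch_size = batch_size,
                    seed = seed + 11L, augment_rc = augment_rc,
                    passes_per_epoch = passes_per_epoch, dropout = dropout,
                    head_lr_mult = head_lr_mult, verbose = verbose)
  tf$par <- res$par
  stopifnot(identical(bias_par_before, bias_model$par))  # frozen
  structure(list(tf = tf, bias = bias_model, gamma = gamma,
                 lambda = lambda, config = cfg, fold = fold,
                 history = res$history, best_epoch = res$best_epoch,
                 best_val_loss = res$best_val_loss,
                 peaks = peaks_f, negatives = rbind(tr_ng, va_ng),
                 jitter = jitter, seed = seed),
            class = "cutnet_fit")
}
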