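#' Dinucleotide-preserving sequence shuffles
#'
#' Euler-path (Altschul–Erickson) shuffle: every output has exactly the
#' same dinucleotide count multiset as the input. Deterministic given
#' `seed`.
#'
#' @param seq character string.
#' @param n number of shuffles.
#' @param seed RNG seed.
#' @return character vector of `n` shuffled sequences.
#' @export
dinuc_shuffle <- function(seq, n = 20L, seed = 1L) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  with_seed(seed, vapply(seq_len(n), function(i) dinuc_shuffle_one(chars),
                         character(1)))
}

dinuc_shuffle_one <- function(chars) {
  L <- length(chars)
  if (L <= 2L) return(paste(chars, collapse = ""))
  # successor edge lists of the de Bruijn-style multigraph
  succ <- split(chars[-1L], factor(chars[-L], levels = unique(chars[-L])))
  verts <- names(succ)
  last_char <- chars[L]
  repeat {
    # choose a random terminal edge per vertex; valid iff following the
    # terminal edges from every vertex reaches the sequence's last symbol
    term <- vapply(verts, function(v) {
      e <- succ[[v]]
      e[[sample.int(length(e), 1L)]]
    }, character(1))
    ok <- TRUE
    for (v in verts) {
      if (v == last_char) next
      cur <- v
      for (step in seq_len(length(verts) + 1L)) {
        if (cur == last_char) break
        if (!cur %in% verts) { ok <- FALSE; break }
        cur <- term[[cur]]
      }
      if (cur != last_char) ok <- FALSE
      if (!ok) break
    }
    if (ok) break
  }
  # shuffle the remaining edges; terminal edge is used last
  pool <- lapply(verts, function(v) {
    e <- succ[[v]]
    i <- match(term[[v]], e)
    rest <- e[-i]
    if (v == last_char && length(rest) > 0) {
      c(sample(rest), term[[v]])
    } else if (length(rest) > 0) {
      c(rest[sample.int(length(rest))], term[[v]])
    } else {
      term[[v]]
    }
  })
  names(pool) <- verts
  used <- stats::setNames(integer(length(verts)), verts)
  out <- character(L)
  out[1L] <- chars[1L]
  cur <- chars[1L]
  for (i in 2:L) {
    used[[cur]] <- used[[cur]] + 1L
    nxt <- pool[[cur]][[used[[cur]]]]
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Per-base contribution scores against shuffled references
#'
#' DeepLIFT-style (Rescale rule) contributions of a model head's scalar
#' output relative to dinucleotide-shuffled references, averaged over
#' `n_refs` references. For the count head the scalar is the predicted
#' log(1 + total). For the profile head, per-output-position
#' contributions are aggregated with weights equal to the predicted
#' profile probabilities of the input sequence (mean-centered logits), so
#' the scalar is `sum_j p_j (f_j - mean(f))`. The completeness identity
#' `sum(scores) = mean_ref(f(x) - f(ref))` holds to float precision.
#'
#' @param model a `cutnet_model`, or a `cutnet_fit` (its bias-corrected
#'   residual submodel is used).
#' @param seq input sequence of length input_len (character), at most 20%
#'   N.
#' @param head `"count"` or `"profile"`.
#' @param n_refs number of shuffled references.
#' @param seed RNG seed for the shuffles.
#' @return list of class `cutnet_attribution`: `scores` (4 x L matrix,
#'   hypothetical at all bases), `projected` (length-L scores at the
#'   observed bases), `delta` (mean f(x) - f(ref)), `completeness`
#'   (relative residual), `head`, `n_refs`.
#' @export
attribute <- function(model, seq, head = c("count", "profile"),
                      n_refs = 20L, seed = 1L) {
  if (inherits(model, "cutnet_fit")) model <- model$tf
  stopifnot(inherits(model, "cutnet_model"))
  head <- match.arg(head)
  cfg <- model$config
  if (nchar(seq) != cfg$input_len)
    stop("sequence must have length ", cfg$input_len)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (mean(!chars %in% .BASES) > 0.2)
    stop("more than 20% ambiguous bases: attribution is meaningless")
  x <- one_hot(seq)
  hw <- numeric(0)
  head_i <- 0L
  if (head == "profile") {
    fw <- forward(model, x)
    p <- softmax(fw$logits)
    hw <- p - sum(p) / cfg$output_len   # realizes sum_j p_j (f_j - mean f)
    head_i <- 1L
  }
  refs <- dinuc_shuffle(seq, n_refs, seed)
  acc <- matrix(0, 4L, cfg$input_len)
  deltas <- numeric(n_refs)
  for (r in seq_len(n_refs)) {
    res <- .cn_deeplift(model$par, unclass(cfg), x, one_hot(refs[r]),
                        head_i, hw)
    acc <- acc + res$contrib
    deltas[r] <- res$delta
  }
  scores <- acc / n_refs
  delta <- mean(deltas)
  # per-position projection sums the 4 base rows: the contribution at a
  # position splits between the observed base (+) and the reference base
  # (-) rows, and only their sum preserves completeness
  projected <- colSums(scores)
  structure(list(scores = scores, projected = projected,
                 delta = delta,
                 completeness = abs(sum(projected) - delta) /
                   max(abs(delta), 1e-12),
                 head = head, n_refs = n_refs),
            class = "cutnet_attribution")
}

#' Write an attribution as per-base TSV
#' @param att a `cutnet_attribution`.
#' @param path output path.
#' @export
write_attribution <- function(att, path) {
  df <- data.frame(pos = seq_along(att$projected) - 1L,
                   t(att$scores), projected = att$projected)
  names(df)[2:5] <- c("A", "C", "G", "T")
  utils::write.table(format(df, digits = 6, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Replace the center of a sequence with a motif
#'
#' The motif replaces bases centered at the window midpoint; even-length
#' motifs sit 1 bp left of center.
#'
#' @param background sequence to modify.
#' @param motif motif sequence.
#' @return modified sequence.
#' @export
insert_motif <- function(background, motif) {
  L <- nchar(background); w <- nchar(motif)
  if (w >= L) stop("motif must be shorter than the background window")
  s0 <- (L - w) %/% 2L
  substr(background, s0 + 1L, s0 + w) <- motif
  background
}

#' GC-matched synthetic background sequence library
#'
#' Random i.i.d. sequences whose GC fractions are drawn from the peak
#' set's empirical GC distribution; used as the insertion background for
#' marginal footprinting.
#'
#' @param genome a `cutnet_genome`.
#' @param peaks peak regions.
#' @param n library size.
#' @param input_len sequence length.
#' @param seed RNG seed.
#' @return character vector of `n` sequences.
#' @export
background_library <- function(genome, peaks, n = 100L, input_len = 1114L,
                               seed = 1L) {
  gcs <- gc_content(genome, peaks)$gc
  gcs <- gcs[!is.na(gcs)]
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      gc <- gcs[[sample.int(length(gcs), 1L)]]
      pr <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
      paste(sample(.BASES, input_len, replace = TRUE, prob = pr[.BASES]),
            collapse = "")
    }, character(1))
  })
}

# predicted counts-scale profile (probabilities * totals) for sequences,
# averaged with the flipped reverse-complement prediction
response_profile <- function(model_fun, seqs) {
  prof <- NULL
  for (s in seqs) {
    fw <- model_fun(s)
    rv <- model_fun(revcomp(s))
    pf <- softmax(fw$logits) * max(expm1(fw$log_total), 1e-8)
    pr <- rev(softmax(rv$logits) * max(expm1(rv$log_total), 1e-8))
    prof <- if (is.null(prof)) (pf + pr) / 2 else prof + (pf + pr) / 2
  }
  prof / length(seqs)
}

#' Marginal footprint of a motif
#'
#' Inserts the motif at the center of each background sequence, predicts
#' the counts-scale profile for the sequence and its reverse complement
#' (flipping the latter), averages over the library, and compares against
#' uninserted controls. The footprint vector `M` is the control-relative
#' response — the motif library's profile probabilities scaled by the
#' exponentiated log fold change in totals versus control — smoothed with
#' a width-5 moving average. Valley boundaries, height and width follow
#' [footprint_geometry()].
#'
#' @param model a `cutnet_fit` or `cutnet_model`.
#' @param motif motif sequence to insert.
#' @param backgrounds background sequence library
#'   (see [background_library()]).
#' @param corrected for a `cutnet_fit`: use the bias-corrected residual
#'   submodel (`TRUE`, default) or the combined factorized prediction.
#' @param smooth moving-average width (bp).
#' @return object of class `cutnet_footprint` with `M`, `profile`,
#'   `control`, `logfc`, `rs`, `ls`, `height`, `width`, `degenerate`.
#' @export
marginal_footprint <- function(model, motif, backgrounds, corrected = TRUE,
                               smooth = 5L) {
  fun <- prediction_fun(model, corrected)
  out_len <- prediction_output_len(model)
  resp <- response_profile(fun, vapply(backgrounds, insert_motif,
                                       character(1), motif = motif))
  ctrl <- response_profile(fun, backgrounds)
  logfc <- log(sum(resp)) - log(sum(ctrl))
  prob <- resp / sum(resp)
  M <- smooth_ma(prob * exp(logfc), smooth)
  geo <- footprint_geometry(M, center = out_len %/% 2L)
  structure(c(list(M = M, profile = resp, control = ctrl, logfc = logfc,
                   motif = motif), geo),
            class = "cutnet_footprint")
}

#' @export
print.cutnet_footprint <- function(x, ...) {
  cat(sprintf("cutnet_footprint [%s]: height %.4g, width %d, logFC %.3f%s\n",
              x$motif, x$height, x$width, x$logfc,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

smooth_ma <- function(v, w) {
  if (w <= 1L) return(v)
  sm <- as.numeric(stats::filter(v, rep(1 / w, w), sides = 2L))
  # shrink the window at the edges instead of dropping to NA
  na <- which(is.na(sm))
  for (i in na) {
    lo <- max(1L, i - w %/% 2L); hi <- min(length(v), i + w %/% 2L)
    sm[i] <- mean(v[lo:hi])
  }
  sm
}

prediction_fun <- function(model, corrected = TRUE) {
  if (inherits(model, "cutnet_fit")) {
    if (corrected) {
      m <- model$tf
      function(s) forward(m, s)
    } else {
      tf <- model$tf; bias <- model$bias
      gamma <- model$gamma; cm <- model$config$count_mode
      function(s) {
        combine_predictions(forward(tf, s), forward(bias, s), gamma, cm)$combined
      }
    }
  } else if (inherits(model, "cutnet_model")) {
    function(s) forward(model, s)
  } else stop("model must be a cutnet_fit or cutnet_model")
}

prediction_output_len <- function(model) {
  if (inherits(model, "cutnet_fit")) model$config$output_len
  else model$config$output_len
}

#' Footprint valley geometry
#'
#' The valley boundaries are the positions of maximum gradient change —
#' implemented as the largest |second difference| of `M` — on either side
#' of the center, ties broken toward the center. Height is
#' `max(M[1:rs], M[ls:end]) - min(M[rs:ls])`; width is `ls - rs`. A flat
#' profile is reported as degenerate with height 0.
#'
#' @param M footprint vector.
#' @param center center index (1-based; insertion point).
#' @return list with `rs`, `ls`, `height`, `width`, `degenerate`.
#' @export
footprint_geometry <- function(M, center = length(M) %/% 2L) {
  L <- length(M)
  stopifnot(L >= 5L, center > 2L, center < L - 1L)
  d2 <- abs(diff(M, differences = 2L))   # d2[j] is curvature at index j+1
  curv_at <- function(i) d2[i - 1L]
  left <- 2L:(center - 1L)
  right <- (center + 1L):(L - 1L)
  pick <- function(cand) {
    v <- vapply(cand, curv_at, numeric(1))
    best <- cand[v == max(v)]
    best[which.min(abs(best - center))]   # tie toward the center
  }
  rs <- pick(left)
  ls <- pick(right)
  degenerate <- max(d2) == 0
  height <- max(c(M[seq_len(rs)], M[ls:L])) - min(M[rs:ls])
  list(rs = rs, ls = ls, height = height, width = ls - rs,
       degenerate = degenerate)
}

#' Bias-correction audit
#'
#' Compares uncorrected (factorized) and corrected (residual-only)
#' marginal footprint heights for enzyme-bias k-mers and TF motifs. The
#' audit passes when every bias k-mer's corrected/uncorrected height
#' ratio is below `bias_ratio_max` and every TF motif's ratio stays
#' within `tf_band`.
#'
#' @param fit a `cutnet_fit`.
#' @param bias_kmers character vector of bias k-mers.
#' @param tf_motifs named character vector of TF motif sequences.
#' @param backgrounds background library.
#' @param bias_ratio_max maximum tolerated corrected/uncorrected height
#'   ratio for bias k-mers (default 0.1).
#' @param tf_band allowed corrected/uncorrected ratio band for TF motifs.
#' @return list of class `cutnet_audit` with `table` and `verdict`.
#' @export
bias_audit <- function(fit, bias_kmers, tf_motifs, backgrounds,
                       bias_ratio_max = 0.1, tf_band = c(0.8, 1.2)) {
  if (length(bias_kmers) == 0L || length(tf_motifs) == 0L)
    stop("bias_kmers and tf_motifs must both be non-empty")
  one <- function(m, kind, name) {
    un <- marginal_footprint(fit, m, backgrounds, corrected = FALSE)
    co <- marginal_footprint(fit, m, backgrounds, corrected = TRUE)
    data.frame(motif = name, kind = kind,
               uncorrected = un$height, corrected = co$height,
               ratio = co$height / max(un$height, 1e-12),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (i in seq_along(bias_kmers))
    rows[[length(rows) + 1L]] <- one(bias_kmers[[i]], "bias",
                                     paste0("bias_", bias_kmers[[i]]))
  nm <- names(tf_motifs)
  if (is.null(nm)) nm <- paste0("tf_", seq_along(tf_motifs))
  for (i in seq_along(tf_motifs))
    rows[[length(rows) + 1L]] <- one(tf_motifs[[i]], "tf", nm[[i]])
  tab <- do.call(rbind, rows)
  bias_ok <- all(tab$ratio[tab$kind == "bias"] < bias_ratio_max)
  tf_ok <- all(tab$ratio[tab$kind == "tf"] >= tf_band[1L] &
               tab$ratio[tab$kind == "tf"] <= tf_band[2L])
  structure(list(table = tab,
                 verdict = if (bias_ok && tf_ok) "PASS" else "FAIL",
                 bias_ok = bias_ok, tf_ok = tf_ok,
                 bias_ratio_max = bias_ratio_max, tf_band = tf_band),
            class = "cutnet_audit")
}

#' @export
print.cutnet_audit <- function(x, ...) {
  cat("cutnet_audit:", x$verdict, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
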