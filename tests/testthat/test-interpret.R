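test_that("dinucleotide shuffles preserve dinucleotide counts exactly", {
  expect_equal(dinuc_shuffle("AAAA", 3L, seed = 1L), rep("AAAA", 3L))
  for (s in c("ACGTACGT", random_seq(120L, 51L), random_seq(301L, 52L))) {
    out <- dinuc_shuffle(s, 20L, seed = 2L)
    want <- dinuc_counts(s)
    for (o in out) {
      got <- dinuc_counts(o)
      expect_identical(sort(names(got)), sort(names(want)))
      expect_equal(as.integer(got[names(want)]), as.integer(want))
      expect_equal(substr(o, 1L, 1L), substr(s, 1L, 1L))
      expect_equal(substr(o, nchar(o), nchar(o)),
                   substr(s, nchar(s), nchar(s)))
    }
    # seeded determinism
    expect_identical(out, dinuc_shuffle(s, 20L, seed = 2L))
  }
})

test_that("attribution satisfies the completeness contract", {
  cfg <- tiny_cfg()
  m <- tiny_model(61L)
  s <- random_seq(cfg$input_len, 62L)
  for (head in c("count", "profile")) {
    att <- attribute(m, s, head = head, n_refs = 10L, seed = 3L)
    expect_lt(att$completeness, 1e-6)
    expect_equal(sum(att$projected), att$delta, tolerance = 1e-8)
  }
  # a model that ignores sequence attributes nothing
  m0 <- m; m0$par[] <- 0; m0$par[length(m0$par)] <- 1
  att0 <- attribute(m0, s, head = "count", n_refs = 5L, seed = 3L)
  expect_true(all(abs(att0$scores) < 1e-12))
  expect_error(attribute(m, paste(rep("N", cfg$input_len), collapse = "")),
               "ambiguous")
})

test_that("attribution averaging is reference-order-free", {
  cfg <- tiny_cfg()
  m <- tiny_model(63L)
  s <- random_seq(cfg$input_len, 64L)
  att <- attribute(m, s, head = "count", n_refs = 6L, seed = 9L)
  refs <- dinuc_shuffle(s, 6L, seed = 9L)
  x <- one_hot(s)
  acc <- matrix(0, 4L, cfg$input_len)
  for (r in rev(refs)) {
    acc <- acc + cutnet:::.cn_deeplift(m$par, unclass(cfg), x, one_hot(r),
                                       0L, numeric(0))$contrib
  }
  expect_equal(acc / 6L, att$scores, tolerance = 1e-12)
})

test_that("footprint geometry matches construction and exhaustive search", {
  # symmetric V-shaped valley of half-width 10: kinks at center +/- 10
  x <- 1:41
  M <- pmin(10, abs(x - 21))
  geo <- footprint_geometry(M, center = 21L)
  expect_equal(geo$rs, 11L)
  expect_equal(geo$ls, 31L)
  expect_equal(geo$width, 20L)
  expect_false(geo$degenerate)
  expect_equal(geo$height, 10)

  flat <- footprint_geometry(rep(2, 50), center = 25L)
  expect_true(flat$degenerate)
  expect_equal(flat$height, 0)

  brute <- function(M, center) {
    d2 <- abs(diff(M, differences = 2L))
    curv <- function(i) d2[i - 1L]
    best_side <- function(cand) {
      v <- vapply(cand, curv, numeric(1))
      hit <- cand[v == max(v)]
      hit[which.min(abs(hit - center))]
    }
    rs <- best_side(2:(center - 1L))
    ls <- best_side((center + 1L):(length(M) - 1L))
    list(rs = rs, ls = ls,
         height = max(c(M[1:rs], M[ls:length(M)])) - min(M[rs:ls]),
         width = ls - rs)
  }
  set.seed(70)
  for (i in 1:100) {
    L <- sample(30:200, 1L)
    center <- L %/% 2L
    xs <- seq_len(L)
    M <- 2 - 1.5 * exp(-(xs - center)^2 / sample(20:200, 1L)) +
      cumsum(rnorm(L, 0, 0.03))
    geo <- footprint_geometry(M, center)
    want <- brute(M, center)
    expect_identical(geo$rs, want$rs)
    expect_identical(geo$ls, want$ls)
    expect_equal(geo$height, want$height)
    expect_equal(geo$width, want$width)
  }
})

test_that("marginal footprints are strand-symmetric", {
  cfg <- tiny_cfg()             # odd input length: exact mirror math
  m <- tiny_model(71L)
  g <- as_genome(c(chr1 = random_seq(20000L, 72L)))
  peaks <- regions("chr1", c(2000L, 6000L), c(2500L, 6500L), summit = 250L)
  bgs <- background_library(g, peaks, n = 10L, input_len = cfg$input_len,
                            seed = 73L)
  bgs <- c(bgs, vapply(bgs, revcomp, character(1)))  # rc-closed library
  motif <- "TGACGTCAT"                                # odd length
  fp <- marginal_footprint(m, motif, bgs)
  fr <- marginal_footprint(m, revcomp(motif), bgs)
  expect_equal(fr$M, rev(fp$M), tolerance = 1e-9)
  expect_equal(fr$logfc, fp$logfc, tolerance = 1e-9)
  expect_equal(fr$height, fp$height, tolerance = 1e-6)
})

test_that("a sequence-blind model yields a null footprint", {
  cfg <- tiny_cfg()
  m <- tiny_model(74L)
  m$par[] <- 0
  m$par[length(m$par)] <- 2
  g <- as_genome(c(chr1 = random_seq(8000L, 75L)))
  peaks <- regions("chr1", 1000L, 1500L, summit = 250L)
  bgs <- background_library(g, peaks, n = 6L, input_len = cfg$input_len,
                            seed = 76L)
  fp <- marginal_footprint(m, "TGCATAACGGTC", bgs)
  expect_lt(fp$height, 1e-9)
  expect_equal(fp$logfc, 0, tolerance = 1e-12)
})

test_that("the bias audit demands non-empty motif lists", {
  b <- prop_fit_bundle()
  bgs <- background_library(b$ex$genome, b$ex$peaks, n = 4L,
                            input_len = 1114L, seed = 1L)
  expect_error(bias_audit(b$fit, character(0), c(deep = "TGCATAACGGTC"),
                          bgs), "non-empty")
  expect_error(bias_audit(b$fit, "GTGCAC", character(0), bgs), "non-empty")
})

test_that("attribution TSV output is well-formed", {
  cfg <- tiny_cfg()
  m <- tiny_model(77L)
  att <- attribute(m, random_seq(cfg$input_len, 78L), n_refs = 3L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_attribution(att, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(back), cfg$input_len)
  expect_named(back, c("pos", "A", "C", "G", "T", "projected"))
})
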