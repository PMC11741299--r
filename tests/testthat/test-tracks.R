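toy_genome <- function(len = 3000L, chroms = "chr1") {
  as_genome(stats::setNames(
    vapply(seq_along(chroms),
           function(i) random_seq(len, seed = 100L + i), character(1)),
    chroms))
}

test_that("assay shifts follow the +4/-4 (ATAC) and 0/+1 (DNase) rules", {
  g <- toy_genome()
  s <- cut_sites("chr1", c(100L, 100L, 100L), c("+", "-", "-"))
  atac <- shift_cuts(s[1:2, ], "ATAC", g)
  expect_equal(atac$pos, c(104L, 96L))
  dnase <- shift_cuts(s[3, ], "DNASE", g)
  expect_equal(dnase$pos, 101L)
  expect_equal(dnase$strand, "-")
  # round trip restores positions exactly
  back <- shift_cuts(atac, "ATAC", g, reverse = TRUE)
  expect_equal(back$pos, c(100L, 100L))
  # out-of-bounds shifted sites are dropped with a counted warning
  edge <- cut_sites("chr1", c(1L, 50L), c("-", "+"))
  expect_warning(kept <- shift_cuts(edge, "ATAC", g), "dropped")
  expect_equal(nrow(kept), 1L)
  expect_equal(attr(kept, "dropped"), 1L)
})

test_that("coverage pools shifted strands and conserves counts", {
  g <- toy_genome()
  s <- cut_sites("chr1", c(10L, 10L, 18L), c("+", "+", "-"))
  tr <- build_coverage(s, g, assay = "ATAC")
  expect_equal(tr$counts$chr1[15L], 3L)      # 10+4 = 18-4 = 14 (0-based)
  expect_equal(sum(tr$counts$chr1), 3L)
  empty <- build_coverage(cut_sites(character(0), integer(0), character(0)),
                          g)
  expect_true(all(empty$counts$chr1 == 0L))
  expect_error(build_coverage(cut_sites("chrX", 5L, "+"), g), "chrX")
  # conservation on a simulated set with droppable edge sites
  set.seed(20)
  n <- 1000L
  sites <- cut_sites("chr1", sample(0:2999, n, replace = TRUE),
                     sample(c("+", "-"), n, replace = TRUE))
  tr2 <- suppressWarnings(build_coverage(sites, g, assay = "ATAC"))
  expect_equal(sum(tr2$counts$chr1), n - tr2$dropped)
})

test_that("bin enumeration matches brute force and the printed cases", {
  g1 <- toy_genome(4114L)
  b <- tile_genome(g1, 2114L, 1000L)
  expect_equal(b$start, c(0L, 1000L, 2000L))
  expect_equal(nrow(tile_genome(toy_genome(2114L), 2114L, 1000L)), 1L)
  expect_equal(nrow(tile_genome(toy_genome(2113L), 2114L, 1000L)), 0L)
  # brute force over all starts on a <= 10 kb chromosome
  g2 <- toy_genome(9731L)
  for (win in c(500L, 1114L)) {
    for (stride in c(173L, 500L)) {
      got <- tile_genome(g2, win, stride)$start
      want <- Filter(function(s) s + win <= 9731L,
                     seq(0L, 9731L, by = stride))
      expect_equal(got, as.integer(want))
    }
  }
})

test_that("subsampling is a seeded Bernoulli thinning", {
  sim <- small_sim()
  expect_identical(subsample_cuts(sim$sites, 1.0), sim$sites)
  expect_equal(nrow(subsample_cuts(sim$sites, 0.0)), 0L)
  ss <- subsample_cuts(sim$sites[1:10000, ], 0.5, seed = 99L)
  bounds <- qbinom(c(0.005, 0.995), 10000L, 0.5)
  expect_gte(nrow(ss), bounds[1])
  expect_lte(nrow(ss), bounds[2])
  expect_identical(ss, subsample_cuts(sim$sites[1:10000, ], 0.5, seed = 99L))
})

test_that("PWM alignment check recovers the planted shift convention", {
  sim <- small_sim()   # ATAC-convention reads with planted Tn5-like bias
  chk <- strand_shift_check(sim$sites, sim$genome, max_sites = 8000L)
  rec <- attr(chk, "recommended")
  expect_equal(as.integer(rec), c(4L, -4L))
  expect_false(attr(chk, "tie"))

  dn_spec <- sim_spec(chrom_lengths = c(chr1 = 60000L, chr2 = 50000L,
                                        chr3 = 50000L),
                      n_peaks = 9L, n_decoys = 0L, depth = 1e5,
                      bias = sim_bias_truth(assay_shift = "DNASE"),
                      seed = 21L)
  dn <- simulate_experiment(dn_spec)
  chk2 <- strand_shift_check(dn$sites, dn$genome, max_sites = 8000L)
  expect_equal(as.integer(attr(chk2, "recommended")), c(0L, 1L))

  # a strand-symmetric featureless genome ties all candidate shifts
  gA <- as_genome(c(chr1 = strrep("A", 5000L)))
  set.seed(22)
  su <- cut_sites("chr1", sample(100:4900, 400L, replace = TRUE),
                  rep(c("+", "-"), 200L))
  chk3 <- strand_shift_check(su, gA)
  expect_true(attr(chk3, "tie"))
})

test_that("tracks round-trip through bedGraph and cut-site BED", {
  sim <- small_sim()
  d <- withr::local_tempdir()
  bg <- file.path(d, "t.bedGraph")
  write_track(sim$track, bg)
  tr2 <- read_track(bg, sim$genome)
  expect_identical(tr2$counts, sim$track$counts)
  cb <- file.path(d, "c.bed")
  write_cuts_bed(sim$sites[1:500, ], cb)
  s2 <- read_cuts_bed(cb)
  expect_equal(nrow(s2), 500L)
  expect_equal(sort(s2$pos), sort(sim$sites$pos[1:500]))
})
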