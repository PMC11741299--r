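test_that("the simulator is deterministic given its seed", {
  spec <- sim_spec(chrom_lengths = c(chr1 = 30000L, chr2 = 30000L),
                   n_peaks = 6L, n_decoys = 4L, depth = 5e4, seed = 5L)
  a <- sim_genome(spec); b <- sim_genome(spec)
  expect_identical(a$genome$seq, b$genome$seq)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.fa"); f2 <- file.path(d, "b.fa")
  write_genome(a$genome, f1); write_genome(b$genome, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  ra <- true_cut_rate(a$genome, spec)
  s1 <- sim_cut_sites(ra, 1e4, seed = 3L)
  s2 <- sim_cut_sites(ra, 1e4, seed = 3L)
  expect_identical(s1, s2)
})

test_that("base composition matches the target GC within sampling bounds", {
  spec <- sim_spec(chrom_lengths = c(chr1 = 50000L), n_peaks = 1L,
                   n_decoys = 0L, gc = 0.41,
                   motifs = list(), depth = 1e4, seed = 6L)
  spec$motifs <- default_motifs()["shallow"]   # one tiny plant only
  sg <- sim_genome(spec)
  ch <- strsplit(sg$genome$seq[["chr1"]], "")[[1]]
  gc <- mean(ch %in% c("G", "C"))
  se <- sqrt(0.41 * 0.59 / 50000)
  expect_lt(abs(gc - 0.41), 4 * se)
})

test_that("every planted peak contains a motif match above threshold", {
  sim <- small_sim()
  spec <- small_spec()
  pl <- sim$planted[sim$planted$kind == "peak", ]
  for (i in seq_len(nrow(pl))) {
    s <- get_seq(sim$genome, pl$chrom[i], pl$center[i] - 30L,
                 pl$center[i] + 30L)
    hits <- scan_motif(s, spec$motifs[[pl$motif[i]]], spec$match_frac)
    expect_gte(nrow(hits), 1L)
  }
})

test_that("the bias truth is mean-centered and strength-scaled", {
  tr <- sim_bias_truth(k = 6L, strength = 1.0)
  kmers <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 6)))
  lp <- bias_log_pref(tr, kmers)
  expect_lt(abs(mean(lp)), 1e-10)
  expect_equal(sqrt(mean(lp^2)), 1.0, tolerance = 1e-9)
  expect_true(all(sim_bias_truth(strength = 0)$weights == 0))
})

test_that("the rate field factorizes accessibility, bias and protection", {
  # bias only, no motifs: rate/background equals the bias factor exactly
  spec <- sim_spec(chrom_lengths = c(chr1 = 4000L), n_peaks = 1L,
                   n_decoys = 0L, depth = 100, seed = 8L, margin = 1500L)
  spec$motifs <- list()
  g <- as_genome(c(chr1 = random_seq(4000L, seed = 81L)))
  rate <- true_cut_rate(g, spec)
  expect_true(all(rate$rate$chr1 >= 0))
  for (p in c(100L, 512L, 2000L)) {
    kmer <- get_seq(g, "chr1", p - 3L, p + 3L)
    expect_equal(rate$rate$chr1[p + 1L],
                 spec$background_access * exp(bias_log_pref(spec$bias, kmer)),
                 tolerance = 1e-12)
  }
  # without bias and motifs the field is flat
  spec0 <- spec; spec0$bias <- sim_bias_truth(strength = 0)
  r0 <- true_cut_rate(g, spec0)
  expect_true(all(abs(r0$rate$chr1 - spec0$background_access) < 1e-12))
})

test_that("multinomial sampling hits the requested depth exactly", {
  sim <- small_sim()
  expect_equal(nrow(sim$sites), small_spec()$depth)
  expect_equal(sum(vapply(sim$track$counts, sum, 0)),
               small_spec()$depth)          # nothing dropped at edges
  # uniform field: per-bin occupancy is multinomially consistent
  spec <- sim_spec(chrom_lengths = c(chr1 = 20000L), n_peaks = 1L,
                   n_decoys = 0L, seed = 9L)
  spec$motifs <- list(); spec$bias <- sim_bias_truth(strength = 0)
  g <- as_genome(c(chr1 = random_seq(20000L, seed = 91L)))
  rate <- true_cut_rate(g, spec)
  sites <- sim_cut_sites(rate, 1e5, seed = 10L)
  shifted <- shift_cuts(sites, "ATAC", g)
  bins <- cut(shifted$pos, breaks = seq(0L, 20000L, by = 200L))
  cs <- chisq.test(table(bins))
  expect_gt(cs$p.value, 1e-4)
})

test_that("emitted variant truth equals a full-genome rebuild", {
  spec <- sim_spec(chrom_lengths = c(chr1 = 40000L, chr2 = 30000L),
                   n_peaks = 6L, n_decoys = 4L, depth = 1e4, seed = 12L)
  sim <- sim_genome(spec)
  vars <- sim_variants(sim$genome, sim, spec, n = 9L, seed = 13L)
  expect_true(all(vars$true_logfc[vars$label == "decrease"] < 0))
  expect_true(all(vars$true_logfc[vars$label == "increase"] > 0))
  expect_true(all(abs(vars$true_logfc[vars$label == "null"]) < 0.02))
  for (i in seq_len(min(5L, nrow(vars)))) {
    g2 <- sim$genome
    ch <- vars$chrom[i]; p0 <- vars$pos[i] - 1L
    expect_equal(get_seq(g2, ch, p0, p0 + 1L), vars$ref[i])
    seqs <- g2$seq
    substr(seqs[[ch]], p0 + 1L, p0 + 1L) <- vars$alt[i]
    galt <- as_genome(seqs)
    rr <- true_cut_rate(sim$genome, spec)$rate[[ch]]
    ra <- true_cut_rate(galt, spec)$rate[[ch]]
    win <- (p0 - 500L + 1L):(p0 + 500L)
    expect_equal(log(sum(ra[win])) - log(sum(rr[win])), vars$true_logfc[i],
                 tolerance = 1e-9)
  }
})

test_that("planted strand conventions re-align under the assay shift", {
  # with bias on, the shifted coverage at the true cut base should match
  # the planted rate better than unshifted pooling
  sim <- small_sim()
  spec <- small_spec()
  rate <- sim$rate$rate$chr1
  shifted <- sim$track$counts$chr1
  raw <- build_coverage(sim$sites, sim$genome)$counts$chr1
  expect_gt(cor(shifted, rate), cor(raw, rate))
})
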