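# Shared fixtures, memoized across test files (one R process per run).
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# tiny architecture for fast unit tests (odd input so reverse-complement
# window math is exact in the strand-symmetry test)
tiny_cfg <- function(...) {
  cutnet_config(filters = 8L, conv_width = 21L, n_dilated = 2L,
                profile_width = 11L, input_len = 215L, output_len = 151L,
                ...)
}

tiny_model <- function(seed = 1L, cfg = tiny_cfg(), bias = 0) {
  with_seed(seed, init_model(cfg, count_bias_init = bias))
}

random_seq <- function(n, seed = 1L) {
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                        collapse = ""))
}

# small simulated experiment shared by track / region / simulator tests
small_spec <- function() {
  sim_spec(chrom_lengths = c(chr1 = 60000L, chr2 = 60000L, chr3 = 50000L,
                             chr4 = 50000L),
           n_peaks = 16L, n_decoys = 12L, depth = 2e5, seed = 42L)
}

small_sim <- function() memo("small_sim", simulate_experiment(small_spec()))

# compact trained fit for interpretation / variant property tests: a real
# two-stage fit on a small genome with a small architecture
prop_fit_bundle <- function() memo("prop_fit", {
  spec <- sim_spec(chrom_lengths = c(chr1 = 70000L, chr2 = 70000L,
                                     chr3 = 50000L, chr4 = 50000L),
                   n_peaks = 20L, n_decoys = 12L, depth = 3e5, seed = 11L)
  ex <- simulate_experiment(spec, variants = 24L)
  fold <- fold_spec(train = c("chr1", "chr2"), val = "chr3", test = "chr4")
  cfg <- cutnet_config(filters = 32L, input_len = 1114L, output_len = 500L)
  bcfg <- bias_config(filters = 16L)
  cand <- tile_genome(ex$genome, 1114L, 800L)
  neg <- gc_match_negatives(cand, ex$peaks, NULL, ex$genome,
                            multiplier = 2, seed = 3L)
  bf <- suppressWarnings(
    fit_bias(ex$genome, ex$track, ex$peaks, neg, fold,
             cfg = bcfg, motif_pwms = list(), max_epochs = 15L, seed = 5L))
  fit <- fit_cutnet(ex$genome, ex$track, ex$peaks, neg, bf, fold,
                    cfg = cfg, max_epochs = 25L, seed = 5L)
  list(ex = ex, fit = fit, fold = fold, negatives = neg, bias = bf)
})

# dinucleotide count table oracle
dinuc_counts <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}
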