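# cutnet

Bias-factorized, base-resolution models of chromatin accessibility
cleavage profiles, in R.

## What problem this solves, and for whom

ATAC-seq and DNase-seq read out chromatin accessibility through enzyme
cleavage (Tn5 transposition, DNase-I digestion), but the enzymes
themselves have strong intrinsic sequence preferences. At base
resolution those preferences dominate profile *shape* (while barely
affecting regional totals), so models, footprints and attribution maps
built on raw profiles confound enzyme artefacts with regulatory syntax.
`cutnet` is for regulatory-genomics analysts who want base-resolution
sequence-to-profile models whose footprints, contribution scores and
variant-effect predictions reflect regulatory signal rather than Tn5 or
DNase-I preference.

## The model

The observed cut-count profile over an output window is factorized as

```
p_pred_i  ∝  p_tf_i · p_bias_i            (profile; softmax of summed logits)
n_pred    =  n_tf + γ · n_bias            (log-scale count heads)
γ         =  exp( mean[ log(n_bias+1) − log(n_obs+1) ] )
```

where the **bias submodel** (width-21 conv + 4 dilated width-3 convs,
dilation doubling from 2; 81 bp receptive field) is trained only on
count-filtered, GC-matched background chromatin and then frozen, and the
**residual (TF) submodel** (same design, 8 dilated layers and a 1041 bp
receptive field at full scale) is trained on peaks plus background with
the loss

```
L  =  MNLL(k_obs | n_obs, p_pred)  +  λ · (log(1+n_obs) − log(1+n_pred))²,
λ  =  median(validation totals) / 10.
```

Disconnecting the bias submodel gives bias-corrected predictions; on top
of them the package provides DeepLIFT-style contribution scores against
dinucleotide-shuffled references, marginal footprinting with
height/width geometry, a corrected-vs-uncorrected bias audit, variant
scores (logFC, signed JSD, AAQ, IES, IPS, empirical p), and profile/
count evaluation metrics. A seeded simulator generates genomes with
planted enzyme bias, motif-driven accessibility and footprints so the
whole pipeline is testable offline. The convolutional network itself
(forward, backprop, Adam) is implemented in the package's compiled code;
no deep-learning framework is required.

## Worked example

A desk-scale run on simulated data (a few minutes on one CPU):

```r
library(cutnet)

spec <- sim_spec(chrom_lengths = c(chr1 = 70000, chr2 = 70000,
                                   chr3 = 50000, chr4 = 50000),
                 n_peaks = 20, depth = 3e5, seed = 11)
ex   <- simulate_experiment(spec, variants = 24)
fold <- fold_spec(train = c("chr1", "chr2"), val = "chr3", test = "chr4")

neg  <- gc_match_negatives(tile_genome(ex$genome, 1114, 800),
                           ex$peaks, NULL, ex$genome, multiplier = 2,
                           seed = 3)
bias <- fit_bias(ex$genome, ex$track, ex$peaks, neg, fold,
                 cfg = bias_config(filters = 16),
                 motif_pwms = lapply(spec$motifs, function(m) m$pwm),
                 seed = 5)
fit  <- fit_cutnet(ex$genome, ex$track, ex$peaks, neg, bias, fold,
                   cfg = cutnet_config(filters = 32), seed = 5)
fit
#> cutnet_fit (bias-factorized accessibility model)
#>   gamma 0.1148, lambda 514.800, best epoch 15 (val loss 3240.8516)
#>   fold: train chr1,chr2 | val chr3 | test chr4
#> cutnet_config: 32 filters, first conv 21 bp, 6 dilated layers (width 3, rates 2,4,8,16,32,64)
#>   input 1114 bp -> output 500 bp, receptive field 273 bp, count_mode=additive
```

`gamma` is the estimated scale between bias-model and observed totals;
the validation loss is the combined MNLL + λ·MSE objective per region.
Footprinting the enzyme's favourite 6-mer shows what correction does:

```r
bg <- background_library(ex$genome, ex$peaks, n = 50,
                         input_len = 1114, seed = 7)
marginal_footprint(fit, bias_top_kmer(spec$bias), bg, corrected = FALSE)
#> cutnet_footprint [GTGCAC]: height 0.009708, width 5, logFC 0.000
marginal_footprint(fit, bias_top_kmer(spec$bias), bg, corrected = TRUE)
#> cutnet_footprint [GTGCAC]: height 0.0001182, width 56, logFC 0.000
```

The uncorrected (factorized) model responds sharply to inserting the
enzyme's preferred 6-mer; disconnecting the bias submodel collapses
that response ~80-fold, to a noise-level ripple with no defined valley
— the enzyme preference lives in the frozen bias submodel, not in the
residual. `bias_audit()` runs this comparison over a panel of bias
k-mers and TF motifs and reports PASS/FAIL; `score_variants()` then
scores SNVs with the corrected model.

A command-line wrapper (`inst/scripts/cutnet`) exposes
`simulate | prep | fit-bias | fit | audit | footprint | attribute |
score-variants | evaluate` over the same functions.

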