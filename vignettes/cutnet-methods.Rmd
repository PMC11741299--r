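---
title: "Modelling base-resolution cleavage profiles with enzyme-bias factorization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling base-resolution cleavage profiles with enzyme-bias factorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

ATAC-seq and DNase-seq measure chromatin accessibility by counting where
an enzyme (the Tn5 transposase or DNase-I) cuts DNA. At base resolution
the observed cut-count profile is a product of two signals: the
regulatory state of the locus (accessibility, transcription-factor
footprints) and the enzyme's own intrinsic sequence preference, which
strongly distorts *profile shape* while having little effect on
*regional totals*. A model trained naively on observed profiles learns
the enzyme preference as if it were regulatory syntax; footprints and
attribution maps then report enzyme artefacts.

`cutnet` models the observed profile as an explicit factorization:

* a small **bias submodel** is trained only on background (non-peak)
  chromatin, where enzyme preference is essentially the only
  sequence-driven structure;
* a larger **residual (TF) submodel** is trained on peaks and background
  with the bias submodel frozen, predicting what the bias submodel
  cannot;
* the **bias-corrected** prediction is the residual submodel alone, with
  the bias submodel disconnected.

## Model

Both submodels share a sequence-to-profile architecture. A one-hot
encoded window (A=(1,0,0,0), C=(0,1,0,0), G=(0,0,1,0), T=(0,0,0,1);
N is an all-zero column) passes through a width-21 convolution, then a
stack of width-3 dilated convolutions whose dilation rate doubles each
layer starting at 2, with residual skip connections (each layer's ReLU
output is added to the previous layer's output, center-cropped to the
new length) in the style of the BPNet model family this design extends
— without the skips, the same data trains markedly worse. The
bottleneck feeds two heads: a width-75 transposed convolution producing
per-base profile logits (center-cropped to the output window), and a
global average pool plus dense layer producing the predicted
`log(1 + total counts)`. Both heads are initialized near zero so the
initial profile is uniform regardless of depth. The receptive field is
`21 + sum_l 2 * rate_l`: 1041 bp for the full-scale residual
architecture (8 dilated layers) and 81 bp for the bias architecture
(4 layers). `receptive_field()` computes this; dilation doubling from 2
is the only rate schedule consistent with both printed fields.

Given profile logits `f` and count head `n` from each submodel, the
factorized prediction is

* profile: `p_pred ∝ p_tf * p_bias`, realized as softmax of summed
  logits (the elementwise product of softmaxes, renormalized — an exact
  algebraic identity, asserted in the tests);
* counts: `n_pred = n_tf + γ * n_bias` on the log-count head scale
  (`count_mode = "additive"`, the default, reproducing the combination
  rule as written); a physically motivated alternative
  `log(exp(n_tf) + γ exp(n_bias))` is available as
  `count_mode = "logsumexp"`. Whether γ scales log or linear counts is
  genuinely ambiguous in the source description, which is why both are
  implemented and the literal reading is the default.

γ accounts for the difference between the bias model's total-coverage
scale (fit on background) and observed coverage:
`γ = exp(mean(log(n_bias + 1) − log(n_obs + 1)))` over training and
validation examples, computed once before residual training
("fit and scale"); no other bias calibration is learned.

### Loss

Training minimizes `MNLL + λ * MSE`: the multinomial negative
log-likelihood of observed per-base counts under the predicted profile
probabilities, plus the squared error between `log(1+n_obs)` and the
predicted log total. `λ = median(validation totals) / 10`
(`default_lambda()`). The bias model reuses the same λ rule on its
filtered background totals; the source only states the rule for the
factorized model, so this is an assumption, recorded here.

### Training procedure

Stage 1 (`fit_bias()`): negatives are GC-matched bins (2× the peak
count) filtered to totals at or below
`0.01-quantile(peak totals) × fraction`. Starting at `fraction = 0.8`
and decreasing (0.8, 0.6, 0.4, 0.2, 0.1), a bias model is trained and
audited: contribution scores over sampled peak regions are aggregated
into each region's top-|score| subsequence, which is log-odds scanned
against the supplied TF motif PWMs (threshold: 70% of each PWM's
maximum). Any match fails the check and lowers the fraction. This scan
is a deterministic, desk-scale stand-in for a de novo motif-discovery
audit, which is out of scope.

Stage 2 (`fit_cutnet()`): Adam (lr 0.001), peaks re-jittered each epoch
by a uniform offset (±500 bp at full scale, clamped so the summit stays
inside the output window — ±200 bp at the desk-scale window sizes), a
1:10 capped random subset of negatives fixed across epochs but
reshuffled in order, early stopping on validation combined loss with
patience 5 and best-weights restore, and an epoch cap of 100 as a
safety bound. The bias submodel's parameters are asserted bit-identical
before and after.

Four additional training choices matter at desk scale, where a few
hundred training regions replace the hundreds of thousands available at
full scale:

* **Reverse-complement augmentation** (`augment_rc`): every window is
  presented in a random orientation each epoch. Flipping base-resolution
  cut data is subtle: cuts sit *between* bases, so the mirror of cut
  position p lies at p+1 on the reverse strand. The flipped example
  therefore pairs the reverse-complemented sequence with the count
  window shifted +1 bp before reversal — the naive reversal is exactly
  1 bp misaligned, the same off-by-one that motivates the strand-shift
  alignment check, and with a sharp enzyme-bias field that single base
  is the difference between augmentation and data corruption.
* **Channel dropout** (`dropout`, desk default 0.3) on the ReLU branch
  of every dilated layer (the first convolution — the motif detectors —
  is spared). Without it the model memorizes a few hundred training
  sequences outright and validation loss diverges from the first
  epochs.
* **Passes per epoch** (`passes_per_epoch`): the early-stopping unit is
  the epoch, with patience 5; at desk scale one pass over the data is
  only a handful of optimizer steps, so each epoch makes several
  independently re-jittered, re-oriented passes to keep the patience
  criterion meaningful.
* **Count-head rate multiplier** (`head_lr_mult`): the count head sits
  behind global average pooling, which divides a localized motif
  activation by the bottleneck length; with a uniform learning rate the
  head cannot reach its working weight magnitude within a desk-scale
  step budget, so its parameters train at a higher rate.

The network itself (forward, backprop, dropout, Adam) is implemented in
compiled code under `src/`; there is no deep-learning framework
dependency, and training is deterministic given the seed on a fixed
BLAS.

## Interpretation

Contribution scores (`attribute()`) satisfy the completeness contract:
summed per-base contributions equal the mean difference between the
model's scalar output on the sequence and on 20 dinucleotide-shuffled
references (Euler-path shuffles preserving the dinucleotide multiset
exactly). The backend is the DeepLIFT Rescale rule propagated through
the network's linear/ReLU structure, which makes completeness exact to
float precision with one backward pass per reference; the contract, not
the algorithm, is the normative choice, and the 5% tolerance is
asserted in the tests. For the profile head, per-position contributions
are aggregated with stop-gradient weights equal to the predicted
probabilities (the scalar is `Σ_j p_j (f_j − mean f)`).

Marginal footprints (`marginal_footprint()`) insert a motif at the
center of GC-matched background sequences (replacement, even-length
motifs 1 bp left of center), predict counts-scale profiles for each
sequence and its reverse complement (flipping the latter), average over
the library, and compare with uninserted controls. The footprint vector
`M` is the motif library's probability profile scaled by the
exponentiated total-count log fold change versus control, then smoothed
with a width-5 moving average: the description's "identity filter of
width 5" is read as a moving average, since a literal identity kernel
would be a no-op and smoothing is the stated intent. The operation
order (probability × fold change, then smooth) is fixed here because
the source is ambiguous about it. Valley boundaries are the positions
of maximum gradient change on either side of the center, implemented as
the largest |second difference| with ties broken toward the center;
height and width follow the printed formulas
(`max(M[:rs], M[ls:]) − min(M[rs:ls])`, `ls − rs`). A flat profile is
reported as degenerate.

`bias_audit()` tabulates corrected/uncorrected footprint heights: bias
k-mers must drop below 10% of their uncorrected height while TF motif
heights stay within [0.8, 1.2] of uncorrected.

## Variant scoring

For a SNV, both alleles are substituted at the center of the input
window. Per fold: `logFC` is the difference of predicted log totals;
`JSD` the Jensen-Shannon divergence between the allelic probability
profiles with **natural** logs, signed by `sign(logFC)`; `AAQ` the
larger allele's empirical percentile (fraction ≤, in [0,1]) of
predicted log counts within the fold's peak distribution. Across folds
`IES = mean(logFC)·mean(JSD)` and
`IPS = mean(|logFC|)·mean(JSD)·mean(AAQ)`. Predictions are
strand-symmetrized (averaged with the flipped reverse-complement
prediction), which makes allele-swap antisymmetry exact and scoring
robust to strand. Note the deliberate base-convention split: variant
JSD uses natural logs; the evaluation metric `profile_jsd()` uses
base-2 logs so its range is [0, 1].

Empirical p-values come from a null of dinucleotide-shuffled reference
windows with the alleles re-inserted;
`p = (1 + #{null ≥ obs}) / (1 + n_null)` never returns zero. The
full-scale null uses 10^6 draws; the desk default is 10,000 and tests
use far fewer — the convention, not the resolution, is what is
asserted.

Enrichment of high-scoring variants among fine-mapped variants is
`Observed / Expected` over a (score, PIP) threshold grid, with
`Expected` = background rate of high scores among PIP≈0 controls times
the number of fine-mapped variants. The printed definition of the
expected count is typographically garbled in the source; this
background-rate reading is a documented interpretation.

## Evaluation

`count_metric()` is Pearson r between observed and predicted log1p
totals. `profile_jsd()` is the base-2 Jensen-Shannon divergence, whose
range matches the printed 0–1 without a square root (the square-root
variant would also lie in [0,1]; the divergence form is fixed and
documented). `jsd_baselines()` provides pseudoreplicate (random 50/50
read splits), mean-profile and shuffled-profile reference
distributions. `label_bins()` labels 100 bp bins positive (fully inside
IDR summit ± 100 bp), ambiguous (partial IDR overlap; overlap-peak
overlap; blacklist overlap; <50% uniquely mappable — skipped with a
warning when no mappability track is supplied), or negative, with
reason codes; `genomewide_classification()` scores bins by the max
(optionally mean) predicted log count over 250 bp-stride windows and
reports AUROC/AUPRC over positive vs negative bins.

## The simulator

`simulate_experiment()` generates the ground truth every stage is
tested against: i.i.d. sequence at a target GC; 400 peaks per 2 Mb
carrying one planted motif instance each (sampled from the motif PWM
conditional on scoring above the match threshold) whose center is the
summit — a testbed density of one peak per 5 kb, deliberately denser
than the genome-wide average, because a peak-trained model needs enough
training examples for the training stage to be testable at all; decoy
near-miss instances in background (one worst-base substitution off
consensus, restorable by a "motif-creating" variant); a hand-set
reverse-complement-palindromic 6-mer cleavage preference scaled to a
target log-sd (strong enough to dominate profile shape, learnable by a
small model); and multinomial read sampling at exact depth, with
strands recorded under the assay's shift convention so `shift_cuts()`
re-aligns them.

The true rate is `accessibility × exp(bias) × protection`:
accessibility is a constant background plus a Gaussian bump
(σ = peak width / 6, truncated at 4σ) per scanned motif match;
protection is a raised-cosine valley across each match with depth 0.15
(deep), 0.45 (moderate) or 0.75 (shallow). Because accessibility is
driven by scanning the sequence, substituting a base re-shapes the
field, which defines exact variant ground truth; the 4σ truncation
makes the emitted local computation equal a full-genome rebuild
exactly. Variant labels are assigned by construction and verified
against the recomputed truth.

What the simulator does **not** emulate: paired-end fragment-length
structure, nucleosome positioning, copy-number and mappability
artefacts, replicate structure, or single-cell sparsity. Passing tests
therefore demonstrate that the implementation recovers planted
structure under the stated generative model, not that it reaches any
particular accuracy on real ENCODE-scale data.

## Numerical choices and problem sizes

* Coordinates are 0-based half-open (BED) throughout; summits are
  offsets from region starts.
* GC matching uses 0.01-wide bins over the full interval; intervals
  with >5% N are excluded; empty peak GC bins borrow from the nearest
  non-empty bin, logged.
* The 0.99 peak-count filter uses the linear-interpolation sample
  quantile (`type = 7`).
* The desk-scale residual architecture is 32 filters and 6 dilated
  layers (273 bp receptive field) over a 1114 bp input and 500 bp
  output; with only 4 dilated layers the 81 bp receptive field cannot
  relate a central motif to the several-hundred-bp accessibility bump
  around it, which in practice forces the optimizer into memorizing
  training sequences. The bias submodel keeps its specified 4-layer,
  81 bp architecture (32 filters at desk scale); the full-scale
  512/8/2114/1000 configuration is available via `paper_config()`. The
  Results-level claim of a ~100 bp bias receptive field is inconsistent
  with the bias architecture itself, which yields 81 bp; the
  architecture is implemented as specified.
* The test suite exercises the full pipeline on a 2 Mb genome with 400
  peaks and 2M reads (the simulation benchmark; the factorized model
  trains for up to 35 epochs of 8 passes there), smaller genomes for
  unit properties, and a ~30 kb-per-chromosome micro pipeline for CLI
  determinism; these sizes are the package's chosen desk-scale study
  conditions.
* All randomness flows through explicit seeds (R's RNG); compiled code
  is deterministic.

## Known limitations

* SNVs only in variant scoring; indel window re-centering is future
  work.
* Training is CPU-oriented; the full-scale architecture on
  ENCODE-sized data is out of reach without accelerator support.
* The contamination audit relies on a supplied motif library rather
  than de novo discovery; a motif absent from the library cannot fail
  the audit.
* bigWig IO is supported through `rtracklayer` where the platform
  allows; bedGraph is the canonical text format.
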