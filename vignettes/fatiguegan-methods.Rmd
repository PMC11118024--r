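---
title: "Detecting driver fatigue from EEG with an attention-based auxiliary-classifier GAN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting driver fatigue from EEG with an attention-based auxiliary-classifier GAN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Drowsiness at the wheel shows up in the EEG long before behaviour degrades:
alpha (8–14 Hz) and theta (4–8 Hz) rhythms strengthen while beta and gamma
activity recedes. A practical fatigue monitor therefore needs (i) a feature
representation that keeps the frequency, spatial and temporal structure of
multi-channel EEG together, (ii) a classifier that exploits all three, and
(iii) a way to cope with the chronic scarcity of labelled EEG, for which
conditional generation is an attractive augmentation strategy. `fatiguegan`
implements all three pieces and a seeded synthetic-EEG module so the whole
pipeline is testable without access to a driving-vigilance recording
campaign.

Ground truth is PERCLOS, the fraction of an 8-second observation window the
eyes are closed: `PERCLOS = eye_closure_time / total_observed_time`. Windows
with PERCLOS below 0.35 count as awake, at or above 0.35 as fatigued, and a
ternary scheme adds drowsy at 0.7. Values landing exactly on a threshold go
to the more fatigued class by default; both conventions are supported
because boundary handling differs between datasets
(`label_from_perclos(strict = )`).

## From raw EEG to 4D feature tensors

A recording is trimmed (a minute at each end by convention, where electrode
settling and task transients live), resampled to 200 Hz, and cut into
non-overlapping 8-s segments, one per label window; the trailing remainder
is discarded. Resampling is performed in the frequency domain — the spectrum
is truncated at the new Nyquist frequency, an ideal anti-aliasing guard —
because the polyphase resampler available to us showed percent-level ripple
on pure tones, which would leak into the band-power features.

Each segment is band-passed into the five canonical bands δ(1–4), θ(4–8),
α(8–14), β(14–31) and γ(31–51 Hz) with an order-4 Butterworth filter applied
forward and backward (zero phase). The two-pass magnitude response is
evaluated on the FFT grid and applied spectrally, which filters a whole
17-channel segment with two FFTs per channel and is exact for the periodic
extension; the test-suite cross-checks it against a direct
`signal::filtfilt()` pass away from the segment edges. Band edges are
half-power (−3 dB) corners. Filtering happens *before* the segment is cut
into its sixteen half-second frames so the 100-sample frames carry no filter
transients.

The per-frame feature is differential entropy,
`DE = −∫ f(x) log f(x) dx`. For a band-limited frame modelled as Gaussian
this has the closed form `½·log(2πe·σ²)`, estimated from the frame sample
variance — the established practice for DE features on band-passed EEG,
with the general integral kept as a quadrature oracle in the tests. A
variance floor of 1e−12 inside the logarithm guards degenerate frames (a
flat-lined channel yields a large negative entropy and a warning rather
than −∞).

The channel dimension is then spatialised: each of the 17 electrodes (the
10–20 montage FT7/FT8, T7/T8, TP7/TP8, CP1/CP2, P1/PZ/P2, PO3/POZ/PO4,
O1/OZ/O2 — CPZ is the reference) is placed on a 6 × 9 grid, rows running
front to back and columns left to right; unused cells are zero everywhere
and stay zero through the whole pipeline, an invariant the tests check on
random inputs. The exact cell assignment is data, not code: it ships as an
editable CSV (`write_grid_csv()`), and a sparse 9 × 9 variant exists for
ablation against the dense default. One segment becomes an
`h × w × d × 2T = 6 × 9 × 5 × 16` tensor.

Datasets are standardised by z-scoring the mapped cells with one global
mean and standard deviation (`scale_features()`); unmapped cells are
untouched so the zero-padding invariant survives. No within-segment
normalisation is applied before the entropy step — the entropies themselves
carry the class signal, and an extra normalisation would remove the
band-level shifts the classifier relies on.

## The network pair

Both networks share three building blocks, all operating per half-second
frame with shared weights (temporal mixing is delegated to the Transformer).

**Spatial and frequency attention.** The spatial branch compresses the band
axis with a 1 × 1 convolution and gates every (row, col, frame) cell through
a sigmoid; the frequency branch pools the grid globally to 1 × 1 × 5, passes
two pointwise layers (5 → 2 → 5, ReLU6 between) and gates each band. The two
gated tensors are averaged, so gates saturated at one reproduce the input
exactly — the identity configuration the tests exercise. Gating is
multiplicative, following squeeze-excitation practice.

**Inverted bottleneck residual blocks.** Pointwise expansion to `k`·C
channels (ReLU6), 3 × 3 depthwise convolution at stride 1 with same padding
(ReLU6), and a linear pointwise projection; a residual connection is added
when input and output widths match. The expansion factor defaults to
`k = 2`: with the documented widths this puts the classifier's forward pass
at ≈ 0.21 GFLOPs (`count_flops()`), the complexity budget this architecture
is designed to; `k = 6` would roughly triple it without changing any shape
contract. Eight blocks form each trunk, accounted as expansion (1) +
halving (1) + branch A (1) + branch B (2) + tail (2) + fusion (1), with the
two branches merged by elementwise addition.

**Transformer encoder.** The sixteen 64-dimensional frame tokens pass two
pre-norm blocks of 4-head self-attention and a GELU MLP (hidden width 128),
each sub-block wrapped in a residual connection with dropout 0.1. A learned
positional embedding is added first; without it the encoder is exactly
token-permutation-equivariant, a property the tests use. Self-attention for
a whole minibatch is computed in one matrix product per head with
cross-sample scores masked to −∞, so samples never mix.

The **discriminator** runs attention → bottleneck trunk
(5 → 128 → 64 → branches → 48 → 32) → 3 × 4 average pooling (6 × 9 → 2 × 2,
the only pooling stage, keeping spatial information elsewhere) → a 64-node
fully connected map to the token sequence `Q ∈ R^{64×16}` → Transformer →
mean-pooled tokens feeding two linear heads: an unbounded Wasserstein critic
scalar and a softmax class head. The **generator** embeds `[z, one-hot
label]` (z of length 64) linearly into 16 tokens, refines them with the
Transformer, expands token features through a transposed convolution from a
2 × 2 coarse grid to 6 × 9 (kernel 3 × 5, strides 3 × 4 — any stack meeting
the shape contract is admissible; this is the minimal one), applies the
attention module and a mirrored eight-block trunk whose two concluding
blocks reduce the channels back to the five bands.

Two generator details matter in practice. Generated tensors must satisfy
the same invariant as real ones — unmapped grid cells exactly zero — so the
output is masked by the electrode grid; without the mask the critic wins
immediately by reading the off-grid cells and adversarial training
destabilises. And the conditioning label receives a direct per-band output
bias (class differences in entropy features are, to first order, band-level
shifts), alongside the usual concatenated-input conditioning; the trunk's
final projection starts at a tenth of its He scale so early samples sit
near zero in the standardised feature space.

## Losses and optimisation

The critic is trained with the Wasserstein objective under a gradient
penalty: for mixes `x̂ = ε·x_real + (1−ε)·x_fake` (ε uniform per sample),

```
L_D = −( E[D_adv(x)] − E[D_adv(G(z,c))] ) + λ_gp · E[(‖∇_x̂ D_adv(x̂)‖₂ − 1)²]
      + λ · E[−log D_cls(c′ | x)]
L_G = −E[D_adv(G(z,c))] + λ · E[−log D_cls(c | G(z,c))]
```

with λ = 1 and λ_gp = 10. The penalty term enters the critic's loss with a
positive sign — it is a constraint on D, not a reward — and the loss-bundle
identity tests pin this composition exactly. The classification term for D
uses real samples only; whether generated samples should also feed it is
genuinely open, so it is the default-off choice here. Optimisation is AdamW
(decoupled weight decay 0.02 on weight matrices, not on biases, gains or
embeddings) at learning rates 1e−4 (generator) and 3e−4 (discriminator),
batch 150, one critic step per generator step — all defaults of
`train_config()`; desk-scale runs below override them.

The whole model is differentiated by a small reverse-mode tape
(`R/autodiff.R`) whose primitives register vector-Jacobian products built
from the same primitive set, so the input gradient inside the penalty is an
ordinary tape node and the penalty's *parameter* gradient (double backprop)
is exact — verified against central finite differences, including through
the fused C++ depthwise-convolution kernels. ReLU6 contributes a piecewise-
constant Jacobian whose second-derivative terms vanish almost everywhere;
sigmoid, softmax, layer-norm and GELU (realised as `x·σ(1.702x)` to stay
inside the primitive set) propagate curvature exactly. Every source of
randomness — latents, mixing weights, dropout, shuffles, folds — draws from
the seeded R RNG, so training trajectories are bitwise reproducible.

## Evaluation

Classification is scored by accuracy, precision, recall, F1 and Cohen's
kappa from the contingency table (binary metrics refer to the fatigue
class; multiclass versions macro-average). Kappa is cross-checked against
`e1071::classAgreement()` on random label vectors.

Similarity between signal sets uses wavelet coherence: with `C_x(a,b)` the
continuous wavelet transform, `wc = |S(C̄_x·C_y)|² / (S|C_x|²·S|C_y|²)`,
valued in [0, 1] per (scale, time) cell. The wavelet is the analytic Morlet
(ω₀ = 6) on 32 logarithmic voices spanning periods from 4 samples to n/4;
the smoothing operator S is a boxcar in time of width proportional to scale
plus a 3-voice boxcar across scales — without smoothing the expression is
identically 1. The matrix collapses to a scalar by averaging along time and
then across scales, keeping the score length-independent and readable as a
percentage; multi-channel signals average over channels, and two groups
average over all cross pairs. Self-coherence is 1 to machine precision,
the measure is symmetric, and independent noise pairs score strictly below
self pairs across seeded trials — the property suite the package treats as
the metric's contract.

When the compared objects are feature tensors rather than raw signals, a
reduction to time series is needed. Per-band frame courses are only 16
samples long — below the transform's 32-sample minimum — so the default
reduction (`feature_profile()`) traces each mapped electrode's five band
entropies frame by frame into an 80-sample series. The reduction is a
plain exported function and deliberately pluggable.

## The synthetic-EEG module

`synth_config()` emulates the structure the pipeline expects from a
vigilance recording: 17 channels at 200 Hz, one class per 8-s window, five
band-limited oscillations per window realised as narrowband-filtered noise
(pure sinusoids would give near-degenerate frame variances), pink 1/f
background plus a white floor, and a paired eye-closure stream. The default
class profiles encode the conventional drowsiness signature — fatigue
triples alpha amplitude, doubles theta and roughly halves beta and gamma
relative to awake, with a 1.5× posterior alpha gain — making the two classes
strongly separable by design: a linear classifier on band-power features
exceeds 0.95 accuracy, which is the point of a fixture meant to certify the
learning machinery rather than the difficulty of real EEG. Per-window
closure fractions draw from Beta(2, 18) (awake) and Beta(9, 3.5) (fatigue),
each placing ≈ 0.3% of windows on the wrong side of the 0.35 threshold, so
embedded PERCLOS labels agree with the requested classes in over 99% of
windows.

What the generator does *not* emulate — ocular and muscle artifacts,
nonstationary drift, inter-subject variability, realistic cross-channel
covariance, label noise beyond the Beta tails — bounds what green tests
mean: they certify the pipeline's mechanics and learning behaviour on
clean, separable signals, not performance on real driving EEG.

## Augmentation experiments

Generated samples are filtered by classification confidence: a sample is
kept when its maximum class probability from the discriminator's class head
is at least 0.90 *and* the predicted class matches the conditioning label —
the agreement requirement extends the plain threshold rule, since a
confidently mis-classified sample would otherwise enter the training set
under the wrong label. Retention is monotone in the threshold by
construction.

The mixing experiment trains a fresh classifier per scenario — purely real,
purely synthetic, few real (20% of the total; "few" is not quantified in
the source conventions, so it is a configurable default), and few real
topped up to the full total with selected synthetic samples — on a common
held-out real test set. The three full-size scenarios share the same
aggregate volume; `few_real` is deliberately smaller, being the scarce-data
regime the hybrid is meant to rescue. When the confidence filter keeps
fewer samples than the scenarios need, the shortfall is topped up with the
highest label-consistent-confidence remainder so scenario sizes stay exact.
Scenario orderings are reported, never enforced.

## Scaled-down study sizes

Everything above runs at two scales. The `full` profile (widths
5→128→64→32, 64-dim tokens, two Transformer blocks) is used for shape
contracts, the FLOP audit, gradient-flow checks and single forward passes.
Training-scale experiments use the `compact` profile — the same architecture
at widths 5→16→8→4 with 16-dim tokens and one Transformer block — because a
desk-scale CPU run of the full-width model would take hours where the
compact one takes minutes. The package's standing benchmark settings are:
400 windows (200 per class) with five-fold stratified cross-validation,
five epochs, batch 20, learning rate 1e−3 for the classifier; 150–300
adversarial steps at batch 16 and symmetric rates 5e−4 for GAN runs; mixing
totals of 60 with threshold 0.7 and 3 epochs per scenario. Fold metrics
follow the best-test-epoch convention (flagged as optimistic;
`selection = "holdout"` provides the conservative alternative).

## Known limitations

Desk-scale adversarial runs match the marginal feature distribution but
condition weakly: a few hundred small-batch steps are one to two orders of
magnitude less optimisation than a full training campaign, and the
generated samples' class separation relies substantially on the conditional
output bias and the confidence filter. The spectral filter and resampler
assume periodic extension, so a few samples at segment edges deviate from a
direct time-domain pass (framing after whole-segment filtering keeps this
out of the features). Checkpoint selection on the test fold inflates
cross-validated scores slightly by construction. None of these affect the
deterministic feature arithmetic, the loss identities, or the coherence
metric's contracts, which is where the package's guarantees live.
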