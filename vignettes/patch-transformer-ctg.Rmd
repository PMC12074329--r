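---
title: "Patch-transformer classification of antepartum CTG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-transformer classification of antepartum CTG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ctgpatch)
```

This vignette is the package's own account of what it computes and why:
the classifier and its assumptions, the synthetic data it is exercised on,
the numerical conventions, and the design decisions that were genuinely
open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The classification problem

An antepartum cardiotocograph records two channels: fetal heart rate (FHR,
beats per minute) and relative uterine tone (TOCO, 0–100). The clinical
question addressed here is binary: does a one-hour recording, taken up to a
week before delivery, come from a pregnancy that will end in an adverse
outcome? The package represents a recording as a `ctg_trace` (raw scale,
with `-1` marking dropped samples) and a model input as a `2 × 960` window
on the unit interval with an explicit per-sample validity mask — 960 steps
covering one hour, i.e. one sample per 3.75 s.

## The model

Each channel is encoded independently ("channel independence"): FHR and
TOCO have different dynamics, and fusing them only at the classification
head prevents one channel's scale or artefacts from contaminating the
other's representation. Per channel:

**Instance normalisation.** `x̃ = (x − μ)/(σ + 1e−8)`, with μ and σ (the
*population* SD) computed per sequence from observed samples only, at
training and at inference alike. This removes the patient-specific baseline
and amplitude — between-patient distribution shift is the dominant nuisance
in clinical time series. The important modelling consequence: a class
difference in raw variability *amplitude* is largely erased; what survives
is waveform *shape* (decelerations, accelerations, the texture of
variability relative to its own scale). Masked positions are set to exactly
0 (the post-normalisation mean) so they cannot leak information.

**Patching.** Patch `j` covers input indices `[jS, jS + P)` (0-based,
half-open; the patch count is `N = ⌊(L−P)/S⌋ + 1`). With the tuned
`P = S = 16` a window becomes 60 non-overlapping tokens; `S < P` would give
overlapping tokens. A patch is *valid* iff at least half its samples are
observed — a 50% threshold keeps attention focused on tokens that carry
real signal while tolerating the bursty dropout that CTG transducers
produce.

**Embedding.** `e_j = W_P p_j + W_pos[j]` with `W_pos` a *learned* `N × d`
table, initialised from N(0, 0.02²), one per channel. A learned table was
chosen over a sinusoidal code because the position count is small and fixed
(60) and the notation of the underlying method names a parameter matrix;
per-channel tables follow from the channel-independence reading.

**Encoder stack.** Each of `n_layers` layers applies multi-head
self-attention (`softmax(QKᵀ/√d_k)V`, `d_k = d_model/n_heads`) followed by a
position-wise feed-forward network (`d_model → d_ff → d_model`, ReLU by
default), each wrapped in a post-norm residual: `LN(x + Sublayer(x))`.
Masking: invalid tokens receive −∞ attention scores as keys (exactly zero
weight after the softmax) and contribute zero context as queries. Attention
rows over valid keys therefore always sum to one, and the output is a
function of observed samples only — both properties are asserted by tests.

**Pooling and head.** Valid tokens are averaged per channel
(`g = Σ e_j / N_valid`); the two summaries are concatenated, FHR first, and
a single dense unit with a sigmoid yields the adverse-outcome probability.
Concatenation (head input `2·d_model`) was chosen over summation so the
head can weigh the channels asymmetrically. Training minimises the standard
binary cross-entropy `−[y log ŷ + (1−y) log(1−ŷ)]`.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_layers` | 6 | encoder depth (search grid 3–6) |
| `n_heads` | 4 | attention heads; must divide `d_model` |
| `d_model` | 512 | token width |
| `d_ff` | 128 | feed-forward hidden width |
| `dropout` | 0.1 | after patch embedding and inside the FFN |
| `attn_dropout` | 0.2 | on attention weights |
| `fc_dropout` | 0.4 | before the classification head |
| `patch_len`, `stride` | 16, 16 | patch geometry (steps) |
| `activation` | ReLU | FFN non-linearity (ReLU/GELU/ELU) |
| `kernel_size` | 15 | optional input-smoother width, **off** by default |

The defaults are the tuned operating configuration for the 960-step task.
The three dropout rates have standard placements; only the rates themselves
are tuned quantities. `kernel_size` deserves a note: the tuned parameter
set names a kernel width with no architectural slot attached to it. It is
interpreted here as an optional per-channel moving-average input smoother
(same-padded, renormalised over observed neighbours, *not* trained),
applied after instance normalisation and before patching, and it is
disabled by default; enabling it (`smooth_input = TRUE`) is a config
switch. The FFN activation is likewise configurable because the
architecture's description names GELU while the tuned value is ReLU — the
configured value wins.

### Numerical conventions

* ε = 1e−8 in the instance-norm and layer-norm denominators; probabilities
  clamped to [1e−7, 1 − 1e−7] inside the loss.
* All patch indices are 0-based with half-open intervals.
* Gradients are analytic (reverse-mode, written out layer by layer) and are
  verified against central finite differences to ~1e−6 relative error in
  the test suite. Optimisation is Adam (β = 0.9/0.999, ε = 1e−8) — the
  optimiser was an open choice; Adam with the tuned learning rate 1e−4 is
  the field's default for transformer training.
* Degenerate inputs fail loudly: an all-missing channel, a window with no
  valid tokens, or attention with no valid keys raise classed errors rather
  than returning numbers.
* Evaluation-mode forward passes are deterministic (dropout is
  training-only); two calls agree bitwise, which the suite asserts.

## Preprocessing pipeline

`clean_channels()` clips observed FHR into [50, 250] bpm and TOCO into
[0, 100] — clipping, not discarding, is the least destructive reading of
"adjusting" a signal into its physical range; marking out-of-range samples
missing instead is available by pre-masking them. `scale_unit()` maps FHR
by `(x−50)/200` and TOCO by `x/100` and converts the `-1` sentinel into
explicit masks (the sentinel exists only in raw files). `quality_filter()`
excludes traces missing strictly more than 30% of their samples, assessed
jointly over both channels (per-channel assessment is a one-line variant;
the joint reading was chosen and is flagged in the function's docs).
`windowize()` cuts 960-step windows from the *end* of the trace backwards,
so the delivery-proximal hour is always a complete window; a leading
remainder is kept as a right-padded window iff it has ≥ 480 fully observed
steps (50% — prevents near-empty padded windows while keeping every trace
that passed the 30% filter eligible), otherwise it is dropped. Every
observed sample lands in exactly one window or the dropped remainder.

`split_cohort()` implements the 80–20 split with the floor rule
(`⌊0.8·N⌋` training ids, per-stratum floors topped up by largest fractional
remainder): 20,589 ids yield exactly 16,471/4,118, which the acceptance
script recomputes. Stratification by label is the default; the reference
protocol states only the ratio.

`propensity_match()` fits a logistic propensity model, then greedily pairs
cases (descending propensity) with their nearest unused control on the
logit scale, optionally under a caliper expressed in logit SDs. SMD uses
the two-group pooled form `|μ₁−μ₀|/√((s₁²+s₀²)/2)` with sample variances —
the conventional balance diagnostic; the balance flag requires all
post-match SMDs < 0.10. Note that 1:1 matching without replacement can only
improve balance when the control pool is larger than the case list; the
synthetic cohorts used in tests draw controls from a 3× pool for exactly
this reason. On degenerate matched sets (a single pair) the SMD is
undefined and reported as `NA`.

## The synthetic generator

No public CTG corpus ships with this package, so `simulate_cohort()` is a
first-class module that emulates the statistical structure the classifier
assumes: a slowly wandering FHR baseline (clamped at ±2.5 baseline SDs — a
quiet trace must stay inside the clinical band), band-limited short-term
variability, transient accelerations (≥ +15 bpm, 15–40 s), decelerations
(20–35 bpm dips, 30–60 s) that are either spontaneous or time-locked ~15 s
after a contraction peak, smooth unimodal contraction bumps on TOCO, and
bursty dropout from an alternating-renewal process whose stationary missing
fraction and mean burst length are the two calibrated quantities. Defaults
— baseline 135 ± 8 bpm, variability 6 bpm, 8 accelerations/h, 2
decelerations/h, 10 contractions/h, coupling 0.5, 10% missingness in
20-sample bursts — are ordinary values for a term antepartum recording.

The adverse class is planted with a single severity multiplier `m < 1`
(default 0.5): variability and acceleration rate are multiplied by `m`, the
deceleration rate divided by it. Because instance normalisation removes
amplitude, the learnable signal is the changed *shape* composition —
deceleration-dominated, acceleration-poor traces — which is also the
clinically meaningful direction. Cohort metadata adds days-to-delivery
(uniform on a configurable 1–7 range) and four matching covariates
(gestational age, maternal age, BMI, parity) with ~0.4–0.5 SD
label-correlated shifts so that propensity matching is nontrivial.

What the generator does **not** emulate: genuine non-stationarity within a
trace (sleep cycles, medication effects), device-specific noise spectra,
autocorrelated TOCO–FHR physiology beyond the simple coupling, or label
noise. Passing tests on these cohorts therefore demonstrates that the
pipeline is implemented correctly and can learn a planted shape signal —
not that the architecture attains any particular performance on real
antepartum data.

## Training protocol

`train_model()` shuffles per epoch, steps Adam on mean-BCE mini-batches
(default 48), computes the validation AUC after every epoch and stops when
it has not *strictly* improved for `patience` (default 10) consecutive
epochs — ties do not reset patience, and the returned checkpoint is always
the best-AUC epoch's parameters, never a later one. The stopping rule is
factored into `early_stop_scan()` so it can be tested on scripted AUC
streams. `pretrain_finetune()` implements the temporal protocol: train from
scratch on the 3–7-days-to-delivery stratum, then continue — all parameters
updated, no freezing, since nothing in the protocol calls for freezing — on
the 0–2-day stratum with its own early stopping. Validation AUC is computed
over whole-window probabilities; per-trace aggregation over multiple
windows is deliberately left out of the default path.

`hpo_search()` samples the published grids (depth 3–6, heads {4,8,16,32},
widths up to 640, dropouts on [0.1, 0.5], learning rates 1e−6…1e−3, batch
16–64, patch 4–32, stride 4–16, three activations), resamples invalid
combinations (width not divisible by heads) *before* any training, budgets
each trial at 60 epochs / patience 10, and returns the argmax trial. The
sampler is pluggable — uniform random is built in; a Bayesian optimiser can
be plugged behind the same `function(space, seq_len) -> config` interface —
because re-implementing a TPE sampler is explicitly out of scope.

## Evaluation

`roc_curve()` enumerates thresholds at every distinct score (plus an `Inf`
sentinel) under the rule *positive iff score ≥ threshold* — the same closed
rule everywhere, including the default 0.5 cut. The trapezoidal AUC over
this curve equals the tie-corrected Mann–Whitney statistic; both routes are
implemented and asserted equal to 1e−12 against each other and against a
brute-force pairwise oracle. `youden_threshold()` maximises
J = sensitivity + specificity − 1 by exhaustive scan, breaking ties toward
the *higher* threshold — the more specific operating point, i.e. fewer
false alarms, which is the sensible clinical default when J is flat.
High-sensitivity and high-specificity operating points take a configurable
floor (default 0.90 each — the protocol names these points without
numbers): the highest threshold with sensitivity ≥ target, and symmetrically
the lowest with specificity ≥ target. Zero-denominator metrics (PPV with no
predicted positives, etc.) are `NA`, never a silent 0. `temporal_sweep()`
evaluates controls plus the adverse cases within each days-to-delivery
bound d = 1…7, flagging (not dropping) rows whose adverse subset is empty.

## Problem sizes in the test suite

The suite exercises the full architecture at reduced scale, a deliberate
choice to keep the feedback loop tight: component contracts run on 24–96
step windows with 8–16-dimensional models; the end-to-end check trains a
2-layer, 2-head, `d_model` 64 transformer on 400 one-hour windows from
strongly separable cohorts (severity 0.5) for 4 epochs at learning rate
1e−3, and requires a held-out AUC ≥ 0.90 as the median over 3 seeds. The
gradient implementation is validated by finite differences at every
parameter class, which is what licenses trusting the small-scale training
results.

## Known limitations

* Pure-R training: practical for the test-scale models; a 6-layer,
  512-wide production fit on tens of thousands of windows would want a
  compiled backend.
* No calibration analysis and no confidence intervals on AUC.
* The matched-cohort workflow assumes the control pool is larger than the
  case list; equal-size pools pass through matching unchanged.
* Synthetic realism is bounded as described above; claims about real CTG
  performance are out of scope.
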