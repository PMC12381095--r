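---
title: "Models and methods behind retrocue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retrocue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrocue)
```

`retrocue` simulates and analyses a three-phase memory experiment that
combines episodic long-term memory with a working-memory retro-cue task.
Participants first learn object–location associations (encoding), then see
pairs of those objects again in a retro-cue working-memory task where some
objects are attentionally prioritized and/or tested (working memory), and
finally report every object's location from long-term memory (retrieval).
The package provides the full inference machinery for such designs — trial
scheduling, ERP cluster statistics, multivariate location decoding, and the
behavioural statistics battery — together with a synthetic-data generator
that reproduces the statistical structure those analyses assume, so every
stage can be validated end to end without any recorded data.

This vignette documents the models, the tunable parameters, the numerical
choices, and the design decisions that were genuinely open.

## The paradigm and its scheduler

### Conditions

Objects are randomly partitioned into conditions that describe what happens
to them in the working-memory phase:

* `PT` (prioritization + testing): always the cued, tested object.
* `NP` (non-prioritization): shown and maintained but never cued.
* `NPT` (non-prioritization + testing, four-condition designs only): shown
  under an uninformative *neutral* cue, so it must be maintained and is
  tested, but never prioritized.
* `ABS`: encoded and retrieved, but absent from working memory.

Experiment 1 uses `{PT, NP, ABS}` in equal thirds of 180 objects;
Experiment 2 uses all four conditions in equal quarters of 300 objects.

### Location balance

Each object keeps one of four screen locations (`top`, `bottom`, `left`,
`right`) across all phases. Locations are balanced exactly across the full
object set. Within conditions we additionally balance them as far as the
arithmetic allows: exactly for Experiment 1 (60 per condition divides by 4),
and within ±1 for Experiment 2 (75 per condition does not). This
within-condition balance is a deliberate design choice: location is the
decoded variable and condition the ERP variable, and an imbalance would
confound one with the other. The ±1 remainders are allocated by a cyclic
scheme over the axis-alternating order (left, top, right, bottom) in which
`PT` and `NP` take adjacent shifts, which makes their horizontal/vertical
counts complementary — a requirement, because every selective working-memory
trial displays one object on each axis.

### Working-memory trials

Every working-memory-eligible object appears exactly four times. Selective
trials pair one `PT` with one `NP` object across axes and cue the `PT`
object's axis; with four appearances per object the pairing yields
`4 × n_PT` selective trials (240 for Experiment 1, 300 for Experiment 2).
Neutral trials pair two distinct `NPT` objects, consuming `4 × 75 / 2 = 150`
trials, for 450 working-memory trials in the four-condition design. Because
an odd number of `NPT` objects sit on each axis, neutral pairs cannot all
straddle both axes; since the neutral cue carries no axis information, the
scheduler only guarantees that the two objects differ and records which one
occupied the horizontal position.

Probe kinds use *exact* randomized-block counts rather than Bernoulli
sampling, so the designed proportions hold in every realized schedule:
selective trials are probed with the cued object on 50% of trials, the
non-cued object on 25% and a new object on 25%; neutral trials are probed
with one of the two displayed objects (chosen uniformly) on 50% of trials
and a new object otherwise. Both rules make "no" the correct response on
exactly half the trials of each cue type. New-object probes draw from a
reserved pool of identities never used at encoding, so "new" is
unambiguous. The uniform choice of the displayed probe is what produces the
natural 0/1/2 distribution of *probing counts* — how often an object served
as the central probe — which is the grouping variable of the probing
analysis (`count_probe_instances()`).

## The synthetic-data generator

Each participant's epoched EEG is built as a sum of three components:

$$
x_{itc}(t) \;=\; a_{\mathrm{loc}}\, p^{(\phi)}_{c,\ell(i)}\, e_\phi(t)
\;+\; a_{\mathrm{on}}(\mathrm{cond}_i)\, w_c\, e_{\mathrm{on}}(t)
\;+\; \varepsilon_{itc}
$$

* **Location patterns.** For each phase $\phi$ a `channels × 4` matrix of
  orthonormal spatial patterns is drawn, one column per location. Patterns
  are constructed as $\sqrt{\rho}\,\mathbf{s}_\ell +
  \sqrt{1-\rho}\,\mathbf{u}^{(\phi)}_\ell$ from one common orthonormal
  basis, so within a phase the Gram matrix is exactly the identity and the
  cosine similarity between a location's patterns in two phases is exactly
  $\rho$. $\rho = 1$ models a single shared representational format across
  phases, $\rho = 0$ a completely phase-specific one; the default is 0.8,
  a strongly shared format with some phase-specific structure. The
  construction needs `n_channels >= 16` (4 locations × (3 phases + 1 shared
  basis)).
* **Temporal envelopes** are half-cosines over each phase's signal window
  (encoding 60–1000 ms, working memory 70–1460 ms, retrieval 330–1360 ms by
  default). Only the windows are empirically motivated; the smooth
  symmetric envelope is the simplest shape with no onset/offset
  discontinuities.
* **Old/new component.** At retrieval a positivity with weight 1 on the
  left-parietal cluster (`Pz`, `P1`, `P3`, `P5`) and Gaussian falloff with
  schematic scalp distance is added, scaled per condition
  (`oldnew_amplitude`, defaults 1.5/1.0/0.4/0.2 µV for PT/NPT/NP/ABS) under
  a half-cosine envelope over 430–670 ms. Amplitudes in µV are free
  parameters — recollection-related parietal effects have no canonical
  amplitude — so the package's validation targets detection and calibration
  properties, never absolute amplitudes. Setting all amplitudes equal (or
  zero) produces exact null data for false-positive calibration.
* **Noise** is $1/f^a$-coloured in time (default exponent 1, shaped in the
  frequency domain and normalized to unit variance) and spatially mixed by
  a channel covariance $K = \exp(-d/\lambda)$ over schematic electrode
  positions (default length scale 0.6), then scaled to `noise_sd`
  (default 10 µV per channel). This reproduces the two features that matter
  for the statistics: temporal autocorrelation (which inflates naive
  pointwise tests and is exactly what cluster-based permutation corrects
  for) and spatial correlation (which limits how much channel averaging
  helps).

Behaviour is simulated per retrieval trial: accuracy is Bernoulli with a
per-condition probability (defaults ≈ 0.82/0.71/0.66 for Experiment 1 and
0.80/0.71/0.68/0.65 for Experiment 2, typical of object-location retrieval
after prioritization/testing manipulations), and response times are
log-normal with parameters solved so the distribution's mean and SD match
the configured per-condition values (≈ 1060–1230 ms means). Log-normal is
the conventional minimal model for positive, right-skewed RTs.

What the generator does **not** emulate: participant-level random effects
(every simulated participant shares the condition probabilities, so
simulated between-participant variance is binomial only and standardized
effect sizes come out larger than in real data), volume-conducted dipolar
topographies, eye movements and other artifacts, and non-stationary noise.
Passing the package's tests therefore demonstrates the *statistical
machinery* is correct and calibrated — not that real recordings will show
effects of any particular size.

## Preprocessing

* `design_fir()` builds Hamming windowed-sinc FIR filters specified by
  their −6 dB cutoff; for a windowed-sinc design the −6 dB point coincides
  with the ideal cutoff, which the tests verify to within 0.5 dB.
* `apply_filter()` applies the filter with *exact* zero phase: a symmetric
  linear-phase FIR is convolved once and the group delay removed by
  indexing, with reflection padding at the edges. A forward–backward pass
  would also be zero-phase but squares the magnitude response and thus
  moves the −6 dB point; single-pass compensation preserves the designed
  response exactly, which makes the filter tests sharp.
* `reject_epochs()` iterates: flag trials exceeding an absolute amplitude
  threshold (default 500 µV, exposed as a parameter because different
  pipeline positions conventionally use different values) or whose
  deviation score exceeds 5 SDs, then reject at most 5% of the current
  trials per iteration, worst first. The deviation score is the maximum
  absolute z, across trials, of three per-trial summaries (mean,
  log-variance, range) — a simpler, fully specified surrogate for
  joint-probability artifact criteria. Its calibration need not match any
  particular toolbox because rejection here only feeds robustness checks on
  synthetic data.
* `downsample_epochs()` decimates by integer factors after an anti-alias
  lowpass at 80% of the new Nyquist; non-integer ratios are rejected rather
  than resampled.

ICA-based artifact correction, channel rejection and interpolation are out
of scope: imported data are assumed cleaned upstream.

## ERP cluster-based permutation statistics

`condition_erp()` averages trials within condition, then channels within
the left-parietal cluster, restricted to a 0–1200 ms analysis window. The
number of time points is always derived from the configured window and
sampling rate, never hard-coded. The contrast machinery then:

1. computes pointwise paired *t*-tests between two conditions,
2. forms clusters as maximal runs of `p < 0.05` (strict) containing at
   least two significant points,
3. builds the null by randomly exchanging each participant's two condition
   waveforms — equivalently, flipping the sign of the difference waveform —
   recording the maximum cluster length per permutation (10,000 by
   default), and
4. declares observed clusters significant when their length *strictly
   exceeds* the 95th percentile of the null.

Numerical conventions worth stating: the cluster statistic is the run
*length* (not a mass statistic), so ties at the threshold are resolved as
non-significant; the percentile uses the nearest-rank method so thresholds
are integers and reproducible; with $n$ participants and $2^n$ not
exceeding the permutation budget the null is enumerated exhaustively
(automatic for $n \le 13$ at the default budget), making the test exact;
zero-variance time points take `t = 0, p = 1` when the mean difference is
zero and `p = 0` otherwise; and the pointwise tests are two-sided by
default with a one-sided option, since either convention is defensible for
directional recollection effects.

## Location decoding

`lda_fit()`/`lda_predict()` implement multi-class LDA with the pooled
within-class covariance shrunk toward its diagonal,
$\Sigma_\lambda = (1-\lambda)\Sigma + \lambda\,\mathrm{diag}(\Sigma)$. The
default $\lambda$ is the analytic (Ledoit–Wolf-style) estimate computed
from the data — necessary because 64 channels can exceed the number of
training super-trials per fold — with a fixed-λ override. Exact score ties
break to the lowest class index.

`decode_within_phase()` runs, per participant and time point, 10-fold
cross-validation with class-balanced folds (classes subsampled to the
largest common count divisible by the fold number, so empirical chance is
exactly $1/4$), super-trial averaging applied separately to the training
and test side of each split (default 4 trials per super-trial, matching the
paradigm's four appearances per object; averaging across the fold boundary
would leak information), and accuracy averaged over folds and 10
randomization repeats. Fold and super-trial assignments are drawn once per
repeat and reused across time points.

`decode_cross_phase()` trains at each time point of one phase's designated
window (encoding 0–500 ms, working memory 300–800 ms, retrieval
500–1000 ms) and tests across the other phase's window, averages over
training time, repeats with the roles reversed, and reports the mean of the
two directions on a common within-window time axis. Training per time point
(rather than on a window-average pattern) preserves temporal structure in
the training data; the reciprocal average makes the result symmetric in its
arguments, which the tests check to the byte.

The significance test against chance (`decoding_cluster_test()`) swaps, per
participant and time point, the observed accuracy with the chance constant
between the two comparison vectors — a sign flip of `accuracy − chance` per
cell — and applies one-sided *t*-tests (accuracy above chance), then the
same cluster machinery as the ERP contrast. The chance constant defaults to
$1/\text{classes} = 0.25$ for the four-location problem; any other constant
can be supplied explicitly. The exchangeable unit is the participant × time
cell: the participant-level accuracy is the quantity under test, and
per-cell swaps are the finest exchange consistent with the one-sample null.

## Behavioural statistics

All omnibus and pairwise analyses operate on a complete
participant × condition matrix (`condition_matrix()`; RT analyses include
all trials regardless of accuracy). The battery always reports both
parametric and non-parametric routes — Lilliefors normality screening is
attached for information but never gates which tests run:

* `rm_anova_gg()`: one-way repeated-measures decomposition, partial
  $\eta^2$, Mauchly's W with its $\chi^2$ approximation, Greenhouse–Geisser
  $\varepsilon$ from the eigenvalues of the contrast covariance (clamped to
  $[1/(k-1), 1]$), and the ε-corrected p-value.
* `friedman_kendall_w()`: within-participant mid-ranks, tie-corrected
  $\chi^2$, and Kendall's $W = \chi^2 / (n(k-1))$.
* `paired_t_dav()`: paired *t* with Cohen's
  $d_{av} = \bar d / ((s_x + s_y)/2)$ and a 95% CI on the raw mean
  difference.
* `wilcoxon_signed_rank()`: zero differences dropped; mid-ranks; both
  rank-sum conventions are emitted (`w_pos` and `w_min`) since reporting
  practice varies; z uses continuity and tie corrections; p is exact by
  full sign enumeration for up to 12 non-zero pairs; the effect size is
  $r = z/\sqrt{n}$ with $n$ the non-zero pairs used.
* `bh_fdr()`: Benjamini–Hochberg step-up adjustment via `stats::p.adjust`;
  the parametric and non-parametric families are adjusted separately.
* `jzs_bf_paired()`: the default-prior Bayes factor for the paired *t* —
  marginal likelihood under a Cauchy(0, $\sqrt2/2$) prior on the
  standardized effect size (adaptive quadrature over the non-central *t*
  likelihood) against the point null. Only the paired-test Bayes factor is
  provided; Bayesian model-averaged repeated-measures ANOVA is a different
  animal and out of scope.

## Reproducibility and problem sizes

Every stochastic operation takes a seed; sub-streams (per participant, per
permutation batch, per fold randomization) are derived deterministically by
hashing the seed with a context key, so results are independent of
evaluation order and identical runs are byte-identical — the pipeline test
verifies this on serialized outputs.

The test suite validates calibration on reduced problem sizes chosen to
keep the full suite within a few minutes while leaving Monte-Carlo error
well inside the asserted tolerances: false-positive rates use 500 null
datasets of 8 participants × 4 channels at 50 Hz (where the sign-flip null
is enumerated exhaustively, so the only randomness is the data); decoding
calibration uses 6–10 participants at 16 channels; the behavioural
calibration uses the full 180-object, 43-participant design, where the
Monte-Carlo standard error of a condition's grand mean accuracy is ≈ 0.5
percentage points.

## Known limitations

* The montage is schematic (label-derived 2-D positions), adequate for
  distance-decaying covariances but not for source-level realism.
* No participant-level heterogeneity in the behavioural generator (see
  above); standardized effect sizes on synthetic data exceed realistic
  values.
* Cluster inference is 1-D (time only); channel–time cluster formation and
  threshold-free methods are not implemented.
* The Friedman p-value is asymptotic; for very small samples (n ≤ 4) the
  χ² approximation is coarse, which the tests quantify by exhaustive
  enumeration.
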