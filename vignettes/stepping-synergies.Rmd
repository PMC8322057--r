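---
title: "Methods: muscle synergy analysis of voluntary and reactive stepping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: muscle synergy analysis of voluntary and reactive stepping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepsynergy)
```

## The model

Surface EMG recorded from eight muscles during a backward step — the
stepping-limb and stance-limb tibialis anterior (TA), biceps femoris long
head (BFLH), medial gastrocnemius (GAS) and vastus lateralis (VLAT) — is
modeled as a non-negative mixture of a small number of muscle synergies:

$$ M = c_1 w_1 + c_2 w_2 + \dots + c_k w_k + \varepsilon, $$

where each $w_i \ge 0$ is a fixed 8-muscle weight vector (the spatial
synergy, max-normalized to 1), each $c_i(t) \ge 0$ is its time-varying
recruitment coefficient, and $\varepsilon$ is noise.  $M$ is the
muscles-by-time-bins activation matrix built from the window between the
perturbation or cue onset (PON) and the stepping foot's touchdown (TD).
The package factorizes $M \approx W C$ by non-negative matrix
factorization (NNMF) and compares the resulting synergy repertoires
between self-initiated (voluntary) and perturbation-evoked (reactive)
stepping.

## Preprocessing

Raw interference EMG is conditioned with a zero-phase Butterworth
high-pass at 35 Hz (4th order; the order is configurable since different
labs report different choices), full-wave rectification, and a 2nd-order
Butterworth low-pass at 40 Hz applied forward and backward.  Edges are
handled by odd reflection padding of three filter lengths, which keeps the
output bit-stable and suppresses startup transients on short trials.

The high-pass stage removes drift and motion artifact from *raw* EMG.  A
recording that already holds a rectified envelope — which is what the
synthetic generator produces, since the generative model defines the
envelope directly — is flagged `conditioned`, and `condition_emg()` then
skips the high-pass: an envelope's spectral content lies almost entirely
below 35 Hz, so re-applying the high-pass would remove the signal itself
rather than artifact.  Rectification and the 40 Hz low-pass are
near-identities on a smooth non-negative envelope, which is exactly the
idempotence one wants from a conditioning stage.

Conditioned signals are averaged into 15 ms bins over [PON, TD] (28 ms is
the coarser check; at 1200 Hz a 15 ms bin averages exactly 18 samples).
Trailing samples that do not fill a whole bin are discarded so all bins
are homogeneous; a `partial_last` flag keeps them instead.  Each muscle
row is then divided by its maximum over the subject's two voluntary
trials — reactive rows may legitimately exceed 1 and are not clipped —
and finally scaled to unit variance so every muscle weighs equally in the
factorization.  Both divisors are stored, the unit variance is removed
from the extracted weights by multiplying back the row SDs, and the full
round trip is exact to 1e-9.  A muscle that is flat over the analysis
window indicates a dead channel and raises an error by default
(`zero_sd = "one"` substitutes SD = 1 for tolerant batch runs).

## Factorization and model order

`nnmf()` uses multiplicative updates minimizing squared Frobenius error —
the de facto standard in the synergy literature — with 10 uniform-random
restarts, keeping the run with the highest variance accounted for (VAF).
Convergence stops when the *relative* change of the relative
reconstruction error falls below 1e-6 (checked every 10 iterations, cap
2000); an absolute-change rule would freeze prematurely on
near-exact-rank data, where the error itself is tiny long before the
factors separate.  Weight columns are max-normalized with the inverse
scale folded into the coefficients, leaving the reconstruction unchanged
to 1e-12.

VAF is uncentered, overall ($100 (1 - \|M - WC\|_F^2 / \|M\|_F^2)$) and
row-wise per muscle; a centered variant is available behind a flag since
reports differ on this point.  The synergy number is the smallest $k$
whose best factorization exceeds 90% overall VAF while every muscle
exceeds 75% (the conservative validation variant raises the per-muscle
threshold to 80%); each $k$ is fit afresh, ascending from 1, with no warm
starts so the selection is unbiased across $k$.  Muscles with normalized
weight above 0.4 count as major contributors of a synergy.

## Clustering, similarity, merging

Per-subject synergies are pooled within a task and clustered
hierarchically on the correlation distance $d = 1 - r$ with average
linkage (complete linkage is exposed as an option).  The dendrogram is
cut at the smallest cluster count for which no cluster holds two
synergies from the same subject; counts are scanned ascending, and the
returned cut is verified minimal.  Clusters are labeled MV1, MV2, ...
(voluntary) or MR1, ... (reactive) by ascending mean member peak time,
with ties broken by cluster size then lexical subject order.
Member-to-centroid similarity uses the full-cluster centroid rather than
leave-one-out, the simplest reading of how such tables are usually built.

Two synergy vectors are *similar* when their Pearson correlation exceeds
the two-sided p < 0.01 critical value for 8 paired observations,
$r_{crit} = t_{crit} / \sqrt{df + t_{crit}^2} = 0.834$; the threshold can
be recomputed for other lengths or levels via `critical_r()`.  Families
of post-hoc tests use the Benjamini–Yekutieli corrected level
$\alpha / \sum_{i=1}^m 1/i$ (0.024 for four comparisons at 0.05).
Merging expresses a target synergy as a non-negative least-squares
combination of source synergies and scores the merged, max-normalized
vector by $r$ to the target.  When the target lies entirely outside the
source cone the NNLS solution is all-zero; that degenerate case is
reported as $r = 0$ with a flag rather than an undefined correlation.
Note that while the NNLS *objective* of a multi-source merge always
dominates any single source's, the resulting correlation need not — the
correlation is a different functional than the fitted SSE — so only the
objective dominance is asserted as an invariant.

Cross-validation re-clusters a random 80% subject subset and matches the
subset centroids to the full-cohort centroids by exact assignment
(exhaustive over permutations; repertoires have at most 8 synergies).
Because each subject's factorization depends only on that subject's
trials, subsetting the cohort leaves the per-subject extractions
unchanged; re-running them would reproduce identical factor matrices, so
only the pooling and clustering stage is recomputed.

## The synthetic cohort generator

No recorded stepping-EMG cohort is publicly available, so every stage is
validated on synthetic cohorts with planted ground truth.  Defaults
emulate the study conditions: 10 subjects, two voluntary trials (one per
stepping side) and one reactive trial each, 1200 Hz, additive Gaussian
noise with SD 5% of the trial's peak clean signal (clipped at zero to
keep EMG non-negative), and per-subject synergy-weight jitter of SD 0.05
(additive Gaussian, absolute value, columns re-normalized to max 1).
Event timings use mean young-adult step-phase durations: 490 ms reaction
and 270 ms execution for voluntary steps, 210 ms and 155 ms for reactive
steps.  Recruitment coefficients are unimodal bursts — truncated
Gaussians with the tail beyond 2 SD subtracted so each burst reaches zero
smoothly — centered evenly across the PON–TD window.  All randomness
flows from one integer seed through fixed per-subject offsets, so cohorts
are reproducible subject by subject and byte-identical across calls.

Two generator design points deserve emphasis:

* **Identifiability.**  An NNMF with strictly positive $W$ *and* $C$ is
  not unique: an exact factorization can be rotated within the positive
  orthant, so no algorithm could be expected to recover the planted
  weights.  The default templates therefore carry exact zeros on each
  synergy's silent muscles, and the default burst width (SD = 1/4 of the
  inter-burst spacing, truncated at 2 SD) gives each synergy time bins in
  which it alone is active.  Under these conditions the noiseless planted
  factorization is essentially unique up to permutation and scale, and
  the pipeline recovers it with matched-column correlations above 0.999.

* **Templates.**  The four voluntary templates are sparse, sequentially
  recruited patterns (an ankle push-off synergy of stepping GAS with
  stance TA; a swing synergy of stepping TA/BFLH with stance GAS/VLAT; a
  stepping-knee synergy; a stance-loading synergy).  The two reactive
  templates are broad co-activation patterns, each loading more than five
  muscles above the 0.4 contributor threshold — emulating the widespread
  recruitment of protective stepping, and producing the expected contrast
  of fewer, broader synergies in reactive trials.

The generator couples marker traces and EMG statistically, not
mechanically: there is no forward simulation of body dynamics, marker
bumps are smooth analytic shapes, and EMG amplitudes are arbitrary units
(all downstream operations are scale-invariant up to the documented
normalization).  Passing tests on these cohorts therefore demonstrate the
correctness of the algorithms under the stated generative model — not
robustness to the full messiness of recorded EMG (cross-talk,
non-stationary noise, electrode lift-off), which no synthetic model of
this simplicity reproduces.

## Gait events and the belt profile

Lift-off is detected where the vertical foot-marker trace leaves the
quiet-stance baseline band (mean ± 2 baseline SDs), touchdown where it
re-enters the band after the swing apex — a symmetric criterion that is
robust to noise near the contact instant.  Roughly 2% of noisy baseline
samples exceed a 2-SD band by chance, so a crossing only counts when at
least 80% of the following 20 ms stays across the threshold; isolated
spikes are rejected without postponing a genuine crossing, and the event
time is still the first crossing sample.  An SD floor of 1e-9 mm keeps
the rule defined on noiseless traces.  A 6 Hz zero-phase marker low-pass
is available ahead of detection for rough traces.

The slip-like belt translation is a trapezoidal speed profile
(acceleration $t_1$ at $a$, constant phase $t_2$, symmetric deceleration
$t_3$): peak velocity $a t_1$ and displacement
$\tfrac12 a t_1^2 + a t_1 t_2 + a t_1 t_3 - \tfrac12 a t_3^2$.  For the
familiarization intensity (0.04 s at 16.75 m/s², 0.25 s constant) this
gives 0.67 m/s and 0.194 m; the stronger intensity (21.5 m/s², 0.33 s)
gives 0.86 m/s.  The displacement printed alongside the stronger profile
in the source protocol (0.38 m) is inconsistent with its own phase
parameters (the integral gives 0.318 m); the arithmetic is trusted and
only the mutually consistent values are used as checks.

## Problem sizes and runtime

The test-suite and acceptance cohorts use 10 subjects (the study's group
size), 2 s trials at 1200 Hz, and 15 ms bins (about 50 voluntary and 24
reactive bins per trial) — sizes at which a full cohort extraction takes
a few seconds and the complete validation runs comfortably on one CPU.
Cross-validation summarizes 20 subset draws.  The Monte-Carlo check of
the critical correlation uses 1e6 random 8-vector pairs.

## Known limitations

* Statistical coupling only between kinematics and EMG; no biomechanics.
* No MVIC normalization (deliberately: normalization is to the voluntary
  trials' maxima), and no time-varying synergy model — spatial synergies
  are fixed over the trial by assumption.
* Real-cohort similarity tables cannot be reproduced without the recorded
  data; the package reproduces their structure and format on synthetic
  cohorts and validates every computed quantity against planted truth or
  independent oracles instead.
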