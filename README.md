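# stepsynergy

Muscle synergy analysis of voluntary and reactive backward stepping from
8-channel surface EMG.

When balance is lost — say a treadmill belt slides forward under the feet —
people take a rapid protective step; the same movement can also be made
voluntarily after a cue. A central question in neuromuscular control is
whether the nervous system builds both behaviors from the same low-level
building blocks. This package implements the standard computational pipeline
for that question: EMG envelopes from the stepping and stance limbs (TA,
BFLH, GAS, VLAT on each) are factorized into muscle synergies, the
factorization model being

    M = c1*w1 + c2*w2 + ... + ck*wk + noise,

with non-negative 8-muscle weight vectors `w_i` (spatially fixed,
max-normalized) and non-negative recruitment coefficients `c_i(t)`. It is
aimed at movement-science researchers who want a tested, scriptable
implementation of this analysis — and a synthetic cohort generator with
planted ground truth, so the whole pipeline can be validated without
recorded data.

What is implemented, end to end:

* **Conditioning** — zero-phase 35 Hz high-pass, full-wave rectification,
  dual-pass 2nd-order 40 Hz low-pass; reflective edge padding.
* **Binning and normalization** — 15 ms (or 28 ms) bin averages over the
  PON-to-TD window; per-muscle normalization to the two voluntary trials'
  maxima; unit-variance row scaling with exact, bookkept inversion.
* **Extraction** — NNMF by multiplicative updates with random restarts;
  uncentered VAF overall and per muscle; model order selected as the
  smallest k with > 90% overall and > 75% per-muscle VAF (80% variant for
  validation); 0.4 major-contributor threshold; recruitment peak times and
  ordering.
* **Clustering** — pooled synergies grouped by hierarchical clustering on
  1 − r (average linkage), cut at the smallest count where no cluster has
  two synergies from one subject; prevalence and member-centroid
  similarity tables.
* **Comparison** — Pearson similarity with the r > 0.834 (p < 0.01, n = 8)
  criterion computed from first principles; Benjamini–Yekutieli corrected
  levels; NNLS synergy merging; 80% subject-subset cross-validation;
  bin-width robustness; Wilcoxon / Kruskal–Wallis / Cohen's d wrappers for
  synergy counts.
* **Kinematics** — 2-SD gait event detection (LO/TD) with reaction and
  execution periods, step length, sagittal knee/foot angles, and
  trapezoidal belt-profile arithmetic.
* **Synthetic cohorts** — `synthetic_spec()` / `generate_cohort()` plant
  known synergies, bursts, events and noise; delimited-text I/O for all
  artifacts.

## Worked example

The `analysis/` scripts run the full study on a synthetic cohort — 10
subjects, voluntary trials mixing 4 sparse synergy templates, reactive
trials mixing 2 broad co-activation templates, 5% noise, 0.05 weight
jitter:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_extract.R
Rscript analysis/03_cluster.R
Rscript analysis/04_compare.R
Rscript analysis/05_kinematics.R
```

which prints (tables land in `results/`):

```
Selected synergy numbers (subjects x task):
             reactive             voluntary
"2 2 2 2 2 2 2 2 2 2" "4 4 4 4 4 4 4 4 4 4"
Mean k: voluntary 4.0, reactive 2.0

voluntary stepping: 4 clustered synergies
  MV1  recruited by 10/10  mean peak 0.098 s  member r 1.00 +/- 0.00
  MV2  recruited by 10/10  mean peak 0.285 s  member r 0.99 +/- 0.01
  ...
Voluntary vs reactive: 0 of 2 matched centroid pairs similar (r > 0.834)
80% subset cross-validation: matched centroid r in [1.000, 1.000]
Synergy counts: voluntary 4.0 vs reactive 2.0 (Wilcoxon p = 0.001904, ...)
```

Every subject's dual-VAF selection recovers the planted synergy numbers
(4 voluntary, 2 reactive); the clustered repertoires separate cleanly by
task (no voluntary centroid is similar to a reactive one at the 0.834
criterion); and the clustering is stable under 80% subsampling. The belt
profiles evaluate to 0.67 m/s / 0.194 m (familiarization) and 0.86 m/s
(stronger slip), and planted gait events are recovered within 3 ms.

A minimal in-R session:

```r
library(stepsynergy)

spec   <- synthetic_spec(n_subjects = 10, seed = 7)        # 4 planted synergies
cohort <- generate_cohort(spec)
recs   <- cohort$recordings[grep("^S01_", names(cohort$recordings))]
res    <- extract_subject(recs, pipeline_config())
res$voluntary$k                 # 4  (dual VAF rule: >90% overall, >75% per muscle)
res$voluntary$fit$vaf_overall   # 99.9
critical_r(8, 0.01)             # 0.8343 -> the r > 0.834 similarity criterion
by_corrected_alpha(0.05, 4)     # 0.024  -> corrected post-hoc level
```

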