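#!/usr/bin/env Rscript
# Simulate the synthetic stepping-EMG cohort used by the downstream
# analyses: 10 subjects, two voluntary trials and one reactive trial each.
# Voluntary trials mix 4 sparse synergy templates; reactive trials mix 2
# broad co-activation templates (the task contrast of interest).  Writes
# one TSV + JSON sidecar per trial and a ground-truth bundle.

library(stepsynergy)

# Raw trial files are bulky and fully regenerable, so they go under
# scratch/; derived tables from later stages land in results/.
seed <- 7L
out_dir <- "scratch/cohort"

spec <- synthetic_spec(
  n_subjects = 10,
  true_synergies = default_voluntary_templates(),
  true_synergies_reactive = default_reactive_templates(),
  noise_sd = 0.05,
  subject_jitter_sd = 0.05,
  seed = seed
)
cohort <- generate_cohort(spec)
write_cohort(cohort, out_dir)

cat(sprintf("Simulated %d recordings for %d subjects into %s\n",
            length(cohort$recordings), spec$n_subjects, out_dir))
cat(sprintf("Voluntary window %.0f ms (%d templates), reactive window %.0f ms (%d templates)\n",
            1000 * (spec$reaction$voluntary + spec$execution$voluntary),
            ncol(spec$true_synergies),
            1000 * (spec$reaction$reactive + spec$execution$reactive),
            ncol(spec$true_synergies_reactive)))
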