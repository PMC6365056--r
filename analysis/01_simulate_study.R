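#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic study.
#
# Generates the full trial table for 14 subjects (6 alternating blocks per
# condition of 240 trials each, 75% targets): choices and RTs from the
# condition-specific drift-bias diffusion model, pre-stimulus alpha from a
# condition-shifted log-normal, gamma modulation from the sigmoidal
# response-gain curve (liberal amplitude 1.5x conservative), frontal theta
# elevated under liberal, and a positive gamma -> drift-bias coupling.

suppressPackageStartupMessages(library(driftgain))
dir.create("results", showWarnings = FALSE)

seed <- 20260927L
cfg <- study_config(n_subjects = 14L, blocks_per_condition = 6L,
                    seed = seed)
subjects <- sample_subject_params(cfg$n_subjects,
                                  seed = child_seed(seed, "subjects"))
trials <- simulate_study(cfg, subjects, seed = seed)

write_trials(trials, "results/trials.csv")

cat(sprintf("simulated %d trials, %d subjects\n", nrow(trials),
            length(unique(trials$subject))))
print(aggregate(cbind(press = choice == "press") ~ condition + stimulus,
                trials, mean))
cat("wrote results/trials.csv\n")
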