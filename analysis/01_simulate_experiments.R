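#!/usr/bin/env Rscript
# Simulate synthetic subjects for the two task designs with the reference
# adapted-DDM parameter sets, and write their trial tables plus ground-truth
# sidecars under results/.
#
# Design 1 (unbiased): 13 blocks x 120 trials, alternation probability 0.5.
# Design 2 (transition-biased): 9 blocks x 200 trials, alternation
# probability 0.1 / 0.5 / 0.9, three blocks each in seeded balanced order.

library(seqddm)

seed <- 20260924L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

for (design in c("exp1", "exp2")) {
  pars <- adaptive_params_defaults(design)
  sched <- generate_experiment_schedule(design, seed = seed)
  sub <- generate_synthetic_subject(pars, sched, seed = seed,
                                    subject = paste0(design, "_synth"))
  write_trial_table(sub$trials, file.path(out_dir, paste0("trials_", design, ".csv")))
  jsonlite::write_json(sub$truth,
                       file.path(out_dir, paste0("truth_", design, ".json")),
                       auto_unbox = TRUE, digits = NA)
  er <- mean(!sub$trials$correct)
  cat(sprintf("%s: %d trials, overall ER %.3f, mean RT %.3f s -> %s\n",
              design, nrow(sub$trials), er, mean(sub$trials$rt),
              file.path(out_dir, paste0("trials_", design, ".csv"))))
}
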