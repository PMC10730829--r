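#!/usr/bin/env Rscript
# Stage 1 — simulate the call cohort.
#
# Generates the standard 50,000-call synthetic cohort: helpline stroke
# prevalence 0.25%, emergency-line share 6.6% at 2.5% prevalence, call-taker
# triage at sensitivity 52.7% / PPV 17.1%, Zipf background transcripts with
# ten planted stroke-indicator words and ten distractors. Writes the cohort
# as plain-text files under results/cohort/ and prints a short description
# of what was generated.

library(strokecall)

seed <- 1L
cfg <- generator_config(n_calls = 50000L, seed = seed)
cohort <- generate_cohort(cfg)
print(cohort)

cat(sprintf("planted stroke fraction: %.4f%% (target %.4f%% helpline)\n",
            100 * mean(cohort$truth), 100 * cfg$stroke_prevalence))
cat(sprintf("implied call-taker FPR: %.5f\n", cfg$calltaker_fpr))

dir.create("results", showWarnings = FALSE)
write_cohort(cohort, "results/cohort")
cat("cohort written to results/cohort/ (calls.csv, registry.csv, transcripts.jsonl)\n")
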