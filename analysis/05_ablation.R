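#!/usr/bin/env Rscript
# Stage 5 (optional) — emergency-line ablation.
#
# Retrains the pipeline without the emergency-line training data (the
# "w/o 1-1-2" arm) at a reduced run count and compares test metrics with
# the full model from stage 3. Appends a two-row summary to
# results/ablation.csv.

library(strokecall)

full <- jsonlite::fromJSON("results/study/results.json")

cfg <- pipeline_config(n_calls = 50000L, n_runs = 3L, seed = 1L,
                       include_emergency_line = FALSE)
bundle <- run_pipeline(cfg, verbose = TRUE)

abl <- bundle$metrics_model$mean
tab <- data.frame(
  arm = c("with_emergency_line", "without_emergency_line"),
  n_runs = c(full$model$n_runs, bundle$metrics_model$n_runs),
  f1 = c(full$model$f1, abl[["f1"]]),
  sensitivity = c(full$model$sensitivity, abl[["sensitivity"]]),
  ppv = c(full$model$ppv, abl[["ppv"]]))
print(tab)
write.csv(tab, "results/ablation.csv", row.names = FALSE)
cat("ablation summary written to results/ablation.csv\n")
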