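#!/usr/bin/env Rscript
# Stage 2 — registry linkage and dataset splitting.
#
# Reads the cohort written by 01_simulate.R, labels each call against the
# stroke registry (non-SAH entry with onset within -72h/+24h of call start),
# derives the call-taker label (stroke category selected AND appropriate
# ambulance dispatch), and assigns train folds / validation / test subsets.
# Writes results/labelled_calls.csv and prints the subset table.

library(strokecall)

cohort <- read_cohort("results/cohort")
linked <- link_cohort(cohort$calls, cohort$registry)
linked$subset <- split_dataset(linked, test_year = max(cohort$config$years),
                               seed = strokecall:::derive_seed(1L, "split"))

cat("subset sizes and stroke counts:\n")
print(table(linked$subset, linked$ground_truth))
cat(sprintf("\ncall-taker on the test subset: sensitivity %.3f, PPV %.3f\n",
            with(subset(linked, subset == "test"),
                 sum(calltaker_positive & ground_truth) / sum(ground_truth)),
            with(subset(linked, subset == "test"),
                 sum(calltaker_positive & ground_truth) /
                   max(1, sum(calltaker_positive)))))

out <- linked
out$call_start <- format(out$call_start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
write.csv(out, "results/labelled_calls.csv", row.names = FALSE, na = "")
cat("labelled calls written to results/labelled_calls.csv\n")
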