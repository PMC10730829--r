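#!/usr/bin/env Rscript
# Stage 4 — render the occlusion word tables.
#
# Reads the occlusion output of stage 3 and prints the top-30 positive
# (stroke predictions) and negative (non-stroke predictions) word lists as
# a Markdown table, reporting how many of the ten planted indicator words
# were recovered. Writes results/occlusion_table.md.

library(strokecall)

occ <- read.csv("results/study/occlusion.csv", stringsAsFactors = FALSE)
pos <- occ[occ$group == "stroke_predictions", ]
neg <- occ[occ$group == "non_stroke_predictions", ]

recovered <- sum(default_indicator_words() %in% pos$word)
cat(sprintf("indicator words recovered in the top-%d positive list: %d/10\n",
            max(pos$rank), recovered))

res <- jsonlite::fromJSON("results/study/results.json")
md <- format_occlusion_markdown(pos, neg,
                                d_pos = res$occlusion_D$positive,
                                d_neg = res$occlusion_D$negative)
writeLines(md, "results/occlusion_table.md")
cat("table written to results/occlusion_table.md\n\n")
cat(head(md, 12), sep = "\n")
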