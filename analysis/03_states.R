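#!/usr/bin/env Rscript
# Stage 3: discretize pure technical efficiency into relative states.
#
# Pooled 33rd/67th percentile thresholds over all region-years; a quartile
# variant is written alongside as the robustness grouping.

suppressPackageStartupMessages(library(effdyn))

eff <- read.delim("results/efficiency.tsv")
th <- efficiency_thresholds(eff$pte, scheme = "tercile")
st <- classify_states(eff, th)
write.table(st, "results/states.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(threshold = as.numeric(th),
                       scheme = attr(th, "scheme")),
            "results/thresholds.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

th4 <- efficiency_thresholds(eff$pte, scheme = "quartile")
st4 <- classify_states(eff, th4)
write.table(st4, "results/states_quartile.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("tercile thresholds: %.4f / %.4f\n", th[1], th[2]))
cat("state shares:",
    sprintf("%.1f%%", 100 * tabulate(st$state, 3) / nrow(st)), "\n")
cat("quartile shares:",
    sprintf("%.1f%%", 100 * tabulate(st4$state, 4) / nrow(st4)), "\n")
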