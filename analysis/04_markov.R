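#!/usr/bin/env Rscript
# Stage 4: Markov distribution dynamics of the efficiency states.
#
# Pooled one-step transition matrix, stationary distribution, persistence
# summary; then region-group and period subsets (each period's stationary
# vector describes that period's limiting relative ranking, not absolute
# efficiency change).

suppressPackageStartupMessages(library(effdyn))

st <- read.delim("results/states.tsv")
groups <- read.delim("results/region_groups.tsv")

est <- estimate_transitions(st, n_states = 3)
sd_ <- stationary_distribution(est)
pr <- persistence_report(est, sd_)

write.table(as.data.frame(est$counts), "results/transition_counts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(as.data.frame(est$probabilities),
            "results/transition_probabilities.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(state = 1:3, pi = sd_$pi), "results/stationary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("pooled transition matrix (", est$n_transitions, "transitions ):\n")
print(round(est$probabilities, 4))
cat("stationary shares:", sprintf("%.2f%%", 100 * sd_$pi), "\n")
cat(sprintf("mobility index 1 - tr(P)/K: %.4f\n", pr$mobility_index))
if (nrow(pr$zero_leap_cells)) {
  cat("zero cross-tier leap cells:",
      paste(apply(pr$zero_leap_cells, 1, paste, collapse = "->"),
            collapse = ", "), "\n")
}

subset_row <- function(label, est_s) {
  pi_s <- tryCatch(stationary_distribution(est_s)$pi, error = function(e) NA)
  data.frame(subset = label, transitions = est_s$n_transitions,
             p11 = est_s$probabilities[1, 1], p22 = est_s$probabilities[2, 2],
             p33 = est_s$probabilities[3, 3],
             pi_low = pi_s[1], pi_mid = pi_s[2], pi_high = pi_s[3])
}

rows <- list()
for (g in unique(groups$group)) {
  est_g <- estimate_transitions(st, regions = groups$region_id[
    groups$group == g], n_states = 3)
  rows[[g]] <- subset_row(g, est_g)
}
for (per in list(c(2001, 2005), c(2006, 2010), c(2011, 2015),
                 c(2016, 2020))) {
  lab <- paste(per, collapse = "-")
  rows[[lab]] <- subset_row(lab, estimate_transitions(st, years = per,
                                                      n_states = 3))
}
subsets <- do.call(rbind, rows)
write.table(subsets, "results/subset_dynamics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nsubset dynamics (region groups, then periods):\n")
print(subsets, row.names = FALSE, digits = 4)
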