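#!/usr/bin/env Rscript

# Step 3: compute the seven node-level integration measures for every
# individual-year in every network composition and join the individual
# attributes. Writes the tidy metrics table to results/metrics.csv.

library(socnetage)

obs <- read_observations("results/data/observations.csv")
roster <- read_roster("results/data/roster.csv")

metrics <- compute_metrics(obs, roster)
write.csv(metrics, "results/metrics.csv", row.names = FALSE)

message(sprintf("metrics table: %d rows (node-year-composition)", nrow(metrics)))
mix <- subset(metrics, composition == "mixed")
for (s in c("F", "M")) {
  ms <- mix[mix$sex == s, ]
  message(sprintf(
    "  %s (mixed): mean out-strength %.3f, in-strength %.3f, transitivity %.2f, eigen %.2f",
    s, mean(ms$out_strength), mean(ms$in_strength),
    mean(ms$local_transitivity, na.rm = TRUE),
    mean(ms$eigenvector_centrality)))
}
message("wrote results/metrics.csv")
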