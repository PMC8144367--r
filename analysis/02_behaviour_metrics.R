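#!/usr/bin/env Rscript

# Compute the behavioural statistics from the simulated game logs written
# by 01_simulate_setups.R: per-player activity, activity by cluster size
# (risk-averseness), strategy values (inclusive-mean convention), and
# per-game-averaged interaction-count matrices by controller type.
# Results land as tidy CSVs under results/metrics/<setup>/.

library(groupswap)

log_root <- "results/logs"
if (!dir.exists(log_root)) stop("run analysis/01_simulate_setups.R first")

for (name in list.dirs(log_root, recursive = FALSE, full.names = FALSE)) {
  files <- list.files(file.path(log_root, name), pattern = "\\.jsonl$",
                      full.names = TRUE)
  records <- lapply(files, read_game_record)
  out <- file.path("results", "metrics", name)
  tabs <- write_metric_tables(records, out)
  cat(sprintf("setup %s: %d games -> %s\n", name, length(records), out))
  im <- tabs$interaction_matrix
  cat("  mean interactions/game by controller type:\n")
  print(round(im, 1))
}
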