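#!/usr/bin/env Rscript
# Changing environment: patch 1 opens at step 0, a superior patch 2 (three
# times the feeding capacity) opens at step 900. Threshold pairs 8v24, 24v72,
# 72v216; 30 replicates each. Also re-runs the high-crowding pair with zero
# pheromone decay to show the switch does not rely on trail evaporation.

library(antcrowd)

dir.create("results", showWarnings = FALSE)

ex <- experiment_changing(pairs = list(c(8, 24), c(24, 72), c(72, 216)),
                          delay = 900, n_runs = 30, seed_base = 1)
write.csv(ex$summary, "results/model2_summary.csv", row.names = FALSE)
write.csv(ex$per_run, "results/model2_per_run.csv", row.names = FALSE)

series <- do.call(rbind, lapply(names(ex$mean_series), function(key) {
  m <- ex$mean_series[[key]]
  cbind(pair = key, m)
}))
write.csv(series, "results/model2_mean_series.csv", row.names = FALSE)

cat("Crossing times of the across-run mean series (delay 900):\n")
print(ex$summary, row.names = FALSE)

zero <- run_replicates(sim_config(thresholds = c(8, 24), patch2_delay = 900,
                                  decay_rate = 0),
                       n_runs = 30, seed_base = 500, keep_fields = FALSE)
sw0 <- switch_summary(zero)
cat("\nZero-decay control at 8 vs 24: agents cross at",
    sw0$crossing_time_agents, "steps (switch without any evaporation).\n")
cat("Under strong crowding the colony reallocates its foragers before the\n")
cat("branch pheromone balance flips; without crowding (72 vs 216) it stays\n")
cat("committed to the first patch for the whole run.\n")
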