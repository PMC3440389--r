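#!/usr/bin/env Rscript
# Pheromone decay-rate sweep at the high-crowding pair (8 v 24, delay 900):
# how evaporation speed relates to the time of the forager switch and of the
# branch-pheromone switch, plus the log-decay regression.

library(antcrowd)

dir.create("results", showWarnings = FALSE)

rates <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6, 2.0)
sw <- sensitivity_sweep("decay_rate", values = rates, thresholds = c(8, 24),
                        delay = 900, n_runs = 30, seed_base = 21)
write.csv(sw$table, "results/decay_sweep_runs.csv", row.names = FALSE)
write.csv(sw$summary, "results/decay_sweep_summary.csv", row.names = FALSE)

cat("Crossing times by decay rate (mean series over 30 runs):\n")
print(sw$summary[c("value", "crossing_agents", "crossing_pheromone")],
      row.names = FALSE)

fit_a <- regress_switch_logdecay(sw$summary$value, sw$summary$crossing_agents)
fit_p <- regress_switch_logdecay(sw$summary$value,
                                 sw$summary$crossing_pheromone)
reg <- data.frame(series = c("agents", "arm_pheromone"),
                  slope = c(fit_a$slope, fit_p$slope),
                  t_value = c(fit_a$t_value, fit_p$t_value),
                  r_squared = c(fit_a$r_squared, fit_p$r_squared))
write.csv(reg, "results/decay_regression.csv", row.names = FALSE)
cat("\nRegression of crossing time on log(decay rate):\n")
print(reg, row.names = FALSE)
cat("\nIn this implementation the forager switch is carried by dissatisfied\n")
cat("random walkers that ignore the trail, so its timing barely moves with\n")
cat("the decay rate; the evaporation memory shows up in the branch-pheromone\n")
cat("crossing instead (negative slope). See the methods vignette.\n")
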