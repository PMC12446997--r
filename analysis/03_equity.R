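#!/usr/bin/env Rscript
# Distributional analysis: Atkinson EDEH per arm across the inequality
# aversion grid, the incremental EDEH per equity partition, equity-efficiency
# plane coordinates, population inequality burden, and the break-even
# inequality aversion at which expansion becomes welfare enhancing.

suppressPackageStartupMessages(library(dceacvd))

dir.create("results", showWarnings = FALSE)
seed <- 20260925

cfg <- population_config(n = 8141)
pop <- if (file.exists("results/population.csv")) {
  load_population("results/population.csv")
} else {
  generate_population(cfg, seed = seed)
}
rc <- run_config()
params <- apply_run_config(default_parameters(), rc)

res_non <- run_arm(pop, params, "nonexpansion", seed = seed, config = cfg)
res_exp <- run_arm(pop, params, "expansion", seed = seed, config = cfg)

summ <- dcea_summary(res_exp, res_non, params, epsilon = rc$epsilon_grid)
readr::write_csv(summ$equity, "results/equity_grid.csv")

plane <- summ$equity[summ$equity$epsilon == rc$epsilon,
                     c("partition", "plane_x", "plane_y", "quadrant")]
readr::write_csv(plane, "results/equity_efficiency_plane.csv")

for (p in unique(summ$equity$partition)) {
  eps_star <- suppressMessages(
    break_even_epsilon(res_exp, res_non, rc$wtp, partition = p)
  )
  cat(sprintf("%-15s IEDEH(eps=%.1f) = %+.5f; break-even eps: %s\n",
              p, rc$epsilon,
              summ$equity$iedeh[summ$equity$partition == p &
                                  summ$equity$epsilon == rc$epsilon],
              ifelse(is.na(eps_star), "none in [0, 20]",
                     sprintf("%.3f", eps_star))))
}
cat("wrote results/equity_grid.csv, results/equity_efficiency_plane.csv\n")
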