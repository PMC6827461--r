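#!/usr/bin/env Rscript
# Generate a duplex-seq-like data set from the model.
#
# The raw duplex-sequencing series behind the original turbidostat runs is
# not redistributed here, so the analysis is exercised end to end on
# synthetic data with the same statistical structure: per-site family
# counts at the ten focal sites drawn binomially at DCS depth 1e4 around
# the model's true trajectory, plus sporadic single-family flickering
# records at non-focal positions. Usage: Rscript 02_synthesize_data.R [--seed N]

suppressPackageStartupMessages(library(plasmidhet))

args <- commandArgs(trailingOnly = TRUE)
seed <- if ("--seed" %in% args) {
  as.integer(args[match("--seed", args) + 1L])
} else 20240901L

dir.create("results", showWarnings = FALSE)

cfg <- synth_config(
  true_params = optimized_params(),
  sampling_hours = c(12, 24, 36, 48, 60, 72, 84, 108, 156, 240, 318),
  dcs_depth_per_site = 1e4,
  flicker_rate = 2,
  seed = seed
)
out <- simulate_observed_series(cfg, replicate = "S1")

write_variant_table(out$table, "results/synthetic_variants.tsv")
write_series(out$noiseless, "results/true_series.csv")
write_trajectory(out$truth, "results/true_trajectory.csv")

cat(sprintf("seed %d: %d variant records over %d time points\n",
            seed, nrow(out$table), length(cfg$sampling_hours)))
cat(sprintf("true mutant frequency range: %.2e - %.2e\n",
            min(out$noiseless$frequency), max(out$noiseless$frequency)))
cat("wrote results/synthetic_variants.tsv\n")
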