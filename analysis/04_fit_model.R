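#!/usr/bin/env Rscript
# Multi-start least-squares fit of the seven model parameters.
#
# Minimizes the sum of squared differences between the simulated mutant
# fraction beta_t and the observed series, restarting a bounded
# Nelder-Mead search from starting points sampled inside the biological
# bounds (gamma, mu log10-uniform on [1e-10, 1e-2]; r, R on [1, 5]; S on
# (0.5, 1]; kappa*, kappa_T integers on {1..40}). The cost surface has
# multiple local minima, so only the trajectory -- not the individual
# parameters -- is identifiable. Usage: Rscript 04_fit_model.R [--seed N] [--restarts N]

suppressPackageStartupMessages(library(plasmidhet))

args <- commandArgs(trailingOnly = TRUE)
arg_of <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i)) default else as.integer(args[i + 1L])
}
seed <- arg_of("--seed", 4242L)
n_restarts <- arg_of("--restarts", 50L)

series <- read_series("results/observed_series.csv")
t0 <- Sys.time()
f <- fit(series, n_restarts = n_restarts, seed = seed, maxit = 1e4,
         abstol = 1e-8)
cat(sprintf("%d restarts (%d converged) in %.1f min\n", n_restarts,
            f$n_converged, as.numeric(Sys.time() - t0, units = "mins")))
print(f)

write_fit_json(f, "results/fit.json")
utils::write.csv(f$restarts, "results/fit_restarts.csv", row.names = FALSE)

fitted <- simulate_trajectory(f$best_params, max(series$generation))
resid <- fitted$beta[series$generation + 1] - series$frequency
cat(sprintf("best cost %.3g; max |residual| %.3g\n", f$best_cost,
            max(abs(resid))))
cat("wrote results/fit.json and results/fit_restarts.csv\n")
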