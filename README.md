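# plasmidhet

Why do adaptive mutations in a multicopy plasmid's copy-number control
machinery never fix? `plasmidhet` models the generation-to-generation
dynamics of wild-type and mutant copies of a ColE1-type plasmid (pBR322)
inside an evolving *E. coli* population, and fits that model to
duplex-sequencing allele-frequency time series. It is written for
experimental-evolution and plasmid-biology groups who track very
low-frequency variants (below the ~1% resolution of conventional
sequencing) across turbidostat time courses.

The core is a deterministic expected-value recursion over cell classes
`(g, w, m)` — chromosomal genotype, wild-type and mutant plasmid counts —
iterating three stages per generation:

* **division**, with random plasmid partitioning: a daughter receives
  `(j, k)` of its parent's `(w, m)` copies with probability
  `C(w,j) C(m,k) / 2^(w+m)` (binomial total × hypergeometric split);
* **replication**, at floor rates `w → ⌊wr⌋`, `m → ⌊mR⌋`, with chromosomal
  mutation at rate `γ` and each newly synthesized wild-type copy mutating
  with probability `μ`;
* **selection**, by a piecewise survival function that kills plasmid-free
  cells, ramps from the base-line `S` up to 1 at the optimal copy number
  `κ*`, falls to 0 at the lethal threshold `κ_T`, and grants chromosomal
  mutants survival 1 below the threshold.

The fitted statistic is the population mutant-plasmid fraction
`β_t = Σ m·p_t(w,m) / Σ (w+m)·p_t(w,m)`, and the seven parameters
`θ = (γ, μ, r, R, S, κ*, κ_T)` are estimated by multi-start bounded
least squares, `θ̂ = argmin Σ_i (x_ti − β_ti)²`, against the summed
frequencies of variants at the ten focal pBR322 sites (3,027–3,035 and
3,118). A synthetic duplex-seq generator with binomial sampling noise and
"flickering" single-family records makes the whole analysis runnable
end-to-end without the original data.

## Worked example

```r
library(plasmidhet)

params <- optimized_params()   # the optimized seven-parameter estimate
traj <- simulate_trajectory(params, 1000)
tail(traj, 1)
#>      generation        beta chrom_mutant_fraction
#> 1001       1000 0.004177748                     1

100 * max(traj$beta)      # peak mutant-plasmid fraction, percent
#> [1] 0.4177748
```

The mutant fraction climbs two orders of magnitude within ten generations
(mutant plasmids replicate at `R = 3.417` against `r = 1.539`), the
chromosomal mutation sweeps (half the population by generation 25), and
`β` settles at a plateau of 0.418% — below 0.5%, nowhere near fixation:
cells that accumulate mutant copies overshoot the lethal threshold
`κ_T = 25` and die, and the chromosomal sweep happens on wild-type-plasmid
backgrounds.

Fitting a series (here, one prepared from a synthetic variant table):

```r
cfg <- synth_config(params, seed = 20240901)
out <- simulate_observed_series(cfg, replicate = "S1")
series <- variant_series(out$table, "S1")
f <- fit(series, n_restarts = 40, seed = 4242, maxit = 1e4, abstol = 1e-8)
f$best_cost        # ~1e-6: at the binomial noise floor of depth-1e4 data
```

Only the trajectory is identifiable — the cost surface has many local
minima, so different restarts reach indistinguishable trajectories from
very different parameter sets (see the methods vignette,
`vignettes/plasmidhet-model.Rmd`).

## The analysis workflow

Numbered drivers under `analysis/` run the full study and write their
tables under `results/`:

1. `01_simulate_reference.R` — 1,000-generation reference trajectory;
2. `02_synthesize_data.R` — synthetic duplex-seq variant table at DCS
   depth 10⁴ over the turbidostat sampling hours;
3. `03_prepare_series.R` — variant table → observed mutant-frequency
   series (focal-site sums, hours → generations);
4. `04_fit_model.R` — multi-start fit of the series;
5. `05_growth_rates.R` — turbidostat growth-rate and generation-time
   arithmetic.

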