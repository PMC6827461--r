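---
title: "Modeling plasmid heteroplasmy under random segregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling plasmid heteroplasmy under random segregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidhet)
```

## The question

A multicopy ColE1-type plasmid such as pBR322 lives in 15--20 copies per
*E. coli* cell and segregates randomly at division. When a mutation in the
plasmid's replication-control machinery (the RNAI inhibitor loop at pBR322
positions 3,027--3,035, or the RNAII promoter at 3,118) raises copy number,
the cell becomes *heteroplasmic*: mutant and wild-type plasmid copies
coexist and compete inside one lineage. Duplex sequencing of turbidostat
populations shows such variants appearing almost immediately, hovering at
frequencies well below 1%, and collapsing once beneficial chromosomal
mutations sweep. `plasmidhet` implements the quantitative model of that
dynamics, the statistic it is fitted with, the least-squares fitting
protocol, and a synthetic duplex-seq data generator, so the whole analysis
is reproducible without the original sequencing data.

## The model

The population is described by masses $n_t(g, w, m)$ over cell classes:
chromosomal genotype $g \in \{0, 1\}$, $w$ wild-type and $m$ mutant plasmid
copies with $w + m \le \kappa_T - 1$. One generation applies, in order:

1. **Division.** Every cell divides; each plasmid independently lands in
   either daughter (a circular cell cut in half with plasmids scattered
   uniformly). One daughter's load is binomial in $w + m$ trials at
   probability $1/2$ and, given the total, the wild-type/mutant split is
   hypergeometric; algebraically the joint probability is
   $\binom{w}{j}\binom{m}{k} / 2^{w+m}$. Both daughters are kept, so mass
   doubles and the expected copy totals are conserved.
2. **Chromosomal mutation.** A fraction $\gamma$ of $g = 0$ mass moves to
   $g = 1$; there is no back-mutation.
3. **Plasmid replication.** Copy numbers grow at fixed floor rates:
   $(w, m) \mapsto (\lfloor w r \rfloor, \lfloor m R \rfloor)$, with
   $R > r$ encoding the replication advantage of copy-number mutants. The
   newly synthesized wild-type copies number
   $w_{\mathrm{new}} = \lfloor w r \rfloor - w$ (the model leaves
   $w_{\mathrm{new}}$ implicit; this post-minus-pre definition is the
   package's reading, and is non-negative because $r \ge 1$). Newly made
   mutant copies do not back-mutate.
4. **Plasmid mutation.** Each of the $w_{\mathrm{new}}$ new wild-type
   copies mutates independently with probability $\mu$, spreading
   $(w, m) \mapsto (w - k, m + k)$ with binomial weights. The per-cell
   total $w + m$ is conserved exactly.
5. **Selection.** Mass is weighted by the piecewise survival function
   $$S(g, n) = \begin{cases}
     1 & g = 1,\ 0 < n < \kappa_T\\
     S + (1 - S)\frac{n - 1}{\kappa^* - 1} & g = 0,\ 1 \le n \le \kappa^*\\
     \frac{\kappa_T - n}{\kappa_T - \kappa^*} & g = 0,\ \kappa^* < n \le \kappa_T\\
     0 & n = 0 \text{ or } n > \kappa_T
   \end{cases}$$
   with $n = w + m$: plasmid-free cells die (tetracycline selection),
   survival ramps up to 1 at the optimal copy number $\kappa^*$ and falls
   to 0 at the lethal threshold $\kappa_T$ (metabolic burden plus
   efflux-pump toxicity), and a chromosomal mutation confers the full
   advantage regardless of copy number.

The fitted statistic is the population mutant-plasmid fraction
$$\beta_t = \frac{\sum m\, p_t(w, m)}{\sum (w + m)\, p_t(w, m)},$$
pooling both genotypes, recorded after selection and renormalization of
each generation ($\beta_0 = 0$ on the founder state).

### Resolved ambiguities

The written recursion leaves a few cases open; the package resolves them as
follows and treats the choices as part of the model definition.

* **Survival at exactly $\kappa_T$ for $g = 1$:** the first branch requires
  $n < \kappa_T$ and the last $n > \kappa_T$. The package sets survival 0
  at $n = \kappa_T$, consistent with the $g = 0$ ramp which reaches exactly
  0 there: the threshold is lethal for both genotypes.
* **$\kappa^* = 1$:** the up-ramp divides by $\kappa^* - 1$; the package
  collapses it to its endpoint, survival 1 at a single copy.
* **Deterministic weights versus Bernoulli draws:** survival probabilities
  are applied as expected-value weights, which is what the displayed
  recursion $n_{t+1} = n\, S$ states. The stochastic reading is covered by
  an independent agent-based Monte-Carlo simulator in the test suite
  (explicit cells, Bernoulli survival), which must agree with the
  recursion within 3 Monte-Carlo standard errors on small instances
  ($\kappa_T = 8$, $10^4$ founder cells, 5 generations, 20 seeds).
* **Transient domain overshoot:** floor-rate replication necessarily
  pushes $w + m$ past $\kappa_T - 1$ even though the model's sums index
  only up to $\kappa_T - 1$; the pure-R step functions hold these states
  on an extended grid until selection zeroes everything at or above
  $\kappa_T$. The compiled engine notes that a class's post-replication
  total already determines its fate and skips doomed classes outright.

## Parameters

| Parameter | Meaning | Units / range | Reference value |
|---|---|---|---|
| $\gamma$ | chromosomal mutation probability | per cell per generation, $[10^{-10}, 10^{-2}]$ | $1.55 \times 10^{-3}$ |
| $\mu$ | plasmid mutation probability | per new copy, $[10^{-10}, 10^{-2}]$ | $5.09 \times 10^{-5}$ |
| $r$ | wild-type replication rate | dimensionless, $[1, 5]$ | 1.539 |
| $R$ | mutant replication rate | dimensionless, $[1, 5]$ | 3.417 |
| $S$ | base-line fitness at one plasmid | probability, $(0.5, 1]$ | 0.780 |
| $\kappa^*$ | optimal copy number | integer, $\{1..40\}$ | 20 |
| $\kappa_T$ | lethal threshold | integer, $\{1..40\}$, $> \kappa^*$ | 25 |
| $w_0$ | founder wild-type copies | integer, $< \kappa_T$ | 20 |

The reference column is the optimized estimate from fitting the long-term
turbidostat series; it ships as `inst/extdata/optimized_params.json` and
loads with `optimized_params()`. $S \le 0.5$ would mean no net growth
between generations, hence the open lower bound. The search treats both
copy-number parameters as drawn from $\{1, \dots, 40\}$ with
$\kappa^* < \kappa_T$ (the published bounds table; the accompanying text
narrows $\kappa_T$ to $\{21..40\}$, but the package follows the table).

## What the reference simulation shows

```{r}
traj <- simulate_trajectory(optimized_params(), 1000)
c(peak = max(traj$beta), terminal = traj$beta[1001])
```

Under the reference parameters the mutant fraction rises by two orders of
magnitude within the first ten generations (the $R/r$ advantage), while
the chromosomal mutation sweeps within a few dozen generations, and
$\beta_t$ settles at a plateau of about 0.42% -- below 0.5%, and far from
fixation. Copy-number variants linger but cannot fix: cells that
accumulate mutant copies overshoot $\kappa_T$ and die, and chromosomally
mutated cells (which arise essentially always on wild-type-plasmid
backgrounds) take over the population. In this implementation the approach
to the plateau is essentially monotone -- the pronounced transient
overshoot-and-decline seen in the original figure is not produced by the
recursion as written here; the quantitative headline (plateau below 0.5%)
is.

## Inference

Given an observed series $x = (x_{t_1}, \dots, x_{t_I})$, the cost is
$J_\theta(x) = \sum_i (x_{t_i} - \beta_{t_i})^2$. Parameter sets that
drive the population extinct score $+\infty$ so the optimizer routes
around them rather than aborting.

The surface is genuinely awkward: $r$ and $R$ act only through the floor
maps $a \mapsto \lfloor a r \rfloor$, and $\kappa^*, \kappa_T$ are
integers, so the cost is piecewise constant in four of the seven
coordinates and finite-difference gradients vanish almost everywhere.
`fit()` therefore runs Nelder-Mead on a logistic-transformed box
($\gamma$, $\mu$ on the log10 scale; the integer parameters as continuous
values on $[0.5, 40.5]$ rounded inside every evaluation, clamping
$\kappa^* \le \kappa_T - 1$), with one simplex restart from the first
endpoint to escape degenerate simplexes, a configurable evaluation cap
(default $10^6$), and an optional absolute stop once the cost is good
enough. Starts are sampled inside the bounds on the documented scales; one
master seed spawns a per-restart seed stream, so any prefix of restarts
replays identically and the best cost is non-increasing in the restart
count. A restart counts as converged when the optimizer reports normal
termination; the best converged restart wins.

Because the surface has many local minima, individual parameters are not
identifiable -- on a noiseless series generated from known parameters the
fit routinely lands in a different basin whose trajectory is
indistinguishable (the tests assert trajectory recovery, with the best
cost at or below $10^{-6}$ and the refitted trajectory within $10^{-3}$ of
the series, never per-parameter equality). This mirrors the published
protocol, which reports the best of 1,863 converged restarts; the restart
count here is a knob (default 100) since that figure was a stopping
artifact rather than a requirement.

## Synthetic duplex-seq data

The raw per-time-point variant tables behind the original analysis are not
redistributed, so `synth_config()` / `simulate_observed_series()` emulate
their statistical structure: the model's true $\beta$ at each sampling
hour (60-minute generations, so hour $h$ is generation $h$) is split
across the ten focal sites by weights (uniform by default; real per-site
frequencies are heterogeneous but unpublished), each site's duplex family
count is drawn binomially at a configurable DCS depth, and sporadic
non-focal "flickering" records with a single supporting family are added
at a Poisson rate per time point, at positions independent across time
points. The default depth of $10^4$ per site makes frequencies near
$10^{-3}$ -- the regime of the experiment -- resolvable but visibly noisy,
which is what the inference must cope with.

What the generator does *not* emulate: duplex family-size distributions
and consensus-calling artifacts, depth variation across sites and time
points, indels, linkage between sites (none was observed), or persistent
low-frequency variants. Passing tests therefore demonstrate correctness of
the pipeline's statistics under binomial sampling noise, not robustness to
every failure mode of real duplex data.

`empirical_mutant_frequency()` is the reader-side counterpart: it sums
`family_count / dcs_depth` over single-nucleotide records at the focal
sites (1-based pBR322 coordinates), excludes everything else -- flickering
positions and indels, which showed no frequency fluctuation -- sums
multiple alternate alleles at one site, never pools replicates, and clamps
at 1 with a warning (unreachable in the experiment's $\ll 1$ regime). With
sum-normalized site weights a single site's sampling probability can never
exceed 1, so the generator's corresponding guard is purely defensive.

## Numerical choices

* **Partition kernel:** built once from exact binomial coefficients
  ($\binom{40}{20} \approx 1.4 \times 10^{11}$, comfortably inside double
  precision) as a half-binomial matrix $H[a, j] = \binom{a}{j}/2^a$, whose
  outer products give every daughter table; division is the rank-reduced
  product $2 H^\top N H$.
* **Floors:** $\lfloor a r \rfloor$ is computed as
  `floor(a * r + 1e-9)` to guard against products like
  $6 - 10^{-16}$; the guard is far below the spacing of attainable
  products.
* **Renormalization:** masses are renormalized to 1 after selection each
  generation. Every step is linear in mass, so $\beta_t$ is unaffected
  (a tested invariant), and the $2\times$ growth at division cannot
  overflow over long horizons.
* **Truncation in the compiled engine:** mutant-count columns and genotype
  classes carrying less than $10^{-30}$ of the population are skipped;
  their per-generation feedback is below double-precision resolution of
  any reported statistic. The pure-R reference path does no truncation,
  and both engines agree to $10^{-12}$ in the tests (observed agreement is
  $\sim 10^{-16}$).
* **Problem sizes:** the test suite exercises trajectory recovery with 50
  restarts at an evaluation cap of $10^4$ per restart and an absolute stop
  of $10^{-8}$, the end-to-end synthetic fit with 25 restarts, the
  Monte-Carlo oracle with 20 seeds of $10^4$ cells for 5 generations, and
  the kernel identity over the full $a + b \le 40$ range. These sizes make
  the whole suite run in minutes on one core while keeping every check at
  the scale the claims require.

## Limitations

The model is deterministic in expectation and well-mixed: no spatial
structure or biofilms, no plasmid multimerization or non-random
segregation, and a single mutant class (no distinct per-site effects, no
multi-mutation plasmids -- none were observed). Selection's functional
form is one of many plausible frequency-dependent choices; alternative
fitness families are out of scope. Inference reports point estimates only,
with no uncertainty quantification, and fits one series at a time --
pooling replicates is deliberately left to the caller.
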