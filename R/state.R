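#' Population state over (genotype, wild-type, mutant) cell classes
#'
#' The model tracks, for every cell class `(g, w, m)` -- chromosomal genotype
#' `g` in `{0, 1}`, `w` wild-type and `m` mutant plasmids with
#' `w + m <= bound` -- a non-negative real mass (an expected cell count or,
#' after normalization, a frequency). The steady-state bound is
#' `kappa_T - 1`; replication transiently extends it.
#'
#' @param mass Numeric array of dimension `c(2, bound + 1, bound + 1)`;
#'   `mass[g + 1, w + 1, m + 1]` is the weight of class `(g, w, m)`. Entries
#'   with `w + m > bound` must be zero.
#' @param bound Maximum stored total copy number.
#' @param wnew_by_w Optional integer vector of length `bound + 1`: number of
#'   newly synthesized wild-type plasmids for cells whose post-replication
#'   wild-type count is `w` (index `w + 1`). Present only between the
#'   replication and plasmid-mutation steps.
#' @return An object of class `population_state`.
#' @export
population_state <- function(mass, bound, wnew_by_w = NULL) {
  bound <- as.integer(bound)
  stopifnot(is.array(mass), length(dim(mass)) == 3L,
            all(dim(mass) == c(2L, bound + 1L, bound + 1L)))
  if (any(mass < 0)) stop("population masses must be non-negative")
  tot <- outer(0:bound, 0:bound, "+")
  for (g in 1:2) {
    if (any(mass[g, , ][tot > bound] != 0))
      stop("mass present outside the triangular domain w + m <= bound")
  }
  structure(list(mass = mass, bound = bound, wnew_by_w = wnew_by_w),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf(
    "population_state: bound %d, total mass %.6g, %d live classes\n",
    x$bound, total_mass(x), sum(x$mass > 0)))
  invisible(x)
}

#' Total mass of a population state
#' @param state A `population_state`.
#' @return Sum of all class masses.
#' @export
total_mass <- function(state) sum(state$mass)

#' Rescale a population state to total mass 1
#' @param state A `population_state` with positive total mass.
#' @return A normalized `population_state`.
#' @export
normalize_state <- function(state) {
  tot <- total_mass(state)
  if (tot <= 0) stop("cannot normalize a state with zero total mass")
  state$mass <- state$mass / tot
  state
}

#' Initial population: founder cells only
#'
#' Places all mass on the class `(g = 0, w = w0, m = 0)`: chromosomally
#' wild-type cells carrying `w0` wild-type plasmids and no mutant plasmids,
#' on the steady-state domain `w + m <= kappa_T - 1`.
#'
#' @param params A `model_params` object.
#' @return A normalized `population_state`.
#' @export
initialize_population <- function(params) {
  stopifnot(inherits(params, "model_params"))
  bound <- params$kappa_T - 1L
  mass <- array(0, dim = c(2L, bound + 1L, bound + 1L))
  mass[1L, params$w0 + 1L, 1L] <- 1
  population_state(mass, bound)
}

# floor() guarded against values like 6 - 1e-16 produced by a * r in
# floating point; the guard is far below any attainable spacing of a * r
.guarded_floor <- function(x) floor(x + 1e-9)

#' Division: random partition of plasmids into two daughters
#'
#' Every cell of class `(g, a, b)` divides into two daughters; each plasmid
#' independently lands in either daughter, so one daughter's composition
#' `(j, k)` has probability `choose(a, j) * choose(b, k) / 2^(a+b)` and the
#' other receives the complement. Both daughters are accumulated, so total
#' cell mass exactly doubles, and the expected wild-type and mutant copy
#' totals are each conserved.
#'
#' @param state A `population_state`.
#' @param kernel A `partition_kernel` with `max_total >= state$bound`.
#' @return The post-division `population_state` (same bound).
#' @export
division_step <- function(state, kernel) {
  stopifnot(inherits(state, "population_state"),
            inherits(kernel, "partition_kernel"))
  if (state$bound > kernel$max_total)
    stop("state compositions exceed the kernel's max_total")
  n <- state$bound + 1L
  A <- kernel$half_binom[seq_len(n), seq_len(n), drop = FALSE]
  out <- state$mass
  for (g in 1:2) {
    # n_div(w, m) = 2 * sum_{a,b} n(a, b) H[a, w] H[b, m]; the factor 2
    # folds in the second daughter, whose table is the reflection of the
    # first and integrates to the same marginal by symmetry of H
    out[g, , ] <- 2 * crossprod(A, state$mass[g, , ] %*% A)
  }
  population_state(out, state$bound)
}

#' Chromosomal mutation
#'
#' Moves a fraction `gamma` of each `g = 0` class to the matching `g = 1`
#' class. No back-mutation; total mass conserved.
#'
#' @param state A `population_state`.
#' @param gamma Chromosomal mutation probability per generation, in `[0, 1]`.
#' @return The updated `population_state`.
#' @export
chromosomal_mutation_step <- function(state, gamma) {
  stopifnot(inherits(state, "population_state"),
            gamma >= 0, gamma <= 1)
  mass <- state$mass
  mass[2L, , ] <- mass[2L, , ] + gamma * mass[1L, , ]
  mass[1L, , ] <- (1 - gamma) * mass[1L, , ]
  population_state(mass, state$bound, state$wnew_by_w)
}

#' Plasmid replication at floor rates
#'
#' Each cell's wild-type count `a` becomes `floor(a * r)` and its mutant
#' count `b` becomes `floor(b * R_mut)`. The domain bound is extended to
#' `floor(bound * max(r, R_mut))` to hold the overshoot until selection
#' removes classes at or above `kappa_T`. The per-class count of newly
#' synthesized wild-type plasmids, `w_new = floor(a * r) - a`, is retained
#' for the plasmid-mutation step.
#'
#' @param state A `population_state`.
#' @param r,R_mut Replication rates, both `>= 1`.
#' @return A `population_state` on the extended domain carrying `wnew_by_w`.
#' @export
plasmid_replication_step <- function(state, r, R_mut) {
  stopifnot(inherits(state, "population_state"))
  if (r < 1 || R_mut < 1) stop("replication rates must be >= 1")
  B <- state$bound
  B2 <- as.integer(.guarded_floor(B * max(r, R_mut)))
  w2 <- as.integer(.guarded_floor((0:B) * r))      # strictly increasing
  m2 <- as.integer(.guarded_floor((0:B) * R_mut))
  mass <- array(0, dim = c(2L, B2 + 1L, B2 + 1L))
  for (g in 1:2) mass[g, w2 + 1L, m2 + 1L] <- state$mass[g, , ]
  wnew <- rep(NA_integer_, B2 + 1L)
  wnew[w2 + 1L] <- w2 - 0:B
  population_state(mass, B2, wnew_by_w = wnew)
}

#' Plasmid mutation of newly synthesized wild-type copies
#'
#' Each of a cell's `w_new` newly synthesized wild-type plasmids mutates
#' independently with probability `mu`, sending class `(w, m)` to
#' `(w - k, m + k)` with binomial weight `dbinom(k, w_new, mu)`. Total cell
#' mass and each cell's total copy number `w + m` are conserved exactly.
#'
#' @param state A `population_state` produced by [plasmid_replication_step()]
#'   (it must carry the `wnew_by_w` record).
#' @param mu Mutation probability per newly synthesized plasmid, in `[0, 1]`.
#' @return The updated `population_state` (record cleared).
#' @export
plasmid_mutation_step <- function(state, mu) {
  stopifnot(inherits(state, "population_state"), mu >= 0, mu <= 1)
  if (is.null(state$wnew_by_w))
    stop("plasmid_mutation_step needs the w_new record from plasmid_replication_step")
  B <- state$bound
  nc <- B + 1L
  mass <- array(0, dim = dim(state$mass))
  for (g in 1:2) {
    N <- state$mass[g, , ]
    for (wi in seq_len(nc)) {
      if (all(N[wi, ] == 0)) next
      v <- state$wnew_by_w[wi]
      if (is.na(v)) v <- 0L  # row unreachable by replication but mass-free anyway
      wts <- stats::dbinom(0:v, v, mu)
      for (k in 0:v) {
        cols <- seq_len(nc - k)
        mass[g, wi - k, cols + k] <- mass[g, wi - k, cols + k] +
          wts[k + 1L] * N[wi, cols]
      }
    }
  }
  population_state(mass, B)
}

#' Piecewise frequency-dependent survival probability
#'
#' Survival of a cell as a function of its chromosomal genotype and total
#' plasmid count `n = w + m`:
#' \itemize{
#'   \item `g = 1`, `0 < n < kappa_T`: survival 1 (the chromosomal mutation
#'     confers the full growth advantage regardless of copy number);
#'   \item `g = 0`, `1 <= n <= kappa_star`: linear ramp from `S_base` at one
#'     copy up to 1 at the optimal number `kappa_star`;
#'   \item `g = 0`, `kappa_star < n <= kappa_T`: linear fall from 1 down to 0
#'     at the lethal threshold `kappa_T`;
#'   \item `n = 0` or `n >= kappa_T`: survival 0 (plasmid-free cells are
#'     killed by the antibiotic; overloaded cells by the metabolic burden and
#'     efflux-pump overexpression). The threshold itself is lethal for both
#'     genotypes.
#' }
#' With `kappa_star = 1` the ramp collapses to its endpoint: one plasmid
#' already gives survival 1.
#'
#' @param g Chromosomal genotype flag, 0 or 1 (vectorized).
#' @param n_plasmids Total plasmid count, non-negative integer (vectorized).
#' @param params A `model_params` object.
#' @return Survival probabilities in `[0, 1]`.
#' @export
fitness <- function(g, n_plasmids, params) {
  stopifnot(inherits(params, "model_params"), all(g %in% c(0, 1)))
  if (any(n_plasmids < 0)) stop("n_plasmids must be non-negative")
  ks <- params$kappa_star
  kT <- params$kappa_T
  S <- params$S_base
  n <- n_plasmids
  ramp_up <- if (ks == 1L) rep(1, length(n)) else S + (1 - S) * (n - 1) / (ks - 1)
  ramp_down <- (kT - n) / (kT - ks)
  out <- numeric(length(n))
  out[g == 1 & n > 0 & n < kT] <- 1
  i <- which(g == 0 & n >= 1 & n <= ks)
  out[i] <- ramp_up[i]
  i <- which(g == 0 & n > ks & n <= kT)
  out[i] <- ramp_down[i]
  out
}

#' Selection: weight each class by its survival probability
#'
#' Multiplies every class mass by [fitness()]. All classes with `w + m = 0`
#' or `w + m >= kappa_T` end with zero mass, so the output is returned on the
#' steady-state domain `w + m <= kappa_T - 1`.
#'
#' @param state A `population_state`, possibly on an extended domain.
#' @param params A `model_params` object.
#' @return A `population_state` with bound `kappa_T - 1`.
#' @export
selection_step <- function(state, params) {
  stopifnot(inherits(state, "population_state"),
            inherits(params, "model_params"))
  B <- state$bound
  tot <- outer(0:B, 0:B, "+")
  keep <- tot <= B  # guard: entries beyond the triangle are structurally 0
  mass <- state$mass
  for (g in 1:2) {
    f <- matrix(fitness(g - 1L, pmax(tot, 0L), params), B + 1L, B + 1L)
    mass[g, , ] <- mass[g, , ] * f * keep
  }
  Bout <- params$kappa_T - 1L
  out <- array(0, dim = c(2L, Bout + 1L, Bout + 1L))
  idx <- seq_len(min(B, Bout) + 1L)
  out[, idx, idx] <- mass[, idx, idx]
  population_state(out, Bout)
}

#' One full generation of the recursion
#'
#' Composes division, chromosomal mutation, plasmid replication, plasmid
#' mutation and selection, then renormalizes to total mass 1. Every step is
#' linear in mass, so the renormalization leaves the mutant fraction
#' statistic unchanged while preventing overflow from the two-fold growth at
#' division.
#'
#' @param state A normalized `population_state` on the steady-state domain.
#' @param params A `model_params` object.
#' @param kernel A `partition_kernel` covering the state's bound.
#' @return The next generation's normalized `population_state`.
#' @export
generation_step <- function(state, params, kernel) {
  s <- division_step(state, kernel)
  s <- chromosomal_mutation_step(s, params$gamma)
  s <- plasmid_replication_step(s, params$r, params$R_mut)
  s <- plasmid_mutation_step(s, params$mu)
  s <- selection_step(s, params)
  if (total_mass(s) <= 0)
    stop("population extinct: no cells survive selection under these parameters")
  normalize_state(s)
}

#' Mutant-plasmid fraction of a population
#'
#' The population-wide proportion of plasmid molecules that are mutant,
#' pooling both chromosomal genotypes:
#' `beta = sum(m * p(w, m)) / sum((w + m) * p(w, m))`.
#'
#' @param state A `population_state` with a nonzero total plasmid count.
#' @return `beta` in `[0, 1]`.
#' @export
mutant_fraction <- function(state) {
  stopifnot(inherits(state, "population_state"))
  B <- state$bound
  wgrid <- matrix(0:B, B + 1L, B + 1L)
  mgrid <- t(wgrid)
  pooled <- state$mass[1L, , ] + state$mass[2L, , ]
  den <- sum((wgrid + mgrid) * pooled)
  if (den <= 0) stop("mutant fraction undefined: population holds no plasmids")
  sum(mgrid * pooled) / den
}

#' Fraction of cells carrying the chromosomal mutation
#' @param state A `population_state` with positive total mass.
#' @return Mass-weighted fraction of `g = 1` cells.
#' @export
chromosomal_mutant_fraction <- function(state) {
  tot <- total_mass(state)
  if (tot <= 0) stop("empty population")
  sum(state$mass[2L, , ]) / tot
}
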