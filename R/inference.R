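#' Observed mutant-frequency time series
#'
#' @param generations Strictly increasing non-negative integer sampling
#'   generations.
#' @param frequencies Observed mutant-plasmid fractions in `[0, 1]`, one per
#'   generation.
#' @return A data frame of class `observed_series` with columns `generation`
#'   and `frequency`.
#' @export
observed_series <- function(generations, frequencies) {
  stopifnot(length(generations) == length(frequencies),
            length(generations) >= 1L)
  generations <- as.integer(generations)
  if (any(generations < 0) || any(diff(generations) <= 0))
    stop("generations must be strictly increasing and non-negative")
  if (any(frequencies < 0) || any(frequencies > 1))
    stop("frequencies must lie in [0, 1]")
  structure(data.frame(generation = generations, frequency = frequencies),
            class = c("observed_series", "data.frame"))
}

#' Read / write an observed series as CSV
#'
#' Columns: `generation, frequency`.
#' @param path File path.
#' @return `read_series` returns an `observed_series`; `write_series`
#'   returns `path` invisibly.
#' @export
read_series <- function(path) {
  x <- utils::read.csv(path)
  observed_series(x$generation, x$frequency)
}

#' @param series An `observed_series`.
#' @rdname read_series
#' @export
write_series <- function(series, path) {
  utils::write.csv(as.data.frame(series)[, c("generation", "frequency")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default parameter bounds for the multi-start fit
#'
#' The search box for the seven model parameters: mutation rates `gamma`
#' and `mu` in `[1e-10, 1e-2]` sampled uniformly on the log10 scale;
#' replication rates `r`, `R` uniform in `[1, 5]`; base-line fitness `S`
#' uniform in `(0.5, 1]`; `kappa_star`, `kappa_T` integer-uniform on
#' `{1, ..., 40}` resampled until `kappa_star < kappa_T`.
#'
#' @return A named list of `c(lower, upper)` bounds with a `scales`
#'   attribute naming the sampling scale of each parameter.
#' @export
parameter_bounds <- function() {
  structure(
    list(gamma = c(1e-10, 1e-2), mu = c(1e-10, 1e-2),
         r = c(1, 5), R = c(1, 5), S = c(0.5, 1),
         kappa_star = c(1, 40), kappa_T = c(1, 40)),
    scales = c(gamma = "log10", mu = "log10", r = "uniform", R = "uniform",
               S = "uniform", kappa_star = "integer", kappa_T = "integer")
  )
}

#' Draw a random starting parameter set
#'
#' Sampling follows the scales in [parameter_bounds()]: `gamma`, `mu`
#' log10-uniform, `r`, `R`, `S` uniform, `kappa_star`, `kappa_T`
#' integer-uniform resampled until `kappa_star < kappa_T`. Uses the current
#' R random number stream, so draws are reproducible under `set.seed()`.
#'
#' @param bounds Bounds list as returned by [parameter_bounds()].
#' @param w0 Initial copy number passed through to the parameter set.
#' @return A `model_params` object.
#' @export
sample_initial_parameters <- function(bounds = parameter_bounds(), w0 = 20L) {
  gamma <- 10^stats::runif(1, log10(bounds$gamma[1]), log10(bounds$gamma[2]))
  mu <- 10^stats::runif(1, log10(bounds$mu[1]), log10(bounds$mu[2]))
  r <- stats::runif(1, bounds$r[1], bounds$r[2])
  R <- stats::runif(1, bounds$R[1], bounds$R[2])
  S <- stats::runif(1, bounds$S[1], bounds$S[2])
  repeat {
    ks <- sample(bounds$kappa_star[1]:bounds$kappa_star[2], 1L)
    kT <- sample(bounds$kappa_T[1]:bounds$kappa_T[2], 1L)
    if (ks < kT && w0 < kT) break
  }
  model_params(gamma = gamma, mu = mu, r = r, R_mut = R,
               S_base = max(S, 0.5 + 1e-12), kappa_star = ks, kappa_T = kT,
               w0 = w0)
}

#' Least-squares cost of a parameter set against an observed series
#'
#' Simulates the model out to the last observed generation and returns the
#' sum of squared differences between the simulated mutant fraction
#' `beta_t` and the observed frequencies at the sampled generations.
#' Parameter sets that drive the population extinct score `Inf`, so an
#' optimizer routes around them.
#'
#' @param params A `model_params` object.
#' @param observed An `observed_series`.
#' @return Non-negative cost (possibly `Inf`).
#' @export
cost <- function(params, observed) {
  stopifnot(inherits(params, "model_params"),
            inherits(observed, "observed_series"))
  ngen <- max(observed$generation)
  res <- .simulate_trajectory_cpp(params$gamma, params$mu, params$r,
                                  params$R_mut, params$S_base,
                                  params$kappa_star, params$kappa_T,
                                  params$w0, ngen)
  if (res$extinct_at >= 0) return(Inf)
  beta <- res$beta[observed$generation + 1L]
  sum((observed$frequency - beta)^2)
}

# --- bounded Nelder-Mead machinery -----------------------------------------
# The cost surface is piecewise constant in r, R (they act only through
# floor(a * r), floor(b * R)) and in the rounded integer kappas, so
# finite-difference gradients vanish almost everywhere; a simplex search on
# a smoothly transformed box handles this. Coordinates: z in R^7 maps to
# (log10 gamma, log10 mu, r, R, S, kappa*, kappa_T) by a logistic squashed
# into the bounds; the kappas are optimized as continuous values on
# [0.5, 40.5] and rounded to the nearest integer inside every cost
# evaluation (clamping kappa* <= kappa_T - 1).

.z_box <- function(bounds) {
  rbind(c(log10(bounds$gamma[1]), log10(bounds$gamma[2])),
        c(log10(bounds$mu[1]), log10(bounds$mu[2])),
        bounds$r, bounds$R, bounds$S,
        c(bounds$kappa_star[1] - 0.5, bounds$kappa_star[2] + 0.5),
        c(bounds$kappa_T[1] - 0.5, bounds$kappa_T[2] + 0.5))
}

.z_to_p <- function(z, box) {
  box[, 1] + (box[, 2] - box[, 1]) / (1 + exp(-z))
}

.p_to_z <- function(p, box) {
  f <- pmin(pmax((p - box[, 1]) / (box[, 2] - box[, 1]), 1e-9), 1 - 1e-9)
  log(f / (1 - f))
}

.params_from_p <- function(p, w0) {
  kT <- max(2L, as.integer(round(p[7])))
  ks <- min(max(1L, as.integer(round(p[6]))), kT - 1L)
  model_params(gamma = 10^p[1], mu = 10^p[2], r = p[3], R_mut = p[4],
               S_base = min(max(p[5], 0.5 + 1e-9), 1), kappa_star = ks,
               kappa_T = kT, w0 = min(w0, kT - 1L))
}

#' Fit the model to an observed series by multi-start least squares
#'
#' Runs `n_restarts` bounded local optimizations (Nelder-Mead on a
#' logistic-transformed box, with one simplex restart from the first
#' endpoint), each from an independently sampled starting parameter set,
#' and returns the converged restart with the smallest cost. One master
#' seed spawns a per-restart seed stream, so any prefix of restarts is
#' replayable and the best cost is non-increasing in `n_restarts`.
#'
#' The integer copy-number parameters `kappa_star` and `kappa_T` are
#' optimized as continuous values and rounded inside every cost
#' evaluation; `gamma` and `mu` are optimized on the log10 scale.
#'
#' @param observed An `observed_series`.
#' @param bounds Bounds list from [parameter_bounds()].
#' @param n_restarts Number of random restarts (default 100).
#' @param seed Master RNG seed (integer). `NULL` leaves the current stream.
#' @param maxit Cap on cost evaluations per restart (split across the two
#'   Nelder-Mead cycles; default 1e6).
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @param abstol Absolute stop: a restart halts as soon as its cost falls
#'   to or below this value (default 0, i.e. disabled).
#' @param w0 Initial copy number held fixed during fitting (default 20).
#' @return An object of class `plasmid_fit`: list with `best_params`,
#'   `best_cost`, `n_converged`, `restarts` (per-restart table of parameter
#'   values, cost and convergence flag), and `seed`.
#' @export
fit <- function(observed, bounds = parameter_bounds(), n_restarts = 100L,
                seed = NULL, maxit = 1e6, reltol = 1e-8, abstol = 0,
                w0 = 20L) {
  stopifnot(inherits(observed, "observed_series"), n_restarts >= 1L)
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_restarts)
  box <- .z_box(bounds)
  obj <- function(z) {
    p <- .z_to_p(z, box)
    cost(.params_from_p(p, w0), observed)
  }
  rows <- vector("list", n_restarts)
  best_cost <- Inf
  best_params <- NULL
  n_converged <- 0L
  for (i in seq_len(n_restarts)) {
    set.seed(sub_seeds[i])
    start <- sample_initial_parameters(bounds, w0 = w0)
    z0 <- .p_to_z(c(log10(start$gamma), log10(start$mu), start$r,
                    start$R_mut, start$S_base, start$kappa_star,
                    start$kappa_T), box)
    ctl <- list(maxit = ceiling(maxit / 2), reltol = reltol,
                abstol = if (abstol > 0) abstol else -Inf)
    o1 <- stats::optim(z0, obj, method = "Nelder-Mead", control = ctl)
    o2 <- if (abstol > 0 && o1$value <= abstol) o1 else
      stats::optim(o1$par, obj, method = "Nelder-Mead", control = ctl)
    converged <- o2$convergence == 0L
    pars <- .params_from_p(.z_to_p(o2$par, box), w0)
    rows[[i]] <- data.frame(
      restart = i, seed = sub_seeds[i], cost = o2$value,
      converged = converged, gamma = pars$gamma, mu = pars$mu, r = pars$r,
      R = pars$R_mut, S = pars$S_base, kappa_star = pars$kappa_star,
      kappa_T = pars$kappa_T)
    if (converged) {
      n_converged <- n_converged + 1L
      if (o2$value < best_cost) {
        best_cost <- o2$value
        best_params <- pars
      }
    }
  }
  if (n_converged == 0L)
    stop("fit failed: no restart converged")
  structure(list(best_params = best_params, best_cost = best_cost,
                 n_converged = n_converged,
                 restarts = do.call(rbind, rows), seed = seed),
            class = "plasmid_fit")
}

#' @export
print.plasmid_fit <- function(x, ...) {
  cat(sprintf("Multi-start fit: %d/%d restarts converged, best cost %.4g\n",
              x$n_converged, nrow(x$restarts), x$best_cost))
  print(x$best_params)
  invisible(x)
}

#' Write a fit result as JSON
#'
#' Records the best parameter set, its cost, the number of converged
#' restarts, the master seed, and the full per-restart table.
#'
#' @param fit_result A `plasmid_fit` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit_result, path) {
  stopifnot(inherits(fit_result, "plasmid_fit"))
  bp <- fit_result$best_params
  jsonlite::write_json(
    list(best_params = list(gamma = bp$gamma, mu = bp$mu, r = bp$r,
                            R = bp$R_mut, S = bp$S_base,
                            kappa_star = bp$kappa_star,
                            kappa_T = bp$kappa_T, w0 = bp$w0),
         best_cost = fit_result$best_cost,
         n_converged = fit_result$n_converged,
         seed = fit_result$seed,
         restarts = fit_result$restarts),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
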