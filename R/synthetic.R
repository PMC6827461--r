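#' Configuration for the synthetic duplex-seq data generator
#'
#' Describes a simulated turbidostat run sampled by duplex sequencing: the
#' generating model parameters, the sampling schedule, the duplex consensus
#' depth, how the population mutant frequency decomposes over the ten focal
#' sites, and the rate of sporadic single-family "flickering" calls at
#' non-focal positions.
#'
#' @param true_params `model_params` generating the underlying trajectory.
#' @param sampling_hours Sampling times in hours (one generation per hour by
#'   default: the modeled generation time is 60 min).
#' @param dcs_depth_per_site Duplex consensus depth at every site (default
#'   `1e4`, which resolves frequencies near `1e-3` but leaves visible
#'   binomial noise).
#' @param site_weights Ten non-negative weights summing to 1: the fraction
#'   of the mutant signal carried by each focal site (default uniform).
#' @param flicker_rate Expected number of single-family non-focal records
#'   per time point (Poisson; default 2).
#' @param seed RNG seed recorded in the config and used by
#'   [simulate_observed_series()].
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(true_params,
                         sampling_hours = c(12, 24, 36, 48, 60, 72, 84, 108,
                                            156, 240, 318),
                         dcs_depth_per_site = 1e4,
                         site_weights = rep(1 / 10, 10),
                         flicker_rate = 2,
                         seed = 1L) {
  stopifnot(inherits(true_params, "model_params"),
            all(sampling_hours >= 0), dcs_depth_per_site > 0,
            length(site_weights) == 10L, all(site_weights >= 0),
            flicker_rate >= 0)
  if (abs(sum(site_weights) - 1) > 1e-9)
    stop("site_weights must sum to 1")
  structure(list(true_params = true_params,
                 sampling_hours = sort(sampling_hours),
                 dcs_depth_per_site = as.integer(dcs_depth_per_site),
                 site_weights = site_weights,
                 flicker_rate = flicker_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Split a mutant frequency into per-site duplex family counts
#'
#' Site `i` receives `family_count ~ Binomial(depth, beta * weight_i /
#' sum(weights))`, so the expected sum of the ten site frequencies equals
#' `beta` exactly. Uses the current R random number stream.
#'
#' @param beta Population mutant frequency in `[0, 1]`.
#' @param weights Ten non-negative site weights.
#' @param depth Duplex consensus depth per site.
#' @return Integer vector of ten per-site family counts.
#' @export
decompose_into_sites <- function(beta, weights = rep(1 / 10, 10),
                                 depth = 1e4) {
  stopifnot(length(weights) == 10L, all(weights >= 0), sum(weights) > 0,
            beta >= 0, beta <= 1, depth > 0)
  p <- beta * weights / sum(weights)
  if (any(p > 1)) stop("beta * weight exceeds 1 for at least one site")
  stats::rbinom(10L, size = as.integer(depth), prob = p)
}

#' Add flickering sites to a synthetic variant table
#'
#' Appends `Poisson(flicker_rate)` records per time point at uniformly
#' random non-focal positions, each supported by a single duplex family,
#' with positions drawn independently across time points (no persistence).
#' These emulate the sporadic drift-level calls seen in real duplex data
#' and must leave the focal mutant-frequency statistic unchanged.
#'
#' @param tab A variant table (native column layout).
#' @param flicker_rate Expected number of added records per time point.
#' @param plasmid_length Plasmid length in bp for position sampling
#'   (default 4361, the length of pBR322).
#' @param dcs_depth Depth assigned to the added records.
#' @return The variant table with flickering records appended.
#' @export
add_flickering_sites <- function(tab, flicker_rate, plasmid_length = 4361,
                                 dcs_depth = 1e4) {
  stopifnot(flicker_rate >= 0)
  tab <- .validate_variant_table(tab)
  if (flicker_rate == 0) return(tab)
  nonfocal <- setdiff(seq_len(plasmid_length), focal_site_set())
  keys <- unique(tab[, c("replicate", "time_point_hours")])
  bases <- c("A", "C", "G", "T")
  extra <- lapply(seq_len(nrow(keys)), function(i) {
    k <- stats::rpois(1L, flicker_rate)
    if (k == 0L) return(NULL)
    pos <- sample(nonfocal, k)
    ref <- sample(bases, k, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    data.frame(replicate = keys$replicate[i],
               time_point_hours = keys$time_point_hours[i],
               position = pos, ref = ref, alt = alt,
               family_count = 1L, dcs_depth = as.integer(dcs_depth))
  })
  out <- rbind(tab, do.call(rbind, extra))
  rownames(out) <- NULL
  out
}

#' Simulate a duplex-seq-like observed series and variant table
#'
#' Runs the deterministic model under the configured parameters, samples it
#' at the configured hours (60-minute generations), and emulates duplex
#' sequencing: at each time point the true mutant frequency `beta` is split
#' across the ten focal sites and each site's family count is drawn
#' binomially at the configured depth. Sporadic flickering records are
#' added at non-focal positions. Reproducible under the config seed.
#'
#' @param config A [synth_config()].
#' @param replicate Replicate label written into the table (default "S1",
#'   synthetic run 1).
#' @return A list with `truth` (the full `beta` trajectory data frame),
#'   `noiseless` (an [observed_series()] equal to `beta` at the sampled
#'   generations), `noised` (the binomially sampled [observed_series()]),
#'   and `table` (the synthetic variant table, focal sites at every time
#'   point plus flickering records).
#' @export
simulate_observed_series <- function(config, replicate = "S1") {
  stopifnot(inherits(config, "synth_config"))
  gens <- hours_to_generations(config$sampling_hours)
  horizon <- max(gens)
  truth <- simulate_trajectory(config$true_params, horizon)
  set.seed(config$seed)
  beta <- truth$beta[gens + 1L]
  sites <- focal_site_set()
  depth <- config$dcs_depth_per_site
  tabs <- lapply(seq_along(gens), function(i) {
    counts <- decompose_into_sites(beta[i], config$site_weights, depth)
    data.frame(replicate = replicate,
               time_point_hours = config$sampling_hours[i],
               position = sites, ref = "C", alt = "T",
               family_count = counts, dcs_depth = depth)
  })
  tab <- do.call(rbind, tabs)
  tab <- add_flickering_sites(tab, config$flicker_rate, dcs_depth = depth)
  noised <- vapply(seq_along(gens), function(i) {
    sum(tab$family_count[tab$time_point_hours == config$sampling_hours[i] &
                           tab$position %in% sites]) / depth
  }, numeric(1))
  list(truth = truth,
       noiseless = observed_series(gens, beta),
       noised = observed_series(gens, noised),
       table = tab)
}
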