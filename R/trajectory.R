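#' Simulate the mutant-plasmid frequency trajectory
#'
#' Iterates the division / replication / selection recursion from the
#' founder population and records, after selection and renormalization of
#' each generation, the population mutant-plasmid fraction `beta` and the
#' fraction of cells carrying the chromosomal mutation. Generation 0 is the
#' initial state, so `beta[1] == 0`.
#'
#' The default engine is the compiled recursion; `engine = "r"` runs the
#' pure-R step functions ([generation_step()] and friends), which are the
#' readable reference implementation. Both produce identical trajectories
#' up to floating-point round-off.
#'
#' @param params A `model_params` object.
#' @param n_generations Number of generations to iterate (`>= 0`).
#' @param engine `"cpp"` (default) or `"r"`.
#' @return A `data.frame` with columns `generation` (`0:n_generations`),
#'   `beta`, and `chrom_mutant_fraction`.
#' @examples
#' p <- model_params(gamma = 1.55e-3, mu = 5.09e-5, r = 1.539, R_mut = 3.417,
#'                   S_base = 0.780, kappa_star = 20, kappa_T = 25)
#' traj <- simulate_trajectory(p, 50)
#' tail(traj)
#' @export
simulate_trajectory <- function(params, n_generations, engine = c("cpp", "r")) {
  stopifnot(inherits(params, "model_params"),
            is.numeric(n_generations), n_generations >= 0)
  engine <- match.arg(engine)
  n_generations <- as.integer(n_generations)
  if (engine == "cpp") {
    res <- .simulate_trajectory_cpp(params$gamma, params$mu, params$r,
                                    params$R_mut, params$S_base,
                                    params$kappa_star, params$kappa_T,
                                    params$w0, n_generations)
    if (res$extinct_at >= 0)
      stop("population extinct at generation ", res$extinct_at,
           ": no cells survive selection under these parameters")
    return(data.frame(generation = 0:n_generations, beta = res$beta,
                      chrom_mutant_fraction = res$chrom))
  }
  state <- initialize_population(params)
  kernel <- build_partition_kernel(params$kappa_T - 1L)
  beta <- numeric(n_generations + 1L)
  chrom <- numeric(n_generations + 1L)
  beta[1L] <- mutant_fraction(state)
  chrom[1L] <- chromosomal_mutant_fraction(state)
  if (n_generations > 0) {
    for (t in seq_len(n_generations)) {
      state <- generation_step(state, params, kernel)
      beta[t + 1L] <- mutant_fraction(state)
      chrom[t + 1L] <- chromosomal_mutant_fraction(state)
    }
  }
  data.frame(generation = 0:n_generations, beta = beta,
             chrom_mutant_fraction = chrom)
}

#' Write / read a simulated trajectory as CSV
#'
#' Columns: `generation, beta, chrom_mutant_fraction`.
#'
#' @param trajectory A data frame as returned by [simulate_trajectory()].
#' @param path File path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns the data frame.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(all(c("generation", "beta", "chrom_mutant_fraction")
                %in% names(trajectory)))
  utils::write.csv(trajectory, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path)
}
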