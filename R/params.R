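#' Model parameters for the plasmid heteroplasmy recursion
#'
#' Bundles the seven-parameter vector of the division-replication-selection
#' model together with the initial wild-type copy number.
#'
#' @param gamma Probability per chromosome per generation that a cell without
#'   a chromosomal mutation acquires one during replication. In `[0, 1]`.
#' @param mu Probability per newly synthesized wild-type plasmid of mutating
#'   to the mutant class. In `[0, 1]`.
#' @param r Wild-type plasmid replication rate: a cell holding `a` wild-type
#'   copies holds `floor(a * r)` after replication. Dimensionless, `>= 1`.
#' @param R_mut Mutant plasmid replication rate, same convention, `>= 1`.
#' @param S_base Base-line survival probability of a chromosomally wild-type
#'   cell carrying a single plasmid. In `(0.5, 1]`: values at or below 0.5
#'   would mean no net growth from one generation to the next.
#' @param kappa_star Optimal plasmid copy number: survival of a chromosomally
#'   wild-type cell reaches 1 at this total copy number. Positive integer.
#' @param kappa_T Lethal copy-number threshold: cells holding `kappa_T` or
#'   more plasmids do not survive. Integer, `kappa_star < kappa_T <= 40`.
#' @param w0 Initial wild-type copy number per founder cell (default 20,
#'   matching pBR322's copy number in unconstrained growth). Must satisfy
#'   `1 <= w0 <= kappa_T - 1` so founder cells are viable.
#'
#' @return An object of class `model_params`: a named list with the eight
#'   fields above.
#' @examples
#' p <- model_params(gamma = 1.55e-3, mu = 5.09e-5, r = 1.539, R_mut = 3.417,
#'                   S_base = 0.780, kappa_star = 20, kappa_T = 25)
#' p
#' @export
model_params <- function(gamma, mu, r, R_mut, S_base, kappa_star, kappa_T,
                         w0 = 20L) {
  stopifnot(
    is.numeric(gamma), length(gamma) == 1L, gamma >= 0, gamma <= 1,
    is.numeric(mu), length(mu) == 1L, mu >= 0, mu <= 1,
    is.numeric(r), length(r) == 1L, r >= 1,
    is.numeric(R_mut), length(R_mut) == 1L, R_mut >= 1,
    is.numeric(S_base), length(S_base) == 1L, S_base > 0.5, S_base <= 1
  )
  kappa_star <- as.integer(kappa_star)
  kappa_T <- as.integer(kappa_T)
  w0 <- as.integer(w0)
  if (kappa_star < 1L || kappa_T <= kappa_star || kappa_T > 40L)
    stop("need 1 <= kappa_star < kappa_T <= 40")
  if (w0 < 1L || w0 >= kappa_T)
    stop("w0 must satisfy 1 <= w0 <= kappa_T - 1 (initial cells would be nonviable)")
  structure(
    list(gamma = gamma, mu = mu, r = r, R_mut = R_mut, S_base = S_base,
         kappa_star = kappa_star, kappa_T = kappa_T, w0 = w0),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Plasmid heteroplasmy model parameters\n")
  cat(sprintf("  gamma (chromosomal mutation) : %.4g\n", x$gamma))
  cat(sprintf("  mu    (plasmid mutation)     : %.4g\n", x$mu))
  cat(sprintf("  r     (wild-type replication): %.4g\n", x$r))
  cat(sprintf("  R     (mutant replication)   : %.4g\n", x$R_mut))
  cat(sprintf("  S     (base-line fitness)    : %.4g\n", x$S_base))
  cat(sprintf("  kappa* (optimal copy number) : %d\n", x$kappa_star))
  cat(sprintf("  kappa_T (lethal threshold)   : %d\n", x$kappa_T))
  cat(sprintf("  w0    (initial copies)       : %d\n", x$w0))
  invisible(x)
}

#' Reference optimized parameter set
#'
#' The optimized estimates obtained by multi-start least-squares fitting of
#' the model to the long-term turbidostat duplex-sequencing series
#' (gamma = 1.55e-3, mu = 5.09e-5, r = 1.539, R = 3.417, S = 0.780,
#' kappa* = 20, kappa_T = 25, w0 = 20). Shipped as
#' `inst/extdata/optimized_params.json`.
#'
#' @return A `model_params` object.
#' @export
optimized_params <- function() {
  read_model_params(system.file("extdata", "optimized_params.json",
                                package = "plasmidhet", mustWork = TRUE))
}

#' Read / write model parameters as JSON
#'
#' The JSON representation uses keys exactly
#' `gamma, mu, r, R, S, kappa_star, kappa_T, w0`.
#'
#' @param path File path.
#' @return `read_model_params` returns a `model_params` object;
#'   `write_model_params` returns `path` invisibly.
#' @export
read_model_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("gamma", "mu", "r", "R", "S", "kappa_star", "kappa_T")
  if (!all(need %in% names(x)))
    stop("parameter JSON must contain keys: ", paste(need, collapse = ", "))
  model_params(gamma = x$gamma, mu = x$mu, r = x$r, R_mut = x$R,
               S_base = x$S, kappa_star = x$kappa_star, kappa_T = x$kappa_T,
               w0 = if (is.null(x$w0)) 20L else x$w0)
}

#' @param params A `model_params` object.
#' @rdname read_model_params
#' @export
write_model_params <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  jsonlite::write_json(
    list(gamma = params$gamma, mu = params$mu, r = params$r, R = params$R_mut,
         S = params$S_base, kappa_star = params$kappa_star,
         kappa_T = params$kappa_T, w0 = params$w0),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
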