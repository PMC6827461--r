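#' Plasmid partition kernel for cell division
#'
#' Precomputes the probabilities with which a parent cell carrying `a`
#' wild-type and `b` mutant plasmids hands `(j, k)` of them to one daughter
#' at division. Each plasmid independently lands in either daughter with
#' probability 1/2 (a circular cell cut in half with plasmids uniformly
#' scattered), so the number of plasmids a daughter receives is binomial
#' with `a + b` trials and success probability 1/2, and conditional on the
#' total the wild-type/mutant split is hypergeometric. Algebraically the
#' joint probability collapses to
#' `choose(a, j) * choose(b, k) / 2^(a + b)`,
#' which is how the kernel is stored: a single half-binomial matrix
#' `H[a + 1, j + 1] = choose(a, j) / 2^a` whose products give every table.
#'
#' @param max_total Largest total copy number `a + b` the kernel must cover.
#' @return An object of class `partition_kernel` with fields `max_total` and
#'   `half_binom` (the `(max_total + 1) x (max_total + 1)` matrix `H`).
#' @examples
#' k <- build_partition_kernel(4)
#' partition_table(k, a = 1, b = 1)  # all four outcomes probability 1/4
#' @export
build_partition_kernel <- function(max_total) {
  if (!is.numeric(max_total) || length(max_total) != 1L || max_total < 1)
    stop("max_total must be a positive integer")
  max_total <- as.integer(max_total)
  n <- max_total + 1L
  # exact integer binomial coefficients (max_total <= ~40 keeps them well
  # inside double precision: choose(40, 20) ~ 1.4e11)
  H <- matrix(0, n, n)
  for (a in 0:max_total) {
    H[a + 1L, seq_len(a + 1L)] <- choose(a, 0:a) / 2^a
  }
  structure(list(max_total = max_total, half_binom = H),
            class = "partition_kernel")
}

#' Daughter-composition probability table for one parent composition
#'
#' @param kernel A `partition_kernel`.
#' @param a,b Parent wild-type and mutant plasmid counts, `a + b <= max_total`.
#' @return An `(a + 1) x (b + 1)` matrix `P` with `P[j + 1, k + 1]` the
#'   probability that one daughter receives `j` wild-type and `k` mutant
#'   plasmids. Rows index `j = 0..a`, columns `k = 0..b`; entries sum to 1.
#' @export
partition_table <- function(kernel, a, b) {
  stopifnot(inherits(kernel, "partition_kernel"), a >= 0, b >= 0)
  if (a + b > kernel$max_total)
    stop("composition (", a, ", ", b, ") exceeds kernel max_total ",
         kernel$max_total)
  H <- kernel$half_binom
  outer(H[a + 1L, seq_len(a + 1L)], H[b + 1L, seq_len(b + 1L)])
}
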