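# Independent oracles used to check the model implementation.

# Brute-force partition oracle: enumerate every one of the 2^(a+b) equally
# likely assignments of the a wild-type and b mutant plasmids to the two
# daughters and tabulate the first daughter's composition (j, k).
enumerate_partition <- function(a, b) {
  total <- a + b
  P <- matrix(0, a + 1L, b + 1L)
  if (total == 0L) {
    P[1L, 1L] <- 1
    return(P)
  }
  for (code in 0:(2^total - 1L)) {
    bits <- as.integer(intToBits(code))[seq_len(total)]
    j <- sum(bits[seq_len(a)])
    k <- if (b > 0L) sum(bits[a + seq_len(b)]) else 0L
    P[j + 1L, k + 1L] <- P[j + 1L, k + 1L] + 1
  }
  P / 2^total
}

# Agent-based Monte-Carlo simulator: explicit cells, random binomial
# partitioning at division, Bernoulli chromosomal/plasmid mutations and
# Bernoulli survival under the same fitness function. The deterministic
# recursion is its expected-value counterpart.
mc_simulate <- function(params, n_generations, n_cells = 1e4) {
  g <- integer(n_cells)
  w <- rep(params$w0, n_cells)
  m <- integer(n_cells)
  beta <- numeric(n_generations + 1L)
  chrom <- numeric(n_generations + 1L)
  beta[1L] <- sum(m) / sum(w + m)
  chrom[1L] <- mean(g)
  for (t in seq_len(n_generations)) {
    j <- rbinom(length(w), w, 0.5)
    k <- rbinom(length(m), m, 0.5)
    g <- c(g, g)
    w_d <- c(j, w - j)
    m_d <- c(k, m - k)
    flip <- g == 0L & runif(length(g)) < params$gamma
    g[flip] <- 1L
    w2 <- floor(w_d * params$r + 1e-9)
    m2 <- floor(m_d * params$R_mut + 1e-9)
    kmut <- rbinom(length(w2), w2 - w_d, params$mu)
    w <- w2 - kmut
    m <- m2 + kmut
    surv <- runif(length(g)) < fitness(g, w + m, params)
    g <- g[surv]; w <- w[surv]; m <- m[surv]
    if (!length(g)) stop("Monte-Carlo population went extinct")
    beta[t + 1L] <- sum(m) / sum(w + m)
    chrom[t + 1L] <- mean(g)
  }
  list(beta = beta, chrom = chrom)
}

# Reference optimized parameter set used across tests.
test_optimized_params <- function() {
  model_params(gamma = 1.55e-3, mu = 5.09e-5, r = 1.539, R_mut = 3.417,
               S_base = 0.780, kappa_star = 20, kappa_T = 25, w0 = 20)
}

# A random small normalized state on the triangular domain.
random_state <- function(bound, seed) {
  set.seed(seed)
  mass <- array(0, dim = c(2L, bound + 1L, bound + 1L))
  for (g in 1:2) {
    M <- matrix(runif((bound + 1L)^2), bound + 1L)
    M[outer(0:bound, 0:bound, "+") > bound] <- 0
    mass[g, , ] <- M
  }
  normalize_state(population_state(mass, bound))
}
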