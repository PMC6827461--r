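params <- test_optimized_params()

test_that("initialization places the founder mass and no mutant plasmids", {
  s <- initialize_population(params)
  expect_equal(s$mass[1L, 21L, 1L], 1)
  expect_equal(total_mass(s), 1)
  expect_equal(mutant_fraction(s), 0)
  s1 <- initialize_population(model_params(0, 0, 1, 1, 0.9, 2, 5, w0 = 1))
  expect_equal(s1$mass[1L, 2L, 1L], 1)
  expect_error(model_params(0, 0, 1, 1, 0.9, 2, 5, w0 = 5), "nonviable")
})

test_that("division reproduces the hand-expanded two-daughter sum", {
  kernel <- build_partition_kernel(4)
  mass <- array(0, dim = c(2, 5, 5))
  mass[1, 3, 1] <- 1  # all mass at (g = 0, w = 2, m = 0)
  out <- division_step(population_state(mass, 4), kernel)
  expect_equal(out$mass[1, 1, 1], 0.5)
  expect_equal(out$mass[1, 2, 1], 1.0)
  expect_equal(out$mass[1, 3, 1], 0.5)
  expect_equal(total_mass(out), 2)

  mass0 <- array(0, dim = c(2, 5, 5))
  mass0[1, 1, 1] <- 1  # plasmid-free cells still divide
  out0 <- division_step(population_state(mass0, 4), kernel)
  expect_equal(out0$mass[1, 1, 1], 2)
})

test_that("division doubles mass and conserves expected plasmid totals", {
  kernel <- build_partition_kernel(12)
  for (seed in 1:5) {
    s <- random_state(12, seed)
    out <- division_step(s, kernel)
    expect_equal(total_mass(out), 2 * total_mass(s), tolerance = 1e-12)
    wgrid <- matrix(0:12, 13, 13)
    for (g in 1:2) {
      expect_equal(sum(wgrid * out$mass[g, , ]), sum(wgrid * s$mass[g, , ]),
                   tolerance = 1e-10)
      expect_equal(sum(t(wgrid) * out$mass[g, , ]),
                   sum(t(wgrid) * s$mass[g, , ]), tolerance = 1e-10)
    }
  }
  small <- build_partition_kernel(3)
  expect_error(division_step(random_state(12, 1), small), "max_total")
})

test_that("chromosomal mutation moves the right fraction and conserves mass", {
  s <- random_state(6, 11)
  out <- chromosomal_mutation_step(s, 0.1)
  expect_equal(out$mass[2, , ], s$mass[2, , ] + 0.1 * s$mass[1, , ])
  expect_equal(out$mass[1, , ], 0.9 * s$mass[1, , ])
  expect_equal(total_mass(out), total_mass(s), tolerance = 1e-12)
  expect_equal(chromosomal_mutation_step(s, 0)$mass, s$mass)
  all_mut <- chromosomal_mutation_step(s, 1)
  expect_equal(sum(all_mut$mass[1, , ]), 0)
})

test_that("replication applies floor rates and records newly synthesized copies", {
  mass <- array(0, dim = c(2, 11, 11))
  mass[1, 11, 1] <- 1  # (w = 10, m = 0)
  out <- plasmid_replication_step(population_state(mass, 10), 1.539, 3.417)
  expect_equal(out$mass[1, 16, 1], 1)  # floor(10 * 1.539) = 15
  expect_equal(out$wnew_by_w[16], 5L)

  mass2 <- array(0, dim = c(2, 11, 11))
  mass2[1, 1, 9] <- 1  # (w = 0, m = 8)
  out2 <- plasmid_replication_step(population_state(mass2, 10), 1.539, 3.417)
  expect_equal(out2$mass[1, 1, 28], 1)  # floor(8 * 3.417) = 27

  s <- random_state(8, 3)
  id <- plasmid_replication_step(s, 1, 1)
  expect_equal(id$mass, s$mass)
  expect_true(all(id$wnew_by_w == 0L))
  expect_error(plasmid_replication_step(s, 0.9, 1), ">= 1")
})

test_that("plasmid mutation spreads binomially and conserves totals", {
  mass <- array(0, dim = c(2, 31, 31))
  mass[1, 16, 1] <- 1  # (w = 15, m = 0) with w_new = 2
  wnew <- rep(NA_integer_, 31)
  wnew[16] <- 2L
  s <- population_state(mass, 30, wnew_by_w = wnew)
  out <- plasmid_mutation_step(s, 0.5)
  expect_equal(out$mass[1, 16, 1], 1 / 4)
  expect_equal(out$mass[1, 15, 2], 1 / 2)
  expect_equal(out$mass[1, 14, 3], 1 / 4)
  expect_equal(total_mass(out), 1, tolerance = 1e-12)

  unchanged <- plasmid_mutation_step(s, 0)
  expect_equal(unchanged$mass, mass)

  # per-cell copy totals conserved on a random replicated state
  st <- plasmid_replication_step(random_state(6, 7), 1.7, 2.3)
  res <- plasmid_mutation_step(st, 0.3)
  B <- st$bound
  tot <- outer(0:B, 0:B, "+")
  for (g in 1:2) {
    for (n in 0:B) {
      expect_equal(sum(res$mass[g, , ][tot == n]),
                   sum(st$mass[g, , ][tot == n]), tolerance = 1e-12)
    }
  }
})

test_that("fitness follows the piecewise survival function", {
  expect_equal(fitness(1, 10, params), 1)
  expect_equal(fitness(0, 20, params), 1)
  expect_equal(fitness(0, 25, params), 0)
  expect_equal(fitness(0, 0, params), 0)
  expect_equal(fitness(1, 0, params), 0)
  expect_equal(fitness(0, 10, params), 0.78 + 0.22 * 9 / 19)
  expect_equal(fitness(0, 26, params), 0)  # beyond the lethal threshold
  expect_equal(fitness(1, 25, params), 0)  # threshold lethal for g = 1 too
  expect_error(fitness(0, -1, params), "non-negative")

  # kappa* = 1: the ramp collapses to survival 1 at a single copy
  p1 <- model_params(0, 0, 1, 1, 0.9, 1, 5, w0 = 1)
  expect_equal(fitness(0, 1, p1), 1)

  # monotone up to kappa*, strictly decreasing from kappa* to kappa_T
  f <- fitness(rep(0, 26), 0:25, params)
  expect_true(all(diff(f[2:21]) >= 0))
  expect_true(all(diff(f[21:26]) < 0))
})

test_that("selection kills plasmid-free and overloaded cells, keeps g = 1 intact", {
  mass <- array(0, dim = c(2, 28, 28))
  mass[1, 1, 1] <- 1    # (g = 0, w = 0, m = 0)
  mass[2, 11, 1] <- 1   # (g = 1, w = 10, m = 0)
  mass[1, 1, 28] <- 1   # (g = 0, w = 0, m = 27) above kappa_T = 25
  out <- selection_step(population_state(mass, 27), params)
  expect_equal(out$bound, 24L)
  expect_equal(total_mass(out), 1)
  expect_equal(out$mass[2, 11, 1], 1)
})

test_that("mutant fraction is the plasmid-weighted pooled ratio", {
  mass <- array(0, dim = c(2, 21, 21))
  mass[1, 11, 11] <- 0.5  # (10, 10)
  mass[1, 21, 1] <- 0.5   # (20, 0)
  expect_equal(mutant_fraction(population_state(mass, 20)), 0.25)

  pure <- array(0, dim = c(2, 6, 6))
  pure[1, 1, 6] <- 1      # (0, 5): all mutant
  expect_equal(mutant_fraction(population_state(pure, 5)), 1)

  empty <- array(0, dim = c(2, 6, 6))
  empty[1, 1, 1] <- 1     # plasmid-free cells only
  expect_error(mutant_fraction(population_state(empty, 5)), "undefined")
})
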