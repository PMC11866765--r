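test_that("NVE lambda dynamics conserves the extended energy", {
  fx <- make_fixture("symmetric_site")
  cfg <- dynamics_config(timestep = 0.5, friction = 0, seed = 1)
  st <- lambda_state(list(0.3), list(0.8), topology = fx$topology)
  tr <- propagate(fx$system, fx$topology, st, cfg, 10000, sample_every = 10)
  drift <- diff(range(tr$energy)) / abs(mean(tr$energy))
  expect_lt(drift, 1e-5)
})

test_that("thermostatted lambda dynamics equipartitions the kinetic energy
          to within 5 percent", {
  fx <- make_fixture("symmetric_site")
  cfg <- dynamics_config(mode = "qi", seed = 2)
  tr <- propagate(fx$system, fx$topology, fx$lambda, cfg, 2e6, sample_every = 20)
  m <- fx$lambda$masses[[1]]
  ratio <- mean(m * tr$velocity[, 1]^2) / (KB * cfg$temperature)
  expect_lt(abs(ratio - 1), 0.05)
})

test_that("the sampled lambda distribution is Boltzmann in H + V
          (Kolmogorov-Smirnov, alpha = 0.01, thinned samples)", {
  fx <- make_fixture("symmetric_site")
  cfg <- dynamics_config(mode = "qi", seed = 3)
  co <- lambda_hamiltonian_coeffs(fx$system, fx$topology, "qi", p = 24)
  # exact potential on a fine grid (frozen coordinates)
  kT <- KB * cfg$temperature
  grid <- seq(0, 1, length.out = 2001)
  pot <- sapply(grid, function(l) {
    w <- lambda_to_weights(l, 2)
    sum(co$cvec * w) + 0.5 * sum(w * (co$Amat %*% w)) + double_well(l, cfg$barrier)
  })
  dens <- exp(-(pot - min(pot)) / kT)
  cdf_grid <- cumsum(dens) / sum(dens)
  cdf <- stats::approxfun(grid, cdf_grid, yleft = 0, yright = 1)
  # thin to roughly independent samples (10 ps spacing >> well correlation)
  tr <- propagate(fx$system, fx$topology, fx$lambda, cfg, 2e7,
                  sample_every = 10000)
  ks <- suppressWarnings(stats::ks.test(tr$lambda[, 1], cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("transition counting uses hysteresis and behaves on fixtures", {
  expect_equal(count_transitions(rep(0.5, 100))$count, 0)
  sq <- rep(c(0.1, 0.9), 10)  # 19 alternating definite crossings
  expect_equal(count_transitions(sq)$count, 19)
  expect_error(count_transitions(sq, lo = 0.8, hi = 0.2), "smaller")
  # recrossings inside the band are not double counted
  z <- c(0.1, 0.5, 0.1, 0.5, 0.9, 0.75, 0.85, 0.9, 0.1)
  expect_equal(count_transitions(z)$count, 2)
  ct <- count_transitions(z)
  expect_equal(ct$events$direction, c(1L, -1L))  # alternating directions
  # wider hysteresis never counts more transitions
  set.seed(4)
  for (rep_ in 1:10) {
    x <- pmin(pmax(cumsum(rnorm(2000, 0, 0.08)) %% 2, 0), 1)
    x <- ifelse(x > 1, 2 - x, x)
    expect_lte(count_transitions(x, 0.2, 0.8)$count,
               count_transitions(x, 0.4, 0.6)$count)
  }
})

test_that("TST barrier translation of a rate ratio", {
  d <- tst_barrier_from_rates(12, 4)
  expect_equal(as.numeric(d), log(3), tolerance = 1e-12)
  expect_equal(attr(d, "kJ_per_mol"), log(3) * KB * 300, tolerance = 1e-12)
  expect_equal(as.numeric(tst_barrier_from_rates(5, 5)), 0)
  expect_equal(as.numeric(tst_barrier_from_rates(4, 12)),
               -as.numeric(tst_barrier_from_rates(12, 4)))
  expect_error(tst_barrier_from_rates(0, 1), "positive")
})

test_that("adding the analytic QI-HI harmonic to an HI run reproduces the QI
          run (paired noise)", {
  fx <- make_fixture("symmetric_site")
  op <- lattice_operator(24)
  co_hi <- lambda_hamiltonian_coeffs(fx$system, fx$topology, "hi", op = op)
  co_qi <- lambda_hamiltonian_coeffs(fx$system, fx$topology, "qi", op = op)
  st_ <- fx$topology$sites[[1]]
  k <- hi_qi_force_constant(fx$system$positions[st_$particles, ], st_$forms,
                            fx$system$box_edge, p = 24, op = op)
  # DeltaV = -(k/2) w1 w2 on the weight simplex
  A_dv <- matrix(c(0, -k / 2, -k / 2, 0), 2, 2)
  kT <- KB * 300
  set.seed(5)
  hi_plus <- mahi:::cpp_baoab_site(0.5, 0, 5, 2L, co_hi$cvec, A_dv, 1e-3, 5, kT, 5,
                            200000L, 10L)
  set.seed(5)
  qi <- mahi:::cpp_baoab_site(0.5, 0, 5, 2L, co_qi$cvec, co_qi$Amat, 1e-3, 5, kT, 5,
                       200000L, 10L)
  expect_equal(hi_plus$lambda[, 1], qi$lambda[, 1], tolerance = 1e-8)
})

test_that("the multi-site integration path runs and keeps lambda in bounds", {
  gen <- generate_random_system(generator_spec(
    n_env = 20, sites = list(c(2, 2), c(2, 2)), box_edge = 3, seed = 6))
  cfg <- dynamics_config(seed = 7)
  tr <- propagate(gen$system, gen$topology, gen$lambda, cfg, 60,
                  sample_every = 10, p_exact = 8)
  expect_equal(dim(tr$lambda), c(6L, 2L))
  expect_true(all(tr$lambda >= 0 & tr$lambda <= 1))
  expect_true(all(is.finite(tr$energy)))
})

test_that("optional Coulomb-only particle motion propagates jointly with
          lambda and stays in the box", {
  gen <- small_random_gen(seed = 71, n_env = 12, site = c(2, 2))
  cfg <- dynamics_config(seed = 72, timestep = 0.5)
  tr <- propagate(gen$system, gen$topology, gen$lambda, cfg, 30,
                  sample_every = 10, p_exact = 6, particles = "langevin")
  expect_equal(nrow(tr$lambda), 3L)
  expect_true(all(tr$lambda >= 0 & tr$lambda <= 1))
  expect_true(all(tr$final$positions >= 0 & tr$final$positions < gen$system$box_edge))
  expect_true(all(is.finite(tr$energy)))
})
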