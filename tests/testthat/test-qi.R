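test_that("for single-particle sites QI and HI differ only through periodic
          self-image terms: no central-box pair contribution to k", {
  fx <- make_fixture("single_particle_site")
  op <- lattice_operator(24)
  st_ <- fx$topology$sites[[1]]
  # no intra-site pairs: the non-periodic force constant vanishes ...
  expect_equal(hi_qi_force_constant(fx$system$positions[st_$particles, , drop = FALSE],
                                    st_$forms, fx$system$box_edge,
                                    periodic = FALSE), 0)
  # ... and the remaining QI-HI difference is exactly the self-image harmonic
  k <- hi_qi_force_constant(fx$system$positions[st_$particles, , drop = FALSE],
                            st_$forms, fx$system$box_edge, p = 24, op = op)
  hi <- mahi_lambda_forces(fx$system, fx$topology, fx$lambda, p = 24, d = 0,
                           op = op)
  qi <- qi_lambda_forces(fx$system, fx$topology, fx$lambda, p = 24, d = 0,
                         op = op)
  expect_equal(unlist(qi$F_lambda) - unlist(hi$F_lambda), -k * (0.345 - 0.5),
               tolerance = 1e-10)
})

test_that("the QI-HI force difference of a two-form site is the analytic
          harmonic force, and the energies coincide at the end states", {
  fx <- make_fixture("symmetric_site")
  op <- lattice_operator(24)
  k <- hi_qi_force_constant(fx$system$positions[9:10, ],
                            fx$topology$sites[[1]]$forms,
                            fx$system$box_edge, p = 24, op = op)
  for (lam in c(0.15, 0.345, 0.5, 0.8)) {
    st <- lambda_state(list(lam), topology = fx$topology)
    hi <- mahi_lambda_forces(fx$system, fx$topology, st, p = 24, d = 0, op = op)
    qi <- qi_lambda_forces(fx$system, fx$topology, st, p = 24, d = 0, op = op)
    # F_qi - F_hi = -d(DeltaV)/dlambda = -k (lambda - 1/2)
    expect_equal(unlist(qi$F_lambda) - unlist(hi$F_lambda),
                 -k * (lam - 0.5), tolerance = 1e-10)
  }
  for (lam in c(0, 1)) {
    st <- lambda_state(list(lam), topology = fx$topology)
    hi <- mahi_lambda_forces(fx$system, fx$topology, st, p = 24, d = 0, op = op)
    qi <- qi_lambda_forces(fx$system, fx$topology, st, p = 24, d = 0, op = op)
    expect_equal(qi$energy$H_qi, hi$energy$H_hi, tolerance = 1e-12)
    expect_equal(unlist(qi$F_lambda) - unlist(hi$F_lambda), k / 2 - k * lam,
                 tolerance = 1e-10)
  }
})

test_that("the force constant follows the end-state charge differences", {
  L <- 4
  pos <- rbind(c(2, 2, 2), c(2.4, 2, 2))
  same <- rbind(c(0.3, -0.1), c(0.3, -0.1) + 1e-30)
  expect_equal(hi_qi_force_constant(pos, same, L), 0, tolerance = 1e-12)
  # Delta q = (+d, -d): the central-box part of k is -2 k_e d^2 / r
  for (d in c(0.05, 0.1)) {
    forms <- rbind(c(d, -d), c(-d, d))
    k_np <- hi_qi_force_constant(pos, forms, L, periodic = FALSE)
    expect_equal(k_np, -2 * KE * (2 * d)^2 / 0.4, tolerance = 1e-12)
    k_p <- hi_qi_force_constant(pos, forms, L, p = 16)
    expect_lt(k_p, 0)
    expect_false(isTRUE(all.equal(k_p, k_np)))  # image terms contribute
  }
  expect_error(hi_qi_force_constant(pos, rbind(c(1, 0), c(0, 1), c(1, 1)), L),
               "two-form")
})

test_that("k matches the curvature of the two-path energy difference", {
  gen <- small_random_gen(seed = 41, n_env = 30, site = c(3, 2))
  op <- lattice_operator(24)
  st_ <- gen$topology$sites[[1]]
  k <- hi_qi_force_constant(gen$system$positions[st_$particles, ], st_$forms,
                            gen$system$box_edge, p = 24, op = op)
  dd <- function(l) {
    st <- lambda_state(list(l), topology = gen$topology)
    m <- mahi_lambda_forces(gen$system, gen$topology, st, p = 24, d = 0, op = op)
    m$energy$H_qi - m$energy$H_hi
  }
  h <- 1e-3
  k_fd <- (dd(0.5 + h) - 2 * dd(0.5) + dd(0.5 - h)) / h^2
  expect_equal(k_fd, k, tolerance = 1e-5)
  # two-path difference equals the harmonic potential on a lambda grid
  grid <- seq(0, 1, 0.125)
  expect_equal(sapply(grid, dd), hi_qi_potential(grid, k), tolerance = 1e-10)
})

test_that("the harmonic difference potential has the stated shape", {
  k <- -20
  expect_equal(hi_qi_potential(0, k), 0)
  expect_equal(hi_qi_potential(1, k), 0)
  expect_equal(hi_qi_potential(0.5, k), -k / 8)
  lam <- seq(0, 1, 0.05)
  expect_equal(hi_qi_potential(lam, k), hi_qi_potential(1 - lam, k))
  expect_error(hi_qi_potential(1.5, k), "\\[0, 1\\]")
})
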