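test_that("intra-site correction potential: hand value for a two-particle
          site, image-only terms for a single particle, translation
          invariance", {
  L <- 5
  pos <- rbind(c(2.45, 2.5, 2.5), c(2.55, 2.5, 2.5))
  cor <- intra_site_correction_potential(pos, c(1, -1), L)
  # central-box pair term plus the explicit 26-image sum, independently in R
  e_central <- -KE / 0.1
  e_images <- brute_shell_sum(pos, c(1, -1), L, 1, 1)
  expect_equal(cor$energy, e_central + e_images, tolerance = 1e-12)
  # single-particle site: no intra-box pair, only self-image terms
  cor1 <- intra_site_correction_potential(matrix(c(2.5, 2.5, 2.5), 1), 1, L)
  expect_equal(cor1$energy, brute_shell_sum(matrix(c(2.5, 2.5, 2.5), 1), 1, L, 1, 1),
               tolerance = 1e-12)
  # rigid translation leaves the energy unchanged (pair and image distances)
  cor2 <- intra_site_correction_potential(pos + 0.7, c(1, -1), L)
  expect_equal(cor2$energy, cor$energy, tolerance = 1e-12)
})

test_that("lattice correction equals a brute-force shell sum over the distant
          images and is invariant under site translation", {
  L <- 5
  pos <- rbind(c(2.45, 2.5, 2.5), c(2.55, 2.5, 2.5))
  q <- c(1, -1)
  lc <- lattice_correction(pos, q, L, p = 20, op = lattice_operator(30))
  e_brute <- brute_shell_sum(pos, q, L, 2, 35)
  expect_lt(abs(lc$energy - e_brute), 1e-6)
  lc2 <- lattice_correction(pos + 0.9, q, L, p = 20, op = lattice_operator(30))
  expect_equal(lc2$energy, lc$energy, tolerance = 1e-8)
  # a chargeless form contributes nothing
  expect_equal(lattice_correction(pos, c(0, 0), L, p = 8)$energy, 0)
})

test_that("dipole correction vanishes for zero-dipole charge sets and MAHI
          under vacuum boundaries matches the Ewald end-state mixture", {
  L <- 5
  pos <- rbind(c(2.3, 2.5, 2.5), c(2.7, 2.5, 2.5))
  expect_lte(dipole_correction(pos, c(1, -1), L)$energy, 0)
  expect_equal(dipole_correction(pos, c(0.4, 0.4), L)$dipole, c(0, 0, 0),
               tolerance = 1e-14)
  expect_equal(dipole_correction(pos, c(0.4, 0.4), L)$energy, 0,
               tolerance = 1e-14)
  # generic two-form site: H_HI(lambda) equals the weighted end-state
  # energies computed by two full Ewald runs, under both boundary choices
  gen <- small_random_gen(seed = 21, n_env = 30, site = c(4, 2),
                          neutralize = TRUE)
  for (bd in c("vacuum", "tinfoil")) {
    mah <- mahi_lambda_forces(gen$system, gen$topology, gen$lambda,
                              backend = "ewald", boundary = bd)
    h01 <- sapply(1:2, function(r) {
      q <- gen$system$charges
      q[gen$topology$sites[[1]]$particles] <- gen$topology$sites[[1]]$forms[r, ]
      ewald_oracle(gen$system, charges = q, boundary = bd,
                   background = TRUE)$energy
    })
    lam <- gen$lambda$lambdas[[1]]
    expect_equal(mah$energy$H_hi, (1 - lam) * h01[1] + lam * h01[2],
                 tolerance = 1e-10)
    expect_equal(unlist(mah$F_lambda), -(h01[2] - h01[1]), tolerance = 1e-10)
  }
})

test_that("MAHI equals the end-state reference exactly at d = 0 (typical,
          worst-case, and four forms)", {
  op <- test_op()
  for (variant in list(list(seed = 22, site = c(10, 2), placement = "typical"),
                       list(seed = 23, site = c(10, 2), placement = "worst_case"),
                       list(seed = 24, site = c(10, 4), placement = "typical"))) {
    gen <- small_random_gen(seed = variant$seed, n_env = 150,
                            site = variant$site, placement = variant$placement)
    expect_lt(max_rel_dev(gen, p = 8, d = 0, op = op), 1e-12)
  }
})

test_that("a system without sites yields an empty report", {
  fx <- make_fixture("nacl")
  rep0 <- mahi_lambda_forces(fx$system, fx$topology,
                             lambda_state(list()), p = 4, d = 0)
  expect_length(rep0$F_lambda, 0)
  expect_length(rep0$sites, 0)
})

test_that("the report decomposition sums to the total weight-force", {
  op <- test_op()
  gen <- small_random_gen(seed = 25, n_env = 60, site = c(6, 2))
  mah <- mahi_lambda_forces(gen$system, gen$topology, gen$lambda, p = 8,
                            d = 0, op = op)
  st <- mah$sites[[1]]
  recon <- st$decomposition[, "baseline"] + st$decomposition[, "boxbox"] +
    st$decomposition[, "lattice"] + st$decomposition[, "dipole"]
  expect_equal(recon, st$F_weights, tolerance = 1e-12)
})

test_that("reference forces equal central finite differences of the full
          Hamiltonian, also with two sites", {
  op <- test_op()
  gen <- generate_random_system(generator_spec(
    n_env = 60, sites = list(c(4, 2), c(3, 2)), seed = 26))
  ref <- reference_forces(gen$system, gen$topology, gen$lambda, p = 8, d = 0,
                          op = op)
  h <- 1e-5
  for (s in 1:2) {
    lam0 <- gen$lambda$lambdas
    hof <- function(x) {
      lam <- lam0; lam[[s]] <- x
      st <- lambda_state(lam, topology = gen$topology)
      mahi_lambda_forces(gen$system, gen$topology, st, p = 8, d = 0,
                         op = op)$energy$H_hi
    }
    fd <- -(hof(lam0[[s]] + h) - hof(lam0[[s]] - h)) / (2 * h)
    expect_equal(ref$F_lambda[[s]], fd, tolerance = 1e-6)
  }
  # four-form site: finite differences in each lambda variable
  gen4 <- small_random_gen(seed = 27, n_env = 60, site = c(5, 4))
  ref4 <- reference_forces(gen4$system, gen4$topology, gen4$lambda, p = 8,
                           d = 0, op = op)
  lam0 <- gen4$lambda$lambdas[[1]]
  for (l in 1:2) {
    hof <- function(x) {
      lam <- lam0; lam[l] <- x
      st <- lambda_state(list(lam), topology = gen4$topology)
      mahi_lambda_forces(gen4$system, gen4$topology, st, p = 8, d = 0,
                         op = op)$energy$H_hi
    }
    fd <- -(hof(lam0[l] + h) - hof(lam0[l] - h)) / (2 * h)
    expect_equal(ref4$F_lambda[[1]][l], fd, tolerance = 1e-6)
  }
})

test_that("reference enumeration refuses combinatorial blow-up", {
  n <- 40
  pos <- matrix(seq(0.05, 0.95, length.out = 3 * n), n, 3)
  sites <- lapply(1:17, function(i)
    list(particles = i, forms = rbind(0.1, -0.1 * i)))
  sys <- particle_system(pos, rep(0, n), 1)
  topo <- site_topology(sites)
  st <- lambda_state(rep(list(0.5), 17), topology = topo)
  expect_error(reference_forces(sys, topo, st, max_evals = 65536), "guard")
})

test_that("correction effort scales linearly with the number of site-forms
          and is independent of the environment size", {
  op <- test_op()
  counts <- sapply(c(50, 200, 800), function(ne) {
    gen <- small_random_gen(seed = 28, n_env = ne, site = c(10, 2))
    mahi_lambda_forces(gen$system, gen$topology, gen$lambda, p = 4, d = 0,
                       op = op)$counts
  })
  expect_equal(counts[, 1], counts[, 2])
  expect_equal(counts[, 2], counts[, 3])  # independent of N_env
  forms_counts <- sapply(c(2, 4, 8), function(nf) {
    gen <- small_random_gen(seed = 29, n_env = 50, site = c(10, nf))
    mahi_lambda_forces(gen$system, gen$topology, gen$lambda, p = 4, d = 0,
                       op = op)$counts
  })
  # pair operations grow as (#forms + 1); exactly linear in the form count
  expect_equal(diff(forms_counts["pair_ops", ]) / c(2, 4),
               rep(forms_counts["pair_ops", 1] / 3, 2), ignore_attr = TRUE)
  expect_equal(forms_counts["lattice_apps", ], c(3, 5, 9))
})

test_that("MAHI with an Ewald baseline agrees with the FMM baseline at high
          multipole order (backend independence)", {
  gen <- small_random_gen(seed = 30, n_env = 80, site = c(6, 2),
                          neutralize = TRUE)
  op <- lattice_operator(30)
  f_fmm <- unlist(mahi_lambda_forces(gen$system, gen$topology, gen$lambda,
                                     p = 30, d = 0, op = op)$F_lambda)
  f_ew <- unlist(mahi_lambda_forces(gen$system, gen$topology, gen$lambda,
                                    backend = "ewald")$F_lambda)
  expect_equal(f_fmm, f_ew, tolerance = 1e-8)
})

test_that("integrating the QI lambda force over [0,1] recovers the end-state
          energy difference", {
  op <- test_op()
  gen <- small_random_gen(seed = 31, n_env = 40, site = c(4, 2))
  grid <- seq(0, 1, length.out = 21)
  fs <- sapply(grid, function(l) {
    st <- lambda_state(list(l), topology = gen$topology)
    unlist(qi_lambda_forces(gen$system, gen$topology, st, p = 8, d = 0,
                            op = op)$F_lambda)
  })
  hs <- sapply(c(0, 1), function(l) {
    st <- lambda_state(list(l), topology = gen$topology)
    qi_lambda_forces(gen$system, gen$topology, st, p = 8, d = 0,
                     op = op)$energy$H_qi
  })
  integral <- sum(diff(grid) * (head(fs, -1) + tail(fs, -1)) / 2)
  expect_equal(integral, hs[1] - hs[2],
               tolerance = 1e-4 * max(1, abs(hs[1] - hs[2])))
})

test_that("MAHI deviations on the 1010-particle benchmark decrease with
          multipole order, are within 1e-6 at p = 8, and reach the
          double-precision floor by p = 28", {
  op <- lattice_operator(28)
  gen <- generate_random_system(generator_spec(n_env = 1000, seed = 1))
  devs <- sapply(c(2, 8, 16, 28), function(p) max_rel_dev(gen, p, d = 1, op = op))
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[2], 1e-6)    # p = 8
  expect_lt(devs[4], 1e-13)   # p = 28: numerical floor
  gen2 <- generate_random_system(generator_spec(n_env = 1000, seed = 2))
  expect_lt(max_rel_dev(gen2, p = 8, d = 3, op = op), 1e-6)
})
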