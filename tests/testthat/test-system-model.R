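test_that("lambda-to-weights transform reproduces the end states and the
          two- and four-form interpolation values", {
  expect_equal(lambda_to_weights(0, 2), c(1, 0))
  expect_equal(lambda_to_weights(1, 2), c(0, 1))
  expect_equal(lambda_to_weights(0.345, 2), c(0.655, 0.345))
  w4 <- lambda_to_weights(c(0.345, 0.721), 4)
  expect_equal(w4, c(0.655 * 0.279, 0.655 * 0.721, 0.345 * 0.279,
                     0.345 * 0.721))
  expect_equal(sum(w4), 1)
})

test_that("weights sum to one, stay in [0,1], and corners give pure forms,
          for any form count including non-powers of two", {
  set.seed(1)
  for (nf in c(2, 3, 4, 5, 8)) {
    nl <- n_lambda(nf)
    for (rep in 1:20) {
      lam <- runif(nl)
      w <- lambda_to_weights(lam, nf)
      expect_equal(sum(w), 1, tolerance = 1e-14)
      expect_true(all(w >= 0 & w <= 1))
    }
    # binary corners of the lambda cube select single forms
    corners <- as.matrix(expand.grid(rep(list(c(0, 1)), nl)))
    for (r in seq_len(nrow(corners))) {
      w <- lambda_to_weights(corners[r, ], nf)
      expect_equal(sum(w == 1), 1)
      expect_equal(sum(w), 1)
    }
  }
})

test_that("weights transform validates input", {
  expect_error(lambda_to_weights(c(0.2, 0.3), 2), "length")
  expect_error(lambda_to_weights(1.2, 2), "\\[0, 1\\]")
  expect_error(weights_jacobian(c(0.1), 4), "length")
})

test_that("weights Jacobian is analytic: matches central finite differences
          to 1e-6 relative and its columns sum to zero", {
  expect_equal(weights_jacobian(0.5, 2)[, 1], c(-1, 1))
  set.seed(2)
  h <- 1e-6
  for (nf in c(2, 3, 4, 6)) {
    nl <- n_lambda(nf)
    for (rep in 1:5) {
      lam <- runif(nl, 0.05, 0.95)
      J <- weights_jacobian(lam, nf)
      expect_equal(colSums(J), rep(0, nl), tolerance = 1e-13)
      for (l in seq_len(nl)) {
        lp <- lam; lm <- lam
        lp[l] <- lp[l] + h; lm[l] <- lm[l] - h
        fd <- (lambda_to_weights(lp, nf) - lambda_to_weights(lm, nf)) / (2 * h)
        expect_equal(J[, l], fd, tolerance = 1e-6)
      }
    }
  }
})

test_that("scaled charges mix form charges and leave the environment alone", {
  pos <- matrix(c(0.1, 0.1, 0.1, 0.4, 0.4, 0.4), 2, 3, byrow = TRUE)
  sys <- particle_system(pos, c(-1, 0), 1)
  topo <- site_topology(list(list(particles = 2L, forms = rbind(0.5, -0.3))))
  expect_equal(scaled_charges(sys, topo, list(c(1, 0))), c(-1, 0.5))
  q <- scaled_charges(sys, topo, list(c(0.655, 0.345)))
  expect_equal(q[2], 0.655 * 0.5 - 0.345 * 0.3)
  expect_equal(q[1], -1)  # environment unchanged for any weights
})

test_that("total scaled charge is lambda-independent exactly when the forms
          share their total charge", {
  pos <- matrix(runif(9), 3, 3) * 0.9
  sys <- particle_system(pos, c(0.3, 0, 0), 1)
  equal_sum <- site_topology(list(list(
    particles = 2:3, forms = rbind(c(0.5, -0.2), c(-0.1, 0.4)))))  # both 0.3
  diff_sum <- site_topology(list(list(
    particles = 2:3, forms = rbind(c(0.5, -0.2), c(0.2, 0.4)))))
  tot <- function(topo, lam)
    sum(scaled_charges(sys, topo, list(lambda_to_weights(lam, 2))))
  expect_equal(tot(equal_sum, 0.1), tot(equal_sum, 0.9), tolerance = 1e-14)
  expect_gt(abs(tot(diff_sum, 0.1) - tot(diff_sum, 0.9)), 1e-3)
})

test_that("containers validate their invariants", {
  expect_error(particle_system(matrix(1.5, 1, 3), 1, 1), "\\[0, box_edge\\)")
  expect_error(site_topology(list(
    list(particles = 1:2, forms = rbind(c(1, 0), c(1, 0))))), "distinct")
  expect_error(site_topology(list(
    list(particles = 1:2, forms = rbind(c(1, 0), c(0, 1))),
    list(particles = 2:3, forms = rbind(c(1, 0), c(0, 1))))), "disjoint")
  topo <- site_topology(list(list(particles = 1:2,
                                  forms = matrix(runif(8), 4))))
  expect_error(lambda_state(list(c(0.5, 0.5, 0.5)), topology = topo), "log2")
  expect_silent(lambda_state(list(c(0.5, 0.5)), topology = topo))
})

test_that("extended-xyz and site-topology files round-trip", {
  gen <- small_random_gen(seed = 3, n_env = 12, site = c(3, 2))
  fx <- tempfile(fileext = ".extxyz")
  fj <- tempfile(fileext = ".json")
  write_extxyz(gen$system, fx)
  write_site_topology(gen$topology, fj)
  sys2 <- read_extxyz(fx)
  topo2 <- read_site_topology(fj)
  expect_equal(sys2$positions, gen$system$positions, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sys2$charges, gen$system$charges, tolerance = 1e-10)
  expect_equal(sys2$box_edge, gen$system$box_edge)
  expect_equal(topo2$sites[[1]]$particles, gen$topology$sites[[1]]$particles)
  expect_equal(topo2$sites[[1]]$forms, gen$topology$sites[[1]]$forms,
               tolerance = 1e-12, ignore_attr = TRUE)
})
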