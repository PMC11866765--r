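test_that("octree partitions every particle into exactly one leaf", {
  gen <- generate_random_system(generator_spec(n_env = 1000, seed = 11))
  oc0 <- build_octree(gen$system, 0)
  expect_equal(oc0$n_boxes, 1L)
  expect_equal(oc0$counts, 1010L)
  oc3 <- build_octree(gen$system, 3)
  expect_equal(oc3$n_boxes, 512L)
  expect_equal(sum(oc3$counts), 1010L)
  expect_true(all(oc3$assignment >= 1 & oc3$assignment <= 512))
})

test_that("octree occupancy of a uniform system is consistent with a
          multinomial draw (chi-squared, alpha = 0.01)", {
  set.seed(12)
  n <- 4000
  sys <- particle_system(matrix(runif(3 * n, 0, 2), n, 3),
                         rep(0, n), 2)
  oc <- build_octree(sys, 2)
  chi2 <- sum((oc$counts - n / 64)^2 / (n / 64))
  expect_gt(pchisq(chi2, df = 63, lower.tail = FALSE), 0.01)
})

test_that("a single charge at the expansion center is a pure monopole", {
  m <- multipole_expand(matrix(c(0.3, 0.4, 0.5), 1), 2.5, c(0.3, 0.4, 0.5), 6)
  expect_equal(unclass(m)[1], 2.5 + 0i)
  expect_equal(max(Mod(unclass(m)[-1])), 0)
})

test_that("operator chain P2M -> M2M -> M2L -> L2L -> L2P reproduces the
          direct potential of separated clusters and converges in p", {
  set.seed(13)
  src_pos <- matrix(runif(30, -0.3, 0.3), 10)
  q <- runif(10, -1, 1)
  tgt_pos <- matrix(runif(30, -0.3, 0.3), 10) + matrix(rep(c(2, 0, 0), each = 10), 10)
  phi_direct <- sapply(seq_len(10), function(i)
    KE * sum(q / sqrt(colSums((t(src_pos) - tgt_pos[i, ])^2))))
  errs <- sapply(c(2, 4, 8, 16), function(p) {
    m <- multipole_expand(src_pos, q, c(0, 0, 0), p)
    m2 <- multipole_translate(m, c(0.05, -0.02, 0.01))
    l <- multipole_to_local(m2, c(2, 0, 0))
    l2 <- local_translate(l, c(2.02, 0.01, -0.03))
    ev <- local_evaluate(l2, tgt_pos)
    max(abs(ev$potential - phi_direct) / abs(phi_direct))
  })
  expect_lt(errs[3], 1e-6)          # p = 8
  expect_true(all(diff(errs) < 0))  # strictly decreasing over the sweep
  # overlapping clusters are a domain error
  m <- multipole_expand(src_pos, q, c(0, 0, 0), 4)
  expect_error(multipole_to_local(m, c(0.4, 0, 0), min_separation = 1),
               "separated")
})

test_that("near-field P2P matches hand-computed Coulomb values and obeys
          Newton's third law", {
  sys <- particle_system(rbind(c(1, 1, 1), c(2, 1, 1)), c(1, 1), 10)
  ds <- direct_sum(sys)
  expect_equal(ds$energy, 138.935458)
  expect_equal(ds$forces[1, ], -ds$forces[2, ])
  expect_equal(ds$forces[1, 1], -138.935458)
  # three collinear charges, hand-summed
  sys3 <- particle_system(rbind(c(1, 1, 1), c(2, 1, 1), c(4, 1, 1)),
                          c(1, -2, 1), 10)
  e_hand <- KE * (1 * -2 / 1 + 1 * 1 / 3 + -2 * 1 / 2)
  expect_equal(direct_sum(sys3)$energy, e_hand)
  expect_equal(colSums(direct_sum(sys3)$forces), rep(0, 3), tolerance = 1e-10)
  # coincident particles raise a singularity error naming the indices
  bad <- particle_system(rbind(c(1, 1, 1), c(1, 1, 1)), c(1, 1), 10)
  expect_error(direct_sum(bad), "coincident particles 1 and 2")
})

test_that("FMM with d = 0 is the direct sum, and deeper trees converge to it
          with increasing multipole order", {
  set.seed(14)
  sys <- particle_system(matrix(runif(1500, 0, 5), 500, 3),
                         runif(500, -1, 1), 5)
  ds <- direct_sum(sys)
  r0 <- fmm_evaluate(sys, 4, 0, periodic = FALSE)
  expect_equal(r0$energy, ds$energy, tolerance = 1e-12)
  expect_equal(max(abs(r0$forces - ds$forces)), 0, tolerance = 1e-10)
  errs <- sapply(c(2, 4, 8, 16), function(p) {
    r <- fmm_evaluate(sys, p, 2, periodic = FALSE)
    median(sqrt(rowSums((r$forces - ds$forces)^2)) /
             sqrt(rowSums(ds$forces^2)))
  })
  expect_lt(errs[3], 1e-4)  # p = 8 median relative force error
  expect_true(all(diff(errs) < 0))
})

test_that("energy from potentials equals the pairwise-summed energy and is
          invariant under rigid translation of an isolated system", {
  set.seed(15)
  n <- 40
  pos <- matrix(runif(3 * n, 1, 2), n, 3)
  q <- runif(n, -1, 1)
  sys <- particle_system(pos, q, 6)
  e_pair <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    e_pair <- e_pair + KE * q[i] * q[j] / sqrt(sum((pos[i, ] - pos[j, ])^2))
  r <- fmm_evaluate(sys, 8, 1, periodic = FALSE)
  expect_equal(r$energy, e_pair, tolerance = 1e-10)
  shifted <- particle_system(pos + 2.5, q, 6)
  r2 <- fmm_evaluate(shifted, 8, 1, periodic = FALSE)
  expect_equal(r2$energy, r$energy, tolerance = 1e-10)
})
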