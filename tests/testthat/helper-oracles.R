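# shared lattice operator (cached per session)
test_op <- function(p = 16) lattice_operator(p)

KE <- 138.935458
KB <- 0.0083144621

# brute-force periodic Coulomb energy by cube-shell-ordered direct summation
# (independent of both the Ewald and the FMM code paths)
brute_lattice_energy <- function(pos, q, L, nshell = 40) {
  n <- nrow(pos)
  e <- 0
  for (s in 0:nshell) {
    es <- 0
    for (nx in -s:s) for (ny in -s:s) for (nz in -s:s) {
      if (max(abs(nx), abs(ny), abs(nz)) != s) next
      for (i in 1:n) for (j in 1:n) {
        if (s == 0 && i == j) next
        r <- sqrt(sum((pos[i, ] - pos[j, ] - c(nx, ny, nz) * L)^2))
        es <- es + q[i] * q[j] / r
      }
    }
    e <- e + es
  }
  0.5 * KE * e
}

# brute-force intra-site image sum over shells smin..smax (pair + self terms)
brute_shell_sum <- function(pos, q, L, smin, smax) {
  n <- nrow(pos)
  e <- 0
  for (s in smin:smax) for (nx in -s:s) for (ny in -s:s) for (nz in -s:s) {
    if (max(abs(nx), abs(ny), abs(nz)) != s) next
    for (i in 1:n) for (j in 1:n) {
      r <- sqrt(sum((pos[i, ] - pos[j, ] - c(nx, ny, nz) * L)^2))
      e <- e + q[i] * q[j] / r
    }
  }
  0.5 * KE * e
}

small_random_gen <- function(seed = 7, n_env = 150, site = c(10, 2),
                             placement = "typical", neutralize = FALSE) {
  generate_random_system(generator_spec(n_env = n_env, sites = list(site),
                                        placement = placement, seed = seed,
                                        neutralize = neutralize))
}

max_rel_dev <- function(gen, p, d, precision = "double", op = test_op()) {
  mah <- mahi_lambda_forces(gen$system, gen$topology, gen$lambda, p = p, d = d,
                            precision = precision, op = op)
  ref <- reference_forces(gen$system, gen$topology, gen$lambda, p = p, d = d,
                          op = op)
  fm <- unlist(mah$F_lambda); fr <- unlist(ref$F_lambda)
  max(abs((fm - fr) / fr))
}
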