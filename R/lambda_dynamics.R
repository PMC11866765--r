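#' Configuration for lambda dynamics
#'
#' @param timestep integration step (fs)
#' @param temperature thermostat temperature (K)
#' @param friction Langevin friction (ps^-1); 0 gives NVE (velocity Verlet)
#' @param mass lambda pseudoparticle mass (u nm^2; numerically kJ mol^-1 ps^2)
#' @param barrier double-well bias barrier height at lambda = 0.5 (kJ/mol)
#' @param mode `"hi"` (Hamiltonian interpolation, via MAHI) or `"qi"`
#'   (charge interpolation)
#' @param seed optional RNG seed
#' @return list of class `dynamics_config`
#' @export
dynamics_config <- function(timestep = 1, temperature = 300, friction = 5,
                            mass = 5, barrier = 5, mode = c("hi", "qi"),
                            seed = NULL) {
  mode <- match.arg(mode)
  if (timestep <= 0) stop("timestep must be positive")
  if (barrier < 0) stop("barrier height must be >= 0")
  structure(list(timestep = timestep, temperature = temperature,
                 friction = friction, mass = mass, barrier = barrier,
                 mode = mode, seed = seed),
            class = "dynamics_config")
}

#' Symmetric double-well bias potential
#'
#' Quartic bias `V(lambda) = 16 h lambda^2 (1 - lambda)^2` with minima at the
#' end states and barrier height `h` at lambda = 0.5, applied independently
#' to every lambda variable during dynamics.
#'
#' @param lambda value(s) in `[0, 1]`
#' @param barrier barrier height h (kJ/mol)
#' @export
double_well <- function(lambda, barrier) {
  16 * barrier * lambda^2 * (1 - lambda)^2
}

#' Exact lambda-Hamiltonian coefficients of a single frozen site
#'
#' With frozen particle coordinates the electrostatic Hamiltonian of a
#' single-site system is a polynomial in the form weights:
#' `H(w) = e0 + c' w` under Hamiltonian interpolation (linear) and
#' `H(w) = e0 + c' w + 0.5 w' A w` under charge interpolation. The
#' coefficients are assembled from full end-state evaluations (box-box at
#' d = 0, order-p lattice operator, tinfoil dipole term) and intra-site
#' self-energies, and drive the fast integrator path of [propagate()].
#'
#' @inheritParams mahi_lambda_forces
#' @param mode `"hi"` or `"qi"`
#' @param p multipole order of the exact evaluations (default 24)
#' @return list with `cvec`, `Amat`, `e0`, `n_forms`
#' @export
lambda_hamiltonian_coeffs <- function(system, topology, mode = c("hi", "qi"),
                                      p = 24, boundary = "tinfoil", op = NULL) {
  mode <- match.arg(mode)
  if (length(topology$sites) != 1L)
    stop("coefficient construction requires exactly one site")
  if (is.null(op)) op <- lattice_operator(p)
  st <- topology$sites[[1]]
  idx <- st$particles
  nf <- nrow(st$forms)
  L <- system$box_edge
  eidx <- env_indices(system, topology)

  e0 <- if (length(eidx)) {
    env_sys <- particle_system(system$positions[eidx, , drop = FALSE],
                               system$charges[eidx], L)
    fmm_evaluate(env_sys, p, 0, boundary = boundary, op = op)$energy
  } else 0

  xs <- system$positions[idx, , drop = FALSE]
  excl <- if (!is.null(topology$exclusions)) topology$exclusions[[1]] else NULL
  hr <- numeric(nf)
  uv <- numeric(nf)
  for (r in seq_len(nf)) {
    q <- system$charges
    q[idx] <- st$forms[r, ]
    hr[r] <- fmm_evaluate(system, p, 0, boundary = boundary, charges = q,
                          op = op)$energy
    uv[r] <- site_self_energy(xs, st$forms[r, ], L, p, op, boundary,
                              exclusions = excl)$energy
  }
  if (mode == "hi") {
    cvec <- hr - e0
    Amat <- matrix(0, nf, nf)
  } else {
    cvec <- hr - e0 - uv
    Amat <- matrix(0, nf, nf)
    for (r in seq_len(nf)) {
      Amat[r, r] <- 2 * uv[r]
      if (r < nf) for (r2 in (r + 1):nf) {
        u12 <- site_self_energy(xs, st$forms[r, ] + st$forms[r2, ], L, p, op,
                                boundary, exclusions = excl)$energy
        Amat[r, r2] <- Amat[r2, r] <- u12 - uv[r] - uv[r2]
      }
    }
  }
  list(cvec = cvec, Amat = Amat, e0 = e0, n_forms = nf)
}

#' Propagate lambda dynamics
#'
#' BAOAB Langevin integration of the lambda pseudoparticles with reflective
#' walls at lambda = 0 and 1 and the [double_well()] bias. Particle
#' coordinates are frozen (the default benchmarking mode, isolating the
#' HI/QI electrostatic difference); single-site systems use a fast kernel
#' driven by exact precomputed Hamiltonian coefficients, multi-site systems
#' fall back to per-step force evaluation. With `friction = 0` and no noise
#' the integrator is velocity Verlet and conserves the extended energy.
#'
#' @inheritParams mahi_lambda_forces
#' @param config a [dynamics_config()]
#' @param n_steps number of integration steps
#' @param sample_every sampling stride for the stored trajectory
#' @param p_exact multipole order of the frozen-coordinate Hamiltonian
#'   coefficients (and of the per-step evaluations on the general path)
#' @param particles `"frozen"` (default) or `"langevin"`: optionally move the
#'   real particles under Coulomb-only forces with the same BAOAB scheme
#'   (desk-scale step counts; every step re-evaluates the electrostatics)
#' @param particle_mass mass of the real particles (u), used only with
#'   `particles = "langevin"`
#' @return object of class `lambda_trajectory`: sampled times (ps), lambda
#'   values, velocities and extended energies
#' @export
propagate <- function(system, topology, state, config, n_steps,
                      sample_every = 10, p_exact = 24, op = NULL,
                      particles = c("frozen", "langevin"),
                      particle_mass = 40) {
  stopifnot(inherits(config, "dynamics_config"))
  particles <- match.arg(particles)
  dt <- config$timestep * 1e-3  # fs -> ps
  kT <- .kB * config$temperature
  if (!is.null(config$seed)) set.seed(config$seed)

  if (particles == "langevin")
    return(propagate_coupled(system, topology, state, config, n_steps,
                             sample_every, p_exact, op, particle_mass))

  if (length(topology$sites) == 1L) {
    co <- lambda_hamiltonian_coeffs(system, topology, config$mode, p_exact,
                                    op = op)
    lam0 <- state$lambdas[[1]]
    v0 <- state$velocities[[1]]
    mass <- state$masses[[1]]
    out <- cpp_baoab_site(lam0, v0, mass, co$n_forms, co$cvec, co$Amat,
                          dt, config$friction, kT, config$barrier,
                          as.integer(n_steps), as.integer(sample_every))
    traj <- list(time = dt * sample_every * seq_len(nrow(out$lambda)),
                 lambda = out$lambda, velocity = out$velocity,
                 energy = out$energy, config = config,
                 final = list(lambda = out$final_lambda,
                              velocity = out$final_velocity),
                 coeffs = co)
    class(traj) <- "lambda_trajectory"
    return(traj)
  }

  # general path: per-step force evaluation (desk-scale step counts only)
  nl <- vapply(state$lambdas, length, 0L)
  lam <- unlist(state$lambdas)
  vel <- unlist(state$velocities)
  mass <- unlist(state$masses)
  split_lam <- function(x) {
    sp <- split(x, rep(seq_along(nl), nl))
    names(sp) <- NULL
    sp
  }
  force_fun <- function(lamv) {
    stt <- lambda_state(split_lam(lamv), topology = topology)
    rep_ <- if (config$mode == "hi")
      mahi_lambda_forces(system, topology, stt, p = p_exact, d = 0, op = op)
    else qi_lambda_forces(system, topology, stt, p = p_exact, d = 0, op = op)
    unlist(rep_$F_lambda) -
      32 * config$barrier * lamv * (1 - lamv) * (1 - 2 * lamv)
  }
  c1 <- if (config$friction > 0) exp(-config$friction * dt) else 1
  nsamp <- n_steps %/% sample_every
  lam_out <- matrix(NA_real_, nsamp, length(lam))
  vel_out <- matrix(NA_real_, nsamp, length(lam))
  ener <- numeric(nsamp)
  f <- force_fun(lam)
  reflect <- function(lam, vel) {
    for (i in seq_along(lam)) {
      while (lam[i] < 0 || lam[i] > 1) {
        lam[i] <- if (lam[i] < 0) -lam[i] else 2 - lam[i]
        vel[i] <- -vel[i]
      }
    }
    list(lam, vel)
  }
  isamp <- 0L
  for (step in seq_len(n_steps)) {
    vel <- vel + 0.5 * dt * f / mass
    lam <- lam + 0.5 * dt * vel
    rf <- reflect(lam, vel); lam <- rf[[1]]; vel <- rf[[2]]
    if (config$friction > 0)
      vel <- c1 * vel + sqrt(kT / mass * (1 - c1^2)) * rnorm(length(vel))
    lam <- lam + 0.5 * dt * vel
    rf <- reflect(lam, vel); lam <- rf[[1]]; vel <- rf[[2]]
    f <- force_fun(lam)
    vel <- vel + 0.5 * dt * f / mass
    if (step %% sample_every == 0) {
      isamp <- isamp + 1L
      lam_out[isamp, ] <- lam
      vel_out[isamp, ] <- vel
      stt <- lambda_state(split_lam(lam), topology = topology)
      rep_ <- mahi_lambda_forces(system, topology, stt, p = p_exact, d = 0,
                                 op = op)
      h <- if (config$mode == "hi") rep_$energy$H_hi else rep_$energy$H_qi
      ener[isamp] <- h + sum(double_well(lam, config$barrier)) +
        sum(0.5 * mass * vel^2)
    }
  }
  traj <- list(time = dt * sample_every * seq_len(nsamp), lambda = lam_out,
               velocity = vel_out, energy = ener, config = config,
               final = list(lambda = lam, velocity = vel))
  class(traj) <- "lambda_trajectory"
  traj
}

#' @export
print.lambda_trajectory <- function(x, ...) {
  cat(sprintf("lambda_trajectory: %d samples over %.4g ps (%s mode)\n",
              nrow(x$lambda), max(x$time), toupper(x$config$mode)))
  cat(sprintf("  mean lambda = %s\n",
              paste(signif(colMeans(x$lambda), 4), collapse = ", ")))
  invisible(x)
}

#' Count protonation-state transitions with hysteresis
#'
#' A transition is registered when lambda crosses from below `lo` to above
#' `hi` or vice versa; recrossings within the hysteresis band are not
#' counted. Successive transitions necessarily alternate in direction.
#'
#' @param x a `lambda_trajectory` (first lambda variable) or numeric vector
#' @param lo,hi hysteresis thresholds, `lo < hi`
#' @param time optional times (ps) matching a numeric `x`
#' @return list with `count`, `rate_per_ns` (NA when no time base), and an
#'   `events` data frame (time, direction)
#' @export
count_transitions <- function(x, lo = 0.2, hi = 0.8, time = NULL) {
  if (inherits(x, "lambda_trajectory")) {
    time <- x$time
    x <- x$lambda[, 1]
  }
  if (lo >= hi) stop("lo must be smaller than hi")
  side <- 0L  # -1 low, +1 high, 0 undetermined
  count <- 0L
  ev_t <- numeric(0)
  ev_d <- integer(0)
  for (i in seq_along(x)) {
    s <- if (x[i] <= lo) -1L else if (x[i] >= hi) 1L else 0L
    if (s != 0L) {
      if (side != 0L && s != side) {
        count <- count + 1L
        ev_t <- c(ev_t, if (!is.null(time)) time[i] else i)
        ev_d <- c(ev_d, s)
      }
      side <- s
    }
  }
  span_ns <- if (!is.null(time) && length(time) > 1)
    (max(time) - min(time)) / 1e3 else NA_real_
  list(count = count,
       rate_per_ns = if (is.na(span_ns) || span_ns <= 0) NA_real_
                     else count / span_ns,
       events = data.frame(time = ev_t, direction = ev_d))
}

#' Barrier difference from a transition-rate ratio (TST)
#'
#' Translates two transition rates into an apparent free-energy barrier
#' difference under a transition-state-theory model with equal prefactors:
#' `Delta = ln(rate_a / rate_b)` in units of k_B T. Antisymmetric in the
#' argument order; zero for equal rates.
#'
#' @param rate_a,rate_b positive rates (any common unit)
#' @param temperature temperature (K), used only for the kJ/mol attribute
#' @return barrier difference in k_B T, with attribute `kJ_per_mol`
#' @export
tst_barrier_from_rates <- function(rate_a, rate_b, temperature = 300) {
  if (rate_a <= 0 || rate_b <= 0) stop("rates must be positive")
  d <- log(rate_a / rate_b)
  attr(d, "kJ_per_mol") <- d * .kB * temperature
  d
}

# coupled lambda + particle Langevin dynamics (Coulomb-only particle forces);
# one full electrostatics evaluation per step -- intended for small systems
propagate_coupled <- function(system, topology, state, config, n_steps,
                              sample_every, p_exact, op, particle_mass) {
  if (is.null(op)) op <- lattice_operator(p_exact)
  L <- system$box_edge
  pos <- system$positions
  n <- nrow(pos)
  pvel <- matrix(0, n, 3)
  nl <- vapply(state$lambdas, length, 0L)
  lam <- unlist(state$lambdas)
  lvel <- unlist(state$velocities)
  lmass <- unlist(state$masses)
  kT <- .kB * config$temperature
  dt <- config$timestep * 1e-3
  c1 <- if (config$friction > 0) exp(-config$friction * dt) else 1
  split_lam <- function(x) {
    sp <- split(x, rep(seq_along(nl), nl))
    names(sp) <- NULL
    sp
  }
  eval_all <- function(pos, lamv) {
    sys <- particle_system(pos, system$charges, L)
    stt <- lambda_state(split_lam(lamv), topology = topology)
    qs <- scaled_charges(sys, topology, state_weights(stt, topology))
    base <- fmm_evaluate(sys, p_exact, 0, charges = qs, op = op)
    rep_ <- if (config$mode == "hi")
      mahi_lambda_forces(sys, topology, stt, p = p_exact, d = 0, op = op)
    else qi_lambda_forces(sys, topology, stt, p = p_exact, d = 0, op = op)
    flam <- unlist(rep_$F_lambda) -
      32 * config$barrier * lamv * (1 - lamv) * (1 - 2 * lamv)
    h <- if (config$mode == "hi") rep_$energy$H_hi else rep_$energy$H_qi
    list(fpart = base$forces, flam = flam, h = h)
  }
  ev <- eval_all(pos, lam)
  nsamp <- n_steps %/% sample_every
  lam_out <- matrix(NA_real_, nsamp, length(lam))
  vel_out <- matrix(NA_real_, nsamp, length(lam))
  ener <- numeric(nsamp)
  isamp <- 0L
  reflect <- function(lam, vel) {
    for (i in seq_along(lam)) {
      while (lam[i] < 0 || lam[i] > 1) {
        lam[i] <- if (lam[i] < 0) -lam[i] else 2 - lam[i]
        vel[i] <- -vel[i]
      }
    }
    list(lam, vel)
  }
  for (step in seq_len(n_steps)) {
    pvel <- pvel + 0.5 * dt * ev$fpart / particle_mass
    lvel <- lvel + 0.5 * dt * ev$flam / lmass
    pos <- (pos + 0.5 * dt * pvel) %% L
    lam <- lam + 0.5 * dt * lvel
    rf <- reflect(lam, lvel); lam <- rf[[1]]; lvel <- rf[[2]]
    if (config$friction > 0) {
      pvel <- c1 * pvel + sqrt(kT / particle_mass * (1 - c1^2)) *
        matrix(rnorm(3 * n), n, 3)
      lvel <- c1 * lvel + sqrt(kT / lmass * (1 - c1^2)) * rnorm(length(lvel))
    }
    pos <- (pos + 0.5 * dt * pvel) %% L
    lam <- lam + 0.5 * dt * lvel
    rf <- reflect(lam, lvel); lam <- rf[[1]]; lvel <- rf[[2]]
    ev <- eval_all(pos, lam)
    pvel <- pvel + 0.5 * dt * ev$fpart / particle_mass
    lvel <- lvel + 0.5 * dt * ev$flam / lmass
    if (step %% sample_every == 0) {
      isamp <- isamp + 1L
      lam_out[isamp, ] <- lam
      vel_out[isamp, ] <- lvel
      ener[isamp] <- ev$h + sum(double_well(lam, config$barrier)) +
        sum(0.5 * lmass * lvel^2) + sum(0.5 * particle_mass * pvel^2)
    }
  }
  traj <- list(time = dt * sample_every * seq_len(nsamp), lambda = lam_out,
               velocity = vel_out, energy = ener, config = config,
               final = list(lambda = lam, velocity = lvel, positions = pos))
  class(traj) <- "lambda_trajectory"
  traj
}
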