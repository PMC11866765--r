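#' Specification for random benchmark systems
#'
#' Captures the construction of the random accuracy-benchmark systems:
#' `n_env` environment particles with charges drawn uniformly from (-1, 1),
#' plus titratable sites whose particles are either clustered within a ball
#' of radius L/20 ("typical", mimicking an amino-acid-sized group) or spread
#' uniformly over the whole box ("worst_case"). Identical spec and seed
#' reproduce the identical system.
#'
#' @param n_env number of environment particles
#' @param sites list of `c(n_particles, n_forms)` pairs, one per site
#' @param placement `"typical"` or `"worst_case"`
#' @param box_edge cubic box edge (nm); the benchmarks are scale-free in L
#' @param seed RNG seed
#' @param neutralize center the environment charges and every form row to a
#'   zero sum (default FALSE: raw uniform draws)
#' @param lambda optional list of per-site lambda vectors; defaults to 0.345
#'   for one lambda variable and (0.345, 0.721) for two
#' @return list of class `generator_spec`
#' @export
generator_spec <- function(n_env = 1000, sites = list(c(10, 2)),
                           placement = c("typical", "worst_case"),
                           box_edge = 5, seed = 1, neutralize = FALSE,
                           lambda = NULL) {
  placement <- match.arg(placement)
  structure(list(n_env = n_env, sites = sites, placement = placement,
                 box_edge = box_edge, seed = seed, neutralize = neutralize,
                 lambda = lambda),
            class = "generator_spec")
}

# uniform point in a ball of radius r about center, clipped into [0, L)
.ball_point <- function(center, r) {
  u <- rnorm(3)
  center + r * runif(1)^(1 / 3) * u / sqrt(sum(u^2))
}

#' Generate a random benchmark system
#'
#' @param spec a [generator_spec()]
#' @return list with `system` ([particle_system()]), `topology`
#'   ([site_topology()]), `lambda` ([lambda_state()]) and the `spec`
#' @export
generate_random_system <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  L <- spec$box_edge
  n_site <- sum(vapply(spec$sites, `[`, 0, 1))
  n <- spec$n_env + n_site
  pos <- matrix(runif(3 * spec$n_env, 0, L), spec$n_env, 3)
  r0 <- L / 20
  for (s in spec$sites) {
    ns <- s[1]
    if (spec$placement == "typical") {
      center <- runif(3, r0, L - r0)
      pts <- t(replicate(ns, .ball_point(center, r0)))
    } else {
      pts <- matrix(runif(3 * ns, 0, L), ns, 3)
    }
    pos <- rbind(pos, pts)
  }
  # resample any particle closer than 1e-4 nm to an earlier one
  repeat {
    dup <- FALSE
    for (i in seq_len(nrow(pos))) {
      if (i == 1) next
      d2 <- rowSums((pos[seq_len(i - 1), , drop = FALSE] -
                       matrix(pos[i, ], i - 1, 3, byrow = TRUE))^2)
      if (any(d2 < 1e-8)) { pos[i, ] <- runif(3, 0, L); dup <- TRUE }
    }
    if (!dup) break
  }
  q_env <- runif(spec$n_env, -1, 1)
  if (spec$neutralize && spec$n_env > 0) q_env <- q_env - mean(q_env)
  charges <- c(q_env, numeric(n_site))
  sites <- list()
  ofs <- spec$n_env
  for (s in spec$sites) {
    ns <- s[1]; nf <- s[2]
    forms <- matrix(runif(nf * ns, -1, 1), nf, ns)
    if (spec$neutralize) forms <- forms - rowMeans(forms)
    sites <- c(sites, list(list(particles = ofs + seq_len(ns), forms = forms)))
    ofs <- ofs + ns
  }
  system <- particle_system(pos, charges, L)
  topology <- site_topology(sites)
  lambdas <- spec$lambda
  if (is.null(lambdas)) {
    lambdas <- lapply(spec$sites, function(s) {
      nl <- n_lambda(s[2])
      lam <- c(0.345, 0.721, runif(max(0, nl - 2)))[seq_len(nl)]
      lam
    })
  }
  state <- lambda_state(lambdas, topology = topology)
  list(system = system, topology = topology, lambda = state, spec = spec)
}

#' Series of random systems with the benchmark site density
#'
#' One 10-particle two-form titratable site per 4000 particles (the density
#' of a solvated globular protein), with a floor of one site for small
#' systems.
#'
#' @param base_spec template [generator_spec()] (placement, box, seed policy)
#' @param particle_counts total particle counts N (each >= 250)
#' @return list of generated systems (as [generate_random_system()])
#' @export
generate_scaling_series <- function(base_spec, particle_counts) {
  stopifnot(all(particle_counts >= 250))
  lapply(seq_along(particle_counts), function(i) {
    N <- particle_counts[i]
    n_sites <- max(1L, N %/% 4000L)
    sp <- base_spec
    sp$sites <- replicate(n_sites, c(10, 2), simplify = FALSE)
    sp$n_env <- N - 10L * n_sites
    sp$seed <- base_spec$seed + i - 1L
    generate_random_system(sp)
  })
}

#' Closed-form test fixtures
#'
#' Registered fixtures with independently known answers:
#' \describe{
#'   \item{`nacl`}{centered rock-salt motif (8 alternating unit charges);
#'     the periodic energy follows from the Madelung constant.}
#'   \item{`dipole_pair`}{a +1/-1 pair displaced along x; probes the dipole
#'     compensation term.}
#'   \item{`symmetric_site`}{two-particle, two-form site with mirror-image
#'     end-state charges in a mirror-symmetric frozen charge bath: the HI
#'     free-energy landscape between the end states is exactly flat and the
#'     whole problem is symmetric under lambda -> 1 - lambda.}
#'   \item{`single_particle_site`}{one-particle site (no intra-site pairs):
#'     the central-box QI-HI force constant vanishes and the remaining
#'     difference is purely the periodic self-image term.}
#' }
#'
#' @param name fixture name
#' @param delta charge asymmetry of the symmetric site (e)
#' @param separation site particle separation (nm)
#' @return list with `system`, `topology`, `lambda` and fixture metadata
#' @export
make_fixture <- function(name = c("nacl", "dipole_pair", "symmetric_site",
                                  "single_particle_site"),
                         delta = 0.085, separation = 0.4) {
  name <- match.arg(name)
  if (name == "nacl") {
    L <- 2
    gr <- as.matrix(expand.grid(0:1, 0:1, 0:1))
    pos <- L / 4 + gr * L / 2
    q <- (-1)^rowSums(gr)
    return(list(system = particle_system(pos, q, L),
                topology = site_topology(list()),
                lambda = NULL,
                madelung = 1.74756459463318,
                nn_distance = L / 2))
  }
  if (name == "dipole_pair") {
    L <- 2
    pos <- rbind(c(L / 2 + 0.25, L / 2, L / 2), c(L / 2 - 0.25, L / 2, L / 2))
    q <- c(1, -1)
    return(list(system = particle_system(pos, q, L),
                topology = site_topology(list()),
                lambda = NULL, dipole = c(0.5, 0, 0)))
  }
  if (name == "symmetric_site") {
    L <- 3
    # mirror plane x = L/2; bath positions come in mirror pairs with equal
    # charge, so the full Hamiltonian is invariant under lambda -> 1 - lambda
    bath <- rbind(c(0.60, 0.80, 1.00), c(L - 0.60, 0.80, 1.00),
                  c(1.00, 2.20, 0.70), c(L - 1.00, 2.20, 0.70),
                  c(0.45, 1.60, 2.30), c(L - 0.45, 1.60, 2.30),
                  c(1.20, 0.50, 2.00), c(L - 1.20, 0.50, 2.00))
    qb <- c(0.25, 0.25, -0.25, -0.25, 0.2, 0.2, -0.2, -0.2)
    site_pos <- rbind(c(L / 2 - separation / 2, L / 2, L / 2),
                      c(L / 2 + separation / 2, L / 2, L / 2))
    pos <- rbind(bath, site_pos)
    charges <- c(qb, 0, 0)
    system <- particle_system(pos, charges, L)
    topology <- site_topology(list(list(
      particles = nrow(bath) + 1:2,
      forms = rbind(c(delta, -delta), c(-delta, delta)))))
    return(list(system = system, topology = topology,
                lambda = lambda_state(list(0.5), topology = topology),
                delta = delta, separation = separation))
  }
  # single_particle_site
  L <- 3
  pos <- rbind(c(0.5, 0.6, 0.7), c(2.5, 2.2, 1.8), c(1.2, 2.6, 0.4),
               c(L / 2, L / 2, L / 2))
  charges <- c(0.4, -0.3, -0.1, 0)
  system <- particle_system(pos, charges, L)
  topology <- site_topology(list(list(particles = 4L,
                                      forms = rbind(0.3, -0.4))))
  list(system = system, topology = topology,
       lambda = lambda_state(list(0.345), topology = topology))
}
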