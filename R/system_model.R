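#' Particle system in a cubic periodic box
#'
#' Container for point charges in a cubic box with edge `box_edge` (nm).
#' Positions must lie in `[0, L)`; charges are in elementary-charge units.
#' Together with a [site_topology()] the particles split into an
#' *environment* (fixed charges) and titratable *sites* whose charges depend
#' on the protonation form.
#'
#' @param positions numeric N x 3 matrix of coordinates (nm).
#' @param charges numeric vector of length N (e). For particles belonging to
#'   a titratable site this is a placeholder; the effective charge is set by
#'   the form weights.
#' @param box_edge cubic box edge L (nm).
#' @return An object of class `particle_system`.
#' @export
particle_system <- function(positions, charges, box_edge) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be an N x 3 matrix")
  charges <- as.numeric(charges)
  if (nrow(positions) != length(charges))
    stop("positions and charges disagree in length")
  if (!is.numeric(box_edge) || length(box_edge) != 1L || box_edge <= 0)
    stop("box_edge must be a positive scalar")
  if (any(positions < 0) || any(positions >= box_edge))
    stop("all coordinates must lie in [0, box_edge)")
  structure(list(positions = positions, charges = charges,
                 box_edge = as.numeric(box_edge)),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("particle_system: %d particles, L = %g nm, total charge %.4g e\n",
              nrow(x$positions), x$box_edge, sum(x$charges)))
  invisible(x)
}

#' Site topology: titratable sites and their protonation forms
#'
#' A *site* is the group of particles whose partial charges change upon
#' (de)protonation; a *form* is one chemically distinct charge state of the
#' site. Each site entry carries 1-based particle indices into the particle
#' system and a `forms` matrix with one row per form and one column per site
#' particle.
#'
#' @param sites list; each element a list with `particles` (integer vector)
#'   and `forms` (numeric matrix, `n_forms x length(particles)`, e).
#' @param exclusions optional list (same length as `sites`) of 2-column
#'   integer matrices of intra-site pairs (local indices) whose central-box
#'   interaction is excluded (bonded-pair exclusions); image interactions of
#'   excluded pairs are retained.
#' @return An object of class `site_topology`.
#' @export
site_topology <- function(sites, exclusions = NULL) {
  if (!length(sites)) {
    return(structure(list(sites = list(), exclusions = NULL),
                     class = "site_topology"))
  }
  seen <- integer(0)
  sites <- lapply(sites, function(s) {
    s$particles <- as.integer(s$particles)
    s$forms <- as.matrix(s$forms)
    if (nrow(s$forms) < 2L)
      stop("a site needs at least two forms")
    if (ncol(s$forms) != length(s$particles))
      stop("forms matrix must have one column per site particle")
    if (anyDuplicated(s$forms) > 0L)
      stop("form charge rows must be pairwise distinct")
    s
  })
  for (s in sites) {
    if (any(s$particles %in% seen))
      stop("particle indices of distinct sites must be disjoint")
    seen <- c(seen, s$particles)
  }
  structure(list(sites = sites, exclusions = exclusions),
            class = "site_topology")
}

#' @export
print.site_topology <- function(x, ...) {
  cat(sprintf("site_topology: %d site(s)\n", length(x$sites)))
  for (i in seq_along(x$sites))
    cat(sprintf("  site %d: %d particles, %d forms\n", i,
                length(x$sites[[i]]$particles), nrow(x$sites[[i]]$forms)))
  invisible(x)
}

#' Number of lambda variables for a site with `n_forms` forms
#' @param n_forms integer number of forms (>= 2)
#' @return `ceiling(log2(n_forms))`
#' @export
n_lambda <- function(n_forms) as.integer(ceiling(log2(n_forms)))

#' Lambda state of the titratable sites
#'
#' Dynamic state of the lambda pseudoparticles: one vector of
#' `ceiling(log2(n_forms))` lambda values per site, with matching velocities
#' (ps^-1) and masses (u nm^2, numerically equal to kJ mol^-1 ps^2).
#'
#' @param lambdas list of numeric vectors in `[0, 1]`, one per site.
#' @param velocities like `lambdas`; defaults to zero.
#' @param masses like `lambdas`; defaults to 5 u nm^2.
#' @param topology optional [site_topology()] used to check vector lengths.
#' @export
lambda_state <- function(lambdas, velocities = NULL, masses = NULL,
                         topology = NULL) {
  lambdas <- lapply(lambdas, as.numeric)
  if (any(unlist(lambdas) < 0 | unlist(lambdas) > 1))
    stop("lambda values must lie in [0, 1]")
  if (is.null(velocities)) velocities <- lapply(lambdas, function(v) v * 0)
  if (is.null(masses)) masses <- lapply(lambdas, function(v) v * 0 + 5)
  if (!is.null(topology)) {
    if (length(lambdas) != length(topology$sites))
      stop("one lambda vector per site required")
    for (i in seq_along(lambdas))
      if (length(lambdas[[i]]) != n_lambda(nrow(topology$sites[[i]]$forms)))
        stop(sprintf("site %d: lambda vector must have length ceiling(log2(#forms))", i))
  }
  structure(list(lambdas = lambdas, velocities = velocities, masses = masses),
            class = "lambda_state")
}

#' Map lambda values to per-form weights
#'
#' Binary-tree product transform: write the form index rho (0-based) in
#' binary with `lambda[1]` controlling the most significant bit; the weight
#' of form rho is the product over levels l of `lambda[l]` (bit set) or
#' `1 - lambda[l]` (bit clear). For form counts that are not a power of two,
#' the weights of the surplus (ghost) leaves are folded into the last real
#' form, preserving the sum rule and differentiability. At `lambda = 0` the
#' site is purely form 0 ("protonated" end state by convention), at
#' `lambda = 1` (two forms) purely form 1.
#'
#' Weights lie in `[0, 1]` and sum to exactly 1 for any lambda in the unit
#' cube.
#'
#' @param lambda numeric vector of length `n_lambda(n_forms)`, each in `[0,1]`.
#' @param n_forms integer number of forms.
#' @return numeric vector of `n_forms` weights.
#' @export
lambda_to_weights <- function(lambda, n_forms) {
  nl <- n_lambda(n_forms)
  if (length(lambda) != nl)
    stop(sprintf("lambda vector must have length %d for %d forms", nl, n_forms))
  if (any(lambda < 0 | lambda > 1)) stop("lambda values must lie in [0, 1]")
  nleaf <- 2L^nl
  w <- numeric(n_forms)
  for (b in 0:(nleaf - 1L)) {
    wb <- 1
    for (l in seq_len(nl)) {
      bit <- bitwAnd(bitwShiftR(b, nl - l), 1L)
      wb <- wb * if (bit == 1L) lambda[l] else 1 - lambda[l]
    }
    rho <- if (b < n_forms) b + 1L else n_forms
    w[rho] <- w[rho] + wb
  }
  w
}

#' Jacobian of the lambda-to-weights transform
#'
#' Analytic derivative matrix `d w_rho / d lambda_l` of
#' [lambda_to_weights()]. Columns sum to zero (the weights sum to one for
#' every lambda).
#'
#' @inheritParams lambda_to_weights
#' @return numeric `n_forms x n_lambda` matrix.
#' @export
weights_jacobian <- function(lambda, n_forms) {
  nl <- n_lambda(n_forms)
  if (length(lambda) != nl)
    stop(sprintf("lambda vector must have length %d for %d forms", nl, n_forms))
  if (any(lambda < 0 | lambda > 1)) stop("lambda values must lie in [0, 1]")
  nleaf <- 2L^nl
  J <- matrix(0, n_forms, nl)
  for (b in 0:(nleaf - 1L)) {
    rho <- if (b < n_forms) b + 1L else n_forms
    for (l in seq_len(nl)) {
      d <- 1
      for (l2 in seq_len(nl)) {
        bit <- bitwAnd(bitwShiftR(b, nl - l2), 1L)
        d <- d * if (l2 == l) (if (bit == 1L) 1 else -1)
                 else (if (bit == 1L) lambda[l2] else 1 - lambda[l2])
      }
      J[rho, l] <- J[rho, l] + d
    }
  }
  J
}

#' Form weights for every site of a lambda state
#' @param state a [lambda_state()]
#' @param topology a [site_topology()]
#' @return list of per-site weight vectors
#' @export
state_weights <- function(state, topology) {
  lapply(seq_along(topology$sites), function(i)
    lambda_to_weights(state$lambdas[[i]], nrow(topology$sites[[i]]$forms)))
}

#' Weight-scaled charges
#'
#' Environment charges are returned unchanged; each site particle carries the
#' weight-averaged charge `sum_rho w_rho q_i^(rho)`.
#'
#' @param system a [particle_system()]
#' @param topology a [site_topology()]
#' @param weights list of per-site weight vectors (from [state_weights()] or
#'   [lambda_to_weights()])
#' @return numeric charge vector of length N
#' @export
scaled_charges <- function(system, topology, weights) {
  q <- system$charges
  n <- length(q)
  for (i in seq_along(topology$sites)) {
    s <- topology$sites[[i]]
    if (any(s$particles < 1L | s$particles > n))
      stop("site particle index out of range")
    w <- weights[[i]]
    if (length(w) != nrow(s$forms)) stop("weight/form count mismatch")
    q[s$particles] <- as.numeric(w %*% s$forms)
  }
  q
}

# indices of environment (non-site) particles
env_indices <- function(system, topology) {
  setdiff(seq_along(system$charges),
          unlist(lapply(topology$sites, `[[`, "particles")))
}
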