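#' Periodic lattice operator
#'
#' Linear operator mapping the multipole expansion of the simulation box to
#' the local expansion describing all periodic images beyond the first shell.
#' Its coefficients are lattice sums of irregular solid harmonics over the
#' cubic lattice, computed by shellwise direct summation for high degrees and
#' a factor-3 hierarchical renormalization fixed point for low degrees,
#' converged to near machine precision. The conditionally convergent degrees
#' (monopole and dipole responses) are pinned to zero; with this convention
#' the bare box-box + lattice energy corresponds to vacuum boundary
#' conditions, and [dipole_compensation_energy()] supplies the boundary term
#' that restores tinfoil (Ewald-consistent) energies.
#'
#' The operator is linear in the box multipole, vanishes on a neutral
#' monopole-only box, and is symmetric under the cubic point group (degrees
#' that are not cubic invariants are identically zero).
#'
#' @param p multipole order the operator will serve (sums built to degree 2p)
#' @param jtop optional override of the highest lattice-sum degree
#' @param tol fixed-point convergence tolerance
#' @return list with the complex coefficient vector `sums`, its degree `jtop`
#'   and order `p`; cached per session
#' @export
lattice_operator <- function(p, jtop = NULL, tol = 1e-15) {
  if (is.null(jtop)) jtop <- max(2L * as.integer(p), 80L)
  key <- sprintf("lattice_%d", jtop)
  if (!is.null(.mahi_cache[[key]]))
    return(.mahi_cache[[key]])
  sums <- cpp_lattice_sums(as.integer(jtop), 60L, 24L, 16L, tol, 200L)
  out <- list(sums = sums, jtop = as.integer(jtop), p = as.integer(p))
  .mahi_cache[[key]] <- out
  out
}

#' Apply the lattice operator to a box multipole
#' @param m a `multipole_expansion` about the box center
#' @param L box edge (nm)
#' @param op lattice operator (built automatically when omitted)
#' @return `local_expansion` about the box center describing the periodic
#'   far field beyond the first image shell
#' @export
lattice_local_expansion <- function(m, L, op = NULL) {
  p <- attr(m, "p")
  if (is.null(op)) op <- lattice_operator(p)
  out <- cpp_lattice_apply(unclass(m), op$sums, p, op$jtop, L)
  structure(out, center = attr(m, "center"), p = p, class = "local_expansion")
}

#' Dipole compensation (tinfoil boundary term)
#'
#' Quadratic boundary term converting the vacuum-convention lattice-summed
#' energy to the intrinsic (tinfoil) energy of Ewald summation:
#' `Xi = -(2 pi k / 3 L^3) |D|^2` with `D` the box dipole about the box
#' center. It equals minus the classic vacuum-minus-tinfoil surface term, is
#' zero for a vanishing dipole, and quadratic in the dipole.
#'
#' @param system a [particle_system()]
#' @param charges optional replacement charges
#' @return list with `energy` (kJ/mol), per-particle `potential` (kJ/mol/e),
#'   `forces` (N x 3), the raw per-particle gradient vector `grad_raw`
#'   (identical for all particles) and the box `dipole` (e nm)
#' @export
dipole_compensation_energy <- function(system, charges = NULL) {
  q <- if (is.null(charges)) system$charges else as.numeric(charges)
  L <- system$box_edge
  xc <- sweep(system$positions, 2, L / 2)
  D <- colSums(q * xc)
  c0 <- 2 * pi / (3 * L^3)
  # potential such that (1/2) sum q phi = -ke c0 |D|^2
  phi <- -.ke * 2 * c0 * as.numeric(xc %*% D)
  grad_raw <- -2 * c0 * D
  list(energy = -.ke * c0 * sum(D^2),
       potential = phi,
       forces = matrix(.ke * 2 * c0 * q, length(q), 1) %*% D,
       grad_raw = grad_raw,
       dipole = D)
}

#' Ewald summation oracle (tinfoil boundary conditions)
#'
#' Classic Ewald sum used as the independent reference for the periodic FMM.
#' Parameters are chosen automatically from the requested tolerance; energies
#' are intrinsic (tinfoil). For non-neutral systems a uniform neutralizing
#' background must be requested explicitly, otherwise a domain error is
#' raised.
#'
#' @param system a [particle_system()]
#' @param charges optional replacement charges
#' @param tol target relative accuracy (drives the splitting parameter and
#'   cutoffs)
#' @param beta optional Ewald splitting parameter (nm^-1); overrides `tol`
#' @param nreal real-space image shells
#' @param kmax reciprocal-space cutoff (integer)
#' @param background add a uniform neutralizing background for charged
#'   systems
#' @param boundary `"tinfoil"` (default) or `"vacuum"` (adds the surface
#'   dipole term `+ (2 pi k / 3 L^3) |D|^2`)
#' @return list with `energy`, `potential`, `forces`, `parts`
#' @export
ewald_oracle <- function(system, charges = NULL, tol = 1e-12, beta = NULL,
                         nreal = NULL, kmax = NULL, background = FALSE,
                         boundary = c("tinfoil", "vacuum")) {
  boundary <- match.arg(boundary)
  q <- if (is.null(charges)) system$charges else as.numeric(charges)
  L <- system$box_edge
  if (abs(sum(q)) > 1e-9 && !background)
    stop("non-neutral system: set background = TRUE for a neutralizing background")
  # betaL sets real-space accuracy erfc(beta * nreal * L); reciprocal cutoff
  # follows from exp(-(pi h / beta L)^2)
  betaL <- if (is.null(beta)) max(5.5, sqrt(-log(tol * 1e-2))) else beta * L
  if (is.null(beta)) beta <- betaL / L
  if (is.null(nreal)) nreal <- max(1L, ceiling(betaL * 0 + 5.4 / betaL))
  if (is.null(kmax)) kmax <- ceiling(betaL * sqrt(-log(tol * 1e-3)) / pi) + 1L
  ew <- cpp_ewald(system$positions, q, L, beta, as.integer(nreal),
                  as.integer(kmax), background)
  phi <- ew$phi
  grad <- ew$grad
  energy <- 0.5 * .ke * sum(q * phi)
  parts <- c(ewald = energy, surface = 0)
  if (boundary == "vacuum") {
    xc <- sweep(system$positions, 2, L / 2)
    D <- colSums(q * xc)
    c0 <- 2 * pi / (3 * L^3)
    parts["surface"] <- .ke * c0 * sum(D^2)
    phi <- phi + 2 * c0 * as.numeric(xc %*% D)
    grad <- grad + matrix(2 * c0 * D, length(q), 3, byrow = TRUE)
    energy <- energy + parts[["surface"]]
  }
  list(energy = energy, potential = .ke * phi, forces = -.ke * q * grad,
       parts = parts, beta = beta, nreal = nreal, kmax = kmax)
}
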