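#' Build an octree over the simulation box
#'
#' The cubic box is divided into `8^depth` equal leaf cells; every particle is
#' assigned to exactly one leaf. `depth = 0` keeps everything in a single box
#' (all interactions are near field).
#'
#' @param system a [particle_system()]
#' @param depth tree depth d >= 0
#' @return object of class `octree` with the per-particle leaf assignment and
#'   per-leaf occupancy
#' @export
build_octree <- function(system, depth) {
  depth <- as.integer(depth)
  if (depth < 0) stop("depth must be >= 0")
  ids <- cpp_leaf_assign(system$positions, system$box_edge, depth)
  nb <- 8L^depth
  counts <- tabulate(ids, nbins = nb)
  structure(list(depth = depth, n_boxes = nb,
                 box_width = system$box_edge / 2^depth,
                 assignment = ids, counts = counts),
            class = "octree")
}

#' @export
print.octree <- function(x, ...) {
  cat(sprintf("octree: depth %d, %d leaf boxes (width %g nm), %d particles\n",
              x$depth, x$n_boxes, x$box_width, length(x$assignment)))
  invisible(x)
}

#' Multipole expansion of a charge cloud
#'
#' Truncated solid-harmonic multipole expansion of order `p` about `center`
#' (the P2M operator). The monopole coefficient equals the total charge and
#' the coefficients of a real charge distribution obey conjugate symmetry
#' across +/- m.
#'
#' @param positions N x 3 matrix (nm)
#' @param charges length-N charges (e)
#' @param center expansion center (3-vector)
#' @param p multipole order
#' @return complex coefficient vector of length `(p+1)^2`, class
#'   `multipole_expansion` with attributes `center` and `p`
#' @export
multipole_expand <- function(positions, charges, center, p) {
  m <- cpp_p2m(as.matrix(positions), as.numeric(charges), as.numeric(center),
               as.integer(p))
  structure(m, center = as.numeric(center), p = as.integer(p),
            class = "multipole_expansion")
}

#' Translate a multipole expansion to a new center (M2M)
#' @param m a `multipole_expansion`
#' @param new_center new expansion center
#' @export
multipole_translate <- function(m, new_center) {
  p <- attr(m, "p")
  t <- attr(m, "center") - as.numeric(new_center)
  out <- cpp_m2m(unclass(m), t, p)
  structure(out, center = as.numeric(new_center), p = p,
            class = "multipole_expansion")
}

#' Convert a multipole into a local expansion about a distant center (M2L)
#'
#' Requires well-separated source and target clusters (non-adjacent boxes);
#' the caller supplies the separation criterion via `min_separation`, checked
#' against the distance between centers.
#'
#' @param m a `multipole_expansion`
#' @param center target expansion center
#' @param min_separation optional minimum center distance; an error is thrown
#'   when the centers are closer (overlapping clusters)
#' @export
multipole_to_local <- function(m, center, min_separation = NULL) {
  p <- attr(m, "p")
  t <- as.numeric(center) - attr(m, "center")
  if (!is.null(min_separation) && sqrt(sum(t^2)) < min_separation)
    stop("source and target clusters are not well separated")
  out <- cpp_m2l(unclass(m), t, p)
  structure(out, center = as.numeric(center), p = p, class = "local_expansion")
}

#' Translate a local expansion to a child center (L2L)
#' @param l a `local_expansion`
#' @param new_center new center (inside the region of validity)
#' @export
local_translate <- function(l, new_center) {
  p <- attr(l, "p")
  s <- as.numeric(new_center) - attr(l, "center")
  out <- cpp_l2l(unclass(l), s, p)
  structure(out, center = as.numeric(new_center), p = p, class = "local_expansion")
}

#' Evaluate a local expansion at particle positions (L2P)
#' @param l a `local_expansion`
#' @param positions N x 3 evaluation points
#' @return list with `potential` (kJ/mol per e) and `field_grad` (raw
#'   potential gradient, 1/nm^2 units before the Coulomb prefactor)
#' @export
local_evaluate <- function(l, positions) {
  ev <- cpp_l2p(unclass(l), as.matrix(positions), attr(l, "center"), attr(l, "p"))
  list(potential = .ke * ev$phi, grad = ev$grad)
}

#' Evaluate a multipole expansion at distant points (potential only)
#' @param m a `multipole_expansion`
#' @param positions evaluation points (outside the source cluster)
#' @export
multipole_evaluate <- function(m, positions) {
  .ke * cpp_m2p(unclass(m), as.matrix(positions), attr(m, "center"), attr(m, "p"))
}

#' Direct Coulomb sum (isolated system oracle)
#'
#' All-pairs Coulomb potential, field and energy without periodicity, in a
#' deterministic summation order. Self-interactions are omitted; coincident
#' distinct particles raise an error naming the offending indices.
#'
#' @param system a [particle_system()]
#' @return list with `energy` (kJ/mol), `potential` (per particle, kJ/mol/e)
#'   and `forces` (N x 3, kJ/mol/nm)
#' @export
direct_sum <- function(system) {
  ds <- cpp_direct_isolated(system$positions, system$charges)
  list(energy = 0.5 * .ke * sum(system$charges * ds$phi),
       potential = .ke * ds$phi,
       forces = -.ke * system$charges * ds$grad)
}

#' Near-field particle-particle Coulomb sum
#'
#' Direct evaluation of the near-field pairs. With
#' `image_policy = "first_shell"` the pairs comprise the central box and all
#' 26 first-layer periodic images (self-images included), i.e. the d = 0 near
#' field; with `"none"` only the central box (isolated all-pairs).
#'
#' @param system a [particle_system()]
#' @param image_policy `"first_shell"` or `"none"`
#' @param precision `"double"` or `"single"` accumulation
#' @return list with `energy`, `potential`, `forces`
#' @export
near_field_p2p <- function(system, image_policy = c("first_shell", "none"),
                           precision = c("double", "single")) {
  image_policy <- match.arg(image_policy)
  precision <- match.arg(precision)
  if (image_policy == "none") return(direct_sum(system))
  ds <- cpp_direct_first_shell(system$positions, system$charges,
                               system$box_edge, precision == "single")
  list(energy = 0.5 * .ke * sum(system$charges * ds$phi),
       potential = .ke * ds$phi,
       forces = -.ke * system$charges * ds$grad)
}

#' FMM evaluation of Coulomb energy, potentials and forces
#'
#' Octree fast multipole evaluation at multipole order `p` and depth `d`.
#' For `periodic = TRUE` the far field includes the lattice contribution of
#' all periodic images beyond the first shell (lattice operator acting on the
#' box multipole) and, under tinfoil boundary conditions, the dipole
#' compensation term that makes energies match Ewald summation. At `d = 0`
#' the box-box part is a direct sum over the central box and its 26 first
#' images, so the only approximation is the order-p lattice far field.
#'
#' `precision = "single"` stores every stage result (multipoles, local
#' expansions, accumulated potentials) in 32-bit precision, emulating a
#' single-precision pipeline.
#'
#' @param system a [particle_system()]
#' @param p multipole order (>= 1)
#' @param d octree depth (>= 0)
#' @param periodic logical; periodic boundary conditions
#' @param precision `"double"` or `"single"`
#' @param boundary `"tinfoil"` (conducting, Ewald-consistent; default) or
#'   `"vacuum"` (no dipole compensation)
#' @param charges optional replacement charge vector (defaults to the
#'   system's charges)
#' @param op lattice operator from [lattice_operator()]; built automatically
#'   when omitted
#' @return object of class `fmm_result`: `energy` (kJ/mol), named `parts`
#'   (near, far, lattice, dipole), `potential` (kJ/mol/e per particle),
#'   `forces` (kJ/mol/nm), and the box multipole `omega`
#' @export
fmm_evaluate <- function(system, p, d, periodic = TRUE,
                         precision = c("double", "single"),
                         boundary = c("tinfoil", "vacuum"),
                         charges = NULL, op = NULL) {
  precision <- match.arg(precision)
  boundary <- match.arg(boundary)
  if (p < 1) stop("multipole order p must be >= 1")
  q <- if (is.null(charges)) system$charges else as.numeric(charges)
  L <- system$box_edge
  single <- precision == "single"
  if (periodic) {
    if (is.null(op)) op <- lattice_operator(p)
    if (op$jtop < 2 * p) op <- lattice_operator(p)
    res <- cpp_fmm(system$positions, q, L, as.integer(p), as.integer(d),
                   TRUE, op$sums, op$jtop, single)
  } else {
    res <- cpp_fmm(system$positions, q, L, as.integer(p), as.integer(d),
                   FALSE, NULL, 0L, single)
  }
  phi_raw <- res$phi_near + res$phi_far + res$phi_lat
  grad <- res$grad_near + res$grad_far + res$grad_lat
  parts <- c(near = 0.5 * .ke * sum(q * res$phi_near),
             far = 0.5 * .ke * sum(q * res$phi_far),
             lattice = 0.5 * .ke * sum(q * res$phi_lat),
             dipole = 0)
  phi_dip <- numeric(length(q))
  if (periodic && boundary == "tinfoil") {
    dc <- dipole_compensation_energy(system, charges = q)
    parts["dipole"] <- dc$energy
    phi_dip <- dc$potential / .ke
    grad <- grad + matrix(dc$grad_raw, nrow(grad), 3, byrow = TRUE)
  }
  if (single) {
    phi_raw <- cpp_float_round(phi_raw + phi_dip)
  } else {
    phi_raw <- phi_raw + phi_dip
  }
  structure(list(energy = 0.5 * .ke * sum(q * phi_raw),
                 parts = parts,
                 potential = .ke * phi_raw,
                 forces = -.ke * q * grad,
                 omega = res$omega,
                 p = p, d = d, periodic = periodic,
                 precision = precision, boundary = boundary),
            class = "fmm_result")
}

#' @export
print.fmm_result <- function(x, ...) {
  cat(sprintf("fmm_result: p = %d, d = %d, %s, %s precision\n",
              x$p, x$d, if (x$periodic) "periodic" else "isolated",
              x$precision))
  cat(sprintf("  energy = %.10g kJ/mol (near %.4g, far %.4g, lattice %.4g, dipole %.4g)\n",
              x$energy, x$parts["near"], x$parts["far"], x$parts["lattice"],
              x$parts["dipole"]))
  invisible(x)
}
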