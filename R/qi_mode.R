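#' Charge-interpolation (QI) lambda forces
#'
#' Derivative of the fully charge-scaled Hamiltonian with respect to lambda:
#' the per-form weight force is the contraction of the baseline per-particle
#' potentials with the form charges, with no intra-site correction. QI and
#' Hamiltonian interpolation coincide for sites with at most one particle
#' (no intra-site pairs) and at the end states in energy.
#'
#' @inheritParams mahi_lambda_forces
#' @return object of class `lambda_force_report`
#' @export
qi_lambda_forces <- function(system, topology, state, p = 8, d = 0,
                             backend = c("fmm", "ewald"),
                             precision = c("double", "single"),
                             boundary = c("tinfoil", "vacuum"),
                             op = NULL) {
  backend <- match.arg(backend)
  precision <- match.arg(precision)
  boundary <- match.arg(boundary)
  weights <- state_weights(state, topology)
  qs <- scaled_charges(system, topology, weights)
  if (backend == "fmm") {
    if (is.null(op)) op <- lattice_operator(p)
    base <- fmm_evaluate(system, p, d, periodic = TRUE, precision = precision,
                         boundary = boundary, charges = qs, op = op)
    base_energy <- base$energy
    phi_base <- base$potential
  } else {
    ew <- ewald_oracle(system, charges = qs, background = abs(sum(qs)) > 1e-9,
                       boundary = boundary)
    base_energy <- ew$energy
    phi_base <- ew$potential
  }
  sites <- vector("list", length(topology$sites))
  flam <- list()
  for (s in seq_along(topology$sites)) {
    st <- topology$sites[[s]]
    nf <- nrow(st$forms)
    f_wt <- vapply(seq_len(nf), function(r)
      -sum(phi_base[st$particles] * st$forms[r, ]), 0)
    J <- weights_jacobian(state$lambdas[[s]], nf)
    f_l <- as.numeric(t(J) %*% f_wt)
    decomp <- matrix(0, nf, 4,
                     dimnames = list(NULL, c("baseline", "boxbox", "lattice", "dipole")))
    decomp[, "baseline"] <- f_wt
    sites[[s]] <- list(F_lambda = f_l, F_weights = f_wt, decomposition = decomp)
    flam[[s]] <- f_l
  }
  structure(list(sites = sites, F_lambda = flam,
                 energy = list(H_qi = base_energy, H_hi = NA_real_,
                               correction = 0),
                 counts = c(pair_ops = 0L, lattice_apps = 0L),
                 params = list(p = p, d = d, backend = backend,
                               precision = precision, boundary = boundary,
                               mode = "qi")),
            class = "lambda_force_report")
}

#' Harmonic force constant of the QI-HI difference
#'
#' For a single site with two forms, the difference between the QI and HI
#' Hamiltonians is the harmonic potential [hi_qi_potential()] whose force
#' constant depends only on the atomic positions and the end-state charge
#' differences: `k = 2 U_site(q0 - q1)` with `U_site` the periodic intra-site
#' self-energy (first-image terms and lattice/dipole parts included when
#' `periodic = TRUE`, consistent with the MAHI corrections; `periodic =
#' FALSE` restricts to central-box pairs). The sign convention follows
#' `Delta V = H_QI - H_HI`, so `k = d^2 (H_QI - H_HI) / d lambda^2`.
#'
#' @param positions site particle coordinates (n x 3)
#' @param forms 2 x n matrix of end-state charges
#' @param L box edge (nm)
#' @param p multipole order for the lattice part
#' @param periodic include periodic-image intra-site terms (default TRUE)
#' @param op optional lattice operator
#' @return force constant k (kJ/mol)
#' @export
hi_qi_force_constant <- function(positions, forms, L, p = 8, periodic = TRUE,
                                 op = NULL) {
  forms <- as.matrix(forms)
  if (nrow(forms) != 2L)
    stop("the harmonic QI-HI difference is defined for two-form sites")
  dq <- forms[1, ] - forms[2, ]
  positions <- as.matrix(positions)
  if (periodic) {
    u <- site_self_energy(positions, dq, L, p, op)$energy
  } else {
    n <- nrow(positions)
    u <- 0
    if (n >= 2)
      for (i in seq_len(n - 1)) for (j in (i + 1):n)
        u <- u + .ke * dq[i] * dq[j] / sqrt(sum((positions[i, ] - positions[j, ])^2))
  }
  2 * u
}

#' QI-minus-HI potential difference
#'
#' `Delta V(lambda) = (k/2) (lambda^2 - lambda)`: a harmonic potential
#' centered at lambda = 0.5 with extremum `-k/8`, vanishing exactly at the
#' end states lambda = 0 and lambda = 1, present in charge interpolation but
#' absent in Hamiltonian interpolation.
#'
#' @param lambda value(s) in `[0, 1]`
#' @param k force constant from [hi_qi_force_constant()] (kJ/mol)
#' @return potential difference (kJ/mol)
#' @export
hi_qi_potential <- function(lambda, k) {
  if (any(lambda < 0 | lambda > 1)) stop("lambda must lie in [0, 1]")
  0.5 * k * (lambda^2 - lambda)
}
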