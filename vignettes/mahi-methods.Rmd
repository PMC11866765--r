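---
title: "Multipole-accelerated Hamiltonian interpolation: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multipole-accelerated Hamiltonian interpolation: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Constant-pH molecular dynamics treats the protonation state of each
titratable group ("site") as a dynamic degree of freedom. In lambda
dynamics, every site carries one or more pseudoparticles `lambda` with a
mass and a velocity; the system Hamiltonian interpolates between the
electrostatic end states ("forms") of the site, and the force on the
pseudoparticle, `F_lambda = -dH/dlambda`, drives protonation and
deprotonation along with the Cartesian dynamics.

Two interpolation schemes are in use:

* **Hamiltonian interpolation (HI)** - the total Hamiltonian is the
  weight-averaged sum of pure-form Hamiltonians. Intra-site interactions are
  computed with *pure* form charges. This is the rigorous formulation, but a
  naive implementation evaluates one full electrostatics pass per form
  combination.
* **Charge interpolation (QI)** - the partial charges themselves are
  interpolated before one electrostatics pass. Intra-site interactions are
  computed with *scaled* charges. One pass suffices for any number of sites,
  but the Hamiltonian differs from HI.

This package implements both, plus the device that makes HI affordable:
recovering the exact HI lambda forces from a *single* charge-scaled
electrostatics pass by small per-site-form corrections
(multipole-accelerated Hamiltonian interpolation, MAHI). Electrostatics are
evaluated with a periodic fast multipole method (FMM) or, as an independent
oracle, Ewald summation.

Units throughout: nm, elementary charges, kJ/mol, ps. The Coulomb prefactor
is 138.935458 kJ mol^-1 nm e^-2.

# From lambda to form weights

A site with `#S` forms carries `ceiling(log2(#S))` lambda variables. The
weights of the forms are binary-tree products: writing the form index in
binary with `lambda[1]` as the most significant bit, the weight is the
product over levels of `lambda[l]` (bit set) or `1 - lambda[l]` (bit
clear). Weights lie in `[0, 1]` and sum to one identically.

For form counts that are not a power of two the tree has surplus leaves. We
fold the weight of every surplus leaf into the *last* real form. This
completion keeps the sum rule exact, is differentiable everywhere, and
reduces to the usual linear interpolation for two forms; it is a design
choice (other normalized completions exist), pinned by tests.

Convention: `lambda = 0` selects form 0 (the "protonated" end state),
`lambda = 1` (two forms) selects form 1.

The chain rule from per-form weight forces to lambda forces uses the
analytic Jacobian `weights_jacobian()`, whose columns sum to zero and which
the tests verify against central finite differences at 1e-6 relative.

# Periodic electrostatics

## FMM

`fmm_evaluate()` implements a classic solid-harmonic FMM on an octree of
depth `d` over the cubic box: P2M at the leaves, M2M up, M2L between
well-separated cells of the standard interaction lists (27-cell adjacency
defines the near field), L2L down, L2P at the particles, and direct P2P for
adjacent leaves. At `d = 0` there is no far field inside the box: the
central box and its 26 first-image cells are summed directly.

Conventions: scaled regular/irregular solid harmonics
(`R_lm = r^l P_lm e^{im phi}/(l+m)!`, `I_lm = (l-m)! P_lm e^{im phi} /
r^{l+1}`) so that all translation operators are coefficient convolutions
without factorial overflow up to order `p = 50`. Translations are the
rotation-free O(p^4) forms; the GPU-grade O(p^3) rotation trick is out of
scope at desk scale. Summation order is deterministic, so depth-zero runs
are reproducibly identical to the direct sum.

## Lattice operator and boundary conditions

Periodic images beyond the first shell enter through a *lattice operator*:
a linear map from the box multipole to a local expansion about the box
center. Its coefficients are lattice sums of irregular solid harmonics over
the cubic lattice with the 27 near cells removed. High degrees (J >= 16)
converge geometrically and are summed shell by shell with per-shell degree
caps; low degrees are obtained from a factor-3 hierarchical renormalization
fixed point (supercells of 27 cells, rescaled and re-expanded), iterated to
1e-15. Degrees 0-2 are conditionally convergent; they are pinned to zero,
which makes the operator exactly cubic-symmetric and linear, with zero
response to a neutral monopole-only box.

With that pinning the bare box-box + lattice energy follows the *vacuum*
summation convention: on dipolar systems it exceeds the tinfoil (conducting
boundary) Ewald energy by exactly the classic surface term
`+2 pi k |D|^2 / (3 L^3)` - a relation the test suite verifies against the
Ewald oracle rather than assumes. The *dipole compensation*
`Xi = -2 pi k |D|^2 / (3 L^3)` (with `D` the box dipole about the box
center, positions taken as given inside `[0, L)`) converts to tinfoil
energies; `boundary = "tinfoil"` is the default everywhere, and
`boundary = "vacuum"` is exposed as a switch. Charged systems are handled
with the monopole lattice response suppressed (FMM) or an explicit uniform
neutralizing background (Ewald); the two conventions coincide for neutral
systems, and cross-backend comparisons in the tests use neutralized
systems.

## Ewald oracle

`ewald_oracle()` is a textbook tinfoil Ewald sum with automatic parameter
selection from a target tolerance (default: splitting parameter
`beta = 6/L`, one real-space image shell, reciprocal cutoff from the
Gaussian tail). It recovers the Madelung constant of the rock-salt motif to
ten digits, is independent of the splitting parameter to 1e-10 over a
factor-of-two range, and agrees with an independent brute-force cube-shell
direct sum on a dipolar fixture. It is the reference for every periodic-FMM
claim and never stands in for the implementation under test.

# MAHI

## The correction algebra

With frozen coordinates the periodic electrostatic energy is a quadratic
form `H(q) = q' G q / 2`. Because HI and QI differ only in intra-site
terms, the HI Hamiltonian can be written as the QI (charge-scaled) energy
plus per-site replacements of the site-block quadratic form:

```
H_HI = H_QI(q_scaled)
     + sum_sites [ sum_forms w_rho U_site(q_rho) - U_site(q_scaled_site) ]
```

where `U_site(v) = v' G_site v / 2` is the *periodic self-energy of the
site's charge set alone*: direct intra-site pairs over the central box and
the 26 first images (self-images included), the lattice part beyond the
first shell via the same order-p lattice operator as the baseline, and the
site's dipole-compensation term. Differentiating with respect to the
weights gives the per-form weight force

```
F_w(rho) = -[ sum_{i in site} (phi_i - phi_self_i) q_i(rho) + U_site(q_rho) ]
```

with `phi_i` the baseline per-particle potentials of the charge-scaled pass
and `phi_self_i` the potentials of the site's own scaled charges. The
lambda forces follow through the weight Jacobian. The reported
decomposition (baseline, box-box, lattice, dipole corrections) sums to the
total by construction, and the factor-of-two bookkeeping of the correction
charges is pinned by the requirement that depth-zero MAHI equals the
end-state reference combination to 1e-12 relative - which the acceptance
tests verify on 1010-particle systems at p = 2, 8, 16.

Corrections always use the depth-zero direct scheme for the first image
shell regardless of the baseline depth, and one lattice-operator
application per site-form (plus one per site for the scaled charges). The
operation count is linear in the total number of site-forms and independent
of the environment size; `mahi_lambda_forces()` returns the counts so the
tests can assert exactly that.

## Reference forces

`reference_forces()` evaluates every pure-form combination with a full
separate electrostatics run and contracts the energies with the derivative
of the combination weights - two runs for a two-form site, with the
complementary weights as coefficients in the multiform/multisite case, and
a guard at 2^16 evaluations. It matches central finite differences of
`H(lambda)` to 1e-6 relative and is the oracle for all accuracy scans.

## Where deviations come from at d >= 1

At depth zero MAHI and the reference agree to machine precision because
both use the identical operators. At `d >= 1` the baseline (and the
reference) treat some intra-site interactions - notably first-image and
self-image terms, and for spread-out sites also central-box pairs - through
order-p multipole translations, while the corrections replace them with
exact direct sums. The residual deviation is the order-p translation error
of precisely those terms, weighted by `w (1 - w)` and the end-state charge
differences. It decreases monotonically with p (to ~1e-8 relative by
p = 8 and to the double-precision floor by p ~ 28 under the default study
conditions) but its absolute scale at very low p depends on the geometry
of the generated systems: with the defaults here (box edge 5 nm, cluster
radius L/20) the typical-case deviations at p <= 3 are of order 1e-5 to
1e-4, dominated by the image terms of the clustered site. The accuracy
scan reports per-lambda deviations and per-(p, d) maxima so this structure
is visible rather than averaged away.

## Single precision

`precision = "single"` runs the entire operator pipeline - harmonic
recursions, translations, P2P accumulation - in genuine 32-bit arithmetic
(the lattice-sum coefficients involve factorial-scale magnitudes and stay
in double; their contribution is rounded to 32 bits). Storage-only rounding
of stage results proved far too benign to reproduce the characteristic
error floor of single-precision pipelines; float arithmetic in the
recursions is what limits the attainable accuracy, to about 1e-6..1e-7
relative on the lambda forces here. The float range limits the mode to
p <= 20.

# QI and the harmonic difference

For a two-form site the QI-minus-HI energy difference is exactly

```
Delta V(lambda) = (k/2) (lambda^2 - lambda),   k = 2 U_site(q_form0 - q_form1)
```

a harmonic potential centered at lambda = 0.5 with extremum `-k/8`,
vanishing only at the end states. `hi_qi_force_constant()` computes `k`
from the end-state charge differences; by default it includes the periodic
intra-site terms (first images, lattice, dipole), which is the variant that
satisfies the two-path equivalence `H_QI - H_HI = Delta V` to 1e-10 in the
tests; `periodic = FALSE` gives the central-box-pairs-only variant. The
sign convention is `Delta V = H_QI - H_HI`, so a negative `k` means QI
carries an additional barrier at the midpoint. Note that with periodic
terms included a single-particle site still has a nonzero `k` from its
self-image terms; only the non-periodic variant vanishes there.

# Lambda dynamics

`propagate()` integrates the lambda pseudoparticles with the BAOAB Langevin
splitting, reflective walls at 0 and 1, and a symmetric quartic bias
`V(lambda) = 16 h lambda^2 (1-lambda)^2` whose barrier height `h` defaults
to 5 kJ/mol. Particle coordinates are frozen by default, which isolates the
HI/QI electrostatic difference; for a single site this makes the
Hamiltonian an exact (linear or quadratic) polynomial in the form weights,
assembled once from full end-state evaluations at p = 24 and integrated in
a fast kernel. Multi-site systems use a per-step force evaluation path, and
`particles = "langevin"` optionally moves the real particles under
Coulomb-only forces with the same BAOAB scheme (one full electrostatics
evaluation per step; meant for small systems and step counts).

Parameter defaults and why:

* timestep 1 fs - at least three orders of magnitude below the lambda
  oscillation period for the default mass.
* lambda mass 5 u nm^2 (numerically kJ mol^-1 ps^2) - gives ~ps
  oscillation periods for typical force-constant scales; the value is a
  choice, user-tunable, since no standard value exists for the frozen-bath
  toy model.
* friction 5 ps^-1, temperature 300 K - conventional Langevin settings.
* transition counting uses hysteresis thresholds (0.2, 0.8); hysteresis
  prevents double-counting recrossings, and the threshold pair is a
  documented default (no standard definition exists).

With friction 0 the integrator is velocity Verlet and conserves the
extended energy (drift below 1e-5 relative over 1e4 half-femtosecond
steps in the tests); thermostatted runs equipartition the lambda kinetic
energy to within 5% and sample `exp(-(H + V)/kT)` (Kolmogorov-Smirnov on
thinned samples at alpha = 0.01).

`tst_barrier_from_rates()` converts a rate ratio into an apparent barrier
difference `ln(r_a/r_b)` in units of kT, assuming equal transition-state
prefactors - the usual TST reading of "HI transitions N times more often
than QI".

# Synthetic systems

`generate_random_system()` builds the accuracy-benchmark systems: 1000
environment particles and one 10-particle site, all charges uniform in
(-1, 1), lambda fixed at 0.345 (two forms) or (0.345, 0.721) (four forms).
The box edge defaults to 5 nm (the benchmark quantities are relative
deviations and scale-free in L; the value is documented, not prescribed).
"Typical" placement clusters the site in a ball of radius L/20 - the size
of an amino-acid-scale titratable group in such a box - around a random
center; "worst case" spreads the site uniformly over the box. Systems are
bit-reproducible under a fixed seed. A `neutralize` flag recenters the
environment charges and every form row to zero sum; the accuracy harness
can run both since the paper-style draws are not neutral.

`make_fixture()` provides closed-form fixtures: the centered rock-salt
motif (Madelung constant), a dipole pair (surface term), a two-particle
two-form site with mirror-image end-state charges in a mirror-symmetric
frozen bath, and a single-particle site. The symmetric-site fixture is the
"calibrated" toy: by construction `H(lambda) = H(1 - lambda)` exactly, so
the HI landscape between the end states is flat without any calibration
potential, and the mean lambda must be 0.5 in both modes. Its charge
asymmetry (0.085 e at 0.4 nm separation) was chosen so the QI harmonic
barrier `|k|/8` is about 1 kT at 300 K - the magnitude reported for
carboxyl-type residues - making the HI-vs-QI sampling contrast visible at
toy scale. Absolute transition rates of the toy are *not* comparable to
solvated-residue rates (no solvent friction, frozen coordinates); only the
HI > QI ordering and the TST translation are asserted.

# What the tests do and do not show

The generated systems exercise the electrostatics and the interpolation
algebra exactly as specified, but they are point charges without bonded
terms, exclusions (an optional per-site exclusion-pair list exists but is
not populated by the generators), polarizability, or solvent structure.
Passing tests therefore demonstrate the correctness of the method - force
exactness at depth zero, operator convergence, boundary-condition
consistency, sampling correctness of the integrator - not the biological
fidelity of any constant-pH protocol. pH coupling, calibration potentials
(`V_MM`), pKa values and performance claims are out of scope.

Problem sizes used by the test suite were chosen to keep the full suite in
the minutes range on one CPU: 1010-particle benchmark systems for the
acceptance checks, 40-300-particle systems for module tests, multipole
orders up to 50 on the 8-charge lattice fixture, and 4e6-step dynamics
replicas (the mean-lambda criterion aggregates 10 replicas per mode).

# Known limitations

* Cubic boxes only; positions must lie in `[0, L)`.
* Conditionally convergent lattice degrees are fixed by convention (see
  above); for charged systems FMM and Ewald backends use different but
  internally consistent conventions, so lambda forces for sites whose
  forms differ in net charge are convention-dependent (as they are for any
  method without explicit co-ion bookkeeping).
* Single precision is limited to p <= 20 and its error floor (~1e-6
  relative on lambda forces) reflects this CPU float pipeline; hardware
  pipelines with different accumulation orders will show different floors.
* The multi-site dynamics path re-evaluates forces per step and is meant
  for small step counts; production-style long trajectories use the
  single-site fast path.
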