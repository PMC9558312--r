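---
title: "Constant-pH lambda-dynamics at desk scale: models, parameters and design"
author: "lambdaCPH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constant-pH lambda-dynamics at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lambdaCPH)
```

## The model

In constant-pH molecular dynamics based on lambda-dynamics, each titratable
site carries an alchemical coordinate $\lambda$ with a fictitious mass
$m_\lambda$ that evolves by Newtonian dynamics alongside the atoms.
$\lambda = 0$ is the protonated form, $\lambda = 1$ the deprotonated form,
and the partial charges of the site's atoms are interpolated linearly:
$q_i(\lambda) = (1-\lambda)\,q_i^A + \lambda\, q_i^B$.  Because the total
Coulomb energy is then a quadratic form in the charges, a single
electrostatic evaluation yields the per-atom potentials
$\Phi(R_i) = \partial E/\partial q_i$, from which both the atomic forces and
the forces on every lambda-particle follow:
$\partial V/\partial \lambda_k = \sum_{i \in k} \Delta q_i\, \Phi(R_i)$.
This is the engine's central cost claim, restated in code by an
evaluation counter: charge interpolation needs one evaluation per step
regardless of the number of sites, while the older scheme that interpolates
the end-state *Hamiltonians* needs two full evaluations per site.  That
older scheme is implemented here as `potentialInterpOracle()`, purely as a
verification oracle: outside a lambda-group the two schemes are
algebraically identical (products of affine charges expand bilinearly), and
within a group they differ by a computable quadratic-vs-linear term
(`schemeDiscrepancy()`), which the test suite checks against hand-derived
expressions.

Three analytic terms act on each lambda-coordinate in addition to the
interpolated Coulomb landscape:

* **V^MM**, a polynomial correction fitted so that the force-field
  deprotonation free energy of the reference site vanishes, making the
  reference site titrate exactly at its reference pKa;
* **V^bias**, a double well $16\,b\,\lambda^2(1-\lambda)^2$ with minima at
  the physical states and barrier $b$ at $\lambda = 1/2$, which suppresses
  nonphysical intermediate states while allowing transitions;
* **V^pH**, a smooth step carrying the proton chemical potential,
  $V^{pH}(\lambda) = \ln(10)\,k_B T\,(\mathrm{p}K_a^{ref} - \mathrm{pH})\,
  \sigma(\lambda)$.

Chemically coupled sites (the imidazole ring with its two tautomers) use
the multisite representation: one coordinate per physical protonation
state, constrained to $\sum_k \lambda_k = 1$, so a three-state group moves
on a two-dimensional simplex plane.  Buffer particles keep the box neutral:
all buffers share one collective coordinate whose charge
$q \in [-0.5, +0.5]\,e$ absorbs every titration charge through a global
linear charge constraint.

## Parameters and defaults

| parameter | default | units | role |
|---|---|---|---|
| $m_\lambda$ | 5 | amu | fictitious lambda mass |
| $T$, $\tau_\lambda$ | 300, 2.0 | K, ps | lambda v-rescale thermostat |
| bias barrier $b$ | 5.0 | kJ/mol | double-well height (7.5 for coarse-grained-like settings) |
| $k_1$, $x_0$ | 50, 0.1 | — | pH-step steepness and kink positions |
| thresholds | 0.2 / 0.8 | — | protonated / deprotonated frame classification |
| TI grid | $-0.1 \ldots 1.1$, step 0.05 | — | calibration scan (beyond the physical range on both sides) |
| V^MM order | 5 (2-state), 8 (3-state) | — | correction polynomial degree |
| $k_B$ | 0.0083144621 | kJ/(mol K) | unit system kJ/mol, nm, ps, amu, e |
| $f$ | 138.935458 | kJ mol$^{-1}$ nm e$^{-2}$ | Coulomb conversion factor |

Lambda values are never clipped: the calibration grid itself extends to
$-0.1$ and $1.1$, so every potential term is defined and differentiable on
the extended range; confinement comes from the quartic growth of the bias.

## The shape of the pH step

Only the end-state difference of V^pH is physically prescribed:
$V^{pH}(1) - V^{pH}(0) = \ln(10) k_B T (\mathrm{p}K_a^{ref} - \mathrm{pH})$,
which the implementation satisfies to machine precision by explicit
normalization.  The interior shape is a design choice, and it matters for
a subtle reason: frames are *classified* at $\lambda < 0.2$ and
$\lambda > 0.8$, so any part of the pH free energy that develops inside
those basins tilts the basin-restricted populations away from the ideal
Henderson--Hasselbalch ratio.  A step built from two logistics centered at
$x_0 = 0.1$ and $0.9$ develops half of its jump below $\lambda = 0.2$; with
it, the basin ratio at one pH unit from the pKa comes out near 6.5 instead
of 10.  We therefore use a single logistic ramp in the rescaled coordinate
$(\lambda - x_0)/(1 - 2x_0)$ with steepness $k_1$: its rise is confined
between the kinks at $x_0$ and $1 - x_0$, it is flat to better than
$10^{-3}$ of the jump within both classification basins, and the
basin-restricted Boltzmann ratio then equals $10^{\mathrm{pH} - pK_a}$
essentially exactly (the quadrature oracle reproduces ratios and fitted
pKas to the $10^{-5}$ level).  A convenient corollary: because the step is
flat inside the basins, both basins have identical curvature profiles, so
leapfrog discretization ("shadow Hamiltonian") corrections cancel out of
the basin-population ratio.

## Multisite pH terms and microscopic pKas

Each coordinate of a multisite group evolves on its own one-dimensional
bias and pH potential.  The coordinate of the fully protonated state
carries no pH term; the coordinate of each deprotonated tautomer $k$
carries the step scaled by $\ln(10) k_B T (\mathrm{p}K_{a,k}^{micro} -
\mathrm{pH})$.  With this assignment the end-state Boltzmann weights give
exactly $P_k/P_p = 10^{\mathrm{pH} - pK_{a,k}}$, each microscopic fraction
$N_k/(N_p + N_k)$ follows its own Henderson--Hasselbalch curve with the
microscopic pKa, the macroscopic fraction follows the combined curve with
$10^{-pK_a^{macro}} = \sum_k 10^{-pK_{a,k}}$, and the two-state special
case reduces to the uncoupled single-site form.  The microscopic
estimator conditions tautomer $k$'s fraction on frames in either the
protonated basin or basin $k$ (excluding the other tautomer); this is the
reading under which the estimator reproduces exact Henderson--Hasselbalch
behavior, which the quadrature oracle confirms.

## Constraints

All constraints are linear in the stacked coordinate vector: one simplex
row per group and, with buffers, one global charge row.  They are solved
in closed form every step by mass-weighted Lagrange multipliers (the
linear generalization of the analytic charge-constraint solution), after
which velocity components along the constraint gradients are removed —
the standard holonomic treatment applied to both positions and
velocities.  The collective buffer coordinate is an ordinary dynamical
variable with mass $m_\lambda$ that participates only in the charge
constraint; because the constraint is exact, the buffer coordinate is
slaved to the titration coordinates, and the thermodynamic-integration
gradient along a constrained path includes the corresponding chain term.

## Sampling protocol

Titration campaigns integrate the lambda system with a leapfrog scheme
and a stochastic velocity-rescaling (canonical) thermostat.  In the
lockstep campaign sampler the global thermostat couples every 10 steps —
the stochastic kinetic-energy update is exact for any elapsed interval,
and sparse coupling is the usual practice in production MD codes; the
general coupled-dynamics engine couples every step.  The default
campaign protocol is 13 pH values $\times$ 5 replicas $\times$ 20 ns
(2 x 10^6 steps of 0.01 ps), frames written every 1 ps, the first 10%
discarded as burn-in, and every run started from the simplex midpoint.
The 0.01 ps lambda-only step is safe here for the basin-ratio reasons
above (the acceptance checks compare sampled populations against the
quadrature oracle); fully coupled atom+lambda dynamics default to the
conservative 0.002 ps step, for which the suite verifies NVE energy
conservation and the analytic frequency of a constrained harmonic
oscillator.  For the single-site parameter-recovery checks we double the
campaign length to 40 ns per replica: pilot runs put the seed-to-seed
scatter of the fitted pKa near 0.04 at 20 ns, and 40 ns brings it
comfortably inside the $\pm 0.05$ recovery band; the three-state
campaigns keep 20 ns against their wider $\pm 0.08$ band.  Campaign
statistics are replica-based: per-pH means and standard errors over
replicas, an unweighted nonlinear least-squares Henderson--Hasselbalch
fit to the mean curve (plateau points have near-zero replica scatter and
would otherwise dominate an inverse-variance fit), and a 95% confidence
interval from the linearized fit covariance.

## Calibration

`tiScan()` holds the group's coordinates fixed at each grid point,
resolves the buffer coordinate from the charge constraint, and records
the mean force-field gradient along the free simplex coordinates; only
the Coulomb term is integrated during calibration, exactly because the
bias and pH terms are analytic and known.  For frozen-atom fixtures the
scan is deterministic (one evaluation per point, zero standard error);
for mobile fixtures the atoms move under the thermostat with harmonic
position restraints, and standard errors come from block averages (up to
10 contiguous blocks), which stay honest when successive samples are
correlated.  `fitVmm()` performs least squares of $-dV^{MM}/dx$ on the
mean gradients with a monomial basis and pivoted-QR rank handling:
linearly dependent directions are dropped rather than propagated.  The
self-consistency contract — calibrate on a deliberately sloped landscape,
install the fit, re-scan with the correction and pH terms active at
pH = pKa, observe a flat landscape — is checked both deterministically
(frozen curved fixture, flat to machine precision) and statistically
(thermal fixture, residuals compatible with zero within a simultaneous
multiple-comparison band).  The bias double well is excluded from the
flatness check: it is non-flat at interior lambda by construction and is
never part of the free-energy landscape the correction must cancel.

## What the fixtures emulate — and what they do not

The synthetic fixtures stand in for solvated reference peptides: an
isolated ideal site (analytically flat landscape), a site perturbed by
fixed environment charges (closed-form pKa shift
$f\,\Delta q\, q/(d\,\ln 10\, k_B T)$), a three-state imidazole-like
group, and a buffer bath on a 2.5 nm shell.  Under open-boundary vacuum
electrostatics the buffers couple strongly to the site (every
deprotonation charges all buffers, shifting the apparent pKa by several
units) — that fixture doubles as the deliberately sloped calibration
target; under the reaction-field setting (1.1 nm cutoff,
$\epsilon_r = 2.5$, $\epsilon_{RF} = \infty$) the buffers sit beyond the
cutoff and interact only through the charge constraint, emulating
well-screened solvent buffers.  None of the fixtures contain water,
Lennard-Jones structure, bonded terms, or conformational degrees of
freedom, so passing tests demonstrate the correctness of the lambda
machinery — interpolation, constraints, thermostatting, calibration,
estimators — not force-field accuracy on real proteins.  Mesh Ewald
electrostatics, exclusion rules, barostats and lambda-dependent
Lennard-Jones terms are out of scope by design.

## Numerical notes

* Coincident atoms (pair distance below $10^{-6}$ nm) raise a singularity
  error; a cutoff larger than half the periodic box is a configuration
  error.
* Lambda-gradients must be read off the evaluation that used the current
  interpolated charges; a stale potential raises a contract error.
* The quadrature oracle integrates each classification basin on its own
  threshold-aligned grid (the affine re-parameterizations of the simplex
  have unit Jacobian), so the integrals converge at second order; a
  refinement step verifies every reported fraction to $10^{-6}$.
* The constraint solver refuses singular systems (e.g. zero buffer charge
  capacity with titrating sites) via a reciprocal-condition check.
* v-rescale with infinite coupling time returns velocities unchanged and
  consumes no random numbers; all stochastic components draw from R's RNG
  so every run is reproducible from its seed.

## Known limitations

Desk-scale direct-sum electrostatics limit systems to tens of atoms; the
sequential mobile-atom engine is an R loop intended for fixtures, not for
production sampling.  The lockstep vectorized sampler requires frozen
atoms.  Microscopic-pKa estimators assume the simplex constraint holds
exactly (two coordinates above the upper threshold is treated as a
violated invariant, not data).  The Henderson--Hasselbalch confidence
interval is a linearized single-parameter interval and underestimates
seed-to-seed scatter when transitions are rare; the campaign defaults are
sized so that this scatter, not the fit error, dominates and is small.
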