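## Analytic lambda-dependent potential terms: the smooth-step pH potential,
## the double-well biasing potential, and the polynomial correction V^MM.

## Normalized smooth step: 0 at lambda = 0 and 1 at lambda = 1 exactly (by
## construction), with the rise confined between the kinks at x0 and 1 - x0:
## a logistic ramp in the rescaled coordinate (lambda - x0) / (1 - 2 x0), so
## the potential is flat within the classification basins and the whole pH
## free-energy jump develops across the nonphysical interior.
.smoothStep <- function(lambda, k1, x0) {
  kEff <- k1 / (1 - 2 * x0)
  raw <- function(l) stats::plogis(kEff * (l - 0.5))
  s0 <- raw(0)
  s1 <- raw(1)
  p <- raw(lambda)
  list(value = (p - s0) / (s1 - s0),
       deriv = kEff * p * (1 - p) / (s1 - s0))
}

#' pH-dependent potential of one lambda-coordinate
#'
#' A smooth step-function potential `V(lambda) = dG * sigma(lambda)` with
#' `dG = ln(10) kB T (pKaRef - pH)` and `sigma` a normalized logistic step
#' (steepness `k1`) whose rise is confined between the kinks at `x0` and
#' `1 - x0`.  The convention `V(0) = 0` and the exact end-state contract
#' `V(1) - V(0) = ln(10) kB T (pKaRef - pH)` hold by construction; because
#' the step is flat within the end-state basins, the whole pH free-energy
#' difference develops across the nonphysical interior, which both preserves
#' the Boltzmann weights of the classified basins and discourages sampling
#' of intermediate lambda.
#'
#' @param lambda coordinate value(s); any real value is allowed.
#' @param pKaRef reference pKa of the state the coordinate switches on.
#' @param pH solvent pH.
#' @param temperature temperature, K (must be positive).
#' @param settings a [LambdaPotentialSettings-class] supplying `k1` and `x0`.
#' @return list with components `energy` (kJ/mol) and `gradient`
#'   (kJ/mol per unit lambda), each the length of `lambda`.
#' @examples
#' ## one pH unit below the reference pKa at 300 K
#' phPotential(1, pKaRef = 5, pH = 4)$energy   # ln(10) kB T = 5.7436
#' @export
phPotential <- function(lambda, pKaRef, pH, temperature = 300,
                        settings = LambdaPotentialSettings()) {
  if (temperature <= 0) stop("temperature must be positive")
  dG <- log(10) * .kB * temperature * (pKaRef - pH)
  s <- .smoothStep(lambda, settings@k1, settings@x0)
  list(energy = dG * s$value, gradient = dG * s$deriv)
}

#' Double-well biasing potential
#'
#' `V(lambda) = 16 b lambda^2 (1 - lambda)^2`: minima of value 0 at
#' lambda = 0 and 1, a maximum equal to the barrier height `b` at
#' lambda = 0.5, symmetric about 0.5, and confining (quartic growth) outside
#' the physical range.  It penalizes nonphysical intermediate states while
#' permitting transitions between the end states.
#'
#' @param lambda coordinate value(s).
#' @param settings a [LambdaPotentialSettings-class] supplying the barrier
#'   height (kJ/mol), or a single number giving the barrier directly.
#' @return list with components `energy` and `gradient`.
#' @examples
#' biasPotential(0.5)$energy  # the barrier height, 5 kJ/mol by default
#' @export
biasPotential <- function(lambda, settings = LambdaPotentialSettings()) {
  b <- if (is.numeric(settings)) settings else settings@barrier
  if (b < 0) stop("barrier must be >= 0")
  list(energy = 16 * b * lambda^2 * (1 - lambda)^2,
       gradient = 32 * b * lambda * (1 - lambda) * (1 - 2 * lambda))
}

#' Evaluate a V^MM correction polynomial
#'
#' @param lambdas free-coordinate value(s): a vector of length `arity`, or a
#'   matrix with `arity` columns for several points at once.  For univariate
#'   polynomials a plain vector of points is accepted.
#' @param poly a [VmmPolynomial-class].
#' @return list with `energy` (one value per point, kJ/mol) and `gradient`
#'   (matrix `[n_points x arity]`, dropped to a vector for a single point).
#' @examples
#' p <- VmmPolynomial(c(2, -1))   # V = 2 x - x^2
#' evalVmm(0.25, p)
#' @export
evalVmm <- function(lambdas, poly) {
  stopifnot(is(poly, "VmmPolynomial"))
  ar <- poly@arity
  if (is.null(dim(lambdas))) {
    if (ar == 1L) X <- matrix(lambdas, ncol = 1L)
    else if (length(lambdas) == ar) X <- matrix(lambdas, nrow = 1L)
    else stop("lambdas length does not match polynomial arity ", ar)
  } else {
    X <- as.matrix(lambdas)
    if (ncol(X) != ar)
      stop("lambdas columns do not match polynomial arity ", ar)
  }
  n <- nrow(X)
  energy <- numeric(n)
  grad <- matrix(0, n, ar)
  E <- poly@exponents
  for (t in seq_along(poly@coefficients)) {
    ct <- poly@coefficients[t]
    mono <- rep(ct, n)
    for (j in seq_len(ar)) mono <- mono * X[, j]^E[t, j]
    energy <- energy + mono
    for (j in seq_len(ar)) {
      if (E[t, j] == 0L) next
      dm <- rep(ct * E[t, j], n)
      for (jj in seq_len(ar)) {
        p <- E[t, jj] - (jj == j)
        dm <- dm * X[, jj]^p
      }
      grad[, j] <- grad[, j] + dm
    }
  }
  if (n == 1L || ar == 1L) grad <- drop(grad)
  list(energy = energy, gradient = grad)
}

## V^MM gradient mapped onto the full per-state coordinate vector of a group:
## the polynomial lives on the free coordinates (all states except the
## protonated one, in state order); the protonated coordinate is eliminated
## by the simplex constraint and receives zero direct gradient.
.vmmStateGradient <- function(group, vmm) {
  ns <- length(group@lambda)
  g <- numeric(ns)
  if (is.null(vmm)) return(g)
  free <- setdiff(seq_len(ns), group@protonatedState)
  if (vmm@arity != length(free))
    stop("V^MM arity ", vmm@arity, " does not match the ", length(free),
         " free coordinates of group '", group@name, "'")
  ev <- evalVmm(group@lambda[free], vmm)
  g[free] <- ev$gradient
  g
}

.vmmEnergyOfGroup <- function(group, vmm) {
  if (is.null(vmm)) return(0)
  free <- setdiff(seq_along(group@lambda), group@protonatedState)
  evalVmm(group@lambda[free], vmm)$energy
}

#' Total force on the lambda-coordinates of one group
#'
#' Assembles `F_k = -(dV^Coul/dlambda_k + dV^MM/dlambda_k +
#' dV^bias/dlambda_k + dV^pH/dlambda_k)` for every coordinate of the group.
#' The bias acts on each coordinate; the pH potential acts on each
#' deprotonated-state coordinate with that state's microscopic reference pKa
#' (the fully protonated reference state carries no pH term); V^MM acts on
#' the free simplex coordinates.  The four terms are returned individually
#' for diagnostics.
#'
#' @param group a [LambdaGroup-class] (its current `lambda` is used).
#' @param coulombGradients numeric per-state electrostatic gradients
#'   `dV^Coul/dlambda_k`, e.g. one group's entry of [lambdaGradients()].
#' @param pH solvent pH.
#' @param temperature temperature, K.
#' @param settings a [LambdaPotentialSettings-class].
#' @param vmm a [VmmPolynomial-class] correction for this group, or `NULL`
#'   for a flat correction.
#' @return list with `force` (per-coordinate, kJ/mol) and `terms`, a list of
#'   the four per-coordinate gradient contributions.
#' @export
totalLambdaForce <- function(group, coulombGradients, pH, temperature = 300,
                             settings = LambdaPotentialSettings(),
                             vmm = NULL) {
  ns <- length(group@lambda)
  if (length(coulombGradients) != ns)
    stop("need one Coulomb gradient per state coordinate")
  gBias <- biasPotential(group@lambda, settings)$gradient
  gPh <- numeric(ns)
  for (k in seq_len(ns)) {
    if (k == group@protonatedState) next
    gPh[k] <- phPotential(group@lambda[k], group@pKaRefs[k], pH,
                          temperature, settings)$gradient
  }
  gVmm <- .vmmStateGradient(group, vmm)
  list(force = -(coulombGradients + gVmm + gBias + gPh),
       terms = list(coulomb = coulombGradients, vmm = gVmm, bias = gBias,
                    pH = gPh))
}
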