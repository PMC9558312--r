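## Pairwise electrostatics at desk scale: direct O(N^2) sums, optional
## minimum-image periodicity and reaction-field kernel.  Mesh Ewald is a
## documented non-goal.

## Pair geometry: displacement arrays (i minus j) and distances, with the
## minimum-image convention in a periodic cubic box.
.pairGeometryP <- function(P, box = NULL) {
  n <- nrow(P)
  dx <- lapply(1:3, function(d) outer(P[, d], P[, d], "-"))
  if (!is.null(box)) {
    for (d in 1:3) dx[[d]] <- dx[[d]] - box[d] * round(dx[[d]] / box[d])
  }
  r <- sqrt(dx[[1]]^2 + dx[[2]]^2 + dx[[3]]^2)
  if (n > 1L) {
    off <- r[upper.tri(r)]
    if (any(off < 1e-6))
      stop("coincident atoms (pair distance < 1e-6 nm): Coulomb singularity")
  }
  diag(r) <- Inf
  list(dx = dx, r = r, n = n)
}

.pairGeometry <- function(system) {
  .pairGeometryP(as.matrix(system@atoms[, c("x", "y", "z")]), system@box)
}

## Kernel value k(r) and derivative k'(r) such that
## E = (f / epsR) * sum_{i<j} q_i q_j k(r_ij).
## plain: k = 1/r.  reaction-field (eps_RF = Inf): k = 1/r + r^2/(2 rc^3)
## - 3/(2 rc), zero and continuous at the cutoff.
.kernelMatricesP <- function(scheme, cutoff, epsilonR, geom) {
  r <- geom$r
  pref <- .fCoulomb / epsilonR
  within <- r <= cutoff
  if (scheme == "plain") {
    K <- pref * within / r
    dK <- -pref * within / r^2
  } else {
    rc <- cutoff
    krf <- 1 / (2 * rc^3)
    crf <- 3 / (2 * rc)
    K <- pref * within * (1 / r + krf * r^2 - crf)
    dK <- pref * within * (-1 / r^2 + 2 * krf * r)
  }
  diag(K) <- 0
  diag(dK) <- 0
  list(K = K, dK = dK)
}

.kernelMatrices <- function(system, geom) {
  .kernelMatricesP(system@scheme, system@cutoff, system@epsilonR, geom)
}

#' Coulomb energy, forces and per-atom electrostatic potentials
#'
#' Direct pairwise evaluation under the charge-interpolation scheme: one
#' electrostatic computation yields the energy, the atomic forces and the
#' per-atom potential `Phi(R_i, lambda) = dE/dq_i` from which all
#' lambda-gradients follow (see [lambdaGradients()]), independent of the
#' number of titratable sites.
#'
#' @param system a [TitratableSystem-class].
#' @param charges per-atom charges, e; defaults to
#'   [interpolatedCharges()] of the system.
#' @return an [ElectrostaticsResult-class] with `nEvaluations = 1`.
#' @examples
#' at <- data.frame(x = c(0, 1), y = 0, z = 0, mass = 12, charge = 1)
#' coulombEnergy(TitratableSystem(at))@energy   # 138.935458 kJ/mol
#' @export
coulombEnergy <- function(system, charges = interpolatedCharges(system)) {
  geom <- .pairGeometry(system)
  if (length(charges) != geom$n)
    stop("need one charge per atom")
  km <- .kernelMatrices(system, geom)
  phi <- drop(km$K %*% charges)
  energy <- 0.5 * sum(charges * phi)
  ## F_i = -sum_j q_i q_j (f/epsR) k'(r_ij) (r_i - r_j)/r_ij
  W <- -(charges %o% charges) * km$dK / geom$r
  forces <- vapply(1:3, function(d) rowSums(W * geom$dx[[d]]), numeric(geom$n))
  new("ElectrostaticsResult", energy = energy,
      forces = matrix(forces, ncol = 3), phi = phi, charges = charges,
      nEvaluations = 1L)
}

#' Lambda-gradients under charge interpolation
#'
#' `dV^Coul/dlambda_{g,k} = sum_{i in g} q_i^(k) Phi(R_i, lambda)`: the raw
#' gradient of the Coulomb energy with respect to each state coordinate of
#' each group, plus the gradient with respect to the collective buffer
#' coordinate, all read off a single electrostatic evaluation.  For a
#' two-state group the gradient along the deprotonation pathway on the
#' constraint line is the difference
#' `g[deprotonated] - g[protonated] = sum_i (q_i^B - q_i^A) Phi(R_i)`.
#'
#' The result must have been computed with the system's current interpolated
#' charges; a stale potential (charges changed since the evaluation) is a
#' contract violation and raises an error.
#'
#' @param system a [TitratableSystem-class].
#' @param result an [ElectrostaticsResult-class] from [coulombEnergy()] at
#'   the current charges.
#' @return list with `groups` (per group, named per-state gradient vector,
#'   kJ/mol) and `buffer` (scalar gradient with respect to the collective
#'   buffer coordinate, or `NULL`).
#' @export
lambdaGradients <- function(system, result) {
  cur <- interpolatedCharges(system)
  if (length(cur) != length(result@charges) ||
      max(abs(cur - result@charges)) > 1e-12)
    stop("stale electrostatic potential: charges changed since evaluation")
  phi <- result@phi
  gg <- lapply(system@groups, function(g) {
    v <- drop(crossprod(g@stateCharges, phi[g@atomIds]))
    names(v) <- g@stateNames
    v
  })
  names(gg) <- vapply(system@groups, function(g) g@name, "")
  gb <- NULL
  if (!is.null(system@buffers)) {
    b <- system@buffers
    gb <- (b@qMax - b@qMin) * sum(phi[b@atomIds])
  }
  list(groups = gg, buffer = gb)
}

## ---- potential-interpolation oracle --------------------------------------

## Atom classification for the four-term decomposition: group membership per
## atom (0 = environment; buffer atoms count as environment at their current
## charge).
.atomClasses <- function(system) {
  n <- nrow(system@atoms)
  cls <- integer(n)
  for (gi in seq_along(system@groups)) cls[system@groups[[gi]]@atomIds] <- gi
  cls
}

## Energy of the potential-interpolation scheme for two-state groups at
## deprotonation coordinates x (one per site): interactions involving at most
## one group atom use interpolated charges (identical to charge
## interpolation, both being bilinear expansions of affine charges), while
## intra-group pair energies are linearly interpolated between the end-state
## pair energies.  Returns the four components.
.piComponents <- function(system, x, K) {
  cls <- .atomClasses(system)
  env <- which(cls == 0L)
  qFull <- interpolatedCharges(system)          # buffers/env at current values
  nG <- length(system@groups)
  qInterp <- qFull
  intra <- numeric(nG)
  for (gi in seq_len(nG)) {
    g <- system@groups[[gi]]
    p <- g@protonatedState
    d <- setdiff(1:2, p)
    qA <- g@stateCharges[, p]
    qB <- g@stateCharges[, d]
    qInterp[g@atomIds] <- (1 - x[gi]) * qA + x[gi] * qB
    Kgg <- K[g@atomIds, g@atomIds, drop = FALSE]
    eA <- 0.5 * drop(qA %*% Kgg %*% qA)
    eB <- 0.5 * drop(qB %*% Kgg %*% qB)
    intra[gi] <- (1 - x[gi]) * eA + x[gi] * eB
  }
  rest <- if (length(env))
    0.5 * drop(qInterp[env] %*% K[env, env, drop = FALSE] %*% qInterp[env])
  else 0
  groupEnv <- 0
  interGroup <- 0
  for (gi in seq_len(nG)) {
    idg <- system@groups[[gi]]@atomIds
    if (length(env))
      groupEnv <- groupEnv +
        drop(qInterp[idg] %*% K[idg, env, drop = FALSE] %*% qInterp[env])
    if (gi < nG) for (hi in seq((gi + 1L), nG)) {
      idh <- system@groups[[hi]]@atomIds
      interGroup <- interGroup +
        drop(qInterp[idg] %*% K[idg, idh, drop = FALSE] %*% qInterp[idh])
    }
  }
  list(rest = rest, groupEnv = groupEnv, interGroup = interGroup,
       intraGroup = intra)
}

## Deprotonation coordinate of every two-state group.
.deprotCoords <- function(system) {
  vapply(system@groups, function(g) {
    if (length(g@lambda) != 2L)
      stop("potential interpolation supports chemically uncoupled ",
           "(two-state) sites only; group '", g@name, "' has ",
           length(g@lambda), " states")
    g@lambda[setdiff(1:2, g@protonatedState)]
  }, numeric(1))
}

#' Potential-interpolation scheme (verification oracle)
#'
#' Linear interpolation of the end-state Hamiltonians for chemically
#' uncoupled two-state sites: environment and inter-group interactions use
#' interpolated charges (identical to charge interpolation), intra-group pair
#' energies are interpolated linearly between the end states, and the
#' gradient for each site is obtained from two full evaluations, one with the
#' site's protonated charges and one with its deprotonated charges (the
#' energy is affine in each site coordinate), for `2 N_sites` electrostatic
#' computations in total.  Serves as the independent cost/consistency oracle
#' for the single-evaluation charge-interpolation path.
#'
#' @param system a [TitratableSystem-class] whose groups are all two-state.
#' @return list with `energy` (kJ/mol), `gradients` (named per site,
#'   d/d lambda along the deprotonation coordinate), `components` (energies:
#'   `rest`, `groupEnv`, `interGroup`, per-group `intraGroup`),
#'   `gradientComponents` (per site: `external` = environment + inter-group
#'   part, `intra` = end-state intra-group energy difference) and
#'   `nEvaluations = 2 * nSites`.
#' @export
potentialInterpOracle <- function(system) {
  geom <- .pairGeometry(system)
  K <- .kernelMatrices(system, geom)$K
  nG <- nSites(system)
  if (nG == 0L) {
    res <- coulombEnergy(system)
    return(list(energy = res@energy, gradients = numeric(),
                components = .piComponents(system, numeric(), K),
                gradientComponents = list(), nEvaluations = 0L))
  }
  x <- .deprotCoords(system)
  grad <- numeric(nG)
  gradComp <- vector("list", nG)
  energy <- NA_real_
  for (s in seq_len(nG)) {
    x0 <- replace(x, s, 0)
    x1 <- replace(x, s, 1)
    cA <- .piComponents(system, x0, K)
    cB <- .piComponents(system, x1, K)
    eA <- cA$rest + cA$groupEnv + cA$interGroup + sum(cA$intraGroup)
    eB <- cB$rest + cB$groupEnv + cB$interGroup + sum(cB$intraGroup)
    grad[s] <- eB - eA
    gradComp[[s]] <- list(
      external = (cB$groupEnv + cB$interGroup) - (cA$groupEnv + cA$interGroup),
      intra = cB$intraGroup[s] - cA$intraGroup[s])
    if (s == 1L) energy <- (1 - x[s]) * eA + x[s] * eB
  }
  nm <- vapply(system@groups, function(g) g@name, "")
  names(grad) <- nm
  names(gradComp) <- nm
  list(energy = energy, gradients = grad,
       components = .piComponents(system, x, K),
       gradientComponents = gradComp,
       nEvaluations = 2L * nG)
}

## Charge-interpolation counterpart of the four-term decomposition, plus the
## matching gradient split (external = environment + inter-group part of
## sum_i dq_i Phi_i; intra = the quadratic intra-group part).  Used by the
## scheme-equivalence tests.
.ciComponents <- function(system) {
  geom <- .pairGeometry(system)
  K <- .kernelMatrices(system, geom)$K
  cls <- .atomClasses(system)
  env <- which(cls == 0L)
  q <- interpolatedCharges(system)
  nG <- nSites(system)
  rest <- if (length(env))
    0.5 * drop(q[env] %*% K[env, env, drop = FALSE] %*% q[env]) else 0
  groupEnv <- 0
  interGroup <- 0
  intra <- numeric(nG)
  gradComp <- vector("list", nG)
  phi <- drop(K %*% q)
  for (gi in seq_len(nG)) {
    g <- system@groups[[gi]]
    idg <- g@atomIds
    if (length(env))
      groupEnv <- groupEnv + drop(q[idg] %*% K[idg, env, drop = FALSE] %*% q[env])
    if (gi < nG) for (hi in seq(gi + 1L, nG)) {
      idh <- system@groups[[hi]]@atomIds
      interGroup <- interGroup +
        drop(q[idg] %*% K[idg, idh, drop = FALSE] %*% q[idh])
    }
    intra[gi] <- 0.5 * drop(q[idg] %*% K[idg, idg, drop = FALSE] %*% q[idg])
    if (length(g@lambda) == 2L) {
      p <- g@protonatedState
      dq <- g@stateCharges[, setdiff(1:2, p)] - g@stateCharges[, p]
      phiIntra <- drop(K[idg, idg, drop = FALSE] %*% q[idg])
      gradComp[[gi]] <- list(external = sum(dq * (phi[idg] - phiIntra)),
                             intra = sum(dq * phiIntra))
    }
  }
  names(gradComp) <- vapply(system@groups, function(g) g@name, "")
  list(rest = rest, groupEnv = groupEnv, interGroup = interGroup,
       intraGroup = intra, gradientComponents = gradComp)
}

#' Intra-group energy difference between interpolation schemes
#'
#' Within a lambda-group the potential-interpolation scheme is linear in the
#' site coordinate (it mixes the two end-state pair energies), while charge
#' interpolation is quadratic (product of two interpolated charges), so the
#' schemes agree at the end states but generally differ at intermediate
#' lambda.  Returns, per group, `V^intra_potential - V^intra_charge`.
#'
#' @param system a [TitratableSystem-class] with two-state groups.
#' @return named numeric vector, kJ/mol; zero at lambda in \{0, 1\}.
#' @export
schemeDiscrepancy <- function(system) {
  if (!nSites(system)) stop("no lambda-groups in the system")
  geom <- .pairGeometry(system)
  K <- .kernelMatrices(system, geom)$K
  x <- .deprotCoords(system)
  pi <- .piComponents(system, x, K)
  ci <- .ciComponents(system)
  d <- pi$intraGroup - ci$intraGroup
  names(d) <- vapply(system@groups, function(g) g@name, "")
  d
}

#' Pairwise 12-6 Lennard-Jones energy (diagnostic)
#'
#' A plain, never lambda-dependent, 12-6 term for buffer-realism diagnostics.
#' Default parameters are the buffer-particle values (sigma 0.25 nm,
#' epsilon 4 kJ/mol).  Not used by the dynamics engine.
#'
#' @param system a [TitratableSystem-class].
#' @param sigma,epsilon LJ parameters (nm, kJ/mol), scalars or per-atom.
#' @return total LJ energy, kJ/mol.
#' @export
ljEnergy <- function(system, sigma = 0.25, epsilon = 4) {
  geom <- .pairGeometry(system)
  n <- geom$n
  sig <- rep_len(sigma, n)
  eps <- rep_len(epsilon, n)
  sij <- outer(sig, sig, "+") / 2
  eij <- sqrt(outer(eps, eps))
  sr6 <- (sij / geom$r)^6
  E <- 4 * eij * (sr6^2 - sr6)
  E[geom$r > system@cutoff] <- 0
  sum(E[upper.tri(E)])
}
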