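## Time integration of atoms and lambda-particles: leapfrog, stochastic
## velocity rescaling, and the closed-form Lagrange solver for the linear
## constraints (per-group simplex sums and the global charge constraint).

## Coordinate bookkeeping over the stacked lambda vector (group-major state
## coordinates, collective buffer coordinate last).
.coordLayout <- function(system) {
  groupIndex <- integer()
  stateIndex <- integer()
  for (gi in seq_along(system@groups)) {
    ns <- length(system@groups[[gi]]@lambda)
    groupIndex <- c(groupIndex, rep(gi, ns))
    stateIndex <- c(stateIndex, seq_len(ns))
  }
  hasBuffer <- !is.null(system@buffers)
  if (hasBuffer) {
    groupIndex <- c(groupIndex, 0L)
    stateIndex <- c(stateIndex, 0L)
  }
  nCoords <- length(groupIndex)
  protonated <- logical(nCoords)
  pKaRef <- rep(NA_real_, nCoords)
  for (i in seq_len(nCoords)) {
    gi <- groupIndex[i]
    if (gi > 0L) {
      g <- system@groups[[gi]]
      protonated[i] <- stateIndex[i] == g@protonatedState
      pKaRef[i] <- g@pKaRefs[stateIndex[i]]
    }
  }
  list(nCoords = nCoords, groupIndex = groupIndex, stateIndex = stateIndex,
       hasBuffer = hasBuffer, protonated = protonated, pKaRef = pKaRef,
       names = .coordNames(system))
}

## Charge map: q = q0 + S %*% lambda reproduces interpolatedCharges() for any
## stacked coordinate vector.
.chargeMap <- function(system, layout) {
  n <- nrow(system@atoms)
  q0 <- system@atoms$charge
  S <- matrix(0, n, layout$nCoords)
  off <- 0L
  for (gi in seq_along(system@groups)) {
    g <- system@groups[[gi]]
    ns <- length(g@lambda)
    q0[g@atomIds] <- 0
    S[g@atomIds, off + seq_len(ns)] <- g@stateCharges
    off <- off + ns
  }
  if (layout$hasBuffer) {
    b <- system@buffers
    q0[b@atomIds] <- b@qMin
    S[b@atomIds, layout$nCoords] <- b@qMax - b@qMin
  }
  list(q0 = q0, S = S)
}

#' Build the linear constraint set of a system
#'
#' One simplex row per lambda-group (`sum_k lambda_{i,k} = 1`) and, when
#' buffers are present, one global charge row coupling every state coordinate
#' (through its group's total state charge) and the collective buffer
#' coordinate, with the right-hand side chosen so that the total interpolated
#' system charge equals the system's target.  All rows are linear in the
#' coordinates, so the constraint is solvable in closed form each step.
#'
#' @param system a [TitratableSystem-class].
#' @param lambdaMass fictitious mass of the lambda-particles, amu.
#' @return a [ConstraintSet-class].
#' @seealso [solveConstraints()]
#' @export
constraintSet <- function(system, lambdaMass = 5) {
  layout <- .coordLayout(system)
  rows <- list()
  target <- numeric()
  off <- 0L
  for (gi in seq_along(system@groups)) {
    ns <- length(system@groups[[gi]]@lambda)
    row <- numeric(layout$nCoords)
    row[off + seq_len(ns)] <- 1
    rows[[length(rows) + 1L]] <- row
    target <- c(target, system@groups[[gi]]@constrainedSum)
    off <- off + ns
  }
  if (layout$hasBuffer) {
    cm <- .chargeMap(system, layout)
    row <- colSums(cm$S)
    rows[[length(rows) + 1L]] <- row
    target <- c(target, system@totalChargeTarget - sum(cm$q0))
  }
  C <- do.call(rbind, rows)
  if (is.null(C)) C <- matrix(0, 0L, layout$nCoords)
  new("ConstraintSet", Cmat = C, target = target,
      masses = rep(lambdaMass, layout$nCoords), tolerance = 1e-10)
}

## Precompute the correction operator A = M^-1 C^T (C M^-1 C^T)^-1 so that
## lambda' = lambda - A (C lambda - d) is the minimal mass-weighted
## correction and v' = v - A C v removes velocity components along the
## constraint gradients.
.constraintOperator <- function(constraints) {
  C <- constraints@Cmat
  if (nrow(C) == 0L)
    return(list(C = C, d = constraints@target,
                A = matrix(0, ncol(C), 0L)))
  Minv <- 1 / constraints@masses
  CMC <- C %*% (Minv * t(C))
  if (nrow(CMC) > 0L && (!all(is.finite(CMC)) || rcond(CMC) < 1e-12))
    stop("singular constraint system (e.g. zero buffer charge capacity ",
         "with titrating sites)")
  A <- (Minv * t(C)) %*% solve(CMC)
  list(C = C, d = constraints@target, A = A)
}

#' Solve the lambda constraints in closed form
#'
#' Applies the minimal mass-weighted least-squares correction (closed-form
#' Lagrange multipliers) that returns the coordinates to the constraint
#' manifold, and removes the velocity components along the constraint
#' gradients.
#'
#' @param lambda stacked coordinate vector (see [lambdaValues()]).
#' @param constraints a [ConstraintSet-class].
#' @param velocities optional matching velocity vector.
#' @return list with corrected `lambda`, corrected `velocities` (or `NULL`)
#'   and `correction`, the Euclidean norm of the position correction.
#' @examples
#' cs <- new("ConstraintSet", Cmat = matrix(1, 1, 3), target = 1,
#'           masses = rep(5, 3), tolerance = 1e-10)
#' solveConstraints(c(0.5, 0.4, 0.3), cs)$lambda
#' @export
solveConstraints <- function(lambda, constraints, velocities = NULL) {
  op <- .constraintOperator(constraints)
  if (nrow(op$C) == 0L)
    return(list(lambda = lambda, velocities = velocities, correction = 0))
  err <- drop(op$C %*% lambda) - op$d
  corr <- drop(op$A %*% err)
  lambda <- lambda - corr
  if (!is.null(velocities))
    velocities <- velocities - drop(op$A %*% (op$C %*% velocities))
  list(lambda = lambda, velocities = velocities,
       correction = sqrt(sum(corr^2)))
}

## Stochastic velocity-rescaling factor (canonical-sampling kinetic-energy
## update).  K: current kinetic energy (vectorized over independent
## replicas); returns the scale factor alpha.  Draws ndf-dependent random
## numbers from the R stream.
.vrescaleAlpha <- function(K, ndf, Tt, tau, dt) {
  Kbar <- 0.5 * ndf * .kB * Tt
  cc <- exp(-dt / tau)
  n <- length(K)
  R1 <- stats::rnorm(n)
  S <- if (ndf > 1L) stats::rchisq(n, df = ndf - 1L) else numeric(n)
  Knew <- (sqrt(cc * K) + R1 * sqrt((1 - cc) * Kbar / ndf))^2 +
    (1 - cc) * (Kbar / ndf) * S
  alpha <- sqrt(Knew / K)
  alpha[K <= 0] <- 1
  alpha
}

#' Stochastic velocity-rescaling thermostat
#'
#' One update of the canonical velocity-rescaling scheme: the kinetic energy
#' performs the exact stochastic evolution toward its canonical distribution
#' at the target temperature and all velocities are scaled by the common
#' factor.  With an infinite coupling time the velocities are returned
#' unchanged (no-coupling limit, no random numbers consumed).
#'
#' @param velocities numeric vector (or matrix, e.g. `[n x 3]` atomic
#'   velocities) of one thermostat pool.
#' @param masses per-particle masses, amu (recycled across matrix columns).
#' @param Ttarget target temperature, K.
#' @param tau coupling time, ps.
#' @param dt integration step, ps.
#' @param ndf number of degrees of freedom of the pool (defaults to the
#'   number of velocity components; reduce by the number of active
#'   constraints).
#' @return rescaled velocities, same shape.
#' @export
vRescale <- function(velocities, masses, Ttarget, tau, dt,
                     ndf = length(velocities)) {
  if (!length(velocities)) return(velocities)
  if (is.infinite(tau)) return(velocities)
  if (tau <= 0) stop("tau must be positive")
  K <- if (is.matrix(velocities)) 0.5 * sum(masses * rowSums(velocities^2))
       else 0.5 * sum(masses * velocities^2)
  alpha <- .vrescaleAlpha(K, as.integer(ndf), Ttarget, tau, dt)
  velocities * alpha
}

## ---- engine ---------------------------------------------------------------

## Compile a system into plain-vector structures for the integrator.
.makeEngine <- function(system, pH, settings = LambdaPotentialSettings(),
                        vmm = NULL, lambdaMass = 5) {
  layout <- .coordLayout(system)
  cm <- .chargeMap(system, layout)
  cons <- constraintSet(system, lambdaMass)
  op <- .constraintOperator(cons)
  if (!is.null(vmm) && is(vmm, "VmmPolynomial")) vmm <- list(vmm)
  if (!is.null(vmm) && length(vmm) != length(system@groups))
    stop("need one V^MM entry (or NULL) per group")
  P0 <- as.matrix(system@atoms[, c("x", "y", "z")])
  frozen <- system@frozen
  geom0 <- if (frozen) .pairGeometryP(P0, system@box) else NULL
  km0 <- if (frozen) .kernelMatricesP(system@scheme, system@cutoff,
                                      system@epsilonR, geom0) else NULL
  ## free-coordinate columns of each group's V^MM within the stacked vector
  freeIdx <- lapply(seq_along(system@groups), function(gi) {
    which(layout$groupIndex == gi & !layout$protonated)
  })
  list(system = system, layout = layout, q0 = cm$q0, S = cm$S,
       cons = cons, op = op, P0 = P0, masses = system@atoms$mass,
       frozen = frozen, geom0 = geom0, km0 = km0, pH = pH,
       settings = settings, vmm = vmm, lambdaMass = lambdaMass,
       freeIdx = freeIdx, temperature = system@temperature,
       ndfLambda = layout$nCoords - nrow(cons@Cmat))
}

## Energies, atomic forces and lambda forces at (P, lambda).
.engineForces <- function(eng, P, lambda) {
  sys <- eng$system
  if (eng$frozen) {
    geom <- eng$geom0; km <- eng$km0
  } else {
    geom <- .pairGeometryP(P, sys@box)
    km <- .kernelMatricesP(sys@scheme, sys@cutoff, sys@epsilonR, geom)
  }
  q <- eng$q0 + drop(eng$S %*% lambda)
  phi <- drop(km$K %*% q)
  coulE <- 0.5 * sum(q * phi)
  atomF <- NULL
  restE <- 0
  if (!eng$frozen) {
    W <- -(q %o% q) * km$dK / geom$r
    atomF <- vapply(1:3, function(d) rowSums(W * geom$dx[[d]]),
                    numeric(geom$n))
    atomF <- matrix(atomF, ncol = 3)
    if (sys@restraintK > 0) {
      dP <- P - eng$P0
      atomF <- atomF - sys@restraintK * dP
      restE <- 0.5 * sys@restraintK * sum(dP^2)
    }
  }
  lay <- eng$layout
  gCoul <- drop(crossprod(eng$S, phi))
  gBias <- numeric(lay$nCoords)
  eBias <- 0
  isGroup <- lay$groupIndex > 0L
  if (any(isGroup)) {
    bp <- biasPotential(lambda[isGroup], eng$settings)
    gBias[isGroup] <- bp$gradient
    eBias <- sum(bp$energy)
  }
  gPh <- numeric(lay$nCoords)
  ePh <- 0
  dep <- which(isGroup & !lay$protonated)
  if (length(dep)) {
    pp <- phPotential(lambda[dep], lay$pKaRef[dep], eng$pH,
                      eng$temperature, eng$settings)
    gPh[dep] <- pp$gradient
    ePh <- sum(pp$energy)
  }
  gVmm <- numeric(lay$nCoords)
  eVmm <- 0
  if (!is.null(eng$vmm)) {
    for (gi in seq_along(eng$vmm)) {
      pg <- eng$vmm[[gi]]
      if (is.null(pg)) next
      fi <- eng$freeIdx[[gi]]
      ev <- evalVmm(lambda[fi], pg)
      gVmm[fi] <- ev$gradient
      eVmm <- eVmm + ev$energy
    }
  }
  list(lambdaForce = -(gCoul + gBias + gPh + gVmm), atomForce = atomF,
       coulGrad = gCoul,
       potential = coulE + restE + eBias + ePh + eVmm)
}

#' Run leapfrog dynamics of a titratable system
#'
#' Leapfrog integration of the atomic coordinates (unless the system is
#' frozen) and of the lambda-particles, with separate stochastic
#' velocity-rescaling thermostats for the two pools, and closed-form
#' re-establishment of the simplex and charge constraints after every
#' position update (velocity components along the constraint gradients are
#' removed as well).  Initial velocities are drawn from the
#' Maxwell-Boltzmann distribution and projected onto the constraint
#' manifold; an infinite thermostat coupling time gives NVE dynamics.
#'
#' @param system a [TitratableSystem-class]; its current lambda values are
#'   the initial conditions.
#' @param spec an [IntegratorSpec-class].
#' @param pH solvent pH.
#' @param settings a [LambdaPotentialSettings-class].
#' @param vmm optional list of [VmmPolynomial-class] corrections, one per
#'   group (or a single polynomial for a one-group system); `NULL` = flat.
#' @param recordEnergies also record per-frame potential and kinetic
#'   energies.
#' @param integrateLambda set `FALSE` to hold the lambda-coordinates fixed
#'   (used by thermodynamic-integration scans).
#' @return a [LambdaTrajectory-class]; the final coordinate values are its
#'   last frame.
#' @examples
#' sys <- makeFixture("ideal_site", pKaRefs = 4)
#' tr <- runDynamics(sys, IntegratorSpec(nSteps = 200, outputInterval = 0.1),
#'                   pH = 4)
#' @export
runDynamics <- function(system, spec, pH,
                        settings = LambdaPotentialSettings(), vmm = NULL,
                        recordEnergies = FALSE, integrateLambda = TRUE) {
  stopifnot(is(spec, "IntegratorSpec"))
  validObject(spec)
  eng <- .makeEngine(system, pH, settings, vmm, spec@lambdaMass)
  set.seed(spec@seed)
  lay <- eng$layout
  nC <- lay$nCoords
  dt <- spec@dt
  mL <- rep(spec@lambdaMass, nC)
  lambda <- unname(lambdaValues(system))
  sc <- solveConstraints(lambda, eng$cons)
  lambda <- sc$lambda
  P <- eng$P0
  mobile <- !eng$frozen
  ## Maxwell-Boltzmann initial velocities, constraint-projected
  vL <- stats::rnorm(nC, sd = sqrt(.kB * spec@lambdaT / mL))
  vL <- solveConstraints(lambda, eng$cons, vL)$velocities
  vA <- if (mobile)
    matrix(stats::rnorm(3L * nrow(P), sd = sqrt(.kB * spec@atomT /
                                                rep(eng$masses, 3L))),
           ncol = 3) else NULL
  if (!integrateLambda) vL <- numeric(nC)
  outEvery <- max(1L, round(spec@outputInterval / dt))
  nFrames <- spec@nSteps %/% outEvery
  frames <- matrix(NA_real_, nFrames, nC)
  times <- numeric(nFrames)
  eRows <- if (recordEnergies) vector("list", nFrames) else NULL
  fi <- 0L
  for (step in seq_len(spec@nSteps)) {
    f <- .engineForces(eng, P, lambda)
    if (!all(is.finite(f$lambdaForce)) ||
        (mobile && !all(is.finite(f$atomForce))))
      stop("non-finite forces at step ", step, ": integration blow-up")
    if (mobile) {
      vA <- vA + dt * f$atomForce / eng$masses
      P <- P + dt * vA
    }
    if (integrateLambda) {
      vL <- vL + dt * f$lambdaForce / mL
      lamRaw <- lambda + dt * vL
      scc <- solveConstraints(lamRaw, eng$cons)
      vL <- (scc$lambda - lambda) / dt
      lambda <- scc$lambda
    }
    if (mobile && is.finite(spec@atomTau))
      vA <- vRescale(vA, eng$masses, spec@atomT, spec@atomTau, dt,
                     ndf = 3L * nrow(P))
    if (integrateLambda && is.finite(spec@lambdaTau) && eng$ndfLambda > 0L)
      vL <- vRescale(vL, mL, spec@lambdaT, spec@lambdaTau, dt,
                     ndf = eng$ndfLambda)
    if (step %% outEvery == 0L) {
      fi <- fi + 1L
      frames[fi, ] <- lambda
      times[fi] <- step * dt
      if (recordEnergies) {
        kA <- if (mobile) 0.5 * sum(eng$masses * rowSums(vA^2)) else 0
        kL <- 0.5 * sum(mL * vL^2)
        eRows[[fi]] <- data.frame(time = step * dt, potential = f$potential,
                                  kineticAtoms = kA, kineticLambda = kL)
      }
    }
  }
  colnames(frames) <- lay$names
  energies <- if (recordEnergies) do.call(rbind, eRows[seq_len(fi)])
              else data.frame(time = numeric(), potential = numeric(),
                              kineticAtoms = numeric(),
                              kineticLambda = numeric())
  if (is.null(energies)) energies <- data.frame(time = numeric(),
                                                potential = numeric(),
                                                kineticAtoms = numeric(),
                                                kineticLambda = numeric())
  new("LambdaTrajectory", time = times[seq_len(fi)],
      lambdas = frames[seq_len(fi), , drop = FALSE],
      coordinateNames = lay$names, pH = pH, seed = spec@seed,
      replica = 1L, energies = energies)
}
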