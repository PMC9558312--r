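## Lockstep leapfrog sampler for frozen-atom systems: many independent
## lambda-only runs (e.g. all pH values x replicas of a titration campaign)
## advance as columns of one coordinate matrix, so each step is a handful of
## small matrix operations.  Physics identical to runDynamics() with frozen
## atoms: same forces, same constraint projection, same v-rescale thermostat.

.sampleEnsemble <- function(system, pH, nSteps, dt = 0.002, lambdaMass = 5,
                            lambdaT = 300, lambdaTau = 2.0,
                            settings = LambdaPotentialSettings(), vmm = NULL,
                            outputEvery = 500L, initLambda = NULL,
                            thermostatEvery = 10L) {
  if (!system@frozen)
    stop("ensemble sampling requires frozen atoms")
  eng <- .makeEngine(system, pH[1], settings, vmm, lambdaMass)
  lay <- eng$layout
  nC <- lay$nCoords
  nRuns <- length(pH)
  ## Coulomb gradient is affine in the stacked coordinates:
  ## g = h + G lambda with G = S^T K S, h = S^T K q0.
  K <- eng$km0$K
  G <- crossprod(eng$S, K %*% eng$S)
  h <- drop(crossprod(eng$S, K %*% eng$q0))
  op <- eng$op
  isGroup <- lay$groupIndex > 0L
  dep <- which(isGroup & !lay$protonated)
  ## per-(coordinate, run) pH free energies
  dG <- matrix(0, nC, nRuns)
  for (k in dep)
    dG[k, ] <- log(10) * .kB * eng$temperature * (lay$pKaRef[k] - pH)
  b <- settings@barrier
  k1 <- settings@k1
  x0 <- settings@x0
  vmmTerms <- NULL
  if (!is.null(vmm)) {
    if (is(vmm, "VmmPolynomial")) vmm <- list(vmm)
    vmmTerms <- lapply(seq_along(system@groups), function(gi) {
      pg <- vmm[[gi]]
      if (is.null(pg)) return(NULL)
      list(free = eng$freeIdx[[gi]], coef = pg@coefficients,
           expo = pg@exponents)
    })
  }
  if (is.null(initLambda)) {
    initLambda <- unname(lambdaValues(system))
  }
  Lam <- matrix(initLambda, nC, nRuns)
  mL <- rep(lambdaMass, nC)
  ndf <- eng$ndfLambda
  project <- function(M, target = TRUE) {
    if (nrow(op$C) == 0L) return(M)
    err <- op$C %*% M
    if (target) err <- err - op$d
    M - op$A %*% err
  }
  Lam <- project(Lam)
  V <- matrix(stats::rnorm(nC * nRuns, sd = sqrt(.kB * lambdaT / mL)),
              nC, nRuns)
  V <- project(V, target = FALSE)
  nFrames <- as.integer(nSteps %/% outputEvery)
  frames <- array(NA_real_, c(nFrames, nC, nRuns))
  fi <- 0L
  ## loop-invariant precomputation: affine position projector
  ## lambda' = P1 lambda + c0, zero-coupling shortcut, pH-step constants
  hasCons <- nrow(op$C) > 0L
  P1 <- if (hasCons) diag(nC) - op$A %*% op$C else diag(nC)
  c0 <- if (hasCons) drop(op$A %*% op$d) else numeric(nC)
  hasCoul <- any(G != 0) || any(h != 0)
  dGdep <- dG[dep, , drop = FALSE]
  kEff <- k1 / (1 - 2 * x0)
  sNorm <- stats::plogis(kEff * 0.5) - stats::plogis(-kEff * 0.5)
  thermostatEvery <- max(1L, as.integer(thermostatEvery))
  dtInvM <- dt / mL
  bufRow <- if (lay$hasBuffer) nC else 0L
  for (step in seq_len(nSteps)) {
    ## bias on every group coordinate
    gB <- (32 * b) * Lam * (1 - Lam) * (1 - 2 * Lam)
    if (bufRow) gB[bufRow, ] <- 0
    g <- if (hasCoul) h + G %*% Lam + gB else gB
    ## pH smooth step on deprotonated-state coordinates
    if (length(dep)) {
      p <- 1 / (1 + exp(-kEff * (Lam[dep, , drop = FALSE] - 0.5)))
      g[dep, ] <- g[dep, ] + dGdep * ((kEff / sNorm) * p * (1 - p))
    }
    if (!is.null(vmmTerms)) {
      for (vt in vmmTerms) {
        if (is.null(vt)) next
        X <- Lam[vt$free, , drop = FALSE]
        for (t in seq_along(vt$coef)) {
          for (j in seq_along(vt$free)) {
            e <- vt$expo[t, j]
            if (e == 0L) next
            dm <- rep(vt$coef[t] * e, nRuns)
            for (jj in seq_along(vt$free)) {
              p <- vt$expo[t, jj] - (jj == j)
              if (p != 0L) dm <- dm * X[jj, ]^p
            }
            g[vt$free[j], ] <- g[vt$free[j], ] + dm
          }
        }
      }
    }
    V <- V - dtInvM * g                 # g already includes the bias term
    LamNew <- P1 %*% (Lam + dt * V) + c0
    V <- (LamNew - Lam) / dt
    Lam <- LamNew
    ## global coupling every few steps: the stochastic kinetic-energy
    ## update is exact for any elapsed interval
    if (is.finite(lambdaTau) && ndf > 0L &&
        step %% thermostatEvery == 0L) {
      Krun <- (0.5 * lambdaMass) * .colSums(V * V, nC, nRuns)
      alpha <- .vrescaleAlpha(Krun, ndf, lambdaT, lambdaTau,
                              thermostatEvery * dt)
      V <- V * rep(alpha, each = nC)
    }
    if (step %% outputEvery == 0L) {
      fi <- fi + 1L
      frames[fi, , ] <- Lam
    }
  }
  list(frames = frames, time = seq_len(nFrames) * outputEvery * dt,
       coordNames = lay$names, layout = lay)
}
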