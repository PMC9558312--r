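## Thermodynamic-integration scans over a fixed lambda grid and polynomial
## fitting of the correction potential V^MM.

## Stacked lambda vector for one group at a free-coordinate grid point,
## buffer coordinate solved from the charge constraint.
.gridLambda <- function(eng, gi, xfree) {
  lay <- eng$layout
  lambda <- numeric(lay$nCoords)
  for (gj in seq_along(eng$system@groups)) {
    g <- eng$system@groups[[gj]]
    idx <- which(lay$groupIndex == gj)
    lam <- g@lambda
    if (gj == gi) {
      lam <- numeric(length(g@lambda))
      lam[setdiff(seq_along(lam), g@protonatedState)] <- xfree
      lam[g@protonatedState] <- 1 - sum(xfree)
    }
    lambda[idx] <- lam
  }
  if (lay$hasBuffer) {
    Qc <- colSums(eng$S)
    cap <- Qc[lay$nCoords]
    if (abs(cap) < 1e-12)
      stop("zero buffer charge capacity: charge constraint unsolvable")
    rhs <- eng$system@totalChargeTarget - sum(eng$q0) -
      sum(Qc[-lay$nCoords] * lambda[-lay$nCoords])
    lambda[lay$nCoords] <- rhs / cap
  }
  lambda
}

## Directional derivative map from the stacked per-state Coulomb gradient to
## the free simplex coordinates: d/dx_k = g[free_k] - g[p], plus the chain
## term through the charge-constrained buffer coordinate.
.directionalGradient <- function(eng, gi, gStacked) {
  lay <- eng$layout
  g <- eng$system@groups[[gi]]
  idx <- which(lay$groupIndex == gi)
  p <- idx[g@protonatedState]
  free <- setdiff(idx, p)
  out <- gStacked[free] - gStacked[p]
  if (lay$hasBuffer) {
    Qc <- colSums(eng$S)
    dbuf <- -(Qc[free] - Qc[p]) / Qc[lay$nCoords]
    out <- out + gStacked[lay$nCoords] * dbuf
  }
  out
}

#' Thermodynamic-integration scan along the lambda grid
#'
#' Holds the lambda-coordinates of one group fixed at each grid point
#' (extending beyond the physical range on both sides, default -0.1 to 1.1
#' in steps of 0.05, with the protonated-state coordinate eliminated by the
#' simplex constraint and the buffer coordinate solved from the charge
#' constraint) and records the time-averaged gradient of the potential with
#' respect to the free coordinates.  By default only the force-field
#' (Coulomb) term is integrated - the bias, pH and correction terms are
#' excluded, as required when calibrating V^MM; they can be switched on
#' individually to verify that a calibrated landscape is flat.
#'
#' For frozen-atom systems the gradient is deterministic: one evaluation per
#' grid point, zero standard error.  For mobile systems the atoms evolve
#' under the thermostat while lambda is held fixed, the first
#' `equilibrationFraction` of each trajectory is discarded, and samples are
#' recorded every `sampleEvery` steps (chosen of the order of the gradient
#' autocorrelation time, so the naive standard error is meaningful).
#'
#' @param system a [TitratableSystem-class].
#' @param group index of the group to scan.
#' @param grid optional matrix of free-coordinate grid points (one row per
#'   point); by default a regular grid from `gridMin` to `gridMax` in steps
#'   of `gridStep`, restricted (for multisite groups) to points whose
#'   eliminated coordinate also stays within the range.
#' @param gridMin,gridMax,gridStep default grid limits and spacing.
#' @param nStepsPerPoint MD steps per grid point (ignored for frozen atoms).
#' @param dt,atomT,atomTau integrator step and atom thermostat settings.
#' @param sampleEvery gradient sampling interval, steps.
#' @param equilibrationFraction discarded prefix fraction.
#' @param seed RNG seed.
#' @param includeVmm,vmm include a correction potential in the gradient.
#' @param includePh,pH include the pH potential at this pH.
#' @param includeBias include the biasing potential.
#' @param settings a [LambdaPotentialSettings-class].
#' @param minSteps refuse (in strict mode) scans shorter than this.
#' @param strict error instead of warn on a too-short scan.
#' @return a [TiScanResult-class].
#' @seealso [fitVmm()], [tiFreeEnergy()]
#' @export
tiScan <- function(system, group = 1L, grid = NULL, gridMin = -0.1,
                   gridMax = 1.1, gridStep = 0.05, nStepsPerPoint = 2000L,
                   dt = 0.002, atomT = system@temperature, atomTau = 0.5,
                   sampleEvery = 20L, equilibrationFraction = 0.1,
                   seed = 1L, includeVmm = FALSE, vmm = NULL,
                   includePh = FALSE, pH = NULL, includeBias = FALSE,
                   settings = LambdaPotentialSettings(), minSteps = 200L,
                   strict = FALSE) {
  g <- system@groups[[group]]
  ns <- length(g@lambda)
  arity <- ns - 1L
  if (is.null(grid)) {
    xs <- seq(gridMin, gridMax, by = gridStep)
    if (arity == 1L) grid <- matrix(xs, ncol = 1L)
    else {
      grid <- as.matrix(expand.grid(rep(list(xs), arity)))
      lamP <- 1 - rowSums(grid)
      grid <- grid[lamP >= gridMin - 1e-9 & lamP <= gridMax + 1e-9, ,
                   drop = FALSE]
      dimnames(grid) <- NULL
    }
  }
  grid <- as.matrix(grid)
  if (ncol(grid) != arity)
    stop("grid must have one column per free coordinate (", arity, ")")
  if (!system@frozen && nStepsPerPoint < minSteps) {
    msg <- sprintf("nStepsPerPoint = %d below the configured minimum %d",
                   nStepsPerPoint, minSteps)
    if (strict) stop(msg) else warning(msg)
  }
  eng <- .makeEngine(system, pH = if (is.null(pH)) 0 else pH, settings,
                     vmm = if (includeVmm) vmm else NULL)
  free <- setdiff(seq_len(ns), g@protonatedState)
  nP <- nrow(grid)
  meanG <- matrix(NA_real_, nP, arity)
  semG <- matrix(0, nP, arity)
  nSamp <- integer(nP)
  set.seed(seed)
  for (i in seq_len(nP)) {
    xfree <- grid[i, ]
    lambda <- .gridLambda(eng, group, xfree)
    ## analytic terms are constant while lambda is fixed
    fixedTerm <- numeric(arity)
    if (includeVmm && !is.null(vmm))
      fixedTerm <- fixedTerm + evalVmm(xfree, vmm)$gradient
    if (includePh) {
      if (is.null(pH)) stop("includePh = TRUE needs a pH")
      for (k in seq_len(arity))
        fixedTerm[k] <- fixedTerm[k] +
          phPotential(xfree[k], g@pKaRefs[free[k]], pH,
                      system@temperature, settings)$gradient
    }
    if (includeBias) {
      lamP <- 1 - sum(xfree)
      dbP <- biasPotential(lamP, settings)$gradient
      for (k in seq_len(arity))
        fixedTerm[k] <- fixedTerm[k] +
          biasPotential(xfree[k], settings)$gradient - dbP
    }
    if (system@frozen) {
      f <- .engineForces(eng, eng$P0, lambda)
      meanG[i, ] <- .directionalGradient(eng, group, f$coulGrad) + fixedTerm
      nSamp[i] <- 1L
    } else {
      P <- eng$P0
      vA <- matrix(stats::rnorm(3L * nrow(P),
                                sd = sqrt(.kB * atomT / rep(eng$masses, 3L))),
                   ncol = 3)
      nEq <- floor(equilibrationFraction * nStepsPerPoint)
      samples <- matrix(NA_real_, nStepsPerPoint %/% sampleEvery + 1L, arity)
      si <- 0L
      for (step in seq_len(nStepsPerPoint)) {
        f <- .engineForces(eng, P, lambda)
        vA <- vA + dt * f$atomForce / eng$masses
        P <- P + dt * vA
        if (is.finite(atomTau))
          vA <- vRescale(vA, eng$masses, atomT, atomTau, dt,
                         ndf = 3L * nrow(P))
        if (step > nEq && step %% sampleEvery == 0L) {
          si <- si + 1L
          samples[si, ] <- .directionalGradient(eng, group, f$coulGrad)
        }
      }
      samples <- samples[seq_len(si), , drop = FALSE]
      meanG[i, ] <- colMeans(samples) + fixedTerm
      ## block-averaged standard error: contiguous blocks longer than the
      ## gradient autocorrelation time give an unbiased error estimate even
      ## when successive samples are correlated
      nb <- min(10L, max(2L, si %/% 5L))
      blk <- (seq_len(si) - 1L) %/% ceiling(si / nb)
      for (k in seq_len(arity)) {
        bm <- tapply(samples[, k], blk, mean)
        semG[i, k] <- stats::sd(bm) / sqrt(length(bm))
      }
      nSamp[i] <- si
    }
  }
  new("TiScanResult", grid = grid, meanGradients = meanG, stderr = semG,
      nSamples = nSamp, equilibrationFraction = equilibrationFraction,
      group = as.integer(group))
}

## Monomial exponent set of total degree 1..order in `arity` variables (the
## constant term carries no force and is omitted).
.monomialExponents <- function(arity, order) {
  E <- as.matrix(expand.grid(rep(list(0:order), arity)))
  E <- E[rowSums(E) >= 1L & rowSums(E) <= order, , drop = FALSE]
  dimnames(E) <- NULL
  storage.mode(E) <- "integer"
  E[order(rowSums(E), E[, 1]), , drop = FALSE]
}

#' Fit the polynomial correction potential V^MM
#'
#' Least-squares fit of `-dV^MM/dx` to the mean thermodynamic-integration
#' gradients, so that adding the fitted potential cancels the force-field
#' gradient along the scanned lambda path.  Uses a monomial basis in the
#' free simplex coordinates (fifth order by default for two-state groups;
#' eighth order is the conventional choice for three-state imidazole-like
#' groups) with QR rank detection: linearly dependent basis directions are
#' dropped (their coefficients set to zero) rather than propagated as noise.
#'
#' @param scan a [TiScanResult-class].
#' @param order maximum total degree of the polynomial.
#' @param residualThreshold warn if the maximum absolute gradient residual
#'   exceeds this (kJ/mol; 0.5 is the conventional acceptance for single
#'   sites, 1.0 for three-state groups).
#' @return list with `vmm` (a [VmmPolynomial-class]) and `report` (max and
#'   rms gradient residual, rank, number of coefficients, design condition
#'   number).
#' @export
fitVmm <- function(scan, order = 5L, residualThreshold = 0.5) {
  grid <- scan@grid
  arity <- ncol(grid)
  E <- .monomialExponents(arity, order)
  nT <- nrow(E)
  nP <- nrow(grid)
  if (nP <= nT)
    stop("underdetermined fit: ", nP, " grid points for ", nT,
         " coefficients")
  X <- matrix(0, nP * arity, nT)
  y <- numeric(nP * arity)
  row <- 0L
  for (i in seq_len(nP)) {
    for (k in seq_len(arity)) {
      row <- row + 1L
      y[row] <- -scan@meanGradients[i, k]
      for (t in seq_len(nT)) {
        e <- E[t, k]
        if (e == 0L) next
        v <- e
        for (j in seq_len(arity)) {
          p <- E[t, j] - (j == k)
          if (p != 0L) v <- v * grid[i, j]^p
        }
        X[row, t] <- v
      }
    }
  }
  qf <- qr(X)
  coef <- qr.coef(qf, y)
  coef[is.na(coef)] <- 0
  resid <- drop(X %*% coef) - y
  report <- list(maxResidual = max(abs(resid)),
                 rmse = sqrt(mean(resid^2)),
                 rank = qf$rank, nCoefficients = nT,
                 condition = kappa(X))
  if (report$maxResidual > residualThreshold)
    warning(sprintf("V^MM fit residual %.3f kJ/mol exceeds %.2f kJ/mol",
                    report$maxResidual, residualThreshold))
  list(vmm = VmmPolynomial(coef, E), report = report)
}

#' Deprotonation free energy by thermodynamic integration
#'
#' Trapezoidal quadrature of the mean gradients over the physical range
#' `x` in `[0, 1]` of a two-state scan, with the standard error propagated
#' from the per-point standard errors.
#'
#' @param scan a [TiScanResult-class] with a single free coordinate whose
#'   grid covers `[0, 1]`.
#' @return list with `dG` (kJ/mol) and `se`.
#' @export
tiFreeEnergy <- function(scan) {
  if (ncol(scan@grid) != 1L)
    stop("tiFreeEnergy integrates a single free coordinate")
  x <- scan@grid[, 1]
  o <- order(x)
  x <- x[o]
  gr <- scan@meanGradients[o, 1]
  sem <- scan@stderr[o, 1]
  keep <- x >= -1e-9 & x <= 1 + 1e-9
  x <- x[keep]; gr <- gr[keep]; sem <- sem[keep]
  if (length(x) < 2L || min(x) > 1e-9 || max(x) < 1 - 1e-9)
    stop("grid must span [0, 1]")
  dx <- diff(x)
  if (any(dx > 2 * stats::median(dx) + 1e-12))
    stop("grid gap inside [0, 1] exceeds twice the nominal spacing")
  n <- length(x)
  w <- numeric(n)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2L) w[2:(n - 1)] <- (dx[-(n - 1)] + dx[-1]) / 2
  list(dG = sum(w * gr), se = sqrt(sum((w * sem)^2)))
}

#' Write / read a plain-text calibration file
#'
#' Stores the TI grid, mean gradients and standard errors together with the
#' fitted polynomial (coefficients, exponents, order, arity) and the fit
#' report, as YAML.
#'
#' @param path file path.
#' @param scan a [TiScanResult-class].
#' @param fit the list returned by [fitVmm()].
#' @return `writeCalibration` returns the path invisibly;
#'   `readCalibration` returns a list with `scan`, `vmm` and `report`.
#' @export
writeCalibration <- function(path, scan, fit) {
  obj <- list(
    grid = apply(scan@grid, 1, as.numeric, simplify = FALSE),
    meanGradients = apply(scan@meanGradients, 1, as.numeric,
                          simplify = FALSE),
    stderr = apply(scan@stderr, 1, as.numeric, simplify = FALSE),
    nSamples = as.integer(scan@nSamples),
    equilibrationFraction = scan@equilibrationFraction,
    group = scan@group,
    vmm = list(coefficients = as.numeric(fit$vmm@coefficients),
               exponents = apply(fit$vmm@exponents, 1, as.integer,
                                 simplify = FALSE),
               order = as.integer(fit$vmm@order),
               arity = as.integer(fit$vmm@arity)),
    report = fit$report)
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  obj <- yaml::read_yaml(path)
  grid <- do.call(rbind, lapply(obj$grid, as.numeric))
  scan <- new("TiScanResult", grid = grid,
              meanGradients = do.call(rbind, lapply(obj$meanGradients,
                                                    as.numeric)),
              stderr = do.call(rbind, lapply(obj$stderr, as.numeric)),
              nSamples = as.integer(obj$nSamples),
              equilibrationFraction = obj$equilibrationFraction,
              group = as.integer(obj$group))
  vmm <- VmmPolynomial(as.numeric(obj$vmm$coefficients),
                       do.call(rbind, lapply(obj$vmm$exponents, as.integer)))
  list(scan = scan, vmm = vmm, report = obj$report)
}
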