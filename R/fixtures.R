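## Synthetic fixture systems (desk-scale stand-ins for solvated reference
## tripeptides) and the brute-force quadrature oracle.

## Deterministic spherical Fibonacci shell, keeps buffers spread out.
.sphereShell <- function(n, radius) {
  i <- seq_len(n)
  z <- (2 * i - 1) / n - 1
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(x = radius * r * cos(phi), y = radius * r * sin(phi),
        z = radius * z)
}

#' Build a synthetic titratable fixture system
#'
#' Four fixture kinds, all fully determined by their arguments:
#' \describe{
#'   \item{`ideal_site`}{one titratable atom (neutral when protonated,
#'     -1 e when deprotonated), no environment: the Coulomb lambda-gradient
#'     is identically zero, so the correction potential is analytically
#'     flat and the site titrates exactly at its reference pKa.}
#'   \item{`shifted_site`}{adds fixed environment point charges, producing a
#'     closed-form lambda-dependent Coulomb term that shifts the apparent
#'     pKa by `f * dq * q / d` per unit charge pair (in free-energy units).}
#'   \item{`his_like`}{a three-state imidazole-like group (doubly protonated
#'     +1 e; two neutral singly-protonated tautomers) with microscopic
#'     reference pKas, three lambda-coordinates on the simplex.}
#'   \item{`buffer_bath`}{any of the above plus `nBuffers` collective buffer
#'     particles on a spherical shell, coupled through the charge constraint
#'     so the cell stays neutral.}
#' }
#'
#' @param kind fixture kind.
#' @param pKaRefs reference pKa(s): one value for single-site kinds
#'   (default 4.0), two microscopic values (delta-protonated then
#'   epsilon-protonated tautomer) for `his_like` (default `c(6.53, 6.94)`).
#' @param environmentCharges data.frame with columns `x`, `y`, `z`, `q` of
#'   fixed environment charges (default for `shifted_site`: +0.05 e at
#'   1.2 nm).
#' @param temperature Kelvin.
#' @param nBuffers buffers for `buffer_bath`.
#' @param base base fixture kind for `buffer_bath`.
#' @param frozen freeze atoms (lambda-only dynamics; the statistical
#'   fixtures default).
#' @param restraintK position-restraint constant used when atoms are mobile.
#' @param scheme,cutoff,epsilonR electrostatics settings.
#' @return a [TitratableSystem-class].
#' @examples
#' makeFixture("ideal_site", pKaRefs = 3.65)
#' @export
makeFixture <- function(kind = c("ideal_site", "shifted_site", "his_like",
                                 "buffer_bath"),
                        pKaRefs = NULL, environmentCharges = NULL,
                        temperature = 300, nBuffers = 10L,
                        base = c("ideal_site", "shifted_site", "his_like"),
                        frozen = TRUE, restraintK = 1000,
                        scheme = "plain", cutoff = Inf, epsilonR = 1) {
  kind <- match.arg(kind)
  if (kind == "buffer_bath") {
    base <- match.arg(base)
    sys <- makeFixture(base, pKaRefs, environmentCharges, temperature,
                       frozen = frozen, restraintK = restraintK,
                       scheme = scheme, cutoff = cutoff,
                       epsilonR = epsilonR)
    n0 <- nrow(sys@atoms)
    shell <- .sphereShell(nBuffers, radius = 2.5)
    bufAtoms <- data.frame(x = shell[, 1], y = shell[, 2], z = shell[, 3],
                           mass = 12, charge = 0)
    atoms <- rbind(sys@atoms, bufAtoms)
    qMin <- -0.5; qMax <- 0.5
    qGroup <- sum(sys@groups[[1]]@stateCharges %*% sys@groups[[1]]@lambda)
    qEnv <- sum(sys@atoms$charge[-sys@groups[[1]]@atomIds])
    lamB <- (0 - qGroup - qEnv - nBuffers * qMin) /
      (nBuffers * (qMax - qMin))
    buf <- BufferSet(n0 + seq_len(nBuffers), qMin, qMax, lamB)
    return(TitratableSystem(atoms, sys@groups, buffers = buf,
                            scheme = scheme, cutoff = cutoff,
                            epsilonR = epsilonR,
                            temperature = temperature,
                            totalChargeTarget = 0, frozen = frozen,
                            restraintK = restraintK))
  }
  if (kind == "his_like") {
    if (is.null(pKaRefs)) pKaRefs <- c(6.53, 6.94)
    if (length(pKaRefs) != 2L)
      stop("his_like needs two microscopic reference pKas")
    atoms <- data.frame(x = 0, y = 0, z = 0, mass = 12, charge = 0)
    grp <- LambdaGroup(1L, cbind(1, 0, 0), pKaRefs = pKaRefs,
                       protonatedState = 1L,
                       stateNames = c("HSP", "HSD", "HSE"), name = "his")
  } else {
    if (is.null(pKaRefs)) pKaRefs <- 4.0
    if (length(pKaRefs) != 1L)
      stop("single-site fixtures need one reference pKa")
    atoms <- data.frame(x = 0, y = 0, z = 0, mass = 12, charge = 0)
    grp <- LambdaGroup(1L, cbind(0, -1), pKaRefs = pKaRefs,
                       stateNames = c("PROT", "DEPROT"), name = "site")
  }
  if (kind == "shifted_site" || !is.null(environmentCharges)) {
    if (kind == "ideal_site" && !is.null(environmentCharges))
      kind <- "shifted_site"
    if (is.null(environmentCharges))
      environmentCharges <- data.frame(x = 1.2, y = 0, z = 0, q = 0.05)
    atoms <- rbind(atoms,
                   data.frame(x = environmentCharges$x,
                              y = environmentCharges$y,
                              z = environmentCharges$z,
                              mass = 12, charge = environmentCharges$q))
  }
  TitratableSystem(atoms, grp, scheme = scheme, cutoff = cutoff,
                   epsilonR = epsilonR, temperature = temperature,
                   totalChargeTarget = NA_real_, frozen = frozen,
                   restraintK = restraintK)
}

## Constraint-resolved total lambda potential on a grid of free coordinates.
## X: matrix [nPts x arity].  Returns V (kJ/mol) per point.
.lambdaLandscape <- function(eng, X, settings, vmm, pH) {
  sys <- eng$system
  g <- sys@groups[[1]]
  ns <- length(g@lambda)
  free <- setdiff(seq_len(ns), g@protonatedState)
  lay <- eng$layout
  nPts <- nrow(X)
  Lam <- matrix(0, nPts, lay$nCoords)
  gidx <- which(lay$groupIndex == 1L)
  for (k in seq_along(free)) Lam[, gidx[free[k]]] <- X[, k]
  Lam[, gidx[g@protonatedState]] <- 1 - rowSums(X)
  if (lay$hasBuffer) {
    Qc <- colSums(eng$S)
    cap <- Qc[lay$nCoords]
    rhs <- sys@totalChargeTarget - sum(eng$q0) -
      Lam[, -lay$nCoords, drop = FALSE] %*% Qc[-lay$nCoords]
    Lam[, lay$nCoords] <- rhs / cap
  }
  K <- eng$km0$K
  G <- crossprod(eng$S, K %*% eng$S)
  h <- drop(crossprod(eng$S, K %*% eng$q0))
  e0 <- 0.5 * drop(eng$q0 %*% K %*% eng$q0)
  V <- e0 + drop(Lam %*% h) + 0.5 * rowSums((Lam %*% G) * Lam)
  b <- settings@barrier
  for (k in gidx) V <- V + 16 * b * Lam[, k]^2 * (1 - Lam[, k])^2
  for (k in seq_along(free))
    V <- V + phPotential(X[, k], g@pKaRefs[free[k]], pH,
                         sys@temperature, settings)$energy
  if (!is.null(vmm)) V <- V + evalVmm(X, vmm)$energy
  V
}

#' Brute-force quadrature oracle for basin populations
#'
#' Integrates the Boltzmann weight `exp(-V_total(lambda) / kB T)` of a
#' frozen-atom fixture over the lambda-line (two-state group) or the
#' constrained simplex plane (three-state group) on a dense regular grid,
#' with every term the dynamics feels (Coulomb with the charge-constrained
#' buffer response, bias, pH, optional V^MM), and splits the population at
#' the classification thresholds.  This is the implementation-independent
#' ground truth against which sampled basin populations and titration curves
#' are tested; it shares only the potential evaluators with the dynamics
#' path, never the sampler.
#'
#' The quadrature is checked by recomputing at twice the resolution; a
#' change above 1e-6 in any reported fraction is a precision error.
#'
#' @param system a frozen [TitratableSystem-class] with one lambda-group.
#' @param pH solvent pH.
#' @param settings a [LambdaPotentialSettings-class].
#' @param vmm optional [VmmPolynomial-class].
#' @param thresholds classification thresholds.
#' @param nPoints grid points per dimension (default 4001 for one free
#'   coordinate, 501 for two).
#' @param range integration range per free coordinate.
#' @return list with `S` (deprotonated fraction; macroscopic for a
#'   three-state group), `Pprot`, `Pdeprot` (basin probabilities normalized
#'   over all of lambda-space), and for three-state groups `Smicro` (named
#'   per tautomer) and `Pbasins`.
#' @seealso [oracleTitration()], [titrationCampaign()]
#' @export
quadratureOracle <- function(system, pH,
                             settings = LambdaPotentialSettings(),
                             vmm = NULL, thresholds = c(0.2, 0.8),
                             nPoints = NULL, range = c(-0.6, 1.6)) {
  if (!system@frozen) stop("the quadrature oracle needs frozen atoms")
  if (length(system@groups) != 1L)
    stop("the quadrature oracle expects one lambda-group")
  g <- system@groups[[1]]
  arity <- length(g@lambda) - 1L
  if (arity > 2L) stop("oracle supports at most three-state groups")
  eng <- .makeEngine(system, pH, settings, vmm)
  beta <- 1 / (.kB * system@temperature)
  ## Vmin shared across all regions so relative weights are consistent
  Vref <- local({
    xs <- seq(range[1], range[2], length.out = 201L)
    X <- if (arity == 1L) matrix(xs, ncol = 1L)
         else as.matrix(expand.grid(xs, xs))
    min(.lambdaLandscape(eng, X, settings, vmm, pH))
  })
  trapw <- function(x) {
    h <- x[2] - x[1]
    w <- rep(h, length(x))
    w[c(1, length(x))] <- h / 2
    w
  }
  ## integral of the Boltzmann weight over an axis-aligned rectangle of
  ## free coordinates produced by `mk(x1, x2)`
  regionMass1 <- function(lo, hi, n, mk) {
    xs <- seq(lo, hi, length.out = n)
    V <- .lambdaLandscape(eng, mk(xs), settings, vmm, pH)
    sum(trapw(xs) * exp(-beta * (V - Vref)))
  }
  regionMass2 <- function(lo1, hi1, lo2, hi2, n, mk) {
    x1 <- seq(lo1, hi1, length.out = n)
    x2 <- seq(lo2, hi2, length.out = n)
    gr <- as.matrix(expand.grid(x1, x2))
    V <- .lambdaLandscape(eng, mk(gr[, 1], gr[, 2]), settings, vmm, pH)
    w <- as.vector(outer(trapw(x1), trapw(x2)))
    sum(w * exp(-beta * (V - Vref)))
  }
  evalAt <- function(n) {
    if (arity == 1L) {
      mk <- function(xs) matrix(xs, ncol = 1L)
      Z <- regionMass1(range[1], range[2], n, mk)
      pProt <- regionMass1(range[1], thresholds[1], n, mk) / Z
      pDeprot <- regionMass1(thresholds[2], range[2], n, mk) / Z
      list(S = pDeprot / (pProt + pDeprot), Pprot = pProt,
           Pdeprot = pDeprot)
    } else {
      ## free coords are (x, y); all simplex re-parameterizations below are
      ## affine with unit Jacobian, so masses are directly comparable
      Z <- regionMass2(range[1], range[2], range[1], range[2], n,
                       function(a, b) cbind(a, b))
      ## basin of free state 1: x > threshold
      p1 <- regionMass2(thresholds[2], range[2], range[1], range[2], n,
                        function(a, b) cbind(a, b)) / Z
      ## basin of free state 2: y > threshold
      p2 <- regionMass2(thresholds[2], range[2], range[1], range[2], n,
                        function(a, b) cbind(b, a)) / Z
      ## protonated basin: lambda_p = 1 - x - y > threshold; use
      ## coordinates (lambda_p, x), i.e. y = 1 - lambda_p - x
      pP <- regionMass2(thresholds[2], range[2], range[1], range[2], n,
                        function(a, b) cbind(b, 1 - a - b)) / Z
      free <- setdiff(seq_along(g@lambda), g@protonatedState)
      nm <- g@stateNames[free]
      sMicro <- c(p1 / (pP + p1), p2 / (pP + p2))
      names(sMicro) <- nm
      pb <- c(pP, p1, p2)
      names(pb) <- c(g@stateNames[g@protonatedState], nm)
      list(S = (p1 + p2) / (pP + p1 + p2), Pprot = pP, Pdeprot = p1 + p2,
           Smicro = sMicro, Pbasins = pb)
    }
  }
  if (is.null(nPoints)) nPoints <- if (arity == 1L) 4001L else 401L
  r1 <- evalAt(nPoints)
  r2 <- evalAt(2L * nPoints - 1L)
  drift <- abs(r2$S - r1$S)
  if (!is.null(r1$Smicro))
    drift <- max(drift, abs(r2$Smicro - r1$Smicro))
  if (drift > 1e-6)
    stop(sprintf("quadrature not converged: refinement changes S by %.2e",
                 drift))
  r2
}

#' Oracle titration curve and pKa
#'
#' Evaluates the quadrature oracle over a pH grid and fits the
#' Henderson-Hasselbalch equation to the resulting exact titration curve,
#' for every species the fixture reports.
#'
#' @inheritParams quadratureOracle
#' @param pH numeric vector of pH values.
#' @return list with `table` (data.frame of pH, species, S) and `fits`
#'   (data.frame of species, pKa, ci95).
#' @export
oracleTitration <- function(system, pH,
                            settings = LambdaPotentialSettings(),
                            vmm = NULL, thresholds = c(0.2, 0.8),
                            nPoints = NULL) {
  rows <- lapply(pH, function(p) {
    o <- quadratureOracle(system, p, settings, vmm, thresholds, nPoints)
    if (is.null(o$Smicro))
      data.frame(pH = p, species = "site", S = o$S)
    else
      data.frame(pH = p,
                 species = c("macro", paste0("micro:", names(o$Smicro))),
                 S = c(o$S, unname(o$Smicro)))
  })
  tab <- do.call(rbind, rows)
  fits <- do.call(rbind, lapply(split(tab, tab$species), function(d) {
    ft <- fitHH(d$pH, d$S)
    data.frame(species = d$species[1], pKa = ft$pKa, ci95 = ft$ci95)
  }))
  rownames(fits) <- NULL
  list(table = tab, fits = fits)
}
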