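## Shared builders for randomized and hand-made toy systems.

## random uncoupled (two-state) system: nSites groups of `atomsPerGroup`
## atoms plus `nEnv` environment atoms, all well separated
randomSystem <- function(nSites, nEnv = 4L, atomsPerGroup = 2L,
                         scheme = "plain", cutoff = Inf, box = NULL,
                         interior = TRUE) {
  nAtoms <- nSites * atomsPerGroup + nEnv
  repeat {
    P <- matrix(runif(3L * nAtoms, 0.2, 2.8), ncol = 3)
    d <- as.matrix(dist(P)); diag(d) <- Inf
    if (min(d) > 0.15) break
  }
  atoms <- data.frame(x = P[, 1], y = P[, 2], z = P[, 3], mass = 12,
                      charge = 0)
  if (nEnv > 0L)
    atoms$charge[nSites * atomsPerGroup + seq_len(nEnv)] <-
      runif(nEnv, -0.8, 0.8)
  groups <- lapply(seq_len(nSites), function(s) {
    ids <- (s - 1L) * atomsPerGroup + seq_len(atomsPerGroup)
    lam2 <- if (interior) runif(1, 0.1, 0.9) else sample(0:1, 1)
    LambdaGroup(ids,
                cbind(runif(atomsPerGroup, -1, 1),
                      runif(atomsPerGroup, -1, 1)),
                pKaRefs = 4, name = paste0("s", s),
                lambda = c(1 - lam2, lam2))
  })
  TitratableSystem(atoms, groups, scheme = scheme, cutoff = cutoff,
                   box = box)
}

## deprotonation coordinate column index of a one-group system's stacked
## lambda vector
deprotIndex <- function(system) {
  g <- system@groups[[1]]
  setdiff(seq_along(g@lambda), g@protonatedState)
}

## total lambda-landscape energy of a frozen one-group two-state system as a
## function of the deprotonation coordinate x (independent reimplementation
## for finite-difference oracles: plain sums, no engine code)
landscapeEnergy <- function(system, x, pH, settings = LambdaPotentialSettings(),
                            vmm = NULL) {
  g <- system@groups[[1]]
  p <- g@protonatedState
  lam <- numeric(2); lam[p] <- 1 - x; lam[3 - p] <- x
  sys <- system
  lambdaValues(sys) <- c(lam, lambdaValues(system)[-(1:2)])
  e <- coulombEnergy(sys)@energy
  e <- e + sum(biasPotential(lam, settings)$energy)
  e <- e + phPotential(x, g@pKaRefs[3 - p], pH, system@temperature,
                       settings)$energy
  if (!is.null(vmm)) e <- e + evalVmm(x, vmm)$energy
  e
}
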