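f <- coulombConstant()

test_that("pairwise Coulomb energy, forces and potentials are consistent", {
  at <- data.frame(x = c(0, 1), y = 0, z = 0, mass = 12, charge = 1)
  res <- coulombEnergy(TitratableSystem(at))
  expect_equal(res@energy, 138.935458)
  expect_equal(res@nEvaluations, 1L)

  set.seed(3)
  for (rep in 1:5) {
    sys <- randomSystem(nSites = 2L, nEnv = 5L)
    res <- coulombEnergy(sys)
    ## Newton's third law
    expect_lt(max(abs(colSums(res@forces))), 1e-9)
    ## phi[i] = dE/dq_i by central finite difference in the charge
    q <- res@charges
    h <- 1e-6
    for (i in sample(length(q), 3)) {
      qp <- q; qp[i] <- q[i] + h
      qm <- q; qm[i] <- q[i] - h
      fd <- (coulombEnergy(sys, qp)@energy -
             coulombEnergy(sys, qm)@energy) / (2 * h)
      expect_lt(abs(fd - res@phi[i]) / max(1, abs(fd)), 1e-6)
    }
  }
  ## atomic forces equal -dE/dR by finite difference
  sys <- randomSystem(nSites = 1L, nEnv = 3L)
  res <- coulombEnergy(sys)
  h <- 1e-6
  for (i in c(1L, 4L)) for (d in 1:3) {
    up <- sys; up@atoms[i, d] <- up@atoms[i, d] + h
    dn <- sys; dn@atoms[i, d] <- dn@atoms[i, d] - h
    fd <- (coulombEnergy(up, res@charges)@energy -
           coulombEnergy(dn, res@charges)@energy) / (2 * h)
    expect_lt(abs(-fd - res@forces[i, d]) / max(1, abs(fd)), 1e-5)
  }
  expect_error(coulombEnergy(TitratableSystem(
    data.frame(x = c(0, 1e-8), y = 0, z = 0, mass = 12, charge = 1))),
    "singular|coincident")
})

test_that("reaction-field kernel is continuous at the cutoff and periodic images work", {
  pair <- function(r, scheme, cutoff = 1.1, epsR = 2.5) {
    at <- data.frame(x = c(0, r), y = 0, z = 0, mass = 12, charge = 1)
    coulombEnergy(TitratableSystem(at, scheme = scheme, cutoff = cutoff,
                                   epsilonR = epsR))@energy
  }
  ## kernel goes to zero continuously at the cutoff
  expect_lt(abs(pair(1.1 - 1e-7, "reaction-field")), 1e-4)
  expect_identical(pair(1.2, "reaction-field"), 0)
  ## eps_RF = Inf closed form at r: f/epsR (1/r + r^2/(2 rc^3) - 3/(2 rc))
  r <- 0.7
  expect_equal(pair(r, "reaction-field"),
               f / 2.5 * (1 / r + r^2 / (2 * 1.1^3) - 3 / (2 * 1.1)))
  ## minimum image: 4.5 nm separation in a 5 nm box is 0.5 nm
  at <- data.frame(x = c(0.25, 4.75), y = 0.5, z = 0.5, mass = 12,
                   charge = 1)
  res <- coulombEnergy(TitratableSystem(at, box = c(5, 5, 5), cutoff = 2))
  expect_equal(res@energy, f / 0.5)
})

test_that("charge-interpolation lambda-gradients are exact", {
  ## dq = 0 for all group atoms -> zero gradient
  at <- data.frame(x = c(0, 1), y = 0, z = 0, mass = 12, charge = c(0, 0.3))
  sys <- TitratableSystem(at, LambdaGroup(1L, cbind(0.2, 0.2), pKaRefs = 4,
                                          lambda = c(0.6, 0.4)))
  lg <- lambdaGradients(sys, coulombEnergy(sys))
  expect_equal(unname(diff(lg$groups[[1]])), 0)

  ## single site + one fixed charge: d/dx of the closed-form pair energy
  sys <- makeFixture("shifted_site", pKaRefs = 4,
                     environmentCharges = data.frame(x = 1.2, y = 0, z = 0,
                                                     q = 0.3))
  lambdaValues(sys) <- c(0.7, 0.3)
  lg <- lambdaGradients(sys, coulombEnergy(sys))$groups[[1]]
  expect_equal(unname(lg["DEPROT"] - lg["PROT"]), f * (-1) * 0.3 / 1.2)

  ## random three-site system: raw per-coordinate gradient matches the
  ## central finite difference of the energy in each lambda alone
  set.seed(11)
  sys <- randomSystem(nSites = 3L, nEnv = 4L)
  lg <- lambdaGradients(sys, coulombEnergy(sys))
  h <- 1e-6
  lam0 <- unname(lambdaValues(sys))
  for (k in seq_along(lam0)) {
    up <- sys; lambdaValues(up) <- replace(lam0, k, lam0[k] + h)
    dn <- sys; lambdaValues(dn) <- replace(lam0, k, lam0[k] - h)
    fd <- (coulombEnergy(up)@energy - coulombEnergy(dn)@energy) / (2 * h)
    expect_lt(abs(fd - unlist(lg$groups)[k]) / max(1, abs(fd)), 1e-6)
  }

  ## stale potential contract
  res <- coulombEnergy(sys)
  lambdaValues(sys) <- replace(lam0, 2L, 0.9)
  expect_error(lambdaGradients(sys, res), "stale")
})

test_that("buffer coordinate gradient comes from the same single evaluation", {
  sys <- makeFixture("buffer_bath", pKaRefs = 4, base = "shifted_site")
  lambdaValues(sys) <- c(0.6, 0.4, 0.45)
  res <- coulombEnergy(sys)
  lg <- lambdaGradients(sys, res)
  h <- 1e-6
  up <- sys; lambdaValues(up) <- c(0.6, 0.4, 0.45 + h)
  dn <- sys; lambdaValues(dn) <- c(0.6, 0.4, 0.45 - h)
  fd <- (coulombEnergy(up)@energy - coulombEnergy(dn)@energy) / (2 * h)
  expect_equal(lg$buffer, fd, tolerance = 1e-6)
  expect_equal(res@nEvaluations, 1L)
})

test_that("potential interpolation agrees with charge interpolation except within groups", {
  set.seed(21)
  for (rep in 1:20) {
    nS <- sample(1:4, 1)
    sys <- randomSystem(nSites = nS, nEnv = sample(2:6, 1))
    pi <- potentialInterpOracle(sys)
    ci <- lambdaCPH:::.ciComponents(sys)
    scale <- max(1, abs(pi$components$groupEnv), abs(pi$components$interGroup))
    expect_lt(abs(pi$components$groupEnv - ci$groupEnv) / scale, 1e-10)
    expect_lt(abs(pi$components$interGroup - ci$interGroup) / scale, 1e-10)
    expect_lt(abs(pi$components$rest - ci$rest) / max(1, abs(ci$rest)),
              1e-10)
    ## gradients: external (environment + inter-group) parts identical
    for (s in seq_len(nS)) {
      expect_lt(abs(pi$gradientComponents[[s]]$external -
                    ci$gradientComponents[[s]]$external) /
                  max(1, abs(ci$gradientComponents[[s]]$external)), 1e-10)
    }
    ## total energies differ exactly by the intra-group discrepancy
    eCI <- coulombEnergy(sys)@energy
    expect_equal(pi$energy - eCI, sum(schemeDiscrepancy(sys)),
                 tolerance = 1e-10)
  }
})

test_that("evaluation counts restate the cost scaling of the two schemes", {
  set.seed(5)
  for (nS in 1:8) {
    sys <- randomSystem(nSites = nS, nEnv = 2L)
    expect_identical(coulombEnergy(sys)@nEvaluations, 1L)
    expect_identical(potentialInterpOracle(sys)$nEvaluations, 2L * nS)
  }
  sys0 <- randomSystem(nSites = 0L, nEnv = 5L)
  pi0 <- potentialInterpOracle(sys0)
  expect_identical(pi0$nEvaluations, 0L)
  expect_equal(pi0$energy, coulombEnergy(sys0)@energy)
})

test_that("intra-group discrepancy is the hand-derived quadratic-vs-linear difference", {
  ## two-atom group, q^A = (1, 0), q^B = (0, 1), r = 0.5 nm, lambda = 0.5:
  ## charge interpolation has the cross term f * 0.25 / 0.5, potential
  ## interpolation has zero intra energy in both end states
  at <- data.frame(x = c(0, 0.5), y = 0, z = 0, mass = 12, charge = 0)
  g <- LambdaGroup(1:2, cbind(c(1, 0), c(0, 1)), pKaRefs = 4,
                   lambda = c(0.5, 0.5))
  sys <- TitratableSystem(at, g)
  expect_equal(unname(schemeDiscrepancy(sys)), -f * 0.25 / 0.5)
  expect_equal(unname(schemeDiscrepancy(sys)), -69.467729)
  ## end states agree
  for (x in c(0, 1)) {
    lambdaValues(sys) <- c(1 - x, x)
    expect_lt(abs(schemeDiscrepancy(sys)), 1e-12)
  }
  ## general closed form on random two-atom groups
  set.seed(31)
  for (rep in 1:10) {
    qA <- runif(2, -1, 1); qB <- runif(2, -1, 1)
    x <- runif(1)
    r <- runif(1, 0.4, 1.5)
    at <- data.frame(x = c(0, r), y = 0, z = 0, mass = 12, charge = 0)
    sys <- TitratableSystem(at, LambdaGroup(1:2, cbind(qA, qB),
                                            pKaRefs = 4,
                                            lambda = c(1 - x, x)))
    qi <- (1 - x) * qA + x * qB
    hand <- ((1 - x) * qA[1] * qA[2] + x * qB[1] * qB[2] -
             qi[1] * qi[2]) * f / r
    expect_equal(unname(schemeDiscrepancy(sys)), hand, tolerance = 1e-10)
  }
})

test_that("potential interpolation refuses chemically coupled groups", {
  sys <- makeFixture("his_like")
  expect_error(potentialInterpOracle(sys), "two-state")
})
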