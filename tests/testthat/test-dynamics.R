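kB <- boltzmannConstant()

test_that("constraint solver applies the minimal closed-form correction", {
  cs <- new("ConstraintSet", Cmat = matrix(1, 1, 3), target = 1,
            masses = rep(5, 3), tolerance = 1e-10)
  ## already satisfied -> identity
  sc <- solveConstraints(c(0.2, 0.3, 0.5), cs)
  expect_lt(sc$correction, 1e-14)
  ## equal masses: uniform shift by (sum - 1)/3
  sc <- solveConstraints(c(0.5, 0.4, 0.3), cs)
  expect_equal(sc$lambda, c(0.5, 0.4, 0.3) - 0.2 / 3)
  ## velocity components along the constraint gradient are removed
  sc <- solveConstraints(c(0.2, 0.3, 0.5), cs, velocities = c(1, -2, 4))
  expect_lt(abs(sum(sc$velocities)), 1e-12)
  expect_equal(sc$velocities, c(1, -2, 4) - 1)
})

test_that("charge constraint spreads a titration charge over all buffers", {
  sys <- makeFixture("buffer_bath", pKaRefs = 4, nBuffers = 10L)
  cs <- constraintSet(sys)
  ## two constraint-satisfying states: a titration step changing the site
  ## charge by delta must change every buffer charge by -delta/10
  lam0 <- solveConstraints(c(1, 0, 0.5), cs)$lambda
  lam1 <- solveConstraints(c(0.55, 0.45, 0.5), cs)$lambda
  siteId <- sys@groups[[1]]@atomIds
  lambdaValues(sys) <- lam0
  q0 <- interpolatedCharges(sys)
  expect_lt(abs(sum(q0)), 1e-12)
  lambdaValues(sys) <- lam1
  q1 <- interpolatedCharges(sys)
  expect_lt(abs(sum(q1)), 1e-12)
  delta <- sum((q1 - q0)[siteId])
  dBuf <- (q1 - q0)[sys@buffers@atomIds]
  expect_gt(abs(delta), 0.1)               # a real titration step
  expect_equal(unname(dBuf), rep(-delta / 10, 10), tolerance = 1e-12)
})

test_that("singular constraint systems are refused", {
  ## linearly dependent rows make the Lagrange system singular
  cs <- new("ConstraintSet", Cmat = rbind(c(1, 1, 1), c(1, 1, 1)),
            target = c(1, 1), masses = rep(5, 3), tolerance = 1e-10)
  expect_error(solveConstraints(c(0.5, 0.3, 0.1), cs), "singular")
})

test_that("v-rescale thermostat honors the no-coupling limit and determinism", {
  v <- c(0.3, -0.2, 0.5)
  m <- rep(5, 3)
  expect_identical(vRescale(v, m, 300, Inf, 0.002), v)
  set.seed(9)
  a <- vRescale(v, m, 300, 2, 0.002)
  set.seed(9)
  b <- vRescale(v, m, 300, 2, 0.002)
  expect_identical(a, b)
  expect_false(identical(a, v))
  ## long-run first moment: repeated updates drive K toward ndf kB T / 2
  set.seed(1)
  vv <- c(0.01, -0.01)
  ks <- numeric(4000)
  for (i in seq_along(ks)) {
    vv <- vRescale(vv, c(5, 5), 300, 0.5, 0.01, ndf = 2L)
    ks[i] <- 0.5 * sum(5 * vv^2)
  }
  expect_equal(mean(ks[-(1:500)]), kB * 300, tolerance = 0.1)
})

test_that("leapfrog reproduces the analytic constrained oscillator", {
  ## V^MM = (k/2) x^2 on the deprotonation coordinate of a two-coordinate
  ## group; both coordinates move (lambda_p = 1 - x), so the effective mass
  ## is 2 m_lambda and omega = sqrt(k / (2 m_lambda))
  k <- 100
  sys <- makeFixture("ideal_site", pKaRefs = 4)
  lambdaValues(sys) <- c(0.7, 0.3)
  spec <- IntegratorSpec(nSteps = 10000L, dt = 0.002, lambdaT = 1e-12,
                         lambdaTau = Inf, outputInterval = 0.01, seed = 1)
  tr <- runDynamics(sys, spec, pH = 4,
                    settings = LambdaPotentialSettings(barrier = 0),
                    vmm = VmmPolynomial(c(0, k / 2)))
  x <- tr@lambdas[, 2]
  omega <- sqrt(k / (2 * 5))
  ## period from zero crossings of x over ~10 periods
  z <- which(diff(sign(x)) != 0)
  tz <- tr@time[z]
  period <- 2 * mean(diff(tz))
  expect_equal(period, 2 * pi / omega, tolerance = 0.01)
  ## amplitude preserved (no thermostat, symplectic)
  expect_equal(max(abs(x[tr@time > 15])), 0.3, tolerance = 0.01)
})

test_that("zero forces and zero velocities leave the state unchanged", {
  sys <- makeFixture("ideal_site", pKaRefs = 4)
  lambdaValues(sys) <- c(1, 0)
  spec <- IntegratorSpec(nSteps = 50L, lambdaT = 0, lambdaTau = Inf,
                         outputInterval = 0.002)
  tr <- runDynamics(sys, spec, pH = 4,
                    settings = LambdaPotentialSettings(barrier = 0))
  expect_true(all(abs(tr@lambdas[, 1] - 1) < 1e-14))
  expect_true(all(abs(tr@lambdas[, 2]) < 1e-14))
})

test_that("NVE dynamics conserves the total energy", {
  ## frozen atoms: lambda subsystem alone
  sys <- makeFixture("shifted_site", pKaRefs = 4)
  spec <- IntegratorSpec(nSteps = 10000L, dt = 0.002, lambdaT = 300,
                         lambdaTau = Inf, outputInterval = 0.05, seed = 4)
  tr <- runDynamics(sys, spec, pH = 3, recordEnergies = TRUE)
  E <- tr@energies$potential + tr@energies$kineticLambda
  drift <- abs(coef(lm(E ~ tr@energies$time))[2])
  expect_lt(drift, 0.01)                     # kJ/mol per ps
  ## mobile restrained atoms + lambda, both thermostats off
  msys <- makeFixture("shifted_site", pKaRefs = 4, frozen = FALSE,
                      restraintK = 500)
  spec <- IntegratorSpec(nSteps = 5000L, dt = 0.001, atomT = 150,
                         atomTau = Inf, lambdaT = 150, lambdaTau = Inf,
                         outputInterval = 0.05, seed = 5)
  tr <- runDynamics(msys, spec, pH = 3, recordEnergies = TRUE)
  E <- tr@energies$potential + tr@energies$kineticLambda +
    tr@energies$kineticAtoms
  drift <- abs(coef(lm(E ~ tr@energies$time))[2])
  expect_lt(drift, 0.01)
})

test_that("fixed seeds give bit-identical trajectories", {
  sys <- makeFixture("buffer_bath", pKaRefs = 4)
  spec <- IntegratorSpec(nSteps = 500L, seed = 77, outputInterval = 0.01)
  t1 <- runDynamics(sys, spec, pH = 4)
  t2 <- runDynamics(sys, spec, pH = 4)
  expect_identical(t1@lambdas, t2@lambdas)
})

test_that("lambda kinetic energy satisfies equipartition under the thermostat", {
  sys <- makeFixture("ideal_site", pKaRefs = 4)
  spec <- IntegratorSpec(nSteps = 100000L, dt = 0.002, lambdaT = 300,
                         lambdaTau = 2.0, outputInterval = 0.2, seed = 8)
  tr <- runDynamics(sys, spec, pH = 4, recordEnergies = TRUE)
  kl <- tr@energies$kineticLambda
  ## one constrained degree of freedom: <K> = kB T / 2, blocked SEM
  blocks <- tapply(kl, (seq_along(kl) - 1) %/% 50, mean)
  sem <- sd(blocks) / sqrt(length(blocks))
  expect_lt(abs(mean(kl) - 0.5 * kB * 300), 3 * sem + 1e-4)
})

test_that("simplex and charge constraints hold along trajectories", {
  sys <- makeFixture("buffer_bath", base = "his_like",
                     nBuffers = 10L)
  spec <- IntegratorSpec(nSteps = 5000L, outputInterval = 0.01, seed = 3)
  tr <- runDynamics(sys, spec, pH = 6.5)
  sums <- rowSums(tr@lambdas[, 1:3])
  expect_lt(max(abs(sums - 1)), 1e-9)
  qTot <- apply(tr@lambdas, 1, function(l) {
    lambdaValues(sys) <- l
    totalCharge(sys)
  })
  expect_lt(max(abs(qTot)), 1e-9)
})
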