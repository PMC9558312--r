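f <- coulombConstant()

## TiScanResult built directly from synthetic gradient data
syntheticScan <- function(x, grad, sem = 0) {
  new("TiScanResult", grid = matrix(x, ncol = 1L),
      meanGradients = matrix(grad, ncol = 1L),
      stderr = matrix(sem, length(x), 1L),
      nSamples = rep(1L, length(x)), equilibrationFraction = 0.1,
      group = 1L)
}

test_that("frozen-atom TI scans reproduce the analytic gradient exactly", {
  ## lambda-independent system: zero gradient at every grid point
  scan <- tiScan(makeFixture("ideal_site", pKaRefs = 4))
  expect_equal(scan@grid[, 1], seq(-0.1, 1.1, 0.05))
  expect_true(all(scan@meanGradients == 0))
  expect_true(all(scan@stderr == 0))
  ## single environment charge: constant closed-form gradient f dq q / d
  sys <- makeFixture("shifted_site", pKaRefs = 4)
  scan <- tiScan(sys)
  expect_equal(scan@meanGradients[, 1],
               rep(f * (-1) * 0.05 / 1.2, nrow(scan@grid)))
})

test_that("noise-free polynomial gradients are recovered to 1e-8", {
  x <- seq(-0.1, 1.1, 0.05)
  truth <- c(2.5, -30, 80, -70, 18)             # a fifth-order V^MM
  tg <- evalVmm(x, VmmPolynomial(truth))$gradient
  ft <- fitVmm(syntheticScan(x, -tg), order = 5)
  expect_equal(ft$vmm@coefficients, truth, tolerance = 1e-8)
  expect_lt(ft$report$maxResidual, 1e-8)
  ## nested-model exactness: quadratic data, order-5 basis
  tg2 <- evalVmm(x, VmmPolynomial(c(3, -4)))$gradient
  ft2 <- fitVmm(syntheticScan(x, -tg2), order = 5)
  expect_equal(ft2$vmm@coefficients[1:2], c(3, -4), tolerance = 1e-8)
  expect_lt(max(abs(ft2$vmm@coefficients[3:5])), 1e-8)
})

test_that("fit error stays within the conventional bound under realistic noise", {
  ## Gaussian noise of 0.3 kJ/mol on the gradients, 100 seeded repeats: the
  ## fitted gradient curve deviates from the true underlying curve by at
  ## most 0.5 kJ/mol over the physical range in >= 95% of repeats
  x <- seq(-0.1, 1.1, 0.05)
  truth <- VmmPolynomial(c(2, -30, 80, -70, 18))
  tg <- evalVmm(x, truth)$gradient
  xin <- seq(0, 1, 0.01)
  tin <- evalVmm(xin, truth)$gradient
  ok <- logical(100)
  for (s in 1:100) {
    set.seed(s)
    noisy <- -(tg + rnorm(length(x), 0, 0.3))
    ft <- suppressWarnings(fitVmm(syntheticScan(x, noisy, 0.3), order = 5))
    ok[s] <- max(abs(evalVmm(xin, ft$vmm)$gradient - tin)) <= 0.5
  }
  expect_gte(mean(ok), 0.95)
})

test_that("degenerate fits are refused and rank deficiency is handled", {
  x <- seq(-0.1, 1.1, 0.3)
  expect_error(fitVmm(syntheticScan(x, rep(1, length(x))), order = 5),
               "underdetermined")
  ## duplicated grid points create exact collinearity across rows; the
  ## pivoted QR still returns a valid fit
  xd <- rep(seq(-0.1, 1.1, 0.05), 2)
  tg <- evalVmm(xd, VmmPolynomial(c(1, -2)))$gradient
  ft <- fitVmm(syntheticScan(xd, -tg), order = 2)
  expect_equal(ft$vmm@coefficients, c(1, -2), tolerance = 1e-8)
})

test_that("thermodynamic integration integrates the physical range", {
  x <- seq(-0.1, 1.1, 0.05)
  expect_equal(tiFreeEnergy(syntheticScan(x, rep(0, length(x))))$dG, 0)
  expect_equal(tiFreeEnergy(syntheticScan(x, rep(3.7, length(x))))$dG, 3.7)
  ## frozen pair fixture: dG equals the end-state energy difference
  sys <- makeFixture("shifted_site", pKaRefs = 4)
  ti <- tiFreeEnergy(tiScan(sys))
  lambdaValues(sys) <- c(1, 0)
  e0 <- coulombEnergy(sys)@energy
  lambdaValues(sys) <- c(0, 1)
  e1 <- coulombEnergy(sys)@energy
  expect_equal(ti$dG, e1 - e0, tolerance = 1e-6)
  expect_identical(ti$se, 0)
  ## error propagation from per-point standard errors
  ti2 <- tiFreeEnergy(syntheticScan(x, rep(1, length(x)), sem = 0.2))
  expect_gt(ti2$se, 0)
  ## grid gap error
  xg <- c(seq(-0.1, 0.3, 0.05), seq(0.55, 1.1, 0.05))
  expect_error(tiFreeEnergy(syntheticScan(xg, rep(1, length(xg)))), "gap")
})

test_that("mobile-atom scans are statistically consistent across seeds", {
  sys <- makeFixture("shifted_site", pKaRefs = 4, frozen = FALSE,
                     restraintK = 2000)
  grid <- matrix(c(-0.1, 0.5, 1.1), ncol = 1)
  s1 <- tiScan(sys, grid = grid, nStepsPerPoint = 4000L, seed = 1,
               sampleEvery = 10L)
  s2 <- tiScan(sys, grid = grid, nStepsPerPoint = 4000L, seed = 2,
               sampleEvery = 10L)
  expect_true(all(s1@stderr > 0))
  pooled <- sqrt(s1@stderr^2 + s2@stderr^2)
  expect_true(all(abs(s1@meanGradients - s2@meanGradients) <= 3 * pooled))
  ## too-short scans are refused in strict mode
  expect_warning(tiScan(sys, grid = grid, nStepsPerPoint = 50L, seed = 1),
                 "minimum")
  expect_error(tiScan(sys, grid = grid, nStepsPerPoint = 50L, seed = 1,
                      strict = TRUE), "minimum")
})

test_that("multisite scans fit a bivariate correction polynomial", {
  sys <- makeFixture("his_like")
  scan <- tiScan(sys, gridStep = 0.1)
  expect_equal(ncol(scan@grid), 2L)
  ## every kept point has the eliminated coordinate inside the range too
  lamP <- 1 - rowSums(scan@grid)
  expect_true(all(lamP >= -0.1 - 1e-9 & lamP <= 1.1 + 1e-9))
  ## synthetic bivariate recovery through the same pipeline
  E <- cbind(c(1, 0, 2, 1), c(0, 1, 0, 2))
  truth <- VmmPolynomial(c(4, -3, 2, 1.5), E)
  tg <- evalVmm(scan@grid, truth)$gradient
  scan2 <- new("TiScanResult", grid = scan@grid, meanGradients = -tg,
               stderr = tg * 0, nSamples = rep(1L, nrow(tg)),
               equilibrationFraction = 0.1, group = 1L)
  ft <- fitVmm(scan2, order = 3)
  rec <- evalVmm(scan@grid, ft$vmm)$gradient
  expect_equal(rec, tg, tolerance = 1e-8)
})
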