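kB <- boltzmannConstant()

test_that("single-site fraction counting follows the threshold rule", {
  expect_equal(deprotFraction(rep(0.95, 40))$S, 1.0)
  fr <- deprotFraction(c(rep(0.1, 30), rep(0.9, 10), rep(0.5, 5)))
  expect_equal(fr$S, 0.25)
  expect_equal(fr$nProt, 30L)
  expect_equal(fr$nDeprot, 10L)
  expect_equal(fr$nExcluded, 5L)
  ## boundary frames are excluded from both counts
  expect_equal(deprotFraction(c(0.2, 0.8, 0.1))$nExcluded, 2L)
  expect_error(deprotFraction(runif(50, 0.3, 0.7)), "undefined")
  expect_error(deprotFraction(numeric()), "empty")
})

test_that("multisite fractions implement the macro and micro estimators", {
  mkFrames <- function(np, nd, ne, nmid = 5L) {
    m <- matrix(1 / 3, np + nd + ne + nmid, 3)
    if (np) m[seq_len(np), ] <- rep(c(0.9, 0.05, 0.05), each = np)
    if (nd) m[np + seq_len(nd), ] <- rep(c(0.05, 0.9, 0.05), each = nd)
    if (ne) m[np + nd + seq_len(ne), ] <- rep(c(0.05, 0.05, 0.9), each = ne)
    m
  }
  fr <- deprotFractionMultisite(mkFrames(50, 30, 20),
                                stateNames = c("HSP", "HSD", "HSE"))
  expect_equal(fr$Smacro, 0.5)
  expect_equal(unname(fr$Smicro["HSD"]), 30 / 80)
  expect_equal(unname(fr$Smicro["HSE"]), 20 / 70)
  expect_equal(unname(fr$counts), c(50, 30, 20))
  expect_equal(fr$nExcluded, 5L)
  ## all frames in the protonated basin: S_macro = 0
  expect_equal(deprotFractionMultisite(mkFrames(40, 0, 0))$Smacro, 0)
  ## two coordinates above threshold cannot happen on the simplex
  bad <- matrix(c(0.9, 0.9, -0.8), 1, 3)
  expect_error(deprotFractionMultisite(bad), "impossible")
})

test_that("Henderson-Hasselbalch fitting recovers exact and noisy curves", {
  pH <- seq(1, 7, 0.5)
  S <- 1 / (1 + 10^(4 - pH))
  ft <- fitHH(pH, S)
  expect_equal(ft$pKa, 4, tolerance = 1e-6)
  expect_lt(ft$ci95, 1e-4)
  ## midpoint and symmetry of the fitted curve
  hh <- function(p) 1 / (1 + 10^(ft$pKa - p))
  expect_equal(hh(ft$pKa), 0.5)
  for (x in c(0.5, 1, 2))
    expect_equal(hh(ft$pKa + x) + hh(ft$pKa - x), 1)
  ## Monte-Carlo: sigma = 0.02 noise, 100 seeded repeats
  recov <- vapply(1:100, function(s) {
    set.seed(s)
    fitHH(pH, pmin(1, pmax(0, S + rnorm(length(pH), 0, 0.02))))$pKa
  }, numeric(1))
  expect_lt(abs(mean(recov) - 4), 0.02)
  ## plateau-only data are non-identifiable
  expect_error(fitHH(pH, rep(0.01, length(pH))), "identifiable")
  expect_error(fitHH(c(3, 4), c(0.2, 0.8)), "at least 3")
  ## inverse-variance weighting is accepted
  ftw <- fitHH(pH, S, sErr = rep(0.02, length(pH)))
  expect_equal(ftw$pKa, 4, tolerance = 1e-6)
})

test_that("sampled basin populations agree with the quadrature oracle", {
  ## short ideal-site campaign versus the exact oracle at 5 pH values
  sys <- makeFixture("ideal_site", pKaRefs = 4)
  pH <- c(3, 3.5, 4, 4.5, 5)
  ## 10 ns x 4 replicas: the measured per-replica sd of S near the
  ## midpoint at 10 ns is about 0.07 (the basin-occupation correlation
  ## time is of order 1 ns), so the replica SEM is floored at 0.07/sqrt(4)
  ## against its own small-n noise
  res <- titrationCampaign(sys, pH, nReplicas = 4L, nSteps = 1e6,
                           dt = 0.01, seed = 101)
  fr <- deprotonatedFractions(res)
  for (i in seq_along(pH)) {
    o <- quadratureOracle(sys, pH[i])
    row <- fr[fr$pH == pH[i], ]
    expect_lt(abs(row$S - o$S), 3 * max(row$sem, 0.035))
  }
})

test_that("an environment charge shifts the recovered pKa by dG/(ln10 kB T)", {
  q <- 0.05; d <- 1.2
  delta <- coulombConstant() * (-1) * q / d        # shift in kJ/mol
  shift <- delta / (log(10) * kB * 300)            # about -1 pKa unit
  sys <- makeFixture("shifted_site", pKaRefs = 4.65,
                     environmentCharges = data.frame(x = d, y = 0, z = 0,
                                                     q = q))
  ## the oracle confirms the closed-form shift almost exactly
  o <- oracleTitration(sys, seq(1, 7, 0.5))
  expect_equal(o$fits$pKa, 4.65 + shift, tolerance = 0.01)
  ## and the sampled campaign agrees within its protocol scatter (about
  ## 0.05 pKa units at 3 replicas x 20 ns)
  res <- titrationCampaign(sys, seq(1, 7, 0.5), nReplicas = 3L,
                           nSteps = 2e6, dt = 0.01, seed = 7)
  p <- pKaEstimates(res)
  expect_lt(abs(p$pKa - (4.65 + shift)), 0.15)
})

test_that("disjoint seed sets give statistically compatible pKa estimates", {
  sys <- makeFixture("ideal_site", pKaRefs = 4)
  pH <- seq(2, 6, 0.5)
  r1 <- titrationCampaign(sys, pH, nReplicas = 3L, nSteps = 4e5,
                          dt = 0.01, seed = 1001)
  r2 <- titrationCampaign(sys, pH, nReplicas = 3L, nSteps = 4e5,
                          dt = 0.01, seed = 2002)
  p1 <- pKaEstimates(r1); p2 <- pKaEstimates(r2)
  expect_lt(abs(p1$pKa - p2$pKa), sqrt(p1$ci95^2 + p2$ci95^2) + 0.01)
})

test_that("macroscopic and microscopic pKas of a multisite group are consistent", {
  ## oracle titration of the imidazole-like fixture: the macroscopic acid
  ## constant is the sum of the microscopic ones
  o <- oracleTitration(makeFixture("his_like"), seq(4, 10, 0.5))
  pk <- setNames(o$fits$pKa, o$fits$species)
  combined <- -log10(10^(-pk[["micro:HSD"]]) + 10^(-pk[["micro:HSE"]]))
  expect_lt(abs(pk[["macro"]] - combined), 0.01)
})

test_that("campaigns flag pH points where no frames classify", {
  expect_error(deprotFraction(rep(0.5, 100)), "undefined")
  ## unreachable thresholds: every replica is flagged, the campaign refuses
  expect_error(
    suppressWarnings(titrationCampaign(makeFixture("ideal_site"),
                                       pH = c(3, 4, 5), nReplicas = 2L,
                                       nSteps = 5000L, seed = 1,
                                       thresholds = c(-5, 5))),
    "no pH point")
})
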