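kB <- boltzmannConstant()

test_that("pH potential honors the end-state free-energy contract exactly", {
  for (pKa in c(3.65, 4.25, 6.53, 9.1))
    for (pH in c(1, 3.65, 7.4, 10))
      for (Tt in c(280, 300, 310)) {
        v0 <- phPotential(0, pKa, pH, Tt)$energy
        v1 <- phPotential(1, pKa, pH, Tt)$energy
        expect_identical(v0, 0)
        expect_lt(abs((v1 - v0) - log(10) * kB * Tt * (pKa - pH)), 1e-12)
      }
  ## closed-form anchor: one pH unit at 300 K
  expect_equal(phPotential(1, 5, 4, 300)$energy, log(10) * kB * 300,
               tolerance = 1e-12)
  expect_equal(phPotential(1, 5, 4, 300)$energy, 5.7434, tolerance = 1e-4)
  expect_identical(phPotential(1, 4, 4)$energy, 0)
  expect_error(phPotential(0.5, 4, 4, temperature = -1), "temperature")
})

test_that("pH step is monotone and flat inside the classification basins", {
  x <- seq(-0.1, 1.1, 0.001)
  v <- phPotential(x, 5, 4)$energy             # dG > 0
  expect_true(all(diff(v) >= 0))
  ## < 0.1% of the jump develops below 0.2 or above 0.8
  dG <- log(10) * kB * 300
  expect_lt(v[which.min(abs(x - 0.2))], 1e-3 * dG)
  expect_gt(v[which.min(abs(x - 0.8))], (1 - 1e-3) * dG)
})

test_that("bias potential is a symmetric double well with the set barrier", {
  for (b in c(5, 7.5)) {
    s <- LambdaPotentialSettings(barrier = b)
    expect_identical(biasPotential(0, s)$energy, 0)
    expect_identical(biasPotential(1, s)$energy, 0)
    expect_equal(biasPotential(0.5, s)$energy, b)
    expect_equal(biasPotential(0.3, s)$energy, biasPotential(0.7, s)$energy)
    expect_equal(biasPotential(c(0, 0.5, 1), s)$gradient, c(0, 0, 0))
  }
  ## confining outside the physical range
  expect_gt(biasPotential(1.5)$energy, biasPotential(1.1)$energy)
  expect_error(biasPotential(0.5, -1), "barrier")
})

test_that("V^MM evaluation and gradients are exact", {
  zero <- VmmPolynomial(rep(0, 5))
  expect_equal(evalVmm(seq(-0.1, 1.1, 0.2), zero)$energy, rep(0, 7))
  lin <- VmmPolynomial(-3.2, 1)                 # V = -3.2 x
  ev <- evalVmm(c(-0.1, 0.4, 1.1), lin)
  expect_equal(ev$gradient, rep(-3.2, 3))
  p2 <- VmmPolynomial(c(1, 2), cbind(c(1L, 0L), c(0L, 1L)))   # arity 2
  expect_error(evalVmm(c(0.1, 0.2, 0.3), p2), "arity")
})

test_that("all lambda-potential derivatives match central finite differences", {
  set.seed(42)
  h <- 1e-6
  p5 <- VmmPolynomial(rnorm(5))
  p2d <- VmmPolynomial(rnorm(6), cbind(c(1, 0, 2, 1, 0, 3),
                                       c(0, 1, 0, 1, 2, 1)))
  s <- LambdaPotentialSettings()
  for (x in seq(-0.1, 1.1, 0.05)) {
    fd <- (phPotential(x + h, 6.2, 4.4)$energy -
           phPotential(x - h, 6.2, 4.4)$energy) / (2 * h)
    an <- phPotential(x, 6.2, 4.4)$gradient
    expect_lt(abs(fd - an) / max(1, abs(an)), 1e-6)
    fd <- (biasPotential(x + h, s)$energy -
           biasPotential(x - h, s)$energy) / (2 * h)
    expect_lt(abs(fd - biasPotential(x, s)$gradient) /
                max(1, abs(fd)), 1e-6)
    fd <- (evalVmm(x + h, p5)$energy - evalVmm(x - h, p5)$energy) / (2 * h)
    expect_lt(abs(fd - evalVmm(x, p5)$gradient) / max(1, abs(fd)), 1e-6)
  }
  ## random fifth-order polynomial at x = 0.37 against the FD oracle
  fd <- (evalVmm(0.37 + h, p5)$energy - evalVmm(0.37 - h, p5)$energy) /
    (2 * h)
  expect_equal(evalVmm(0.37, p5)$gradient, fd, tolerance = 1e-7)
  ## bivariate polynomial gradient
  xy <- c(0.31, 0.44)
  g <- evalVmm(xy, p2d)$gradient
  for (k in 1:2) {
    e <- numeric(2); e[k] <- h
    fd <- (evalVmm(xy + e, p2d)$energy - evalVmm(xy - e, p2d)$energy) /
      (2 * h)
    expect_lt(abs(fd - g[k]) / max(1, abs(fd)), 1e-6)
  }
})

test_that("total lambda force assembles the four additive terms", {
  g <- LambdaGroup(1L, cbind(0, -1), pKaRefs = 4, lambda = c(0.5, 0.5))
  flat <- LambdaPotentialSettings(barrier = 0)
  ## all terms zero
  f0 <- totalLambdaForce(g, c(0, 0), pH = 4, settings = flat)
  expect_equal(f0$force, c(0, 0))
  ## flat V^MM, lambda = 0.5, symmetric bias: only the pH term survives
  f <- totalLambdaForce(g, c(0, 0), pH = 3)
  expect_equal(f$terms$bias, c(0, 0))
  expect_equal(f$force, -f$terms$pH)
  expect_identical(f$terms$pH[g@protonatedState], 0)
  ## terms individually retrievable and additive
  p <- VmmPolynomial(c(1, -2))
  f2 <- totalLambdaForce(g, c(0.3, -0.2), pH = 3, vmm = p)
  expect_equal(f2$force,
               -(f2$terms$coulomb + f2$terms$vmm + f2$terms$bias +
                 f2$terms$pH))
  expect_error(totalLambdaForce(g, 1, pH = 3), "one Coulomb gradient")
})

test_that("lambda force matches the finite difference of the landscape", {
  ## fixture site with one environment charge: directional force along the
  ## deprotonation coordinate equals -dV/dx of the full landscape
  sys <- makeFixture("shifted_site", pKaRefs = 4)
  g <- sys@groups[[1]]
  x <- 0.42; pH <- 3.1
  lambdaValues(sys) <- c(1 - x, x)
  res <- coulombEnergy(sys)
  lg <- lambdaGradients(sys, res)$groups[[1]]
  f <- totalLambdaForce(g2 <- {gg <- g; gg@lambda <- c(1 - x, x); gg},
                        lg, pH = pH)
  h <- 1e-6
  fd <- (landscapeEnergy(sys, x + h, pH) -
         landscapeEnergy(sys, x - h, pH)) / (2 * h)
  expect_equal(unname(f$force[2] - f$force[1]), -fd, tolerance = 1e-6)
})
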