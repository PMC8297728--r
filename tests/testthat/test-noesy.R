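test_that("propagation reproduces the two-spin Solomon closed form", {
  R1 <- 1.3; sg <- -0.06
  rho <- R1 + sg                       # effective auto-rate of the generator
  sys <- solomonSystem(R1 = R1, sigma = sg)
  gen <- buildGenerator(sys)
  meq <- thermalEquilibrium(sys)
  for (t in c(0.05, 0.3, 1, 2.5)) {
    M <- propagateLongitudinal(meq + c(1, 0), gen, t)
    dev <- M - meq
    expect_equal(unname(dev["B"]),
                 0.5 * (exp(-(rho - sg) * t) - exp(-(rho + sg) * t)),
                 tolerance = 1e-8)
    expect_equal(unname(dev["A"]),
                 0.5 * (exp(-(rho - sg) * t) + exp(-(rho + sg) * t)),
                 tolerance = 1e-8)
  }
})

test_that("matrix-exponential propagation matches brute-force Euler", {
  sys <- sugarSpinSystem(kex = 20, sigma = -0.1)
  gen <- buildGenerator(sys)
  meq <- thermalEquilibrium(sys)
  M0 <- meq * c(0.2, 1, 1.5)
  t <- 0.05
  exact <- unname(propagateLongitudinal(M0, gen, t))
  euler <- eulerPropagate(gen@matrix, gen@recovery, M0, t, dt = 2e-7)
  expect_lt(max(abs(euler - exact) / pmax(abs(exact), 1e-6)), 1e-6)
})

test_that("propagation respects its boundary contracts", {
  gen <- buildGenerator(sugarSpinSystem())
  meq <- thermalEquilibrium(sugarSpinSystem())
  expect_identical(unname(propagateLongitudinal(c(1, 2, 3), gen, 0)),
                   c(1, 2, 3))
  expect_error(propagateLongitudinal(meq, gen, -1), "non-negative")
  ## long-time limit relaxes to equilibrium
  Minf <- propagateLongitudinal(meq * 0, gen, 100)
  expect_equal(unname(Minf), unname(meq), tolerance = 1e-6)
})

test_that("no couplings means no cross-peaks; signs follow the convention", {
  bare <- sugarSpinSystem(kex = 0, sigma = 0)
  conv <- runConventionalNoesy(
    bare, sequenceSchedule("conventional", "OH", mixingTime = 0.1))
  expect_identical(crossAmplitude(conv, "OH", "CH"), 0)
  ## negative sigma (fast tumbling): cross-peak opposite in sign to diagonal
  fast <- sugarSpinSystem(kex = 50, sigma = -0.05)
  pa <- runConventionalNoesy(
    fast, sequenceSchedule("conventional", "OH", mixingTime = 0.1))
  expect_lt(crossAmplitude(pa, "OH", "CH"), 0)
  expect_gt(diagonalAmplitude(pa, "OH"), 0)
  ## the exposed display-sign switch flips cross-peaks only
  pa2 <- runConventionalNoesy(
    fast, sequenceSchedule("conventional", "OH", mixingTime = 0.1),
    displaySign = -1)
  expect_equal(crossAmplitude(pa2, "OH", "CH"),
               -crossAmplitude(pa, "OH", "CH"))
  expect_equal(diagonalAmplitude(pa2, "OH"), diagonalAmplitude(pa, "OH"))
})

test_that("conventional cross amplitude decreases with exchange rate", {
  sch <- sequenceSchedule("conventional", "OH", mixingTime = 0.1)
  amps <- vapply(c(10, 50, 200, 600, 1000), function(k)
    abs(crossAmplitude(runConventionalNoesy(sugarSpinSystem(kex = k), sch),
                       "OH", "CH")), numeric(1))
  expect_true(all(diff(amps) < 0))
})

test_that("selective targets must be labile pools", {
  sys <- sugarSpinSystem()
  expect_error(runConventionalNoesy(
    sys, sequenceSchedule("conventional", "CH", mixingTime = 0.1)),
    "labile")
})

test_that("single-loop L-PROSY without exchange equals conventional exactly", {
  sys <- sugarSpinSystem(kex = 0)
  conv <- runConventionalNoesy(
    sys, sequenceSchedule("conventional", "OH", mixingTime = 0.08))
  lp <- runLprosyNoesy(
    sys, sequenceSchedule("lprosy", "OH", mixingTime = 0.08, loops = 1))
  expect_identical(crossAmplitude(lp, "OH", "CH"),
                   crossAmplitude(conv, "OH", "CH"))
  expect_identical(diagonalAmplitude(lp, "OH"), diagonalAmplitude(conv, "OH"))
})

test_that("L-PROSY cross amplitude grows with loop count to a plateau", {
  sys <- sugarSpinSystem(kex = 1000, sigma = -0.05)  # k_ex >> 1/tau_loop
  amps <- vapply(c(1, 2, 5, 10, 20, 40), function(l)
    abs(crossAmplitude(runLprosyNoesy(
      sys, sequenceSchedule("lprosy", "OH", mixingTime = 0.04, loops = l)),
      "OH", "CH")), numeric(1))
  expect_true(all(diff(amps) > -1e-12))        # non-decreasing
  ## per-loop marginal gain shrinks (plateau)
  expect_lt((amps[6] - amps[5]) / 20, amps[2] - amps[1])
})

test_that("without exchange looping cannot beat one long optimized mixing", {
  sys <- sugarSpinSystem(kex = 0)
  conv <- optimizeConventionalMixing(sys, c("OH", "CH"), "noesy")
  lp <- optimizeLprosySchedule(sys, c("OH", "CH"), "noesy")
  expect_lte(lp$amplitude / conv$amplitude, 1 + 0.05)
  expect_identical(lp$loops, 1L)
})

test_that("finite water pool converges to the clamped infinite reservoir", {
  sch <- sequenceSchedule("lprosy", "OH", mixingTime = 0.03, loops = 15)
  clamped <- crossAmplitude(runLprosyNoesy(
    sugarSpinSystem(kex = 500, waterRatio = 1000), sch, clampWater = TRUE),
    "OH", "CH")
  finite <- vapply(c(1e2, 1e3, 1e5), function(w)
    crossAmplitude(runLprosyNoesy(
      sugarSpinSystem(kex = 500, waterRatio = w), sch), "OH", "CH"),
    numeric(1))
  err <- abs(finite - clamped)
  expect_true(all(diff(err) < 0))              # monotone approach
  expect_lt(err[3] / abs(clamped), 1e-3)       # recovered at 1e5
})

test_that("enhancement arithmetic and the undefined case behave", {
  sys <- sugarSpinSystem(kex = 400)
  conv <- runConventionalNoesy(
    sys, sequenceSchedule("conventional", "OH", mixingTime = 0.05))
  expect_identical(enhancement(conv, conv, "OH", "CH"), 1)
  zero <- runConventionalNoesy(
    sugarSpinSystem(kex = 0, sigma = 0),
    sequenceSchedule("conventional", "OH", mixingTime = 0.05))
  expect_error(enhancement(conv, zero, "OH", "CH"),
               class = "lprosyUndefinedEnhancement")
})

test_that("peak amplitudes stay bounded by the source equilibrium", {
  for (k in c(0, 100, 1000)) {
    pa <- runLprosyNoesy(
      sugarSpinSystem(kex = k),
      sequenceSchedule("lprosy", "OH", mixingTime = 0.05, loops = 25))
    expect_true(all(abs(peakTable(pa)$amplitude) <= 1 + 1e-9))
  }
})
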