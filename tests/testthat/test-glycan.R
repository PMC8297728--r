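test_that("Karplus curve reproduces its printed anchor values", {
  expect_equal(karplusJ(0), 0.48 + 10.18 - 0.03)
  expect_lt(karplusJ(90), 2)
  expect_lt(karplusJ(-90), 2)
  expect_equal(karplusJ(90), 0.48, tolerance = 1e-12)
  ## even function of the torsion
  om <- seq(-180, 180, by = 7.3)
  expect_equal(karplusJ(om), karplusJ(-om))
})

test_that("torsion candidates agree with a dense scan oracle and round-trip", {
  params <- karplusParams()
  iv <- torsionCandidates(0.48, 0.01, params)
  ## contains both +90 and -90
  contains <- function(iv, x) any(iv$lower <= x & iv$upper >= x)
  expect_true(contains(iv, 90))
  expect_true(contains(iv, -90))
  ## dense 0.1-degree scan oracle: membership matches
  om <- seq(-180, 179.9, by = 0.1)
  inIv <- vapply(om, contains, logical(1), iv = iv)
  inOracle <- abs(karplusJ(om, params) - 0.48) <= 0.01
  expect_identical(inIv, inOracle)
  ## round-trip: interval endpoints re-evaluate within tolerance
  for (r in seq_len(nrow(iv)))
    expect_true(all(abs(karplusJ(c(iv$lower[r], iv$upper[r]), params) -
                        0.48) <= 0.01 + 1e-9))
  ## above the curve maximum: empty set
  expect_identical(nrow(torsionCandidates(20, 0.5)), 0L)
})

test_that("effective NOE distance is the r^-6 ensemble average", {
  ## two frames at 2 and 4 Angstrom along x
  coords <- list(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 5, 0), c(0, 0, 5),
                       c(5, 5, 0), c(5, 0, 5)),
                 rbind(c(0, 0, 0), c(4, 0, 0), c(0, 5, 0), c(0, 0, 5),
                       c(5, 5, 0), c(5, 0, 5)))
  ens <- conformerEnsemble(coords)
  expect_equal(effectiveNoeDistance(ens, 1, 2),
               ((2^-6 + 4^-6) / 2)^(-1 / 6), tolerance = 1e-12)
  expect_equal(round(effectiveNoeDistance(ens, 1, 2), 2), 2.24)
  ## constant distance is returned unchanged
  one <- conformerEnsemble(coords[c(1, 1, 1)])
  expect_equal(effectiveNoeDistance(one, 1, 2), 2)
  expect_error(effectiveNoeDistance(ens, 1, "nope"), "matches no atom")
})

test_that("effective NOE distance obeys power-mean bounds and frame order", {
  ens <- generateSyntheticEnsemble(40, 8, mode = "uniform-torsion",
                                   noise = 0.15, seed = 11)
  d <- vapply(seq_len(nFrames(ens)), function(f) {
    x <- frameCoords(ens, f); sqrt(sum((x[2, ] - x[7, ])^2))
  }, numeric(1))
  eff <- effectiveNoeDistance(ens, 2, 7)
  expect_gte(eff, min(d))
  expect_lte(eff, max(d))
  ## heavily weighted toward the shortest distances
  expect_lt(eff, mean(d))
  ## permutation invariance over frames
  perm <- conformerEnsemble(
    ens@coords[sample(nFrames(ens)), , , drop = FALSE], atomTable(ens))
  expect_equal(effectiveNoeDistance(perm, 2, 7), eff, tolerance = 1e-12)
})

test_that("multi-proton selections use the per-frame shortest distance", {
  coords <- list(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 2.5, 0), c(1, 1, 1),
                       c(4, 4, 4), c(-3, 0, 0)))
  ens <- conformerEnsemble(coords)
  ## pair {2,3} versus atom 1: shortest is atom 3 at 2.5 A
  expect_equal(effectiveNoeDistance(ens, 1, c(2, 3)), 2.5)
})

test_that("hydrogen-bond detection honors its inclusive geometric cutoffs", {
  mk <- function(dDA, theta) {
    ## D at origin, H on x axis at 1 A; place A so that angle D-H-A = theta
    ## and |D-A| = dDA
    th <- theta * pi / 180
    ## A = H + r*(cos(pi - th'), ...): choose direction from H making the
    ## required angle with H->D = (-1, 0, 0)
    ## unit vector at angle `th` from (-1,0,0) in the xy plane:
    u <- c(-cos(th), sin(th), 0)
    ## find r > 0 with |D - (H + r u)| = dDA
    H <- c(1, 0, 0)
    r <- stats::uniroot(function(r) sqrt(sum((H + r * u)^2)) - dDA,
                        c(1e-6, 10))$root
    rbind(D = c(0, 0, 0), H = H, A = H + r * u,
          X1 = c(0, 6, 0), X2 = c(0, 0, 6), X3 = c(6, 6, 6))
  }
  donors <- data.frame(donor = 1, hydrogen = 2)
  occ <- function(dDA, theta) {
    ens <- conformerEnsemble(list(mk(dDA, theta)))
    detectHbonds(ens, donors, acceptors = 3)$occupancy
  }
  expect_identical(occ(2.8, 170), 1)   # detected
  expect_identical(occ(3.2, 180), 0)   # too far despite linear
  expect_identical(occ(2.8, 120), 0)   # too bent
  expect_identical(occ(3.0, 135), 1)   # boundary: inclusive
})

test_that("tightening hydrogen-bond criteria never raises occupancy", {
  ens <- generateSyntheticEnsemble(60, 8, mode = "uniform-torsion",
                                   noise = 0.3, seed = 4)
  donors <- data.frame(donor = 1, hydrogen = 2)
  loose <- detectHbonds(ens, donors, 5, hBondCriteria(3.5, 120))$occupancy
  tight <- detectHbonds(ens, donors, 5, hBondCriteria(3.0, 135))$occupancy
  expect_true(all(tight <= loose))
  expect_true(all(c(loose, tight) >= 0 & c(loose, tight) <= 1))
  expect_error(detectHbonds(ens, data.frame(donor = 1, hydrogen = NA), 5),
               "hydrogen")
})

test_that("Arrhenius scaling has its limit and monotonicity properties", {
  expect_identical(arrheniusScale(100, 278, 278, ea = 30), 100)
  expect_identical(arrheniusScale(100, 263, 310, ea = 0), 100)
  k <- arrheniusScale(100, 263.15, c(263.15, 278.15, 288.15, 310.15),
                      ea = 25)
  expect_true(all(diff(k) > 0))
  expect_error(arrheniusScale(1, -3, 300, 10), "temperatures")
})

test_that("temperature coefficients come out in ppb/K", {
  expect_equal(tempCoefficient(c(6.00, 5.95), c(278, 288))$slope, -5)
  expect_equal(tempCoefficient(rep(7.1, 4), c(270, 280, 290, 300))$slope, 0)
  expect_error(tempCoefficient(c(1, 2), c(300, 300)), "degenerate")
  ## noisy synthetic line: slope recovered within 2 standard errors
  set.seed(42)
  temps <- seq(268, 308, length.out = 6)
  shifts <- 6.2 - 8e-3 * (temps - 268) + rnorm(6, sd = 2e-3)  # -8 ppb/K
  fit <- tempCoefficient(shifts, temps)
  expect_lt(abs(fit$slope - (-8)), 2 * fit$se)
})

test_that("Stejskal-Tanner fits recover D and the intercept", {
  gamma <- 26752.218744
  delta <- 0.002; Delta <- 0.1
  g <- seq(2, 55, length.out = 8)
  b <- gamma^2 * g^2 * delta^2 * (Delta - delta / 3)
  D <- 3e-6
  areas <- 12 * exp(-D * b)
  fit <- stejskalTannerFit(areas, g, delta, Delta)
  expect_equal(fit$D, D, tolerance = 1e-4)
  expect_equal(fit$A0, 12, tolerance = 1e-4)
  ## g = 0 point pins the intercept exactly
  fit0 <- stejskalTannerFit(c(12, areas), c(0, g), delta, Delta)
  expect_equal(fit0$A0, 12, tolerance = 1e-8)
  ## non-decaying data are a classed error
  expect_error(stejskalTannerFit(rev(areas), g, delta, Delta),
               class = "lprosyNonDecaying")
  ## diffusion ratio contract: D_ref/D_analyte = Rh_analyte/Rh_ref
  expect_equal(hydrodynamicRadiusRatio(5.2e-6, fit$D), 5.2e-6 / 3e-6,
               tolerance = 1e-4)
})

test_that("restraint tables apply the +-1 A and +-30 degree windows", {
  rt <- buildRestraints(
    noe = data.frame(atomA = "IIOH7", atomB = "IIIH3", distance = 3.2),
    torsions = data.frame(atoms = c("H7-C7-C8-H8", "H6-C6-C7-H7"),
                          target = c(180, 90),
                          degenerate = c(FALSE, TRUE)))
  expect_equal(rt@noe$lower, 2.2)
  expect_equal(rt@noe$upper, 4.2)
  ## 180-degree torsion window wraps into [-180, 180)
  t180 <- rt@torsions[rt@torsions$atoms == "H7-C7-C8-H8", ]
  expect_equal(t180$lower, 150)
  expect_equal(t180$upper, -150)
  ## degenerate +-90 torsion emits both branches
  t90 <- rt@torsions[rt@torsions$atoms == "H6-C6-C7-H7", ]
  expect_identical(nrow(t90), 2L)
  expect_setequal(t90$target, c(90, -90))
  expect_error(buildRestraints(noe = data.frame(atomA = "a", atomB = "b",
                                                distance = -1)), "> 0")
})
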