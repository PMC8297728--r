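rotationMatrix <- function(ax, th) {
  ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

test_that("Kabsch superposition is exact under rigid motion", {
  set.seed(1)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(kabschSuperpose(A, A)$rmsd, 0, tolerance = 1e-10)
  R <- rotationMatrix(c(1, 2, 0.5), 1.1)
  B <- A %*% R + matrix(c(3, -1, 2), 10, 3, byrow = TRUE)
  fit <- kabschSuperpose(A, B)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$Bfit, A, tolerance = 1e-8)
  ## degenerate geometry is refused
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabschSuperpose(line, line), "degenerate")
  expect_error(kabschSuperpose(A[1:2, ], A[1:2, ]), ">= 3")
})

test_that("Kabsch RMSD matches the quaternion-eigenvalue oracle", {
  set.seed(7)
  for (i in 1:20) {
    A <- matrix(rnorm(30), 10, 3)
    B <- matrix(rnorm(30), 10, 3)
    expect_equal(kabschSuperpose(A, B)$rmsd, quaternionRmsd(A, B),
                 tolerance = 1e-8)
  }
})

test_that("2D-RMSD maps are symmetric, zero-diagonal and block-structured", {
  still <- generateSyntheticEnsemble(6, 8, mode = "single-well", noise = 0,
                                     seed = 1)
  expect_identical(max(abs(rmsd2dMap(still))), 0)
  ens <- generateSyntheticEnsemble(40, 10, mode = "two-state", noise = 0.15,
                                   mixture = 0.6, seed = 3)
  M <- rmsd2dMap(ens)
  expect_equal(M, t(M))
  expect_identical(max(abs(diag(M))), 0)
  ## between-state RMSD exceeds within-state RMSD
  st <- attr(ens, "state")
  within <- M[st == 1, st == 1]
  between <- M[st == 1, st == 2]
  expect_gt(min(between), max(within))
  ## striding subsets the frames
  M2 <- rmsd2dMap(ens, stride = 2L)
  expect_identical(attr(M2, "frames"), seq(1L, 40L, by = 2L))
  expect_error(rmsd2dMap(ens, subset = integer()), "empty")
})

test_that("cutoff clustering resolves the constructed two-state mixture", {
  ens <- generateSyntheticEnsemble(80, 10, mode = "two-state", noise = 0.1,
                                   mixture = 0.7, seed = 9)
  M <- rmsd2dMap(ens)
  rep <- clusterByCutoff(M, cutoff = 2)
  expect_identical(length(rep@fractions), 2L)
  expect_equal(sum(rep@fractions), 1)
  ## cluster membership reproduces the generating state labels: every
  ## cluster is pure (maps to exactly one state)
  st <- attr(ens, "state")
  tab <- table(rep@assignments, st)
  expect_true(all(rowSums(tab > 0) == 1))
  ## limits
  expect_identical(length(clusterByCutoff(M, cutoff = 100)@fractions), 1L)
  allSame <- matrix(0, 5, 5)
  one <- clusterByCutoff(allSame, cutoff = 2)
  expect_equal(unname(one@fractions), 1)
  expect_error(clusterByCutoff(M, cutoff = -1), "> 0")
  expect_error(clusterByCutoff(M[1:3, 1:4, drop = FALSE], 2), "symmetric")
})

test_that("clustering is invariant to frame relabeling", {
  ens <- generateSyntheticEnsemble(30, 10, mode = "two-state", noise = 0.1,
                                   mixture = 0.5, seed = 21)
  M <- rmsd2dMap(ens)
  r1 <- clusterByCutoff(M, 2)
  set.seed(5)
  perm <- sample(nrow(M))
  r2 <- clusterByCutoff(M[perm, perm], 2)
  ## same partition up to label names: co-membership matrices agree
  co1 <- outer(r1@assignments, r1@assignments, "==")
  a2 <- r2@assignments[order(perm)]  # back to original frame order
  co2 <- outer(a2, a2, "==")
  expect_identical(co1, co2)
  expect_equal(sort(unname(r1@fractions)), sort(unname(r2@fractions)))
})

test_that("averaged reference models recover mixture fractions", {
  ## a block trajectory: 42 frames in conformation A then 18 in B (70/30),
  ## so that an 11-frame window sits inside one conformational region
  blockA <- generateSyntheticEnsemble(42, 10, mode = "two-state",
                                      noise = 0.1, mixture = 1, seed = 13)
  blockB <- generateSyntheticEnsemble(18, 10, mode = "two-state",
                                      noise = 0.1, mixture = 0, seed = 14)
  arr <- array(0, c(60, 10, 3))
  arr[1:42, , ] <- blockA@coords
  arr[43:60, , ] <- blockB@coords
  ens <- conformerEnsemble(arr)
  rep <- representativeModels(ens, c(21, 51), window = 11L, cutoff = 2)
  expect_identical(dim(rep@representatives[[1]]), c(10L, 3L))
  fr <- unname(rep@fractions)
  expect_equal(fr, c(42, 18) / 60, tolerance = 1e-9)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  ## default window is centered and odd; bounds are enforced
  expect_error(representativeModels(ens, anchors = 2, window = 11L),
               "bounds")
  expect_error(representativeModels(ens, anchors = 30, window = 10L), "odd")
  ## constant trajectory: the averaged reference equals any frame
  still <- generateSyntheticEnsemble(21, 8, mode = "single-well", noise = 0,
                                     seed = 2)
  r0 <- representativeModels(still, 11, window = 11L, cutoff = 2)
  expect_equal(unname(r0@fractions), 1)
  fit <- kabschSuperpose(frameCoords(still, 1), r0@representatives[[1]])
  expect_lt(fit$rmsd, 1e-10)
})

test_that("adding anchors never shrinks the represented fraction", {
  ens <- generateSyntheticEnsemble(61, 10, mode = "two-state", noise = 0.1,
                                   mixture = 0.7, seed = 13)
  st <- attr(ens, "state")
  aA <- which(st == 1)[which(st == 1) %in% 6:55][1]
  aB <- which(st == 2)[which(st == 2) %in% 6:55][1]
  oneAnchor <- representativeModels(ens, aA, window = 11L, cutoff = 1)
  twoAnchors <- representativeModels(ens, c(aA, aB), window = 11L,
                                     cutoff = 1)
  expect_gte(sum(twoAnchors@fractions), sum(oneAnchor@fractions))
})

test_that("torsion population maps are normalized 5-degree histograms", {
  ens <- generateSyntheticEnsemble(400, 8, mode = "uniform-torsion",
                                   noise = 0, seed = 17)
  tp <- torsionPopulationMap(ens, c(2, 3, 4, 5), c(3, 4, 5, 6), bin = 5)
  expect_identical(length(tp$marginalA), 72L)
  expect_equal(sum(tp$marginalA), 1)
  expect_equal(sum(tp$marginalB), 1)
  expect_equal(sum(tp$joint), 1)
  ## uniformly drawn central torsion: flat marginal (each bin ~ 1/72)
  expect_lt(max(abs(tp$marginalA - 1 / 72)), 5 * sqrt((1 / 72) / 400))
  expect_error(torsionPopulationMap(ens, 1:4, 2:5, bin = 7), "divide")
  fe <- torsionPopulationMap(ens, 2:5, 3:6, bin = 45, freeEnergy = TRUE)
  expect_true(all(fe$freeEnergy >= 0 | is.infinite(fe$freeEnergy)))
})

test_that("torsion trajectories follow the IUPAC sign convention", {
  ## butane-like chain: trans = 180, gauche+ = +60
  base <- rbind(c(0, 1, 0), c(0, 0, 0), c(1.5, 0, 0), c(1.5, -1, 0))
  mk <- function(theta) {
    R <- rotationMatrix(c(1, 0, 0), theta * pi / 180)
    x <- base
    x[4, ] <- (base[4, ] - base[3, ]) %*% t(R) + base[3, ]
    conformerEnsemble(list(rbind(x, c(3, 3, 3), c(-3, 3, 3))))
  }
  expect_equal(torsionTrajectory(mk(0), 1:4), -180, tolerance = 1e-8)
  for (th in c(-120, -60, 60, 120)) {
    got <- torsionTrajectory(mk(th), 1:4)
    expect_equal(abs(got), 180 - abs(th), tolerance = 1e-6)
  }
})
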