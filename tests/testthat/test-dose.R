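test_that("resampling is identity-safe and linear", {
  g <- uniformGrid(10)
  expect_identical(resampleGrid(g, 1.5), g)
  expect_error(resampleGrid(g, -1), "spacing")

  # constant field stays constant at any spacing
  r <- resampleGrid(g, 0.7)
  expect_true(all(abs(doseValues(r) - 10) < 1e-12))

  # 1D ramp 0 -> 10 across two voxels: midpoint interpolates to 5
  ramp <- doseGrid(array(c(0, 10), c(2, 1, 1)), spacing = 2)
  fine <- resampleGrid(ramp, 1)
  expect_equal(as.vector(doseValues(fine)), c(0, 5, 10))
})

test_that("plan sums behave like voxel-wise addition", {
  set.seed(3)
  a <- doseGrid(array(runif(64, 0, 20), c(4, 4, 4)), 1.5, label = "a")
  zero <- doseGrid(array(0, c(4, 4, 4)), 1.5)
  expect_equal(doseValues(planSum(a, zero)), doseValues(a))
  b <- doseGrid(array(runif(64, 0, 20), c(4, 4, 4)), 1.5, label = "b")
  cc <- doseGrid(array(runif(64, 0, 20), c(4, 4, 4)), 1.5, label = "c")
  expect_identical(doseValues(planSum(a, b)), doseValues(planSum(b, a)))
  expect_identical(doseValues(planSum(planSum(a, b), cc)),
                   doseValues(planSum(a, planSum(b, cc))))
  expect_true(all(doseValues(planSum(uniformGrid(10), uniformGrid(10))) == 20))
  # summing marks the grid composite
  expect_true(is.na(nFractions(planSum(a, b))))

  far <- doseGrid(array(1, c(4, 4, 4)), 1.5, origin = c(100, 0, 0))
  expect_error(planSum(a, far), "lattice|extent")
})

test_that("DVHs conserve volume and report correct quantiles", {
  g <- doseGrid(array(10, c(2, 2, 2)), 1.5)
  mask <- array(TRUE, c(2, 2, 2))
  dvh <- computeDVH(g, mask, binWidth = 0.1)
  expect_equal(sum(dvh@volume > 0), 1L)
  expect_equal(dvhTotalVolume(dvh), 8 * 0.15^3) # 0.027 cm3
  expect_equal(dvhMids(dvh)[which(dvh@volume > 0)], 10, tolerance = 0.05)

  # mass conservation to machine precision
  expect_equal(dvhTotalVolume(dvh), maskVolume(mask, 1.5), tolerance = 1e-14)

  cum <- cumulativeDVH(dvh)
  expect_equal(cum$volume[1], dvhTotalVolume(dvh))
  expect_true(all(diff(cum$volume) <= 0))
  expect_equal(dvhVolumeAtDose(dvh, max(dvh@breaks)), 0)

  # two voxels at 10 and 20 Gy: V(15 Gy) is half the structure volume
  g2 <- doseGrid(array(c(10, 20), c(2, 1, 1)), 1.5)
  dvh2 <- computeDVH(g2, array(TRUE, c(2, 1, 1)), 0.1)
  expect_equal(dvhVolumeAtDose(dvh2, 15), dvhTotalVolume(dvh2) / 2)

  expect_error(computeDVH(g, array(FALSE, c(2, 2, 2)), structure = "skin"),
               "skin")
})

test_that("resample-then-DVH of a uniform field keeps the dose bin", {
  g <- uniformGrid(12.34, dims = c(9, 9, 9))
  r <- resampleGrid(g, 2)
  dvhG <- computeDVH(g, array(TRUE, dim(doseValues(g))), 0.1)
  dvhR <- computeDVH(r, array(TRUE, dim(doseValues(r))), 0.1)
  expect_equal(dvhMids(dvhG)[dvhG@volume > 0], dvhMids(dvhR)[dvhR@volume > 0])
})

test_that("EQD2 conversion reproduces the standard worked values", {
  expect_equal(eqd2(30, 10, 10.5), 32.4)
  expect_equal(eqd2(15, 1, 10.5), 30.6)
  # 2 Gy per fraction is the fixed point for any alpha/beta
  for (ab in c(3.5, 8.8, 10.5))
    expect_equal(eqd2(20, 10, ab), 20)
  expect_error(eqd2(30, 10, 0), "alpha/beta")
})

test_that("EQD2 is monotone and ordered around the 2 Gy fixed point", {
  D <- seq(0.5, 80, by = 0.5)
  e <- eqd2(D, 10, 10.5)
  expect_true(all(diff(e) > 0))
  d <- D / 10
  expect_true(all(e[d > 2] > D[d > 2]))
  expect_true(all(e[d < 2] < D[d < 2]))
})

test_that("grid and DVH EQD2 methods agree and tag the scale", {
  set.seed(5)
  g <- doseGrid(array(runif(27, 0, 18), c(3, 3, 3)), 1.5, nFractions = 3L)
  ge <- eqd2(g, alphaBeta = 10.5)
  expect_equal(doseScale(ge), "EQD2")
  expect_equal(doseValues(ge), eqd2(doseValues(g), 3, 10.5))
  expect_error(eqd2(ge, 3, 10.5), "EQD2")

  mask <- array(TRUE, c(3, 3, 3))
  dvh <- computeDVH(g, mask, 0.05)
  dvhE <- eqd2(dvh, 3, 10.5)
  expect_equal(dvhE@scale, "EQD2")
  expect_equal(sum(dvhE@volume), sum(dvh@volume))
  # bin edges follow the monotone dose mapping
  expect_equal(dvhE@breaks, eqd2(dvh@breaks, 3, 10.5))
})

test_that("plan-sum EQD2 converts course by course", {
  boost <- uniformGrid(15, nFractions = 1L)   # 15 Gy x 1
  standard <- uniformGrid(30, nFractions = 10L) # 3 Gy x 10
  total <- eqd2Sum(list(boost, standard), 10.5)
  expect_equal(doseValues(total)[1, 1, 1], 30.6 + 32.4)
  # converting the summed physical grid is refused
  expect_error(eqd2(planSum(boost, standard), alphaBeta = 10.5), "composite")
})
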