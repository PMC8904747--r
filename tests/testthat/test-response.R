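test_that("LQ survival matches hand arithmetic, with OER as dose modifier", {
  p <- radiosensParams(alpha = 0.3, beta = 0.03)
  expect_equal(lqSurvival(0, 1, p), 1)
  expect_equal(lqSurvival(2, 1, p), exp(-0.72))
  p2 <- radiosensParams(alpha = 0.3, beta = 0.03, oer = 2)
  expect_equal(lqSurvival(2, 1, p2), exp(-0.33))
  expect_gt(lqSurvival(2, 1, p2), lqSurvival(2, 1, p)) # hypoxia protects
  expect_error(radiosensParams(alpha = 0.3, beta = 0.03, oer = 0.5), "OER")
})

test_that("Poisson TCP anchors its parameters exactly", {
  expect_equal(poissonTCP(51.77), 0.5)
  expect_lt(poissonTCP(0), 1e-6)
  # normalized slope at TCD50 equals gamma by construction
  h <- 0.01
  slope <- 51.77 * (poissonTCP(51.77 + h) - poissonTCP(51.77 - h)) / (2 * h)
  expect_equal(slope, 2.28, tolerance = 1e-3)
  # Kallman convention keeps the 50% anchor but changes the slope scale
  expect_equal(poissonTCP(51.77, form = "kallman"), 0.5)
  expect_false(isTRUE(all.equal(poissonTCP(60, form = "kallman"),
                                poissonTCP(60))))
})

test_that("heterogeneous TCP is the volume-weighted geometric combination", {
  # half volume at TCD50, half at saturation: TCP = sqrt(0.5)
  dvh <- dvhFromLevels(c(51.77, 200), c(50, 50))
  expect_equal(poissonTCP(dvh), sqrt(0.5), tolerance = 1e-6)

  # voxel-product on a uniform grid equals the closed form to < 1e-10
  g <- doseGrid(array(47.3, c(5, 5, 5)), 1.5, scale = "EQD2")
  mask <- array(TRUE, c(5, 5, 5))
  expect_lt(abs(poissonTCP(g, mask = mask) - poissonTCP(47.3)), 1e-10)

  # physical-scale input is a scale error
  gp <- doseGrid(array(47.3, c(2, 2, 2)), 1.5)
  expect_error(poissonTCP(gp, mask = array(TRUE, c(2, 2, 2))), "EQD2")
})

test_that("gEUD reproduces worked values and its limit behavior", {
  dvh <- dvhFromLevels(c(60, 0), c(50, 50))
  expect_equal(gEUD(dvh, 0.1), 60 * 0.5^0.1, tolerance = 1e-6)
  expect_equal(gEUD(dvh, 0.1), 55.98, tolerance = 1e-3)

  # uniform dose is a fixed point for every n
  u <- uniformDVH(43.21)
  for (n in c(0.01, 0.1, 0.5, 1)) expect_equal(gEUD(u, n), 43.21,
                                               tolerance = 1e-9)

  # n -> 0 approaches the maximum dose
  two <- dvhFromLevels(c(60, 30), c(50, 50))
  expect_gte(gEUD(two, 0.01), 59)

  # gEUD sits between min and max and decreases with n under cold spots
  ns <- c(0.05, 0.1, 0.3, 0.6, 1)
  gs <- vapply(ns, function(n) gEUD(two, n), numeric(1))
  expect_true(all(gs <= 60 & gs >= 30))
  expect_true(all(diff(gs) < 0))

  expect_error(gEUD(two, 1.5), "exponent")
})

test_that("LKB NTCP anchors TD50 and matches the quadrature oracle", {
  pms <- defaultParams()
  expect_equal(lkbNTCP(uniformDVH(68), pms$ntcp$chest_wall), 0.5)
  expect_equal(lkbNTCP(uniformDVH(70), pms$ntcp$skin), 0.5)
  expect_lt(lkbNTCP(uniformDVH(0.001), pms$ntcp$chest_wall), 1e-4)

  # worked two-bin example: gEUD 55.98 -> t = -0.8417 -> NTCP 0.200
  dvh <- dvhFromLevels(c(60, 0), c(50, 50))
  expect_equal(lkbNTCP(dvh, pms$ntcp$chest_wall), 0.200, tolerance = 1e-3)

  # independent oracle: numerical integration of the normal density
  for (d in c(40, 55.98, 68, 80)) {
    t <- (gEUD(uniformDVH(d), 0.1) - 68) / (0.21 * 68)
    ref <- integrate(dnorm, -Inf, t, rel.tol = 1e-12)$value
    expect_lt(abs(lkbNTCP(uniformDVH(d), pms$ntcp$chest_wall) - ref), 1e-8)
  }

  # physical-scale DVH is rejected
  phys <- computeDVH(uniformGrid(50), array(TRUE, c(4, 4, 4)))
  expect_error(lkbNTCP(phys, pms$ntcp$chest_wall), "EQD2")
})

test_that("voxel-wise and DVH LKB routes agree on heterogeneous dose", {
  set.seed(11)
  vals <- array(runif(343, 30, 75), c(7, 7, 7))
  g <- doseGrid(vals, 1.5, scale = "EQD2")
  mask <- array(runif(343) < 0.6, c(7, 7, 7))
  pms <- defaultParams()
  pGrid <- lkbNTCP(g, pms$ntcp$chest_wall, mask = mask)
  pDvh <- lkbNTCP(computeDVH(g, mask, 0.01), pms$ntcp$chest_wall)
  expect_equal(pGrid, pDvh, tolerance = 1e-3)
})

test_that("TCP and NTCP are monotone under voxel-wise dose increase", {
  set.seed(23)
  pms <- defaultParams()
  for (rep in 1:8) {
    base <- runif(40, 10, 70)
    up <- base + runif(40, 0, 15)
    v <- runif(40, 0.5, 2)
    dvhLo <- dvhFromLevels(base, v)
    dvhHi <- dvhFromLevels(up, v)
    expect_gte(poissonTCP(dvhHi), poissonTCP(dvhLo))
    expect_gte(lkbNTCP(dvhHi, pms$ntcp$skin), lkbNTCP(dvhLo, pms$ntcp$skin))
  }
})

test_that("dose bisection finds probability crossings", {
  d50 <- doseAtProbability(function(D) poissonTCP(uniformDVH(D)))
  expect_lt(abs(d50 - 51.77), 0.01)
  expect_error(doseAtProbability(function(D) 0 * D), "bracket")
})

test_that("OAR restriction keeps the exposed region only", {
  g <- doseGrid(array(c(0, 1, 3, 5), c(4, 1, 1)), 1.5)
  mask <- array(TRUE, c(4, 1, 1))
  expect_equal(sum(restrictOARMask(mask, g, 2)), 2L)
  expect_identical(restrictOARMask(mask, g, 0), mask)
  # an empty restriction falls back to the full organ
  expect_identical(restrictOARMask(mask, g, 100), mask)
})
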