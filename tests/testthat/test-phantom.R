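test_that("voxelized subvolumes reproduce the requested partition", {
  ph <- defaultTestPhantom()
  s <- gridSpacing(ph)
  vols <- vapply(c(necrotic = "necrotic", hypoxic = "hypoxic",
                   normoxic = "normoxic", gtv = "gtv"),
                 function(nm) maskVolume(structureMask(ph, nm), s), numeric(1))
  target <- c(necrotic = 86.8, hypoxic = 13, normoxic = 71.5, gtv = 171.3)
  expect_true(all(abs(vols - target) / target < 0.02))

  # mask identity: the three compartments partition the GTV exactly
  nec <- structureMask(ph, "necrotic")
  hyp <- structureMask(ph, "hypoxic")
  nor <- structureMask(ph, "normoxic")
  expect_false(any(nec & hyp) || any(nec & nor) || any(hyp & nor))
  expect_identical(nec | hyp | nor, structureMask(ph, "gtv"))
  expect_equal(sum(vols[1:3]), vols[["gtv"]])
})

test_that("analytic sphere radius matches hand arithmetic", {
  expect_equal(sphereRadiusForVolume(86.8), 2.747, tolerance = 5e-4)
  # solved core radius is within half a voxel diagonal of the analytic one
  ph <- defaultTestPhantom()
  expect_lt(abs(ph@radii[["necrotic"]] - 27.47), 1.3)
})

test_that("zero hypoxic margin degenerates to an empty ring", {
  ph <- coarseTestPhantom(hypoxicMargin = 0)
  expect_equal(sum(structureMask(ph, "hypoxic")), 0)
  expect_identical(structureMask(ph, "normoxic"),
                   structureMask(ph, "gtv") & !structureMask(ph, "necrotic"))
})

test_that("mask expansion is an isotropic Euclidean dilation", {
  ph <- defaultTestPhantom()
  s <- gridSpacing(ph)
  nec <- structureMask(ph, "necrotic")
  expect_identical(expandMask(nec, 0, s), nec)
  expect_error(expandMask(nec, -1, s), "margin")

  # sphere of r = 2.747 cm expanded 2 mm: analytic volume 107.2 cm3, up to
  # a one-voxel surface shell of voxelization uncertainty
  vol <- maskVolume(expandMask(nec, 2, s), s)
  rOut <- 2.947 # cm
  shellTol <- 4 * pi * rOut^2 * s[1] / 10
  expect_lt(abs(vol - 107.2), shellTol)

  # CTV strictly contains GTV
  gtv <- structureMask(ph, "gtv")
  ctv <- structureMask(ph, "ctv")
  expect_false(any(gtv & !ctv))
  expect_gt(sum(ctv), sum(gtv))
})

test_that("distance transform matches brute force on a small mask", {
  set.seed(7)
  dims <- c(7, 6, 5)
  mask <- array(runif(prod(dims)) < 0.15, dims)
  mask[4, 3, 2] <- TRUE
  sp <- c(1.5, 2, 1)
  d <- distanceToMask(mask, sp)
  pts <- which(mask, arr.ind = TRUE)
  brute <- array(Inf, dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3]))
      brute[i, j, k] <- sqrt(min(colSums((t(pts) - c(i, j, k))^2 * sp^2)))
  expect_equal(d, brute, tolerance = 1e-12)
})

test_that("vertices sit astride the core boundary at the required separation", {
  ph <- defaultTestPhantom()
  expect_length(ph@vertices, 5L)
  cen <- attr(ph@vertices, "centers")
  sep <- as.matrix(dist(cen))
  expect_true(all(sep[upper.tri(sep)] >= 20)) # mm, asserted exactly
  nec <- structureMask(ph, "necrotic")
  hyp <- structureMask(ph, "hypoxic")
  gtv <- structureMask(ph, "gtv")
  for (v in ph@vertices) {
    expect_gt(sum(v & nec), 0)
    expect_gt(sum(v & hyp), 0)
    expect_false(any(v & !gtv))
  }
})

test_that("single-vertex placement needs no separation constraint", {
  ph <- coarseTestPhantom(vertexCount = 1L)
  expect_length(ph@vertices, 1L)
  expect_gt(sum(structureMask(ph, "vertex1")), 0)
})

test_that("infeasible vertex packing raises a placement error", {
  expect_error(buildPhantom(phantomSpec(spacing = 3, vertexCount = 40L)),
               "placement")
})

test_that("phantom construction is deterministic given the seed", {
  a <- coarseTestPhantom(seed = 11L)
  b <- coarseTestPhantom(seed = 11L)
  expect_identical(a@masks, b@masks)
  expect_identical(attr(a@vertices, "centers"), attr(b@vertices, "centers"))
  c <- coarseTestPhantom(seed = 12L)
  expect_false(identical(attr(a@vertices, "centers"),
                         attr(c@vertices, "centers")))
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantomSpec(gtvVolume = 50), "gtvVolume")
  expect_error(phantomSpec(vertexMinSep = 0.5), "overlap")
  expect_error(phantomSpec(hypoxicVolume = 100), "gtvVolume")
})

test_that("dose synthesis honors steps, null plans and target coverage", {
  ph <- defaultTestPhantom()
  zero <- synthesizeDose(ph, "gtv", 0, 1L, sigma = 3)
  expect_true(all(doseValues(zero) == 0))

  step <- synthesizeDose(ph, "gtv", 15, 1L, sigma = 0)
  gtv <- structureMask(ph, "gtv")
  expect_true(all(doseValues(step)[gtv] == 15))
  expect_true(all(doseValues(step)[!gtv] == 0))

  expect_error(synthesizeDose(ph, "nonesuch", 15), "nonesuch")

  # lattice vertex course: minimum dose over every vertex >= 14.85 Gy
  gD <- synthesizeDose(ph, "vertices", 15, 1L, sigma = 3,
                       technique = "lattice")
  for (i in seq_along(ph@vertices))
    expect_gte(min(doseValues(gD)[ph@vertices[[i]]]), 14.85)

  # conformal coverage calibration: prescription covers the target, dose
  # never exceeds the prescription
  gB <- synthesizeDose(ph, "gtv", 15, 1L, sigma = 3, technique = "conformal")
  expect_gte(min(doseValues(gB)[gtv]), 0.99 * 15)
  expect_lte(max(doseValues(gB)), 15 + 1e-9)
})

test_that("Gaussian smoothing conserves the field integral away from edges", {
  ph <- defaultTestPhantom()
  nec <- structureMask(ph, "necrotic") # deep interior structure
  step <- array(15 * as.numeric(nec), dim(nec))
  blurred <- gaussBlur3d(step, gridSpacing(ph), 3)
  expect_lt(abs(sum(blurred) - sum(step)) / sum(step), 0.005)
  expect_true(all(blurred >= 0))
})
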