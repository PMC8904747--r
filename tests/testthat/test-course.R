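test_that("compartment states initialize from the phantom", {
  ph <- coarseTestPhantom()
  st <- compartmentStates(ph, clonogenDensity = 1e7, oerHypoxic = 2)
  expect_setequal(st$name, c("normoxic", "hypoxic", "necrotic"))
  expect_equal(st$count, st$density * st$volume)
  expect_equal(st$count[st$name == "necrotic"], 0) # photopenic core
  expect_equal(st$oer[st$name == "hypoxic"], 2)
})

test_that("compartment mean doses are arithmetic means over the masks", {
  ph <- coarseTestPhantom()
  g <- doseGrid(array(15, dim(structureMask(ph, "gtv"))), gridSpacing(ph),
                origin = ph@origin)
  m <- compartmentMeanDoses(g, ph)
  expect_equal(unname(m), rep(15, 3))

  set.seed(2)
  vals <- array(runif(length(doseValues(g)), 0, 20), dim(doseValues(g)))
  g2 <- doseGrid(vals, gridSpacing(ph), origin = ph@origin)
  m2 <- compartmentMeanDoses(g2, ph)
  expect_equal(m2[["hypoxic"]], mean(vals[structureMask(ph, "hypoxic")]))
})

test_that("null treatment leaves counts unchanged", {
  ph <- coarseTestPhantom()
  st <- compartmentStates(ph)
  sched <- courseSchedule()
  rs <- radiosensParams(alpha = 0.25, alphaBeta = 10.5)
  out <- simulateCourse(st, sched, phase1Dose = 0, phase2Dose = 0, rs)
  expect_equal(out$finalCounts, setNames(st$count, st$name))
  expect_equal(nrow(out$trajectory), 12L) # 1 + 10 fractions + initial row
})

test_that("regrowth-off course equals the closed-form survival product", {
  ph <- coarseTestPhantom()
  st <- compartmentStates(ph)
  rs <- radiosensParams(alpha = 0.25, alphaBeta = 10.5)
  p1 <- c(normoxic = 10.44, hypoxic = 15, necrotic = 12)
  p2 <- c(normoxic = 3, hypoxic = 3, necrotic = 3)
  out <- simulateCourse(st, courseSchedule(), p1, p2, rs)
  for (i in seq_len(nrow(st))) {
    pOer <- radiosensParams(alpha = 0.25, alphaBeta = 10.5, oer = st$oer[i])
    sf1 <- lqSurvival(p1[[st$name[i]]], 1, pOer)
    sf2 <- lqSurvival(p2[[st$name[i]]], 1, pOer)
    expect_equal(out$finalCounts[[st$name[i]]],
                 st$count[i] * sf1 * sf2^10, tolerance = 1e-12)
    if (st$count[i] > 0)
      expect_equal(out$phase1Survival[[st$name[i]]], sf1, tolerance = 1e-12)
  }
})

test_that("exponential regrowth doubles per doubling time", {
  ph <- coarseTestPhantom()
  st <- compartmentStates(ph)
  rs <- radiosensParams(alpha = 0.25, alphaBeta = 10.5)
  sched <- courseSchedule(regrowth = "exponential", doublingTime = 1)
  out <- simulateCourse(st, sched, phase1Dose = 0, phase2Dose = 0, rs)
  # 11 fractions -> 10 inter-fraction daily intervals -> 2^10
  expect_equal(out$finalCounts[["normoxic"]],
               st$count[st$name == "normoxic"] * 1024)
})

test_that("survival responds monotonically to dose and OER", {
  ph <- coarseTestPhantom()
  st <- compartmentStates(ph)
  rs <- radiosensParams(alpha = 0.25, alphaBeta = 10.5)
  doses <- c(2, 5, 10, 15)
  finals <- vapply(doses, function(d)
    simulateCourse(st, courseSchedule(), d, 3, rs)$finalCounts[["hypoxic"]],
    numeric(1))
  expect_true(all(diff(finals) < 0))

  byOer <- vapply(c(1, 1.5, 2, 3), function(o) {
    st2 <- compartmentStates(ph, oerHypoxic = o)
    simulateCourse(st2, courseSchedule(), 15, 3, rs)$finalCounts[["hypoxic"]]
  }, numeric(1))
  expect_true(all(diff(byOer) > 0))
})

test_that("control probability is the Poisson eradication complement", {
  expect_equal(controlProbability(0), 1)
  expect_equal(controlProbability(log(2)), 0.5)
  expect_equal(controlProbability(1e6), 0)
  expect_error(controlProbability(-1), "counts")
  # monotone non-increasing in the surviving count
  ns <- c(0, 0.1, 1, 10, 100)
  expect_true(all(diff(vapply(ns, controlProbability, numeric(1))) <= 0))
})
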