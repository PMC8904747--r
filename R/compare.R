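## End-to-end plan comparison: phantom -> course doses -> EQD2 -> DVH ->
## TCP / NTCP -> compartment course, with Table-style report and ordering
## checks.

#' Construct a plan specification
#'
#' @param planId identifier ("A".."D" or custom).
#' @param courses data.frame with columns `target`, `dose` (Gy),
#'   `nFractions`, `sigma` (mm), `technique`.
#' @return a [PlanSpec-class].
#' @export
planSpec <- function(planId, courses) {
  new("PlanSpec", planId = planId, courses = courses)
}

#' The four default plans
#'
#' Plan A: 30 Gy in 10 daily fractions to the CTV. Plans B, C, D: a single
#' 15 Gy fraction to the GTV, the hypoxic ring, and the five vertices
#' respectively — each evaluated both alone and summed with plan A. The
#' vertex course uses the lattice technique (hot-centered, margin-free);
#' the others are conformal.
#'
#' @param sigma mm Gaussian penumbra for every course (default 3).
#' @return named list of [PlanSpec-class] objects.
#' @export
defaultPlans <- function(sigma = 3) {
  course <- function(target, dose, nFx, technique)
    data.frame(target = target, dose = dose, nFractions = nFx,
               sigma = sigma, technique = technique,
               stringsAsFactors = FALSE)
  list(
    A = planSpec("A", course("ctv", 30, 10L, "conformal")),
    B = planSpec("B", course("gtv", 15, 1L, "conformal")),
    C = planSpec("C", course("hypoxic", 15, 1L, "conformal")),
    D = planSpec("D", course("vertices", 15, 1L, "lattice"))
  )
}

#' Assemble a run configuration
#'
#' @param phantomSpec a [PhantomSpec-class].
#' @param plans named list of [PlanSpec-class] (default [defaultPlans()]).
#' @param params parameter set from [defaultParams()].
#' @param seed integer seed (overrides the phantom spec seed).
#' @param binWidth Gy DVH bin width.
#' @param coursePlans plans for which the compartment course is simulated.
#' @return a list configuration for [runComparison()].
#' @export
runConfig <- function(phantomSpec = latticeRT::phantomSpec(),
                      plans = defaultPlans(), params = defaultParams(),
                      seed = 1L, binWidth = 0.1,
                      coursePlans = c("C", "D")) {
  phantomSpec@seed <- as.integer(seed)
  list(phantomSpec = phantomSpec, plans = plans, params = params,
       seed = as.integer(seed), binWidth = binWidth,
       coursePlans = coursePlans)
}

#' Run the full plan comparison
#'
#' Builds the phantom, synthesizes every course, forms plan sums with the
#' baseline fractionated plan (plan "A" is the baseline: every other plan
#' is evaluated as its plan sum with A, and additionally as the boost
#' course alone), converts to EQD2 course by course, and evaluates tumor
#' TCP on the GTV, LKB NTCP on chest wall and skin (restricted to the
#' region receiving at least the configured physical dose), and the
#' three-compartment course model for the configured plans.
#'
#' @param config list from [runConfig()].
#' @return a [ComparisonReport-class]. The table has one row per plan with
#'   columns `plan`, `tcp` (plan-sum), `tcpBoostOnly`, `ntcpChestWall`,
#'   `ntcpSkin`, `meanDoseNormoxic`, `meanDoseHypoxic` (boost-course
#'   compartment means, Gy), `phase1SurvHypoxic`, `phase1SurvNormoxic`,
#'   `finalSurvHypoxic`, `finalSurvNormoxic`, `controlProbability`.
#' @export
runComparison <- function(config = runConfig()) {
  params <- config$params
  ab <- params$alphaBeta
  phantom <- buildPhantom(config$phantomSpec)
  gtv <- structureMask(phantom, "gtv")
  oarMasks <- list(chest_wall = structureMask(phantom, "chest_wall"),
                   skin = structureMask(phantom, "skin"))
  thr <- params$course$oarDoseThreshold

  if (!"A" %in% names(config$plans))
    stop("configuration must contain baseline plan 'A'")
  courseGrids <- lapply(config$plans, function(pl) {
    lapply(seq_len(nrow(pl@courses)), function(i) {
      co <- pl@courses[i, ]
      if (!co$target %in% structureNames(phantom))
        stop("plan ", pl@planId, ": unknown target structure '",
             co$target, "'")
      synthesizeDose(phantom, co$target, co$dose, co$nFractions, co$sigma,
                     co$technique)
    })
  })
  baseline <- courseGrids$A

  rows <- list()
  details <- list()
  for (pid in names(config$plans)) {
    grids <- if (pid == "A") baseline else c(baseline, courseGrids[[pid]])
    physSum <- Reduce(planSum, grids)

    tumorEqd2 <- eqd2Sum(grids, ab[["tumor"]])
    tcp <- poissonTCP(tumorEqd2, params$tcp, mask = gtv)
    tcpBoost <- if (pid == "A") NA_real_ else
      poissonTCP(eqd2Sum(courseGrids[[pid]], ab[["tumor"]]), params$tcp,
                 mask = gtv)

    ntcp <- vapply(names(oarMasks), function(oar) {
      tissue <- if (oar == "chest_wall") "chest_wall" else "skin"
      m <- restrictOARMask(oarMasks[[oar]], physSum, thr)
      oarEqd2 <- eqd2Sum(grids, ab[[tissue]])
      lkbNTCP(oarEqd2, params$ntcp[[tissue]], mask = m)
    }, numeric(1))

    boostGrid <- if (pid == "A") NULL else courseGrids[[pid]][[1]]
    boostMeans <- if (is.null(boostGrid))
      c(normoxic = NA_real_, hypoxic = NA_real_, necrotic = NA_real_) else
      compartmentMeanDoses(boostGrid, phantom)

    courseOut <- NULL
    if (pid %in% config$coursePlans && !is.null(boostGrid)) {
      states <- compartmentStates(phantom, params$course$clonogenDensity,
                                  params$course$oer)
      rs <- radiosensParams(alpha = params$course$alpha,
                            alphaBeta = ab[["tumor"]])
      aMeansPerFx <- compartmentMeanDoses(baseline[[1]], phantom) /
        baseline[[1]]@nFractions
      sched <- courseSchedule(
        phase1Fractions = boostGrid@nFractions,
        phase2Fractions = baseline[[1]]@nFractions)
      courseOut <- simulateCourse(states, sched,
                                  phase1Dose = boostMeans / boostGrid@nFractions,
                                  phase2Dose = aMeansPerFx, params = rs)
    }

    rows[[pid]] <- data.frame(
      plan = pid, tcp = tcp, tcpBoostOnly = tcpBoost,
      ntcpChestWall = ntcp[["chest_wall"]], ntcpSkin = ntcp[["skin"]],
      meanDoseNormoxic = boostMeans[["normoxic"]],
      meanDoseHypoxic = boostMeans[["hypoxic"]],
      phase1SurvHypoxic = if (is.null(courseOut)) NA_real_ else
        courseOut$phase1Survival[["hypoxic"]],
      phase1SurvNormoxic = if (is.null(courseOut)) NA_real_ else
        courseOut$phase1Survival[["normoxic"]],
      finalSurvHypoxic = if (is.null(courseOut)) NA_real_ else
        courseOut$finalSurvival[["hypoxic"]],
      finalSurvNormoxic = if (is.null(courseOut)) NA_real_ else
        courseOut$finalSurvival[["normoxic"]],
      controlProbability = if (is.null(courseOut)) NA_real_ else
        courseOut$controlProbability,
      stringsAsFactors = FALSE)
    details[[pid]] <- list(course = courseOut, boostMeans = boostMeans,
                           physMax = max(physSum@values))
  }

  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  new("ComparisonReport", table = tab, details = details,
      seed = config$seed,
      configHash = configHash(list(config$phantomSpec,
                                   lapply(config$plans, function(p) p@courses),
                                   config$binWidth)))
}

#' Check the qualitative orderings of a comparison report
#'
#' Asserts the dose-volume-effect structure expected of the four default
#' plans: tumor TCP ordered B > C > D; chest-wall and skin NTCP each
#' ordered B > C > D; and the lattice plan's chest-wall NTCP comparable to
#' the baseline (`NTCP_D / NTCP_A < 2`). Failures are reported, not
#' raised.
#'
#' @param report a [ComparisonReport-class].
#' @return data.frame with one row per comparison: `check`, `margin`
#'   (signed; > 0 means pass), `pass`.
#' @export
checkOrderings <- function(report) {
  tab <- reportTable(report)
  val <- function(plan, col) tab[tab$plan == plan, col]
  res <- list()
  add <- function(name, margin) res[[length(res) + 1L]] <<-
    data.frame(check = name, margin = margin, pass = margin > 0,
               stringsAsFactors = FALSE)
  for (col in c("tcp", "ntcpChestWall", "ntcpSkin")) {
    add(paste0(col, ": B > C"), val("B", col) - val("C", col))
    add(paste0(col, ": C > D"), val("C", col) - val("D", col))
  }
  add("ntcpChestWall: D within 2x of A",
      2 - val("D", "ntcpChestWall") / val("A", "ntcpChestWall"))
  do.call(rbind, res)
}
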