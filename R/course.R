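## Three-compartment course model: normoxic / hypoxic / necrotic clonogen
## populations under a large first fraction (delivered as compartment-mean
## dose) followed by a fractionated course, with optional exponential
## regrowth between fractions.

#' Initialize compartment states from a phantom
#'
#' One state per tumor compartment. Clonogen counts are density times
#' volume; the necrotic compartment is photopenic and carries zero
#' clonogens; the hypoxic compartment carries the configured OER.
#'
#' @param phantom a [Phantom-class].
#' @param clonogenDensity cells per cm3 for viable compartments.
#' @param oerHypoxic oxygen enhancement ratio of the hypoxic compartment.
#' @return data.frame with columns `name`, `volume` (cm3), `density`,
#'   `count`, `oer`.
#' @export
compartmentStates <- function(phantom, clonogenDensity = 1e7,
                              oerHypoxic = 2.0) {
  stopifnot(is(phantom, "Phantom"))
  vols <- vapply(c("normoxic", "hypoxic", "necrotic"), function(nm)
    maskVolume(structureMask(phantom, nm), phantom@spacing), numeric(1))
  dens <- c(clonogenDensity, clonogenDensity, 0)
  data.frame(name = names(vols), volume = as.numeric(vols), density = dens,
             count = dens * as.numeric(vols),
             oer = c(1, oerHypoxic, 1), row.names = NULL)
}

#' Course schedule: one large fraction then a fractionated phase
#'
#' @param phase1Fractions fractions in the boost phase (default 1).
#' @param phase2Fractions fractions in the standard phase (default 10).
#' @param interval days between fractions (default 1).
#' @param regrowth `"off"` or `"exponential"`.
#' @param doublingTime days, clonogen doubling time when regrowth is on.
#' @return list describing the schedule.
#' @export
courseSchedule <- function(phase1Fractions = 1L, phase2Fractions = 10L,
                           interval = 1, regrowth = c("off", "exponential"),
                           doublingTime = 5) {
  regrowth <- match.arg(regrowth)
  if (interval <= 0) stop("inter-fraction interval must be > 0")
  if (regrowth == "exponential" && doublingTime <= 0)
    stop("doubling time must be > 0")
  list(phase1Fractions = as.integer(phase1Fractions),
       phase2Fractions = as.integer(phase2Fractions), interval = interval,
       regrowth = regrowth, doublingTime = doublingTime)
}

#' Mean dose per compartment
#'
#' Arithmetic mean of the voxel doses over each tumor compartment mask.
#'
#' @param grid a [DoseGrid-class] on the phantom lattice.
#' @param phantom a [Phantom-class].
#' @param compartments structure names (default the three tumor
#'   compartments).
#' @return named numeric vector of mean doses (Gy).
#' @export
compartmentMeanDoses <- function(grid, phantom,
                                 compartments = c("normoxic", "hypoxic",
                                                  "necrotic")) {
  stopifnot(is(grid, "DoseGrid"), is(phantom, "Phantom"))
  if (!identical(dim(grid@values), dim(structureMask(phantom, "gtv"))))
    stop("grid and phantom do not share a lattice")
  vapply(compartments, function(nm) {
    m <- structureMask(phantom, nm)
    if (!any(m)) stop("compartment '", nm, "' is empty")
    mean(grid@values[m])
  }, numeric(1))
}

#' Simulate a treatment course over the compartments
#'
#' Per fraction, each compartment's clonogen count is multiplied by its LQ
#' survival fraction at its (OER-modified) compartment-mean dose for that
#' phase; between fractions, if regrowth is on, counts grow by
#' `2^(interval / doublingTime)`. The phase-1 dose is the boost course
#' delivered as compartment-mean dose (nominal 15 Gy); phase 2 is the
#' standard fractionated course (10 x 3 Gy by default).
#'
#' @param states data.frame from [compartmentStates()].
#' @param schedule list from [courseSchedule()].
#' @param phase1Dose,phase2Dose named numeric: dose per fraction (Gy) per
#'   compartment in each phase (names matching `states$name`; a scalar is
#'   recycled). `phase2Dose` is per fraction.
#' @param params a [RadiosensParams-class] for the tumor cells; the OER of
#'   each compartment overrides `params@oer`.
#' @return list with `trajectory` (data.frame: fraction index 0..N, day,
#'   one count column per compartment), `phase1Survival` and
#'   `finalSurvival` (named survival fractions relative to the initial
#'   count), `finalCounts`, and `controlProbability`.
#' @export
simulateCourse <- function(states, schedule, phase1Dose, phase2Dose,
                           params) {
  stopifnot(is(params, "RadiosensParams"))
  if (any(phase1Dose < 0) || any(phase2Dose < 0))
    stop("doses must be >= 0")
  nm <- states$name
  p1 <- .recycleDose(phase1Dose, nm)
  p2 <- .recycleDose(phase2Dose, nm)

  sf1 <- vapply(seq_along(nm), function(i)
    lqSurvival(p1[i], 1L, .withOer(params, states$oer[i])), numeric(1))
  sf2 <- vapply(seq_along(nm), function(i)
    lqSurvival(p2[i], 1L, .withOer(params, states$oer[i])), numeric(1))

  growth <- if (schedule$regrowth == "exponential")
    2^(schedule$interval / schedule$doublingTime) else 1
  nTotal <- schedule$phase1Fractions + schedule$phase2Fractions
  counts <- matrix(NA_real_, nTotal + 1L, length(nm),
                   dimnames = list(NULL, nm))
  counts[1L, ] <- states$count
  cur <- states$count
  for (f in seq_len(nTotal)) {
    sf <- if (f <= schedule$phase1Fractions) sf1 else sf2
    if (f > 1L) cur <- cur * growth # regrowth in the interval before this fraction
    cur <- cur * sf
    counts[f + 1L, ] <- cur
  }
  idxP1 <- schedule$phase1Fractions + 1L
  init <- states$count
  survAt <- function(row) {
    s <- counts[row, ] / init
    s[init == 0] <- 0
    s
  }
  list(
    trajectory = data.frame(fraction = 0:nTotal,
                            day = c(0, seq_len(nTotal) - 1) *
                              schedule$interval,
                            counts),
    phase1Survival = survAt(idxP1),
    finalSurvival = survAt(nTotal + 1L),
    finalCounts = counts[nTotal + 1L, ],
    controlProbability = controlProbability(counts[nTotal + 1L, ])
  )
}

.recycleDose <- function(dose, nm) {
  if (length(dose) == 1L) return(stats::setNames(rep(dose, length(nm)), nm))
  if (is.null(names(dose))) {
    stopifnot(length(dose) == length(nm))
    return(stats::setNames(as.numeric(dose), nm))
  }
  stopifnot(all(nm %in% names(dose)))
  dose[nm]
}

.withOer <- function(params, oer) {
  params@oer <- oer
  params
}

#' Poisson tumor control probability from surviving clonogens
#'
#' `P = exp(-sum(N_final))`: the probability that no clonogen survives,
#' under Poisson statistics. Reported alongside the raw survival fractions
#' so that cancer-cell survival can be read either way.
#'
#' @param finalCounts numeric, surviving clonogens per compartment.
#' @return probability in `[0, 1]`.
#' @examples
#' controlProbability(log(2)) # 0.5
#' @export
controlProbability <- function(finalCounts) {
  if (any(finalCounts < 0)) stop("counts must be >= 0")
  exp(-sum(finalCounts))
}
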