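## Dose-response models: LQ cell survival with OER, Poisson-LQ TCP,
## gEUD reduction and LKB NTCP, plus the default parameter file.

#' Construct radiosensitivity parameters
#'
#' If only two of `alpha`, `beta`, `alphaBeta` are given the third is
#' completed from `alpha / beta = alphaBeta`.
#'
#' @param alpha Gy^-1; @param beta Gy^-2; @param alphaBeta Gy;
#' @param oer oxygen enhancement ratio (>= 1; dose-modifying factor).
#' @return a [RadiosensParams-class].
#' @export
radiosensParams <- function(alpha = NA, beta = NA, alphaBeta = NA, oer = 1) {
  if (is.na(beta) && !is.na(alpha) && !is.na(alphaBeta)) beta <- alpha / alphaBeta
  if (is.na(alpha) && !is.na(beta) && !is.na(alphaBeta)) alpha <- beta * alphaBeta
  if (is.na(alphaBeta) && !is.na(alpha) && !is.na(beta) && beta > 0)
    alphaBeta <- alpha / beta
  new("RadiosensParams", alpha = alpha, beta = beta, alphaBeta = alphaBeta,
      oer = oer)
}

#' @rdname poissonTCP
#' @param tcd50 Gy (EQD2) 50% control dose; @param gamma50 normalized slope.
#' @export
tcpParams <- function(tcd50 = 51.77, gamma50 = 2.28)
  new("TcpParams", tcd50 = tcd50, gamma50 = gamma50)

#' @rdname lkbNTCP
#' @param n volume-effect exponent; @param m slope; @param td50 Gy (EQD2);
#' @param endpoint endpoint label.
#' @export
ntcpParams <- function(n, m, td50, endpoint = "")
  new("NtcpParams", n = n, m = m, td50 = td50, endpoint = endpoint)

#' Default model parameter set
#'
#' Reads the packaged parameter file: tumor alpha/beta 10.5 Gy, skin 8.8
#' Gy, chest wall 3.5 Gy; head-and-neck squamous TCP (TCD50 = 51.77 Gy,
#' gamma = 2.28); LKB chest wall (pathological fracture: n = 0.1, m =
#' 0.21, TD50 = 68.00 Gy) and skin (necrosis/ulceration: n = 0.1, m =
#' 0.12, TD50 = 70.00 Gy); compartment-course defaults (alpha = 0.25
#' Gy^-1 with beta from the tumor ratio, hypoxic OER 2.0, clonogen
#' density 1e7 cm^-3).
#'
#' @param file optional path to a YAML parameter file with the same layout.
#' @return named list with elements `alphaBeta` (named numeric), `tcp`
#'   ([TcpParams-class]), `ntcp` (named list of [NtcpParams-class]),
#'   `course` (list with `alpha`, `oer`, `clonogenDensity`,
#'   `oarDoseThreshold`).
#' @export
defaultParams <- function(file = system.file("extdata", "default_params.yaml",
                                             package = "latticeRT")) {
  y <- yaml::read_yaml(file)
  list(
    alphaBeta = unlist(y$alpha_beta),
    tcp = tcpParams(y$tcp$tcd50, y$tcp$gamma),
    ntcp = lapply(y$ntcp, function(p)
      ntcpParams(p$n, p$m, p$td50, p$endpoint)),
    course = y$course
  )
}

#' Linear-quadratic survival fraction with OER
#'
#' `SF = exp(-nFx (alpha d' + beta d'^2))` with the effective fraction dose
#' `d' = d / OER`: hypoxia enters as a dose-modifying factor (equivalently
#' `alpha -> alpha / OER`, `beta -> beta / OER^2`). `OER = 1` for normoxic
#' cells.
#'
#' @param d Gy dose per fraction (vectorized).
#' @param nFx number of fractions.
#' @param params a [RadiosensParams-class].
#' @return survival fraction in `[0, 1]`.
#' @examples
#' p <- radiosensParams(alpha = 0.3, beta = 0.03)
#' lqSurvival(2, 1, p) # exp(-0.72)
#' @export
lqSurvival <- function(d, nFx, params) {
  stopifnot(is(params, "RadiosensParams"), all(d >= 0), nFx >= 1)
  validObject(params)
  de <- d / params@oer
  exp(-nFx * (params@alpha * de + params@beta * de^2))
}

## closed-form Poisson-LQ dose-response at uniform dose (EQD2)
.tcpUniform <- function(dose, params, form = c("slope", "kallman")) {
  form <- match.arg(form)
  k <- switch(form, slope = 2 * params@gamma50 / log(2),
              kallman = exp(1) * params@gamma50)
  2^(-exp(k * (1 - dose / params@tcd50)))
}

#' Poisson-LQ tumor control probability
#'
#' At uniform EQD2 dose `D` the adopted dose-response is
#' `TCP(D) = 2^(-exp((2 gamma / ln 2) (1 - D / TCD50)))`,
#' constructed so that `TCP(TCD50) = 1/2` exactly and the normalized slope
#' `TCD50 dTCP/dD` at `TCD50` equals `gamma` exactly. For a heterogeneous
#' dose the whole-structure TCP is the volume-weighted geometric
#' combination `prod_i TCP(D_i)^(v_i / V)` (uniform clonogen density
#' Poisson statistics), which reduces to the closed form under uniform
#' dose. The alternative Kallman convention (`e gamma` in place of
#' `2 gamma / ln 2`) is available via `form = "kallman"`.
#'
#' Inputs must be on the EQD2 scale: a DVH or grid tagged `"physical"` is
#' rejected.
#'
#' @param x uniform EQD2 dose(s) (numeric), an EQD2 [DVH-class], or an
#'   EQD2 [DoseGrid-class] (then `mask` selects the structure).
#' @param params a [TcpParams-class] (default: the packaged head-and-neck
#'   squamous set).
#' @param mask logical array, required for grid input.
#' @param form `"slope"` (default) or `"kallman"`.
#' @return control probability in `[0, 1]`.
#' @examples
#' poissonTCP(51.77) # 0.5
#' @export
setGeneric("poissonTCP",
           function(x, params = tcpParams(), mask = NULL,
                    form = c("slope", "kallman")) standardGeneric("poissonTCP"))

#' @rdname poissonTCP
setMethod("poissonTCP", "numeric", function(x, params, mask, form) {
  validObject(params)
  .tcpUniform(x, params, form)
})

#' @rdname poissonTCP
setMethod("poissonTCP", "DVH", function(x, params, mask, form) {
  validObject(params)
  if (x@scale != "EQD2")
    stop("TCP requires an EQD2-scale DVH (got '", x@scale, "')")
  w <- x@volume / sum(x@volume)
  .tcpCombine(dvhMids(x), w, params, form)
})

#' @rdname poissonTCP
setMethod("poissonTCP", "DoseGrid", function(x, params, mask, form) {
  validObject(params)
  if (x@scale != "EQD2")
    stop("TCP requires an EQD2-scale dose grid (got '", x@scale, "')")
  if (is.null(mask)) stop("grid input requires a structure mask")
  d <- x@values[mask]
  .tcpCombine(d, rep(1 / length(d), length(d)), params, form)
})

# volume-weighted geometric combination, evaluated in log2 space so that
# voxels at (near-)zero dose underflow gracefully
.tcpCombine <- function(doses, weights, params, form = c("slope", "kallman")) {
  form <- match.arg(form)
  k <- switch(form, slope = 2 * params@gamma50 / log(2),
              kallman = exp(1) * params@gamma50)
  log2p <- -exp(pmin(k * (1 - doses / params@tcd50), 700))
  2^sum(weights * log2p)
}

#' Generalized equivalent uniform dose (gEUD)
#'
#' DVH reduction step of the LKB model:
#' `gEUD = (sum_i (v_i / V) D_i^(1/n))^n`. For `n -> 0` the gEUD tends to
#' the maximum structure dose; at `n = 1` it is the mean dose; a uniform
#' dose is a fixed point for every `n`.
#'
#' @param dvh a [DVH-class] (EQD2 scale for use inside the LKB model).
#' @param n volume-effect exponent in (0, 1].
#' @return gEUD in Gy.
#' @examples
#' gEUD(dvhFromLevels(c(60, 0), c(50, 50)), 0.1) # 60 * 0.5^0.1 = 55.98
#' @export
gEUD <- function(dvh, n) {
  stopifnot(is(dvh, "DVH"))
  if (n <= 0 || n > 1) stop("volume exponent n must be in (0, 1]")
  v <- dvh@volume
  if (sum(v) <= 0) stop("empty DVH")
  w <- v / sum(v)
  d <- dvhMids(dvh)
  sum(w * d^(1 / n))^n
}

#' Lyman-Kutcher-Burman normal tissue complication probability
#'
#' `NTCP = Phi(t)` with `t = (gEUD - TD50) / (m TD50)` and `Phi` the
#' standard normal cumulative distribution; the DVH is first reduced to
#' its gEUD with the volume exponent `n` of the parameter set. A uniform
#' whole-organ dose equal to TD50 gives NTCP = 1/2 exactly.
#'
#' A [DoseGrid-class] method evaluates the gEUD from the voxel EQD2 values
#' directly (a zero-bin-width DVH), which the comparison pipeline uses so
#' that sub-bin dose differences between plans are not quantized away;
#' the DVH method is the classic histogram route.
#'
#' @param x an EQD2-scale [DVH-class] of the organ at risk, or an EQD2
#'   [DoseGrid-class] (then `mask` selects the organ).
#' @param params an [NtcpParams-class].
#' @param mask logical array, required for grid input.
#' @return complication probability in `[0, 1]`.
#' @examples
#' lkbNTCP(uniformDVH(68), ntcpParams(0.1, 0.21, 68)) # 0.5
#' @export
setGeneric("lkbNTCP", function(x, params, mask = NULL)
  standardGeneric("lkbNTCP"))

#' @rdname lkbNTCP
setMethod("lkbNTCP", "DVH", function(x, params, mask) {
  stopifnot(is(params, "NtcpParams"))
  validObject(params)
  if (x@scale != "EQD2")
    stop("LKB NTCP requires an EQD2-scale DVH (got '", x@scale, "')")
  .lkbFromGeud(gEUD(x, params@n), params)
})

#' @rdname lkbNTCP
setMethod("lkbNTCP", "DoseGrid", function(x, params, mask) {
  stopifnot(is(params, "NtcpParams"))
  validObject(params)
  if (x@scale != "EQD2")
    stop("LKB NTCP requires an EQD2-scale dose grid (got '", x@scale, "')")
  if (is.null(mask)) stop("grid input requires a structure mask")
  d <- x@values[mask]
  if (!length(d)) stop("empty structure mask")
  geud <- mean(d^(1 / params@n))^params@n
  .lkbFromGeud(geud, params)
})

.lkbFromGeud <- function(geud, params)
  pnorm((geud - params@td50) / (params@m * params@td50))

#' Restrict an OAR mask to the region receiving at least a threshold dose
#'
#' NTCP predictions depend on the organ volume under consideration; the
#' default evaluation restricts the OAR to the portion exposed to at least
#' 2 Gy physical dose. A threshold of 0 disables the restriction.
#'
#' @param mask logical OAR mask.
#' @param grid physical-dose [DoseGrid-class] of the evaluated plan.
#' @param threshold Gy (default 2).
#' @return logical mask (the full mask if the restriction empties it).
#' @export
restrictOARMask <- function(mask, grid, threshold = 2) {
  if (threshold <= 0) return(mask)
  out <- mask & grid@values >= threshold
  if (!any(out)) mask else out
}

#' Find the uniform dose giving a target probability by bisection
#'
#' Bisects the uniform-dose axis of a probability model (e.g. TCP or NTCP
#' as a function of a single-bin DVH dose) until the bracket is narrower
#' than `tol`.
#'
#' @param f function(dose) -> probability, monotone increasing.
#' @param target target probability (default 0.5).
#' @param lower,upper Gy initial bracket.
#' @param tol Gy bracket tolerance (default 0.01).
#' @return dose in Gy at which `f` crosses `target`.
#' @export
doseAtProbability <- function(f, target = 0.5, lower = 0, upper = 200,
                              tol = 0.01) {
  flo <- f(lower) - target
  fhi <- f(upper) - target
  if (flo * fhi > 0) stop("bisection bracket does not contain the crossing")
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if ((f(mid) - target) * flo <= 0) upper <- mid else lower <- mid
  }
  (lower + upper) / 2
}
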