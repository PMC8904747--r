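## Dose synthesis and grid arithmetic: idealized course dose distributions,
## trilinear resampling, plan summation, DVH extraction, EQD2 conversion.

#' Construct a DoseGrid
#'
#' @param values Gy, 3D numeric array of total dose for the course.
#' @param spacing mm voxel spacing (length 1 or 3).
#' @param origin mm coordinate of the first voxel center.
#' @param nFractions fractions the total dose is delivered in (`NA` marks a
#'   composite plan sum).
#' @param scale `"physical"` or `"EQD2"`.
#' @param label free-text label.
#' @return a [DoseGrid-class].
#' @export
doseGrid <- function(values, spacing, origin = c(0, 0, 0), nFractions = 1L,
                     scale = "physical", label = "") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("DoseGrid", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), nFractions = as.integer(nFractions),
      scale = scale, label = label)
}

#' Synthesize an idealized course dose distribution
#'
#' Emulates a planned dose distribution for one course: a Gaussian-penumbra
#' field delivering the prescription to the target structure. Two planning
#' techniques are modeled:
#'
#' * `"conformal"`: the beam aperture is the target expanded by a margin;
#'   the margin is calibrated by bisection so that the minimum target dose
#'   reaches `coverage` times the prescription (the prescription isodose
#'   wraps the target, as a conformal optimizer enforces). Dose never
#'   exceeds the prescription.
#' * `"lattice"`: no aperture margin; the blurred target field is scaled so
#'   the minimum target dose reaches `coverage` times the prescription,
#'   giving the hot-centered vertex profile characteristic of lattice
#'   boosts (peak well above prescription, rapid fall-off outside).
#'
#' With `sigma = 0` both reduce to an exact step: prescription inside the
#' target, zero outside.
#'
#' @param phantom a [Phantom-class].
#' @param target structure name (see [structureMask()]).
#' @param dose Gy prescription.
#' @param nFractions fraction count for the course.
#' @param sigma mm Gaussian penumbra standard deviation.
#' @param technique `"conformal"` or `"lattice"`.
#' @param coverage fraction of the prescription that must cover the whole
#'   target (default 0.99: at least 99% of the prescribed dose covering
#'   100% of the target volume).
#' @return a physical-scale [DoseGrid-class] tagged with `nFractions`.
#' @export
synthesizeDose <- function(phantom, target, dose, nFractions = 1L,
                           sigma = 3, technique = c("conformal", "lattice"),
                           coverage = 0.99) {
  stopifnot(is(phantom, "Phantom"), dose >= 0, nFractions >= 1)
  technique <- match.arg(technique)
  mask <- structureMask(phantom, target)
  if (!any(mask)) stop("target structure '", target, "' is empty")
  spacing <- phantom@spacing
  lab <- sprintf("%g Gy / %d fx to %s", dose, as.integer(nFractions), target)

  if (dose == 0 || sigma == 0) {
    vals <- array(dose * as.numeric(mask), dim(mask))
    return(doseGrid(vals, spacing, phantom@origin, nFractions, label = lab))
  }

  if (technique == "lattice") {
    field <- gaussBlur3d(array(as.numeric(mask), dim(mask)), spacing, sigma)
    scale <- coverage * dose / min(field[mask])
    vals <- scale * field
  } else {
    dist <- distanceToMask(mask, spacing)
    fieldFor <- function(m) {
      ap <- dist <= m
      gaussBlur3d(array(as.numeric(ap), dim(ap)), spacing, sigma)
    }
    # smallest aperture margin whose blurred field covers the target
    lo <- 0
    hi <- 6 * sigma
    while (min(fieldFor(hi)[mask]) < coverage && hi < 20 * sigma) hi <- hi * 1.5
    for (i in seq_len(12L)) {
      mid <- (lo + hi) / 2
      if (min(fieldFor(mid)[mask]) >= coverage) hi <- mid else lo <- mid
    }
    vals <- dose * fieldFor(hi)
  }
  doseGrid(pmax(vals, 0), spacing, phantom@origin, nFractions, label = lab)
}

#' Resample a dose grid onto a new lattice
#'
#' Trilinear interpolation onto a lattice with the requested spacing
#' covering the same physical extent (the default analysis resolution is
#' 1.5 mm isotropic).
#'
#' @param grid a [DoseGrid-class].
#' @param newSpacing mm (length 1 or 3).
#' @return a resampled [DoseGrid-class].
#' @export
resampleGrid <- function(grid, newSpacing) {
  stopifnot(is(grid, "DoseGrid"))
  if (length(newSpacing) == 1L) newSpacing <- rep(newSpacing, 3L)
  if (any(newSpacing <= 0)) stop("spacing must be > 0")
  if (all(abs(newSpacing - grid@spacing) < 1e-12)) return(grid)
  d <- dim(grid@values)
  newAxes <- lapply(1:3, function(a) {
    end <- grid@origin[a] + (d[a] - 1) * grid@spacing[a]
    seq(grid@origin[a], end, by = newSpacing[a])
  })
  vals <- .trilinear(grid@values, grid@spacing, grid@origin, newAxes)
  doseGrid(vals, newSpacing, vapply(newAxes, `[`, numeric(1), 1),
           grid@nFractions, grid@scale, grid@label)
}

# trilinear interpolation of arr at the tensor grid given by newAxes
.trilinear <- function(arr, spacing, origin, newAxes) {
  d <- dim(arr)
  # fractional (0-based) indices per axis, clamped to the grid
  fi <- lapply(1:3, function(a) {
    t <- (newAxes[[a]] - origin[a]) / spacing[a]
    pmin(pmax(t, 0), d[a] - 1)
  })
  nd <- lengths(fi)
  i0 <- lapply(seq_along(fi), function(a)
    pmin(floor(fi[[a]]), max(d[a] - 2, 0)) + 1)
  i1 <- lapply(seq_along(fi), function(a) pmin(i0[[a]] + 1, d[a]))
  fr <- lapply(seq_along(fi), function(a) fi[[a]] - (i0[[a]] - 1))
  IX <- array(rep(i0[[1]], times = nd[2] * nd[3]), nd)
  IY <- array(rep(rep(i0[[2]], each = nd[1]), times = nd[3]), nd)
  IZ <- array(rep(i0[[3]], each = nd[1] * nd[2]), nd)
  JX <- array(rep(i1[[1]], times = nd[2] * nd[3]), nd)
  JY <- array(rep(rep(i1[[2]], each = nd[1]), times = nd[3]), nd)
  JZ <- array(rep(i1[[3]], each = nd[1] * nd[2]), nd)
  FX <- array(rep(fr[[1]], times = nd[2] * nd[3]), nd)
  FY <- array(rep(rep(fr[[2]], each = nd[1]), times = nd[3]), nd)
  FZ <- array(rep(fr[[3]], each = nd[1] * nd[2]), nd)
  at <- function(dx, dy, dz)
    arr[cbind(as.vector(if (dx) JX else IX),
              as.vector(if (dy) JY else IY),
              as.vector(if (dz) JZ else IZ))]
  v <- (1 - FX) * (1 - FY) * (1 - FZ) * at(0, 0, 0) +
       FX * (1 - FY) * (1 - FZ) * at(1, 0, 0) +
       (1 - FX) * FY * (1 - FZ) * at(0, 1, 0) +
       FX * FY * (1 - FZ) * at(1, 1, 0) +
       (1 - FX) * (1 - FY) * FZ * at(0, 0, 1) +
       FX * (1 - FY) * FZ * at(1, 0, 1) +
       (1 - FX) * FY * FZ * at(0, 1, 1) +
       FX * FY * FZ * at(1, 1, 1)
  array(v, nd)
}

#' Voxel-wise sum of two physical dose grids
#'
#' Grids on different lattices are first resampled to the finer spacing.
#' The result carries `nFractions = NA` ("composite"): EQD2 conversion of a
#' plan sum must be done course by course (see [eqd2Sum()]) because courses
#' with different fraction sizes convert differently.
#'
#' @param a,b [DoseGrid-class] objects on the physical dose scale.
#' @return a composite [DoseGrid-class].
#' @export
planSum <- function(a, b) {
  stopifnot(is(a, "DoseGrid"), is(b, "DoseGrid"))
  if (a@scale != b@scale) stop("cannot sum grids on different dose scales")
  if (!all(abs(a@spacing - b@spacing) < 1e-9)) {
    target <- pmin(a@spacing, b@spacing)
    a <- resampleGrid(a, target)
    b <- resampleGrid(b, target)
  }
  if (!identical(dim(a@values), dim(b@values)) ||
      any(abs(a@origin - b@origin) > 1e-6))
    stop("grids do not share a lattice / physical extent")
  doseGrid(a@values + b@values, a@spacing, a@origin, NA_integer_, a@scale,
           label = paste(a@label, "+", b@label))
}

#' Compute a dose-volume histogram
#'
#' Differential histogram of the voxel doses inside a structure mask,
#' weighted by voxel volume.
#'
#' @param grid a [DoseGrid-class].
#' @param mask logical array on the same lattice.
#' @param binWidth Gy bin width (default 0.1).
#' @param structure structure name stored in the DVH.
#' @return a [DVH-class] carrying the grid's dose scale.
#' @export
computeDVH <- function(grid, mask, binWidth = 0.1, structure = "structure") {
  stopifnot(is(grid, "DoseGrid"))
  if (!identical(dim(grid@values), dim(mask)))
    stop("mask and grid do not share a lattice")
  if (!any(mask)) stop("structure '", structure, "' has an empty mask")
  doses <- grid@values[mask]
  voxvol <- prod(grid@spacing) / 1000
  nbin <- max(1L, ceiling((max(doses) + 1e-9) / binWidth))
  breaks <- seq(0, nbin * binWidth, by = binWidth)
  idx <- pmin(pmax(floor(doses / binWidth), 0), nbin - 1) + 1
  vol <- as.numeric(tabulate(idx, nbins = nbin)) * voxvol
  new("DVH", breaks = breaks, volume = vol, structure = structure,
      scale = grid@scale)
}

#' Construct a single-bin uniform-dose DVH
#'
#' @param dose Gy uniform dose (the single bin is centered on it).
#' @param volume cm3 structure volume.
#' @param structure,scale stored tags (default scale `"EQD2"`).
#' @param binWidth Gy width of the single bin.
#' @return a [DVH-class].
#' @export
uniformDVH <- function(dose, volume = 100, structure = "uniform",
                       scale = "EQD2", binWidth = 0.01) {
  new("DVH", breaks = c(max(dose - binWidth / 2, 0), dose + binWidth / 2),
      volume = volume, structure = structure, scale = scale)
}

#' Build a DVH directly from dose levels and volumes
#'
#' Convenience constructor for worked examples: narrow bins centered on the
#' given dose levels.
#'
#' @param doses Gy dose levels.
#' @param volumes cm3 volume at each level.
#' @param structure,scale stored tags.
#' @return a [DVH-class].
#' @export
dvhFromLevels <- function(doses, volumes, structure = "levels",
                          scale = "EQD2") {
  o <- order(doses)
  doses <- doses[o]; volumes <- volumes[o]
  eps <- 1e-6
  breaks <- as.vector(rbind(doses - eps, doses + eps))
  vol <- as.vector(rbind(volumes, rep(0, length(volumes))))[-2 * length(doses)]
  new("DVH", breaks = c(pmax(breaks[1], 0), breaks[-1]), volume = vol,
      structure = structure, scale = scale)
}

#' DVH bin centers, cumulative form and summaries
#'
#' `cumulativeDVH` returns the cumulative histogram: volume receiving at
#' least each bin's lower-edge dose (monotone non-increasing, starting at
#' the structure volume).
#'
#' @param dvh a [DVH-class].
#' @return `dvhMids`: bin-center doses; `cumulativeDVH`: data.frame with
#'   `dose` (Gy) and `volume` (cm3); `dvhTotalVolume`: structure volume;
#'   `dvhMeanDose`: volume-weighted mean dose.
#' @export
cumulativeDVH <- function(dvh) {
  stopifnot(is(dvh, "DVH"))
  data.frame(dose = dvh@breaks[-length(dvh@breaks)],
             volume = rev(cumsum(rev(dvh@volume))))
}

#' @rdname cumulativeDVH
#' @export
dvhMids <- function(dvh) {
  (dvh@breaks[-1] + dvh@breaks[-length(dvh@breaks)]) / 2
}

#' @rdname cumulativeDVH
#' @export
dvhTotalVolume <- function(dvh) sum(dvh@volume)

#' @rdname cumulativeDVH
#' @export
dvhMeanDose <- function(dvh) {
  v <- dvh@volume
  sum(dvhMids(dvh) * v) / sum(v)
}

#' Volume receiving at least a given dose
#' @param dvh a [DVH-class]; @param dose Gy threshold.
#' @return cm3 volume with dose >= `dose` (bins interpolated linearly).
#' @export
dvhVolumeAtDose <- function(dvh, dose) {
  mids <- dvhMids(dvh)
  sum(dvh@volume[mids >= dose])
}

## ---- EQD2 ---------------------------------------------------------------

.eqd2Factor <- function(dosePerFraction, alphaBeta) {
  if (alphaBeta <= 0) stop("alpha/beta must be > 0")
  (dosePerFraction + alphaBeta) / (2 + alphaBeta)
}

#' Equivalent dose in 2-Gy fractions
#'
#' Converts total dose `D` delivered in `n` fractions (voxel-wise dose per
#' fraction `d = D / n`) to the isoeffective total dose in 2-Gy fractions
#' under the linear-quadratic model:
#' `EQD2 = D * (d + alpha/beta) / (2 + alpha/beta)`.
#'
#' Methods exist for plain numeric doses, [DoseGrid-class] (voxel-wise; the
#' returned grid is tagged `"EQD2"`) and [DVH-class] (bin edges are mapped
#' through the monotone conversion, bin volumes are unchanged). Composite
#' plan-sum grids (`nFractions = NA`) are rejected: convert course by
#' course with [eqd2Sum()].
#'
#' @param x numeric vector of total doses, a [DoseGrid-class] or a
#'   [DVH-class].
#' @param nFractions fraction count (taken from the grid if missing).
#' @param alphaBeta Gy, the alpha/beta ratio of the tissue.
#' @return object of the same shape on the EQD2 scale.
#' @examples
#' eqd2(30, 10, 10.5) # 32.4 Gy
#' eqd2(15, 1, 10.5)  # 30.6 Gy
#' @export
setGeneric("eqd2", function(x, nFractions, alphaBeta) standardGeneric("eqd2"))

#' @rdname eqd2
setMethod("eqd2", "numeric", function(x, nFractions, alphaBeta) {
  if (nFractions < 1) stop("fraction count must be >= 1")
  x * .eqd2Factor(x / nFractions, alphaBeta)
})

#' @rdname eqd2
setMethod("eqd2", "array", function(x, nFractions, alphaBeta) {
  if (nFractions < 1) stop("fraction count must be >= 1")
  x * .eqd2Factor(x / nFractions, alphaBeta)
})

#' @rdname eqd2
setMethod("eqd2", "DoseGrid", function(x, nFractions, alphaBeta) {
  if (missing(nFractions)) nFractions <- x@nFractions
  if (is.na(nFractions))
    stop("composite plan sum: convert each course separately (eqd2Sum)")
  if (x@scale == "EQD2") stop("grid is already on the EQD2 scale")
  vals <- x@values * .eqd2Factor(x@values / nFractions, alphaBeta)
  doseGrid(vals, x@spacing, x@origin, NA_integer_, scale = "EQD2",
           label = paste0("EQD2(", x@label, ")"))
})

#' @rdname eqd2
setMethod("eqd2", "DVH", function(x, nFractions, alphaBeta) {
  if (nFractions < 1) stop("fraction count must be >= 1")
  if (x@scale == "EQD2") stop("DVH is already on the EQD2 scale")
  newBreaks <- x@breaks * .eqd2Factor(x@breaks / nFractions, alphaBeta)
  new("DVH", breaks = newBreaks, volume = x@volume, structure = x@structure,
      scale = "EQD2")
})

#' EQD2 plan sum over several courses
#'
#' Converts each course grid to EQD2 with its own fraction size, then sums
#' voxel-wise. This is the correct order for plan sums: a 15 Gy x 1 course
#' and a 3 Gy x 10 course have different fraction sizes, so converting the
#' summed physical dose with either scheme would be wrong for both.
#'
#' @param grids list of physical-scale [DoseGrid-class] objects.
#' @param alphaBeta Gy, tissue alpha/beta ratio.
#' @return a composite EQD2 [DoseGrid-class].
#' @export
eqd2Sum <- function(grids, alphaBeta) {
  stopifnot(length(grids) >= 1)
  converted <- lapply(grids, eqd2, alphaBeta = alphaBeta)
  out <- converted[[1]]
  for (g in converted[-1]) {
    if (!identical(dim(out@values), dim(g@values)))
      stop("course grids do not share a lattice")
    out@values <- out@values + g@values
  }
  out@label <- paste(vapply(grids, function(g) g@label, ""), collapse = " + ")
  out
}
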