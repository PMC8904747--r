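## S4 containers for the phantom, dose grids, DVHs and model parameters.

#' PhantomSpec: geometry specification for the synthetic phantom
#'
#' Holds every tunable of the concentric-spheroid tumor phantom: the three
#' subvolume sizes, margins, vertex geometry, organ-at-risk placement and
#' grid resolution. Defaults reproduce the study conditions of the case the
#' package models: an 86.8 cm3 necrotic core, a 13 cm3 hypoxic ring obtained
#' from a 2-mm expansion of the core, a 171.3 cm3 GTV, a 0.5-cm CTV margin
#' and five 1.0-cm vertices separated by at least 2.0 cm (center to center).
#'
#' @slot necroticVolume cm3, volume of the central necrotic core.
#' @slot hypoxicVolume cm3, volume of the hypoxic ring; `NA` means the full
#'   expansion shell `(core + margin) \\ core` is used.
#' @slot hypoxicMargin mm, isometric expansion of the core that bounds the
#'   hypoxic ring outward.
#' @slot gtvVolume cm3, total gross tumor volume (the normoxic shell is
#'   sized last so the three subvolumes sum to this).
#' @slot ctvMargin mm, isometric GTV-to-CTV expansion.
#' @slot vertexCount number of high-dose vertices.
#' @slot vertexDiameter cm, vertex sphere diameter.
#' @slot vertexMinSep cm, minimum center-to-center vertex separation.
#' @slot skinStandoff,skinThickness mm, gap between GTV surface and the skin
#'   shell, and shell thickness (planar shell on the +x face).
#' @slot chestwallStandoff,chestwallThickness mm, same for the chest-wall
#'   slab on the -x face.
#' @slot spacing mm, isotropic voxel spacing.
#' @slot padding mm, air padding around all structures.
#' @slot seed integer, RNG seed for the vertex-placement jitter.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    necroticVolume = "numeric", hypoxicVolume = "numeric",
    hypoxicMargin = "numeric", gtvVolume = "numeric", ctvMargin = "numeric",
    vertexCount = "integer", vertexDiameter = "numeric",
    vertexMinSep = "numeric", skinStandoff = "numeric",
    skinThickness = "numeric", chestwallStandoff = "numeric",
    chestwallThickness = "numeric", spacing = "numeric", padding = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@necroticVolume <= 0) msg <- c(msg, "necroticVolume must be > 0")
  if (object@gtvVolume <= object@necroticVolume)
    msg <- c(msg, "gtvVolume must exceed necroticVolume")
  if (!is.na(object@hypoxicVolume) &&
      object@gtvVolume < object@necroticVolume + object@hypoxicVolume)
    msg <- c(msg, "gtvVolume < necroticVolume + hypoxicVolume")
  if (object@hypoxicMargin < 0 || object@ctvMargin < 0)
    msg <- c(msg, "margins must be >= 0")
  if (object@vertexCount < 1L) msg <- c(msg, "vertexCount must be >= 1")
  if (object@vertexMinSep < object@vertexDiameter)
    msg <- c(msg, "vertexMinSep must be >= vertexDiameter (no overlap)")
  if (object@spacing <= 0) msg <- c(msg, "spacing must be > 0")
  if (length(msg)) msg else TRUE
})

#' Phantom: voxelized structures on a shared grid
#'
#' Boolean masks for the tumor subvolumes (necrotic, hypoxic, normoxic),
#' GTV, CTV, the individual vertices, skin and chest wall, all on one
#' regular lattice. Masks are 3D logical arrays; `origin` is the physical
#' coordinate (mm) of the center of voxel `[1,1,1]`.
#'
#' @slot spacing mm, voxel spacing (length-3).
#' @slot origin mm, coordinate of the first voxel center (length-3).
#' @slot masks named list of logical arrays.
#' @slot vertices list of logical arrays, one per vertex.
#' @slot radii named numeric: solved sphere radii (mm).
#' @slot spec the [PhantomSpec-class] the phantom was built from.
#' @exportClass Phantom
setClass("Phantom",
  representation(
    spacing = "numeric", origin = "numeric", masks = "list",
    vertices = "list", radii = "numeric", spec = "PhantomSpec"
  )
)

setValidity("Phantom", function(object) {
  msg <- character()
  need <- c("necrotic", "hypoxic", "normoxic", "gtv", "ctv", "skin",
            "chest_wall")
  if (!all(need %in% names(object@masks)))
    msg <- c(msg, paste("missing masks:",
                        paste(setdiff(need, names(object@masks)), collapse = ", ")))
  else {
    nec <- object@masks$necrotic; hyp <- object@masks$hypoxic
    nor <- object@masks$normoxic; gtv <- object@masks$gtv
    if (any(nec & hyp) || any(nec & nor) || any(hyp & nor))
      msg <- c(msg, "necrotic/hypoxic/normoxic masks overlap")
    if (!identical(as.vector(nec | hyp | nor), as.vector(gtv)))
      msg <- c(msg, "subvolume union != gtv")
    if (any(object@masks$skin & gtv) || any(object@masks$chest_wall & gtv))
      msg <- c(msg, "OAR masks intersect gtv")
    for (v in object@vertices)
      if (any(v & !gtv)) msg <- c(msg, "vertex extends outside gtv")
  }
  if (length(msg)) msg else TRUE
})

#' DoseGrid: 3D absorbed-dose field on a regular lattice
#'
#' @slot values Gy, 3D numeric array (total dose for the course).
#' @slot spacing mm, voxel spacing (length-3).
#' @slot origin mm, coordinate of the first voxel center.
#' @slot nFractions integer, number of fractions the grid was delivered in
#'   (`NA` for composite plan sums, which must be EQD2-converted course by
#'   course before summation).
#' @slot scale `"physical"` or `"EQD2"`.
#' @slot label free-text course label.
#' @exportClass DoseGrid
setClass("DoseGrid",
  representation(
    values = "array", spacing = "numeric", origin = "numeric",
    nFractions = "integer", scale = "character", label = "character"
  ),
  prototype(nFractions = 1L, scale = "physical", label = "")
)

setValidity("DoseGrid", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L) msg <- c(msg, "values must be a 3D array")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "dose values must be finite and >= 0")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be a positive length-3 vector")
  if (!object@scale %in% c("physical", "EQD2"))
    msg <- c(msg, "scale must be 'physical' or 'EQD2'")
  if (length(msg)) msg else TRUE
})

#' DVH: dose-volume histogram of a structure
#'
#' Stored in differential form: `volume[i]` is the structure volume (cm3)
#' receiving a dose in `[breaks[i], breaks[i+1])`. The cumulative form is
#' derived on demand by [cumulativeDVH()].
#'
#' @slot breaks Gy, bin edges (length nbins + 1).
#' @slot volume cm3, differential volume per bin.
#' @slot structure structure name.
#' @slot scale `"physical"` or `"EQD2"`.
#' @exportClass DVH
setClass("DVH",
  representation(breaks = "numeric", volume = "numeric",
                 structure = "character", scale = "character"),
  prototype(scale = "physical")
)

setValidity("DVH", function(object) {
  msg <- character()
  if (length(object@volume) != length(object@breaks) - 1L)
    msg <- c(msg, "volume must have length(breaks) - 1 entries")
  if (any(object@volume < -1e-12)) msg <- c(msg, "differential volumes must be >= 0")
  if (is.unsorted(object@breaks, strictly = TRUE))
    msg <- c(msg, "breaks must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' RadiosensParams: linear-quadratic radiosensitivity parameters
#'
#' @slot alpha Gy^-1 linear coefficient; @slot beta Gy^-2 quadratic
#' coefficient; @slot alphaBeta Gy, the alpha/beta ratio; @slot oer
#' dimensionless oxygen enhancement ratio (>= 1, 1 = normoxic).
#' @exportClass RadiosensParams
setClass("RadiosensParams",
  representation(alpha = "numeric", beta = "numeric", alphaBeta = "numeric",
                 oer = "numeric"),
  prototype(oer = 1)
)

setValidity("RadiosensParams", function(object) {
  msg <- character()
  if (object@alpha < 0 || object@beta < 0) msg <- c(msg, "alpha, beta must be >= 0")
  if (object@oer < 1) msg <- c(msg, "OER must be >= 1")
  if (object@alphaBeta <= 0) msg <- c(msg, "alpha/beta must be > 0")
  if (object@beta > 0 &&
      abs(object@alpha / object@beta - object@alphaBeta) > 1e-6 * object@alphaBeta)
    msg <- c(msg, "alphaBeta inconsistent with alpha and beta")
  if (length(msg)) msg else TRUE
})

#' TcpParams: Poisson-LQ tumor control probability parameters
#'
#' @slot tcd50 Gy (EQD2), uniform dose giving 50% control.
#' @slot gamma50 dimensionless normalized slope at TCD50.
#' @exportClass TcpParams
setClass("TcpParams", representation(tcd50 = "numeric", gamma50 = "numeric"))

setValidity("TcpParams", function(object) {
  if (object@tcd50 <= 0 || object@gamma50 <= 0)
    "tcd50 and gamma50 must be > 0" else TRUE
})

#' NtcpParams: Lyman-Kutcher-Burman model parameters
#'
#' @slot n volume-effect exponent in (0, 1]; @slot m slope parameter;
#' @slot td50 Gy (EQD2), 50% complication dose; @slot endpoint label.
#' @exportClass NtcpParams
setClass("NtcpParams",
  representation(n = "numeric", m = "numeric", td50 = "numeric",
                 endpoint = "character"),
  prototype(endpoint = "")
)

setValidity("NtcpParams", function(object) {
  msg <- character()
  if (object@n <= 0 || object@n > 1) msg <- c(msg, "n must be in (0, 1]")
  if (object@m <= 0) msg <- c(msg, "m must be > 0")
  if (object@td50 <= 0) msg <- c(msg, "td50 must be > 0")
  if (length(msg)) msg else TRUE
})

#' PlanSpec: prescription courses of one treatment plan
#'
#' @slot planId plan identifier ("A".."D" or custom).
#' @slot courses data.frame with columns `target` (structure name), `dose`
#'   (Gy), `nFractions`, `sigma` (mm Gaussian penumbra) and `technique`
#'   (`"conformal"` or `"lattice"`).
#' @exportClass PlanSpec
setClass("PlanSpec",
  representation(planId = "character", courses = "data.frame"))

setValidity("PlanSpec", function(object) {
  msg <- character()
  need <- c("target", "dose", "nFractions", "sigma", "technique")
  if (!all(need %in% names(object@courses)))
    msg <- c(msg, paste("courses must have columns:", paste(need, collapse = ", ")))
  else {
    if (any(object@courses$dose < 0)) msg <- c(msg, "prescription dose must be >= 0")
    if (any(object@courses$nFractions < 1)) msg <- c(msg, "fraction count must be >= 1")
    if (!all(object@courses$technique %in% c("conformal", "lattice")))
      msg <- c(msg, "technique must be 'conformal' or 'lattice'")
  }
  if (length(msg)) msg else TRUE
})

#' ComparisonReport: Table-1-style plan comparison
#'
#' @slot table one row per plan: TCP, NTCPs, compartment summaries.
#' @slot details per-plan list with DVHs, dose summaries and course output.
#' @slot seed integer seed the report was generated with.
#' @slot configHash hash of the full configuration (reproducibility tag).
#' @exportClass ComparisonReport
setClass("ComparisonReport",
  representation(table = "data.frame", details = "list", seed = "integer",
                 configHash = "character")
)

## ---- show methods -------------------------------------------------------

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:",
      sprintf("necrotic %.1f / hypoxic %s / GTV %.1f cm3,",
              object@necroticVolume,
              ifelse(is.na(object@hypoxicVolume), "shell",
                     sprintf("%.1f", object@hypoxicVolume)),
              object@gtvVolume),
      sprintf("%d vertices d=%.1f cm, grid %.2g mm, seed %d\n",
              object@vertexCount, object@vertexDiameter, object@spacing,
              object@seed))
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@masks$gtv)
  cat(sprintf("Phantom on a %d x %d x %d grid (%.2g mm)\n",
              d[1], d[2], d[3], object@spacing[1]))
  for (nm in names(object@masks))
    cat(sprintf("  %-10s %8.2f cm3\n", nm,
                maskVolume(object@masks[[nm]], object@spacing)))
  cat(sprintf("  %d vertices\n", length(object@vertices)))
})

setMethod("show", "DoseGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("DoseGrid '%s' [%s]: %d x %d x %d @ %.2g mm, %s fx, max %.2f Gy\n",
              object@label, object@scale, d[1], d[2], d[3],
              object@spacing[1],
              ifelse(is.na(object@nFractions), "composite",
                     as.character(object@nFractions)),
              max(object@values)))
})

setMethod("show", "DVH", function(object) {
  cat(sprintf("DVH of '%s' [%s]: %d bins, volume %.3f cm3, mean %.2f Gy\n",
              object@structure, object@scale, length(object@volume),
              dvhTotalVolume(object), dvhMeanDose(object)))
})

setMethod("show", "ComparisonReport", function(object) {
  cat(sprintf("ComparisonReport (seed %d, config %s)\n", object@seed,
              object@configHash))
  print(object@table, digits = 3)
})

## ---- accessors ----------------------------------------------------------

#' Extract a structure mask from a phantom
#'
#' @param phantom a [Phantom-class].
#' @param name one of `"necrotic"`, `"hypoxic"`, `"normoxic"`, `"gtv"`,
#'   `"ctv"`, `"skin"`, `"chest_wall"`, `"vertices"` (union of all vertex
#'   spheres) or `"vertexK"` for the K-th vertex.
#' @return logical 3D array.
#' @export
structureMask <- function(phantom, name) {
  stopifnot(is(phantom, "Phantom"))
  if (name %in% names(phantom@masks)) return(phantom@masks[[name]])
  if (name == "vertices") {
    m <- phantom@vertices[[1]]
    for (v in phantom@vertices[-1]) m <- m | v
    return(m)
  }
  k <- suppressWarnings(as.integer(sub("^vertex", "", name)))
  if (grepl("^vertex[0-9]+$", name) && !is.na(k) &&
      k >= 1 && k <= length(phantom@vertices))
    return(phantom@vertices[[k]])
  stop("unknown structure: '", name, "'")
}

#' Names of all structures available in a phantom
#' @param phantom a [Phantom-class].
#' @return character vector of mask names usable with [structureMask()].
#' @export
structureNames <- function(phantom) {
  c(names(phantom@masks), "vertices",
    paste0("vertex", seq_along(phantom@vertices)))
}

#' Dose values, grid spacing and fractionation accessors
#' @param x a [DoseGrid-class].
#' @return `doseValues`: the 3D dose array (Gy); `gridSpacing`: mm spacing;
#'   `nFractions`: integer fraction count; `doseScale`: "physical"/"EQD2".
#' @export
doseValues <- function(x) { stopifnot(is(x, "DoseGrid")); x@values }

#' @rdname doseValues
#' @export
gridSpacing <- function(x) {
  if (is(x, "Phantom")) return(x@spacing)
  stopifnot(is(x, "DoseGrid")); x@spacing
}

#' @rdname doseValues
#' @export
nFractions <- function(x) { stopifnot(is(x, "DoseGrid")); x@nFractions }

#' @rdname doseValues
#' @export
doseScale <- function(x) { stopifnot(is(x, "DoseGrid")); x@scale }

#' Volume of a voxel mask in cm3
#' @param mask logical array.
#' @param spacing mm voxel spacing (length 1 or 3).
#' @return volume in cm3.
#' @export
maskVolume <- function(mask, spacing) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  sum(mask) * prod(spacing) / 1000
}

#' Comparison report table
#' @param report a [ComparisonReport-class].
#' @return the per-plan summary data.frame.
#' @export
reportTable <- function(report) { stopifnot(is(report, "ComparisonReport")); report@table }
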