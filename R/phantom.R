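## Synthetic phantom: concentric-spheroid tumor with necrotic core, hypoxic
## ring and normoxic shell, planar skin and chest-wall OARs, and spherical
## high-dose vertices seated on the core surface.

#' Create a phantom specification
#'
#' Defaults reproduce the study geometry: 86.8 cm3 necrotic core, 13 cm3
#' hypoxic ring bounded by a 2-mm expansion of the core, 171.3 cm3 GTV,
#' 0.5-cm CTV margin, five 1.0-cm vertices with >= 2.0 cm center-to-center
#' separation, a 2-mm skin shell and a 10-mm chest-wall slab near the
#' tumor, on a 1.5-mm isotropic grid.
#'
#' @param necroticVolume cm3 necrotic core volume.
#' @param hypoxicVolume cm3 hypoxic ring volume (`NA` = use the full
#'   expansion shell).
#' @param hypoxicMargin mm outward expansion of the core bounding the ring.
#' @param gtvVolume cm3 total gross tumor volume.
#' @param ctvMargin mm GTV-to-CTV isometric expansion.
#' @param vertexCount number of vertices.
#' @param vertexDiameter cm vertex diameter.
#' @param vertexMinSep cm minimum center-to-center separation.
#' @param skinStandoff,skinThickness mm skin-shell placement on the +x face.
#' @param chestwallStandoff,chestwallThickness mm chest-wall slab placement
#'   on the -x face.
#' @param spacing mm isotropic voxel spacing.
#' @param padding mm clearance between the outermost structure and the grid
#'   boundary.
#' @param seed integer seed for the vertex-placement jitter.
#' @return a validated [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec()
#' spec
#' @export
phantomSpec <- function(necroticVolume = 86.8, hypoxicVolume = 13,
                        hypoxicMargin = 2, gtvVolume = 171.3, ctvMargin = 5,
                        vertexCount = 5L, vertexDiameter = 1.0,
                        vertexMinSep = 2.0, skinStandoff = 5,
                        skinThickness = 2, chestwallStandoff = 5,
                        chestwallThickness = 10, spacing = 1.5,
                        padding = 12, seed = 1L) {
  new("PhantomSpec", necroticVolume = necroticVolume,
      hypoxicVolume = hypoxicVolume, hypoxicMargin = hypoxicMargin,
      gtvVolume = gtvVolume, ctvMargin = ctvMargin,
      vertexCount = as.integer(vertexCount),
      vertexDiameter = vertexDiameter, vertexMinSep = vertexMinSep,
      skinStandoff = skinStandoff, skinThickness = skinThickness,
      chestwallStandoff = chestwallStandoff,
      chestwallThickness = chestwallThickness, spacing = spacing,
      padding = padding, seed = as.integer(seed))
}

#' Radius of a sphere of given volume
#'
#' @param volume cm3.
#' @return radius in cm, `(3 V / 4 pi)^(1/3)`.
#' @examples
#' sphereRadiusForVolume(86.8) # 2.747 cm
#' @export
sphereRadiusForVolume <- function(volume) (3 * volume / (4 * pi))^(1 / 3)

# threshold radius (mm) between the k-th and (k+1)-th sorted center distance
# so that exactly k voxel centers fall inside; keeps voxelized volumes within
# half a voxel of the requested ones
.solveRadius <- function(sortedDist, k) {
  if (k < 1 || k >= length(sortedDist)) stop("grid too small for requested volume")
  (sortedDist[k] + sortedDist[k + 1]) / 2
}

#' Build the voxelized phantom
#'
#' Solves the concentric sphere radii against the voxelized volumes (so the
#' printed subvolume triple is honoured to within half a voxel), places the
#' vertices on the necrotic-core surface, and rasterizes CTV, skin and
#' chest wall.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [Phantom-class] with masks `necrotic`, `hypoxic`, `normoxic`,
#'   `gtv`, `ctv`, `skin`, `chest_wall` and one mask per vertex.
#' @examples
#' ph <- buildPhantom(phantomSpec(spacing = 3))
#' maskVolume(structureMask(ph, "gtv"), gridSpacing(ph))
#' @export
buildPhantom <- function(spec) {
  validObject(spec)
  s <- spec@spacing
  voxvol <- s^3 / 1000 # cm3

  rGtvA <- sphereRadiusForVolume(spec@gtvVolume) * 10 # mm, analytic seed
  rCtv <- rGtvA + spec@ctvMargin
  pad <- spec@padding

  # grid extent: tumor centered at the origin, chest wall on -x, skin on +x
  xlo <- -(rCtv + spec@chestwallStandoff + spec@chestwallThickness + pad)
  xhi <- rCtv + spec@skinStandoff + spec@skinThickness + pad
  yhi <- rCtv + pad
  ix <- seq.int(floor(xlo / s), ceiling(xhi / s))
  iy <- seq.int(-ceiling(yhi / s), ceiling(yhi / s))
  dims <- c(length(ix), length(iy), length(iy))
  origin <- c(ix[1], iy[1], iy[1]) * s
  spacing <- rep(s, 3L)

  # sub-voxel center offset: breaks the tie degeneracy of lattice distances
  # so the solved radii hit the requested voxel counts almost exactly
  center <- s * c(0.251, 0.379, 0.433)
  dist <- sqrt(distSqToPoint(dims, spacing, origin, center))
  sortedDist <- sort(as.vector(dist))

  kNec <- round(spec@necroticVolume / voxvol)
  kGtv <- round(spec@gtvVolume / voxvol)
  rNec <- .solveRadius(sortedDist, kNec)
  rGtv <- .solveRadius(sortedDist, kGtv)
  rCap <- rNec + spec@hypoxicMargin
  if (is.na(spec@hypoxicVolume)) {
    rHyp <- rCap
  } else {
    rHyp <- .solveRadius(sortedDist, kNec + round(spec@hypoxicVolume / voxvol))
    rHyp <- min(rHyp, rCap)
  }
  if (rGtv < rHyp) stop("inconsistent volumes: gtv smaller than core + ring")
  if (rGtv + spec@ctvMargin + pad / 2 > yhi + pad)
    stop("grid too small to contain the CTV")

  necrotic <- dist <= rNec
  hypoxic <- dist > rNec & dist <= rHyp
  gtv <- dist <= rGtv
  normoxic <- gtv & !necrotic & !hypoxic
  ctv <- expandMask(gtv, spec@ctvMargin, spacing)

  xs <- axisCoords(dims, spacing, origin)[[1]]
  xArr <- array(rep(xs, times = dims[2] * dims[3]), dims)
  skin <- xArr >= center[1] + rGtv + spec@skinStandoff &
    xArr < center[1] + rGtv + spec@skinStandoff + spec@skinThickness
  chest <- xArr <= center[1] - (rGtv + spec@chestwallStandoff) &
    xArr > center[1] - (rGtv + spec@chestwallStandoff + spec@chestwallThickness)
  if (!any(skin) || !any(chest)) stop("grid too small to contain the OARs")

  centers <- placeVertices(spec, rNec)
  centers <- centers + rep(center, each = nrow(centers))
  vertices <- lapply(seq_len(nrow(centers)), function(i) {
    distSqToPoint(dims, spacing, origin, centers[i, ]) <=
      (spec@vertexDiameter * 10 / 2)^2
  })

  ph <- new("Phantom", spacing = spacing, origin = origin,
            masks = list(necrotic = necrotic, hypoxic = hypoxic,
                         normoxic = normoxic, gtv = gtv, ctv = ctv,
                         skin = skin, chest_wall = chest),
            vertices = vertices,
            radii = c(necrotic = rNec, hypoxic = rHyp, gtv = rGtv),
            spec = spec)
  validObject(ph)
  attr(ph@vertices, "centers") <- centers
  ph
}

#' Place vertex centers on the necrotic-core surface
#'
#' Vertex centers lie on the core surface so that each sphere straddles the
#' core/ring boundary. Directions are seeded from a Fibonacci spiral on the
#' unit sphere, randomly rotated and jittered (deterministically, from the
#' spec seed); candidate sets violating the minimum center-to-center
#' separation are rejected and re-jittered for a bounded number of
#' attempts.
#'
#' @param spec a [PhantomSpec-class].
#' @param coreRadius mm radius of the sphere carrying the centers.
#' @return numeric matrix (count x 3) of center coordinates in mm, with the
#'   pairwise-distance matrix in attribute `"separation"`.
#' @export
placeVertices <- function(spec, coreRadius) {
  n <- spec@vertexCount
  minSep <- spec@vertexMinSep * 10 # mm
  if (n > 1 && minSep > 2 * coreRadius)
    stop("vertex placement infeasible: separation exceeds core diameter")
  base <- .fibonacciSphere(n)
  withSeed(spec@seed, {
    for (attempt in seq_len(200L)) {
      R <- .randomRotation()
      jitterSd <- 0.06 # radians of angular jitter
      pts <- t(R %*% t(base))
      pts <- pts + matrix(rnorm(3 * n, sd = jitterSd), n, 3)
      pts <- pts / sqrt(rowSums(pts^2))
      centers <- pts * coreRadius
      d <- as.matrix(stats::dist(centers))
      if (n == 1L || min(d[upper.tri(d)]) >= minSep) {
        attr(centers, "separation") <- d
        return(centers)
      }
    }
    stop("vertex placement failed: could not satisfy the separation ",
         "constraint in 200 attempts")
  })
}

.fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

.randomRotation <- function() {
  # QR of a Gaussian matrix, sign-fixed: Haar-distributed rotation
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' @importFrom stats rnorm dist
NULL
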