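## Low-level lattice helpers: coordinates, separable Gaussian smoothing,
## Euclidean distance transform, morphological expansion.

# physical coordinates (mm) of voxel centers along each axis
axisCoords <- function(dims, spacing, origin) {
  lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * spacing[a])
}

# 3D arrays of voxel-center coordinates (memory-cheap outer products)
coordArrays <- function(dims, spacing, origin) {
  cs <- axisCoords(dims, spacing, origin)
  list(
    x = array(rep(cs[[1]], times = dims[2] * dims[3]), dims),
    y = array(rep(rep(cs[[2]], each = dims[1]), times = dims[3]), dims),
    z = array(rep(cs[[3]], each = dims[1] * dims[2]), dims)
  )
}

# squared distance of every voxel center to a point (mm^2)
distSqToPoint <- function(dims, spacing, origin, point) {
  cs <- axisCoords(dims, spacing, origin)
  dx2 <- (cs[[1]] - point[1])^2
  dy2 <- (cs[[2]] - point[2])^2
  dz2 <- (cs[[3]] - point[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`)
}

# apply an n x n band matrix along one axis of a 3D array
applyAxis <- function(arr, K, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                 `3` = c(3L, 1L, 2L))
  a <- aperm(arr, perm)
  dp <- dim(a)
  m <- K %*% matrix(a, nrow = dp[1])
  dim(m) <- dp
  aperm(m, order(perm))
}

# 1D discrete Gaussian convolution matrix with zero padding at the borders
gaussMatrix <- function(n, spacing, sigma) {
  half <- max(1L, ceiling(4 * sigma / spacing))
  offs <- (-half):half
  w <- exp(-(offs * spacing)^2 / (2 * sigma^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (k in seq_along(offs)) {
    j <- seq_len(n) + offs[k]
    ok <- j >= 1 & j <= n
    K[cbind(seq_len(n)[ok], j[ok])] <- K[cbind(seq_len(n)[ok], j[ok])] + w[k]
  }
  K
}

#' Separable 3D Gaussian smoothing
#'
#' Convolves a 3D field with an isotropic Gaussian kernel (truncated at 4
#' sigma, renormalized), with zero padding outside the grid. The discrete
#' kernel sums to one, so the field integral is conserved except for mass
#' blurred across the grid boundary.
#'
#' @param arr 3D numeric array.
#' @param spacing mm voxel spacing (length 1 or 3).
#' @param sigma mm Gaussian standard deviation; `0` returns `arr` unchanged.
#' @return smoothed array of the same dimensions.
#' @export
gaussBlur3d <- function(arr, spacing, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(arr)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  d <- dim(arr)
  for (a in 1:3) arr <- applyAxis(arr, gaussMatrix(d[a], spacing[a], sigma), a)
  arr
}

#' Euclidean distance to a mask
#'
#' Exact anisotropic 3D Euclidean distance (mm) from every voxel center to
#' the nearest voxel center belonging to `mask` (0 inside the mask).
#'
#' @param mask logical 3D array with at least one `TRUE` voxel.
#' @param spacing mm voxel spacing (length 1 or 3).
#' @return numeric array of distances in mm.
#' @export
distanceToMask <- function(mask, spacing) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop("mask is empty")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  .edt3d(as.vector(mask), dim(mask), as.numeric(spacing))
}

#' Isotropic morphological expansion of a mask
#'
#' Dilates a structure mask by a Euclidean ball of the given radius: the
#' result contains every voxel whose center lies within `margin` mm of a
#' voxel center of the input mask (clipped to the grid).
#'
#' @param mask logical 3D array.
#' @param margin mm expansion radius (>= 0; 0 returns the mask unchanged).
#' @param spacing mm voxel spacing (length 1 or 3).
#' @return logical array of the same dimensions.
#' @export
expandMask <- function(mask, margin, spacing) {
  if (margin < 0) stop("margin must be >= 0")
  if (margin == 0) return(mask)
  distanceToMask(mask, spacing) <= margin
}

# run an expression under a temporary RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

# FNV-1a hash over a serialized R object (reproducibility tag for outputs)
configHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # exact 32-bit modular product in double arithmetic
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 4294967296
  }
  # h is a double holding a 32-bit value; format as hex via two halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
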