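#' Construct an ImageVolume
#'
#' @param data 3D or 4D numeric array.
#' @param spacing voxel spacing in mm, length 3.
#' @param origin world coordinates (mm) of the centre of voxel (1,1,1).
#' @param direction 3x3 direction cosine matrix (RAS).
#' @param timeStep frame spacing in seconds for time-resolved 4D data.
#' @return An \linkS4class{ImageVolume}.
#' @export
imageVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        direction = diag(3), timeStep = NA_real_) {
  if (is.null(dim(data))) stop("data must be an array")
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), direction = direction,
      timeStep = as.numeric(timeStep))
}

#' @describeIn imageVolume voxel data array.
#' @param x,vol an ImageVolume.
#' @export
volData <- function(x) x@data

#' @describeIn imageVolume voxel spacing (mm).
#' @export
volSpacing <- function(x) x@spacing

#' @describeIn imageVolume spatial dimensions (voxels).
#' @export
volDims <- function(x) dim(x@data)[1:3]

#' @describeIn imageVolume number of frames (1 for 3D volumes).
#' @export
nFrames <- function(x) if (length(dim(x@data)) == 4L) dim(x@data)[4] else 1L

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume: %s voxels, spacing %s mm\n",
              paste(d, collapse = " x "),
              paste(signif(object@spacing, 3), collapse = " x ")))
  if (!is.na(object@timeStep))
    cat(sprintf("  frame spacing: %g s\n", object@timeStep))
})

#' Voxel/world coordinate conversion
#'
#' Voxel indices are continuous and 1-based; voxel (1,1,1) centre sits at
#' \code{origin}.
#'
#' @param vol an ImageVolume.
#' @param ijk n x 3 matrix of voxel indices.
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix.
#' @export
voxelToWorld <- function(vol, ijk) {
  ijk <- rbind(ijk)
  sweep((ijk - 1) %*% t(vol@direction %*% diag(vol@spacing)), 2,
        vol@origin, "+")
}

#' @rdname voxelToWorld
#' @export
worldToVoxel <- function(vol, xyz) {
  xyz <- rbind(xyz)
  sweep(xyz, 2, vol@origin, "-") %*%
    t(solve(vol@direction %*% diag(vol@spacing))) + 1
}

#' @rdname voxelToWorld
#' @export
volAffine <- function(vol) {
  A <- diag(4)
  A[1:3, 1:3] <- vol@direction %*% diag(vol@spacing)
  A[1:3, 4] <- vol@origin - A[1:3, 1:3] %*% c(1, 1, 1)  # 1-based indices
  A
}

## ---- interpolation ---------------------------------------------------------

#' Trilinear interpolation at continuous voxel coordinates
#'
#' @param arr 3D array.
#' @param ijk n x 3 continuous 1-based voxel coordinates.
#' @param fill value for points outside the grid.
#' @return numeric vector of length n.
#' @export
interpTrilinear <- function(arr, ijk, fill = NA_real_) {
  d <- dim(arr)
  ijk <- rbind(ijk)
  inside <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] &
            ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
            ijk[, 3] >= 1 & ijk[, 3] <= d[3]
  out <- rep(fill, nrow(ijk))
  if (!any(inside)) return(out)
  p <- ijk[inside, , drop = FALSE]
  i0 <- pmin(floor(p[, 1]), max(d[1] - 1, 1)); fx <- p[, 1] - i0
  j0 <- pmin(floor(p[, 2]), max(d[2] - 1, 1)); fy <- p[, 2] - j0
  k0 <- pmin(floor(p[, 3]), max(d[3] - 1, 1)); fz <- p[, 3] - k0
  i1 <- pmin(i0 + 1, d[1]); j1 <- pmin(j0 + 1, d[2]); k1 <- pmin(k0 + 1, d[3])
  lin <- function(i, j, k) arr[cbind(i, j, k)]
  v <- lin(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
       lin(i1, j0, k0) * fx       * (1 - fy) * (1 - fz) +
       lin(i0, j1, k0) * (1 - fx) * fy       * (1 - fz) +
       lin(i1, j1, k0) * fx       * fy       * (1 - fz) +
       lin(i0, j0, k1) * (1 - fx) * (1 - fy) * fz +
       lin(i1, j0, k1) * fx       * (1 - fy) * fz +
       lin(i0, j1, k1) * (1 - fx) * fy       * fz +
       lin(i1, j1, k1) * fx       * fy       * fz
  out[inside] <- v
  out
}

#' @rdname interpTrilinear
#' @export
interpNearest <- function(arr, ijk, fill = NA_real_) {
  d <- dim(arr)
  ijk <- round(rbind(ijk))
  inside <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] &
            ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
            ijk[, 3] >= 1 & ijk[, 3] <= d[3]
  out <- rep(fill, nrow(ijk))
  out[inside] <- arr[ijk[inside, , drop = FALSE]]
  out
}

#' Resample a volume onto a template grid through a world affine
#'
#' The transform follows the resampling (pull-back) convention: for each
#' output voxel centre x in the template's world frame, the output value is
#' the moving volume interpolated at world point \code{transform \%*\% x}.
#'
#' @param moving source ImageVolume (3D).
#' @param template ImageVolume defining the output grid.
#' @param transform 4x4 world affine, template world -> moving world.
#' @param interpolation "linear" or "nearest".
#' @param fill value outside the moving field of view.
#' @return ImageVolume on the template grid.
#' @export
resampleVolume <- function(moving, template, transform = diag(4),
                           interpolation = c("linear", "nearest"), fill = 0) {
  interpolation <- match.arg(interpolation)
  d <- volDims(template)
  ijk <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  xyz <- voxelToWorld(template, ijk)
  xyz <- cbind(xyz, 1) %*% t(transform)
  src <- worldToVoxel(moving, xyz[, 1:3, drop = FALSE])
  vals <- if (interpolation == "linear") {
    interpTrilinear(volData3(moving), src, fill = fill)
  } else {
    interpNearest(volData3(moving), src, fill = fill)
  }
  imageVolume(array(vals, dim = d), spacing = template@spacing,
              origin = template@origin, direction = template@direction)
}

## first frame for 4D inputs, identity for 3D
volData3 <- function(vol) {
  a <- vol@data
  if (length(dim(a)) == 4L) a <- a[, , , 1, drop = TRUE]
  if (length(dim(a)) < 3L) dim(a) <- c(dim(a), 1L)
  a
}

## ---- separable Gaussian smoothing -----------------------------------------

.gaussKernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r):r / sigma)^2)
  k / sum(k)
}

.convAxis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  r <- (length(kernel) - 1L) / 2L
  mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
              m[rep(nrow(m), r), , drop = FALSE])
  f <- stats::filter(mp, kernel, sides = 2)
  m2 <- as.matrix(f)[(r + 1L):(r + d[axis]), , drop = FALSE]
  a2 <- array(m2, dim = d[perm])
  aperm(a2, order(perm))
}

#' Separable Gaussian smoothing of a 3D array
#'
#' @param arr 3D array.
#' @param sigmaVox per-axis standard deviation in voxels (0 = no smoothing).
#' @return smoothed array.
#' @export
gaussianSmooth3D <- function(arr, sigmaVox) {
  sigmaVox <- rep_len(sigmaVox, 3L)
  for (ax in 1:3) {
    if (sigmaVox[ax] > 0.05 && dim(arr)[ax] > 1)
      arr <- .convAxis(arr, .gaussKernel1d(sigmaVox[ax]), ax)
  }
  arr
}

## ---- reframing and anti-aliased down-sampling (PET/CT -> MRI grid) --------

#' Reframe slices by averaging to a thicker slice spacing
#'
#' Adjacent slices are averaged in non-overlapping groups so the output slice
#' thickness equals \code{targetThickness}; the in-plane grid is unchanged.
#' Requires an integer thickness ratio.
#'
#' @param vol ImageVolume (3D or 4D; frames reframed independently).
#' @param targetThickness output slice thickness, mm.
#' @return reframed ImageVolume.
#' @export
reframeSlices <- function(vol, targetThickness) {
  ratio <- targetThickness / vol@spacing[3]
  if (abs(ratio - round(ratio)) > 1e-8 || ratio < 1)
    stop("target thickness must be an integer multiple of the source slice ",
         "thickness; for non-integer ratios use downsampleAntialias()")
  r <- as.integer(round(ratio))
  a <- vol@data
  is4d <- length(dim(a)) == 4L
  if (!is4d) dim(a) <- c(dim(a), 1L)
  d <- dim(a)
  nz <- d[3] %/% r
  if (nz < 1) stop("too few slices to reframe")
  out <- array(0, c(d[1], d[2], nz, d[4]))
  for (k in seq_len(nz)) {
    sl <- a[, , ((k - 1L) * r + 1L):(k * r), , drop = FALSE]
    out[, , k, ] <- apply(sl, c(1, 2, 4), mean)
  }
  if (!is4d) out <- out[, , , 1, drop = TRUE]
  if (length(dim(out)) < 3L) dim(out) <- c(dim(out), 1L)
  ## new slice centres sit at the mean of the averaged slice centres
  shift <- vol@direction %*% (c(0, 0, (r - 1) / 2) * vol@spacing)
  imageVolume(out, spacing = c(vol@spacing[1:2], vol@spacing[3] * r),
              origin = vol@origin + as.numeric(shift),
              direction = vol@direction, timeStep = vol@timeStep)
}

#' Anti-aliased linear down-sampling onto a coarser grid
#'
#' Gaussian prefilter (sigma matched to the decimation factor per axis)
#' followed by linear interpolation onto the target spacing, preserving the
#' field of view.
#'
#' @param vol 3D ImageVolume.
#' @param targetSpacing numeric(3) output spacing, mm (each >= source).
#' @return ImageVolume at the target spacing.
#' @export
downsampleAntialias <- function(vol, targetSpacing) {
  targetSpacing <- rep_len(targetSpacing, 3L)
  f <- targetSpacing / vol@spacing
  if (any(f < 1 - 1e-8)) stop("targetSpacing must be >= source spacing")
  sigma <- ifelse(f > 1.05, 0.7 * f, 0)
  sm <- gaussianSmooth3D(volData3(vol), sigma)
  smoothed <- imageVolume(sm, spacing = vol@spacing, origin = vol@origin,
                          direction = vol@direction)
  d <- volDims(vol)
  extent <- d * vol@spacing
  nd <- pmax(1L, as.integer(floor(extent / targetSpacing + 1e-8)))
  ## centre the new grid on the old field of view
  offWorld <- vol@direction %*% ((targetSpacing * (nd - 1) -
                                  vol@spacing * (d - 1)) / -2)
  template <- imageVolume(array(0, nd), spacing = targetSpacing,
                          origin = vol@origin + as.numeric(offWorld),
                          direction = vol@direction)
  resampleVolume(smoothed, template, interpolation = "linear", fill = 0)
}

#' Dice similarity coefficient of two masks
#'
#' 2|A n B| / (|A| + |B|) on a common grid.
#'
#' @param maskA,maskB logical arrays of identical dimension.
#' @return Dice coefficient in [0, 1].
#' @export
diceCoefficient <- function(maskA, maskB) {
  maskA <- as.logical(maskA); maskB <- as.logical(maskB)
  if (length(maskA) != length(maskB)) stop("masks must share a grid")
  sa <- sum(maskA); sb <- sum(maskB)
  if (sa + sb == 0) stop("both masks are empty")
  2 * sum(maskA & maskB) / (sa + sb)
}
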