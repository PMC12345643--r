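#' Read / write ImageVolumes as NIfTI-1
#'
#' Round trips preserve data, spacing and pose.  4D volumes store their frame
#' spacing (s) in the NIfTI time pixdim.
#'
#' @param path NIfTI file path (.nii or .nii.gz).
#' @param vol an ImageVolume.
#' @return \code{readVolume}: an ImageVolume; \code{writeVolume}: the path,
#'   invisibly.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  a <- array(as.vector(img), dim(img))
  pd <- attr(img, "pixdim")
  x <- RNifti::xform(img)
  M <- matrix(x, 4, 4)[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  direction <- sweep(M, 2, spacing, "/")
  ## NIfTI indexes voxels from 0; our origin is the (1,1,1) voxel centre
  origin <- matrix(x, 4, 4)[1:3, 4]
  nd <- length(dim(a))
  ts <- if (nd == 4L && length(pd) >= 4 && pd[4] > 0) pd[4] else NA_real_
  imageVolume(a, spacing = spacing, origin = origin, direction = direction,
              timeStep = ts)
}

#' @rdname readVolume
#' @export
writeVolume <- function(vol, path) {
  a <- vol@data
  img <- RNifti::asNifti(a)
  pd <- vol@spacing
  if (length(dim(a)) == 4L)
    pd <- c(pd, if (is.na(vol@timeStep)) 1 else vol@timeStep)
  RNifti::pixdim(img) <- pd
  M <- diag(4)
  M[1:3, 1:3] <- vol@direction %*% diag(vol@spacing)
  M[1:3, 4] <- vol@origin
  RNifti::sform(img) <- structure(M, code = 2L)
  RNifti::qform(img) <- structure(M, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Validated configuration for the synthetic end-to-end run; unknown keys are
#' rejected.
#'
#' @param ... overrides of the defaults below.
#' @return list of class "habitatPipelineConfig".
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    gridDims = c(48, 48, 10),
    spacing = c(0.5, 0.5, 1),
    nSubjects = 4L,
    timepoints = c(0L, 4L),
    nHabitats = 5L,
    necroticFraction = c(0.25, 0.5),   # per-subject range
    mapNoiseSd = c(adc = 0.05e-3, ktrans = 0.015, ve = 0.03,
                   suv_fdg = 0.08, suv_flt = 0.08),
    kRange = 2:8,
    maxClusterRows = 8000L,
    msiConnectivity = 6L,
    msiRandomizations = 200L,
    histKernelPx = 10L,
    histPxPerVoxel = 4L,
    histTargetPixelSizeMm = 0.25,
    sliceWindow = 2L,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "habitatPipelineConfig"
  cfg
}
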