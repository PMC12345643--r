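#' @import methods
NULL

#' Spatially referenced image volume
#'
#' A 3D scalar volume or 4D stack (space x space x space x frame) with voxel
#' spacing in mm and a world pose given by an origin (world coordinates of the
#' centre of voxel (1,1,1)) and a 3x3 direction matrix.  World coordinates are
#' RAS; voxel indices are 1-based in R, with the continuous coordinate of a
#' voxel centre equal to its index.
#'
#' @slot data numeric array, 3 or 4 dimensions.
#' @slot spacing numeric(3), mm per voxel along each spatial axis.
#' @slot origin numeric(3), world position (mm) of the first voxel centre.
#' @slot direction 3x3 orthonormal direction cosine matrix.
#' @slot timeStep frame spacing in seconds for 4D volumes (NA for 3D, and for
#'   4D stacks indexed by something other than time, e.g. b-value or TR).
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 direction = "matrix", timeStep = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0),
            direction = diag(3), timeStep = NA_real_))

setValidity("ImageVolume", function(object) {
  nd <- length(dim(object@data))
  if (!nd %in% c(3L, 4L)) return("data must be a 3D or 4D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive values (mm)")
  if (length(object@origin) != 3L) return("origin must have length 3")
  if (!all(dim(object@direction) == c(3L, 3L)))
    return("direction must be a 3x3 matrix")
  TRUE
})

#' Ground-truth digital tumor phantom
#'
#' Habitat label volume plus the generative per-habitat physiological
#' parameters.  Labels: 0 = background, -1 = necrotic core, 1..n = viable
#' habitats.
#'
#' @slot labels integer 3D array of habitat ids.
#' @slot spacing voxel spacing, mm.
#' @slot habitatParams data.frame, one row per viable habitat with columns
#'   adc (mm^2/s), ktrans (1/min), ve, vp, suv_fdg, suv_flt, t1 (ms), s0 (a.u.).
#' @slot necroticParams single-row data.frame with the same columns,
#'   parameterizing the non-enhancing necrotic core.
#' @slot seed integer seed the phantom was generated from.
#' @export
setClass("PhantomTruth",
  representation(labels = "array", spacing = "numeric",
                 habitatParams = "data.frame", necroticParams = "data.frame",
                 seed = "integer"))

.paramCols <- c("adc", "ktrans", "ve", "vp", "suv_fdg", "suv_flt", "t1", "s0")

setValidity("PhantomTruth", function(object) {
  if (length(dim(object@labels)) != 3L) return("labels must be a 3D array")
  if (!all(.paramCols %in% names(object@habitatParams)))
    return(paste("habitatParams needs columns:", paste(.paramCols, collapse = ", ")))
  lab <- unique(as.integer(object@labels))
  pos <- sort(lab[lab > 0])
  if (length(pos) && max(pos) > nrow(object@habitatParams))
    return("labels reference habitats without parameters")
  TRUE
})

#' Acquisition protocol parameters
#'
#' @slot bValues diffusion b-values, s/mm^2 (strictly increasing, first = 0).
#' @slot trList variable repetition times for T1 mapping, ms (increasing).
#' @slot dceTemporalRes DCE frame spacing, s.
#' @slot nPrecontrastFrames baseline DCE frames before contrast arrival.
#' @slot dceNFrames total DCE frames.
#' @slot dceTrMs repetition time of the dynamic T1-weighted sequence, ms.
#' @slot relaxivity contrast agent longitudinal relaxivity r1, 1/s/mM.
#' @slot injectedDose injected tracer activity (arbitrary activity units).
#' @slot bodyWeight subject mass (arbitrary mass units).
#' @slot noiseSd acquisition noise scale, a.u.
#' @slot misalignment 4x4 world affine used to misalign PET/CT vs MRI.
#' @export
setClass("AcquisitionConfig",
  representation(bValues = "numeric", trList = "numeric",
                 dceTemporalRes = "numeric", nPrecontrastFrames = "integer",
                 dceNFrames = "integer", dceTrMs = "numeric",
                 relaxivity = "numeric", injectedDose = "numeric",
                 bodyWeight = "numeric", noiseSd = "numeric",
                 misalignment = "matrix"))

setValidity("AcquisitionConfig", function(object) {
  if (is.unsorted(object@bValues, strictly = TRUE))
    return("bValues must be strictly increasing")
  if (is.unsorted(object@trList, strictly = TRUE))
    return("trList must be strictly increasing")
  if (object@dceTemporalRes <= 0) return("dceTemporalRes must be > 0")
  if (object@nPrecontrastFrames < 1L) return("nPrecontrastFrames must be >= 1")
  if (object@dceNFrames <= object@nPrecontrastFrames)
    return("dceNFrames must exceed nPrecontrastFrames")
  if (!all(dim(object@misalignment) == c(4L, 4L)))
    return("misalignment must be a 4x4 affine")
  TRUE
})

#' Population arterial input function
#'
#' Biexponential bolus Cp(t) = scale * A * (exp(-k1 (t - t0)) - exp(-k2 (t - t0)))
#' for t >= t0, zero before contrast arrival at t0.
#'
#' @slot amplitude A, mM.
#' @slot k1 slow (washout) rate, 1/s.
#' @slot k2 fast (uptake) rate, 1/s; k2 > k1.
#' @slot amplitudeScale per-scan calibration factor (muscle reference).
#' @slot onsetTime contrast arrival time t0, s.
#' @export
setClass("AIFModel",
  representation(amplitude = "numeric", k1 = "numeric", k2 = "numeric",
                 amplitudeScale = "numeric", onsetTime = "numeric"))

setValidity("AIFModel", function(object) {
  if (object@amplitudeScale <= 0) return("amplitudeScale must be > 0")
  if (object@k2 <= object@k1) return("k2 must exceed k1")
  TRUE
})

#' Apparent diffusion coefficient map
#' @slot adc ADC in mm^2/s per voxel (NA = invalid).
#' @slot s0 fitted b=0 signal, a.u.
#' @slot excludedSlices slice indices excluded from ADC analysis.
#' @export
setClass("ADCMap",
  representation(adc = "array", s0 = "array", excludedSlices = "integer"))

#' Longitudinal relaxation time map
#' @slot t1 T1 in ms per voxel (NA = invalid).
#' @slot s0 fitted equilibrium signal, a.u.
#' @export
setClass("T1Map", representation(t1 = "array", s0 = "array"))

#' Extended Tofts parameter map
#' @slot ktrans volume transfer constant, 1/min.
#' @slot ve extravascular extracellular volume fraction.
#' @slot vp plasma volume fraction.
#' @slot enhancement peak fractional signal enhancement over baseline.
#' @slot valid logical mask of voxels passing fit and physiological filters.
#' @export
setClass("ToftsMap",
  representation(ktrans = "array", ve = "array", vp = "array",
                 enhancement = "array", valid = "array"))

#' Standardized uptake value map
#' @slot suv unitless SUV per voxel.
#' @slot injectedDose activity units.
#' @slot bodyWeight mass units.
#' @export
setClass("SUVMap",
  representation(suv = "array", injectedDose = "numeric",
                 bodyWeight = "numeric"))

setValidity("SUVMap", function(object) {
  if (object@injectedDose <= 0 || object@bodyWeight <= 0)
    return("injectedDose and bodyWeight must be > 0")
  TRUE
})

#' Co-registered per-voxel parametric map set
#'
#' The five clustering features (ADC, Ktrans, ve, FDG-SUV, FLT-SUV) plus vp
#' (computed but withheld from clustering), and a joint validity mask.
#'
#' @slot adc,ktrans,ve,vp,suvFdg,suvFlt numeric arrays on a common grid.
#' @slot valid logical array: voxel valid in every map.
#' @slot spacing mm.
#' @export
setClass("ParametricMapSet",
  representation(adc = "array", ktrans = "array", ve = "array", vp = "array",
                 suvFdg = "array", suvFlt = "array", valid = "array",
                 spacing = "numeric"))

#' Pooled voxel feature matrix for habitat discovery
#'
#' @slot features voxels x 5 matrix in original units
#'   (adc, ktrans, ve, suv_fdg, suv_flt).
#' @slot normFeatures z-scored features (empty until \code{normalizeFeatures}).
#' @slot provenance data.frame with subject, timepoint, voxel (linear index)
#'   and grid dims per row.
#' @slot normStats per-feature mean/sd used for normalization.
#' @export
setClass("HabitatFeatures",
  representation(features = "matrix", normFeatures = "matrix",
                 provenance = "data.frame", normStats = "data.frame"))

#' Fitted habitat clustering model
#'
#' @slot k number of habitats.
#' @slot assignments integer cluster id per pooled voxel row (ids ordered by
#'   decreasing cluster size).
#' @slot centroids k x 5 matrix of per-cluster feature means, original units.
#' @slot signatures k x 5 character matrix ("high"/"low") relative to the
#'   cross-cluster median centroid per feature.
#' @slot habitatNames habitat label per cluster (HV, HRSP, TZ, ATMR, RSP or
#'   generic).
#' @slot provenance row provenance copied from the feature matrix.
#' @export
setClass("HabitatModel",
  representation(k = "integer", assignments = "integer", centroids = "matrix",
                 signatures = "matrix", habitatNames = "character",
                 provenance = "data.frame"))

setValidity("HabitatModel", function(object) {
  if (length(object@assignments) &&
      !all(seq_len(object@k) %in% object@assignments))
    return("every cluster id 1..k must be nonempty")
  TRUE
})

#' Multiregional spatial interaction statistics
#'
#' @slot pairFraction symmetric k x k matrix of neighboring-voxel-pair
#'   fractions; the unique unordered entries (upper triangle incl. diagonal)
#'   sum to 1.
#' @slot nullMean,nullSd randomized-null statistics, same layout.
#' @slot z (observed - null mean) / null sd; NA where null sd is 0.
#' @slot nRandomizations number of label shuffles.
#' @slot connectivity 6 (faces) or 26 (full 3D neighborhood).
#' @export
setClass("MSIMatrix",
  representation(pairFraction = "matrix", nullMean = "matrix",
                 nullSd = "matrix", z = "matrix", nRandomizations = "integer",
                 connectivity = "integer"))

#' Affine registration result
#'
#' @slot affine 4x4 world-coordinate resampling transform mapping fixed-image
#'   world points to moving-image world points.
#' @slot metricTrace Mattes mutual information per accepted iteration.
#' @slot diceBefore,diceAfter tumor-mask Dice overlap before/after.
#' @export
setClass("RegistrationResult",
  representation(affine = "matrix", metricTrace = "numeric",
                 diceBefore = "numeric", diceAfter = "numeric"))

setValidity("RegistrationResult", function(object) {
  if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
  if (abs(det(object@affine[1:3, 1:3])) < 1e-12)
    return("affine must be invertible")
  TRUE
})

#' Histology stain-density section
#'
#' 2D per-stain density maps from cell detections, with a living-tissue
#' validity mask.  Stains: nuclei (H&E), cd31 (vessels), ki67 (proliferating
#' nuclei), glut1 (glucose transporter area), pimo (pimonidazole hypoxia).
#'
#' @slot stains named list of numeric matrices, all the same dimension.
#' @slot valid logical matrix, TRUE on living tissue.
#' @slot pixelSizeMm pixel edge length, mm.
#' @slot truthLabels integer matrix of generating habitat ids (0 when the
#'   section does not come from a phantom).
#' @export
setClass("StainDensitySection",
  representation(stains = "list", valid = "matrix", pixelSizeMm = "numeric",
                 truthLabels = "matrix"))

setValidity("StainDensitySection", function(object) {
  d <- dim(object@valid)
  for (s in object@stains)
    if (!all(dim(s) == d)) return("all stain maps must share the mask dims")
  if (any(unlist(object@stains) < 0, na.rm = TRUE))
    return("stain densities must be >= 0")
  TRUE
})
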