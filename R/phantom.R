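#' Default per-habitat physiological parameters
#'
#' Five phenotypes patterned on the habitat signatures reported for
#' trastuzumab-treated HER2+ tumors: high vascularity (high Ktrans/ve),
#' hypoxic responding (low Ktrans, high ve, low FDG), transitional zone
#' (highest ADC), active tumor (high FDG/FLT, low Ktrans) and responding
#' (low everywhere).  Rows 6-8 provide generic extra habitats for phantoms
#' with more clusters.  All values sit inside the physiological filter ranges.
#'
#' @param n number of habitats (2..8).
#' @return data.frame with columns adc, ktrans, ve, vp, suv_fdg, suv_flt,
#'   t1, s0.
#' @export
defaultHabitatParams <- function(n = 5) {
  tab <- data.frame(
    adc     = c(0.70e-3, 0.95e-3, 1.30e-3, 0.60e-3, 0.72e-3,
                1.05e-3, 0.50e-3, 1.50e-3),
    ktrans  = c(0.44, 0.05, 0.15, 0.12, 0.10, 0.30, 0.20, 0.06),
    ve      = c(0.45, 0.60, 0.30, 0.20, 0.15, 0.50, 0.25, 0.70),
    vp      = c(0.040, 0.010, 0.020, 0.020, 0.010, 0.030, 0.015, 0.008),
    suv_fdg = c(1.2, 0.7, 1.0, 2.2, 0.6, 1.5, 1.8, 0.9),
    suv_flt = c(1.0, 0.8, 0.9, 2.0, 0.5, 1.3, 1.6, 0.7),
    t1      = c(1600, 1900, 2000, 1700, 1800, 1750, 1650, 2100),
    s0      = rep(1000, 8))
  if (n < 1 || n > 8) stop("supported habitat count is 1..8")
  tab[seq_len(n), , drop = FALSE]
}

#' @rdname defaultHabitatParams
#' @export
defaultNecroticParams <- function() {
  ## designed to fail the 25% enhancement rule: negligible exchange/plasma
  data.frame(adc = 1.8e-3, ktrans = 0.002, ve = 0.10, vp = 0.002,
             suv_fdg = 0.30, suv_flt = 0.25, t1 = 2200, s0 = 1000)
}

#' Generate a digital tumor phantom with planted habitats
#'
#' Places an ellipsoidal tumor in the grid, carves out a central necrotic
#' core occupying \code{necroticFraction} of the tumor, and partitions the
#' remaining viable tissue into \code{nHabitats} spatially contiguous
#' subregions (nearest-seed regions of well-separated seed points).
#' Deterministic for a fixed seed.
#'
#' @param gridDims voxel counts, length 3.
#' @param nHabitats number of viable habitats (1..8).
#' @param necroticFraction fraction of tumor voxels in the necrotic core
#'   (0 <= f < 0.8).
#' @param seed integer RNG seed.
#' @param spacing voxel spacing, mm.
#' @param habitatParams per-habitat generative parameters
#'   (\code{\link{defaultHabitatParams}}).
#' @param shuffled if TRUE, habitat labels are randomly permuted across
#'   viable voxels (non-contiguous control for spatial-interaction nulls).
#' @return A \linkS4class{PhantomTruth}.
#' @export
generatePhantom <- function(gridDims = c(64, 64, 10), nHabitats = 5,
                            necroticFraction = 0.37, seed = 1,
                            spacing = c(0.5, 0.5, 1),
                            habitatParams = defaultHabitatParams(nHabitats),
                            shuffled = FALSE) {
  if (nHabitats < 1 || nHabitats > 8) stop("nHabitats must be in 1..8")
  if (necroticFraction < 0 || necroticFraction >= 0.8)
    stop("necroticFraction must be in [0, 0.8)")
  gridDims <- as.integer(gridDims)
  rng <- .localRNG(seed)
  on.exit(rng())

  ctr <- (gridDims + 1) / 2
  semi <- pmax(gridDims * 0.38, 1)
  ijk <- as.matrix(expand.grid(i = seq_len(gridDims[1]),
                               j = seq_len(gridDims[2]),
                               k = seq_len(gridDims[3])))
  rho2 <- rowSums(sweep(sweep(ijk, 2, ctr, "-"), 2, semi, "/")^2)
  tumor <- rho2 <= 1
  ntum <- sum(tumor)
  if (ntum < 10 * nHabitats)
    stop("grid too small to place ", nHabitats, " distinct habitats")

  labels <- integer(nrow(ijk))
  tumIdx <- which(tumor)
  ## necrotic core: innermost voxels by the ellipsoidal radius
  nNec <- floor(necroticFraction * ntum)
  ord <- tumIdx[order(rho2[tumIdx])]
  necIdx <- ord[seq_len(nNec)]
  labels[necIdx] <- -1L
  viaIdx <- setdiff(tumIdx, necIdx)
  if (length(viaIdx) < nHabitats)
    stop("grid too small to place ", nHabitats, " distinct habitats")

  ## greedy farthest-point seeds in mm space, then weighted nearest-seed
  ## partition; random per-habitat growth weights vary the habitat sizes
  ## between phantoms (tumor composition differs between subjects) while the
  ## regions stay contiguous
  pts <- sweep(ijk[viaIdx, , drop = FALSE], 2, spacing, "*")
  seeds <- sample.int(length(viaIdx), 1L)
  dmin <- .rowDist2(pts, pts[seeds, ])
  while (length(seeds) < nHabitats) {
    nxt <- which.max(dmin)
    seeds <- c(seeds, nxt)
    dmin <- pmin(dmin, .rowDist2(pts, pts[nxt, ]))
  }
  growth <- exp(stats::runif(nHabitats, -0.6, 0.6))
  d2 <- sapply(seq_along(seeds), function(h)
    .rowDist2(pts, pts[seeds[h], ]) * growth[h]^2)
  assign <- max.col(-d2, ties.method = "first")
  if (shuffled) assign <- assign[sample.int(length(assign))]
  labels[viaIdx] <- assign

  new("PhantomTruth", labels = array(labels, gridDims),
      spacing = as.numeric(spacing), habitatParams = habitatParams,
      necroticParams = defaultNecroticParams(), seed = as.integer(seed))
}

.rowDist2 <- function(pts, p) colSums((t(pts) - p)^2)

## run code under a local RNG state; returns a restore function
.localRNG <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

setMethod("show", "PhantomTruth", function(object) {
  lab <- as.integer(object@labels)
  cat(sprintf(
    "PhantomTruth: %s grid, %d habitats, %d tumor voxels (%.1f%% necrotic)\n",
    paste(dim(object@labels), collapse = " x "),
    nrow(object@habitatParams), sum(lab != 0),
    100 * sum(lab == -1L) / max(1L, sum(lab != 0L))))
})

#' Phantom accessors
#'
#' @param truth a PhantomTruth.
#' @return \code{tumorMask}/\code{viableMask}: logical arrays;
#'   \code{labelVolume}: ImageVolume of habitat ids; \code{truthParamMap}:
#'   numeric array of the requested generative parameter.
#' @export
tumorMask <- function(truth) truth@labels != 0L

#' @rdname tumorMask
#' @export
viableMask <- function(truth) truth@labels > 0L

#' @rdname tumorMask
#' @export
labelVolume <- function(truth)
  imageVolume(truth@labels, spacing = truth@spacing)

#' @rdname tumorMask
#' @param param one of adc, ktrans, ve, vp, suv_fdg, suv_flt, t1, s0.
#' @param background value outside the tumor.
#' @export
truthParamMap <- function(truth, param, background = NA_real_) {
  stopifnot(param %in% .paramCols)
  vals <- c(truth@necroticParams[[param]], background,
            truth@habitatParams[[param]])
  array(vals[as.integer(truth@labels) + 2L], dim(truth@labels))
}

#' Default acquisition configuration
#'
#' Reference small-animal protocol: 4 diffusion b-values (0/150/500/800
#' s/mm^2), variable TR series (255..5500 ms), 6.4 s DCE frames with 20
#' pre-contrast frames, FLASH TR 100 ms, r1 = 4.5 /s/mM at 9.4 T.
#'
#' @param bValues,trList,dceTemporalRes,nPrecontrastFrames,dceNFrames,dceTrMs,relaxivity,injectedDose,bodyWeight,noiseSd,misalignment see slots.
#' @return An \linkS4class{AcquisitionConfig}.
#' @export
acquisitionConfig <- function(bValues = c(0, 150, 500, 800),
                              trList = c(255, 400, 800, 1500, 3000, 5500),
                              dceTemporalRes = 6.4,
                              nPrecontrastFrames = 20L, dceNFrames = 70L,
                              dceTrMs = 100, relaxivity = 4.5,
                              injectedDose = 100, bodyWeight = 20,
                              noiseSd = 0, misalignment = diag(4)) {
  new("AcquisitionConfig", bValues = bValues, trList = trList,
      dceTemporalRes = dceTemporalRes,
      nPrecontrastFrames = as.integer(nPrecontrastFrames),
      dceNFrames = as.integer(dceNFrames), dceTrMs = dceTrMs,
      relaxivity = relaxivity, injectedDose = injectedDose,
      bodyWeight = bodyWeight, noiseSd = noiseSd,
      misalignment = misalignment)
}

## Rician-distributed magnitude signal
.ricianNoise <- function(signal, sd) {
  if (sd <= 0) return(signal)
  sqrt((signal + stats::rnorm(length(signal), 0, sd))^2 +
       stats::rnorm(length(signal), 0, sd)^2)
}

#' Simulate a multi-b-value diffusion acquisition
#'
#' Monoexponential forward model S(b) = S0 exp(-b ADC) per voxel with Rician
#' magnitude noise of scale \code{cfg@noiseSd}.
#'
#' @param truth a PhantomTruth.
#' @param cfg an AcquisitionConfig.
#' @param seed RNG seed for the noise draw.
#' @return 4D ImageVolume, one frame per b-value.
#' @export
simulateDWI <- function(truth, cfg, seed = 1) {
  rng <- .localRNG(seed); on.exit(rng())
  adc <- truthParamMap(truth, "adc", background = 0)
  s0 <- truthParamMap(truth, "s0", background = 0)
  d <- dim(truth@labels)
  out <- array(0, c(d, length(cfg@bValues)))
  for (f in seq_along(cfg@bValues)) {
    s <- s0 * exp(-cfg@bValues[f] * adc)
    s[is.na(s)] <- 0
    out[, , , f] <- array(.ricianNoise(s, cfg@noiseSd), d)
  }
  imageVolume(out, spacing = truth@spacing)
}

#' Simulate a variable-TR saturation-recovery series
#'
#' S(TR) = S0 (1 - exp(-TR/T1)) per voxel plus Gaussian noise.
#'
#' @inheritParams simulateDWI
#' @return 4D ImageVolume, one frame per TR.
#' @export
simulateVTR <- function(truth, cfg, seed = 1) {
  rng <- .localRNG(seed); on.exit(rng())
  t1 <- truthParamMap(truth, "t1", background = NA)
  s0 <- truthParamMap(truth, "s0", background = 0)
  d <- dim(truth@labels)
  out <- array(0, c(d, length(cfg@trList)))
  for (f in seq_along(cfg@trList)) {
    s <- s0 * (1 - exp(-cfg@trList[f] / t1))
    s[is.na(s)] <- 0
    if (cfg@noiseSd > 0) s <- s + stats::rnorm(length(s), 0, cfg@noiseSd)
    out[, , , f] <- array(s, d)
  }
  imageVolume(out, spacing = truth@spacing)
}

#' DCE frame times for a configuration
#' @param cfg an AcquisitionConfig.
#' @return frame times, s (first frame at t = 0).
#' @export
dceTimes <- function(cfg) (seq_len(cfg@dceNFrames) - 1) * cfg@dceTemporalRes

## saturation-recovery signal from concentration (shared by simulation & fit)
.dceSignal <- function(conc, t1Ms, s0, trMs, relaxivity) {
  r10 <- 1000 / t1Ms                     # 1/s
  tr <- trMs / 1000                      # s
  s0 * (1 - exp(-tr * (r10 + relaxivity * conc)))
}

#' Simulate a dynamic contrast-enhanced acquisition
#'
#' Per-habitat Extended Tofts concentration curves are computed on a fine
#' grid (step <= 0.5 s), converted to signal with the same
#' saturation-recovery model used in fitting, and sampled at the acquisition
#' frames.  Contrast arrives after \code{nPrecontrastFrames} baseline frames;
#' necrotic voxels enhance by less than 25%.
#'
#' @inheritParams simulateDWI
#' @param aif population AIF; its onset is set to the arrival time implied by
#'   the baseline frame count.
#' @return 4D ImageVolume time series (frame spacing \code{dceTemporalRes}).
#' @export
simulateDCE <- function(truth, aif, cfg, seed = 1) {
  rng <- .localRNG(seed); on.exit(rng())
  times <- dceTimes(cfg)
  arrival <- cfg@nPrecontrastFrames * cfg@dceTemporalRes
  aif@onsetTime <- arrival
  subdiv <- max(1L, ceiling(cfg@dceTemporalRes / 0.5))
  pars <- rbind(truth@necroticParams, truth@habitatParams)
  curves <- lapply(seq_len(nrow(pars)), function(i) {
    p <- pars[i, ]
    if (p$ve <= 0) stop("habitat ve must be in (0, 1]")
    ct <- toftsConcentration(p$ktrans, p$ve, p$vp, aif, times,
                             subdivide = subdiv)
    .dceSignal(ct, p$t1, p$s0, cfg@dceTrMs, cfg@relaxivity)
  })
  d <- dim(truth@labels)
  lab <- as.integer(truth@labels)
  out <- array(0, c(d, length(times)))
  sig <- matrix(0, length(lab), length(times))
  nec <- lab == -1L
  if (any(nec)) sig[nec, ] <- matrix(curves[[1]], sum(nec), length(times),
                                     byrow = TRUE)
  for (h in seq_len(nrow(truth@habitatParams))) {
    idx <- lab == h
    if (any(idx)) sig[idx, ] <- matrix(curves[[h + 1]], sum(idx),
                                       length(times), byrow = TRUE)
  }
  if (cfg@noiseSd > 0) sig <- matrix(.ricianNoise(sig, cfg@noiseSd),
                                     nrow(sig), ncol(sig))
  sig[lab == 0L, ] <- 0
  out[] <- sig
  imageVolume(out, spacing = truth@spacing, timeStep = cfg@dceTemporalRes)
}

#' Simulate a static PET activity volume
#'
#' Activity = habitat SUV * injected dose / body weight, blurred by a
#' Gaussian point-spread function and degraded with Gaussian noise.  The
#' volume is produced on a finer grid than the MRI (half the in-plane spacing
#' and half the slice thickness) to exercise the reframing/down-sampling path.
#'
#' @inheritParams simulateDWI
#' @param tracer "FDG" or "FLT".
#' @param psfFwhm PSF full width at half maximum, mm.
#' @param noiseSd Gaussian activity noise, activity units.
#' @return 3D ImageVolume on the finer PET grid.
#' @export
simulatePET <- function(truth, cfg, tracer = c("FDG", "FLT"), psfFwhm = 1.5,
                        noiseSd = 0, seed = 1) {
  tracer <- match.arg(tracer)
  rng <- .localRNG(seed); on.exit(rng())
  suv <- truthParamMap(truth,
                       if (tracer == "FDG") "suv_fdg" else "suv_flt",
                       background = 0)
  suv[is.na(suv)] <- 0
  act <- suv * cfg@injectedDose / cfg@bodyWeight
  ## refine grid 2x in-plane and 2x in slice direction
  d <- dim(truth@labels)
  fine <- imageVolume(array(0, d * 2L), spacing = truth@spacing / 2,
                      origin = -truth@spacing / 4 * c(1, 1, 1))
  coarse <- imageVolume(act, spacing = truth@spacing)
  vol <- resampleVolume(coarse, fine, interpolation = "nearest", fill = 0)
  a <- volData(vol)
  if (psfFwhm > 0) {
    sigma <- psfFwhm / (2 * sqrt(2 * log(2))) / (truth@spacing / 2)
    a <- gaussianSmooth3D(a, sigma)
  }
  if (noiseSd > 0) a <- a + stats::rnorm(length(a), 0, noiseSd)
  imageVolume(a, spacing = vol@spacing, origin = vol@origin)
}

#' Apply a known affine misalignment to a volume
#'
#' Resamples the volume on its own grid through the given world affine
#' (pull-back convention: output value at world x is the input at
#' \code{affine \%*\% x}; a translation +t in the transform therefore moves
#' image content by -t).  Registering the result back to the original should
#' recover \code{affine}.
#'
#' @param vol 3D ImageVolume.
#' @param affine invertible 4x4 world transform.
#' @return misaligned ImageVolume on the source grid.
#' @export
applyMisalignment <- function(vol, affine) {
  if (abs(det(affine[1:3, 1:3])) < 1e-12) stop("affine must be invertible")
  resampleVolume(vol, vol, transform = affine, interpolation = "linear",
                 fill = 0)
}

#' Simulate a matched histology stain-density section
#'
#' Extracts one axial section of the phantom and draws per-pixel stain
#' densities from habitat-specific Poisson rates that map monotonically from
#' the habitat imaging parameters: nuclei density rises as ADC falls, vessel
#' count with Ktrans, Ki67 with FLT uptake, GLUT1 with FDG uptake, and
#' pimonidazole with FDG uptake relative to perfusion.  Necrotic and
#' background pixels are marked invalid (non-living tissue).
#'
#' @param truth a PhantomTruth.
#' @param sectionIndex axial slice index.
#' @param pxPerVoxel histology pixels per imaging voxel edge.
#' @param seed RNG seed.
#' @return A \linkS4class{StainDensitySection}.
#' @export
simulateHistology <- function(truth, sectionIndex, pxPerVoxel = 4, seed = 1) {
  d <- dim(truth@labels)
  if (sectionIndex < 1 || sectionIndex > d[3]) stop("section out of range")
  slab <- truth@labels[, , sectionIndex]
  if (!any(slab != 0L)) stop("section does not intersect the tumor")
  rng <- .localRNG(seed); on.exit(rng())
  up <- matrix(1, pxPerVoxel, pxPerVoxel)
  lab <- kronecker(slab, up)
  rates <- stainRates(rbind(truth@necroticParams, truth@habitatParams))
  stains <- lapply(rates, function(rate) {
    ## rate[1] = necrotic row, rate[1 + h] = habitat h; background rate 0
    r <- numeric(length(lab))
    r[lab == -1L] <- rate[1]
    idx <- lab > 0L
    r[idx] <- rate[lab[idx] + 1L]
    matrix(stats::rpois(length(r), r), nrow(lab), ncol(lab))
  })
  names(stains) <- names(rates)
  new("StainDensitySection", stains = stains, valid = lab > 0L,
      pixelSizeMm = truth@spacing[1] / pxPerVoxel,
      truthLabels = matrix(as.integer(lab), nrow(lab), ncol(lab)))
}

#' Monotone mapping from habitat imaging parameters to stain Poisson rates
#'
#' @param params data.frame of habitat parameters (rows: habitats).
#' @return named list of per-habitat rate vectors.
#' @export
stainRates <- function(params) {
  list(nuclei = 25 * (1e-3 / params$adc),
       cd31   = 1 + 12 * params$ktrans,
       ki67   = 12 * params$suv_flt,
       glut1  = 12 * params$suv_fdg,
       pimo   = 5 * params$suv_fdg / (0.3 + params$ktrans))
}
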