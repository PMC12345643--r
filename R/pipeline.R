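#' Run the synthetic end-to-end habitat pipeline
#'
#' Simulates a phantom cohort (subjects x timepoints), builds parametric map
#' sets, pools and clusters voxel features into habitats, characterizes and
#' names them, quantifies longitudinal composition, runs the spatial-
#' interaction analysis, simulates and clusters matched histology sections,
#' and validates imaging habitats against histology by permutation matching
#' and Pearson correlation.  Deterministic for a fixed seed.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @param outDir optional directory for a machine-readable JSON report and
#'   NIfTI habitat maps.
#' @return report list (resolved config snapshot, voxel counts, exclusion
#'   fraction, selected k, silhouette scores, composition table, habitat
#'   recovery ARI when truth is known, MSI summary, matching result).
#' @export
runPipeline <- function(config = pipelineConfig(), seed = config$seed,
                        outDir = NULL) {
  seed <- as.integer(seed)
  nf <- config$necroticFraction
  subjects <- seq_len(config$nSubjects)
  truths <- list()
  cohort <- list()
  for (s in subjects) {
    for (tp in seq_along(config$timepoints)) {
      sseed <- seed * 997L + s * 17L + tp
      frac <- nf[1] + (nf[2] - nf[1]) * (s - 1) / max(1, config$nSubjects - 1)
      truth <- generatePhantom(config$gridDims, config$nHabitats,
                               necroticFraction = frac, seed = sseed,
                               spacing = config$spacing)
      maps <- simulateMapSet(truth, noiseSd = config$mapNoiseSd,
                             seed = sseed + 1L)
      key <- sprintf("s%d_t%d", s, config$timepoints[tp])
      truths[[key]] <- truth
      cohort[[key]] <- list(maps = maps, tumor = tumorMask(truth),
                            subject = s, timepoint = config$timepoints[tp])
    }
  }

  hf <- normalizeFeatures(assembleFeatures(cohort))
  k <- selectK(hf, kRange = config$kRange, seed = seed)
  model <- characterizeHabitats(
    clusterHabitats(hf, k, maxRows = config$maxClusterRows, seed = seed))
  comp <- habitatComposition(model)

  ## habitat recovery vs planted truth (pooled ARI by majority mapping)
  truthLab <- unlist(lapply(names(cohort), function(key) {
    pv <- model@provenance
    rows <- pv$subject == cohort[[key]]$subject &
      pv$timepoint == cohort[[key]]$timepoint
    truths[[key]]@labels[pv$voxel[rows]]
  }))
  ari <- adjustedRandIndex(model@assignments, truthLab)

  ## MSI per subject at the first timepoint, averaged
  tp1 <- config$timepoints[1]
  diagZ <- vapply(subjects, function(s) {
    lab <- remapHabitats(model, s, tp1)
    msi <- computeMSI(lab, connectivity = config$msiConnectivity,
                      n = config$msiRandomizations, seed = seed + s,
                      k = model@k)
    mean(diag(msi@z), na.rm = TRUE)
  }, numeric(1))

  ## histology at the final timepoint: central section per subject
  tpLast <- config$timepoints[length(config$timepoints)]
  centralZ <- ceiling(config$gridDims[3] / 2)
  sections <- lapply(subjects, function(s) {
    truth <- truths[[sprintf("s%d_t%d", s, tpLast)]]
    densityFeatures(
      simulateHistology(truth, centralZ, pxPerVoxel = config$histPxPerVoxel,
                        seed = seed * 31L + s),
      kernelPx = config$histKernelPx,
      targetPixelSizeMm = config$histTargetPixelSizeMm)
  })
  hist <- clusterHistology(sections, k = model@k, seed = seed)
  histComp <- .percentMatrix(hist$composition, subjects, model@k)

  ## imaging composition in the five-slice window around the central slice,
  ## then permutation matching and per-subject central-slice selection
  win <- (centralZ - config$sliceWindow):(centralZ + config$sliceWindow)
  win <- win[win >= 1 & win <= config$gridDims[3]]
  sliceComp <- lapply(subjects, function(s) {
    lab <- remapHabitats(model, s, tpLast)
    t(vapply(win, function(z) {
      counts <- tabulate(lab[, , z][lab[, , z] > 0], model@k)
      if (sum(counts) == 0) rep(0, model@k) else 100 * counts / sum(counts)
    }, numeric(model@k)))
  })
  windowMean <- t(vapply(sliceComp, colMeans, numeric(model@k)))
  match0 <- matchByPermutation(histComp, windowMean)
  selected <- vapply(subjects, function(s) {
    histVec <- histComp[s, ]
    img <- sliceComp[[s]][, match0$permutation, drop = FALSE]
    as.integer(win[selectCentralSlice(img, histVec)])
  }, integer(1))
  imgCentral <- t(vapply(subjects, function(s)
    sliceComp[[s]][match(selected[s], win), match0$permutation],
    numeric(model@k)))
  final <- correlateCompositions(histComp, imgCentral)

  report <- list(
    config = unclass(config), seed = seed,
    pooledVoxels = nrow(model@provenance),
    selectedK = as.integer(k),
    silhouette = as.list(attr(k, "silhouette")),
    habitatNames = model@habitatNames,
    centroids = model@centroids,
    composition = comp,
    pooledARI = ari,
    msiMeanDiagonalZ = mean(diagZ),
    histologyK = hist$k,
    matchPermutation = match0$permutation,
    selectedCentralSlices = selected,
    matchedR2 = final$r2,
    matchedP = final$p)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    rj <- report
    rj$composition <- comp
    rj$centroids <- as.data.frame(model@centroids)
    jsonlite::write_json(rj, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (s in subjects) {
      lab <- remapHabitats(model, s, tpLast)
      writeVolume(imageVolume(lab + 0, spacing = config$spacing),
                  file.path(outDir, sprintf("habitats_s%d.nii.gz", s)))
    }
  }
  report
}

## composition data.frame -> subjects x k percent matrix
.percentMatrix <- function(comp, subjects, k) {
  m <- matrix(0, length(subjects), k)
  for (i in seq_along(subjects)) {
    rows <- comp$subject == subjects[i]
    m[i, comp$habitat[rows]] <- comp$percent[rows]
  }
  m
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement of two labelings of the same items (delegates
#' to \code{mclust::adjustedRandIndex}); used to score planted-habitat
#' recovery.
#'
#' @param a,b label vectors of equal length.
#' @return ARI (1 = identical partitions).
#' @export
adjustedRandIndex <- function(a, b) mclust::adjustedRandIndex(a, b)

#' Fit all parametric maps from simulated signal-domain acquisitions
#'
#' The full inverse path for one subject: ADC from the DWI series (with
#' artifact-slice exclusion), T1 from the variable-TR series, AIF calibration
#' from the muscle reference, voxel-wise Extended Tofts fitting with the
#' physiological filters, and SUV conversion of both PET tracers after
#' reframing, anti-aliased down-sampling and (optionally) registration onto
#' the MRI grid.
#'
#' @param truth a PhantomTruth.
#' @param cfg an AcquisitionConfig.
#' @param aif population AIFModel.
#' @param register if TRUE, PET volumes are misaligned by
#'   \code{cfg@misalignment} and re-registered; otherwise they are assumed
#'   aligned.
#' @param seed RNG seed.
#' @param voxelSubset optional linear indices limiting the Tofts fit.
#' @return list with the fitted maps (\code{adcMap}, \code{t1Map},
#'   \code{toftsMap}, \code{suvFdg}, \code{suvFlt}), the calibrated AIF and a
#'   \code{maps} ParametricMapSet.
#' @export
fitSubject <- function(truth, cfg, aif = aifModel(), register = FALSE,
                       seed = 1, voxelSubset = NULL) {
  dwi <- simulateDWI(truth, cfg, seed = seed)
  vtr <- simulateVTR(truth, cfg, seed = seed + 1L)
  dce <- simulateDCE(truth, aif, cfg, seed = seed + 2L)

  adcMap <- excludeDwiSlices(fitADC(dwi, cfg@bValues), tumorMask(truth))
  t1Map <- fitT1(vtr, cfg@trList, mask = tumorMask(truth))

  times <- dceTimes(cfg)
  sig <- matrix(volData(dce), ncol = cfg@dceNFrames)
  tumorIdx <- which(tumorMask(truth))
  if (!is.null(voxelSubset)) tumorIdx <- intersect(tumorIdx, voxelSubset)

  ## muscle reference: simulate a muscle curve from the same AIF
  muscleTruth <- new("PhantomTruth",
                     labels = array(1L, c(2, 2, 1)), spacing = truth@spacing,
                     habitatParams = data.frame(adc = 1.5e-3, ktrans = 0.1,
                                                ve = 0.1, vp = 0,
                                                suv_fdg = 0.5, suv_flt = 0.5,
                                                t1 = 1400, s0 = 1000),
                     necroticParams = defaultNecroticParams(),
                     seed = as.integer(seed))
  muscleDce <- simulateDCE(muscleTruth, aif, cfg, seed = seed + 3L)
  muscleSig <- colMeans(matrix(volData(muscleDce), ncol = cfg@dceNFrames))
  muscleConc <- signalToConcentration(matrix(muscleSig, 1), 1400,
                                      baselineFrames = cfg@nPrecontrastFrames,
                                      trMs = cfg@dceTrMs,
                                      relaxivity = cfg@relaxivity)$conc[1, ]
  calAif <- calibrateAIF(aifModel(amplitude = aif@amplitude, k1 = aif@k1,
                                  k2 = aif@k2),
                         muscleConc, times,
                         baselineFrames = cfg@nPrecontrastFrames)

  t1vals <- t1Map@t1[tumorIdx]
  sc <- signalToConcentration(sig[tumorIdx, , drop = FALSE], t1vals,
                              baselineFrames = cfg@nPrecontrastFrames,
                              trMs = cfg@dceTrMs, relaxivity = cfg@relaxivity)
  enh <- computeEnhancement(sig[tumorIdx, , drop = FALSE],
                            baselineFrames = cfg@nPrecontrastFrames)
  fits <- fitExtendedTofts(sc$conc, times, calAif)
  toftsMap <- filterDceVoxels(
    toftsMapFromFits(fits, enh, tumorIdx, dim(truth@labels)))

  suvMaps <- lapply(c("FDG", "FLT"), function(tr) {
    pet <- simulatePET(truth, cfg, tracer = tr, psfFwhm = 1.0,
                       noiseSd = cfg@noiseSd * cfg@injectedDose /
                         cfg@bodyWeight / 1000,
                       seed = seed + if (tr == "FDG") 4L else 5L)
    template <- imageVolume(array(0, dim(truth@labels)),
                            spacing = truth@spacing)
    reframed <- reframeSlices(pet, truth@spacing[3])
    down <- downsampleAntialias(reframed, truth@spacing)
    A <- diag(4)
    if (register) {
      moved <- applyMisalignment(down, cfg@misalignment)
      reg <- registerAffineMI(down, moved, weightRoi = tumorMask(truth),
                              iterations = 100L, seed = seed)
      aligned <- applyTransformChain(moved, reg, template)
      suv <- computeSUV(aligned, cfg@injectedDose, cfg@bodyWeight)
    } else {
      aligned <- resampleVolume(down, template, diag(4), "linear", 0)
      suv <- computeSUV(aligned, cfg@injectedDose, cfg@bodyWeight)
    }
    suv
  })

  maps <- parametricMapSet(
    adc = adcMap@adc, ktrans = toftsMap@ktrans, ve = toftsMap@ve,
    vp = toftsMap@vp, suvFdg = suvMaps[[1]]@suv, suvFlt = suvMaps[[2]]@suv,
    valid = toftsMap@valid & !is.na(adcMap@adc) & !is.na(t1Map@t1),
    spacing = truth@spacing)
  list(adcMap = adcMap, t1Map = t1Map, toftsMap = toftsMap,
       suvFdg = suvMaps[[1]], suvFlt = suvMaps[[2]], aif = calAif,
       maps = maps)
}
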