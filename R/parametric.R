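#' Fit voxel-wise apparent diffusion coefficient maps
#'
#' Log-linear least squares through ln S(b) vs b (slope = -ADC).  Voxels with
#' any non-positive signal are marked invalid (NA), never raised as errors.
#'
#' @param dwi 4D ImageVolume, one frame per b-value.
#' @param bValues b-values, s/mm^2 (>= 2 values including b = 0).
#' @return An \linkS4class{ADCMap}.
#' @export
fitADC <- function(dwi, bValues) {
  if (length(bValues) < 2 || min(bValues) != 0)
    stop("need >= 2 b-values including b = 0")
  a <- volData(dwi)
  if (length(dim(a)) != 4L || dim(a)[4] != length(bValues))
    stop("dwi must be 4D with one frame per b-value")
  d <- dim(a)[1:3]
  s <- matrix(a, ncol = length(bValues))
  ok <- rowSums(s <= 0) == 0
  y <- log(pmax(s, .Machine$double.xmin))
  bc <- bValues - mean(bValues)
  slope <- (y %*% bc) / sum(bc^2)
  adc <- as.numeric(-slope)
  s0 <- exp(rowMeans(y) + adc * mean(bValues))
  adc[!ok] <- NA_real_
  s0[!ok] <- NA_real_
  new("ADCMap", adc = array(adc, d), s0 = array(s0, d),
      excludedSlices = integer(0))
}

#' Exclude artifact-affected slices from the ADC analysis
#'
#' A slice is excluded when its within-tumor mean ADC strictly exceeds the
#' median of all tumor-voxel ADC values plus two standard deviations.
#' Excluded slices are recorded and their ADC values invalidated.
#'
#' @param adcMap an ADCMap.
#' @param tumor logical tumor mask on the same grid.
#' @return the ADCMap with \code{excludedSlices} set.
#' @export
excludeDwiSlices <- function(adcMap, tumor) {
  adc <- adcMap@adc
  if (!any(tumor)) stop("tumor mask is empty")
  sliceHas <- which(apply(tumor, 3, any))
  if (length(sliceHas) < 2L) {
    warning("single-slice tumor: no slice exclusion possible")
    return(adcMap)
  }
  vals <- adc[tumor]
  thr <- stats::median(vals, na.rm = TRUE) + 2 * stats::sd(vals, na.rm = TRUE)
  excl <- integer(0)
  for (k in sliceHas) {
    m <- mean(adc[, , k][tumor[, , k]], na.rm = TRUE)
    if (is.finite(m) && m > thr) excl <- c(excl, k)
  }
  for (k in excl) adc[, , k] <- NA_real_
  new("ADCMap", adc = adc, s0 = adcMap@s0,
      excludedSlices = as.integer(excl))
}

#' Fit voxel-wise T1 maps from a variable-TR series
#'
#' Nonlinear least squares of S = S0 (1 - exp(-TR/T1)) per voxel
#' (Levenberg-Marquardt).  Non-convergent or non-positive fits are invalid
#' (NA).
#'
#' @param vtr 4D ImageVolume, one frame per TR.
#' @param trList repetition times, ms (>= 3).
#' @param mask optional logical array restricting the fit.
#' @return A \linkS4class{T1Map}.
#' @export
fitT1 <- function(vtr, trList, mask = NULL) {
  if (length(trList) < 3) stop("need >= 3 TR values")
  a <- volData(vtr)
  d <- dim(a)[1:3]
  s <- matrix(a, ncol = length(trList))
  t1 <- rep(NA_real_, nrow(s))
  s0 <- rep(NA_real_, nrow(s))
  idx <- if (is.null(mask)) seq_len(nrow(s)) else which(as.logical(mask))
  for (v in idx) {
    sv <- s[v, ]
    if (all(sv <= 0) || max(sv) - min(sv) < 1e-9 * max(abs(sv))) next
    s0i <- max(sv)
    e1 <- 1 - sv[1] / (s0i * 1.05)
    t1i <- if (e1 > 0 && e1 < 1) -trList[1] / log(e1) else 1000
    fit <- tryCatch(
      minpack.lm::nlsLM(sv ~ S0 * (1 - exp(-trList / T1)),
                        start = list(S0 = s0i * 1.05, T1 = t1i),
                        lower = c(1e-6, 1),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    if (cf["T1"] > 0 && cf["S0"] > 0) {
      t1[v] <- cf[["T1"]]
      s0[v] <- cf[["S0"]]
    }
  }
  new("T1Map", t1 = array(t1, d), s0 = array(s0, d))
}

#' Convert DCE signal to contrast-agent concentration
#'
#' Steady-state saturation-recovery inversion: the pre-contrast T1 and the
#' mean baseline signal give the equilibrium signal, from which the dynamic
#' relaxation rate R1(t) and concentration C(t) = (R1(t) - R1(0)) / r1
#' follow.  Baseline frames map to C ~ 0; voxels with invalid T1 return NA.
#'
#' @param signal frames-in-columns matrix (voxels x frames) or 4D ImageVolume.
#' @param t1Ms pre-contrast T1 per voxel, ms.
#' @param baselineFrames number of pre-contrast frames averaged for baseline.
#' @param trMs repetition time of the dynamic sequence, ms.
#' @param relaxivity r1, 1/s/mM.
#' @return list with \code{conc} (voxels x frames, mM) and \code{baseline}
#'   (mean baseline signal per voxel).
#' @export
signalToConcentration <- function(signal, t1Ms, baselineFrames = 20,
                                  trMs = 100, relaxivity = 4.5) {
  if (is(signal, "ImageVolume")) signal <- matrix(volData(signal),
                                                  ncol = nFrames(signal))
  t1Ms <- as.numeric(t1Ms)
  if (baselineFrames < 1) stop("baselineFrames must be >= 1")
  sbase <- rowMeans(signal[, seq_len(baselineFrames), drop = FALSE])
  r10 <- 1000 / t1Ms
  tr <- trMs / 1000
  e0 <- 1 - exp(-tr * r10)
  s0 <- sbase / e0
  frac <- pmin(pmax(1 - signal / s0, 1e-9), 1 - 1e-9)
  r1 <- -log(frac) / tr
  conc <- pmax(sweep(r1, 1, r10, "-") / relaxivity, 0)
  conc[!is.finite(t1Ms) | t1Ms <= 0, ] <- NA_real_
  list(conc = conc, baseline = sbase)
}

#' Peak fractional enhancement over baseline
#'
#' Enhancement = (mean of the top decile of post-baseline signals -
#' baseline) / baseline, a noise-robust peak estimate.
#'
#' @param signal voxels x frames matrix.
#' @param baselineFrames pre-contrast frame count.
#' @return enhancement fraction per voxel.
#' @export
computeEnhancement <- function(signal, baselineFrames = 20) {
  sbase <- rowMeans(signal[, seq_len(baselineFrames), drop = FALSE])
  post <- signal[, -seq_len(baselineFrames), drop = FALSE]
  ntop <- max(1L, ceiling(ncol(post) / 10))
  peak <- apply(post, 1, function(x) mean(sort(x, decreasing = TRUE)[1:ntop]))
  (peak - sbase) / sbase
}

#' Calibrate the population AIF against a muscle reference region
#'
#' Contrast arrival is detected as the first post-baseline frame whose muscle
#' concentration exceeds the baseline mean + 3 SD; the AIF onset is set to
#' the preceding frame time.  The amplitude scale is then the least-squares
#' factor matching the Extended Tofts prediction for muscle (fixed literature
#' Ktrans and ve) to the observed muscle curve — the prediction is linear in
#' the AIF amplitude, so the optimum is closed form.
#'
#' @param populationAif an AIFModel.
#' @param muscleConc observed muscle concentration curve, mM.
#' @param times frame times, s.
#' @param baselineFrames pre-contrast frame count.
#' @param muscleKtrans,muscleVe,muscleVp fixed muscle reference parameters.
#' @return calibrated AIFModel.
#' @export
calibrateAIF <- function(populationAif, muscleConc, times,
                         baselineFrames = 20, muscleKtrans = 0.1,
                         muscleVe = 0.1, muscleVp = 0) {
  base <- muscleConc[seq_len(baselineFrames)]
  thr <- mean(base) + 3 * stats::sd(base) + 1e-9
  post <- which(muscleConc > thr)
  post <- post[post > baselineFrames]
  if (!length(post)) stop("flat muscle curve: cannot calibrate AIF")
  arrive <- post[1]
  dt <- times[2] - times[1]
  aif <- populationAif
  aif@onsetTime <- times[arrive] - dt
  aif@amplitudeScale <- 1
  subdiv <- max(1L, ceiling(dt / 0.5))
  pred <- toftsConcentration(muscleKtrans, muscleVe, muscleVp, aif, times,
                             subdivide = subdiv)
  if (sum(pred^2) < 1e-12) stop("degenerate muscle prediction")
  aif@amplitudeScale <- sum(pred * muscleConc) / sum(pred^2)
  if (aif@amplitudeScale <= 0) stop("calibration failed: non-positive scale")
  validObject(aif)
  aif
}

#' Fit the Extended Tofts model voxel-wise
#'
#' Bounded Levenberg-Marquardt least squares over Ktrans in [0, 5] 1/min,
#' ve in (0, 1], vp in [0, 1), with the convolution evaluated by trapezoidal
#' quadrature on a refinement of the acquisition grid.  Voxels whose fit does
#' not converge are invalid; identically-zero curves return Ktrans = 0 with
#' ve flagged unidentifiable (NA).
#'
#' @param conc voxels x frames concentration matrix (or a single curve), mM.
#' @param times uniform frame times, s.
#' @param aif calibrated AIFModel.
#' @param init optimizer start (ktrans, ve, vp).
#' @param subdivide quadrature substeps per frame interval.
#' @return data.frame with ktrans, ve, vp, converged, rss per voxel.
#' @export
fitExtendedTofts <- function(conc, times, aif, init = c(0.1, 0.2, 0.01),
                             subdivide = 4L) {
  if (is.null(dim(conc))) conc <- matrix(conc, nrow = 1)
  n <- nrow(conc)
  lower <- c(0, 1e-3, 0)
  upper <- c(5, 1, 0.999)
  out <- data.frame(ktrans = rep(NA_real_, n), ve = NA_real_, vp = NA_real_,
                    converged = FALSE, rss = NA_real_)
  model <- function(p) toftsConcentration(p[1], p[2], p[3], aif, times,
                                          subdivide = subdivide)
  for (v in seq_len(n)) {
    y <- conc[v, ]
    if (anyNA(y)) next
    if (max(abs(y)) < 1e-9) {
      out[v, ] <- list(0, NA_real_, 0, TRUE, 0)
      next
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = init, lower = lower, upper = upper,
                         fn = function(p) model(p) - y,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-8, ptol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    p <- fit$par
    out[v, ] <- list(p[1], p[2], p[3], fit$info %in% 1:4,
                     sum(fit$fvec^2))
  }
  out
}

#' Build a ToftsMap from voxel fits
#'
#' @param fits data.frame from \code{\link{fitExtendedTofts}} for the voxels
#'   in \code{index}.
#' @param enhancement enhancement per fitted voxel.
#' @param index linear voxel indices of the fitted voxels.
#' @param dims grid dimensions.
#' @return A \linkS4class{ToftsMap}; validity not yet filtered
#'   (\code{\link{filterDceVoxels}}).
#' @export
toftsMapFromFits <- function(fits, enhancement, index, dims) {
  mk <- function(x) {
    a <- array(NA_real_, dims)
    a[index] <- x
    a
  }
  valid <- array(FALSE, dims)
  valid[index] <- fits$converged
  new("ToftsMap", ktrans = mk(fits$ktrans), ve = mk(fits$ve),
      vp = mk(fits$vp), enhancement = mk(enhancement), valid = valid)
}

#' Apply the physiological DCE voxel filters
#'
#' Clears validity for voxels outside Ktrans in [0, 5] 1/min, ve in (0, 1],
#' vp in [0, 1], or with enhancement below a 25% increase from baseline.
#' Idempotent.
#'
#' @param map a ToftsMap.
#' @param minEnhancement enhancement threshold (fraction over baseline).
#' @return filtered ToftsMap; \code{attr(, "exclusionFraction")} reports the
#'   fraction of previously valid voxels removed.
#' @export
filterDceVoxels <- function(map, minEnhancement = 0.25) {
  wasValid <- map@valid
  ok <- wasValid &
    !is.na(map@ktrans) & map@ktrans >= 0 & map@ktrans <= 5 &
    !is.na(map@ve) & map@ve > 0 & map@ve <= 1 &
    !is.na(map@vp) & map@vp >= 0 & map@vp <= 1 &
    !is.na(map@enhancement) & map@enhancement >= minEnhancement
  res <- new("ToftsMap", ktrans = map@ktrans, ve = map@ve, vp = map@vp,
             enhancement = map@enhancement, valid = ok)
  nv <- sum(wasValid)
  attr(res, "exclusionFraction") <- if (nv) 1 - sum(ok) / nv else 0
  res
}

#' Convert a PET activity volume to standardized uptake values
#'
#' SUV = activity / (injected dose / body weight), voxel-wise.
#'
#' @param activity ImageVolume of tracer activity.
#' @param injectedDose injected activity (> 0).
#' @param bodyWeight subject mass (> 0).
#' @return An \linkS4class{SUVMap}.
#' @export
computeSUV <- function(activity, injectedDose, bodyWeight) {
  if (injectedDose <= 0 || bodyWeight <= 0)
    stop("injectedDose and bodyWeight must be > 0")
  new("SUVMap", suv = volData(activity) / (injectedDose / bodyWeight),
      injectedDose = injectedDose, bodyWeight = bodyWeight)
}

#' Assemble a co-registered parametric map set
#'
#' @param adc,ktrans,ve,vp,suvFdg,suvFlt numeric arrays on a common grid.
#' @param valid logical array; defaults to joint non-NA of the five
#'   clustering features.
#' @param spacing voxel spacing, mm.
#' @return A \linkS4class{ParametricMapSet}.
#' @export
parametricMapSet <- function(adc, ktrans, ve, vp, suvFdg, suvFlt,
                             valid = NULL, spacing = c(1, 1, 1)) {
  if (is.null(valid))
    valid <- !is.na(adc) & !is.na(ktrans) & !is.na(ve) &
             !is.na(suvFdg) & !is.na(suvFlt)
  new("ParametricMapSet", adc = adc, ktrans = ktrans, ve = ve, vp = vp,
      suvFdg = suvFdg, suvFlt = suvFlt, valid = valid,
      spacing = as.numeric(spacing))
}

#' Simulate a parametric map set directly from phantom truth
#'
#' Bypasses the signal-domain forward/inverse path: each map equals the
#' generative habitat parameter plus independent Gaussian map noise.  Voxels
#' in the necrotic core are invalid (they fail the enhancement filter in the
#' signal-domain path).
#'
#' @param truth a PhantomTruth.
#' @param noiseSd named list/vector of per-feature map noise SDs
#'   (adc, ktrans, ve, suv_fdg, suv_flt).
#' @param seed RNG seed.
#' @return A \linkS4class{ParametricMapSet}.
#' @export
simulateMapSet <- function(truth,
                           noiseSd = c(adc = 0.05e-3, ktrans = 0.015,
                                       ve = 0.03, suv_fdg = 0.08,
                                       suv_flt = 0.08),
                           seed = 1) {
  rng <- .localRNG(seed); on.exit(rng())
  d <- dim(truth@labels)
  noisy <- function(param, sd) {
    a <- truthParamMap(truth, param)
    a + array(stats::rnorm(length(a), 0, sd), d)
  }
  adc <- noisy("adc", noiseSd[["adc"]])
  kt <- noisy("ktrans", noiseSd[["ktrans"]])
  ve <- noisy("ve", noiseSd[["ve"]])
  fdg <- noisy("suv_fdg", noiseSd[["suv_fdg"]])
  flt <- noisy("suv_flt", noiseSd[["suv_flt"]])
  vp <- truthParamMap(truth, "vp")
  valid <- viableMask(truth)
  parametricMapSet(adc, kt, ve, vp, fdg, flt, valid = valid,
                   spacing = truth@spacing)
}

setMethod("show", "ADCMap", function(object) {
  v <- object@adc[!is.na(object@adc)]
  cat(sprintf("ADCMap: %s voxels, %d invalid, %d excluded slice(s)\n",
              paste(dim(object@adc), collapse = " x "),
              sum(is.na(object@adc)), length(object@excludedSlices)))
  if (length(v)) cat(sprintf("  ADC range: %.3g - %.3g mm^2/s\n",
                             min(v), max(v)))
})

setMethod("show", "T1Map", function(object) {
  v <- object@t1[!is.na(object@t1)]
  cat(sprintf("T1Map: %s voxels, %d invalid\n",
              paste(dim(object@t1), collapse = " x "),
              sum(is.na(object@t1))))
  if (length(v)) cat(sprintf("  T1 range: %.4g - %.4g ms\n", min(v), max(v)))
})

setMethod("show", "ToftsMap", function(object) {
  cat(sprintf("ToftsMap: %s voxels, %d valid after filtering\n",
              paste(dim(object@ktrans), collapse = " x "),
              sum(object@valid)))
})

setMethod("show", "SUVMap", function(object) {
  cat(sprintf("SUVMap: %s voxels, dose %.3g / weight %.3g\n",
              paste(dim(object@suv), collapse = " x "),
              object@injectedDose, object@bodyWeight))
})

setMethod("show", "ParametricMapSet", function(object) {
  cat(sprintf("ParametricMapSet: %s voxels, %d jointly valid\n",
              paste(dim(object@adc), collapse = " x "),
              sum(object@valid)))
})

setMethod("show", "AcquisitionConfig", function(object) {
  cat("AcquisitionConfig\n")
  cat("  b-values (s/mm^2):", paste(object@bValues, collapse = ", "), "\n")
  cat("  TR list (ms):", paste(object@trList, collapse = ", "), "\n")
  cat(sprintf("  DCE: %d frames at %g s (%d pre-contrast), TR %g ms\n",
              object@dceNFrames, object@dceTemporalRes,
              object@nPrecontrastFrames, object@dceTrMs))
  cat(sprintf("  dose %g / weight %g, noise SD %g\n", object@injectedDose,
              object@bodyWeight, object@noiseSd))
})
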