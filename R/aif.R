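#' Population arterial input function
#'
#' Biexponential bolus model of plasma contrast concentration,
#' Cp(t) = scale * A * (exp(-k1 (t - t0)) - exp(-k2 (t - t0))) for t >= t0.
#' Defaults give a mouse-like bolus peaking near 4.4 mM about 28 s after
#' arrival.  The per-scan \code{amplitudeScale} and \code{onsetTime} are set
#' by \code{\link{calibrateAIF}} against a skeletal-muscle reference region.
#'
#' @param amplitude A, mM.
#' @param k1 washout rate, 1/s.
#' @param k2 uptake rate, 1/s (k2 > k1).
#' @param amplitudeScale calibration factor.
#' @param onsetTime contrast arrival, s.
#' @return An \linkS4class{AIFModel}.
#' @export
aifModel <- function(amplitude = 6, k1 = 0.008, k2 = 0.10,
                     amplitudeScale = 1, onsetTime = 0) {
  new("AIFModel", amplitude = amplitude, k1 = k1, k2 = k2,
      amplitudeScale = amplitudeScale, onsetTime = onsetTime)
}

#' Evaluate plasma concentration Cp(t)
#'
#' @param aif an AIFModel.
#' @param t times, s.
#' @return concentrations, mM (0 before onset).
#' @export
aifConcentration <- function(aif, t) {
  s <- t - aif@onsetTime
  ifelse(s > 0,
         aif@amplitudeScale * aif@amplitude *
           (exp(-aif@k1 * s) - exp(-aif@k2 * s)),
         0)
}

setMethod("show", "AIFModel", function(object) {
  cat(sprintf(
    "AIFModel: A=%g mM, k1=%g/s, k2=%g/s, scale=%.4g, onset=%.4g s\n",
    object@amplitude, object@k1, object@k2, object@amplitudeScale,
    object@onsetTime))
})

#' Extended Tofts tissue concentration
#'
#' Ct(t) = vp Cp(t) + Ktrans int_0^t Cp(tau) exp(-(Ktrans/ve)(t - tau)) dtau.
#' The convolution is evaluated by trapezoidal quadrature on a uniform grid;
#' \code{subdivide} refines each acquisition interval into that many substeps
#' (acquisition times remain quadrature nodes), which controls discretization
#' bias for sharply peaked input functions.
#'
#' @param ktrans volume transfer constant, 1/min.
#' @param ve extravascular extracellular volume fraction (> 0).
#' @param vp plasma volume fraction.
#' @param aif an AIFModel.
#' @param times uniform acquisition times, s.
#' @param subdivide integer substeps per acquisition interval.
#' @return tissue concentration at \code{times}, mM.
#' @export
toftsConcentration <- function(ktrans, ve, vp, aif, times, subdivide = 1L) {
  n <- length(times)
  if (n < 2) stop("need at least two time points")
  dt <- diff(times)
  if (max(dt) - min(dt) > 1e-6 * max(dt)) stop("times must be uniform")
  subdivide <- max(1L, as.integer(subdivide))
  h <- dt[1] / subdivide
  grid <- seq(times[1], times[n], by = h)
  cp <- aifConcentration(aif, grid)
  kep <- if (ve > 0) ktrans / ve / 60 else 0  # 1/s
  e <- exp(-kep * h)
  ## recursive trapezoid of int cp(tau) exp(-kep (t - tau)) dtau
  m <- length(grid)
  conv <- numeric(m)
  for (i in 2:m) conv[i] <- conv[i - 1] * e + h / 2 * (cp[i] + cp[i - 1] * e)
  ct <- vp * cp + (ktrans / 60) * conv
  ct[seq(1, m, by = subdivide)]
}

#' Independent fine-grid convolution oracle for the Extended Tofts model
#'
#' Direct O(n^2) trapezoidal evaluation of the convolution integral at each
#' requested time, sharing no code with the recursive path used by
#' \code{\link{toftsConcentration}}.  Used for cross-validation.
#'
#' @inheritParams toftsConcentration
#' @param gridStep quadrature step, s.
#' @return tissue concentration at \code{times}, mM.
#' @export
toftsOracle <- function(ktrans, ve, vp, aif, times, gridStep = 0.1) {
  kep <- if (ve > 0) ktrans / ve / 60 else 0
  sapply(times, function(t) {
    tau <- seq(times[1], t, by = gridStep)
    if (length(tau) < 2) return(vp * aifConcentration(aif, t))
    integrand <- aifConcentration(aif, tau) * exp(-kep * (t - tau))
    vp * aifConcentration(aif, t) + (ktrans / 60) * pracma::trapz(tau, integrand)
  })
}
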