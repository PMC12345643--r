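test_that("ADC fitting inverts the exponential decay exactly", {
  b <- c(0, 150, 500, 800)
  s <- 1000 * exp(-b * 1.0e-3)      # (1000, 860.7, 606.5, 449.3)
  dwi <- imageVolume(array(rep(s, each = 4), c(2, 2, 1, 4)))
  m <- fitADC(dwi, b)
  expect_equal(as.vector(m@adc), rep(1.0e-3, 4), tolerance = 1e-10)
  expect_equal(as.vector(m@s0), rep(1000, 4), tolerance = 1e-6)
  ## constant signal across b gives ADC = 0
  cst <- imageVolume(array(500, c(2, 2, 1, 4)))
  expect_equal(max(abs(fitADC(cst, b)@adc)), 0)
  ## non-positive signals are invalid, not errors
  bad <- imageVolume(array(c(rep(0, 4), rep(s, each = 3))[1:16], c(2, 2, 1, 4)))
  expect_true(anyNA(fitADC(bad, b)@adc))
  expect_error(fitADC(dwi, c(150, 800)), "b = 0")
})

test_that("artifact slices are excluded by the median + 2 SD rule", {
  ## 6 slices, tumor everywhere; slice 4 inflated far above the threshold
  d <- c(4, 4, 6)
  set.seed(8)
  adc <- array(rnorm(prod(d), 1.0e-3, 0.02e-3), d)
  adc[, , 4] <- adc[, , 4] + 5 * sd(adc) + 5e-4
  m <- new("ADCMap", adc = adc, s0 = array(1, d), excludedSlices = integer(0))
  tumor <- array(TRUE, d)
  out <- excludeDwiSlices(m, tumor)
  expect_identical(out@excludedSlices, 4L)
  expect_true(all(is.na(out@adc[, , 4])))
  ## all slices identical: none excluded
  flat <- new("ADCMap", adc = array(1.0e-3, d), s0 = array(1, d),
              excludedSlices = integer(0))
  expect_length(excludeDwiSlices(flat, tumor)@excludedSlices, 0)
  ## boundary: a slice mean exactly at median + 2 SD is retained (strict >);
  ## a constant map has SD 0, putting every slice exactly on the threshold
  m2 <- new("ADCMap", adc = array(1e-3, d), s0 = array(1, d),
            excludedSlices = integer(0))
  expect_length(excludeDwiSlices(m2, tumor)@excludedSlices, 0)
  ## single-slice tumor warns and does nothing
  t1 <- array(FALSE, d); t1[, , 2] <- TRUE
  expect_warning(excludeDwiSlices(m, t1), "single-slice")
})

test_that("T1 fitting recovers saturation-recovery parameters", {
  trs <- c(255, 400, 800, 1500, 3000, 5500)
  s <- 1000 * (1 - exp(-trs / 1800))
  vtr <- imageVolume(array(rep(s, each = 4), c(2, 2, 1, 6)))
  m <- fitT1(vtr, trs)
  expect_equal(as.vector(m@t1), rep(1800, 4), tolerance = 1e-3)
  expect_equal(as.vector(m@s0), rep(1000, 4), tolerance = 1e-2)
  ## all-zero voxel is invalid
  z <- imageVolume(array(0, c(1, 1, 1, 6)))
  expect_true(is.na(fitT1(z, trs)@t1[1, 1, 1]))
  expect_error(fitT1(vtr, c(255, 400)), ">= 3 TR")
})

test_that("signal-concentration conversion is exact and invertible", {
  ## known delta-R1: C = dR1 / r1 = 1 / 4.5 = 0.2222 mM
  t1 <- 1800; tr <- 100
  r10 <- 1000 / t1
  base <- 1000 * (1 - exp(-tr / 1000 * r10))
  post <- 1000 * (1 - exp(-tr / 1000 * (r10 + 1)))
  sig <- matrix(c(rep(base, 5), rep(post, 5)), 1)
  out <- signalToConcentration(sig, t1, baselineFrames = 5, trMs = tr,
                               relaxivity = 4.5)
  expect_equal(out$conc[1, 10], 1 / 4.5, tolerance = 1e-9)
  expect_equal(out$conc[1, 3], 0, tolerance = 1e-9)
  ## signal equal to baseline at all t: C(t) = 0
  flat <- matrix(base, 1, 10)
  expect_equal(max(signalToConcentration(flat, t1, 5, tr, 4.5)$conc), 0)
  ## invalid T1 propagates NA
  expect_true(all(is.na(signalToConcentration(flat, NA, 5, tr, 4.5)$conc)))
})

test_that("AIF calibration recovers amplitude scale and onset shifts", {
  times <- (0:69) * 6.4
  pop <- aifModel()
  mkMuscle <- function(scale, onset)
    toftsConcentration(0.1, 0.1, 0, aifModel(amplitudeScale = scale,
                                             onsetTime = onset),
                       times, subdivide = 13)
  ## self-consistency at scale 1
  cal1 <- calibrateAIF(pop, mkMuscle(1, 128), times, baselineFrames = 20)
  expect_equal(cal1@amplitudeScale, 1, tolerance = 1e-3)
  ## scale 2 recovered within 1%
  cal2 <- calibrateAIF(pop, mkMuscle(2, 128), times, baselineFrames = 20)
  expect_equal(cal2@amplitudeScale, 2, tolerance = 0.01)
  ## +3 frame (19.2 s) arrival shift moves the onset by +19.2 s
  cal3 <- calibrateAIF(pop, mkMuscle(1, 128 + 19.2), times,
                       baselineFrames = 20)
  expect_equal(cal3@onsetTime - cal1@onsetTime, 19.2, tolerance = 1e-9)
  expect_error(calibrateAIF(pop, rep(0, 70), times, 20), "flat muscle")
})

test_that("Extended Tofts fitting handles degenerate and planted voxels", {
  times <- (0:69) * 6.4
  aif <- aifModel(onsetTime = 128)
  ## identically zero curve: Ktrans = 0, ve unidentifiable
  f0 <- fitExtendedTofts(rep(0, 70), times, aif)
  expect_equal(f0$ktrans, 0)
  expect_true(is.na(f0$ve))
  ## plasma-only voxel: vp = 0.05, Ktrans = 0
  cp <- aifConcentration(aif, times)
  fp <- fitExtendedTofts(0.05 * cp, times, aif)
  expect_equal(fp$vp, 0.05, tolerance = 1e-3)
  expect_lt(fp$ktrans, 1e-4)
  ## phantom voxel at 6.4 s resolution, zero noise: recovery within 2%
  ct <- toftsConcentration(0.25, 0.4, 0.02, aif, times, subdivide = 13)
  fr <- fitExtendedTofts(ct, times, aif)
  expect_equal(fr$ktrans, 0.25, tolerance = 0.02)
  expect_equal(fr$ve, 0.4, tolerance = 0.02)
  expect_equal(fr$vp, 0.02, tolerance = 0.02)
})

test_that("physiological DCE filters match hand enumeration and are idempotent", {
  ## printed 6-voxel toy table: exactly rows 1 and 6 survive
  toy <- data.frame(
    ktrans = c(0.30, 6.00, 0.30, 0.30, -0.1, 0.44),
    ve     = c(0.40, 0.40, 1.20, 0.40, 0.40, 0.45),
    vp     = c(0.02, 0.02, 0.02, 0.02, 0.02, 0.04),
    enh    = c(0.50, 0.50, 0.50, 0.20, 0.50, 0.90))
  dims <- c(6, 1, 1)
  map <- new("ToftsMap", ktrans = array(toy$ktrans, dims),
             ve = array(toy$ve, dims), vp = array(toy$vp, dims),
             enhancement = array(toy$enh, dims),
             valid = array(TRUE, dims))
  out <- filterDceVoxels(map)
  expect_identical(as.vector(out@valid), c(TRUE, FALSE, FALSE, FALSE, FALSE,
                                           TRUE))
  expect_equal(attr(out, "exclusionFraction"), 4 / 6)
  ## idempotence
  again <- filterDceVoxels(out)
  expect_identical(again@valid, out@valid)
  expect_equal(attr(again, "exclusionFraction"), 0)
})

test_that("SUV conversion is linear and guards its arguments", {
  act <- imageVolume(array(runif(27), c(3, 3, 3)))
  s1 <- computeSUV(act, 100, 20)
  expect_equal(s1@suv, volData(act) / 5, tolerance = 1e-12)
  ## activity = dose/weight gives SUV 1; zero activity gives 0
  unit <- imageVolume(array(5, c(2, 2, 2)))
  expect_true(all(computeSUV(unit, 100, 20)@suv == 1))
  expect_true(all(computeSUV(imageVolume(array(0, c(2, 2, 2))), 100,
                             20)@suv == 0))
  ## linearity: computeSUV(alpha A) = alpha computeSUV(A)
  a2 <- imageVolume(volData(act) * 3.7)
  expect_equal(computeSUV(a2, 100, 20)@suv, 3.7 * s1@suv, tolerance = 1e-12)
  expect_error(computeSUV(act, 0, 20), "must be > 0")
  expect_error(computeSUV(act, 100, -1), "must be > 0")
})

test_that("valid Tofts voxels always satisfy the range invariants", {
  truth <- fixPhantom()
  cfg <- acquisitionConfig(noiseSd = 2.7)   # baseline SNR ~ 20
  dce <- simulateDCE(truth, aifModel(), cfg, seed = 3)
  sig <- matrix(volData(dce), ncol = cfg@dceNFrames)
  idx <- which(viableMask(truth))[1:150]
  t1T <- truthParamMap(truth, "t1")
  conc <- signalToConcentration(sig[idx, ], t1T[idx], 20)$conc
  f <- fitExtendedTofts(conc, dceTimes(cfg), aifModel(onsetTime = 128))
  enh <- computeEnhancement(sig[idx, ], 20)
  map <- filterDceVoxels(toftsMapFromFits(f, enh, idx, dim(truth@labels)))
  v <- map@valid
  expect_true(all(map@ktrans[v] >= 0 & map@ktrans[v] <= 5))
  expect_true(all(map@ve[v] > 0 & map@ve[v] <= 1))
  expect_true(all(map@vp[v] >= 0 & map@vp[v] <= 1))
  expect_true(all(map@enhancement[v] >= 0.25))
})
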