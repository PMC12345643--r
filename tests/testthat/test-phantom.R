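test_that("phantom generation plants habitats, necrosis and is deterministic", {
  truth <- generatePhantom(c(48, 48, 10), 5, 0.37, seed = 7)
  lab <- truth@labels
  expect_setequal(sort(unique(lab[lab > 0])), 1:5)
  necFrac <- sum(lab == -1) / sum(lab != 0)
  expect_equal(necFrac, 0.37, tolerance = 0.01)
  ## same seed twice: identical volumes
  again <- generatePhantom(c(48, 48, 10), 5, 0.37, seed = 7)
  expect_identical(lab, again@labels)
  ## single habitat, no necrosis
  one <- generatePhantom(c(16, 16, 6), 1, 0, seed = 1)
  expect_true(all(one@labels[one@labels != 0] == 1L))
  ## sizing error
  expect_error(generatePhantom(c(3, 3, 2), 5, 0, seed = 1), "too small")
  expect_error(generatePhantom(c(16, 16, 6), 2, 0.9, seed = 1),
               "necroticFraction")
})

test_that("habitat regions are spatially contiguous blobs", {
  truth <- generatePhantom(c(32, 32, 8), 5, 0.3, seed = 11)
  ## every habitat's voxels connect to its seed region: check that >=95% of
  ## each habitat's voxels have a same-label face neighbor
  lab <- truth@labels
  for (h in 1:5) {
    idx <- which(lab == h, arr.ind = TRUE)
    hasNb <- apply(idx, 1, function(v) {
      nb <- rbind(v + c(1, 0, 0), v - c(1, 0, 0), v + c(0, 1, 0),
                  v - c(0, 1, 0), v + c(0, 0, 1), v - c(0, 0, 1))
      nb <- nb[nb[, 1] >= 1 & nb[, 1] <= 32 & nb[, 2] >= 1 & nb[, 2] <= 32 &
                 nb[, 3] >= 1 & nb[, 3] <= 8, , drop = FALSE]
      any(lab[nb] == h)
    })
    expect_gt(mean(hasNb), 0.95)
  }
})

test_that("DWI forward model matches the closed-form exponential", {
  ## S = S0 exp(-b ADC): 1000 * exp(-800 * 1e-3) = 449.33
  expect_equal(1000 * exp(-800 * 1.0e-3), 449.3290, tolerance = 1e-4)
  truth <- generatePhantom(c(16, 16, 6), 1, 0, seed = 2)
  truth@habitatParams$adc <- 1.0e-3
  truth@habitatParams$s0 <- 1000
  cfg <- acquisitionConfig(noiseSd = 0)
  dwi <- simulateDWI(truth, cfg)
  tm <- tumorMask(truth)
  frames <- volData(dwi)
  expect_equal(unique(frames[, , , 4][tm]), 449.3290, tolerance = 1e-3)
  ## b = 0 identity and spatial constancy at zero noise
  expect_equal(unique(frames[, , , 1][tm]), 1000)
  expect_equal(sd(frames[, , , 2][tm]), 0)
})

test_that("variable-TR forward model matches saturation recovery", {
  ## S = S0 (1 - exp(-TR/T1)): 1000 * (1 - exp(-5500/1800)) = 952.88
  expect_equal(1000 * (1 - exp(-5500 / 1800)), 952.8822, tolerance = 1e-4)
  truth <- generatePhantom(c(16, 16, 6), 1, 0, seed = 2)
  truth@habitatParams$t1 <- 1800
  cfg <- acquisitionConfig(noiseSd = 0)
  vtr <- simulateVTR(truth, cfg)
  tm <- tumorMask(truth)
  expect_equal(unique(volData(vtr)[, , , 6][tm]), 952.8822, tolerance = 1e-3)
  ## TR -> infinity approaches S0; TR = 0 gives 0
  cfgLim <- acquisitionConfig(trList = c(1e-6, 1e6), noiseSd = 0)
  lim <- simulateVTR(truth, cfgLim)
  expect_equal(unique(volData(lim)[, , , 2][tm]), 1000, tolerance = 1e-3)
  expect_lt(max(volData(lim)[, , , 1][tm]), 1e-3)
})

test_that("Tofts convolution agrees with the independent trapezoidal oracle", {
  aif <- aifModel(onsetTime = 30)
  times <- (0:59) * 6.4
  fast <- toftsConcentration(0.25, 0.4, 0.02, aif, times, subdivide = 13)
  slow <- toftsOracle(0.25, 0.4, 0.02, aif, times, gridStep = 0.05)
  expect_lt(max(abs(fast - slow)) / max(slow), 0.005)
  ## no exchange, no plasma: flat zero
  expect_equal(max(abs(toftsConcentration(0, 0.3, 0, aif, times))), 0)
  ## plasma-only voxel: Ct = vp * Cp
  po <- toftsConcentration(0, 0.3, 0.05, aif, times)
  expect_equal(po, 0.05 * aifConcentration(aif, times), tolerance = 1e-12)
})

test_that("DCE simulation gives baseline-only frames and <25% necrotic enhancement", {
  truth <- fixPhantom()
  cfg <- acquisitionConfig(noiseSd = 0, dceNFrames = 60L)
  dce <- simulateDCE(truth, aifModel(), cfg)
  sig <- matrix(volData(dce), ncol = 60)
  tm <- which(tumorMask(truth))
  base <- sig[tm, 1:20]
  expect_equal(max(apply(base, 1, sd)), 0)
  enh <- computeEnhancement(sig[tm, , drop = FALSE], 20)
  nec <- truth@labels[tm] == -1L
  expect_true(all(enh[nec] < 0.25))
  expect_true(all(enh[!nec] > 0.25))
})

test_that("PET simulation inverts through SUV and respects the PSF", {
  truth <- fixPhantom()
  cfg <- acquisitionConfig()
  ## psf = 0, noise = 0: compute_suv inverts the simulation exactly
  pet <- simulatePET(truth, cfg, "FDG", psfFwhm = 0, noiseSd = 0)
  suv <- computeSUV(pet, cfg@injectedDose, cfg@bodyWeight)
  fdg <- truthParamMap(truth, "suv_fdg", background = 0)
  fdg[is.na(fdg)] <- 0
  ## PET grid is 2x finer but piecewise constant: same SUV level set
  expect_equal(sort(unique(round(as.vector(suv@suv), 6))),
               sort(unique(round(as.vector(fdg), 6))))
  ## psf 1.5 mm: habitat-interior mean SUV within 5% of truth (blur oracle on
  ## a single-habitat phantom whose tumor interior is known geometry)
  one <- generatePhantom(c(32, 32, 10), 1, 0, seed = 6)
  pet2 <- simulatePET(one, cfg, "FDG", psfFwhm = 1.5, noiseSd = 0)
  suv2 <- computeSUV(pet2, cfg@injectedDose, cfg@bodyWeight)
  d <- dim(one@labels)
  labFine <- (one@labels != 0)[rep(seq_len(d[1]), each = 2),
                               rep(seq_len(d[2]), each = 2),
                               rep(seq_len(d[3]), each = 2)]
  interior <- labFine & !TumorHabitats:::dilateMask(!labFine, 5L)
  expect_gt(sum(interior), 100)
  truthVal <- one@habitatParams$suv_fdg[1]
  expect_lt(abs(mean(suv2@suv[interior]) - truthVal) / truthVal, 0.05)
})

test_that("histology sections draw habitat-specific Poisson densities", {
  truth <- generatePhantom(c(24, 24, 6), 2, 0, seed = 9)
  truth@habitatParams$adc <- c(0.5e-3, 2.0e-3)  # 4-fold nuclei-rate contrast
  sec <- simulateHistology(truth, 3, pxPerVoxel = 4, seed = 3)
  lab <- sec@truthLabels
  m1 <- mean(sec@stains$nuclei[lab == 1])
  m2 <- mean(sec@stains$nuclei[lab == 2])
  expect_equal(m1 / m2, 4, tolerance = 0.15)   # Poisson mean oracle
  ## zero-rate stain gives an all-zero map
  truth0 <- truth
  truth0@habitatParams$suv_flt <- c(0, 0)
  truth0@necroticParams$suv_flt <- 0
  sec0 <- simulateHistology(truth0, 3, pxPerVoxel = 4, seed = 3)
  expect_true(all(sec0@stains$ki67 == 0))
  ## single-habitat section is homogeneous in rate (means agree across halves)
  one <- generatePhantom(c(24, 24, 6), 1, 0, seed = 4)
  secOne <- simulateHistology(one, 3, pxPerVoxel = 4, seed = 5)
  v <- secOne@stains$nuclei[secOne@valid]
  expect_equal(mean(v[seq_len(length(v) / 2)]),
               mean(v[-seq_len(length(v) / 2)]), tolerance = 0.1)
  expect_error(simulateHistology(one, 1, 4), "intersect")
})

test_that("misalignment moves content as prescribed and inverts", {
  truth <- fixPhantom()
  a <- gaussianSmooth3D(viableMask(truth) + 0, c(1, 1, 0.5))
  vol <- imageVolume(a, spacing = truth@spacing)
  ## identity transform: voxelwise identical
  same <- applyMisalignment(vol, diag(4))
  expect_equal(volData(same), a, tolerance = 1e-12)
  ## pure translation: centroid shift by -t (pull-back convention)
  A <- diag(4); A[1, 4] <- 2
  moved <- applyMisalignment(vol, A)
  com <- function(v) {
    x <- volData(v)
    idx <- which(x > 0, arr.ind = TRUE)
    colSums(voxelToWorld(v, idx) * x[idx]) / sum(x[idx])
  }
  expect_equal(com(moved)[1] - com(vol)[1], -2, tolerance = 0.05)
  ## round trip with the inverse transform: Dice >= 0.99
  back <- applyMisalignment(moved, solve(A))
  expect_gte(diceCoefficient(volData(back) > 0.3, a > 0.3), 0.99)
  expect_error(applyMisalignment(vol, matrix(0, 4, 4)), "invertible")
})
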