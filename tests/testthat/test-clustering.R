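test_that("feature assembly intersects validity, tumor and ranges", {
  truth <- fixPhantom()
  maps <- simulateMapSet(truth, seed = 2)
  entry <- list(maps = maps, tumor = tumorMask(truth), subject = 1,
                timepoint = 0)
  hf <- assembleFeatures(list(entry))
  ## necrotic voxels (invalid in DCE) are dropped: ~37% of tumor voxels
  necFrac <- 1 - nrow(hf@features) / sum(tumorMask(truth))
  expect_equal(necFrac, 0.37, tolerance = 0.02)
  ## a voxel invalid in one map only is dropped
  maps2 <- maps
  v <- which(maps2@valid)[1]
  maps2@valid[v] <- FALSE
  hf2 <- assembleFeatures(list(list(maps = maps2, tumor = tumorMask(truth),
                                    subject = 1, timepoint = 0)))
  expect_equal(nrow(hf2@features), nrow(hf@features) - 1L)
  ## all valid and in range: row count equals the viable voxel count
  expect_equal(nrow(hf@features), sum(maps@valid & tumorMask(truth)))
  ## empty result names the dominant filter
  noTumor <- list(maps = maps, tumor = array(FALSE, dim(maps@adc)),
                  subject = 1, timepoint = 0)
  expect_error(assembleFeatures(list(noTumor)), "dominant filter")
})

test_that("normalization gives exact pooled z-scores and flags degeneracy", {
  x <- cbind(adc = c(0, 2, 0, 2), ktrans = c(1, 2, 3, 4), ve = c(1, 2, 3, 4),
             suv_fdg = c(1, 2, 3, 4), suv_flt = c(0, 0, 2, 2))
  hf <- featuresFromMatrix(x)
  norm <- normalizeFeatures(hf)
  ## two-value column {0,2} maps to {-1,+1} (sample SD convention scales by
  ## sd = 1.1547 for n=4; hand z-score: (0-1)/sd)
  expect_equal(as.vector(norm@normFeatures[, "adc"]),
               (c(0, 2, 0, 2) - 1) / sd(c(0, 2, 0, 2)))
  expect_equal(colMeans(norm@normFeatures), rep(0, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(norm@normFeatures, 2, sd), rep(1, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  ## re-normalizing an already standardized column leaves it unchanged
  norm2 <- normalizeFeatures(featuresFromMatrix(norm@normFeatures))
  expect_equal(norm2@normFeatures[, "ktrans"], norm@normFeatures[, "ktrans"],
               tolerance = 1e-9)
  ## constant column errors with the feature name
  bad <- x; bad[, "ve"] <- 1
  expect_error(normalizeFeatures(featuresFromMatrix(bad)), "ve")
})

test_that("Ward clustering recovers planted Gaussian blobs", {
  pb <- plantedBlobs(n = 200, k = 5, sd = 0.1, sep = 3, seed = 42)
  hf <- normalizeFeatures(featuresFromMatrix(pb$x))
  model <- clusterHabitats(hf, 5, seed = 1)
  expect_gte(adjustedRandIndex(model@assignments, pb$labels), 0.99)
  ## k = 1: everything in one cluster
  m1 <- clusterHabitats(hf, 1, seed = 1)
  expect_true(all(m1@assignments == 1L))
  ## duplication invariance: doubling every row keeps the partition
  hfd <- normalizeFeatures(featuresFromMatrix(rbind(pb$x, pb$x)))
  md <- clusterHabitats(hfd, 5, seed = 1)
  expect_gte(adjustedRandIndex(md@assignments[seq_len(1000)],
                               model@assignments), 0.99)
  expect_error(clusterHabitats(hf, nrow(pb$x) + 1), "exceeds")
})

test_that("clustering is invariant to feature order and row shuffling", {
  pb <- plantedBlobs(n = 100, k = 4, sd = 0.1, sep = 3, seed = 7)
  hf <- normalizeFeatures(featuresFromMatrix(pb$x))
  base <- clusterHabitats(hf, 4, seed = 1)
  ## column permutation
  xp <- pb$x[, c(3, 1, 5, 2, 4)]
  hfp <- normalizeFeatures(featuresFromMatrix(xp))
  mp <- clusterHabitats(hfp, 4, seed = 1)
  expect_equal(adjustedRandIndex(mp@assignments, base@assignments), 1)
  ## row shuffling, up to label permutation
  set.seed(3)
  ord <- sample.int(nrow(pb$x))
  hfs <- normalizeFeatures(featuresFromMatrix(pb$x[ord, ]))
  ms <- clusterHabitats(hfs, 4, seed = 1)
  expect_equal(adjustedRandIndex(ms@assignments, base@assignments[ord]), 1)
})

test_that("silhouette selection finds the planted cluster count", {
  pb <- plantedBlobs(n = 200, k = 5, sd = 0.1, sep = 3, seed = 42)
  hf <- normalizeFeatures(featuresFromMatrix(pb$x))
  k <- selectK(hf, kRange = 2:8, seed = 1)
  expect_identical(as.integer(k), 5L)
  ## two blobs: k = 2
  pb2 <- plantedBlobs(n = 150, k = 2, sd = 0.1, sep = 3, seed = 9)
  k2 <- selectK(normalizeFeatures(featuresFromMatrix(pb2$x)), 2:8, seed = 1)
  expect_identical(as.integer(k2), 2L)
  expect_error(selectK(hf, kRange = 1:3), "kRange")
})

test_that("characterization assigns the phenotype names from signatures", {
  truth <- generatePhantom(c(48, 48, 10), 5, 0.3, seed = 21)
  maps <- simulateMapSet(truth, seed = 22)
  hf <- normalizeFeatures(assembleFeatures(list(
    list(maps = maps, tumor = tumorMask(truth), subject = 1, timepoint = 0))))
  model <- characterizeHabitats(clusterHabitats(hf, 5, seed = 1))
  expect_setequal(model@habitatNames, c("HV", "HRSP", "TZ", "ATMR", "RSP"))
  ## signature semantics: HV is high in both ktrans and ve
  hv <- which(model@habitatNames == "HV")
  expect_identical(unname(model@signatures[hv, c("ktrans", "ve")]),
                   c("high", "high"))
  rsp <- which(model@habitatNames == "RSP")
  expect_true(all(model@signatures[rsp, ] == "low"))
})

test_that("composition conserves 100% and matches planted splits", {
  fx <- fixCohort()
  hf <- normalizeFeatures(assembleFeatures(fx$cohort))
  model <- clusterHabitats(hf, 5, seed = 1)
  comp <- habitatComposition(model)
  sums <- aggregate(percent ~ subject + timepoint, comp, sum)
  expect_true(all(abs(sums$percent - 100) < 1e-6))
  ## composition matches the planted habitat fractions (labels matched by
  ## majority vote through the confusion table)
  truthLab <- truthLabelsFor(model, fx$cohort, fx$truths)
  expect_gte(adjustedRandIndex(model@assignments, truthLab), 0.9)
  ## single-habitat subject sits at 100%
  one <- generatePhantom(c(24, 24, 8), 1, 0, seed = 2)
  mone <- simulateMapSet(one, seed = 3)
  hone <- normalizeFeatures(assembleFeatures(list(
    list(maps = mone, tumor = tumorMask(one), subject = 9, timepoint = 0))))
  cone <- habitatComposition(clusterHabitats(hone, 1, seed = 1))
  expect_equal(cone$percent, 100)
})

test_that("remapping to the spatial domain round-trips the composition", {
  fx <- fixCohort()
  hf <- normalizeFeatures(assembleFeatures(fx$cohort))
  model <- clusterHabitats(hf, 5, seed = 1)
  comp <- habitatComposition(model)
  lab <- remapHabitats(model, 1, 0)
  counts <- tabulate(lab[lab > 0], model@k)
  pct <- 100 * counts / sum(counts)
  ref <- comp$percent[comp$subject == 1 & comp$timepoint == 0]
  expect_equal(pct, ref, tolerance = 1e-9)
  ## excluded voxels are 0; labeled voxel count matches provenance
  pv <- model@provenance
  expect_equal(sum(lab > 0), sum(pv$subject == 1 & pv$timepoint == 0))
  ## planted-partition recovery in space
  expect_gte(adjustedRandIndex(lab[lab > 0],
                               fx$truths[["s1_t0"]]@labels[lab > 0]), 0.9)
  expect_error(remapHabitats(model, 99, 0), "no voxels")
})
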