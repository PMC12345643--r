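# shared fixtures, built once per test run

.fix <- new.env()

fixPhantom <- function() {
  if (is.null(.fix$phantom))
    .fix$phantom <- generatePhantom(c(32, 32, 8), 5, 0.37, seed = 5)
  .fix$phantom
}

# small cohort of map sets simulated directly from truth (direct path)
fixCohort <- function(nSubjects = 4, timepoints = c(0, 4)) {
  key <- sprintf("cohort_%d", nSubjects)
  if (is.null(.fix[[key]])) {
    cohort <- list(); truths <- list()
    for (s in seq_len(nSubjects)) for (tp in timepoints) {
      truth <- generatePhantom(c(48, 48, 10), 5,
                               necroticFraction = 0.25 + 0.03 * s,
                               seed = 100 * s + tp)
      k <- sprintf("s%d_t%d", s, tp)
      truths[[k]] <- truth
      cohort[[k]] <- list(maps = simulateMapSet(truth, seed = 100 * s + tp + 1),
                          tumor = tumorMask(truth), subject = s,
                          timepoint = tp)
    }
    .fix[[key]] <- list(cohort = cohort, truths = truths)
  }
  .fix[[key]]
}

# truth labels aligned with a model's provenance rows
truthLabelsFor <- function(model, cohort, truths) {
  unlist(lapply(names(cohort), function(k) {
    pv <- model@provenance
    rows <- pv$subject == cohort[[k]]$subject &
      pv$timepoint == cohort[[k]]$timepoint
    truths[[k]]@labels[pv$voxel[rows]]
  }))
}

# five well-separated 5D Gaussian blobs (planted-partition oracle input)
plantedBlobs <- function(n = 200, k = 5, sd = 0.1, sep = 3, seed = 42) {
  set.seed(seed)
  centers <- matrix(0, k, 5)
  for (i in seq_len(k)) centers[i, ] <- (i - 1) * sep * (seq_len(5) == (i %% 5 + 1))
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    sweep(matrix(rnorm(n * 5, 0, sd), n, 5), 2, centers[i, ], "+")))
  list(x = x, labels = rep(seq_len(k), each = n))
}

featuresFromMatrix <- function(x) {
  colnames(x) <- c("adc", "ktrans", "ve", "suv_fdg", "suv_flt")
  new("HabitatFeatures", features = x,
      normFeatures = matrix(numeric(0), 0, 0),
      provenance = data.frame(subject = 1L, timepoint = 0L,
                              voxel = seq_len(nrow(x)),
                              dimX = nrow(x), dimY = 1L, dimZ = 1L),
      normStats = data.frame())
}

## independent full-enumeration oracle for the Mann-Whitney test
mwOracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  sel <- utils::combn(length(pooled), n1)
  uOf <- function(v1, v2) {
    u <- 0
    for (x in v1) u <- u + sum(x > v2) + 0.5 * sum(x == v2)
    u
  }
  u <- uOf(a, b)
  us <- apply(sel, 2, function(ix) uOf(pooled[ix], pooled[-ix]))
  min(1, 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9)))
}

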