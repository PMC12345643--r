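.featureNames <- c("adc", "ktrans", "ve", "suv_fdg", "suv_flt")

#' Default physiological ranges for habitat features
#'
#' Voxels outside these ranges are dropped before pooling.  ADC in mm^2/s,
#' Ktrans in 1/min, ve unitless, SUV unitless.
#'
#' @return named list of c(min, max) per feature (open at zero for rate-like
#'   features).
#' @export
defaultFeatureRanges <- function() {
  list(adc = c(0.1e-3, 3.0e-3), ktrans = c(0, 5), ve = c(0, 1),
       suv_fdg = c(0, 20), suv_flt = c(0, 20))
}

#' Pool voxel features across subjects and timepoints
#'
#' Builds the five-dimensional feature matrix (ADC, Ktrans, ve, FDG-SUV,
#' FLT-SUV) over tumor voxels that are valid in every map and inside the
#' configured physiological ranges, keeping per-row provenance for spatial
#' remapping.
#'
#' @param cohort list of entries, each a list with elements \code{maps}
#'   (a \linkS4class{ParametricMapSet}), \code{tumor} (logical mask),
#'   \code{subject} and \code{timepoint}.
#' @param ranges physiological bounds (\code{\link{defaultFeatureRanges}}).
#' @return A \linkS4class{HabitatFeatures}.
#' @export
assembleFeatures <- function(cohort, ranges = defaultFeatureRanges()) {
  featList <- list()
  provList <- list()
  dropCounts <- stats::setNames(numeric(length(.featureNames) + 1),
                                c("validity", .featureNames))
  for (entry in cohort) {
    maps <- entry$maps
    tumor <- as.logical(entry$tumor)
    dims <- dim(maps@adc)
    feat <- cbind(adc = as.numeric(maps@adc),
                  ktrans = as.numeric(maps@ktrans),
                  ve = as.numeric(maps@ve),
                  suv_fdg = as.numeric(maps@suvFdg),
                  suv_flt = as.numeric(maps@suvFlt))
    keep <- tumor & as.logical(maps@valid) & !is.na(rowSums(feat))
    dropCounts["validity"] <- dropCounts["validity"] +
      sum(tumor) - sum(keep)
    for (f in .featureNames) {
      r <- ranges[[f]]
      inR <- feat[, f] > r[1] & feat[, f] <= r[2]
      dropCounts[f] <- dropCounts[f] + sum(keep & !inR, na.rm = TRUE)
      keep <- keep & inR
    }
    keep <- which(keep)
    if (length(keep)) {
      featList[[length(featList) + 1L]] <- feat[keep, , drop = FALSE]
      provList[[length(provList) + 1L]] <- data.frame(
        subject = entry$subject, timepoint = entry$timepoint, voxel = keep,
        dimX = dims[1], dimY = dims[2], dimZ = dims[3])
    }
  }
  if (!length(featList)) {
    dom <- names(dropCounts)[which.max(dropCounts)]
    stop("no voxels survive pooling; dominant filter: ", dom)
  }
  new("HabitatFeatures", features = do.call(rbind, featList),
      normFeatures = matrix(numeric(0), 0, 0),
      provenance = do.call(rbind, provList),
      normStats = data.frame())
}

#' Normalize pooled features to zero mean and unit SD
#'
#' Column-wise z-scores over the pooled matrix (all subjects and timepoints
#' together); the per-feature statistics are stored on the object.
#'
#' @param hf a HabitatFeatures.
#' @return the HabitatFeatures with \code{normFeatures} and \code{normStats}
#'   filled.
#' @export
normalizeFeatures <- function(hf) {
  x <- hf@features
  if (nrow(x) < 2) stop("need >= 2 rows to normalize")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  if (any(sdv <= 0)) {
    stop("degenerate (constant) feature: ",
         paste(colnames(x)[sdv <= 0], collapse = ", "))
  }
  hf@normFeatures <- scale(x, center = mu, scale = sdv)[, , drop = FALSE]
  hf@normStats <- data.frame(feature = colnames(x), mean = mu, sd = sdv)
  hf
}

setMethod("show", "HabitatFeatures", function(object) {
  cat(sprintf("HabitatFeatures: %d voxels x %d features (%s)\n",
              nrow(object@features), ncol(object@features),
              if (nrow(object@normStats)) "normalized" else "raw"))
})

## Ward hierarchical clustering with an optional fixed-seed subsample;
## out-of-sample rows are assigned to the nearest cluster centroid.
.wardPartition <- function(x, k, maxRows = 8000L, seed = 1) {
  n <- nrow(x)
  if (k > n) stop("k exceeds the number of rows")
  if (n <= maxRows) {
    hc <- stats::hclust(stats::dist(x), method = "ward.D2")
    return(stats::cutree(hc, k = k))
  }
  rng <- .localRNG(seed); on.exit(rng())
  sub <- sort(sample.int(n, maxRows))
  hc <- stats::hclust(stats::dist(x[sub, , drop = FALSE]),
                      method = "ward.D2")
  labSub <- stats::cutree(hc, k = k)
  cent <- t(vapply(seq_len(k), function(c)
    colMeans(x[sub[labSub == c], , drop = FALSE]), numeric(ncol(x))))
  lab <- integer(n)
  lab[sub] <- labSub
  rest <- setdiff(seq_len(n), sub)
  if (length(rest)) {
    d2 <- outer(rowSums(x[rest, , drop = FALSE]^2), rowSums(cent^2), "+") -
      2 * x[rest, , drop = FALSE] %*% t(cent)
    lab[rest] <- max.col(-d2, ties.method = "first")
  }
  lab
}

#' Cluster pooled voxels into habitats
#'
#' Agglomerative hierarchical clustering with Ward linkage on Euclidean
#' distance over the normalized pooled features.  For tractability beyond
#' \code{maxRows} rows the dendrogram is built on a fixed-seed subsample and
#' remaining voxels join their nearest cluster centroid.  Cluster ids are
#' relabelled in order of decreasing size.
#'
#' @param hf normalized HabitatFeatures.
#' @param k number of habitats.
#' @param maxRows dendrogram size cap.
#' @param seed subsampling seed.
#' @return A \linkS4class{HabitatModel} (signatures/names filled by
#'   \code{\link{characterizeHabitats}}).
#' @export
clusterHabitats <- function(hf, k, maxRows = 8000L, seed = 1) {
  if (!nrow(hf@normFeatures)) hf <- normalizeFeatures(hf)
  k <- as.integer(k)
  lab <- .wardPartition(hf@normFeatures, k, maxRows = maxRows, seed = seed)
  ## stable ids: decreasing cluster size
  sizes <- tabulate(lab, k)
  ord <- order(sizes, decreasing = TRUE)
  relab <- integer(k)
  relab[ord] <- seq_len(k)
  lab <- relab[lab]
  cent <- t(vapply(seq_len(k), function(c)
    colMeans(hf@features[lab == c, , drop = FALSE]), numeric(ncol(hf@features))))
  colnames(cent) <- colnames(hf@features)
  new("HabitatModel", k = k, assignments = as.integer(lab),
      centroids = cent,
      signatures = matrix(character(0), 0, 0),
      habitatNames = character(0), provenance = hf@provenance)
}

#' Select the habitat count by mean silhouette
#'
#' Cuts a single Ward dendrogram (on a fixed-seed subsample of at most
#' \code{maxRows} rows) at each candidate k and returns the k maximizing the
#' mean silhouette width; ties resolve to the smaller k.
#'
#' @param hf normalized HabitatFeatures.
#' @param kRange candidate cluster counts (reference range 2..8).
#' @param maxRows silhouette subsample cap.
#' @param seed subsampling seed.
#' @return selected k; \code{attr(, "silhouette")} holds the mean widths.
#' @export
selectK <- function(hf, kRange = 2:8, maxRows = 5000L, seed = 1) {
  if (!nrow(hf@normFeatures)) hf <- normalizeFeatures(hf)
  x <- hf@normFeatures
  n <- nrow(x)
  if (any(kRange < 2) || any(kRange > n - 1))
    stop("kRange must lie in [2, rows - 1]")
  if (n > maxRows) {
    rng <- .localRNG(seed); on.exit(rng())
    x <- x[sort(sample.int(n, maxRows)), , drop = FALSE]
  }
  dm <- stats::dist(x)
  hc <- stats::hclust(dm, method = "ward.D2")
  scores <- vapply(kRange, function(k) {
    lab <- stats::cutree(hc, k = k)
    mean(cluster::silhouette(lab, dm)[, "sil_width"])
  }, numeric(1))
  best <- kRange[which.max(scores)]  # which.max takes the first (smallest k)
  structure(as.integer(best),
            silhouette = stats::setNames(scores, kRange))
}

#' Default habitat naming table
#'
#' Signature patterns (high/low per feature, unspecified = any) mapped to the
#' five phenotype labels, matched in order: responding (RSP, all low),
#' hypoxic responding (HRSP: low Ktrans, high ve, low FDG), active tumor
#' (ATMR: high FDG and FLT, low Ktrans), high vascularity (HV: high Ktrans
#' and ve), transitional zone (TZ: high ADC).
#'
#' @return list of list(name=, pattern=named character).
#' @export
defaultHabitatNames <- function() {
  list(
    list(name = "RSP", pattern = c(adc = "low", ktrans = "low", ve = "low",
                                   suv_fdg = "low", suv_flt = "low")),
    list(name = "HRSP", pattern = c(ktrans = "low", ve = "high",
                                    suv_fdg = "low")),
    list(name = "ATMR", pattern = c(ktrans = "low", suv_fdg = "high",
                                    suv_flt = "high")),
    list(name = "HV", pattern = c(ktrans = "high", ve = "high")),
    list(name = "TZ", pattern = c(adc = "high")))
}

#' Characterize habitats by centroid signatures and assign names
#'
#' For each feature the median of the k cluster-centroid values defines the
#' cut; a cluster is "high" when its centroid lies strictly above it.  Names
#' come from the first matching pattern in \code{namingTable}; unmatched
#' signatures get generic H<i> labels, and duplicate names are suffixed.
#'
#' @param model a HabitatModel.
#' @param namingTable signature-to-name table
#'   (\code{\link{defaultHabitatNames}}).
#' @return the HabitatModel with \code{signatures} and \code{habitatNames}.
#' @export
characterizeHabitats <- function(model, namingTable = defaultHabitatNames()) {
  cent <- model@centroids
  med <- apply(cent, 2, stats::median)
  sig <- ifelse(sweep(cent, 2, med, ">"), "high", "low")
  dimnames(sig) <- dimnames(cent)
  nms <- character(model@k)
  for (c in seq_len(model@k)) {
    hit <- NA_character_
    for (entry in namingTable) {
      pat <- entry$pattern
      if (all(sig[c, names(pat)] == pat)) {
        hit <- entry$name
        break
      }
    }
    nms[c] <- if (is.na(hit)) paste0("H", c) else hit
  }
  dup <- duplicated(nms)
  nms[dup] <- paste0(nms[dup], ".", seq_len(sum(dup)))
  model@signatures <- sig
  model@habitatNames <- nms
  model
}

setMethod("show", "HabitatModel", function(object) {
  cat(sprintf("HabitatModel: k = %d over %d voxels\n", object@k,
              length(object@assignments)))
  if (length(object@habitatNames)) {
    df <- as.data.frame(signif(object@centroids, 3))
    df$name <- object@habitatNames
    df$size <- tabulate(object@assignments, object@k)
    print(df)
  }
})

#' Habitat composition per subject and timepoint
#'
#' @param model a HabitatModel with provenance.
#' @return data.frame (subject, timepoint, habitat, name, percent); per
#'   subject-timepoint the percentages sum to 100.
#' @export
habitatComposition <- function(model) {
  pv <- model@provenance
  if (!nrow(pv)) stop("model carries no provenance")
  key <- interaction(pv$subject, pv$timepoint, drop = TRUE)
  out <- list()
  nms <- if (length(model@habitatNames)) model@habitatNames
         else paste0("H", seq_len(model@k))
  for (g in levels(key)) {
    rows <- key == g
    counts <- tabulate(model@assignments[rows], model@k)
    out[[g]] <- data.frame(
      subject = pv$subject[rows][1], timepoint = pv$timepoint[rows][1],
      habitat = seq_len(model@k), name = nms,
      percent = 100 * counts / sum(counts))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remap habitat assignments to a label volume
#'
#' @param model a HabitatModel.
#' @param subject,timepoint which subject-timepoint to remap.
#' @return integer 3D array of habitat ids; voxels excluded from clustering
#'   are 0.
#' @export
remapHabitats <- function(model, subject, timepoint) {
  pv <- model@provenance
  rows <- pv$subject == subject & pv$timepoint == timepoint
  if (!any(rows)) stop("no voxels for this subject-timepoint")
  dims <- c(pv$dimX[rows][1], pv$dimY[rows][1], pv$dimZ[rows][1])
  lab <- array(0L, dims)
  lab[pv$voxel[rows]] <- model@assignments[rows]
  lab
}
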