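## 2D box smoothing with circular boundary (sum-preserving) via cumulative
## sums; kernel may be even-sized, footprint anchored like a convolution.
boxSmooth2D <- function(m, k) {
  if (k < 1) stop("kernel size must be >= 1")
  if (k == 1) return(m)
  d <- dim(m)
  lo <- floor((k - 1) / 2)
  hi <- k - 1 - lo
  ## circular pad
  padIdx <- function(n) ((seq(-lo + 1, n + hi) - 1) %% n) + 1
  mp <- m[padIdx(d[1]), padIdx(d[2]), drop = FALSE]
  cs <- apply(apply(mp, 2, cumsum), 1, cumsum)  # transposed cumsum matrix
  cs <- t(cs)
  cs <- rbind(0, cbind(0, cs))
  i <- seq_len(d[1]); j <- seq_len(d[2])
  (cs[i + k, j + k, drop = FALSE] - cs[i, j + k, drop = FALSE] -
     cs[i + k, j, drop = FALSE] + cs[i, j, drop = FALSE]) / (k * k)
}

## bilinear / nearest resize via EBImage
bilinearResize2D <- function(m, n1, n2)
  as.matrix(EBImage::resize(m, w = n1, h = n2))

nearestResize2D <- function(m, n1, n2)
  as.matrix(EBImage::resize(m, w = n1, h = n2, filter = "none"))

#' Smoothed, down-sampled stain density features
#'
#' Applies a uniform (box) spatial smoothing kernel to every stain map, then
#' bilinearly resamples to the analysis resolution.  The validity mask is
#' eroded consistently: an analysis pixel is valid only if its entire
#' smoothing footprint lay on living tissue.
#'
#' @param section a \linkS4class{StainDensitySection}.
#' @param kernelPx box kernel size in pixels (reference setting 10).
#' @param targetPixelSizeMm analysis resolution, mm/pixel (default 0.1 to
#'   approach the imaging resolution).
#' @return a StainDensitySection at the analysis resolution.
#' @export
densityFeatures <- function(section, kernelPx = 10L,
                            targetPixelSizeMm = 0.1) {
  if (kernelPx < 1) stop("kernelPx must be >= 1")
  d <- dim(section@valid)
  fac <- targetPixelSizeMm / section@pixelSizeMm
  n1 <- max(1L, as.integer(round(d[1] / fac)))
  n2 <- max(1L, as.integer(round(d[2] / fac)))
  sm <- lapply(section@stains, function(s)
    bilinearResize2D(boxSmooth2D(s, kernelPx), n1, n2))
  validSm <- boxSmooth2D(section@valid + 0, kernelPx) > 1 - 1e-9
  valid <- nearestResize2D(validSm + 0, n1, n2) > 0.5
  truth <- if (length(section@truthLabels)) {
    tr <- nearestResize2D(section@truthLabels + 0, n1, n2)
    matrix(as.integer(round(tr)), n1, n2)
  } else matrix(integer(0), 0, 0)
  new("StainDensitySection", stains = sm, valid = valid,
      pixelSizeMm = section@pixelSizeMm * d[1] / n1,
      truthLabels = truth)
}

setMethod("show", "StainDensitySection", function(object) {
  cat(sprintf("StainDensitySection: %s px (%.3g mm/px), stains: %s\n",
              paste(dim(object@valid), collapse = " x "),
              object@pixelSizeMm,
              paste(names(object@stains), collapse = ", ")))
})

#' Cluster histology sections into habitats
#'
#' Pools valid pixels of the clustering stains across sections, z-normalizes
#' feature-wise and applies the shared Ward clustering core; pimonidazole is
#' withheld by default so hypoxia can validate the clusters.  Labels are
#' remapped to each section.
#'
#' @param sections list of analysis-resolution StainDensitySections
#'   (from \code{\link{densityFeatures}}).
#' @param k habitat count, or "auto" to select by mean silhouette over
#'   \code{kRange}.
#' @param stains features to cluster on.
#' @param kRange candidate k when \code{k = "auto"}.
#' @param maxRows dendrogram cap, as in \code{\link{clusterHabitats}}.
#' @param seed subsampling seed.
#' @return list with \code{model} (HabitatModel over pixels), \code{labels}
#'   (per-section label matrices, 0 = invalid), \code{composition}
#'   (data.frame of percent area per section and habitat) and \code{k}.
#' @export
clusterHistology <- function(sections, k = "auto",
                             stains = c("nuclei", "cd31", "ki67", "glut1"),
                             kRange = 2:8, maxRows = 8000L, seed = 1) {
  featList <- list(); provList <- list()
  for (s in seq_along(sections)) {
    sec <- sections[[s]]
    idx <- which(sec@valid)
    if (!length(idx)) next
    feat <- vapply(stains, function(st) sec@stains[[st]][idx],
                   numeric(length(idx)))
    featList[[length(featList) + 1L]] <- matrix(feat, ncol = length(stains),
                                                dimnames = list(NULL, stains))
    provList[[length(provList) + 1L]] <- data.frame(
      subject = s, timepoint = 1L, voxel = idx,
      dimX = nrow(sec@valid), dimY = ncol(sec@valid), dimZ = 1L)
  }
  if (!length(featList)) stop("no valid pixels to cluster")
  hf <- new("HabitatFeatures", features = do.call(rbind, featList),
            normFeatures = matrix(numeric(0), 0, 0),
            provenance = do.call(rbind, provList), normStats = data.frame())
  hf <- normalizeFeatures(hf)
  if (identical(k, "auto"))
    k <- selectK(hf, kRange = kRange, maxRows = min(maxRows, 4000L),
                 seed = seed)
  model <- clusterHabitats(hf, k, maxRows = maxRows, seed = seed)
  labels <- lapply(seq_along(sections), function(s) {
    lab <- matrix(0L, nrow(sections[[s]]@valid), ncol(sections[[s]]@valid))
    rows <- model@provenance$subject == s
    if (any(rows)) lab[model@provenance$voxel[rows]] <-
        model@assignments[rows]
    lab
  })
  comp <- habitatComposition(model)
  list(model = model, labels = labels, composition = comp, k = as.integer(k))
}

#' Per-habitat share of pimonidazole-positive density
#'
#' Fraction of the summed hypoxia-stain density (over valid, labeled pixels)
#' falling in each habitat; shares sum to 1.
#'
#' @param labels integer label matrix (0 = unlabeled).
#' @param pimo pimonidazole density matrix, same grid.
#' @param k habitat count (default max label).
#' @return named numeric vector of shares.
#' @export
hypoxiaColocalization <- function(labels, pimo, k = max(labels)) {
  if (!all(dim(labels) == dim(pimo))) stop("grids must match")
  ok <- labels > 0L
  tot <- sum(pimo[ok])
  if (tot <= 0) stop("no pimonidazole-positive density on labeled pixels")
  shares <- vapply(seq_len(k), function(h)
    sum(pimo[ok & labels == h]) / tot, numeric(1))
  stats::setNames(shares, paste0("H", seq_len(k)))
}
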