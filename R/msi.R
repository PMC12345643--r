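## neighbor offsets for 6- (faces) and 26- (full) connectivity; one of each
## antiparallel pair so every unordered voxel pair is visited once
.msiOffsets <- function(connectivity) {
  if (connectivity == 6L) {
    list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else if (connectivity == 26L) {
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, ]
    keep <- apply(offs, 1, function(o) {
      nz <- which(o != 0)[1]
      o[nz] > 0
    })
    lapply(seq_len(sum(keep)), function(i) offs[keep, ][i, ])
  } else stop("connectivity must be 6 or 26")
}

## index pairs (i, j) of neighboring labeled voxels (labels > 0)
.neighborPairs <- function(labels, connectivity) {
  d <- dim(labels)
  lin <- array(seq_along(labels), d)
  pairs <- list()
  for (off in .msiOffsets(connectivity)) {
    if (any(d - abs(off) < 1)) next
    a <- lin
    for (ax in 1:3) {
      n <- d[ax]; o <- off[ax]
      if (o == 0) next
      idx <- if (o > 0) seq_len(n - o) else seq_len(n + o) - o
      a <- switch(ax, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
                  a[, , idx, drop = FALSE])
    }
    ## linear index shift: off[1] + off[2]*d1 + off[3]*d1*d2
    b <- a + off[1] + off[2] * d[1] + off[3] * d[1] * d[2]
    ok <- labels[a] > 0L & labels[b] > 0L
    if (any(ok)) pairs[[length(pairs) + 1L]] <- cbind(a[ok], b[ok])
  }
  if (!length(pairs)) stop("no neighboring labeled voxel pairs")
  do.call(rbind, pairs)
}

## unordered pair-type fractions from label values at pair endpoints
.pairFractions <- function(la, lb, k) {
  u <- pmin(la, lb); v <- pmax(la, lb)
  idx <- (u - 1L) * k + v
  cnt <- tabulate(idx, k * k)
  M <- matrix(0, k, k)
  for (a in seq_len(k)) for (b in a:k) {
    M[a, b] <- cnt[(a - 1L) * k + b]
    M[b, a] <- M[a, b]
  }
  M / length(la)
}

#' Neighboring-voxel-pair fractions between habitats
#'
#' Counts unordered neighboring voxel pairs among labeled (> 0) voxels in 3D
#' and normalizes by the total pair count.  The unique unordered entries
#' (upper triangle including the diagonal) sum to 1.
#'
#' @param labels integer 3D array of habitat labels (0/-1 = unlabeled).
#' @param connectivity 6 (face neighbors, default) or 26.
#' @param k number of habitats (defaults to max label).
#' @return A \linkS4class{MSIMatrix} with only \code{pairFraction} filled.
#' @export
countPairs <- function(labels, connectivity = 6L, k = max(labels)) {
  if (sum(labels > 0L) < 2) stop("need >= 2 labeled voxels")
  pr <- .neighborPairs(labels, as.integer(connectivity))
  M <- .pairFractions(labels[pr[, 1]], labels[pr[, 2]], as.integer(k))
  empty <- matrix(NA_real_, k, k)
  new("MSIMatrix", pairFraction = M, nullMean = empty, nullSd = empty,
      z = empty, nRandomizations = 0L,
      connectivity = as.integer(connectivity))
}

#' Size-preserving randomized null for the MSI matrix
#'
#' Shuffles the habitat labels uniformly over the labeled voxel positions
#' (preserving each habitat's size) \code{n} times and records the per-pair-
#' type mean and SD of the neighboring-pair fractions.
#'
#' @inheritParams countPairs
#' @param n number of randomizations (>= 100 recommended).
#' @param seed RNG seed (fixed seed gives bit-identical statistics).
#' @return list with \code{mean} and \code{sd} k x k matrices.
#' @export
randomizedNull <- function(labels, connectivity = 6L, n = 1000L, seed = 1,
                           k = max(labels)) {
  rng <- .localRNG(seed); on.exit(rng())
  k <- as.integer(k)
  pr <- .neighborPairs(labels, as.integer(connectivity))
  pos <- which(labels > 0L)
  lab <- as.integer(labels[pos])
  slot <- integer(length(labels))
  slot[pos] <- seq_along(pos)
  pa <- slot[pr[, 1]]; pb <- slot[pr[, 2]]
  s1 <- matrix(0, k, k); s2 <- matrix(0, k, k)
  for (r in seq_len(n)) {
    perm <- lab[sample.int(length(lab))]
    M <- .pairFractions(perm[pa], perm[pb], k)
    s1 <- s1 + M
    s2 <- s2 + M^2
  }
  mu <- s1 / n
  va <- pmax(s2 / n - mu^2, 0) * n / max(n - 1, 1)
  list(mean = mu, sd = sqrt(va))
}

#' MSI z-scores against the randomized null
#'
#' z = (observed - null mean) / null SD per pair type; entries with zero null
#' SD are NA.
#'
#' @param observed MSIMatrix from \code{\link{countPairs}}.
#' @param nullStats list from \code{\link{randomizedNull}}.
#' @return the MSIMatrix with null statistics and z filled.
#' @export
msiZScores <- function(observed, nullStats) {
  if (!all(dim(observed@pairFraction) == dim(nullStats$mean)))
    stop("shape mismatch between observed and null")
  z <- (observed@pairFraction - nullStats$mean) / nullStats$sd
  z[nullStats$sd == 0] <- NA_real_
  new("MSIMatrix", pairFraction = observed@pairFraction,
      nullMean = nullStats$mean, nullSd = nullStats$sd, z = z,
      nRandomizations = observed@nRandomizations,
      connectivity = observed@connectivity)
}

#' Full multiregional spatial interaction analysis
#'
#' @inheritParams countPairs
#' @param n randomizations for the null.
#' @param seed RNG seed.
#' @return A complete \linkS4class{MSIMatrix}.
#' @export
computeMSI <- function(labels, connectivity = 6L, n = 1000L, seed = 1,
                       k = max(labels)) {
  obs <- countPairs(labels, connectivity = connectivity, k = k)
  nl <- randomizedNull(labels, connectivity = connectivity, n = n,
                       seed = seed, k = k)
  res <- msiZScores(obs, nl)
  res@nRandomizations <- as.integer(n)
  res
}

setMethod("show", "MSIMatrix", function(object) {
  k <- nrow(object@pairFraction)
  cat(sprintf("MSIMatrix: %d habitats, connectivity %d, %d randomizations\n",
              k, object@connectivity, object@nRandomizations))
  if (object@nRandomizations > 0)
    cat(sprintf("  mean diagonal z: %.2f\n", mean(diag(object@z),
                                                  na.rm = TRUE)))
})
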