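#' Select the central slice by imaging-histology composition correlation
#'
#' Within a candidate window (central slice +/- 2), picks the slice whose
#' habitat-percentage vector has the highest Pearson correlation with the
#' histology habitat percentages; ties resolve to the slice nearest the
#' window centre.
#'
#' @param imagingPercentBySlice slices x habitats matrix of per-slice habitat
#'   percentages (rownames taken as slice ids if present).
#' @param histologyPercent habitat-percentage vector from the matched
#'   histology section.
#' @return selected slice id (row index if unnamed); \code{attr(, "r")} holds
#'   the per-slice correlations.
#' @export
selectCentralSlice <- function(imagingPercentBySlice, histologyPercent) {
  m <- rbind(imagingPercentBySlice)
  n <- nrow(m)
  if (n < 1) stop("empty slice window")
  r <- apply(m, 1, function(x) {
    if (stats::sd(x) == 0 || stats::sd(histologyPercent) == 0) return(-Inf)
    stats::cor(x, histologyPercent)
  })
  best <- which(r == max(r))
  if (length(best) > 1) {
    centre <- (n + 1) / 2
    best <- best[which.min(abs(best - centre))]
  }
  ids <- suppressWarnings(as.numeric(rownames(m)))
  sel <- if (length(ids) && !anyNA(ids)) ids[best] else best
  structure(sel, r = as.numeric(r))
}

#' Match histology clusters to imaging clusters by exhaustive permutation
#'
#' Evaluates all k! bijections from histology cluster labels to imaging
#' cluster labels and selects the one maximizing the summed (optionally mean
#' or minimum) per-habitat Pearson correlation between composition vectors
#' across subjects; ties resolve to the lexicographically smallest
#' permutation.
#'
#' @param histPercent subjects x k matrix of histology habitat percentages.
#' @param imgPercent subjects x k matrix of imaging habitat percentages.
#' @param objective aggregation of per-habitat correlations.
#' @return list with \code{permutation} (imaging cluster matched to each
#'   histology cluster), \code{r}, \code{r2}, \code{p} per matched habitat,
#'   and \code{objective} value.
#' @export
matchByPermutation <- function(histPercent, imgPercent,
                               objective = c("sum", "mean", "min")) {
  objective <- match.arg(objective)
  k <- ncol(histPercent)
  if (k != ncol(imgPercent)) stop("cluster counts differ")
  if (k > 8) stop("exhaustive matching supports k <= 8")
  ## correlation of every (hist, img) column pair, NA-safe
  C <- matrix(0, k, k)
  for (h in seq_len(k)) for (i in seq_len(k)) {
    if (stats::sd(histPercent[, h]) > 0 && stats::sd(imgPercent[, i]) > 0)
      C[h, i] <- stats::cor(histPercent[, h], imgPercent[, i])
  }
  perms <- pracma::perms(seq_len(k))
  ## pracma::perms enumerates in reverse-lexicographic order; reorder so the
  ## first maximum is the lexicographically smallest permutation
  perms <- perms[do.call(order, as.data.frame(perms)), , drop = FALSE]
  agg <- switch(objective, sum = sum, mean = mean, min = min)
  scores <- apply(perms, 1, function(p) agg(C[cbind(seq_len(k), p)]))
  best <- perms[which.max(scores), ]
  cors <- correlateCompositions(histPercent,
                                imgPercent[, best, drop = FALSE])
  list(permutation = as.integer(best), r = cors$r, r2 = cors$r2,
       p = cors$p, objective = max(scores))
}

#' Pearson correlation of matched composition vectors
#'
#' Per habitat: Pearson r across subjects with a two-sided p from the t
#' distribution on n - 2 degrees of freedom, and R^2 = r^2.
#'
#' @param x,y subjects x k matrices, columns matched.
#' @return list of per-habitat \code{r}, \code{r2}, \code{p}.
#' @export
correlateCompositions <- function(x, y) {
  x <- cbind(x); y <- cbind(y)
  if (nrow(x) < 3) stop("need >= 3 subjects")
  k <- ncol(x)
  r <- p <- rep(NA_real_, k)
  for (j in seq_len(k)) {
    if (stats::sd(x[, j]) == 0 || stats::sd(y[, j]) == 0) next
    ct <- stats::cor.test(x[, j], y[, j], method = "pearson")
    r[j] <- unname(ct$estimate)
    p[j] <- ct$p.value
  }
  list(r = r, r2 = r^2, p = p)
}

## Mann-Whitney U with midranks
.uStatistic <- function(a, b) {
  ranks <- rank(c(a, b))
  sum(ranks[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Two-sided Mann-Whitney U test
#'
#' For group sizes up to \code{exactMax} the null distribution of U is
#' enumerated exactly over all assignments of the pooled sample (midranks
#' handle ties), and the two-sided p is twice the smaller tail probability,
#' capped at 1.  Larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param a,b numeric samples (each >= 2 values).
#' @param exactMax per-group size limit for exact enumeration.
#' @return list with \code{U} and two-sided \code{p}.
#' @export
compareGroups <- function(a, b, exactMax = 8L) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 values")
  u <- .uStatistic(a, b)
  pooled <- c(a, b)
  if (n1 <= exactMax && n2 <= exactMax) {
    sel <- utils::combn(n1 + n2, n1)
    us <- apply(sel, 2, function(ix)
      .uStatistic(pooled[ix], pooled[-ix]))
    eps <- 1e-9
    p <- 2 * min(mean(us <= u + eps), mean(us >= u - eps))
    p <- min(p, 1)
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    n <- n1 + n2
    sig2 <- n1 * n2 / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = u, p = p)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Standard one-way F test followed by Tukey's Honest Significant Difference
#' over all group pairs (studentized range).
#'
#' @param groups named list of numeric samples (k >= 2, each >= 2 values).
#' @return list with \code{F}, \code{p} and \code{tukey} (data.frame of
#'   pairwise differences and adjusted p values).
#' @export
anovaTukey <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs >= 2 values")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), lengths(groups))))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      pAdj = tk[, "p adj"], row.names = NULL)
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1], tukey = tukey)
}
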