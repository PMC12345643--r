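test_that("central-slice selection maximizes the composition correlation", {
  hist <- c(30, 25, 20, 15, 10)
  ## construct a 5-slice window with a known correlation ordering
  set.seed(4)
  mk <- function(r) {
    ## vector with Pearson correlation ~r to hist
    z <- as.numeric(scale(hist))
    e <- as.numeric(scale(residuals(lm(rnorm(5) ~ z))))
    as.numeric(r * z + sqrt(1 - r^2) * e)
  }
  win <- rbind(mk(0.2), mk(0.5), mk(0.9), mk(0.4), mk(0.1))
  ## brute-force oracle: the slice with the highest correlation
  oracle <- which.max(apply(win, 1, cor, y = hist))
  expect_equal(as.integer(selectCentralSlice(win, hist)), oracle)
  expect_equal(oracle, 3L)
  ## a slice exactly proportional to the histology vector wins with r = 1
  win2 <- rbind(win[1, ], hist * 1.7, win[4, ])
  expect_equal(as.integer(selectCentralSlice(win2, hist)), 2L)
  ## single candidate returns itself
  expect_equal(as.integer(selectCentralSlice(win[2, , drop = FALSE], hist)),
               1L)
  ## ties resolve to the slice nearest the window centre
  tied <- rbind(hist, c(1, 1, 1, 1, 2), hist, hist, c(2, 1, 1, 1, 1))
  dimnames(tied) <- NULL
  expect_equal(as.integer(selectCentralSlice(tied, hist)), 3L)
})

test_that("permutation matching enumerates k! bijections exactly", {
  set.seed(5)
  x <- matrix(runif(40, 10, 30), 8, 5)
  ## identity when histology equals imaging
  m0 <- matchByPermutation(x, x)
  expect_identical(m0$permutation, 1:5)
  expect_equal(m0$r, rep(1, 5), tolerance = 1e-12)
  ## cyclic relabeling is inverted
  y <- x[, c(2, 3, 4, 5, 1)]
  m1 <- matchByPermutation(x, y)
  expect_identical(m1$permutation, c(5L, 1L, 2L, 3L, 4L))
  ## k = 5 evaluates all 120 permutations: equals a brute-force oracle
  set.seed(6)
  a <- matrix(runif(40), 8, 5); b <- matrix(runif(40), 8, 5)
  mm <- matchByPermutation(a, b)
  allp <- pracma::perms(1:5)
  expect_equal(mm$objective, max(apply(allp, 1, function(p)
    sum(sapply(1:5, function(h) cor(a[, h], b[, p[h]]))))), tolerance = 1e-12)
  expect_equal(nrow(allp), 120)
  expect_error(matchByPermutation(matrix(0, 2, 9), matrix(0, 2, 9)), "k <= 8")
})

test_that("composition correlations match cor.test", {
  set.seed(7)
  x <- matrix(rnorm(24), 8, 3)
  y <- x + matrix(rnorm(24, 0, 0.3), 8, 3)
  out <- correlateCompositions(x, y)
  for (j in 1:3) {
    ct <- cor.test(x[, j], y[, j])
    expect_equal(out$r[j], unname(ct$estimate))
    expect_equal(out$p[j], ct$p.value)
    expect_equal(out$r2[j], unname(ct$estimate)^2)
  }
  ## y = x exactly
  ident <- correlateCompositions(x, x)
  expect_equal(ident$r2, rep(1, 3))
  expect_error(correlateCompositions(x[1:2, ], y[1:2, ]), ">= 3")
})

test_that("Mann-Whitney exact p equals the full-enumeration oracle", {
  ## canonical example: complete separation of 4 vs 4
  res <- compareGroups(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.0286, tolerance = 1e-3)
  ## identical samples: maximal overlap, p = 1
  expect_equal(compareGroups(c(2, 2, 2), c(2, 2, 2))$p, 1)
  ## randomized small samples, with and without ties, vs the oracle
  set.seed(8)
  for (rep in 1:12) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- sample(1:8, n1, replace = TRUE)   # replace=TRUE forces tie handling
    b <- sample(1:8, n2, replace = TRUE)
    expect_equal(compareGroups(a, b)$p, mwOracle(a, b), tolerance = 1e-12)
  }
  ## midranks match the brute-force rank-sum definition under a single tie
  a <- c(1, 2, 3); b <- c(3, 4, 5)
  ranks <- rank(c(a, b))
  expect_equal(compareGroups(a, b)$U,
               sum(ranks[1:3]) - 3 * 4 / 2)
  ## large samples agree with the base normal approximation
  set.seed(9)
  x <- rnorm(15); y <- rnorm(15, 0.8)
  ours <- compareGroups(x, y)$p
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("ANOVA + Tukey match algebraic identities and hand arithmetic", {
  ## two groups reduce to t^2 = F
  set.seed(10)
  a <- rnorm(6); b <- rnorm(7, 1)
  at <- anovaTukey(list(a = a, b = b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(at$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(at$p, tt$p.value, tolerance = 1e-10)
  ## three constructed groups against hand-computed sums of squares
  g <- list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(6, 7, 8))
  means <- sapply(g, mean)                 # 2, 3, 7
  grand <- mean(unlist(g))                 # 4
  ssb <- 3 * sum((means - grand)^2)        # 3 * (4 + 1 + 9) = 42
  ssw <- sum(sapply(g, function(x) sum((x - mean(x))^2)))  # 6 * 1 = 6... (2 each)
  Fhand <- (ssb / 2) / (ssw / 6)
  at3 <- anovaTukey(g)
  expect_equal(at3$F, Fhand, tolerance = 1e-10)
  ## groups with identical distributions: F = 0, all pairwise p = 1
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  atS <- anovaTukey(same)
  expect_equal(atS$F, 0, tolerance = 1e-12)
  expect_true(all(atS$tukey$pAdj > 1 - 1e-9))
  ## Tukey table against TukeyHSD directly
  ref <- TukeyHSD(aov(value ~ group,
                      data.frame(value = unlist(g),
                                 group = factor(rep(names(g), each = 3)))))
  expect_equal(at3$tukey$pAdj, unname(ref$group[, "p adj"]), tolerance = 1e-12)
  expect_error(anovaTukey(list(a = 1:3)), ">= 2 groups")
})
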