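# Independent brute-force PERMANOVA for two groups: enumerate every
# assignment of n1 labels via combn and recompute F from scratch.
bruteForcePermanovaP <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  g <- factor(groups)
  stopifnot(nlevels(g) == 2L)
  n1 <- sum(g == levels(g)[1])
  k <- 2
  fOf <- function(idx1) {
    lab <- rep(2L, n); lab[idx1] <- 1L
    sst <- sum(d^2) / (2 * n)
    ssw <- 0
    for (gg in 1:2) {
      i <- which(lab == gg)
      ssw <- ssw + sum(d[i, i]^2) / (2 * length(i))
    }
    ((sst - ssw) / (k - 1)) / (ssw / (n - k))
  }
  F0 <- fOf(which(g == levels(g)[1]))
  Fs <- combn(n, n1, fOf)
  mean(Fs >= F0 - 1e-12)
}

test_that("full-enumeration PERMANOVA equals brute force for all small two-group splits", {
  set.seed(21)
  for (n in 5:8) {
    x <- matrix(rnorm(n * 3), n, 3)
    d <- as.matrix(dist(x))
    for (n1 in 2:(n - 2)) {
      g <- rep(c("A", "B"), c(n1, n - n1))
      pv <- permanova(d, g, enumerate = TRUE)
      expect_equal(pv$p.value, bruteForcePermanovaP(d, g), tolerance = 1e-12)
    }
  }
})

test_that("the pseudo-F statistic is scale-free and matches vegan", {
  set.seed(22)
  x <- matrix(rnorm(24 * 4), 24, 4)
  d <- as.matrix(dist(x))
  g <- rep(c("A", "B", "C"), each = 8)
  pv <- permanova(d, g, permutations = 99, seed = 1)
  pv2 <- permanova(d * 7.5, g, permutations = 99, seed = 1)
  expect_equal(pv2$statistic, pv$statistic, tolerance = 1e-12)
  expect_equal(pv2$p.value, pv$p.value)

  # independent oracle: vegan::adonis2 on the same distances
  ad <- vegan::adonis2(as.dist(d) ~ g, permutations = 999)
  expect_equal(unname(pv$statistic), ad$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA type-I error is nominal under the null", {
  set.seed(23)
  rejections <- vapply(1:400, function(i) {
    x <- matrix(rnorm(20 * 3), 20, 3)
    d <- as.matrix(dist(x))
    pv <- permanova(d, sample(rep(c("A", "B"), each = 10)),
                    permutations = 199, seed = i)
    pv$p.value <= 0.05
  }, logical(1))
  rate <- mean(rejections)
  ci <- 1.96 * sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(rate - 0.05), ci + 1e-12)
})

test_that("PERMANOVA input validation", {
  d <- matrix(c(0, 1, 1, 0), 2)
  expect_error(permanova(rbind(c(0, 1), c(2, 0)), c("A", "B")), "symmetric")
  dd <- as.matrix(dist(matrix(rnorm(12), 6)))
  expect_error(permanova(dd, c("A", "A", "A", "A", "A", "B")), ">= 2 members")
})

test_that("pairwise Mann-Whitney: exact path, ties, Bonferroni", {
  res <- pairwiseMannWhitney(c(1, 2, 3, 4, 5, 6),
                             rep(c("A", "B"), each = 3))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1, tolerance = 1e-12)

  # identical groups give U = n1*n2/2 under midranks
  resT <- pairwiseMannWhitney(c(1, 2, 3, 1, 2, 3),
                              rep(c("A", "B"), each = 3))
  expect_equal(resT$U, 4.5)

  # Bonferroni: times the number of pairs, capped at 1
  v <- c(rnorm(4), rnorm(4) + 10, rnorm(4) + 10.2)
  g <- rep(c("A", "B", "C"), each = 4)
  res3 <- pairwiseMannWhitney(v, g)
  expect_equal(res3$p_adj, pmin(1, res3$p * 3))
  expect_true(all(res3$p_adj >= res3$p))

  expect_error(pairwiseMannWhitney(v, factor(g, levels = c("A", "B", "C", "D"))),
               "empty group")
})

test_that("Mann-Whitney exact path matches enumeration for all small splits", {
  # brute-force two-sided p by enumerating every group assignment
  bruteP <- function(x, y) {
    all <- c(x, y)
    n1 <- length(x)
    uOf <- function(idx) sum(rank(all)[idx]) - n1 * (n1 + 1) / 2
    U0 <- uOf(seq_len(n1))
    Us <- combn(length(all), n1, uOf)
    mu <- n1 * length(y) / 2
    mean(abs(Us - mu) >= abs(U0 - mu) - 1e-9)
  }
  set.seed(31)
  for (n in 4:8) {
    for (n1 in 2:(n - 2)) {
      v <- sample(seq_len(3 * n), n)   # distinct values, no ties
      g <- rep(c("A", "B"), c(n1, n - n1))
      res <- pairwiseMannWhitney(v, g)
      expect_equal(res$p, bruteP(v[1:n1], v[(n1 + 1):n]), tolerance = 1e-9)
    }
  }
})

test_that("log-ratio regression recovers exact lines and rejects degenerate input", {
  mk <- function(vals, ids) new("LogRatioSeries",
                                values = setNames(vals, ids),
                                numeratorIDs = "a", denominatorIDs = "b",
                                droppedSamples = character(0))
  x <- mk(c(1, 2, 3, 4), paste0("s", 1:4))
  y <- mk(2 * c(1, 2, 3, 4) + 1, paste0("s", 1:4))
  fit <- logratioRegression(x, y)
  expect_equal(fit$r, 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)

  expect_error(logratioRegression(x, mk(rep(1, 4), paste0("s", 1:4))),
               "zero variance")
  expect_error(logratioRegression(x, mk(1:4, paste0("t", 1:4))), ">= 3")

  # independent series: |r| small for most seeds
  small <- vapply(1:60, function(s) {
    set.seed(s)
    a <- mk(rnorm(200), paste0("s", 1:200))
    b <- mk(rnorm(200), paste0("s", 1:200))
    abs(logratioRegression(a, b)$r) < 0.2
  }, logical(1))
  expect_gte(mean(small), 0.95)
})

test_that("the mixed-effects age trend detects a planted interaction and flags degenerate designs", {
  mkData <- function(seed, beta) {
    set.seed(seed)
    meta <- data.frame(
      sample_id = paste0("s", 1:(12 * 6)),
      host_subject_id = rep(paste0("m", 1:12), each = 6),
      host_age = rep(seq(10, 15, by = 1), 12),
      diet = rep(c("RC", "HFHC"), each = 36),
      exposure = "Air", stringsAsFactors = FALSE)
    meta <- validateSampleMetadata(meta)
    b <- rnorm(12, sd = 0.5)[rep(1:12, each = 6)]
    y <- 0.1 * meta$host_age + beta * meta$host_age * (meta$diet == "HFHC") +
      b + rnorm(72, sd = 0.5)
    lr <- new("LogRatioSeries", values = setNames(y, meta$sample_id),
              numeratorIDs = "a", denominatorIDs = "b",
              droppedSamples = character(0))
    list(lr = lr, meta = meta)
  }
  hits <- vapply(1:20, function(s) {
    d <- mkData(s, beta = 0.3)
    fit <- lmeTrend(d$lr, d$meta)
    fit$coefficients["host_age:groupRC-Air", "p"] < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # null: the interaction p-value is roughly uniform
  ps <- vapply(1:60, function(s) {
    d <- mkData(1000 + s, beta = 0)
    lmeTrend(d$lr, d$meta)$coefficients["host_age:groupRC-Air", "p"]
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)

  # single subject fails the precondition
  one <- mkData(1, 0)
  keep <- one$meta$host_subject_id == "m1"
  lr1 <- new("LogRatioSeries",
             values = ratioValues(one$lr)[keep],
             numeratorIDs = "a", denominatorIDs = "b",
             droppedSamples = character(0))
  expect_error(lmeTrend(lr1, one$meta[keep, ]), "subjects")
})
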