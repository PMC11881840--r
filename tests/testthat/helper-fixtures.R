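# Small in-code fixtures shared across test files.

# Tiny counts table with known values.
tinyTable <- function() {
  m <- matrix(c(5, 0, 2, 7, 0, 1), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), c("f1", "f2")))
  FeatureTable(m, "counts")
}

# Random sparse counts table on a log-normal composition.
randomCounts <- function(n = 12, p = 8, seed = 1, depth = 500,
                         zeroFrac = 0.25) {
  set.seed(seed)
  eta <- matrix(rnorm(n * p), n, p)
  keep <- matrix(runif(n * p) >= zeroFrac, n, p)
  keep[cbind(seq_len(n), max.col(eta))] <- TRUE
  cnt <- t(vapply(seq_len(n), function(i) {
    pr <- exp(eta[i, ]) * keep[i, ]
    rmultinom(1, depth, pr / sum(pr))[, 1]
  }, numeric(p)))
  dimnames(cnt) <- list(paste0("s", seq_len(n)), paste0("f", seq_len(p)))
  FeatureTable(cnt, "counts")
}

# Paired tables generated from shared rank-2 sample factors, exponentiated
# to positive tables with multiplicative dropout.
sharedFactorPair <- function(n = 120, p1 = 40, p2 = 50, r = 2, seed = 1,
                             noise = 0.3, dropout = 0.3) {
  set.seed(seed)
  U <- matrix(rnorm(n * r), n, r)
  mk <- function(p, tag) {
    x <- U %*% t(matrix(rnorm(p * r), p, r)) + matrix(rnorm(n * p, sd = noise), n, p)
    x <- exp(1 + x)
    dimnames(x) <- list(paste0("s", seq_len(n)), paste0(tag, seq_len(p)))
    drop <- matrix(runif(n * p) < dropout, n, p)
    drop[cbind(seq_len(n), max.col(x))] <- FALSE
    x[drop] <- 0
    FeatureTable(x, "counts")
  }
  list(t1 = mk(p1, "a"), t2 = mk(p2, "b"), U = U)
}

# Largest principal angle (degrees) between the column spans of A and B.
maxPrincipalAngle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  sv <- svd(crossprod(qa, qb))$d
  k <- min(ncol(qa), ncol(qb))
  max(acos(pmin(pmax(sv[seq_len(k)], -1), 1))) * 180 / pi
}

# Area under the ROC curve for a two-group score separation.
aurocOf <- function(score, isPositive) {
  r <- rank(score)
  n1 <- sum(isPositive); n0 <- sum(!isPositive)
  (sum(r[isPositive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# A compact cohort design used where full scale is not needed.
smallDesign <- function(...) {
  defaults <- list(micePerGroup = 4, timepoints = seq(10, 19, by = 1.5),
                   nMicrobes = 60, nMetabolites = 80, depthMean = 3000)
  do.call(cohortDesign, utils::modifyList(defaults, list(...)))
}

# Separable two-group intensity fixture: one feature carries a large shift.
separableTable <- function(n = 20, p = 10, seed = 1, shift = 6) {
  set.seed(seed)
  x <- exp(matrix(rnorm(n * p, sd = 0.3), n, p) + 3)
  x[1:(n / 2), 1] <- x[1:(n / 2), 1] * exp(shift)
  dimnames(x) <- list(paste0("s", 1:n), paste0("f", 1:p))
  list(table = FeatureTable(x, "intensities"),
       labels = factor(rep(c("hi", "lo"), each = n / 2)))
}

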