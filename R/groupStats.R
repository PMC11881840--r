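# Within-group sum of squared distances; D2 = squared distance matrix.
.ssWithin <- function(D2, groups) {
  s <- 0
  for (g in levels(groups)) {
    i <- which(groups == g)
    s <- s + sum(D2[i, i]) / (2 * length(i))
  }
  s
}

# All distinct arrangements of a label multiset (n small); one column per
# arrangement, values are integer level codes.
.multisetPerms <- function(groups) {
  counts <- table(groups)
  k <- length(counts)
  n <- sum(counts)
  rec <- function(counts) {
    if (sum(counts) == 0L) return(matrix(integer(0), nrow = 0, ncol = 1L))
    out <- NULL
    for (g in seq_len(k)) {
      if (counts[g] == 0L) next
      c2 <- counts
      c2[g] <- c2[g] - 1L
      sub <- rec(c2)
      out <- cbind(out, rbind(rep(g, ncol(sub)), sub))
    }
    out
  }
  rec(as.integer(counts))
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: the pseudo-F statistic
#' is computed from squared distances via the partition
#' `F = (SS_between / (k-1)) / (SS_within / (n-k))`, and its significance
#' by permuting group labels: `p = (#\{F_perm >= F_obs\} + 1) / (permutations
#' + 1)`. With `enumerate = TRUE` all distinct label arrangements are
#' evaluated and the exact permutation p-value is returned (small n only).
#'
#' @param d symmetric distance matrix (or `dist`) with zero diagonal.
#' @param groups group labels; at least 2 groups with at least 2 members.
#' @param permutations number of random permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param enumerate evaluate every distinct arrangement instead of random
#'   permutations.
#' @return an object of class `c("permanova", "htest")` with `statistic`
#'   (pseudo-F), `p.value`, `permutations` and `groupSizes`.
#' @export
permanova <- function(d, groups, permutations = 999, seed = NULL,
                      enumerate = FALSE) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  groups <- factor(groups)
  groups <- droplevels(groups)
  n <- nrow(d)
  if (length(groups) != n) stop("groups length must match distance matrix")
  k <- nlevels(groups)
  if (k < 2L || any(table(groups) < 2L))
    stop("need >= 2 groups with >= 2 members each")
  D2 <- d^2
  sst <- sum(D2) / (2 * n)
  fstat <- function(g) {
    ssw <- .ssWithin(D2, g)
    ((sst - ssw) / (k - 1)) / (ssw / (n - k))
  }
  F0 <- fstat(groups)
  if (enumerate) {
    perms <- .multisetPerms(groups)
    Fs <- apply(perms, 2, function(code)
      fstat(factor(levels(groups)[code], levels = levels(groups))))
    p <- mean(Fs >= F0 - 1e-12)
    nperm <- ncol(perms)
  } else {
    permutations <- .assertScalarCount(permutations, "permutations")
    Fs <- .withSeed(seed, function()
      vapply(seq_len(permutations), function(i)
        fstat(sample(groups)), numeric(1)))
    p <- (sum(Fs >= F0 - 1e-12) + 1) / (permutations + 1)
    nperm <- permutations
  }
  structure(list(statistic = c(`pseudo-F` = F0), p.value = p,
                 permutations = nperm, groupSizes = table(groups),
                 method = if (enumerate) "PERMANOVA (complete enumeration)"
                          else "PERMANOVA",
                 data.name = paste(n, "samples,", k, "groups")),
            class = c("permanova", "htest"))
}

#' Pairwise Mann-Whitney tests with Bonferroni correction
#'
#' Two-sided Mann-Whitney-Wilcoxon tests for every pair of groups. The
#' exact null distribution is used when both group sizes are at most 8 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction is used. Raw p-values are Bonferroni-adjusted
#' across all pairs (`p_adj = min(1, p * n_pairs)`).
#'
#' @param values numeric vector of per-sample values.
#' @param groups group labels, same length; every group must be non-empty.
#' @return data.frame with one row per pair: `group1`, `group2`, `n1`,
#'   `n2`, `U`, `p`, `p_adj`.
#' @export
pairwiseMannWhitney <- function(values, groups) {
  if (!is.factor(groups)) groups <- factor(groups)
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  if (any(table(groups) == 0L))
    stop("empty group: ", paste(levels(groups)[table(groups) == 0L],
                                collapse = ", "))
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  prs <- utils::combn(levels(groups), 2)
  res <- apply(prs, 2, function(pr) {
    x <- values[groups == pr[1]]
    y <- values[groups == pr[2]]
    exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = !exact,
                         alternative = "two.sided"))
    c(n1 = length(x), n2 = length(y), U = unname(wt$statistic),
      p = wt$p.value)
  })
  out <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                    t(res), stringsAsFactors = FALSE)
  out$p_adj <- stats::p.adjust(out$p, method = "bonferroni")
  out
}

#' Regression between two log-ratio series
#'
#' Pearson correlation and least-squares line between paired per-sample log
#' ratios (e.g. a microbial family ratio against a metabolite-set ratio),
#' on the samples retained in both series.
#'
#' @param x,y [LogRatioSeries-class] objects sharing at least 3 samples.
#' @return list with `r`, `p`, `slope`, `intercept`, `n`.
#' @export
logratioRegression <- function(x, y) {
  stopifnot(is(x, "LogRatioSeries"), is(y, "LogRatioSeries"))
  shared <- intersect(names(ratioValues(x)), names(ratioValues(y)))
  if (length(shared) < 3L)
    stop("need >= 3 samples present in both series, got ", length(shared))
  xv <- ratioValues(x)[shared]
  yv <- ratioValues(y)[shared]
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop("zero variance in log-ratio values")
  ct <- stats::cor.test(xv, yv)
  fit <- stats::lm(yv ~ xv)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(shared))
}

#' Linear mixed-effects trend of a log ratio over host age
#'
#' Fits `log_ratio ~ host_age * group + (1 | host_subject_id)` — the
#' repeated-measures trend model for longitudinal log-ratio trajectories —
#' delegating estimation to [lmerTest::lmer()]. A singular fit is reported
#' as a flag, not an error.
#'
#' @param x a [LogRatioSeries-class].
#' @param meta sample metadata (see [validateSampleMetadata()]).
#' @return list with `coefficients` (estimate, std error, df, t, p per
#'   term), `singular`, and the fitted model in `model`.
#' @export
lmeTrend <- function(x, meta) {
  stopifnot(is(x, "LogRatioSeries"))
  meta <- validateSampleMetadata(meta)
  df <- as.data.frame(x)
  i <- match(df$sample_id, meta$sample_id)
  if (anyNA(i)) stop("metadata missing for some samples")
  df$host_age <- meta$host_age[i]
  df$group <- factor(meta$group[i])
  df$host_subject_id <- meta$host_subject_id[i]
  tpPerSubject <- tapply(df$host_age, df$host_subject_id,
                         function(a) length(unique(a)))
  if (length(tpPerSubject) < 2L || mean(tpPerSubject >= 2) < 0.5)
    stop("need >= 2 timepoints per subject for at least half the subjects")
  fit <- suppressMessages(
    lmerTest::lmer(log_ratio ~ host_age * group + (1 | host_subject_id),
                   data = df))
  co <- as.data.frame(summary(fit)$coefficients)
  names(co) <- c("estimate", "std_error", "df", "t", "p")
  list(coefficients = co, singular = lme4::isSingular(fit), model = fit)
}
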