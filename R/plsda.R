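# NIPALS PLS1 on centered/scaled X against a centered two-class y.
.nipals <- function(Xc, yc, A) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  cvec <- numeric(A)
  ssy <- numeric(A)
  for (a in seq_len(A)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) { A <- a - 1L; break }
    w <- w / nw
    t_a <- Xc %*% w
    tt <- sum(t_a^2)
    if (tt < 1e-14) { A <- a - 1L; break }
    p_a <- crossprod(Xc, t_a) / tt
    c_a <- sum(yc * t_a) / tt
    Xc <- Xc - tcrossprod(t_a, p_a)
    yc <- yc - c_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a
    cvec[a] <- c_a
    ssy[a] <- c_a^2 * tt
  }
  if (A < 1L) stop("no usable PLS component (X carries no class signal)")
  idx <- seq_len(A)
  list(W = W[, idx, drop = FALSE], P = P[, idx, drop = FALSE],
       Tm = Tm[, idx, drop = FALSE], c = cvec[idx], ssy = ssy[idx], A = A)
}

.vipScores <- function(np, p) {
  # VIP_j = sqrt( p * sum_a SSY_a w_aj^2 / sum_a SSY_a ); ||w_a|| = 1.
  num <- (np$W^2) %*% np$ssy
  sqrt(p * num / sum(np$ssy))[, 1]
}

.centerScale <- function(X, scale) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  scl <- rep(1, ncol(X))
  if (scale) {
    scl <- apply(Xc, 2, stats::sd)
    scl[scl < 1e-12] <- 1
    Xc <- sweep(Xc, 2, scl, `/`)
  }
  list(X = Xc, center = ctr, scale = scl)
}

# Stratified fold assignment: shuffle within class, deal round-robin.
.stratifiedFolds <- function(labels, folds, seed) {
  fold <- integer(length(labels))
  .withSeed(seed, function() {
    for (cl in levels(labels)) {
      i <- sample(which(labels == cl))
      fold[i] <<- rep_len(seq_len(folds), length(i))
    }
  })
  fold
}

.plsdaCV <- function(X, labels, A, folds, seed, scale) {
  fold <- .stratifiedFolds(labels, folds, seed)
  wrong <- 0L
  for (f in seq_len(folds)) {
    tr <- fold != f
    cs <- .centerScale(X[tr, , drop = FALSE], scale)
    ytr <- ifelse(labels[tr] == levels(labels)[2], 1, -1)
    np <- .nipals(cs$X, ytr - mean(ytr), A)
    Wstar <- np$W %*% solve(crossprod(np$P, np$W))
    Ttr <- cs$X %*% Wstar
    cent <- rbind(colMeans(Ttr[labels[tr] == levels(labels)[1], , drop = FALSE]),
                  colMeans(Ttr[labels[tr] == levels(labels)[2], , drop = FALSE]))
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, cs$center), 2, cs$scale, `/`)
    Tte <- Xte %*% Wstar
    d1 <- rowSums(sweep(Tte, 2, cent[1, ])^2)
    d2 <- rowSums(sweep(Tte, 2, cent[2, ])^2)
    pred <- levels(labels)[ifelse(d2 < d1, 2L, 1L)]
    wrong <- wrong + sum(pred != as.character(labels[!tr]))
  }
  wrong / length(labels)
}

#' Two-group PLS-DA with VIP feature selection
#'
#' NIPALS partial least squares discriminant analysis on an
#' rclr-transformed table (unobserved entries are treated as 0, the
#' row-centered neutral value, for this supervised step). Per-feature VIP
#' scores satisfy `mean(VIP^2) = 1`; features with VIP above the threshold
#' (default 1) are selected. Model performance is summarized by the
#' classification error rate (CER) of held-out predictions pooled over a
#' stratified k-fold cross-validation, with class assignment by nearest
#' class centroid in score space.
#'
#' @param object an [RclrMatrix-class] (or plain numeric matrix, samples in
#'   rows).
#' @param labels two-class labels, one per sample; each class needs at
#'   least `folds` members.
#' @param nComponents number of latent components (default 2).
#' @param folds CV folds (default 5).
#' @param seed seed for the fold assignment (the fit itself is
#'   deterministic given the data).
#' @param scale unit-variance scale features before fitting (default TRUE).
#' @param vipThreshold VIP selection cutoff (default 1).
#' @param autoNcomp choose `nComponents` from 1..3 by smallest CV CER.
#' @return a [PlsdaModel-class].
#' @export
fitPlsda <- function(object, labels, nComponents = 2, folds = 5, seed = 1,
                     scale = TRUE, vipThreshold = 1, autoNcomp = FALSE) {
  X <- if (is(object, "RclrMatrix")) {
    v <- rclrValues(object); v[!observedMask(object)] <- 0; v
  } else as.matrix(object)
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2L)
    stop("PLS-DA comparisons are pairwise: exactly 2 classes required, got ",
         nlevels(labels))
  if (length(labels) != nrow(X)) stop("labels length must match samples")
  folds <- .assertScalarCount(folds, "folds")
  if (any(table(labels) < folds))
    stop("each class needs at least `folds` members")
  if (autoNcomp) {
    cers <- vapply(1:3, function(a)
      .plsdaCV(X, labels, a, folds, seed, scale), numeric(1))
    nComponents <- which.min(cers)
  }
  A <- .assertScalarCount(nComponents, "nComponents")
  A <- min(A, nrow(X) - 1L, ncol(X))
  cs <- .centerScale(X, scale)
  y <- ifelse(labels == levels(labels)[2], 1, -1)
  np <- .nipals(cs$X, y - mean(y), A)
  vip <- .vipScores(np, ncol(X))
  names(vip) <- colnames(X)
  Wstar <- np$W %*% solve(crossprod(np$P, np$W))
  cer <- .plsdaCV(X, labels, np$A, folds, seed, scale)
  rownames(np$W) <- rownames(np$P) <- colnames(X)
  scores <- np$Tm
  rownames(scores) <- rownames(X)
  new("PlsdaModel", nComponents = np$A, weights = np$W, loadings = np$P,
      scores = scores, yLoadings = np$c, rotation = Wstar, vip = vip,
      cvCER = cer,
      selectedFeatures = names(vip)[vip > vipThreshold],
      vipThreshold = vipThreshold, classes = levels(labels),
      center = cs$center, scaleFactors = cs$scale)
}

#' Log ratio of PLS-DA-significant features by class association
#'
#' Splits the model's VIP-selected features by the class they are
#' associated with — the class whose mean rclr value for the feature is
#' higher — and computes the per-sample natural log ratio of
#' first-class-associated over second-class-associated features.
#'
#' @param model a fitted [PlsdaModel-class] with selected features.
#' @param object the [FeatureTable-class] the ratio is evaluated on.
#' @param labels the class labels used for the fit (defines association
#'   direction; the first factor level forms the numerator).
#' @return a [LogRatioSeries-class].
#' @export
significantFeatureLogRatio <- function(model, object, labels) {
  stopifnot(is(model, "PlsdaModel"), is(object, "FeatureTable"))
  sel <- selectedFeatures(model)
  if (!length(sel)) stop("model has no features above the VIP threshold")
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2L) stop("exactly 2 classes required")
  rm <- rclr(object)
  v <- rclrValues(rm)[, sel, drop = FALSE]
  m1 <- colMeans(v[labels == levels(labels)[1], , drop = FALSE], na.rm = TRUE)
  m2 <- colMeans(v[labels == levels(labels)[2], , drop = FALSE], na.rm = TRUE)
  m1[is.nan(m1)] <- -Inf
  m2[is.nan(m2)] <- -Inf
  num <- sel[m1 >= m2]
  den <- sel[m1 < m2]
  if (!length(num) || !length(den))
    stop("all selected features associate with one class; no ratio defined")
  featureSetLogRatio(object, numerator = num, denominator = den)
}
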