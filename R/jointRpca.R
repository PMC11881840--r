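#' Robust Aitchison PCA (RPCA) of a single feature table
#'
#' Ordination of a sparse compositional table: rclr transformation followed
#' by low-rank completion of the observed entries. Sample distances are
#' Euclidean distances between sample score rows (an Aitchison-type
#' distance, inherited from the clr geometry), and feature loadings serve
#' as differential ranks for [loadingRankLogRatio()].
#'
#' @param object a [FeatureTable-class].
#' @param rank,maxIter,tol,seed passed to [optspaceComplete()].
#' @return list with `scores` (n x r, U scaled by singular values),
#'   `loadings` (p x r feature factors), `eigenvalues`,
#'   `proportionExplained`, `distances` (n x n matrix) and `completion`
#'   (the [CompletionResult-class]).
#' @export
rpca <- function(object, rank = 3, maxIter = 200, tol = 1e-6, seed = NULL) {
  stopifnot(is(object, "FeatureTable"))
  cr <- optspaceComplete(rclr(object), rank = rank, maxIter = maxIter,
                         tol = tol, seed = seed)
  scores <- sampleFactors(cr) %*% cr@S
  rownames(scores) <- sampleIDs(object)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  loadings <- featureFactors(cr)
  colnames(loadings) <- colnames(scores)
  ev <- singularValues(cr)
  list(scores = scores,
       loadings = loadings,
       eigenvalues = ev,
       proportionExplained = if (sum(ev^2) > 0) ev^2 / sum(ev^2) else ev * 0,
       distances = as.matrix(stats::dist(scores)),
       completion = cr)
}

#' Joint factorization of several omics tables with shared sample scores
#'
#' Multi-table extension of RPCA: each table is rclr-transformed and the
#' tables are factorized as `X_m ~ U S_m V_m'` with one shared sample basis
#' `U`, minimizing the average of per-table mean squared errors over
#' observed (non-zero) entries. The shared basis and the shared singular
#' values are recomputed at every iteration from the concatenated cores so
#' that the rotation stays consistent across tables.
#'
#' Cross-validation: samples are randomly assigned to training
#' (`trainFraction`, default 80%) and test sets; minimization uses only the
#' training samples, test samples are projected into the trained space by
#' least-squares regression of their observed rclr entries onto
#' `V_m S_m'`, and the observed-entry reconstruction RMSE is reported per
#' split. The returned factorization itself is fit on all samples.
#'
#' @param tables list of [FeatureTable-class] objects over identical
#'   samples in identical order (see [alignTables()]).
#' @param rank shared rank (default 3).
#' @param maxIter,tol optimizer controls.
#' @param seed seed for the CV splits (the fit is deterministic).
#' @param trainFraction training fraction per split, in (0.5, 0.95).
#' @param nSplits number of random train/test splits (default 5; 0 skips
#'   cross-validation).
#' @param weights optional positive per-table weights for the joint
#'   objective; default equal.
#' @return a [JointFactorization-class].
#' @export
jointFactorize <- function(tables, rank = 3, maxIter = 200, tol = 1e-6,
                           seed = 1, trainFraction = 0.8, nSplits = 5,
                           weights = NULL) {
  if (is(tables, "FeatureTable")) tables <- list(tables)
  stopifnot(length(tables) >= 1L, all(vapply(tables, is, TRUE, "FeatureTable")))
  ids <- sampleIDs(tables[[1L]])
  for (tb in tables[-1L])
    if (!identical(sampleIDs(tb), ids))
      stop("sample mismatch between tables; align with alignTables() first")
  if (trainFraction <= 0.5 || trainFraction >= 0.95)
    stop("trainFraction must be in (0.5, 0.95)")
  rank <- .assertScalarCount(rank, "rank")
  n <- length(ids)
  rms <- lapply(tables, rclr)
  xs <- lapply(rms, function(r) {
    v <- rclrValues(r); v[!observedMask(r)] <- 0; v
  })
  masks <- lapply(rms, observedMask)

  cvTrain <- cvTest <- numeric(0)
  if (nSplits > 0) {
    nTrain <- round(trainFraction * n)
    for (s in seq_len(nSplits)) {
      train <- .withSeed(.streamSeed(seed, paste0("split", s)),
                         function() sort(sample.int(n, nTrain)))
      test <- setdiff(seq_len(n), train)
      keepF <- lapply(masks, function(m) which(colSums(m[train, , drop = FALSE]) > 0))
      xsT <- mapply(function(x, k) x[train, k, drop = FALSE], xs, keepF,
                    SIMPLIFY = FALSE)
      msT <- mapply(function(m, k) m[train, k, drop = FALSE], masks, keepF,
                    SIMPLIFY = FALSE)
      fit <- .jointCore(xsT, msT, rank, maxIter = as.integer(maxIter),
                        tol = tol, weights = weights)
      sse <- 0; nob <- 0
      for (m in seq_along(xsT)) {
        R <- xsT[[m]] - fit$U %*% fit$Ss[[m]] %*% t(fit$Vs[[m]])
        sse <- sse + sum(R[msT[[m]]]^2)
        nob <- nob + sum(msT[[m]])
      }
      cvTrain <- c(cvTrain, sqrt(sse / nob))
      Ds <- lapply(seq_along(xsT), function(m) fit$Vs[[m]] %*% t(fit$Ss[[m]]))
      # Entry-level holdout within each test sample: the projection is fit
      # on half of the sample's observed entries and scored on the other
      # half, so the reported test error is genuinely out of sample.
      sseT <- 0; nobT <- 0
      evalSplit <- .withSeed(.streamSeed(seed, paste0("eval", s)),
                             function() stats::runif(sum(vapply(masks, length, 1L))))
      off <- 0L
      entrySel <- lapply(masks, function(m) {
        u <- evalSplit[off + seq_len(length(m))]
        off <<- off + length(m)
        matrix(u < 0.5, nrow(m), ncol(m))
      })
      for (i in test) {
        D <- NULL; y <- NULL; De <- NULL; ye <- NULL
        for (m in seq_along(xsT)) {
          obs <- masks[[m]][i, keepF[[m]]]
          fitHalf <- obs & entrySel[[m]][i, keepF[[m]]]
          evalHalf <- obs & !fitHalf
          if (any(fitHalf)) {
            D <- rbind(D, Ds[[m]][fitHalf, , drop = FALSE])
            y <- c(y, xs[[m]][i, keepF[[m]]][fitHalf])
          }
          if (any(evalHalf)) {
            De <- rbind(De, Ds[[m]][evalHalf, , drop = FALSE])
            ye <- c(ye, xs[[m]][i, keepF[[m]]][evalHalf])
          }
        }
        if (is.null(D) || nrow(D) < rank || is.null(De)) next
        u <- qr.coef(qr(D), y)
        u[is.na(u)] <- 0
        r2 <- ye - De %*% u
        sseT <- sseT + sum(r2^2)
        nobT <- nobT + length(ye)
      }
      cvTest <- c(cvTest, sqrt(sseT / max(nobT, 1L)))
    }
  }

  fit <- .jointCore(xs, masks, rank, maxIter = as.integer(maxIter),
                    tol = tol, weights = weights)
  U <- .fixSigns(fit$U)
  flip <- diag(crossprod(U, fit$U))           # +-1 per column
  Ss <- lapply(fit$Ss, function(S) diag(flip, rank) %*% S)
  Vs <- fit$Vs
  for (m in seq_along(Vs)) {
    rownames(Vs[[m]]) <- featureIDs(tables[[m]])
    colnames(Vs[[m]]) <- paste0("PC", seq_len(rank))
  }
  scores <- U %*% diag(fit$sharedEigs, rank)
  dimnames(scores) <- list(ids, paste0("PC", seq_len(rank)))
  rownames(U) <- ids
  pe <- if (sum(fit$sharedEigs^2) > 0)
    fit$sharedEigs^2 / sum(fit$sharedEigs^2) else fit$sharedEigs * 0
  new("JointFactorization",
      sampleScores = scores, sampleFactors = U,
      tableCores = Ss, tableLoadings = Vs,
      sharedEigenvalues = fit$sharedEigs,
      proportionExplained = pe,
      cvTrainError = cvTrain, cvTestError = cvTest,
      lossTrace = fit$lossTrace)
}

#' Cross-omic feature correlations from a joint factorization
#'
#' Correlates the reconstructed feature profiles (`U S_m V_m'` columns) of
#' two tables of a joint factorization. Features with zero loading on all
#' axes have constant reconstructions and are assigned correlation 0.
#'
#' @param jf a [JointFactorization-class] with at least two tables.
#' @param tablePair indices of the two tables to correlate (default 1, 2).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return a [CrossOmicCorrelations-class].
#' @export
crossCorrelations <- function(jf, tablePair = c(1L, 2L),
                              method = c("pearson", "spearman")) {
  stopifnot(is(jf, "JointFactorization"))
  method <- match.arg(method)
  if (length(tableCores(jf)) < 2L)
    stop("cross-omic correlations need >= 2 tables")
  recon <- function(m)
    sampleFactors(jf) %*% tableCores(jf)[[m]] %*% t(tableLoadings(jf)[[m]])
  X1 <- recon(tablePair[1L])
  X2 <- recon(tablePair[2L])
  sd1 <- apply(X1, 2, stats::sd)
  sd2 <- apply(X2, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(X1, X2, method = method))
  cc[sd1 == 0, ] <- 0
  cc[, sd2 == 0] <- 0
  cc[is.na(cc)] <- 0
  over <- abs(cc) > 1
  if (any(abs(cc[over]) > 1 + 1e-12))
    stop("correlation exceeds 1 beyond numerical dust")
  cc[over] <- sign(cc[over])
  dimnames(cc) <- list(rownames(tableLoadings(jf)[[tablePair[1L]]]),
                       rownames(tableLoadings(jf)[[tablePair[2L]]]))
  new("CrossOmicCorrelations", matrix = cc, method = method)
}

#' Select the most differential features by ordination loading
#'
#' Takes the top and bottom fraction `q` of features ranked by a loading
#' vector (e.g. axis-1 RPCA loadings), mirroring loading-rank-based feature
#' filtering before multi-omics integration.
#'
#' @param loadings named numeric per-feature loadings.
#' @param q fraction per tail, in (0, 0.5].
#' @return list with `top`, `bottom` and their union `selected`.
#' @export
selectFeaturesByLoading <- function(loadings, q = 0.1) {
  if (is.null(names(loadings))) stop("loadings must be named")
  if (q <= 0 || q > 0.5) stop("q must be in (0, 0.5]")
  k <- max(1L, ceiling(q * length(loadings)))
  ord <- order(-loadings, names(loadings))
  top <- names(loadings)[ord[seq_len(k)]]
  bottom <- names(loadings)[rev(ord)[seq_len(k)]]
  list(top = top, bottom = setdiff(bottom, top),
       selected = union(top, bottom))
}

#' Write an ordination in QIIME2/scikit-bio text format
#'
#' @param scores sample scores (n x r), row names = sample ids.
#' @param loadings feature loadings (p x r), row names = feature ids.
#' @param eigenvalues per-axis eigenvalues.
#' @param proportionExplained per-axis proportion explained.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeOrdination <- function(scores, loadings, eigenvalues,
                            proportionExplained, path) {
  r <- ncol(scores)
  fmt <- function(x) paste(formatC(x, digits = 10, format = "g"),
                           collapse = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("Eigvals\t", r), fmt(eigenvalues), "",
               paste0("Proportion explained\t", r), fmt(proportionExplained),
               ""), con)
  writeLines(paste0("Species\t", nrow(loadings), "\t", r), con)
  writeLines(paste(rownames(loadings),
                   apply(loadings, 1, fmt), sep = "\t"), con)
  writeLines("", con)
  writeLines(paste0("Site\t", nrow(scores), "\t", r), con)
  writeLines(paste(rownames(scores), apply(scores, 1, fmt), sep = "\t"), con)
  writeLines(c("", "Biplot\t0\t0", "", "Site constraints\t0\t0"), con)
  invisible(path)
}
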