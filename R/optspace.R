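#' Low-rank completion of a partially observed matrix
#'
#' OptSpace-style matrix completion: spectral initialization on the
#' rescaled zero-filled matrix, then gradient descent on orthonormal factor
#' pairs minimizing squared error over the observed entries only, with a
#' backtracking line search that guarantees a monotone objective. The core
#' is re-solved by least squares at every evaluation, so a fully observed
#' input reproduces the rank-r truncated SVD.
#'
#' @param object an [RclrMatrix-class], or a numeric matrix (then `mask`
#'   must be given, or non-`NA` entries are taken as observed).
#' @param rank target rank r; must satisfy `rank <= min(n, p)`. Default 3.
#' @param maxIter maximum gradient iterations (default 200).
#' @param tol relative loss-change convergence tolerance (default 1e-6).
#' @param seed reserved for stochastic variants; the fit itself is
#'   deterministic. Recorded for provenance.
#' @param mask optional logical matrix of observed entries.
#' @param trim enable OptSpace degree trimming of over-dense rows/columns
#'   at initialization (default off at this scale).
#' @return a [CompletionResult-class] with orthonormal `U`, `V`, diagonal
#'   nonincreasing `S`, and the observed-entry RMSE.
#' @examples
#' x <- outer(1:6, 1:4) / 4
#' res <- optspaceComplete(x, rank = 1)
#' observedRMSE(res) < 1e-8
#' @export
optspaceComplete <- function(object, rank = 3, maxIter = 200, tol = 1e-6,
                             seed = NULL, mask = NULL, trim = FALSE) {
  if (is(object, "RclrMatrix")) {
    x <- rclrValues(object)
    mask <- observedMask(object)
  } else {
    x <- as.matrix(object)
    if (is.null(mask)) mask <- !is.na(x)
  }
  rank <- .assertScalarCount(rank, "rank")
  if (rank > min(dim(x)))
    stop("rank must be <= min(n, p) = ", min(dim(x)))
  x[!mask] <- 0
  fit <- .jointCore(list(x), list(mask), rank, maxIter = as.integer(maxIter),
                    tol = tol, trim = trim)
  # Diagonalize the core so S carries nonincreasing singular values.
  svS <- svd(fit$Ss[[1L]])
  U <- fit$U %*% svS$u
  V <- fit$Vs[[1L]] %*% svS$v
  sg <- .fixSigns(U, V)
  U <- sg$U; V <- sg$V
  rownames(U) <- rownames(x)
  rownames(V) <- colnames(x)
  rmse <- sqrt(fit$loss)
  new("CompletionResult", U = U, S = diag(svS$d, rank), V = V,
      iterations = fit$iterations, observedRMSE = rmse,
      converged = fit$converged, lossTrace = fit$lossTrace)
}
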