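# Shared low-rank factorization engine.
#
# Fits X_m ~ U S_m V_m' over M tables sharing the sample basis U, by
# minimizing the weighted mean squared error over *observed* entries only:
#   L(U, {V_m}) = sum_m w_m * mean_{(i,j) in Omega_m} (X_m - U S_m V_m')_ij^2
# with S_m solved exactly by least squares at each evaluation. Steps:
#   1. spectral initialization: truncated SVD of the zero-filled matrices
#      rescaled by the inverse observed fraction (the OptSpace recipe);
#   2. gradient descent on (U, {V_m}) with QR retraction to orthonormal
#      columns and backtracking line search (step halved until the loss
#      decreases, max 20 halvings) -- the objective is monotone by
#      construction;
#   3. after each accepted step, rotation consistency: the SVD of the
#      concatenated core [S_1 V_1' | ... | S_M V_M'] re-expresses U and the
#      shared singular values without changing the fit.

# Exact least-squares solve for the r x r core given orthonormal U, V.
# The normal equations are assembled without materializing the |Omega| x
# r^2 design: A[(a,b),(c,e)] = sum_k Zi[k,a] Zi[k,c] Zj[k,b] Zj[k,e] is
# filled blockwise over (b,e) pairs.
.solveCore <- function(x, mask, idx, U, V) {
  r <- ncol(U)
  if (nrow(idx) == length(mask))        # fully observed: closed form
    return(crossprod(U, x) %*% V)
  Zi <- U[idx[, 1L], , drop = FALSE]
  Zj <- V[idx[, 2L], , drop = FALSE]
  y <- x[mask]
  A <- matrix(0, r * r, r * r)
  for (b in seq_len(r)) for (e in b:r) {
    Mbe <- crossprod(Zi, Zi * (Zj[, b] * Zj[, e]))
    rows <- (b - 1L) * r + seq_len(r)
    cols <- (e - 1L) * r + seq_len(r)
    A[rows, cols] <- Mbe
    if (e != b) A[cols, rows] <- t(Mbe)
  }
  bvec <- as.vector(crossprod(Zi, Zj * y))
  co <- tryCatch(solve(A, bvec), error = function(e) {
    co <- qr.coef(qr(A, LAPACK = TRUE), bvec)
    co[is.na(co)] <- 0
    co
  })
  matrix(co, r, r)
}

# Loss (weighted mean observed squared error) with the given fixed cores.
.coreLoss <- function(xs, masks, U, Vs, Ss, ws) {
  M <- length(xs)
  resid <- vector("list", M)
  loss <- 0
  for (m in seq_len(M)) {
    fit <- U %*% Ss[[m]] %*% t(Vs[[m]])
    rs <- xs[[m]][masks[[m]]] - fit[masks[[m]]]
    loss <- loss + ws[m] * mean(rs * rs)
    resid[[m]] <- rs
  }
  list(loss = loss, resid = resid)
}

# Loss with cores re-solved by least squares (once per accepted step).
.jointEval <- function(xs, masks, idxs, U, Vs, ws) {
  Ss <- lapply(seq_along(xs), function(m)
    .solveCore(xs[[m]], masks[[m]], idxs[[m]], U, Vs[[m]]))
  ev <- .coreLoss(xs, masks, U, Vs, Ss, ws)
  list(loss = ev$loss, Ss = Ss, resid = ev$resid)
}

.orth <- function(A) {
  q <- qr.Q(qr(A))
  q[, seq_len(ncol(A)), drop = FALSE]
}

# Core fitting routine. xs: list of numeric matrices (NA-free; unobserved
# entries may hold anything), masks: logical matrices, same dims.
.jointCore <- function(xs, masks, rank, maxIter = 200L, tol = 1e-6,
                       weights = NULL, trim = FALSE) {
  M <- length(xs)
  n <- nrow(xs[[1L]])
  if (is.null(weights)) weights <- rep(1, M)
  if (length(weights) != M || any(weights <= 0))
    stop("weights must be positive, one per table")
  ws <- weights / sum(weights)
  for (m in seq_len(M)) {
    x <- xs[[m]]
    x[!masks[[m]]] <- 0
    xs[[m]] <- x
    er <- rowSums(masks[[m]]) == 0L
    ec <- colSums(masks[[m]]) == 0L
    if (any(er))
      stop("rows with no observed entries: ",
           paste(utils::head(rownames(x)[er], 5), collapse = ", "))
    if (any(ec))
      stop("columns with no observed entries: ",
           paste(utils::head(colnames(x)[ec], 5), collapse = ", "))
  }
  idxs <- lapply(masks, function(m) which(m, arr.ind = TRUE))

  # Spectral initialization on rescaled zero-filled matrices.
  z <- vector("list", M)
  for (m in seq_len(M)) {
    x0 <- xs[[m]]
    mk <- masks[[m]]
    if (trim) {
      # OptSpace degree trimming: blank rows/columns whose observation
      # count exceeds twice the mean degree (initialization only).
      rd <- rowSums(mk); cd <- colSums(mk)
      x0[rd > 2 * mean(rd), ] <- 0
      x0[, cd > 2 * mean(cd)] <- 0
    }
    z[[m]] <- x0 * (length(mk) / max(sum(mk), 1L))
  }
  zc <- do.call(cbind, z)
  if (max(abs(zc)) < 1e-300) {
    # All observed entries zero: the zero factorization is exact.
    U <- diag(1, n)[, seq_len(rank), drop = FALSE]
    Vs <- lapply(xs, function(x) diag(1, ncol(x))[, seq_len(rank), drop = FALSE])
    Ss <- replicate(M, matrix(0, rank, rank), simplify = FALSE)
    return(list(U = U, Vs = Vs, Ss = Ss, sharedEigs = rep(0, rank),
                lossTrace = 0, iterations = 0L, converged = TRUE, loss = 0))
  }
  sv <- svd(zc, nu = rank, nv = 0L)
  U <- .fixSigns(sv$u[, seq_len(rank), drop = FALSE])
  Vs <- lapply(z, function(x0) {
    B <- crossprod(x0, U)                       # p x r
    B[!is.finite(B)] <- 0
    Q <- .orth(B)
    if (any(!is.finite(Q)) || ncol(Q) < rank)
      Q <- diag(1, nrow(B))[, seq_len(rank), drop = FALSE]
    Q
  })

  ev <- .jointEval(xs, masks, idxs, U, Vs, ws)
  lossTrace <- ev$loss
  step <- 1
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    # Gradients of the weighted mean observed squared error.
    GU <- matrix(0, n, rank)
    GVs <- vector("list", M)
    for (m in seq_len(M)) {
      Rm <- matrix(0, n, ncol(xs[[m]]))
      Rm[masks[[m]]] <- ev$resid[[m]]
      nob <- nrow(idxs[[m]])
      GU <- GU - (2 * ws[m] / nob) * Rm %*% Vs[[m]] %*% t(ev$Ss[[m]])
      GVs[[m]] <- -(2 * ws[m] / nob) * crossprod(Rm, U %*% ev$Ss[[m]])
    }
    gnorm <- sqrt(sum(GU^2) + sum(vapply(GVs, function(g) sum(g^2), 0)))
    if (gnorm < 1e-14) { converged <- TRUE; break }
    step <- min(step * 2, 1e6)
    accepted <- FALSE
    for (h in 0:20) {
      Ut <- .orth(U - step * GU)
      Vt <- lapply(seq_len(M), function(m) .orth(Vs[[m]] - step * GVs[[m]]))
      evt <- .jointEval(xs, masks, idxs, Ut, Vt, ws)
      if (evt$loss < ev$loss) {
        U <- Ut; Vs <- Vt; ev <- evt
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }
    # Rotation consistency: recompute the shared basis and shared
    # eigenvalues from the concatenated cores; the fit is unchanged.
    Mcat <- do.call(cbind, lapply(seq_len(M), function(m)
      ev$Ss[[m]] %*% t(Vs[[m]])))
    sv2 <- svd(Mcat, nu = rank, nv = 0L)
    U <- U %*% sv2$u
    ev$Ss <- lapply(ev$Ss, function(S) crossprod(sv2$u, S))
    prev <- lossTrace[length(lossTrace)]
    lossTrace <- c(lossTrace, ev$loss)
    if (prev - ev$loss < tol * max(prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  Mcat <- do.call(cbind, lapply(seq_len(M), function(m)
    ev$Ss[[m]] %*% t(Vs[[m]])))
  sharedEigs <- svd(Mcat, nu = 0L, nv = 0L)$d[seq_len(rank)]
  list(U = U, Vs = Vs, Ss = ev$Ss, sharedEigs = sharedEigs,
       lossTrace = lossTrace, iterations = iter, converged = converged,
       loss = ev$loss)
}
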