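# Lawson-Hanson active-set non-negative least squares:
# min ||A x - b||_2 s.t. x >= 0. Dictionaries here are small (tens of
# atoms) but severely ill-conditioned (near-collinear exponential decays),
# so the inner loop guards against degenerate candidates: a variable whose
# trial coefficient is non-positive is excluded for the current pass
# instead of terminating, which matters for exact-data recovery.
nnls_solve <- function(A, b, max_outer = NULL) {
  m <- nrow(A); n <- ncol(A)
  if (is.null(max_outer)) max_outer <- 10L * n
  b <- as.numeric(b)
  x <- numeric(n)
  P <- logical(n)

  ls_sub <- function(Pset) {
    z <- numeric(n)
    cf <- qr.coef(qr(A[, Pset, drop = FALSE], tol = 1e-12), b)
    cf[is.na(cf)] <- 0
    z[Pset] <- cf
    z
  }

  outer <- 0L
  repeat {
    outer <- outer + 1L
    if (outer > max_outer) break
    r <- b - drop(A %*% x)
    w <- drop(crossprod(A, r))
    tol <- 10 * .Machine$double.eps * m * max(abs(w), 1e-300)
    free <- !P & w > tol
    if (!any(free)) break

    excluded <- logical(n)
    added <- FALSE
    while (any(free & !excluded)) {
      cand <- which(free & !excluded)
      j <- cand[which.max(w[cand])]
      Ptry <- P; Ptry[j] <- TRUE
      z <- ls_sub(Ptry)
      if (z[j] > 0) {
        P <- Ptry
        added <- TRUE
        # inner loop: pull x toward z, dropping variables that hit zero
        while (any(z[P] <= 0)) {
          neg <- P & z <= 0
          alpha <- min(x[neg] / (x[neg] - z[neg]))
          x <- x + alpha * (z - x)
          x[abs(x) < 1e-14] <- 0
          P <- P & x > 0
          if (!any(P)) { z <- numeric(n); break }
          z <- ls_sub(P)
        }
        x <- z
        x[!P] <- 0
        break
      }
      excluded[j] <- TRUE
    }
    if (!added) break
  }
  x[x < 0] <- 0
  x
}

# Tikhonov-regularized NNLS: min ||Ax - b||^2 + reg^2 ||x||^2, x >= 0,
# via the augmented system [A; reg*I] x = [b; 0].
nnls_tikhonov <- function(A, b, reg) {
  n <- ncol(A)
  if (reg > 0) {
    A <- rbind(A, diag(reg, n))
    b <- c(b, numeric(n))
  }
  nnls_solve(A, b)
}
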