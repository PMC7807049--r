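# Lawson-Hanson active-set non-negative least squares:
#   min ||A x - b||_2  subject to  x >= 0.
# Written out in full because the non-negativity constraint is central to the
# unmixing model (emission contributions cannot be negative); cross-checked in
# the test suite against brute-force constrained minimisation.
nnls_solve <- function(A, b, tol = NULL) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  m <- nrow(A); k <- ncol(A)
  stopifnot(length(b) == m)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * max(m, k)
  x <- numeric(k)
  passive <- rep(FALSE, k)
  w <- as.numeric(crossprod(A, b))
  iter <- 0L
  max_iter <- 30L * k
  while (any(!passive) && max(w[!passive]) > tol && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(k)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- qr.coef(qr(Ap), b)
      s[is.na(s)] <- 0
      if (all(s[passive] > tol)) { x <- s; break }
      # step back to the feasible boundary, drop the zeroed variables
      idx <- passive & s <= tol
      alpha <- min(x[idx] / (x[idx] - s[idx]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  resid <- b - A %*% x
  list(x = x, residual = as.numeric(resid),
       residual_l2 = sqrt(sum(resid^2)))
}
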