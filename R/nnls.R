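#' Non-negative least squares by the Lawson-Hanson active-set method
#'
#' Solves \eqn{\min_{x \ge 0} \|Ax - b\|_2}. The passive (unconstrained)
#' set is grown greedily on the most positive gradient component and the
#' unconstrained least-squares subproblem is solved by QR on the passive
#' columns, with the classic feasibility backtracking step, so at
#' termination the solution satisfies the Karush-Kuhn-Tucker conditions to
#' numerical tolerance and is exact (machine precision) on the final
#' passive set.
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector (length m).
#' @param tol dual-feasibility tolerance on the gradient; defaults to a
#'   scale-aware multiple of machine epsilon.
#' @param itmax iteration cap (default `50 * n`).
#' @return list with `x` (solution), `resid_norm`, `iterations`,
#'   `converged`.
#' @export
nnls_solve <- function(A, b, tol = NULL, itmax = NULL) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  b <- as.numeric(b)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m)
  if (is.null(tol))
    tol <- 10 * .Machine$double.eps * max(abs(A)) * max(m, n) *
      max(abs(b), 1)
  if (is.null(itmax)) itmax <- 50L * n
  x <- numeric(n)
  P <- logical(n)
  w <- as.numeric(crossprod(A, b))
  it <- 0L
  converged <- TRUE
  while (any(!P & w > tol)) {
    it <- it + 1L
    if (it > itmax) { converged <- FALSE; break }
    cand <- which(!P)
    P[cand[which.max(w[cand])]] <- TRUE
    repeat {
      s <- numeric(n)
      fit <- qr(A[, P, drop = FALSE])
      sp <- qr.coef(fit, b)
      sp[is.na(sp)] <- 0  # exactly collinear passive columns
      s[P] <- sp
      if (all(s[P] > 0)) { x <- s; break }
      # backtrack towards feasibility; guard the degenerate case where a
      # variable sits at zero in both the iterate and the subproblem
      neg <- P & s <= 0 & (x - s) > 0
      if (!any(neg)) { x <- pmax(s, 0); P <- P & x > 0; break }
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      x[x < tol * 1e-6] <- 0
      P <- P & x > 0
      it <- it + 1L
      if (it > itmax) { converged <- FALSE; break }
    }
    if (!converged) break
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  if (!converged)
    warning("NNLS iteration cap reached; returning best feasible iterate")
  list(x = x, resid_norm = sqrt(sum((A %*% x - b)^2)),
       iterations = it, converged = converged)
}
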