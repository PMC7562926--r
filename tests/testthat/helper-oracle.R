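# Independent convex oracle for the constrained weighted-l1 problem
#
#   minimise ||omega * Psi x||_1  s.t.  x >= 0,  ||y - Phi x||_2 <= eps
#
# solved by consensus ADMM with three splitting blocks (l1 shrinkage,
# l2-ball projection, positivity), entirely separate from the package's
# primal-dual forward-backward implementation.  Only practical for small n.

dense_analysis_matrix <- function(model) {
  n <- model$n
  side <- model$grid$side
  psi <- matrix(0, model$L, n)
  for (j in seq_len(n)) {
    e <- numeric(n)
    e[j] <- 1
    psi[, j] <- model$analysis(matrix(e, side, side))
  }
  psi
}

# rho must be large relative to eps/||x|| for the ball constraint to bind
# tightly; 1000 converges the noiseless-floor instances used in the tests
oracle_admm <- function(y, phi, psi, eps, omega = rep(1, nrow(psi)),
                        rho = 1000, iters = 40000) {
  n <- ncol(phi)
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)
  # x-update solves (Psi'Psi + Phi'Phi + I) x = rhs; Psi is a tight frame so
  # Psi'Psi = I
  ch <- chol(diag(n) + crossprod(phi) + diag(n))
  x <- numeric(n)
  z1 <- numeric(nrow(psi)); u1 <- z1
  z2 <- numeric(nrow(phi)); u2 <- z2
  z3 <- numeric(n); u3 <- z3
  for (k in seq_len(iters)) {
    rhs <- as.vector(crossprod(psi, z1 - u1)) +
           as.vector(crossprod(phi, z2 - u2)) + (z3 - u3)
    x <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
    a1 <- as.vector(psi %*% x) + u1
    z1 <- soft(a1, omega / rho)
    a2 <- as.vector(phi %*% x) + u2
    d <- a2 - y
    nd <- sqrt(sum(d^2))
    z2 <- if (nd <= eps) a2 else y + d * (eps / nd)
    a3 <- x + u3
    z3 <- pmax(a3, 0)
    u1 <- a1 - z1
    u2 <- a2 - z2
    u3 <- a3 - z3
  }
  z3
}
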