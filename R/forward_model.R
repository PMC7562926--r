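#' Build the single-pixel measurement operator
#'
#' Row p of the measurement operator is pattern p flattened over the pixel
#' grid, so applying the operator to an image computes the overlap of every
#' illumination pattern with the object — the physical single-pixel reading.
#' The squared spectral norm is estimated by power iteration (relative
#' tolerance 1e-6) from a deterministic positive start vector; since the
#' operator is entrywise nonnegative its leading singular vector is
#' nonnegative, so the iteration cannot start orthogonal to it.
#'
#' @param stack A `pattern_stack`.
#' @return An object of class `measurement_operator` with elements `phi`
#'   (`np x n` matrix), `apply` (image -> length-np vector), `adjoint`
#'   (vector -> image matrix), `operator_norm_sq`, `grid`, `np`, `n`.
#' @export
build_operator <- function(stack) {
  stopifnot(inherits(stack, "pattern_stack"), stack$np >= 1)
  phi <- stack$patterns
  grid <- stack$grid
  n <- ncol(phi)
  apply_fn <- function(x) as.vector(phi %*% as.vector(as_image_matrix(x, grid)))
  adjoint_fn <- function(v) matrix(as.vector(crossprod(phi, v)),
                                   grid$side, grid$side)
  structure(list(phi = phi, grid = grid, np = nrow(phi), n = n,
                 apply = apply_fn, adjoint = adjoint_fn,
                 operator_norm_sq = power_norm_sq(phi)),
            class = "measurement_operator")
}

#' @export
print.measurement_operator <- function(x, ...) {
  cat(sprintf("<measurement_operator> %d x %d, ||Phi||^2 = %.4g\n",
              x$np, x$n, x$operator_norm_sq))
  invisible(x)
}

# squared spectral norm of a matrix by power iteration on t(A) %*% A
power_norm_sq <- function(a, tol = 1e-6, max_iter = 500) {
  v <- as.vector(crossprod(a, rep(1, nrow(a))))
  if (all(v == 0)) return(0)
  v <- v / vec_norm(v)
  lam <- 0
  for (i in seq_len(max_iter)) {
    w <- as.vector(crossprod(a, a %*% v))
    lam_new <- sum(v * w)
    v <- w / vec_norm(w)
    if (abs(lam_new - lam) <= tol * abs(lam_new)) return(lam_new)
    lam <- lam_new
  }
  lam
}

new_measurement_set <- function(y, noise_sigma, epsilon, isnr_db = NULL,
                                seed = NULL) {
  stopifnot(epsilon >= 0, noise_sigma >= 0)
  structure(list(y = as.numeric(y), noise_sigma = noise_sigma,
                 epsilon = epsilon, isnr_db = isnr_db, seed = seed,
                 np = length(y)),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf(
    "<measurement_set> %d readings, sigma = %.4g, epsilon = %.4g%s\n",
    x$np, x$noise_sigma, x$epsilon,
    if (!is.null(x$isnr_db)) sprintf(", iSNR = %g dB", x$isnr_db) else ""))
  invisible(x)
}

#' Simulate single-pixel measurements of an object
#'
#' Computes `y = Phi x + e`.  The noiseless part is the overlap of each
#' pattern with the object.  When `isnr_db` is given, `e` is i.i.d. Gaussian
#' with standard deviation calibrated so that the expected input
#' signal-to-noise ratio `20*log10(||Phi x||_2 / ||e||_2)` equals `isnr_db`
#' (using `E||e||_2^2 = Np sigma^2`); `isnr_db = NULL` gives exact noiseless
#' data.  The fidelity bound `epsilon` is set from [noise_bound()].
#'
#' @param op A [build_operator()] result.
#' @param x Object image: matrix, `phantom`, or length-n vector; must be
#'   nonnegative.
#' @param isnr_db Input SNR in dB, or `NULL` for noiseless.
#' @param seed Integer seed for the noise draw (ignored when noiseless).
#' @return A `measurement_set`.
#' @export
simulate_measurements <- function(op, x, isnr_db = NULL, seed = NULL) {
  stopifnot(inherits(op, "measurement_operator"))
  xm <- as_image_matrix(x, op$grid)
  if (any(xm < 0)) stop("object image must be nonnegative")
  y0 <- op$apply(xm)
  if (is.null(isnr_db)) {
    eps <- noise_bound(0, op$np, y_norm = vec_norm(y0))
    return(new_measurement_set(y0, 0, eps, NULL, seed))
  }
  sigma <- vec_norm(y0) * 10^(-isnr_db / 20) / sqrt(op$np)
  e <- with_seed(seed, stats::rnorm(op$np, sd = sigma))
  y <- y0 + e
  eps <- noise_bound(sigma, op$np, y_norm = vec_norm(y))
  new_measurement_set(y, sigma, eps, isnr_db, seed)
}

#' Fidelity bound from the noise level
#'
#' The residual-energy bound for the l2-ball data-fidelity constraint.  For
#' known Gaussian noise of standard deviation `sigma`, `||e||_2^2` is
#' `sigma^2` times a chi-squared variable with `Np` degrees of freedom, so
#' the bound is set at its mean plus two standard deviations:
#' `epsilon^2 = sigma^2 * (Np + 2*sqrt(2*Np))`, which covers the realised
#' noise energy with probability ~0.97-0.99.  For noiseless data
#' (`sigma = 0`) a small floor `eps_min * ||y||_2` keeps the feasible set
#' well-conditioned.
#'
#' @param noise_sigma Per-sample noise standard deviation (>= 0).
#' @param n_measurements Number of measurements Np.
#' @param y_norm `||y||_2`, required when `noise_sigma = 0`.
#' @param eps_min Relative floor used in the noiseless case (default 1e-3).
#' @return The bound `epsilon`.
#' @examples
#' noise_bound(1, 100)        # sqrt(100 + 2*sqrt(200)) ~ 10.67
#' noise_bound(0, 100, 10)    # 0.01
#' @export
noise_bound <- function(noise_sigma, n_measurements, y_norm = NULL,
                        eps_min = 1e-3) {
  stopifnot(noise_sigma >= 0, n_measurements >= 1)
  if (noise_sigma == 0) {
    if (is.null(y_norm))
      stop("y_norm is required to set the noiseless epsilon floor")
    return(eps_min * y_norm)
  }
  sqrt(noise_sigma^2 * (n_measurements + 2 * sqrt(2 * n_measurements)))
}
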