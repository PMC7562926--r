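#' @useDynLib lanternimg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# cache of Bessel-J zeros, keyed by azimuthal order m
.bessel_zero_cache <- new.env(parent = emptyenv())

#' Positive zeros of the Bessel function J_m
#'
#' Returns the first `n` positive zeros `j_{m,q}` of `J_m`, found by scanning
#' for sign changes beyond `x = m` (the first zero of `J_m` always exceeds
#' `m`) and refining each bracket with [stats::uniroot()] to near machine
#' precision.  Zeros are cached per order.
#'
#' @param m Nonnegative integer azimuthal order.
#' @param n Number of zeros required.
#' @return Numeric vector of length `n`, strictly increasing.
#' @examples
#' bessel_zeros(0, 2)  # 2.404826, 5.520078
#' @export
bessel_zeros <- function(m, n) {
  stopifnot(m >= 0, m == round(m), n >= 1)
  key <- as.character(m)
  zeros <- .bessel_zero_cache[[key]]
  if (is.null(zeros)) zeros <- numeric(0)
  if (length(zeros) >= n) return(zeros[seq_len(n)])
  x <- if (length(zeros)) zeros[length(zeros)] + 0.1 else max(m, 1e-3)
  f_prev <- besselJ(x, m)
  step <- 0.5  # consecutive zeros of J_m are separated by more than this
  while (length(zeros) < n) {
    x_next <- x + step
    f_next <- besselJ(x_next, m)
    if (is.finite(f_prev) && is.finite(f_next) &&
        sign(f_prev) != sign(f_next) && f_prev != 0) {
      root <- stats::uniroot(function(t) besselJ(t, m), c(x, x_next),
                             tol = 1e-13)$root
      zeros <- c(zeros, root)
    }
    x <- x_next
    f_prev <- f_next
  }
  .bessel_zero_cache[[key]] <- zeros
  zeros[seq_len(n)]
}

# ordered (m, q, parity, eigenvalue) table for the n_modes lowest Dirichlet
# disk modes; degenerate cos/sin pairs adjacent, cos first
mode_table <- function(n_modes) {
  jmax <- 2 * sqrt(4 * n_modes) + 10
  repeat {
    rows <- list()
    m <- 0
    repeat {
      z1 <- bessel_zeros(m, 1)
      if (z1 > jmax) break
      q <- 1
      repeat {
        z <- bessel_zeros(m, q)[q]
        if (z > jmax) break
        rows[[length(rows) + 1L]] <- data.frame(m = m, q = q, eigenvalue = z)
        q <- q + 1
      }
      m <- m + 1
    }
    tab <- do.call(rbind, rows)
    # multiplicity: 1 for m = 0, 2 (cos & sin) for m > 0
    if (sum(ifelse(tab$m == 0, 1L, 2L)) >= n_modes) break
    jmax <- jmax * 1.5
  }
  tab <- tab[order(tab$eigenvalue, tab$m), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    if (r$m == 0) cbind(r, parity = "cos")
    else rbind(cbind(r, parity = "cos"), cbind(r, parity = "sin"))
  }))
  rownames(out) <- NULL
  out[seq_len(n_modes), ]
}

#' Eigenmodes of a circular ideal-mirror waveguide on a pixel grid
#'
#' Computes the `n_modes` lowest-order spatial modes of a circular waveguide
#' with perfectly reflecting (Dirichlet) walls, sampled on the pixels of
#' `grid`: \eqn{u_{m,q}(r,\theta) \propto J_m(j_{m,q}\, r/R)\,\{\cos m\theta,
#' \sin m\theta\}} inside the support disk and exactly zero outside it, where
#' \eqn{j_{m,q}} is the q-th positive zero of the Bessel function \eqn{J_m}.
#' Modes are ordered by ascending eigenvalue \eqn{j_{m,q}} (then ascending
#' `m`, cosine before sine), and each field is normalised to unit discrete
#' energy (sum of squared pixel values is 1), so that the discrete Gram
#' matrix is close to the identity on adequately fine grids.
#'
#' @param n_modes Number of modes requested (>= 1).
#' @param grid A [grid_spec()].
#' @return An object of class `mode_basis` with elements `fields` (an
#'   `n_modes x side^2` matrix, one row per mode, pixels flattened
#'   column-major), `modes` (data frame with columns `m`, `q`, `parity`,
#'   `eigenvalue`), `grid` and `count`.
#' @examples
#' basis <- build_mode_basis(6, grid_spec(64))
#' basis$modes[, c("m", "q", "parity")]
#' @export
build_mode_basis <- function(n_modes, grid) {
  stopifnot(inherits(grid, "grid_spec"), n_modes >= 1)
  tab <- mode_table(n_modes)
  jmax <- max(tab$eigenvalue)
  # radial half-period near the rim is ~ pi * R / j pixels; require >= 2 px
  if (pi * grid$radius / jmax < 2)
    stop(sprintf(paste("grid too coarse for mode %d (eigenvalue %.2f):",
                       "radial half-period %.2f px < 2 px"),
                 n_modes, jmax, pi * grid$radius / jmax))
  co <- grid_coords(grid)
  inside <- co$r <= grid$radius
  n_px <- grid$side^2
  fields <- matrix(0, nrow = n_modes, ncol = n_px)
  r_in <- co$r[inside]
  th_in <- co$theta[inside]
  for (i in seq_len(n_modes)) {
    mi <- tab$m[i]
    radial <- besselJ(tab$eigenvalue[i] * r_in / grid$radius, mi)
    ang <- if (tab$parity[i] == "cos") cos(mi * th_in) else sin(mi * th_in)
    u <- numeric(n_px)
    u[inside] <- radial * ang
    fields[i, ] <- u / sqrt(sum(u^2))
  }
  structure(list(fields = fields, modes = tab, grid = grid, count = n_modes),
            class = "mode_basis")
}

#' @export
print.mode_basis <- function(x, ...) {
  cat(sprintf("<mode_basis> %d modes on %d x %d grid, eigenvalues %.3f - %.3f\n",
              x$count, x$grid$side, x$grid$side,
              min(x$modes$eigenvalue), max(x$modes$eigenvalue)))
  invisible(x)
}

#' Step-index fibre description
#'
#' @param core_diameter Core diameter, in micrometres.
#' @param numerical_aperture Numerical aperture (0 < NA < 1).
#' @param wavelength Operating wavelength, in micrometres.
#' @return An object of class `fiber_spec`.
#' @export
fiber_spec <- function(core_diameter, numerical_aperture, wavelength) {
  stopifnot(core_diameter > 0, wavelength > 0,
            numerical_aperture > 0, numerical_aperture < 1)
  structure(list(core_diameter = core_diameter,
                 numerical_aperture = numerical_aperture,
                 wavelength = wavelength),
            class = "fiber_spec")
}

#' Spatial-mode count of a step-index multimode core
#'
#' Uses the standard step-index estimate: the normalised frequency is
#' \eqn{V = \pi d \cdot NA / \lambda} and the number of spatial modes per
#' polarisation is approximately \eqn{V^2/4} (floored to an integer).
#'
#' @param fiber A [fiber_spec()].
#' @return Integer mode count.
#' @examples
#' step_index_mode_count(fiber_spec(63, 0.22, 0.488))  # ~ 2000
#' @export
step_index_mode_count <- function(fiber) {
  stopifnot(inherits(fiber, "fiber_spec"))
  v <- pi * fiber$core_diameter * fiber$numerical_aperture / fiber$wavelength
  as.integer(floor(v^2 / 4))
}

#' Numerical aperture required to support a given mode count
#'
#' Inverse of [step_index_mode_count()]:
#' \eqn{NA = 2 \sqrt{N} \lambda / (\pi d)}.
#'
#' @param core_diameter Core diameter (micrometres).
#' @param wavelength Wavelength (micrometres).
#' @param n_modes Desired spatial-mode count.
#' @return The required numerical aperture.
#' @examples
#' required_na(35, 0.514, 1089)  # ~ 0.31
#' @export
required_na <- function(core_diameter, wavelength, n_modes) {
  stopifnot(core_diameter > 0, wavelength > 0, n_modes > 0)
  na <- 2 * sqrt(n_modes) * wavelength / (pi * core_diameter)
  if (na >= 1)
    stop(sprintf("infeasible waveguide: required NA %.3f >= 1", na))
  na
}

#' Rayleigh two-point resolution
#'
#' @param wavelength Wavelength.
#' @param numerical_aperture Numerical aperture.
#' @return `0.61 * wavelength / numerical_aperture`, in the units of
#'   `wavelength`.
#' @examples
#' rayleigh_resolution(0.488, 0.22)  # 1.353 um
#' @export
rayleigh_resolution <- function(wavelength, numerical_aperture) {
  stopifnot(wavelength > 0, numerical_aperture > 0)
  0.61 * wavelength / numerical_aperture
}

#' Mean feature spacing across a circular facet
#'
#' Centre-to-centre spacing of `n_features` resolvable features tiling the
#' circular core facet with equal areas: \eqn{\sqrt{\pi (d/2)^2 / N}}.
#'
#' @param core_diameter Core diameter.
#' @param n_features Number of features tiling the facet (>= 1).
#' @return Spacing in the units of `core_diameter`.
#' @examples
#' feature_spacing(63, 2000)  # ~ 1.25 um
#' @export
feature_spacing <- function(core_diameter, n_features) {
  stopifnot(core_diameter > 0, n_features >= 1)
  sqrt(pi * (core_diameter / 2)^2 / n_features)
}
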