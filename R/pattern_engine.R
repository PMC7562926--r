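#' Random unitary mixing matrix
#'
#' Draws a complex Gaussian matrix and orthonormalises it (QR with a phase
#' fix on the diagonal of R), giving a Haar-like random unitary.  Exciting
#' one single-mode core of the multicore fibre launches one fixed, but
#' a-priori arbitrary, orthonormal coherent superposition of the multimode
#' core's eigenmodes; the rows of this matrix play that role in simulation.
#'
#' @param dim Matrix dimension (number of superpositions = number of modes).
#' @param seed Integer seed; the result is reproducible bit-for-bit.
#' @return An object of class `mixing_matrix` with complex `entries`
#'   (`dim x dim`, unitary) and the `seed`.
#' @export
random_unitary <- function(dim, seed) {
  stopifnot(dim >= 1)
  z <- with_seed(seed, {
    matrix(complex(real = stats::rnorm(dim * dim),
                   imaginary = stats::rnorm(dim * dim)) / sqrt(2), dim, dim)
  })
  qr_z <- qr(z)
  q <- qr.Q(qr_z)
  d <- diag(qr.R(qr_z))
  ph <- d / Mod(d)                       # make the factorisation unique
  q <- sweep(q, 2, ph, `*`)
  structure(list(entries = q, seed = seed), class = "mixing_matrix")
}

new_pattern_stack <- function(patterns, grid, normalization, provenance,
                              seed = NULL, rotation = NULL) {
  structure(list(patterns = patterns, grid = grid,
                 normalization = normalization, provenance = provenance,
                 seed = seed, rotation = rotation,
                 np = nrow(patterns)),
            class = "pattern_stack")
}

#' Display the first patterns of a stack
#'
#' @param x A `pattern_stack`.
#' @param which Indices of patterns to show (up to 9, in a grid).
#' @param ... Ignored.
#' @export
plot.pattern_stack <- function(x, which = seq_len(min(9, x$np)), ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(which)),
                       mar = c(0.5, 0.5, 1.5, 0.5))
  on.exit(graphics::par(old))
  s <- x$grid$side
  for (i in which)
    plot_image_matrix(matrix(x$patterns[i, ], s, s), main = paste0("p", i))
  invisible(x)
}

#' @export
print.pattern_stack <- function(x, ...) {
  cat(sprintf("<pattern_stack> %d patterns on %d x %d grid (%s, %s)\n",
              x$np, x$grid$side, x$grid$side, x$provenance, x$normalization))
  invisible(x)
}

#' Synthesize multimode intensity patterns
#'
#' Forms intensity patterns as the square modulus of coherent superpositions
#' of the waveguide modes: pattern p is \eqn{|\sum_k U_{pk} u_k|^2} evaluated
#' pixelwise, where `U` is the (unitary) mixing matrix and `u_k` the mode
#' fields.  With `normalization = "unit_sum"` (the default) each pattern is
#' then rescaled to integrate to 1, the simulated analogue of dividing each
#' transmission reading by a reference-detector reading.
#'
#' @param basis A [build_mode_basis()] result.
#' @param mixing A [random_unitary()] result (or any `mixing_matrix` whose
#'   column count equals the basis count).
#' @param normalization `"unit_sum"` or `"none"`.
#' @return A `pattern_stack` with `nrow(mixing$entries)` nonnegative patterns
#'   confined to the support disk.
#' @export
synthesize_patterns <- function(basis, mixing,
                                normalization = c("unit_sum", "none")) {
  stopifnot(inherits(basis, "mode_basis"), inherits(mixing, "mixing_matrix"))
  normalization <- match.arg(normalization)
  u <- mixing$entries
  if (ncol(u) != basis$count)
    stop("mixing matrix column count does not match the mode basis count")
  # |(Re U + i Im U) F|^2 via two real matrix products (F is real)
  re <- Re(u) %*% basis$fields
  im <- Im(u) %*% basis$fields
  p <- re^2 + im^2
  if (normalization == "unit_sum") p <- p / rowSums(p)
  new_pattern_stack(p, basis$grid, normalization, "simulated",
                    seed = mixing$seed)
}

#' Augment a pattern stack by rotation
#'
#' Replicates the stack at `n_rotations` orientations, rotation k applying an
#' angle `k * step_degrees` (k = 0, ..., n_rotations - 1) about the exact
#' grid centre with bilinear interpolation; pixels mapping outside the
#' support disk are set to 0.  Rotating the patterns is mathematically
#' equivalent to rotating the object the opposite way, which is how extra
#' measurements are acquired physically.  Patterns are not re-normalised
#' after rotation; interpolation preserves each pattern's energy to well
#' within 0.5% for support-confined patterns.
#'
#' @param stack A `pattern_stack`.
#' @param n_rotations Number of orientations (>= 1); 1 returns the stack
#'   unchanged.
#' @param step_degrees Angular step between orientations, degrees.
#' @return A `pattern_stack` with `np * n_rotations` patterns, ordered by
#'   rotation then original pattern index.
#' @export
rotate_stack <- function(stack, n_rotations, step_degrees) {
  stopifnot(inherits(stack, "pattern_stack"), n_rotations >= 1)
  if (n_rotations == 1) return(stack)
  g <- stack$grid
  s <- g$side
  co <- grid_coords(g)
  xs <- as.vector(co$x); ys <- as.vector(co$y)
  inside <- as.vector(co$r <= g$radius)
  ctr <- (s + 1) / 2
  out <- vector("list", n_rotations)
  out[[1]] <- stack$patterns
  for (k in seq_len(n_rotations - 1)) {
    th <- -k * step_degrees * pi / 180  # inverse map: sample source at -angle
    sx <- cos(th) * xs - sin(th) * ys + ctr
    sy <- sin(th) * xs + cos(th) * ys + ctr
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0;   fy <- sy - y0
    ok <- inside & x0 >= 1 & x0 <= s - 1 & y0 >= 1 & y0 <= s - 1
    idx <- function(r, c) (pmin(pmax(c, 1), s) - 1) * s + pmin(pmax(r, 1), s)
    w00 <- (1 - fx) * (1 - fy) * ok
    w10 <- (1 - fx) * fy       * ok
    w01 <- fx       * (1 - fy) * ok
    w11 <- fx       * fy       * ok
    p <- stack$patterns
    rk <- p[, idx(y0,     x0),     drop = FALSE] * rep(w00, each = nrow(p)) +
          p[, idx(y0 + 1, x0),     drop = FALSE] * rep(w10, each = nrow(p)) +
          p[, idx(y0,     x0 + 1), drop = FALSE] * rep(w01, each = nrow(p)) +
          p[, idx(y0 + 1, x0 + 1), drop = FALSE] * rep(w11, each = nrow(p))
    out[[k + 1]] <- rk
  }
  new_pattern_stack(do.call(rbind, out), g, stack$normalization,
                    stack$provenance, seed = stack$seed,
                    rotation = list(n_rotations = n_rotations,
                                    step_degrees = step_degrees))
}

#' Load measured pattern images into a stack
#'
#' Reads per-core pattern images (PNG or TIFF), averages colour channels,
#' subtracts a background level, clips any resulting negative pixels to zero
#' (with a message reporting how many), optionally resamples to the target
#' grid by bilinear interpolation, and returns a `pattern_stack` with
#' provenance `"measured"`.
#'
#' @param files Character vector of image paths (all the same shape).
#' @param grid Target [grid_spec()].
#' @param background `"min"` (subtract each image's minimum), `"none"`, or a
#'   numeric level.
#' @param normalization Passed through to the stack: `"unit_sum"` or
#'   `"none"`.
#' @return A `pattern_stack`.
#' @export
load_pattern_images <- function(files, grid,
                                background = "min",
                                normalization = c("unit_sum", "none")) {
  stopifnot(length(files) >= 1, inherits(grid, "grid_spec"))
  normalization <- match.arg(normalization)
  imgs <- lapply(files, read_image_file)
  shp <- dim(imgs[[1]])
  if (!all(vapply(imgs, function(m) all(dim(m) == shp), logical(1))))
    stop("all pattern images must have the same shape")
  n_clipped <- 0L
  rows <- lapply(imgs, function(m) {
    bg <- if (identical(background, "min")) min(m)
          else if (identical(background, "none")) 0
          else as.numeric(background)
    m <- m - bg
    n_clipped <<- n_clipped + sum(m < 0)
    m[m < 0] <- 0
    as.vector(resample_bilinear(m, grid$side))
  })
  if (n_clipped > 0)
    message(sprintf("load_pattern_images: clipped %d negative pixels to 0",
                    n_clipped))
  p <- do.call(rbind, rows)
  if (normalization == "unit_sum") p <- p / rowSums(p)
  new_pattern_stack(p, grid, normalization, "measured")
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' is required to read TIFF images")
    tiff::readTIFF(path)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("package 'png' is required to read PNG images")
    png::readPNG(path)
  } else stop("unsupported image format: ", ext)
  if (length(dim(m)) == 3) m <- apply(m, c(1, 2), mean)
  m
}

# bilinear resample of a matrix to side x side
resample_bilinear <- function(m, side) {
  if (all(dim(m) == c(side, side))) return(m)
  nr <- nrow(m); nc <- ncol(m)
  ri <- seq(1, nr, length.out = side)
  ci <- seq(1, nc, length.out = side)
  r0 <- pmin(floor(ri), nr - 1); fr <- ri - r0
  c0 <- pmin(floor(ci), nc - 1); fc <- ci - c0
  a <- m[r0, c0] * outer(1 - fr, 1 - fc) + m[r0 + 1, c0] * outer(fr, 1 - fc) +
       m[r0, c0 + 1] * outer(1 - fr, fc) + m[r0 + 1, c0 + 1] * outer(fr, fc)
  a
}
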