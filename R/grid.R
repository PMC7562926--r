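#' Pixel grid for patterns, phantoms and reconstructions
#'
#' A `grid_spec` fixes the discretisation shared by every stage of the
#' pipeline: a square image of `side_pixels` x `side_pixels` pixels and a
#' circular support of radius `core_radius_pixels` centred on the grid,
#' representing the multimode core facet.  Fields, patterns and
#' reconstructions live on this grid; everything outside the circular
#' support is dark.
#'
#' @param side_pixels Integer >= 8, image side length in pixels.
#' @param pixel_pitch Physical length per pixel (optional, default 1).
#' @param core_radius_pixels Radius of the circular support in pixels.
#'   Defaults to the inscribed circle, `side_pixels / 2`.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(125)
#' sum(support_mask(g)) / 125^2   # fraction of pixels inside the core
#' @export
grid_spec <- function(side_pixels, pixel_pitch = 1,
                      core_radius_pixels = side_pixels / 2) {
  side_pixels <- as.integer(side_pixels)
  stopifnot(length(side_pixels) == 1, side_pixels >= 8,
            is.numeric(pixel_pitch), pixel_pitch > 0,
            is.numeric(core_radius_pixels), core_radius_pixels > 0)
  if (core_radius_pixels > side_pixels / 2 + 1e-9)
    stop("core_radius_pixels must not exceed side_pixels / 2")
  structure(list(side = side_pixels, pitch = pixel_pitch,
                 radius = core_radius_pixels),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels, core radius %.4g px, pitch %.4g\n",
              x$side, x$side, x$radius, x$pitch))
  invisible(x)
}

# pixel-centre coordinates relative to the grid centre, column-major;
# list(x = ..., y = ..., r = .., theta = ..) of side x side matrices
grid_coords <- function(grid) {
  s <- grid$side
  ctr <- (s + 1) / 2
  x <- matrix(rep(seq_len(s) - ctr, each = s), s, s)  # column index offset
  y <- matrix(rep(seq_len(s) - ctr, times = s), s, s) # row index offset
  list(x = x, y = y, r = sqrt(x^2 + y^2), theta = atan2(y, x))
}

#' Circular support mask of a grid
#'
#' Logical matrix marking pixels whose centre lies within the core radius of
#' the grid centre.
#'
#' @param grid A [grid_spec()].
#' @return A `side x side` logical matrix.
#' @export
support_mask <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  grid_coords(grid)$r <= grid$radius
}

# coerce an image argument (matrix / phantom / image_estimate / vector) to a
# side x side matrix on `grid`
as_image_matrix <- function(x, grid) {
  if (inherits(x, "phantom")) x <- x$image
  if (inherits(x, "image_estimate")) x <- x$x
  if (is.null(dim(x))) {
    if (length(x) != grid$side^2)
      stop("image vector length does not match the grid")
    x <- matrix(x, grid$side, grid$side)
  }
  if (!all(dim(x) == c(grid$side, grid$side)))
    stop("image dimensions do not match the grid")
  x
}
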