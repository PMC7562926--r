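new_phantom <- function(image, kind, params, grid) {
  stopifnot(all(image >= 0), all(image <= 1))
  structure(list(image = image, kind = kind, params = params, grid = grid),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s on %d x %d grid, %d transmissive pixels\n",
              x$kind, x$grid$side, x$grid$side, sum(x$image > 0)))
  invisible(x)
}

#' @export
plot.phantom <- function(x, main = x$kind, ...) {
  plot_image_matrix(x$image, main = main, ...)
}

#' Knife-edge transmission phantom
#'
#' A half-plane mask: transmissive (1) on one side of a straight edge,
#' opaque (0) on the other.  The edge position is chosen so the blocked
#' share of the reference stack's summed illumination equals
#' `blocked_fraction`; the single edge row/column takes a fractional value
#' so the target share is met essentially exactly.  With no reference stack
#' the blocked share of the circular support area is used instead.
#' Orientation `"H"` blocks from the top of the image, `"V"` from the left.
#'
#' @param grid A [grid_spec()].
#' @param orientation `"H"` (horizontal edge) or `"V"` (vertical edge).
#' @param blocked_fraction Fraction of illumination blocked, in (0, 1);
#'   the experiments use ~0.25, ~0.5, ~0.75.
#' @param reference_stack Optional `pattern_stack` whose summed intensity
#'   weights the edge placement.
#' @return A `phantom` of kind `"knife_edge"`.
#' @export
make_knife_edge <- function(grid, orientation = c("H", "V"),
                            blocked_fraction, reference_stack = NULL) {
  stopifnot(inherits(grid, "grid_spec"),
            blocked_fraction > 0, blocked_fraction < 1)
  orientation <- match.arg(orientation)
  s <- grid$side
  weight <- if (is.null(reference_stack)) {
    m <- support_mask(grid)
    storage.mode(m) <- "double"
    m
  } else {
    stopifnot(inherits(reference_stack, "pattern_stack"))
    matrix(colSums(reference_stack$patterns), s, s)
  }
  line_w <- if (orientation == "H") rowSums(weight) else colSums(weight)
  total <- sum(line_w)
  if (total <= 0) stop("degenerate reference stack: zero total illumination")
  cum <- cumsum(line_w) / total
  k <- findInterval(blocked_fraction, cum) + 1L   # edge lies inside line k
  if (k > s) k <- s
  prev <- if (k == 1) 0 else cum[k - 1]
  frac_in_line <- if (line_w[k] > 0)
    (blocked_fraction - prev) * total / line_w[k] else 0
  frac_in_line <- min(max(frac_in_line, 0), 1)
  img <- matrix(1, s, s)
  if (orientation == "H") {
    if (k > 1) img[seq_len(k - 1), ] <- 0
    img[k, ] <- 1 - frac_in_line
  } else {
    if (k > 1) img[, seq_len(k - 1)] <- 0
    img[, k] <- 1 - frac_in_line
  }
  achieved <- sum((1 - img) * weight) / sum(weight)
  if (abs(achieved - blocked_fraction) > 0.01)
    stop(sprintf("unattainable blocked fraction: requested %.3f, best %.3f",
                 blocked_fraction, achieved))
  new_phantom(img, "knife_edge",
              list(orientation = orientation,
                   blocked_fraction = blocked_fraction,
                   achieved_fraction = achieved, edge_index = k,
                   edge_fraction = frac_in_line,
                   weighted = !is.null(reference_stack)),
              grid)
}

#' Off-centre cross phantom
#'
#' Two perpendicular bars crossing at a point offset from the grid centre.
#'
#' @param grid A [grid_spec()].
#' @param arm_width Bar width in pixels.
#' @param centre_offset Length-2 integer vector `(dx, dy)` of the cross
#'   centre relative to the grid centre (columns, rows).
#' @param arm_length Full length of each bar in pixels (default 0.55 of the
#'   core diameter).
#' @return A binary `phantom` of kind `"offset_cross"`.
#' @export
make_offset_cross <- function(grid, arm_width = max(3, round(grid$side / 25)),
                              centre_offset = c(0, 0),
                              arm_length = round(1.1 * grid$radius)) {
  stopifnot(inherits(grid, "grid_spec"), arm_width >= 1, arm_length >= 1)
  s <- grid$side
  co <- grid_coords(grid)
  cx <- centre_offset[1]; cy <- centre_offset[2]
  hw <- arm_width / 2; hl <- arm_length / 2
  horiz <- abs(co$x - cx) <= hl & abs(co$y - cy) <= hw
  vert  <- abs(co$x - cx) <= hw & abs(co$y - cy) <= hl
  img <- matrix(0, s, s)
  img[horiz | vert] <- 1
  if (!any(img[support_mask(grid)] > 0))
    stop("cross lies entirely outside the illuminated support")
  new_phantom(img, "offset_cross",
              list(arm_width = arm_width, centre_offset = centre_offset,
                   arm_length = arm_length), grid)
}

#' Four elliptical dots phantom
#'
#' Filled ellipses at arbitrary (typically asymmetric) positions.
#'
#' @param grid A [grid_spec()].
#' @param centres `k x 2` matrix of dot centres `(dx, dy)` relative to the
#'   grid centre.
#' @param radii `k x 2` matrix of semi-axes (pixels), or a vector recycled
#'   to circles.
#' @return A binary `phantom` of kind `"four_dots"`.
#' @export
make_four_dots <- function(grid,
                           centres = matrix(c(-0.35, -0.3, 0.3, -0.25,
                                              -0.25, 0.3, 0.35, 0.35) *
                                            grid$radius, ncol = 2,
                                            byrow = TRUE),
                           radii = 0.1 * grid$radius) {
  stopifnot(inherits(grid, "grid_spec"))
  centres <- matrix(centres, ncol = 2)
  if (is.null(dim(radii)) || ncol(as.matrix(radii)) == 1)
    radii <- matrix(rep(as.vector(radii), length.out = 2 * nrow(centres)),
                    ncol = 2)
  stopifnot(nrow(radii) == nrow(centres), all(radii > 0))
  co <- grid_coords(grid)
  img <- matrix(0, grid$side, grid$side)
  for (i in seq_len(nrow(centres))) {
    inside <- ((co$x - centres[i, 1]) / radii[i, 1])^2 +
              ((co$y - centres[i, 2]) / radii[i, 2])^2 <= 1
    img[inside] <- 1
  }
  if (!any(img[support_mask(grid)] > 0))
    stop("dots lie entirely outside the illuminated support")
  new_phantom(img, "four_dots", list(centres = centres, radii = radii), grid)
}

#' Three-bar resolution phantom
#'
#' Three parallel bars with a fixed centre-to-centre spacing, emulating a
#' resolution-target bar group.  Bars are vertical for
#' `orientation = "V"` (separated along x) and horizontal for `"H"`.
#'
#' @param grid A [grid_spec()].
#' @param bar_spacing Centre-to-centre spacing in pixels (> bar_width).
#' @param group_position Length-2 vector `(dx, dy)`: group centre relative
#'   to the grid centre.
#' @param bar_width Bar width in pixels.
#' @param bar_length Bar length in pixels.
#' @param orientation `"V"` or `"H"`.
#' @return A binary `phantom` of kind `"three_bar"` whose params record the
#'   bar centre coordinates.
#' @export
make_three_bar <- function(grid, bar_spacing, group_position = c(0, 0),
                           bar_width = max(2, round(bar_spacing / 3)),
                           bar_length = round(2.5 * bar_spacing),
                           orientation = c("V", "H")) {
  stopifnot(inherits(grid, "grid_spec"), bar_spacing > bar_width,
            bar_width >= 1, bar_length >= 1)
  orientation <- match.arg(orientation)
  co <- grid_coords(grid)
  offsets <- c(-1, 0, 1) * bar_spacing
  hw <- bar_width / 2; hl <- bar_length / 2
  img <- matrix(0, grid$side, grid$side)
  across <- if (orientation == "V") co$x - group_position[1]
            else co$y - group_position[2]
  along  <- if (orientation == "V") co$y - group_position[2]
            else co$x - group_position[1]
  for (o in offsets)
    img[abs(across - o) <= hw & abs(along) <= hl] <- 1
  if (!any(img[support_mask(grid)] > 0))
    stop("bars lie entirely outside the illuminated support")
  ctr <- (grid$side + 1) / 2
  bar_centres <- offsets +
    if (orientation == "V") group_position[1] + ctr else group_position[2] + ctr
  new_phantom(img, "three_bar",
              list(bar_spacing = bar_spacing, group_position = group_position,
                   bar_width = bar_width, bar_length = bar_length,
                   orientation = orientation, bar_centres = bar_centres),
              grid)
}

#' Procedural blob phantom
#'
#' A synthetic stand-in for cell-like fluorescence objects: a few smooth
#' elliptical blobs with soft edges, thresholded into `[0, 1]`.  Purely
#' procedural — no micrograph is reproduced.
#'
#' @param grid A [grid_spec()].
#' @param n_blobs Number of blobs.
#' @param seed Integer seed.
#' @return A `phantom` of kind `"blobs"` with values in `[0, 1]`.
#' @export
make_blobs <- function(grid, n_blobs = 5, seed = 1) {
  stopifnot(inherits(grid, "grid_spec"), n_blobs >= 1)
  co <- grid_coords(grid)
  img <- matrix(0, grid$side, grid$side)
  pars <- with_seed(seed, {
    data.frame(cx = stats::runif(n_blobs, -0.5, 0.5) * grid$radius,
               cy = stats::runif(n_blobs, -0.5, 0.5) * grid$radius,
               rx = stats::runif(n_blobs, 0.08, 0.22) * grid$radius,
               ry = stats::runif(n_blobs, 0.08, 0.22) * grid$radius,
               th = stats::runif(n_blobs, 0, pi))
  })
  for (i in seq_len(n_blobs)) {
    xr <- (co$x - pars$cx[i]) * cos(pars$th[i]) +
          (co$y - pars$cy[i]) * sin(pars$th[i])
    yr <- -(co$x - pars$cx[i]) * sin(pars$th[i]) +
           (co$y - pars$cy[i]) * cos(pars$th[i])
    d2 <- (xr / pars$rx[i])^2 + (yr / pars$ry[i])^2
    img <- pmax(img, pmin(pmax(1.5 * (1 - d2), 0), 1))
  }
  new_phantom(img, "blobs", list(n_blobs = n_blobs, seed = seed, pars = pars),
              grid)
}
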