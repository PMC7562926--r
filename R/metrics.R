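#' Overlap integral between two intensity images
#'
#' The normalised squared inner product
#' \deqn{\mathrm{overlap}(I_A, I_B) = \frac{(\sum I_A I_B)^2}
#'   {\sum I_A^2 \, \sum I_B^2},}
#' which is 1 exactly when the two patterns are identical up to a positive
#' scale, bounded by 1 (Cauchy-Schwarz), symmetric, and scale-invariant in
#' each argument.  Used to quantify the stability of multimode patterns.
#'
#' @param i_a,i_b Intensity images (matrices or vectors of equal length);
#'   neither may be identically zero.
#' @return A value in `[0, 1]`.
#' @examples
#' overlap_integral(matrix(1:4, 2), matrix(1:4, 2))  # 1
#' @export
overlap_integral <- function(i_a, i_b) {
  if (inherits(i_a, "phantom")) i_a <- i_a$image
  if (inherits(i_b, "phantom")) i_b <- i_b$image
  if (inherits(i_a, "image_estimate")) i_a <- i_a$x
  if (inherits(i_b, "image_estimate")) i_b <- i_b$x
  if (length(i_a) != length(i_b)) stop("images must have the same shape")
  ea <- sum(i_a^2); eb <- sum(i_b^2)
  if (ea == 0 || eb == 0)
    stop("overlap integral undefined for a zero-energy image")
  sum(i_a * i_b)^2 / (ea * eb)
}

#' Reconstruction signal-to-noise ratio
#'
#' `20 * log10(||truth||_2 / ||truth - alpha * estimate||_2)` with `alpha`
#' the least-squares scale `<truth, estimate> / ||estimate||_2^2`, making
#' the score invariant to the estimate's overall scale.  An estimate equal
#' to the truth gives infinite SNR, reported as the cap `max_db`; a zero
#' estimate scores 0 dB.
#'
#' @param estimate An `image_estimate`, matrix, or vector.
#' @param truth A `phantom`, matrix, or vector on the same grid.
#' @param max_db Cap for a (numerically) perfect reconstruction.
#' @return SNR in dB.
#' @export
reconstruction_snr <- function(estimate, truth, max_db = 300) {
  if (inherits(estimate, "image_estimate")) estimate <- estimate$x
  if (inherits(truth, "phantom")) truth <- truth$image
  if (length(estimate) != length(truth))
    stop("estimate and truth must share a grid")
  nt <- vec_norm(truth)
  if (nt == 0) stop("zero truth image")
  ne2 <- sum(estimate^2)
  alpha <- if (ne2 > 0) sum(truth * estimate) / ne2 else 0
  err <- vec_norm(truth - alpha * estimate)
  if (err == 0) return(max_db)
  min(20 * log10(nt / err), max_db)
}

#' Transect across a three-bar phantom
#'
#' Extracts the intensity profile perpendicular to the bars of a
#' [make_three_bar()] phantom, averaged over the bars' length, from a
#' reconstruction (or any image on the same grid).  The profile spans the
#' bar group plus one spacing of margin on each side.
#'
#' @param image An `image_estimate`, matrix, or vector.
#' @param phantom The `three_bar` phantom that defines the geometry.
#' @return A list with `profile` (numeric vector), `positions` (pixel
#'   coordinates along the transect) and `bar_centres`.
#' @export
bar_transect <- function(image, phantom) {
  stopifnot(inherits(phantom, "phantom"), phantom$kind == "three_bar")
  g <- phantom$grid
  m <- as_image_matrix(image, g)
  p <- phantom$params
  ctr <- (g$side + 1) / 2
  half_len <- floor(p$bar_length / 2)
  margin <- ceiling(p$bar_spacing)
  lo <- max(1, floor(min(p$bar_centres)) - margin)
  hi <- min(g$side, ceiling(max(p$bar_centres)) + margin)
  if (p$orientation == "V") {
    rows <- round(ctr + p$group_position[2]) + seq(-half_len, half_len)
    rows <- rows[rows >= 1 & rows <= g$side]
    profile <- colMeans(m[rows, lo:hi, drop = FALSE])
  } else {
    cols <- round(ctr + p$group_position[1]) + seq(-half_len, half_len)
    cols <- cols[cols >= 1 & cols <= g$side]
    profile <- rowMeans(m[lo:hi, cols, drop = FALSE])
  }
  list(profile = as.numeric(profile), positions = lo:hi,
       bar_centres = p$bar_centres)
}

#' Count prominent local maxima of a 1-D profile
#'
#' A peak is a strict-left / weak-right local maximum whose topographic
#' prominence (height above the higher of the two flanking valleys, walking
#' out to the nearest higher ground or the profile end) is at least
#' `min_prominence` times the profile's range.  Used to decide whether bar
#' groups are resolved in a reconstruction transect.
#'
#' @param profile Numeric vector.
#' @param min_prominence Minimum prominence as a fraction of
#'   `max(profile) - min(profile)` (default 0.2).
#' @return Integer vector of peak indices (possibly empty).
#' @export
find_peaks <- function(profile, min_prominence = 0.2) {
  n <- length(profile)
  if (n < 3) return(integer(0))
  rng <- diff(range(profile))
  if (rng == 0) return(integer(0))
  cand <- which(diff(sign(diff(profile))) < 0) + 1L
  cand <- cand[profile[cand - 1] < profile[cand]]
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    pk <- cand[i]; h <- profile[pk]
    lmin <- h
    j <- pk
    while (j > 1 && profile[j - 1] <= h) { j <- j - 1; lmin <- min(lmin, profile[j]) }
    if (j == 1) lmin <- min(lmin, profile[1])
    rmin <- h
    j <- pk
    while (j < n && profile[j + 1] <= h) { j <- j + 1; rmin <- min(rmin, profile[j]) }
    if (j == n) rmin <- min(rmin, profile[n])
    prom <- h - max(lmin, rmin)
    keep[i] <- prom >= min_prominence * rng
  }
  cand[keep]
}

#' Are the three bars resolved?
#'
#' Convenience wrapper: extracts the [bar_transect()] of a reconstruction
#' over a three-bar phantom and reports whether exactly three prominent
#' peaks appear, one near each bar centre (within half a bar spacing).
#'
#' @inheritParams bar_transect
#' @param min_prominence Passed to [find_peaks()].
#' @return A list with `resolved` (logical), `n_peaks`, `peak_positions`.
#' @export
bars_resolved <- function(image, phantom, min_prominence = 0.2) {
  tr <- bar_transect(image, phantom)
  pk <- find_peaks(tr$profile, min_prominence)
  pos <- tr$positions[pk]
  half <- phantom$params$bar_spacing / 2
  near <- vapply(tr$bar_centres,
                 function(b) any(abs(pos - b) <= half), logical(1))
  list(resolved = length(pk) == 3 && all(near),
       n_peaks = length(pk), peak_positions = pos)
}
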