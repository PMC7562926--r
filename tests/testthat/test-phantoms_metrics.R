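test_that("knife edge blocks the requested share of illumination", {
  g <- grid_spec(64)
  # area-weighted placement: symmetric at 50%
  ph <- make_knife_edge(g, "H", 0.5)
  expect_equal(ph$params$achieved_fraction, 0.5, tolerance = 1e-6)
  mask <- support_mask(g)
  blocked <- sum((1 - ph$image) * mask) / sum(mask)
  expect_equal(blocked, 0.5, tolerance = 1e-6)

  # stack-weighted placement at the 25% used for the H1/V1 objects
  basis <- build_mode_basis(10, g)
  st <- synthesize_patterns(basis, random_unitary(10, 3))
  for (f in c(0.25, 0.5, 0.75)) {
    phw <- make_knife_edge(g, "V", f, reference_stack = st)
    w <- matrix(colSums(st$patterns), 64, 64)
    expect_equal(sum((1 - phw$image) * w) / sum(w), f, tolerance = 0.01)
  }
})

test_that("H and V knife edges at equal fraction are transposes", {
  g <- grid_spec(64)
  h <- make_knife_edge(g, "H", 0.3)
  v <- make_knife_edge(g, "V", 0.3)
  expect_equal(h$image, t(v$image), tolerance = 1e-12)
})

test_that("degenerate reference stacks are rejected", {
  g <- grid_spec(64)
  zero_stack <- lanternimg:::new_pattern_stack(matrix(0, 2, 64^2), g,
                                               "none", "simulated")
  expect_error(make_knife_edge(g, "H", 0.25, reference_stack = zero_stack),
               "degenerate")
})

test_that("zero-offset cross is 4-fold symmetric; geometry must hit support", {
  g <- grid_spec(65)  # odd side so the centre is a pixel
  ph <- make_offset_cross(g, arm_width = 5, centre_offset = c(0, 0),
                          arm_length = 31)
  expect_equal(ph$image, t(ph$image))
  expect_equal(ph$image, ph$image[65:1, ])
  expect_true(all(ph$image %in% c(0, 1)))
  expect_error(make_offset_cross(g, arm_width = 3,
                                 centre_offset = c(200, 200),
                                 arm_length = 5),
               "outside")
})

test_that("four-dot pixel count tracks the analytic ellipse areas", {
  g <- grid_spec(128)
  centres <- matrix(c(-20, -18, 22, -15, -16, 20, 24, 25), ncol = 2,
                    byrow = TRUE)
  radii <- matrix(c(6, 4, 5, 5, 4, 7, 6, 6), ncol = 2, byrow = TRUE)
  ph <- make_four_dots(g, centres, radii)
  analytic <- sum(pi * radii[, 1] * radii[, 2])
  expect_lt(abs(sum(ph$image) - analytic) / analytic, 0.1)
})

test_that("three-bar phantom has the stated geometry", {
  g <- grid_spec(128)
  ph <- make_three_bar(g, bar_spacing = 10, group_position = c(-8, 4),
                       bar_width = 4, bar_length = 30)
  # transect across the phantom itself shows exactly 3 peaks at the centres
  res <- bars_resolved(ph$image, ph)
  expect_true(res$resolved)
  expect_equal(res$n_peaks, 3)
  # centre-to-centre spacing is exactly 10 px
  expect_equal(diff(ph$params$bar_centres), c(10, 10))
  expect_true(all(ph$image %in% c(0, 1)))
})

test_that("overlap integral is 1 for identical patterns and scale-invariant", {
  g <- grid_spec(32)
  st <- synthesize_patterns(build_mode_basis(5, g), random_unitary(5, 4))
  i1 <- matrix(st$patterns[1, ], 32, 32)
  expect_equal(overlap_integral(i1, i1), 1, tolerance = 1e-14)
  expect_equal(overlap_integral(i1, 7.3 * i1), 1, tolerance = 1e-12)
  # disjoint supports
  a <- matrix(0, 4, 4); a[1, 1] <- 2
  b <- matrix(0, 4, 4); b[4, 4] <- 5
  expect_equal(overlap_integral(a, b), 0)
  expect_error(overlap_integral(a, matrix(0, 4, 4)), "zero-energy")
})

test_that("overlap integral obeys Cauchy-Schwarz and symmetry on random pairs", {
  for (k in 1:100) {
    a <- with_seed_test(1000 + k, matrix(runif(64), 8, 8))
    b <- with_seed_test(2000 + k, matrix(runif(64), 8, 8))
    o <- overlap_integral(a, b)
    expect_gte(o, 0)
    expect_lte(o, 1)
    expect_equal(o, overlap_integral(b, a), tolerance = 1e-14)
    expect_equal(o, overlap_integral(2.5 * a, b), tolerance = 1e-12)
  }
})

test_that("reconstruction SNR has the closed form with least-squares scale", {
  truth <- with_seed_test(5, matrix(runif(64), 8, 8))
  expect_equal(reconstruction_snr(truth, truth), 300)       # capped sentinel
  expect_equal(reconstruction_snr(matrix(0, 8, 8), truth), 0)
  # scale invariance of the estimate
  expect_equal(reconstruction_snr(0.01 * truth, truth), 300)
  # known perturbation: direct evaluation of the definition
  pert <- with_seed_test(6, matrix(rnorm(64, sd = 0.1), 8, 8))
  est <- truth + pert
  alpha <- sum(truth * est) / sum(est^2)
  expected <- 20 * log10(sqrt(sum(truth^2)) /
                         sqrt(sum((truth - alpha * est)^2)))
  expect_equal(reconstruction_snr(est, truth), expected, tolerance = 1e-12)
  expect_error(reconstruction_snr(est, matrix(0, 8, 8)), "zero truth")
})

test_that("peak finding honours the prominence threshold", {
  prof <- c(0, 1, 0, 0.05, 0.1, 0.05, 0, 2, 0)
  expect_equal(find_peaks(prof, min_prominence = 0.2), c(2L, 8L))
  expect_equal(find_peaks(prof, min_prominence = 0.01), c(2L, 5L, 8L))
  expect_equal(length(find_peaks(rep(1, 10))), 0)
})
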