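test_that("Bessel zeros match classical values and drive mode ordering", {
  # classical j_{m,q} values (Abramowitz & Stegun table)
  expect_equal(bessel_zeros(0, 2), c(2.404825557695773, 5.520078110286311),
               tolerance = 1e-10)
  expect_equal(bessel_zeros(1, 1), 3.831705970207512, tolerance = 1e-10)
  expect_equal(bessel_zeros(2, 1), 5.135622301840683, tolerance = 1e-10)

  b <- build_mode_basis(6, grid_spec(64))
  expect_equal(b$modes$m, c(0, 1, 1, 2, 2, 0))
  expect_equal(b$modes$q, c(1, 1, 1, 1, 1, 2))  # (0,1),(1,1)x2,(2,1)x2,(0,2)
  expect_equal(b$modes$parity, c("cos", "cos", "sin", "cos", "sin", "cos"))
  expect_true(!is.unsorted(b$modes$eigenvalue))
})

test_that("lowest mode is azimuthally symmetric with monotone radial decay", {
  g <- grid_spec(65)  # odd side: the grid centre is a pixel centre
  b <- build_mode_basis(1, g)
  f <- matrix(b$fields[1, ], 65, 65)
  expect_true(all(f >= -1e-12))
  # profile along the central row decays monotonically from centre to rim
  prof <- f[33, 33:65]
  expect_true(all(diff(prof) <= 1e-12))
  # near zero at the rim (the last pixel centre sits just inside r = R)
  expect_lt(prof[length(prof)], 0.05 * max(f))
  # azimuthal symmetry: the m = 0 field depends only on radius
  expect_equal(f, t(f), tolerance = 1e-12)
})

test_that("fields vanish outside the support and are unit-normalised", {
  g <- grid_spec(64)
  b <- build_mode_basis(10, g)
  outside <- !as.vector(support_mask(g))
  expect_true(all(abs(b$fields[, outside]) == 0))
  expect_equal(rowSums(b$fields^2), rep(1, 10), tolerance = 1e-12)
})

test_that("discrete Gram matrix approaches identity on fine grids", {
  b <- build_mode_basis(25, grid_spec(256))
  gram <- b$fields %*% t(b$fields)
  expect_lt(max(abs(gram - diag(25))), 1e-2)
  # refining the grid improves orthonormality
  b_coarse <- build_mode_basis(25, grid_spec(128))
  gram_c <- b_coarse$fields %*% t(b_coarse$fields)
  expect_lte(max(abs(gram - diag(25))), max(abs(gram_c - diag(25))))
})

test_that("too coarse a grid for the requested modes errors", {
  expect_error(build_mode_basis(40, grid_spec(8)), "coarse")
})

test_that("degenerate cos/sin pairs are adjacent and share eigenvalues", {
  b <- build_mode_basis(20, grid_spec(64))
  tab <- b$modes
  for (i in which(tab$parity == "sin")) {
    expect_equal(tab$eigenvalue[i], tab$eigenvalue[i - 1])
    expect_equal(tab$m[i], tab$m[i - 1])
    expect_equal(tab$parity[i - 1], "cos")
  }
})

test_that("step-index mode count reproduces the design arithmetic", {
  expect_equal(step_index_mode_count(fiber_spec(35, 0.30, 0.514)), 1029L)
  n63 <- step_index_mode_count(fiber_spec(63, 0.22, 0.488))
  expect_equal(n63, 1990L)
  expect_lt(abs(n63 - 2000) / 2000, 0.01)
  # V ~ 1/lambda so the count falls ~4x when the wavelength doubles
  n1 <- step_index_mode_count(fiber_spec(50, 0.25, 0.5))
  n2 <- step_index_mode_count(fiber_spec(50, 0.25, 1.0))
  expect_lt(abs(n1 / n2 - 4), 0.01 * 4)
})

test_that("required NA inverts the mode count and flags infeasible cores", {
  expect_equal(required_na(35, 0.514, 1089), 0.3085, tolerance = 1e-3)
  expect_equal(required_na(63, 0.488, 2000), 0.2205, tolerance = 1e-3)
  for (n in c(100, 1089, 2000)) {
    na <- required_na(40, 0.5, n)
    expect_gte(step_index_mode_count(fiber_spec(40, na, 0.5)), n - 1)
  }
  expect_error(required_na(2, 0.5, 1000), "infeasible")
})

test_that("Rayleigh resolution and facet feature spacing evaluate correctly", {
  expect_equal(rayleigh_resolution(0.488, 0.22), 1.3531, tolerance = 1e-4)
  expect_equal(rayleigh_resolution(0.514, 0.22), 1.4251, tolerance = 1e-4)
  expect_equal(rayleigh_resolution(0.5, 0.4), rayleigh_resolution(0.5, 0.2) / 2)
  expect_equal(feature_spacing(63, 2000), 1.2485, tolerance = 1e-3)
  expect_equal(feature_spacing(63, 8000), 0.6242, tolerance = 1e-3)
  expect_equal(feature_spacing(10, 1), sqrt(pi) * 5)
})
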