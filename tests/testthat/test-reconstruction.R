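test_that("reweighting has the Candes form and properties", {
  c0 <- c(0, 1, 2, 10)
  expect_equal(reweight(c0, 1), c(1, 0.5, 1 / 3, 1 / 11))
  expect_equal(reweight(rep(0, 5), 2), rep(1, 5))
  expect_equal(reweight(3, 3), 0.5)
  cs <- with_seed_test(1, rnorm(100))
  w <- reweight(cs, 0.7)
  expect_true(all(w > 0 & w <= 1))
  ord <- order(abs(cs))
  expect_true(all(diff(w[ord]) <= 1e-15))   # non-increasing in |c|
  # idempotent at a fixed point: same coefficients give same weights
  expect_identical(reweight(cs, 0.7), w)
})

test_that("identity operator with a point fidelity set returns the data", {
  side <- 8
  st <- identity_stack(side)
  op <- build_operator(st)
  model <- build_sparsity_model(st$grid, 3)
  y <- with_seed_test(2, runif(side^2))
  ms <- manual_measurements(y, epsilon = 0)
  est <- solve_sara(ms, op, model,
                    solver_config(n_reweights = 1, max_iter = 4000,
                                  rel_tol = 1e-9))
  expect_equal(as.vector(est$x), y, tolerance = 1e-5)
  expect_true(all(est$x >= 0))
})

test_that("a fidelity ball containing zero yields the zero image", {
  st <- random_stack(6, 8, seed = 3)
  op <- build_operator(st)
  model <- build_sparsity_model(st$grid, 3)
  y <- rep(1e-4, 6)
  ms <- manual_measurements(y, epsilon = 1)  # ||y|| << eps
  est <- solve_sara(ms, op, model, solver_config(n_reweights = 1,
                                                 max_iter = 100))
  expect_equal(max(abs(est$x)), 0)
})

test_that("solution matches an independent ADMM oracle on small instances", {
  for (seed in c(5, 17)) {
    side <- 8
    np <- 12
    st <- random_stack(np, side, seed = seed)
    op <- build_operator(st)
    model <- build_sparsity_model(st$grid, 3)
    x0 <- matrix(0, side, side)
    x0[3, 4] <- 1
    x0[6, 6] <- 0.5
    ms <- simulate_measurements(op, x0)
    cfg <- solver_config(n_reweights = 1, max_iter = 20000, rel_tol = 1e-10)
    est <- solve_sara(ms, op, model, cfg)
    psi <- dense_analysis_matrix(model)
    xo <- oracle_admm(ms$y, st$patterns, psi, ms$epsilon)
    expect_lt(sqrt(sum((as.vector(est$x) - xo)^2)) / sqrt(sum(xo^2)), 1e-3)
  }
})

test_that("reweighting recovers a 1-sparse object exactly from 12 patterns", {
  st <- random_stack(12, 8, seed = 42)
  op <- build_operator(st)
  model <- build_sparsity_model(st$grid, 3)
  x0 <- matrix(0, 8, 8)
  x0[4, 5] <- 1
  ms <- simulate_measurements(op, x0)
  est <- solve_sara(ms, op, model,
                    solver_config(n_reweights = 5, max_iter = 2000,
                                  rel_tol = 1e-7))
  expect_true(est$converged)
  expect_equal(which(est$x > 1e-3), which(x0 == 1))
  expect_lt(max(abs(est$x - x0)), 1e-3)
})

test_that("exit iterate is feasible and positive; traces are recorded", {
  st <- random_stack(10, 8, seed = 6)
  op <- build_operator(st)
  model <- build_sparsity_model(st$grid, 3)
  x0 <- with_seed_test(7, matrix(runif(64) * (runif(64) < 0.2), 8, 8))
  ms <- simulate_measurements(op, x0, isnr_db = 40, seed = 8)
  est <- solve_sara(ms, op, model, solver_config(n_reweights = 3,
                                                 max_iter = 2000))
  expect_true(all(est$x >= 0))
  expect_lte(est$final_residual, ms$epsilon * 1.1 + 1e-12)
  expect_gt(length(est$objective_trace), 0)
  expect_equal(length(est$objective_trace), length(est$feasibility_trace))
})

test_that("misconfigured step sizes violate the convergence condition", {
  st <- random_stack(4, 8, seed = 9)
  op <- build_operator(st)
  model <- build_sparsity_model(st$grid, 3)
  ms <- manual_measurements(rep(0.1, 4), epsilon = 0.01)
  expect_error(
    solve_sara(ms, op, model, solver_config(tau = 10, sigma_phi = 1)),
    "convergence condition")
})

test_that("ghost estimator is the measurement-pattern covariance image", {
  st <- random_stack(2, 8, seed = 10)
  ms <- manual_measurements(c(0, 1), epsilon = 0.01)
  gh <- solve_ghost(ms, st)
  expect_equal(as.vector(gh$x),
               as.vector((st$patterns[2, ] - st$patterns[1, ]) / 4),
               tolerance = 1e-14)
  # constant readings carry no information
  msc <- manual_measurements(rep(2, 2), epsilon = 0.01)
  expect_equal(max(abs(solve_ghost(msc, st)$x)), 0)
  # degenerate statistics
  st1 <- random_stack(1, 8, seed = 11)
  expect_error(solve_ghost(manual_measurements(1, 0.1), st1), "at least 2")
})

test_that("ghost and constrained estimates treat unilluminated corners differently", {
  g <- grid_spec(32)
  basis <- build_mode_basis(6, g)
  st <- synthesize_patterns(basis, random_unitary(6, 12))
  op <- build_operator(st)
  ph <- make_offset_cross(g, arm_width = 3, centre_offset = c(-3, 2),
                          arm_length = 14)
  ms <- simulate_measurements(op, ph)
  model <- build_sparsity_model(g, 4)
  sara <- solve_sara(ms, op, model,
                     solver_config(n_reweights = 2, max_iter = 1500))
  gh <- solve_ghost(ms, st)
  corner <- cbind(c(1, 1, 32, 32), c(1, 32, 1, 32))
  # corners are outside every pattern: (numerically) zero after display
  # normalisation from the constrained solver, mid-scale grey from ghost
  # imaging, whose covariance image is signed around its own mid-level
  sd_ <- display_normalize(sara)
  expect_true(all(sd_[corner] <= 0.02))
  gd <- display_normalize(gh)
  expect_true(all(gd[corner] > 0.05 & gd[corner] < 0.95))
})
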