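#' Solver configuration for the reweighted-l1 reconstruction
#'
#' Parameters of the primal-dual forward-backward (Condat-Vu) solver and the
#' reweighting schedule.  Defaults left `NULL` are derived from the problem:
#' `sigma_phi = 256 / ||Phi||^2` (preconditioning the fidelity dual block —
#' unit-sum patterns make `||Phi||` orders of magnitude smaller than
#' `||Psi|| = 1`, and the tight noiseless fidelity ball converges much
#' faster when its dual ascent is weighted up), and
#' `tau = 0.98 / (sigma_psi * ||Psi||^2 + sigma_phi * ||Phi||^2)`, which
#' satisfies the convergence condition
#' `tau * (sigma_psi ||Psi||^2 + sigma_phi ||Phi||^2) <= 1` with margin.
#'
#' @param tau Primal step (NULL = auto).
#' @param sigma_psi Dual step for the sparsity block (default 1).
#' @param sigma_phi Dual step for the fidelity block (NULL = auto).
#' @param max_iter Maximum inner iterations per reweighting round.
#' @param rel_tol Relative-change stopping tolerance for the inner loop.
#' @param feas_tol Relative fidelity slack accepted at exit: the solution
#'   must satisfy `||y - Phi x||_2 <= epsilon * (1 + feas_tol)`.
#' @param n_reweights Number of outer rounds (the first solves the
#'   unweighted problem; each later round reweights by the previous
#'   solution's analysis coefficients).
#' @param delta0 Initial reweighting scale (NULL = standard deviation of the
#'   first solution's analysis coefficients).
#' @param delta_decay Multiplicative decay of the scale per round.
#' @param delta_min Floor for the scale (NULL = 1e-8 * max |coefficient|).
#' @param patience Iterations without relative feasibility-gap improvement
#'   after which the problem is declared infeasible.
#' @param trace_every Record objective/feasibility traces every this many
#'   iterations.
#' @return A `solver_config` list.
#' @export
solver_config <- function(tau = NULL, sigma_psi = 1, sigma_phi = NULL,
                          max_iter = 5000, rel_tol = 1e-5, feas_tol = 0.1,
                          n_reweights = 5, delta0 = NULL,
                          delta_decay = 0.316, delta_min = NULL,
                          patience = 1000, trace_every = 25) {
  stopifnot(sigma_psi > 0, max_iter >= 1, rel_tol > 0, feas_tol > 0,
            n_reweights >= 1, delta_decay > 0, delta_decay < 1,
            patience >= 10)
  structure(list(tau = tau, sigma_psi = sigma_psi, sigma_phi = sigma_phi,
                 max_iter = max_iter, rel_tol = rel_tol,
                 feas_tol = feas_tol, n_reweights = n_reweights,
                 delta0 = delta0, delta_decay = delta_decay,
                 delta_min = delta_min, patience = patience,
                 trace_every = trace_every),
            class = "solver_config")
}

#' Candes-style reweighting of analysis coefficients
#'
#' `Omega_i = delta / (delta + |c_i|)`: weights are 1 where a coefficient is
#' (near) zero and shrink toward 0 for large coefficients, so that
#' successive weighted l1 problems approximate l0 sparsity ever better.
#'
#' @param coefficients Analysis coefficient vector.
#' @param delta Positive scale of the reweighting.
#' @return Weight vector with entries in (0, 1].
#' @export
reweight <- function(coefficients, delta) {
  stopifnot(delta > 0)
  delta / (delta + abs(coefficients))
}

proj_l2_ball <- function(z, centre, radius) {
  d <- z - centre
  nd <- vec_norm(d)
  if (nd <= radius || nd == 0) z else centre + d * (radius / nd)
}

new_image_estimate <- function(x, method, epsilon, iterations,
                               objective_trace, feasibility_trace,
                               converged, final_residual) {
  structure(list(x = x, method = method, epsilon = epsilon,
                 iterations = iterations,
                 objective_trace = objective_trace,
                 feasibility_trace = feasibility_trace,
                 converged = converged, final_residual = final_residual),
            class = "image_estimate")
}

#' @export
print.image_estimate <- function(x, ...) {
  cat(sprintf(
    "<image_estimate> %s, %d x %d, %d iterations, residual %.4g (eps %.4g)\n",
    x$method, nrow(x$x), ncol(x$x), x$iterations, x$final_residual,
    x$epsilon))
  invisible(x)
}

#' @export
as.matrix.image_estimate <- function(x, ...) x$x

#' Display an image estimate, phantom, or pattern
#'
#' @param x An `image_estimate`.
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @export
plot.image_estimate <- function(x, main = x$method, ...) {
  plot_image_matrix(x$x, main = main, ...)
}

plot_image_matrix <- function(m, main = "", ...) {
  graphics::image(t(m)[, rev(seq_len(nrow(m)))], col = grDevices::gray.colors(256),
                  axes = FALSE, asp = 1, main = main, ...)
  invisible(NULL)
}

#' Reconstruct by sparsity-averaging reweighted-l1 analysis
#'
#' Solves the constrained problem: minimise `||Omega Psi x||_1` subject to
#' `x >= 0` and `||y - Phi x||_2 <= epsilon`, where `Psi` is the nine-basis
#' tight-frame dictionary and `Omega` a diagonal weight matrix, by a
#' primal-dual forward-backward (Condat-Vu) iteration with two dual blocks:
#'
#' * primal: positivity projection of a proximal gradient-free step,
#'   `x <- max(x - tau (Psi' v1 + Phi' v2), 0)`;
#' * sparsity dual: the proximity map of the conjugate of the weighted l1
#'   norm, i.e. clipping to `[-Omega, Omega]`;
#' * fidelity dual: the proximity map of the conjugate of the l2-ball
#'   indicator (Moreau complement of the ball projection).
#'
#' The outer loop performs `n_reweights` rounds: after each round the
#' weights are recomputed from the current solution's analysis coefficients
#' as `delta / (delta + |c|)` with `delta` decayed geometrically down to a
#' floor.  Initialisation is `x = 0` with zero dual variables, so the result
#' is deterministic given the inputs.
#'
#' @param measurements A `measurement_set` (carries `y` and `epsilon`).
#' @param op A [build_operator()] result.
#' @param model A [build_sparsity_model()] on the same grid.
#' @param config A [solver_config()].
#' @return An `image_estimate`: nonnegative image with
#'   `||y - Phi x||_2 <= epsilon * (1 + feas_tol)` at exit, plus objective
#'   and feasibility traces and the iteration count.
#' @export
solve_sara <- function(measurements, op, model, config = solver_config()) {
  stopifnot(inherits(measurements, "measurement_set"),
            inherits(op, "measurement_operator"),
            inherits(model, "sparsity_model"))
  if (op$np != measurements$np)
    stop("measurement count does not match the operator")
  if (model$n != op$n) stop("sparsity model grid does not match the operator")
  y <- measurements$y
  eps <- measurements$epsilon
  cfg <- config
  phi_ns <- op$operator_norm_sq
  sigma_psi <- cfg$sigma_psi
  sigma_phi <- cfg$sigma_phi %||% (256 / phi_ns)
  tau <- cfg$tau %||% (0.98 / (sigma_psi * model$norm_sq + sigma_phi * phi_ns))
  if (tau * (sigma_psi * model$norm_sq + sigma_phi * phi_ns) > 1 + 1e-12)
    stop("configuration violates the convergence condition ",
         "tau*(sigma_psi*||Psi||^2 + sigma_phi*||Phi||^2) <= 1")

  side <- model$grid$side
  # absolute slack so that eps = 0 (single-point feasible set) terminates
  # once the residual is at numerical noise level
  feas_abs <- 1e-9 * max(vec_norm(y), .Machine$double.eps)
  x <- matrix(0, side, side)
  v1 <- numeric(model$L)
  v2 <- numeric(op$np)
  omega <- rep(1, model$L)
  obj_trace <- numeric(0)
  feas_trace <- numeric(0)
  total_iter <- 0L
  delta <- NULL
  delta_min <- cfg$delta_min

  for (round in seq_len(cfg$n_reweights)) {
    best_gap <- Inf
    best_gap_iter <- 0L
    for (it in seq_len(cfg$max_iter)) {
      g <- model$synthesis(v1) + op$adjoint(v2)
      x_new <- pmax(x - tau * g, 0)
      xbar <- 2 * x_new - x
      p <- v1 + sigma_psi * model$analysis(xbar)
      v1 <- pmin(pmax(p, -omega), omega)
      q <- v2 + sigma_phi * op$apply(xbar)
      v2 <- q - sigma_phi * proj_l2_ball(q / sigma_phi, y, eps)
      rel <- vec_norm(x_new - x) / max(vec_norm(x_new), .Machine$double.eps)
      x <- x_new
      total_iter <- total_iter + 1L
      check <- (it %% cfg$trace_every == 0L) || rel < cfg$rel_tol ||
               it == cfg$max_iter
      if (check) {
        resid <- vec_norm(y - op$apply(x))
        gap <- max(0, resid - eps)
        if (it %% cfg$trace_every == 0L) {
          obj_trace <- c(obj_trace, sum(omega * abs(model$analysis(x))))
          feas_trace <- c(feas_trace, resid)
        }
        if (gap < best_gap * (1 - 1e-3)) {
          best_gap <- gap
          best_gap_iter <- it
        }
        feasible <- resid <= eps * (1 + cfg$feas_tol) + feas_abs
        if (rel < cfg$rel_tol && feasible && it > 1) break
        if (!feasible && it - best_gap_iter > cfg$patience &&
            best_gap > eps * cfg$feas_tol)
          stop(sprintf(paste(
            "infeasible fidelity bound: residual %.4g stalled above",
            "epsilon %.4g for %d iterations"), resid, eps, cfg$patience))
      }
    }
    if (round < cfg$n_reweights) {
      coefs <- model$analysis(x)
      if (is.null(delta)) {
        delta <- cfg$delta0 %||% stats::sd(coefs)
        if (delta <= 0) delta <- 1
      } else {
        delta <- delta * cfg$delta_decay
      }
      if (is.null(delta_min)) delta_min <- 1e-8 * max(abs(coefs), 1e-300)
      delta <- max(delta, delta_min)
      omega <- reweight(coefs, delta)
      v1 <- pmin(pmax(v1, -omega), omega)  # warm start stays dual-feasible
    }
  }
  resid <- vec_norm(y - op$apply(x))
  new_image_estimate(x, "sara", eps, total_iter, obj_trace, feas_trace,
                     converged = resid <= eps * (1 + cfg$feas_tol) + feas_abs,
                     final_residual = resid)
}

#' Classical ghost-imaging reconstruction
#'
#' The prior-free correlation estimator: each pattern, weighted by its
#' mean-subtracted reading, is accumulated into the image,
#' `x = (1/Np) * sum_p (y_p - mean(y)) * pattern_p` — the covariance image
#' between readings and patterns.  No positivity or sparsity prior is
#' applied, so values may be negative; regions outside every pattern's
#' support receive exactly 0, which min-max display normalisation then maps
#' to a mid-scale grey (whereas the constrained reconstruction assigns true
#' zeros there).
#'
#' @param measurements A `measurement_set`.
#' @param stack The `pattern_stack` the measurements were made with.
#' @return An `image_estimate` with method `"ghost"`.
#' @export
solve_ghost <- function(measurements, stack) {
  stopifnot(inherits(measurements, "measurement_set"),
            inherits(stack, "pattern_stack"))
  if (stack$np != measurements$np)
    stop("measurement count does not match the stack")
  if (stack$np < 2)
    stop("ghost imaging needs at least 2 patterns (degenerate statistics)")
  y <- measurements$y
  xv <- as.vector(crossprod(stack$patterns, y - mean(y))) / stack$np
  x <- matrix(xv, stack$grid$side, stack$grid$side)
  new_image_estimate(x, "ghost", measurements$epsilon, 1L,
                     numeric(0), numeric(0), converged = TRUE,
                     final_residual = NA_real_)
}

#' Min-max display normalisation
#'
#' Maps an image linearly to `[0, 1]` for publication-style display; a
#' constant image maps to 0.
#'
#' @param x Matrix, `image_estimate`, or `phantom`.
#' @return A matrix with values in `[0, 1]`.
#' @export
display_normalize <- function(x) {
  if (inherits(x, "image_estimate")) x <- x$x
  if (inherits(x, "phantom")) x <- x$image
  rng <- range(x)
  if (rng[2] == rng[1]) return(matrix(0, nrow(x), ncol(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}
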