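# Bracket terms of the replicator system.
#
# Every mechanism's right-hand side factors as
#   dx/dt = x (1 - x) * A(x, y),   dy/dt = y (1 - y) * B(x)
# with A(x, y) = (P + S) y - C - dL - kappa x y  and B a quadratic in x.
# kappa and the quadratic coefficients depend only on the mechanism:
#   static          kappa = 0      B = -(P+S) x + (P - I)
#   dynamic_penalty kappa = P      B = P x^2 - (2P+S) x + (P - I)
#   dynamic_reward  kappa = S      B = S x^2 - (P+S) x + (P - I)
#   dynamic_both    kappa = P + S  B = (P+S) x^2 - (2P+S) x + (P - I)
# These are exactly the forms obtained by substituting the effective
# incentives into the payoff differences.
rhs_coefficients <- function(params, mechanism) {
  mechanism <- match_mechanism(mechanism)
  P <- params$P
  S <- params$S
  kappa <- switch(mechanism,
    static = 0,
    dynamic_penalty = P,
    dynamic_reward = S,
    dynamic_both = P + S
  )
  b2 <- switch(mechanism,
    static = 0,
    dynamic_penalty = P,
    dynamic_reward = S,
    dynamic_both = P + S
  )
  b1 <- switch(mechanism,
    static = -(P + S),
    dynamic_penalty = -(2 * P + S),
    dynamic_reward = -(P + S),
    dynamic_both = -(2 * P + S)
  )
  list(kappa = kappa, b2 = b2, b1 = b1, b0 = P - params$I)
}

# Common positive rescaling of all payoff parameters: leaves the direction
# field (and every equilibrium) unchanged, divides time by `scale`.
rescale_params <- function(params, threshold = 100) {
  scale <- max(abs(c(params$S, params$P, params$I, params$C, params$dL)))
  if (scale <= threshold) {
    return(list(params = params, scale = 1))
  }
  sp <- params
  for (nm in c("S", "P", "I", "C", "dL", "L", "G1")) {
    sp[[nm]] <- sp[[nm]] / scale
  }
  list(params = sp, scale = scale)
}

# A(x, y) and B(x) evaluated at a state.
rhs_brackets <- function(x, y, params, mechanism) {
  co <- rhs_coefficients(params, mechanism)
  A <- (params$P + params$S) * y - params$C - params$dL - co$kappa * x * y
  B <- co$b2 * x^2 + co$b1 * x + co$b0
  c(A = A, B = B)
}

#' Replicator-dynamics right-hand side
#'
#' Evaluates the growth rates of the two strategy frequencies. For every
#' mechanism the institution equation is
#' `dx/dt = x (1 - x) (E_PY - E_PN)` and the government equation
#' `dy/dt = y (1 - y) (E_GY - E_GN)`, with the expected payoffs built from
#' that mechanism's effective incentives. Under the static mechanism this
#' reduces to `x (1 - x) [(S + P) y - C - dL]` and
#' `y (1 - y) [P - I - x (S + P)]`.
#'
#' @inheritParams expected_payoffs
#' @return Named numeric vector `c(dx_dt, dy_dt)`.
#' @export
#' @examples
#' p <- game_params(S = 1, P = 1.5, I = 2, C = 1, dL = 4)
#' replicator_rhs(0.5, 0.5, p, "static")
replicator_rhs <- function(x, y, params, mechanism = "static") {
  st <- check_state(x, y)
  x <- st[["x"]]
  y <- st[["y"]]
  br <- rhs_brackets(x, y, params, mechanism)
  c(
    dx_dt = x * (1 - x) * br[["A"]],
    dy_dt = y * (1 - y) * br[["B"]]
  )
}

#' Solver configuration for trajectory integration
#'
#' @param method `deSolve` integration method; the default is the adaptive
#'   explicit Runge-Kutta 4(5) pair (Dormand-Prince). Closed orbits of the
#'   static center regime show visible first-integral drift at loose
#'   tolerances, hence the tight defaults.
#' @param rtol,atol Relative/absolute solver tolerances.
#' @param n_out Number of equally spaced output samples (the solver steps
#'   adaptively in between).
#' @param clamp_tol States within this distance outside `[0, 1]` are treated
#'   as round-off and clamped; larger excursions raise an error (solver
#'   failure).
#' @return A list of class `"solver_cfg"`.
#' @export
solver_cfg <- function(method = "ode45", rtol = 1e-9, atol = 1e-12,
                       n_out = 2000, clamp_tol = 1e-8) {
  stopifnot(rtol > 0, atol > 0, n_out >= 2, clamp_tol >= 0)
  structure(
    list(
      method = method, rtol = rtol, atol = atol,
      n_out = as.integer(n_out), clamp_tol = clamp_tol
    ),
    class = "solver_cfg"
  )
}

#' Integrate a replicator trajectory
#'
#' Integrates the replicator system from an initial state. Parameter sets
#' with large currency magnitudes (such as per-institution yuan amounts in
#' the hundreds of thousands) are rescaled by the largest of
#' `S, P, I, C, dL` before integration; replicator direction fields are
#' invariant under a common positive rescaling of payoffs, which only
#' rescales time. The returned trajectory reports both the integration time
#' `t` (rescaled units) and the original model time `t_model = t / scale`.
#'
#' @inheritParams effective_incentives
#' @param init Numeric `c(x, y)` initial state in `[0, 1]^2`.
#' @param t_end Integration horizon in (rescaled) model time, > 0.
#' @param cfg A [solver_cfg()].
#' @param scale_threshold Parameter magnitude above which rescaling kicks in.
#' @return An object of class `"trajectory"`: a data frame with columns
#'   `t`, `t_model`, `x`, `y` plus attributes `params`, `mechanism`, `init`
#'   and `scale`.
#' @export
#' @examples
#' p <- game_params(S = 1, P = 1.5, I = 2, C = 1, dL = 4)
#' tr <- integrate_trajectory(p, "static", init = c(0.5, 0.5), t_end = 50)
#' tail(tr, 1)
integrate_trajectory <- function(params, mechanism = "static",
                                 init = c(0.5, 0.5), t_end = 500,
                                 cfg = solver_cfg(),
                                 scale_threshold = 100) {
  stopifnot(inherits(params, "game_params"), length(init) == 2, t_end > 0)
  mechanism <- match_mechanism(mechanism)
  st <- check_state(init[1], init[2])

  rs <- rescale_params(params, scale_threshold)
  sp <- rs$params
  scale <- rs$scale

  deriv <- function(t, state, parms) {
    x <- min(max(state[1], 0), 1)
    y <- min(max(state[2], 0), 1)
    br <- rhs_brackets(x, y, sp, mechanism)
    list(c(x * (1 - x) * br[["A"]], y * (1 - y) * br[["B"]]))
  }

  times <- seq(0, t_end, length.out = cfg$n_out)
  sol <- deSolve::ode(
    y = c(x = st[["x"]], y = st[["y"]]), times = times, func = deriv,
    parms = NULL, method = cfg$method, rtol = cfg$rtol, atol = cfg$atol
  )
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(times)) {
    stop(sprintf(
      "solver failed at t = %g (of %g)", sol[nrow(sol), "time"], t_end
    ))
  }
  xs <- sol[, "x"]
  ys <- sol[, "y"]
  worst <- max(0, -min(xs), max(xs) - 1, -min(ys), max(ys) - 1)
  if (worst > cfg$clamp_tol) {
    stop(sprintf(
      "solver left the unit square by %.3g (clamp_tol %.3g)",
      worst, cfg$clamp_tol
    ))
  }
  traj <- data.frame(
    t = sol[, "time"],
    t_model = sol[, "time"] / scale,
    x = pmin(pmax(xs, 0), 1),
    y = pmin(pmax(ys, 0), 1)
  )
  structure(
    traj,
    params = params, scaled_params = sp, mechanism = mechanism,
    init = c(x = st[["x"]], y = st[["y"]]), scale = scale,
    class = c("trajectory", "data.frame")
  )
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf(
    "Replicator trajectory (%s mechanism): %d samples, t in [%g, %g]\n",
    attr(x, "mechanism"), n, x$t[1], x$t[n]
  ))
  if (attr(x, "scale") != 1) {
    cat(sprintf(
      "  payoffs rescaled by %g; model time t_model = t / %g\n",
      attr(x, "scale"), attr(x, "scale")
    ))
  }
  cat(sprintf(
    "  start (%.4f, %.4f) -> end (%.6f, %.6f)\n",
    x$x[1], x$y[1], x$x[n], x$y[n]
  ))
  invisible(x)
}

#' Assess convergence of a trajectory
#'
#' A trajectory is `converged` when the right-hand side at the final state
#' and the state movement over the trailing window (last 5% of samples) are
#' both below `tol`; the limit point is then the final state. A
#' non-convergent trajectory is flagged `oscillatory` when it keeps moving
#' but recurrently re-enters a neighbourhood of an earlier state, the
#' signature of the closed orbits around the static center.
#'
#' @param traj A `"trajectory"`.
#' @param tol Convergence tolerance on the residual and trailing movement.
#' @return List with `converged`, `oscillatory`, `limit_point` (or `NULL`),
#'   and `residual` (max abs RHS component at the final state, in the
#'   rescaled units used for integration).
#' @export
assess_convergence <- function(traj, tol = 1e-6) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj)
  if (n < 2) stop("trajectory must have at least 2 points")
  sp <- attr(traj, "scaled_params")
  mech <- attr(traj, "mechanism")
  rhs_end <- replicator_rhs(traj$x[n], traj$y[n], sp, mech)
  residual <- max(abs(rhs_end))

  win <- max(2, ceiling(0.05 * n))
  idx <- seq.int(n - win + 1, n)
  movement <- max(
    diff(range(traj$x[idx])),
    diff(range(traj$y[idx]))
  )

  converged <- residual < tol && movement < tol
  oscillatory <- FALSE
  if (!converged) {
    # Recurrence: the distance to the initial state must fall back below a
    # fraction of its maximal excursion after first exceeding it.
    d <- sqrt((traj$x - traj$x[1])^2 + (traj$y - traj$y[1])^2)
    dmax <- max(d)
    if (dmax > tol) {
      # first time the excursion nears its maximum (the global argmax may
      # sit in the last of several cycles, after the final return)
      i_far <- which(d >= 0.9 * dmax)[1]
      returns <- if (i_far < n) min(d[(i_far + 1):n]) else Inf
      oscillatory <- is.finite(returns) && returns < 0.25 * dmax
    }
  }
  list(
    converged = converged,
    oscillatory = oscillatory,
    limit_point = if (converged) c(x = traj$x[n], y = traj$y[n]) else NULL,
    residual = residual
  )
}

#' Write / read a trajectory as CSV
#'
#' The CSV has header `t,x,y` (integration-time units) with one row per
#' saved sample at full double precision, rows in time order.
#'
#' @param traj A `"trajectory"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  lines <- c(
    "t,x,y",
    sprintf("%.17g,%.17g,%.17g", traj$t, traj$x, traj$y)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @return For `read_trajectory_csv`, a data frame with columns `t, x, y`.
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}
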