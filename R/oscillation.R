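#' Linearization constants at the static center
#'
#' In the center regime (`P > max(I, C + dL - S)`) the static interior
#' equilibrium has Jacobian `[[0, tau1], [tau2, 0]]` with
#' `tau1 = (I + S)(P - I)/(P + S) > 0` and
#' `tau2 = (C + dL)(C + dL - P - S)/(P + S) < 0`, giving purely imaginary
#' characteristic roots and angular frequency `omega = sqrt(|tau1 tau2|)`.
#' Nearby orbits are approximated by a harmonic oscillation of amplitude
#' `Am = sqrt((x0 - x*)^2 + (y0 - y*)^2)` and phase `phi`, where `phi` is
#' the arctangent of `(y0 - y*)/(x0 - x*)`, shifted by `pi` when that ratio's
#' product term `(y0 - y*)(x0 - x*)` is non-positive.
#'
#' @param params A `"game_params"` object in the center regime.
#' @param init Numeric `c(x, y)` interior initial state.
#' @return List of class `"center_constants"`: `tau1`, `tau2`, `omega`,
#'   `period` (`2*pi/omega`), `Am`, `phi`, `center` (the interior point) and
#'   `eigenvalues`.
#' @export
#' @examples
#' p <- game_params(S = 3, P = 9, I = 3, C = 1, dL = 4)
#' center_constants(p, init = c(0.55, 0.45))
center_constants <- function(params, init = c(0.5, 0.5)) {
  if (classify_static_regime(params) != "CENTER") {
    stop("center analysis requires the static CENTER regime")
  }
  st <- check_state(init[1], init[2])
  x0 <- st[["x"]]
  y0 <- st[["y"]]
  if (x0 <= 0 || x0 >= 1 || y0 <= 0 || y0 >= 1) {
    stop("init must be strictly interior")
  }
  PS <- params$P + params$S
  CD <- params$C + params$dL
  tau1 <- (params$I + params$S) * (params$P - params$I) / PS
  tau2 <- CD * (CD - PS) / PS
  omega <- sqrt(abs(tau1 * tau2))
  ctr <- interior_closed_form(params, "static")
  dx <- x0 - ctr[["x"]]
  dy <- y0 - ctr[["y"]]
  Am <- sqrt(dx^2 + dy^2)
  phi <- if (Am == 0) {
    0
  } else if (dy * dx > 0) {
    atan(dy / dx)
  } else {
    pi + atan(if (dx == 0) Inf * sign(dy) else dy / dx)
  }
  structure(
    list(
      tau1 = tau1, tau2 = tau2, omega = omega, period = 2 * pi / omega,
      Am = Am, phi = phi, center = ctr,
      eigenvalues = complex(real = 0, imaginary = c(omega, -omega))
    ),
    class = "center_constants"
  )
}

#' @export
print.center_constants <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Center at (%.6g, %.6g): tau1 = %.6g, tau2 = %.6g\n",
      "  omega = %.6g (linearized period %.6g), Am = %.6g, phi = %.6g\n"
    ),
    x$center[1], x$center[2], x$tau1, x$tau2,
    x$omega, x$period, x$Am, x$phi
  ))
  invisible(x)
}

#' Linearized closed orbit around the static center
#'
#' Samples the harmonic approximation
#' `x(t) = x* + Am cos(omega t + phi)`, `y(t) = y* + Am cos(omega t + phi)`
#' at the given times. This is a first-order approximation valid near the
#' center, held to amplitude and period accuracy only: the exact linearized
#' flow keeps `x` and `y` a quarter period out of phase, which the shared
#' cosine cannot represent.
#'
#' @param constants A `"center_constants"` object.
#' @param times Numeric vector of sample times.
#' @return Data frame with columns `t`, `x`, `y`.
#' @export
orbit_linearized <- function(constants, times) {
  stopifnot(inherits(constants, "center_constants"))
  ph <- constants$omega * times + constants$phi
  data.frame(
    t = times,
    x = constants$center[["x"]] + constants$Am * cos(ph),
    y = constants$center[["y"]] + constants$Am * cos(ph)
  )
}

#' First integral of the static replicator system
#'
#' `H(x, y) = (P - I) log x + (S + I) log(1 - x) + (C + dL) log y +
#' (S + P - C - dL) log(1 - y)` is constant along interior trajectories of
#' the static system (its gradient is orthogonal to the flow), and its level
#' sets are the closed orbits of the center regime. The center is a
#' stationary point of `H`.
#'
#' @inheritParams expected_payoffs
#' @param params A `"game_params"` object.
#' @return The scalar value of `H`.
#' @export
#' @examples
#' p <- game_params(S = 3, P = 9, I = 3, C = 1, dL = 4)
#' first_integral(0.4, 0.5, p)
first_integral <- function(x, y, params) {
  if (any(x <= 0 | x >= 1 | y <= 0 | y >= 1)) {
    stop("first integral requires a strictly interior state")
  }
  (params$P - params$I) * log(x) +
    (params$S + params$I) * log(1 - x) +
    (params$C + params$dL) * log(y) +
    (params$S + params$P - params$C - params$dL) * log(1 - y)
}

#' Detect a closed orbit and estimate its period
#'
#' Scans a trajectory for a first return to its initial state: the distance
#' to the initial state must fall below `tol` after first travelling away.
#' The return time is refined by parabolic interpolation of the squared
#' distance. Near the center, the estimated period approaches the
#' linearized period `2 pi / omega` as the amplitude shrinks.
#'
#' @param traj A `"trajectory"`.
#' @param tol Distance at which a state counts as a return.
#' @return List with `is_closed` and `estimated_period` (`NA` when not
#'   closed, or when the orbit has essentially zero excursion).
#' @export
verify_periodicity <- function(traj, tol = 1e-3) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj)
  if (n < 10) stop("trajectory too short to assess periodicity")
  d2 <- (traj$x - traj$x[1])^2 + (traj$y - traj$y[1])^2
  dmax <- sqrt(max(d2))
  if (dmax < tol) {
    # never leaves the tol-ball: a degenerate (zero-excursion) closed orbit
    return(list(is_closed = TRUE, estimated_period = NA_real_))
  }
  away <- which(sqrt(d2) > 0.5 * dmax)[1]
  if (is.na(away) || away >= n) {
    return(list(is_closed = FALSE, estimated_period = NA_real_))
  }
  # local minima of d^2 after travelling away, refined parabolically (the
  # continuous orbit passes between samples, so the sampled minimum
  # overestimates the true return distance)
  idx <- seq.int(away + 1, n - 1)
  loc <- idx[d2[idx] < d2[idx - 1] & d2[idx] <= d2[idx + 1]]
  for (i in loc) {
    denom <- d2[i - 1] - 2 * d2[i] + d2[i + 1]
    if (denom > 0) {
      s <- 0.5 * (d2[i - 1] - d2[i + 1]) / denom
      h <- (traj$t[i + 1] - traj$t[i - 1]) / 2
      d2_min <- d2[i] - 0.125 * (d2[i - 1] - d2[i + 1])^2 / denom
      t_min <- traj$t[i] + s * h
    } else {
      d2_min <- d2[i]
      t_min <- traj$t[i]
    }
    if (sqrt(max(d2_min, 0)) < tol) {
      return(list(
        is_closed = TRUE, estimated_period = t_min - traj$t[1]
      ))
    }
  }
  list(is_closed = FALSE, estimated_period = NA_real_)
}
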