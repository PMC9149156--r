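#' Jacobian of the replicator system at a state
#'
#' Analytic partial derivatives of the mechanism's right-hand side. For the
#' static mechanism the entries are
#' `a11 = (1 - 2x)[(S+P) y - C - dL]`, `a12 = x(1-x)(S+P)`,
#' `a21 = -y(1-y)(S+P)`, `a22 = (1 - 2y)[P - I - x(S+P)]`; the dynamic
#' mechanisms add the terms generated by the `x`-dependence of the
#' effective incentives.
#'
#' @inheritParams expected_payoffs
#' @return A 2x2 numeric matrix.
#' @export
#' @examples
#' p <- game_params(S = 3, P = 9, I = 3, C = 1, dL = 4)
#' jacobian_at(1 / 3, 5 / 9, p, "dynamic_penalty")
jacobian_at <- function(x, y, params, mechanism = "static") {
  st <- check_state(x, y)
  x <- st[["x"]]
  y <- st[["y"]]
  co <- rhs_coefficients(params, mechanism)
  br <- rhs_brackets(x, y, params, mechanism)
  PS <- params$P + params$S
  a11 <- (1 - 2 * x) * br[["A"]] - x * (1 - x) * co$kappa * y
  a12 <- x * (1 - x) * (PS - co$kappa * x)
  a21 <- y * (1 - y) * (2 * co$b2 * x + co$b1)
  a22 <- (1 - 2 * y) * br[["B"]]
  matrix(c(a11, a12, a21, a22), nrow = 2, byrow = TRUE)
}

#' Classify an equilibrium from its Jacobian
#'
#' Applies the planar trace/determinant test: `det J < 0` is a saddle;
#' `det J > 0` with `tr J < 0` an asymptotically stable sink (the
#' evolutionary stable strategy, ESS); `det J > 0` with `tr J = 0` (within
#' tolerance) a center; `det J > 0` with `tr J > 0` a source; anything else
#' (a zero determinant) is non-hyperbolic.
#'
#' @param point Numeric `c(x, y)` equilibrium point.
#' @param params,mechanism Model parameters and mechanism.
#' @param kind `"corner"` or `"interior"` (annotation only).
#' @param residual_tol The point must zero the right-hand side to this
#'   tolerance (relative to parameter magnitude).
#' @return A list of class `"equilibrium_report"` with `point`, `kind`,
#'   `detJ`, `trJ`, `eigenvalues` (complex pair) and `stability`, one of
#'   `"ESS_sink"`, `"center"`, `"saddle"`, `"source"`,
#'   `"nonhyperbolic_other"`.
#' @export
classify_equilibrium <- function(point, params, mechanism = "static",
                                 kind = NULL, residual_tol = 1e-10) {
  mechanism <- match_mechanism(mechanism)
  x <- unname(point[1])
  y <- unname(point[2])
  pscale <- max(1, abs(params$P), abs(params$S), abs(params$C + params$dL))
  res <- max(abs(replicator_rhs(x, y, params, mechanism)))
  if (res > residual_tol * pscale) {
    stop(sprintf(
      "point (%g, %g) is not an equilibrium (residual %.3g)", x, y, res
    ))
  }
  J <- jacobian_at(x, y, params, mechanism)
  detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  trJ <- J[1, 1] + J[2, 2]
  ev <- eigen(J, only.values = TRUE)$values
  ev <- as.complex(ev)
  tau <- 1e-9 * max(1, max(abs(J)))
  stability <- if (detJ < -tau) {
    "saddle"
  } else if (detJ > tau && trJ < -tau) {
    "ESS_sink"
  } else if (detJ > tau && abs(trJ) <= tau) {
    "center"
  } else if (detJ > tau && trJ > tau) {
    "source"
  } else {
    "nonhyperbolic_other"
  }
  if (is.null(kind)) {
    corner <- all(abs(c(x, y) - round(c(x, y))) < 1e-12)
    kind <- if (corner) "corner" else "interior"
  }
  structure(
    list(
      point = c(x = x, y = y), kind = kind, exists = TRUE,
      detJ = detJ, trJ = trJ, eigenvalues = ev, stability = stability
    ),
    class = "equilibrium_report"
  )
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat(sprintf(
    "(%.6g, %.6g) [%s]  det J = %.6g, tr J = %.6g  -> %s\n",
    x$point[1], x$point[2], x$kind, x$detJ, x$trJ, x$stability
  ))
  invisible(x)
}

# Closed-form interior equilibrium for a mechanism, or NULL when the root
# does not lie strictly inside (0, 1)^2. Root selection: the "minus" branch
# of the mechanism's quadratic; a degenerate leading coefficient (P = 0 for
# the dynamic penalty, S = 0 for the dynamic reward) falls back to a
# numeric root of the government bracket B(x) on (0, 1).
interior_closed_form <- function(params, mechanism) {
  P <- params$P
  S <- params$S
  I <- params$I
  CD <- params$C + params$dL
  PS <- P + S
  mechanism <- match_mechanism(mechanism)

  xy <- switch(mechanism,
    static = {
      if (PS <= 0) return(NULL)
      c((P - I) / PS, CD / PS)
    },
    dynamic_penalty = {
      if (P <= 0) return(interior_numeric(params, mechanism))
      r <- sqrt(S^2 + 4 * P * (S + I))
      c(1 - (r - S) / (2 * P), 2 * CD / (S + r))
    },
    dynamic_reward = {
      if (S <= 0) return(interior_numeric(params, mechanism))
      r <- sqrt((P - S)^2 + 4 * S * I)
      c(0.5 + (P - r) / (2 * S), 2 * CD / (PS + r))
    },
    dynamic_both = {
      if (PS <= 0) return(NULL)
      r <- sqrt(S^2 + 4 * I * PS)
      c((2 * P + S - r) / (2 * PS), 2 * CD / (S + r))
    }
  )
  if (is.null(xy) || anyNA(xy) || any(!is.finite(xy))) return(NULL)
  if (xy[1] <= 0 || xy[1] >= 1 || xy[2] <= 0 || xy[2] >= 1) return(NULL)
  # polish away the cancellation error of the quadratic formula: Newton on
  # the government bracket B(x), then y from the institution bracket
  co <- rhs_coefficients(params, mechanism)
  x <- xy[1]
  for (i in 1:3) {
    Bx <- co$b2 * x^2 + co$b1 * x + co$b0
    dBx <- 2 * co$b2 * x + co$b1
    if (dBx == 0) break
    x_new <- x - Bx / dBx
    if (x_new <= 0 || x_new >= 1) break
    x <- x_new
  }
  denom <- PS - co$kappa * x
  y <- if (abs(denom) > 0) CD / denom else xy[2]
  if (x <= 0 || x >= 1 || y <= 0 || y >= 1) return(NULL)
  c(x = x, y = y)
}

# Numeric fallback: root of B(x) in (0, 1), then y from A(x, y) = 0.
interior_numeric <- function(params, mechanism) {
  co <- rhs_coefficients(params, mechanism)
  Bf <- function(x) co$b2 * x^2 + co$b1 * x + co$b0
  eps <- 1e-12
  if (Bf(eps) * Bf(1 - eps) > 0) return(NULL)
  x <- uniroot(Bf, c(eps, 1 - eps), tol = 1e-14)$root
  denom <- (params$P + params$S) - co$kappa * x
  if (abs(denom) < 1e-300) return(NULL)
  y <- (params$C + params$dL) / denom
  xy <- c(x = x, y = y)
  if (any(xy <= 0) || any(xy >= 1)) return(NULL)
  xy
}

#' Enumerate and classify the equilibria of a mechanism
#'
#' Always returns the four corner rest points `(0,0), (1,0), (0,1), (1,1)`
#' classified by the trace/determinant test, and appends the interior
#' mixed-strategy equilibrium when its closed form lies strictly inside the
#' unit square:
#' * static: `x* = (P - I)/(P + S)`, `y* = (C + dL)/(P + S)`;
#' * dynamic penalty: `x* = 1 - (sqrt(S^2 + 4P(S+I)) - S)/(2P)`;
#' * dynamic reward: `x* = 1/2 + (P - sqrt((P-S)^2 + 4SI))/(2S)`;
#' * dynamic both: `x* = (2P + S - sqrt(S^2 + 4I(P+S)))/(2(P+S))`;
#' with the matching `y*` in each case. Every returned interior point zeroes
#' the right-hand side to `1e-10` (relative).
#'
#' @inheritParams effective_incentives
#' @return A list of class `"equilibrium_set"` of `"equilibrium_report"`s.
#' @export
#' @examples
#' enumerate_equilibria(game_params(S = 3, P = 9, I = 3, C = 1, dL = 4),
#'   "dynamic_penalty"
#' )
enumerate_equilibria <- function(params, mechanism = "static") {
  mechanism <- match_mechanism(mechanism)
  corners <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  reports <- lapply(corners, classify_equilibrium,
    params = params, mechanism = mechanism, kind = "corner"
  )
  xy <- interior_closed_form(params, mechanism)
  if (!is.null(xy)) {
    reports <- c(reports, list(
      classify_equilibrium(xy, params, mechanism, kind = "interior")
    ))
  }
  structure(reports,
    params = params, mechanism = mechanism,
    class = "equilibrium_set"
  )
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat(sprintf(
    "Equilibria (%s mechanism):\n", attr(x, "mechanism")
  ))
  for (r in x) print(r)
  invisible(x)
}

#' Static-mechanism regime classification
#'
#' Partitions parameter space by which rest point (if any) of the static
#' system is the ESS:
#' * `ESS_00` when `P < I` — fraud plus passive supervision is absorbing;
#' * `ESS_01` when `I < P < C + dL - S` — fraud persists under active
#'   supervision;
#' * `CENTER` when `P > max(I, C + dL - S)` — the interior point is a center
#'   and trajectories cycle;
#' * `BOUNDARY` when a defining inequality is a tie (within `tol`, relative
#'   to parameter magnitude);
#' * `OTHER` for any remaining parameter set.
#'
#' @param params A `"game_params"` object.
#' @param tol Relative tie tolerance.
#' @return One of `"ESS_00"`, `"ESS_01"`, `"CENTER"`, `"BOUNDARY"`,
#'   `"OTHER"`.
#' @export
#' @examples
#' classify_static_regime(game_params(S = 1, P = 1.5, I = 2, C = 1, dL = 4))
classify_static_regime <- function(params, tol = 1e-9) {
  stopifnot(inherits(params, "game_params"))
  P <- params$P
  I <- params$I
  thr <- max(I, params$C + params$dL - params$S)
  scale <- max(1, abs(P), abs(I), abs(thr))
  near <- function(a, b) abs(a - b) <= tol * scale
  if (near(P, I) || near(P, thr)) return("BOUNDARY")
  if (P < I) return("ESS_00")
  if (P > thr) return("CENTER")
  if (P > I && P < params$C + params$dL - params$S) return("ESS_01")
  "OTHER"
}
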