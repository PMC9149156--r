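#' Incentive mechanisms
#'
#' The four reward/penalty mechanisms the model distinguishes. Under the
#' static mechanism the reward `S` and penalty `P` are constants. Under the
#' dynamic mechanisms the realised intensities scale with the fraction of
#' fraudulent institutions `1 - x`: the dynamic penalty uses
#' `P(x) = (1 - x) P`, the dynamic reward `S(x) = (1 - x) S`, and the
#' combined mechanism both.
#'
#' @return Character vector of the four mechanism names.
#' @export
#' @examples
#' mechanisms()
mechanisms <- function() {
  c("static", "dynamic_penalty", "dynamic_reward", "dynamic_both")
}

match_mechanism <- function(mechanism) {
  match.arg(mechanism, mechanisms())
}

#' Game parameter set
#'
#' Validates and bundles the model constants. All monetary quantities are in
#' one consistent (but arbitrary) currency unit.
#'
#' @param S Maximum reward paid to a self-disciplined institution (>= 0).
#' @param P Maximum penalty imposed on a fraudulent institution (>= 0).
#' @param I Incremental cost to the government of positive supervision (> 0).
#' @param C Incremental cost to an institution of self-discipline (> 0).
#' @param dL Extra benefit an institution obtains from fraud (>= 0).
#' @param L Baseline institution return (any finite real; cancels from the
#'   dynamics and defaults to 0).
#' @param G1 Social benefit to the government when institutions are
#'   self-disciplined (>= 0; cancels from the dynamics, defaults to 0).
#'
#' @details `L` and `G1` appear in the payoff matrix but cancel from every
#'   payoff difference, so they never affect the replicator dynamics. They
#'   are retained so the full payoff matrix can be reproduced.
#'
#' @return An object of class `"game_params"` (a named list with the seven
#'   fields above).
#' @export
#' @examples
#' game_params(S = 1, P = 1.5, I = 2, C = 1, dL = 4)
game_params <- function(S, P, I, C, dL, L = 0, G1 = 0) {
  validate_params(list(S = S, P = P, I = I, C = C, dL = dL, L = L, G1 = G1))
}

#' Validate a raw mapping of parameter names to numbers
#'
#' @param raw Named list or vector with entries `S`, `P`, `I`, `C`, `dL` and
#'   optionally `L`, `G1`.
#' @return A validated `"game_params"` object.
#' @export
validate_params <- function(raw) {
  raw <- as.list(raw)
  required <- c("S", "P", "I", "C", "dL")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("missing required parameter(s): ", paste(missing, collapse = ", "))
  }
  defaults <- list(L = 0, G1 = 0)
  raw <- modifyList(defaults, raw)
  unknown <- setdiff(names(raw), c(required, names(defaults)))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  p <- lapply(raw[c(required, "L", "G1")], function(v) as.numeric(v)[1])
  for (nm in names(p)) {
    if (!is.finite(p[[nm]])) stop(nm, " must be a finite number")
  }
  for (nm in c("I", "C")) {
    if (p[[nm]] <= 0) stop(nm, " must be > 0")
  }
  for (nm in c("S", "P", "dL", "G1")) {
    if (p[[nm]] < 0) stop(nm, " must be >= 0")
  }
  structure(p, class = "game_params")
}

#' @export
print.game_params <- function(x, ...) {
  cat("Game parameters (currency units):\n")
  cat(sprintf("  S  (max reward)            %g\n", x$S))
  cat(sprintf("  P  (max penalty)           %g\n", x$P))
  cat(sprintf("  I  (supervision cost)      %g\n", x$I))
  cat(sprintf("  C  (self-discipline cost)  %g\n", x$C))
  cat(sprintf("  dL (fraud gain)            %g\n", x$dL))
  if (x$L != 0 || x$G1 != 0) {
    cat(sprintf("  L = %g, G1 = %g (cancel from the dynamics)\n", x$L, x$G1))
  }
  invisible(x)
}

check_state <- function(x, y, tol = 1e-9) {
  if (!is.finite(x) || !is.finite(y)) stop("state must be finite")
  if (x < -tol || x > 1 + tol || y < -tol || y > 1 + tol) {
    stop(sprintf("state (%g, %g) outside the unit square", x, y))
  }
  c(x = min(max(x, 0), 1), y = min(max(y, 0), 1))
}

#' Effective reward and penalty under a mechanism
#'
#' Returns the intensities actually applied at population state `x`: the
#' static mechanism keeps `(P, S)`; the dynamic penalty replaces `P` by
#' `(1 - x) P`; the dynamic reward replaces `S` by `(1 - x) S`; the combined
#' mechanism scales both.
#'
#' @param params A `"game_params"` object.
#' @param mechanism One of [mechanisms()].
#' @param x Fraction of self-disciplined institutions, in `[0, 1]`.
#' @return Named numeric vector `c(P_eff, S_eff)`.
#' @export
#' @examples
#' p <- game_params(S = 3, P = 9, I = 3, C = 1, dL = 4)
#' effective_incentives(p, "dynamic_penalty", x = 1 / 3)
effective_incentives <- function(params, mechanism, x) {
  stopifnot(inherits(params, "game_params"))
  mechanism <- match_mechanism(mechanism)
  st <- check_state(x, 0)
  x <- st[["x"]]
  P_eff <- if (mechanism %in% c("dynamic_penalty", "dynamic_both")) {
    (1 - x) * params$P
  } else {
    params$P
  }
  S_eff <- if (mechanism %in% c("dynamic_reward", "dynamic_both")) {
    (1 - x) * params$S
  } else {
    params$S
  }
  c(P_eff = P_eff, S_eff = S_eff)
}
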