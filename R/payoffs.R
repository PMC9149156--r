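#' Payoff matrix of the supervision game
#'
#' Builds the 2x2 bimatrix of the stage game. With the static mechanism the
#' four cells are, as (institution payoff; government payoff):
#'
#' | | positive supervision | passive supervision |
#' |---|---|---|
#' | self-discipline | `L + S - C`; `G1 - S - I` | `L - C`; `G1` |
#' | fraud           | `L - P + dL`; `P - I - G1` | `L + dL`; `-G1` |
#'
#' Under a dynamic mechanism `P` and `S` are replaced by the effective
#' intensities at population state `x` (see [effective_incentives()]).
#'
#' @inheritParams effective_incentives
#' @return An object of class `"payoff_matrix"`: a list of two 2x2 numeric
#'   matrices, `phsi` and `gov`, with rows `self_discipline`, `fraud` and
#'   columns `positive`, `passive`.
#' @export
#' @examples
#' payoff_matrix(game_params(S = 1, P = 1.5, I = 2, C = 1, dL = 4), "static")
payoff_matrix <- function(params, mechanism = "static", x = 0) {
  eff <- effective_incentives(params, mechanism, x)
  P <- eff[["P_eff"]]
  S <- eff[["S_eff"]]
  dn <- list(c("self_discipline", "fraud"), c("positive", "passive"))
  phsi <- matrix(
    c(
      params$L + S - params$C, params$L - params$C,
      params$L - P + params$dL, params$L + params$dL
    ),
    nrow = 2, byrow = TRUE, dimnames = dn
  )
  gov <- matrix(
    c(
      params$G1 - S - params$I, params$G1,
      P - params$I - params$G1, -params$G1
    ),
    nrow = 2, byrow = TRUE, dimnames = dn
  )
  structure(
    list(phsi = phsi, gov = gov, mechanism = match_mechanism(mechanism), x = x),
    class = "payoff_matrix"
  )
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat(sprintf(
    "Payoff matrix (%s mechanism%s)\n", x$mechanism,
    if (x$mechanism == "static") "" else sprintf(", evaluated at x = %g", x$x)
  ))
  cat("PHSI payoffs:\n")
  print(x$phsi)
  cat("Government payoffs:\n")
  print(x$gov)
  invisible(x)
}

#' Expected payoffs at a population state
#'
#' Computes the expected payoff of each pure strategy against the current
#' population mix, and the population-average payoffs. `E_PY`/`E_PN` are the
#' institution's expected payoffs under self-discipline/fraud; `E_GY`/`E_GN`
#' the government's under positive/passive supervision.
#'
#' @inheritParams effective_incentives
#' @param y Fraction of actively supervising governments, in `[0, 1]`.
#' @return Named list with `E_PY`, `E_PN`, `E_GY`, `E_GN`, `mean_phsi`
#'   (`x E_PY + (1-x) E_PN`) and `mean_gov` (`y E_GY + (1-y) E_GN`).
#' @export
#' @examples
#' p <- game_params(S = 1, P = 1.5, I = 2, C = 1, dL = 4)
#' expected_payoffs(p, "static", x = 0.5, y = 0.5)
expected_payoffs <- function(params, mechanism, x, y) {
  st <- check_state(x, y)
  x <- st[["x"]]
  y <- st[["y"]]
  pm <- payoff_matrix(params, mechanism, x)
  E_PY <- y * pm$phsi["self_discipline", "positive"] +
    (1 - y) * pm$phsi["self_discipline", "passive"]
  E_PN <- y * pm$phsi["fraud", "positive"] +
    (1 - y) * pm$phsi["fraud", "passive"]
  E_GY <- x * pm$gov["self_discipline", "positive"] +
    (1 - x) * pm$gov["fraud", "positive"]
  E_GN <- x * pm$gov["self_discipline", "passive"] +
    (1 - x) * pm$gov["fraud", "passive"]
  list(
    E_PY = E_PY, E_PN = E_PN, E_GY = E_GY, E_GN = E_GN,
    mean_phsi = x * E_PY + (1 - x) * E_PN,
    mean_gov = y * E_GY + (1 - y) * E_GN
  )
}
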