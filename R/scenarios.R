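# Isolated pseudo-random stream: draws never touch (or depend on) the
# caller's global RNG state.
local_rng <- function(seed) {
  stopifnot(is.finite(seed))
  state <- NULL
  with_stream <- function(code) {
    g <- globalenv()
    had <- exists(".Random.seed", envir = g, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = g) else NULL
    if (is.null(state)) {
      set.seed(as.integer(seed) %% .Machine$integer.max)
    } else {
      assign(".Random.seed", state, envir = g)
    }
    on.exit({
      state <<- get(".Random.seed", envir = g)
      if (had) {
        assign(".Random.seed", old, envir = g)
      } else {
        rm(".Random.seed", envir = g)
      }
    })
    force(code)
  }
  list(
    draw_params = function(lo = 0.1, hi = 20) {
      with_stream({
        v <- exp(runif(5, log(lo), log(hi)))
        validate_params(
          list(S = v[1], P = v[2], I = v[3], C = v[4], dL = v[5])
        )
      })
    },
    runif = function(n, min = 0, max = 1) {
      with_stream(runif(n, min, max))
    }
  )
}

scenario <- function(name, params, mechanism, init = c(0.5, 0.5),
                     description = "", sweep = NULL) {
  structure(
    list(
      name = name, params = params, mechanism = mechanism,
      init = c(x = init[1], y = init[2]), description = description,
      sweep = sweep
    ),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': %s\n", x$name, x$description))
  cat(sprintf(
    "  mechanism(s): %s; init (%.3g, %.3g)\n",
    paste(x$mechanism, collapse = ", "), x$init[1], x$init[2]
  ))
  print(x$params)
  invisible(x)
}

#' Built-in scenarios
#'
#' A registry of named parameterizations covering the model's reference
#' cases:
#' * `sim1` — `S=1, P=1.5, I=2, C=1, dL=4`, static; penalty below the
#'   supervision cost, converges to (fraud, passive).
#' * `sim2` — `S=1, P=3, I=2, C=1, dL=4`, static; converges to (fraud,
#'   positive).
#' * `case_study` — the home-care provider case: 8,000 clients, ¥150
#'   purchase price, ¥105 contracted cost and ¥120 fraud gain per person,
#'   ¥10,000 supervision cost, ¥700,000 penalty; static center regime.
#' * `fig4` — `S=3, P=9, I=3, C=1, dL=4` under the three dynamic
#'   mechanisms (mechanism comparison case).
#' * `fig5_sweep` — dynamic reward, sweep of `S` over 1..6 at
#'   `P=9, I=3, C=1, dL=4`.
#' * `fig6_sweep` — dynamic reward, sweep of `P` over 6..12 at
#'   `S=3, I=3, C=1, dL=4`.
#'
#' @param name One of the registry names above.
#' @return A `"scenario"` object (`name`, `params`, `mechanism` — possibly
#'   several —, `init`, `description`, optional `sweep`).
#' @export
#' @examples
#' builtin_scenario("sim1")
builtin_scenario <- function(name) {
  registry <- list(
    sim1 = scenario(
      "sim1", game_params(S = 1, P = 1.5, I = 2, C = 1, dL = 4), "static",
      description = "static, P < I: ESS at (0, 0) (fraud, passive)"
    ),
    sim2 = scenario(
      "sim2", game_params(S = 1, P = 3, I = 2, C = 1, dL = 4), "static",
      description = "static, I < P < C + dL - S: ESS at (0, 1)"
    ),
    case_study = scenario(
      "case_study",
      case_study_params(
        n_clients = 8000, price_per_person = 150,
        contract_cost_per_person = 105, per_person_fraud_gain = 120,
        supervision_cost = 10000, penalty = 700000
      )$params,
      "static",
      description = paste(
        "home-care provider case (currency yuan):",
        "P > max(I, C + dL - S), center regime with closed orbits"
      )
    ),
    fig4 = scenario(
      "fig4", game_params(S = 3, P = 9, I = 3, C = 1, dL = 4),
      c("dynamic_penalty", "dynamic_reward", "dynamic_both"),
      description = "dynamic-mechanism comparison at S=3, P=9, I=3, C=1, dL=4"
    ),
    fig5_sweep = scenario(
      "fig5_sweep", game_params(S = 3, P = 9, I = 3, C = 1, dL = 4),
      "dynamic_reward",
      description = "reward-intensity sweep under the dynamic reward mechanism",
      sweep = list(param = "S", grid = c(1, 2, 3, 4, 5, 6))
    ),
    fig6_sweep = scenario(
      "fig6_sweep", game_params(S = 3, P = 9, I = 3, C = 1, dL = 4),
      "dynamic_reward",
      description = "penalty-intensity sweep under the dynamic reward mechanism",
      sweep = list(param = "P", grid = c(6, 7, 8, 9, 10, 11, 12))
    )
  )
  if (!name %in% names(registry)) {
    stop(
      "unknown scenario '", name, "'; valid names: ",
      paste(names(registry), collapse = ", ")
    )
  }
  registry[[name]]
}

#' Aggregate case-study inputs into game parameters
#'
#' Converts per-person contract quantities into the institution-level model
#' parameters: `S = price_per_person * n_clients` (the full purchase payment
#' at stake), `C = contract_cost_per_person * n_clients` (the cost of
#' actually delivering the service), `dL = per_person_fraud_gain *
#' n_clients`; the supervision cost `I` and penalty `P` are per-institution
#' and enter unchanged. Also returns the penalty threshold
#' `max(I, C + dL - S)` above which the static system is in the center
#' regime.
#'
#' @param n_clients Number of older adults served (positive integer).
#' @param price_per_person Government purchase price per person (currency).
#' @param contract_cost_per_person Contracted service cost per person.
#' @param per_person_fraud_gain Extra gain from fraud per person.
#' @param supervision_cost Government supervision cost per institution.
#' @param penalty Penalty imposed on a fraudulent institution.
#' @return List with `params` (a `"game_params"`) and `threshold`.
#' @export
#' @examples
#' case_study_params(8000, 150, 105, 120, 10000, 700000)
case_study_params <- function(n_clients, price_per_person,
                              contract_cost_per_person,
                              per_person_fraud_gain,
                              supervision_cost, penalty) {
  vals <- c(
    n_clients, price_per_person, contract_cost_per_person,
    per_person_fraud_gain, supervision_cost, penalty
  )
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all case-study inputs must be positive and finite")
  }
  if (n_clients != round(n_clients)) stop("n_clients must be an integer")
  params <- game_params(
    S = price_per_person * n_clients,
    C = contract_cost_per_person * n_clients,
    dL = per_person_fraud_gain * n_clients,
    I = supervision_cost,
    P = penalty
  )
  list(
    params = params,
    threshold = max(params$I, params$C + params$dL - params$S)
  )
}

#' Random scenario for property testing
#'
#' Draws `S, P, I, C, dL` log-uniformly from `[0.1, 20]`, optionally
#' rejection-sampling until a requested static regime holds (or, for
#' `"dynamic_interior"`, until all three dynamic mechanisms have an interior
#' equilibrium). Deterministic in `seed` and independent of the caller's
#' RNG state.
#'
#' @param seed Integer seed.
#' @param regime `NULL`, one of `"ESS_00"`, `"ESS_01"`, `"CENTER"`, or
#'   `"dynamic_interior"`.
#' @param max_tries Rejection budget.
#' @return A `"scenario"` object with a static mechanism and init (0.5, 0.5).
#' @export
#' @examples
#' random_scenario(7, regime = "CENTER")$params
random_scenario <- function(seed, regime = NULL, max_tries = 10000) {
  rng <- local_rng(seed)
  ok <- function(p) {
    if (is.null(regime)) return(TRUE)
    if (regime == "dynamic_interior") {
      return(all(vapply(
        c("dynamic_penalty", "dynamic_reward", "dynamic_both"),
        function(m) !is.null(interior_closed_form(p, m)), logical(1)
      )))
    }
    classify_static_regime(p) == regime
  }
  for (i in seq_len(max_tries)) {
    p <- rng$draw_params()
    if (ok(p)) {
      return(scenario(
        sprintf("random_%d", as.integer(seed)), p, "static",
        description = sprintf(
          "random draw (seed %d%s)", as.integer(seed),
          if (is.null(regime)) "" else paste0(", regime ", regime)
        )
      ))
    }
  }
  stop(
    "rejection budget exhausted while sampling for constraint '",
    regime, "'"
  )
}

#' Run a full analysis report for a scenario
#'
#' Bundles regime classification, equilibrium enumeration and stability,
#' trajectory integration and convergence assessment, oscillation analysis
#' (when the static regime is a center) and the cross-mechanism comparison
#' (on request) into one JSON-ready document.
#'
#' @param scn A `"scenario"` (from [builtin_scenario()], [random_scenario()]
#'   or [read_scenario_config()]).
#' @param t_end Integration horizon.
#' @param cfg A [solver_cfg()].
#' @param compare Include [compare_mechanisms()] output.
#' @param trajectory_csv Optional path; when given, the (first mechanism's)
#'   trajectory is written there as CSV.
#' @return A nested list (report) with `schema = 1`; serialize with
#'   [write_report_json()].
#' @export
run_report <- function(scn, t_end = 500, cfg = solver_cfg(),
                       compare = length(scn$mechanism) > 1,
                       trajectory_csv = NULL) {
  stopifnot(inherits(scn, "scenario"))
  p <- scn$params
  regime <- classify_static_regime(p)
  report <- list(
    schema = 1,
    scenario = scn$name,
    description = scn$description,
    params = unclass(p),
    regime = regime
  )

  report$mechanisms <- lapply(setNames(scn$mechanism, scn$mechanism),
    function(m) {
      eqs <- enumerate_equilibria(p, m)
      traj <- integrate_trajectory(p, m, scn$init, t_end, cfg)
      conv <- assess_convergence(traj)
      list(
        equilibria = lapply(eqs, equilibrium_to_list),
        trajectory = list(
          n = nrow(traj),
          t_end = traj$t[nrow(traj)],
          terminal = c(x = traj$x[nrow(traj)], y = traj$y[nrow(traj)]),
          converged = conv$converged,
          oscillatory = conv$oscillatory,
          limit = conv$limit_point,
          residual = conv$residual
        )
      )
    }
  )

  if (regime == "CENTER" && "static" %in% scn$mechanism) {
    cc <- center_constants(p, scn$init)
    sp <- rescale_params(p)$params
    # orbit closure assessed on the rescaled system (same path, unit time)
    n_dense <- max(cfg$n_out, 8000)
    cc_s <- center_constants(sp, scn$init)
    # the nonlinear period of a wide orbit can far exceed the linearized
    # one, so the closure horizon never shrinks below t_end
    traj <- integrate_trajectory(
      sp, "static", scn$init, t_end = max(3 * cc_s$period, t_end),
      solver_cfg(
        method = cfg$method, rtol = cfg$rtol, atol = cfg$atol,
        n_out = n_dense, clamp_tol = cfg$clamp_tol
      )
    )
    per <- verify_periodicity(traj, tol = 1e-3)
    H <- first_integral(traj$x, traj$y, sp)
    report$oscillation <- list(
      tau1 = cc$tau1, tau2 = cc$tau2, omega = cc$omega,
      period_linear = cc$period, Am = cc$Am, phi = cc$phi,
      is_closed = per$is_closed, estimated_period = per$estimated_period,
      H0 = H[1], H_drift_max = max(abs(H - H[1]))
    )
  }

  if (compare) {
    cmp <- compare_mechanisms(p)
    report$comparison <- list(
      table = cmp$table, ordering = cmp$ordering
    )
    report$ordering <- cmp$ordering
  }

  if (!is.null(trajectory_csv)) {
    traj <- integrate_trajectory(p, scn$mechanism[1], scn$init, t_end, cfg)
    write_trajectory_csv(traj, trajectory_csv)
    report$trajectory_csv <- trajectory_csv
  }
  report
}

equilibrium_to_list <- function(r) {
  list(
    x = r$point[["x"]], y = r$point[["y"]], kind = r$kind,
    detJ = r$detJ, trJ = r$trJ,
    eigenvalues = lapply(r$eigenvalues, function(e) {
      list(re = Re(e), im = Im(e))
    }),
    stability = r$stability
  )
}

#' Serialize a report (or equilibrium set) to JSON
#'
#' @param report A report from [run_report()], or an `"equilibrium_set"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  if (inherits(report, "equilibrium_set")) {
    report <- list(
      schema = 1,
      mechanism = attr(report, "mechanism"),
      regime = classify_static_regime(attr(report, "params")),
      equilibria = lapply(report, equilibrium_to_list)
    )
  }
  jsonlite::write_json(report, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read / write flat key-value scenario configuration files
#'
#' The format is one `key = value` pair per line (`#` comments allowed);
#' keys are case-sensitive and restricted to `S, P, I, C, dL, L, G1,
#' mechanism, x0, y0`; unknown keys are rejected.
#'
#' @param path Config file path.
#' @return For `read_scenario_config`, a `"scenario"`; for
#'   `write_scenario_config`, `path` invisibly.
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, function(p) length(p) != 2, logical(1))
  if (any(bad)) stop("malformed config line(s): ", lines[bad][1])
  keys <- vapply(kv, `[[`, "", 1)
  vals <- vapply(kv, `[[`, "", 2)
  allowed <- c("S", "P", "I", "C", "dL", "L", "G1", "mechanism", "x0", "y0")
  unknown <- setdiff(keys, allowed)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(keys)) stop("duplicate config key(s)")
  named <- setNames(as.list(vals), keys)
  mech <- if (!is.null(named$mechanism)) named$mechanism else "static"
  init <- c(
    if (!is.null(named$x0)) as.numeric(named$x0) else 0.5,
    if (!is.null(named$y0)) as.numeric(named$y0) else 0.5
  )
  raw <- named[intersect(names(named), c("S", "P", "I", "C", "dL", "L", "G1"))]
  p <- validate_params(lapply(raw, as.numeric))
  scenario(
    basename(path), p, match_mechanism(mech), init,
    description = paste("loaded from", path)
  )
}

#' @rdname read_scenario_config
#' @param scn A `"scenario"` to write (its first mechanism is stored).
#' @export
write_scenario_config <- function(scn, path) {
  stopifnot(inherits(scn, "scenario"))
  p <- scn$params
  lines <- c(
    sprintf("S = %.17g", p$S),
    sprintf("P = %.17g", p$P),
    sprintf("I = %.17g", p$I),
    sprintf("C = %.17g", p$C),
    sprintf("dL = %.17g", p$dL),
    sprintf("L = %.17g", p$L),
    sprintf("G1 = %.17g", p$G1),
    sprintf("mechanism = %s", scn$mechanism[1]),
    sprintf("x0 = %.17g", scn$init[1]),
    sprintf("y0 = %.17g", scn$init[2])
  )
  writeLines(lines, path)
  invisible(path)
}
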