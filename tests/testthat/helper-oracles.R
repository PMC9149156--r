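# Independent oracles for the replicator systems. These transcribe the
# published polynomial right-hand sides directly and re-find interior
# equilibria by grid scan + damped Newton with finite-difference Jacobians;
# they share no code with the package implementation.

fig1_params <- function() game_params(S = 1, P = 1.5, I = 2, C = 1, dL = 4)
fig2_params <- function() game_params(S = 1, P = 3, I = 2, C = 1, dL = 4)
fig4_params <- function() game_params(S = 3, P = 9, I = 3, C = 1, dL = 4)

# Hard-coded polynomial right-hand sides of the four systems.
poly_rhs <- function(x, y, p, mechanism) {
  S <- p$S; P <- p$P; I <- p$I; C <- p$C; dL <- p$dL
  switch(mechanism,
    static = c(
      x * (1 - x) * ((S + P) * y - C - dL),
      y * (1 - y) * (P - I - x * (S + P))
    ),
    dynamic_penalty = c(
      x * (1 - x) * ((P + S) * y - C - dL - P * x * y),
      y * (1 - y) * ((1 - x)^2 * P - x * S - I)
    ),
    dynamic_reward = c(
      x * (1 - x) * ((P + S) * y - C - dL - S * x * y),
      y * (1 - y) * (S * x^2 - (P + S) * x - I + P)
    ),
    dynamic_both = c(
      x * (1 - x) * ((P + S) * (1 - x) * y - C - dL),
      y * (1 - y) * ((P + S) * x^2 - (2 * P + S) * x - I + P)
    ),
    stop("unknown mechanism")
  )
}

fd_jacobian <- function(x, y, p, mechanism, h = 1e-6) {
  fx <- function(s) poly_rhs(s[1], s[2], p, mechanism)
  J <- matrix(NA_real_, 2, 2)
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- h
    s0 <- c(x, y)
    J[, j] <- (fx(s0 + e) - fx(s0 - e)) / (2 * h)
  }
  J
}

# Published bracket polynomials with the replicator boundary factors
# x(1-x), y(1-y) divided out: an interior equilibrium is exactly a common
# zero of the two brackets, and the boundary rest points are no longer
# zeros, so Newton cannot be captured by them.
poly_brackets <- function(x, y, p, mechanism) {
  S <- p$S; P <- p$P; I <- p$I; C <- p$C; dL <- p$dL
  switch(mechanism,
    static = c((S + P) * y - C - dL, P - I - x * (S + P)),
    dynamic_penalty = c(
      (P + S) * y - C - dL - P * x * y,
      (1 - x)^2 * P - x * S - I
    ),
    dynamic_reward = c(
      (P + S) * y - C - dL - S * x * y,
      S * x^2 - (P + S) * x - I + P
    ),
    dynamic_both = c(
      (P + S) * (1 - x) * y - C - dL,
      (P + S) * x^2 - (2 * P + S) * x - I + P
    ),
    stop("unknown mechanism")
  )
}

# Grid scan over the open unit square followed by damped Newton polish of
# the bracket system. Returns c(x, y) or NULL.
oracle_interior <- function(p, mechanism, n_grid = 41, margin = 1e-3) {
  g <- seq(margin, 1 - margin, length.out = n_grid)
  fb <- function(s) poly_brackets(s[1], s[2], p, mechanism)
  best <- NULL
  best_norm <- Inf
  for (xi in g) {
    for (yi in g) {
      nr <- sum(fb(c(xi, yi))^2)
      if (nr < best_norm) {
        best_norm <- nr
        best <- c(xi, yi)
      }
    }
  }
  s <- best
  h <- 1e-7
  for (it in 1:100) {
    r <- fb(s)
    if (sqrt(sum(r^2)) < 1e-13 * max(1, p$P, p$S, p$C + p$dL)) break
    J <- matrix(NA_real_, 2, 2)
    for (j in 1:2) {
      e <- c(0, 0); e[j] <- h
      J[, j] <- (fb(s + e) - fb(s - e)) / (2 * h)
    }
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      s_new <- s - lam * step
      if (all(s_new > -0.5 & s_new < 1.5)) break
      lam <- lam / 2
      if (lam < 1e-8) return(NULL)
    }
    s <- s_new
  }
  r <- fb(s)
  if (sqrt(sum(r^2)) > 1e-9 * max(1, p$P, p$S, p$C + p$dL)) return(NULL)
  if (any(s <= 1e-9) || any(s >= 1 - 1e-9)) return(NULL)
  s
}

# Log-uniform parameter draw used by the property suites.
draw_params <- function() {
  v <- exp(runif(5, log(0.1), log(20)))
  game_params(S = v[1], P = v[2], I = v[3], C = v[4], dL = v[5])
}

interior_of <- function(params, mechanism) {
  eqs <- enumerate_equilibria(params, mechanism)
  for (r in eqs) {
    if (r$kind == "interior") return(r)
  }
  NULL
}
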