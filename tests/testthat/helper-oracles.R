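# Independent reference implementations used as oracles: plain R loops
# written directly from the model equations, sharing no code with the
# package internals.

p_gamma <- function(g) climate_params(gamma = g)

# piecewise ocean albedo, written independently
oracle_ocean_albedo <- function(T) {
  if (T <= 263) return(0.85)
  if (T > 300) return(0.25)
  0.85 + (0.25 - 0.85) / (300 - 263) * (T - 263)
}

oracle_drift <- function(T, A, gamma) {
  al <- 0.7 * oracle_ocean_albedo(T) + 0.3 * (0.1 * A + 0.4 * (1 - A))
  b <- max(0, 1 - 0.004 * (T - 283)^2)
  c(((1 - al) * 342.5 - (200 + 2.5 * (T - 283))) / 500,
    b * A * (1 - A) - gamma * A)
}

# Euler-Maruyama in plain R, consuming rnorm() one deviate per step
oracle_em <- function(T0, A0, gamma, eps, dt, n_steps, seed) {
  set.seed(seed)
  out <- matrix(NA_real_, n_steps + 1L, 2L)
  T <- T0; A <- A0
  out[1L, ] <- c(T, A)
  for (s in seq_len(n_steps)) {
    z <- rnorm(1)
    d <- oracle_drift(T, A, gamma)
    Tn <- T + d[1] * dt
    An <- A + d[2] * dt + eps * A * (1 - A) * sqrt(dt) * z
    An <- min(1, max(0, An))
    T <- Tn; A <- An
    out[s + 1L, ] <- c(T, A)
  }
  out
}

# deterministic Euler in plain R (no RNG consumption)
oracle_euler <- function(T0, A0, gamma, dt, n_steps) {
  out <- matrix(NA_real_, n_steps + 1L, 2L)
  T <- T0; A <- A0
  out[1L, ] <- c(T, A)
  for (s in seq_len(n_steps)) {
    d <- oracle_drift(T, A, gamma)
    T <- T + d[1] * dt
    A <- min(1, max(0, A + d[2] * dt))
    out[s + 1L, ] <- c(T, A)
  }
  out
}

# Equilibrium locations frozen from an independent dense-grid scan +
# uniroot on the branch residuals (both nullclines substituted by hand).
oracle_equilibria <- list(
  g0.02 = list(snow = c(242.045, 0),
               saddle = c(279.011167, 0.978641),
               warm = c(298.635684, 0.095083)),
  g0.35 = list(snow = c(242.045, 0),
               saddle = c(286.782410, 0.628755),
               warm = c(294.233256, 0.293295)),
  g0.001 = list(snow = c(242.045, 0),
                saddle = c(278.560869, 0.998914),
                warm = c(298.802700, 0.087563))
)
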