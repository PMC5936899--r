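#' Noise and integration settings for stochastic runs
#'
#' @param epsilon Noise intensity multiplying the vegetation growth-rate
#'   fluctuation (same units as the growth rate; the `sqrt(yr)` scaling is
#'   absorbed into the Wiener increment).
#' @param seed Integer seed; stochastic runs are bit-reproducible given
#'   the seed and configuration.
#' @param dt Time step (yr).
#' @param t_max Horizon (yr).
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(epsilon, seed = 1L, dt = 0.01, t_max = 5000) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0,
            dt > 0, t_max >= dt)
  seed <- as.integer(seed)
  structure(list(epsilon = epsilon, seed = seed, dt = dt, t_max = t_max),
            class = "noise_config")
}

#' Euler-Maruyama simulation of the stochastic model
#'
#' Integrates the stochastic system in which the vegetation growth rate is
#' perturbed by Gaussian white noise: the temperature equation is stepped
#' with plain Euler (it carries no noise), and the vegetation fraction with
#' the Euler-Maruyama scheme for the Ito equation
#' `dA = (beta(T) A (1-A) - gamma A) dt + eps A (1-A) dW`.
#' One standard normal deviate is drawn per step from R's generator, so a
#' given `(seed, dt, t_max, epsilon)` reproduces the trajectory
#' bit-identically.  `A` is clamped to `[0, 1]` after each step; the clamp
#' count is kept in the metadata (the exact SDE never leaves `[0, 1]`
#' because both drift and diffusion vanish at the edges, so clamps only
#' absorb discretization overshoot).  With `epsilon = 0` the result is
#' exactly the deterministic Euler solution.
#'
#' @param state0 Initial state `c(T, A)`.
#' @param params A [climate_params()] object.
#' @param noise A [noise_config()].
#' @param stride Record every `stride`-th step.
#' @return A `climate_trajectory` with stochastic metadata.
#' @examples
#' p <- climate_params(gamma = 0.35)
#' tr <- simulate_em(c(294, 0.3), p, noise_config(0.1, seed = 7, t_max = 50))
#' @export
simulate_em <- function(state0, params, noise, stride = 1L) {
  state0 <- as_state(state0)
  stopifnot(inherits(noise, "noise_config"))
  n_steps <- as.integer(round(noise$t_max / noise$dt))
  stride <- as.integer(stride)
  if (n_steps %% stride != 0)
    stop("t_max/dt must be a multiple of stride", call. = FALSE)
  set.seed(noise$seed)
  res <- em_cpp(state0[["T"]], state0[["A"]], noise$dt, n_steps, stride,
                param_vector(params), noise$epsilon)
  new_trajectory(res$traj, params, noise$dt, stride,
                 epsilon = noise$epsilon, seed = noise$seed,
                 n_clamp = res$n_clamp, n_steps = res$n_steps)
}

#' Seeded ensemble of stochastic trajectories
#'
#' Runs `n_runs` independent Euler-Maruyama trajectories; run `i` uses
#' seed `noise$seed + i`, so any single run reproduces its in-batch result
#' when simulated alone (order-independent reproducibility).
#'
#' @inheritParams simulate_em
#' @param n_runs Number of ensemble members (>= 1).
#' @return A list of `climate_trajectory` objects.
#' @export
simulate_ensemble <- function(state0, params, noise, n_runs, stride = 1L) {
  stopifnot(n_runs >= 1)
  lapply(seq_len(n_runs), function(i) {
    ni <- noise; ni$seed <- noise$seed + i
    simulate_em(state0, params, ni, stride = stride)
  })
}

# fast path: first-passage time below T_threshold, nothing stored
first_passage <- function(state0, params, noise, T_threshold) {
  state0 <- as_state(state0)
  n_steps <- as.integer(round(noise$t_max / noise$dt))
  set.seed(noise$seed)
  fp <- em_first_passage_cpp(state0[["T"]], state0[["A"]], noise$dt,
                             n_steps, param_vector(params), noise$epsilon,
                             T_threshold)
  if (fp < 0) NA_real_ else fp
}
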