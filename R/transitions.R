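#' First-passage time of a trajectory below a temperature threshold
#'
#' Earliest recorded time with `T < T_threshold`, marking commitment to
#' the snowball basin.  The default threshold of 260 K lies below every
#' saddle of the default calibration (279-287 K) and well above the
#' snowball state (242 K), so crossings are unambiguous.
#'
#' @param traj A `climate_trajectory`.
#' @param T_threshold Threshold temperature (K).
#' @return First-passage time in years, or `NA_real_` if the threshold is
#'   never crossed.
#' @export
detect_transition <- function(traj, T_threshold = 260) {
  stopifnot(inherits(traj, "climate_trajectory"))
  i <- which(traj$T < T_threshold)
  if (!length(i)) return(NA_real_)
  traj$times[i[1L]]
}

wilson_interval <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ph <- k / n
  den <- 1 + z^2 / n
  ctr <- (ph + z^2 / (2 * n)) / den
  hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
  # the interval endpoints are exact at the degenerate counts
  c(lo = if (k == 0) 0 else max(0, ctr - hw),
    hi = if (k == n) 1 else min(1, ctr + hw))
}

#' Probability of a noise-induced transition to the snowball state
#'
#' Fraction of ensemble members whose temperature drops below
#' `T_threshold` within the horizon, with a Wilson 95% binomial interval.
#' Run `i` uses seed `noise$seed + i`.  Nothing is stored per run; each
#' member is integrated only to its first passage.
#'
#' @param params A [climate_params()] object.
#' @param epsilon Noise intensity (overrides `noise$epsilon`).
#' @param n_runs Ensemble size (>= 10).
#' @param state0 Initial state (warm-attractor start).
#' @param noise A [noise_config()] carrying seed, `dt` and `t_max`.
#' @param T_threshold Transition criterion (K).
#' @return A list: `prob`, `ci_lo`, `ci_hi`, `n_runs`, `times`
#'   (first-passage times, `NA` where no transition), `ci_method`.
#' @export
transition_probability <- function(params, epsilon, n_runs = 100, state0,
                                   noise = noise_config(epsilon),
                                   T_threshold = 260) {
  stopifnot(n_runs >= 10)
  times <- vapply(seq_len(n_runs), function(i) {
    ni <- noise; ni$epsilon <- epsilon; ni$seed <- noise$seed + i
    first_passage(state0, params, ni, T_threshold)
  }, numeric(1))
  k <- sum(!is.na(times))
  ci <- wilson_interval(k, n_runs)
  list(prob = k / n_runs, ci_lo = unname(ci["lo"]), ci_hi = unname(ci["hi"]),
       n_runs = n_runs, times = times, ci_method = "wilson")
}

#' Transition-probability sweep over noise intensity
#'
#' Estimates the transition probability on an ascending grid of noise
#' intensities and extracts the transition window: the smallest grid
#' `epsilon` at which the probability first reaches 0.1 (`lo`) and 0.9
#' (`hi`).  The 0.1/0.9 thresholds operationalize the "transitions occur
#' in this range" reading of the sweep; both the raw curve and the window
#' are returned.  Ensemble `j` at grid point `j` uses seeds
#' `seed + (j-1) n_runs + 1 ... seed + j n_runs` so every run is
#' independently seeded.
#'
#' @param params A [climate_params()] object.
#' @param eps_grid Ascending noise-intensity grid.
#' @param n_runs Runs per grid point.
#' @param state0 Initial state; defaults to a point on the warm attractor
#'   (computed by a 500-yr settle from the warm equilibrium when `NULL`).
#' @param noise Base [noise_config()] (its `epsilon` is ignored).
#' @param T_threshold Transition criterion (K).
#' @return An object of class `epsilon_sweep`: `gamma`, `eps_grid`,
#'   `prob`, `ci_lo`, `ci_hi`, `n_runs`, `window` (`lo`, `hi`; `NA` where
#'   never reached), `criterion`.
#' @export
epsilon_sweep <- function(params, eps_grid, n_runs = 100, state0 = NULL,
                          noise = noise_config(0), T_threshold = 260) {
  stopifnot(!is.unsorted(eps_grid))
  if (is.null(state0)) state0 <- warm_start(params)
  prob <- ci_lo <- ci_hi <- numeric(length(eps_grid))
  for (j in seq_along(eps_grid)) {
    nj <- noise; nj$seed <- noise$seed + (j - 1L) * n_runs
    tp <- transition_probability(params, eps_grid[j], n_runs, state0,
                                 noise = nj, T_threshold = T_threshold)
    prob[j] <- tp$prob; ci_lo[j] <- tp$ci_lo; ci_hi[j] <- tp$ci_hi
  }
  first_at <- function(th) {
    i <- which(prob >= th)
    if (!length(i)) NA_real_ else eps_grid[i[1L]]
  }
  structure(list(gamma = params$gamma, eps_grid = eps_grid, prob = prob,
                 ci_lo = ci_lo, ci_hi = ci_hi, n_runs = n_runs,
                 window = c(lo = first_at(0.1), hi = first_at(0.9)),
                 criterion = list(T_threshold_K = T_threshold,
                                  horizon_yr = noise$t_max),
                 ci_method = "wilson"),
            class = "epsilon_sweep")
}

#' @export
print.epsilon_sweep <- function(x, ...) {
  cat(sprintf("Noise-intensity sweep (gamma = %g, %d runs/eps, T < %g K within %g yr)\n",
              x$gamma, x$n_runs, x$criterion$T_threshold_K,
              x$criterion$horizon_yr))
  print(data.frame(eps = x$eps_grid, prob = x$prob,
                   ci_lo = round(x$ci_lo, 3), ci_hi = round(x$ci_hi, 3)),
        row.names = FALSE)
  cat(sprintf("transition window: eps in (%s, %s)\n",
              format(x$window[["lo"]]), format(x$window[["hi"]])))
  invisible(x)
}

#' @export
plot.epsilon_sweep <- function(x, ...) {
  graphics::plot(x$eps_grid, x$prob, type = "b", ylim = c(0, 1),
                 xlab = "noise intensity", ylab = "transition probability",
                 ...)
  graphics::arrows(x$eps_grid, x$ci_lo, x$eps_grid, x$ci_hi,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = c(0.1, 0.9), lty = 3)
  invisible(x)
}

# a point on the warm attractor: the warm equilibrium itself when it is
# stable, otherwise the endpoint of a long settle onto the limit cycle
# (the focus is weakly unstable, so the cycle takes ~1e4 yr to develop)
warm_start <- function(params, t_settle = 20000) {
  eqs <- find_equilibria(params)
  w <- warm_interior(eqs)
  if (is.null(w)) stop("no warm interior equilibrium", call. = FALSE)
  if (startsWith(w$stability, "stable")) return(w$state)
  tr <- integrate_ode(c(w$state[["T"]] + 1e-3,
                        min(1, w$state[["A"]] + 1e-3)),
                      params, t_max = t_settle, dt = 0.01, stride = 100L)
  n <- length(tr$times)
  c(T = tr$T[n], A = tr$A[n])
}

#' Stationary temperature density from trajectories
#'
#' Pooled, normalized histogram of temperature samples after a burn-in.
#' When `pre_transition = TRUE` each trajectory is truncated at its first
#' passage below `T_threshold`, so that the accumulated snowball mass does
#' not dominate the density of the fluctuation regime.
#'
#' @param trajs A `climate_trajectory` or list of them.
#' @param burn_in Discarded initial span (yr).
#' @param bins Number of bins, or a vector of bin edges (K).
#' @param T_range Histogram support (K) when `bins` is a count.
#' @param pre_transition Truncate each trajectory at its first passage
#'   below `T_threshold`.
#' @param T_threshold Truncation threshold (K).
#' @return An object of class `density_estimate`: `bin_edges` (K), `mass`
#'   (sums to 1), `bin_width`, `n_samples`, `meta`.
#' @export
temperature_density <- function(trajs, burn_in = 500, bins = 60,
                                T_range = c(230, 310),
                                pre_transition = FALSE, T_threshold = 260) {
  if (inherits(trajs, "climate_trajectory")) trajs <- list(trajs)
  samples <- unlist(lapply(trajs, function(tr) {
    stopifnot(burn_in < max(tr$times))
    keep <- tr$times >= burn_in
    if (pre_transition) {
      fp <- detect_transition(tr, T_threshold)
      if (!is.na(fp)) keep <- keep & tr$times < fp
    }
    tr$T[keep]
  }))
  if (!length(samples)) stop("no samples after burn-in/truncation",
                             call. = FALSE)
  if (length(bins) == 1L) {
    edges <- seq(min(T_range[1], min(samples) - 1e-9),
                 max(T_range[2], max(samples) + 1e-9),
                 length.out = bins + 1L)
  } else {
    edges <- bins
    stopifnot(!is.unsorted(edges))
  }
  h <- graphics::hist(samples, breaks = edges, plot = FALSE)
  mass <- h$counts / sum(h$counts)
  eps0 <- trajs[[1L]]$meta$epsilon
  structure(list(bin_edges = edges, mass = mass,
                 bin_width = diff(edges), n_samples = length(samples),
                 meta = list(gamma = trajs[[1L]]$meta$params$gamma,
                             epsilon = eps0, burn_in = burn_in,
                             pre_transition = pre_transition)),
            class = "density_estimate")
}

density_stats <- function(dens) {
  mid <- (dens$bin_edges[-1] + dens$bin_edges[-length(dens$bin_edges)]) / 2
  m <- sum(mid * dens$mass)
  mode <- mid[which.max(dens$mass)]
  cdf <- cumsum(dens$mass)
  qf <- function(q) mid[which(cdf >= q)[1L]]
  c(mean_T = m, mode_T = mode, q05 = qf(0.05), q95 = qf(0.95))
}

#' Noise-induced shift of the temperature distribution
#'
#' Summarizes a series of temperature densities taken at increasing noise
#' intensities: mean and modal temperature and the central 90% interval
#' per level, plus a flag for a monotone decrease of the mean with noise
#' (the noise-induced cooling shift).
#'
#' @param densities List of `density_estimate` objects, ordered by their
#'   noise intensity (each carries `epsilon` in its metadata).
#' @return A data frame (`eps`, `mean_T`, `mode_T`, `q05`, `q95`,
#'   `width90`) with attribute `mean_decreasing`.
#' @export
shift_statistics <- function(densities) {
  stopifnot(length(densities) >= 2L)
  rows <- lapply(densities, function(d) {
    s <- density_stats(d)
    data.frame(eps = d$meta$epsilon, mean_T = s[["mean_T"]],
               mode_T = s[["mode_T"]], q05 = s[["q05"]], q95 = s[["q95"]],
               width90 = s[["q95"]] - s[["q05"]])
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$eps), ]
  attr(tab, "mean_decreasing") <- all(diff(tab$mean_T) < 0)
  tab
}
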