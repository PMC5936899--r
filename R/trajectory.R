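new_trajectory <- function(mat, params, dt, stride, epsilon = 0,
                           seed = NA_integer_, n_clamp = NA_real_,
                           n_steps = NA_real_) {
  structure(list(times = mat[, 1L], T = mat[, 2L], A = mat[, 3L],
                 meta = list(params = params, dt = dt, stride = stride,
                             epsilon = epsilon, seed = seed,
                             n_clamp = n_clamp, n_steps = n_steps)),
            class = "climate_trajectory")
}

#' @export
as.data.frame.climate_trajectory <- function(x, ...) {
  data.frame(time_yr = x$times, T_K = x$T, A = x$A)
}

#' @export
print.climate_trajectory <- function(x, ...) {
  m <- x$meta
  kind <- if (is.null(m$epsilon) || m$epsilon == 0) "deterministic"
          else sprintf("stochastic (epsilon = %g, seed = %s)",
                       m$epsilon, format(m$seed))
  cat(sprintf("Climate-vegetation trajectory, %s\n", kind))
  cat(sprintf("  %d points over %g yr (dt = %g yr, stride = %d)\n",
              length(x$times), max(x$times), m$dt, m$stride))
  cat(sprintf("  T in [%.2f, %.2f] K; A in [%.4f, %.4f]\n",
              min(x$T), max(x$T), min(x$A), max(x$A)))
  if (!is.null(m$n_clamp) && is.finite(m$n_clamp) && m$n_clamp > 0)
    cat(sprintf("  A clamped to [0,1] at %g of %g steps\n",
                m$n_clamp, m$n_steps))
  invisible(x)
}

#' Plot a trajectory
#'
#' Two stacked panels: temperature and vegetation fraction against time.
#'
#' @param x A `climate_trajectory`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.climate_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$times, x$T, type = "l", xlab = "time (yr)",
                 ylab = "T (K)", ...)
  graphics::plot(x$times, x$A, type = "l", xlab = "time (yr)",
                 ylab = "A", ylim = c(0, 1), ...)
  invisible(x)
}
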