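#' Ocean albedo ramp
#'
#' Piecewise-linear dependence of ocean albedo on temperature: the ocean is
#' fully ice-covered (albedo `alpha_max`) at `T <= T_alpha_l`, ice-free
#' (albedo `alpha_min`) for `T > T_alpha_u`, and the albedo interpolates
#' linearly in between.  Continuous everywhere; vectorized in `T`.
#'
#' @param T Temperature(s), kelvin.
#' @param params A [climate_params()] object.
#' @return Albedo value(s) in `[alpha_min, alpha_max]`.
#' @export
ocean_albedo <- function(T, params) {
  stopifnot(is.numeric(T), all(is.finite(T)))
  slope <- (params$alpha_min - params$alpha_max) /
    (params$T_alpha_u - params$T_alpha_l)
  ifelse(T <= params$T_alpha_l, params$alpha_max,
         ifelse(T > params$T_alpha_u, params$alpha_min,
                params$alpha_max + slope * (T - params$T_alpha_l)))
}

#' Planetary albedo
#'
#' Area-weighted albedo of the planet: ocean fraction `1 - p` at the
#' temperature-dependent ocean albedo, land fraction `p` split between
#' vegetation (`alpha_v`) and bare ground (`alpha_g`):
#' `alpha(T, A) = (1 - p) alpha_o(T) + p (alpha_v A + alpha_g (1 - A))`.
#' Affine and decreasing in `A` for fixed `T`.
#'
#' @inheritParams ocean_albedo
#' @param A Vegetated land fraction(s) in `[0, 1]`.
#' @export
planetary_albedo <- function(T, A, params) {
  if (any(!is.finite(A)) || any(A < 0) || any(A > 1))
    stop("A must lie in [0, 1]", call. = FALSE)
  (1 - params$p) * ocean_albedo(T, params) +
    params$p * (params$alpha_v * A + params$alpha_g * (1 - A))
}

#' Outgoing long-wave radiation
#'
#' Linearized outgoing energy flux `R0(T) = B0 + B1 (T - T_opt)`,
#' strictly increasing in `T`.
#'
#' @inheritParams ocean_albedo
#' @return Flux in W m^-2.
#' @export
outgoing_radiation <- function(T, params) {
  stopifnot(is.numeric(T), all(is.finite(T)))
  params$B0 + params$B1 * (T - params$T_opt)
}

#' Vegetation growth rate
#'
#' Parabolic temperature response of the vegetation growth rate,
#' `beta(T) = max(0, 1 - k (T - T_opt)^2)` (yr^-1): maximal (value 1) at
#' the optimum `T_opt`, zero outside `|T - T_opt| >= sqrt(1/k)`.
#'
#' @inheritParams ocean_albedo
#' @export
growth_rate <- function(T, params) {
  stopifnot(is.numeric(T), all(is.finite(T)))
  pmax(0, 1 - params$k * (T - params$T_opt)^2)
}

#' Deterministic drift field
#'
#' Right-hand side of the coupled system:
#' `dT/dt = ((1 - alpha(T, A)) Q0 - R0(T)) / C_T` (K yr^-1) and
#' `dA/dt = beta(T) A (1 - A) - gamma A` (yr^-1).  `A = 0` is an invariant
#' line: `dA/dt` is exactly zero there.
#'
#' @param state A state, `c(T, A)` or [climate_state()].
#' @param params A [climate_params()] object.
#' @return Named numeric vector `c(dT = , dA = )`.
#' @export
drift <- function(state, params) {
  state <- as_state(state)
  T <- state[["T"]]; A <- state[["A"]]
  dT <- ((1 - planetary_albedo(T, A, params)) * params$Q0 -
           outgoing_radiation(T, params)) / params$C_T
  dA <- growth_rate(T, params) * A * (1 - A) - params$gamma * A
  c(dT = dT, dA = dA)
}
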