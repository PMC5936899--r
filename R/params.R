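#' Physical parameters of the climate-vegetation model
#'
#' Constructs and validates the parameter set of the coupled
#' energy-balance / vegetation system.  The defaults are the standard
#' published calibration of the conceptual model: a planet with land
#' fraction `p`, ocean albedo ramping between an ice-covered and an
#' ice-free value, vegetation that is darker than bare ground
#' (`alpha_v < alpha_g`), a linearized outgoing long-wave flux, and a
#' parabolic vegetation growth rate peaking at `T_opt`.
#'
#' @param C_T Heat capacity of the climate system (W yr K^-1 m^-2).
#' @param Q0 Incoming solar flux (W m^-2).
#' @param p Land fraction of the planet surface, in `[0, 1]`.
#' @param alpha_v Albedo of vegetated land.
#' @param alpha_g Albedo of bare ground; must exceed `alpha_v` because
#'   forests and savannas absorb more energy than bare ground.
#' @param alpha_max Albedo of ice-covered ocean.
#' @param alpha_min Albedo of ice-free ocean.
#' @param T_alpha_l Temperature (K) at and below which the ocean is fully
#'   ice-covered.
#' @param T_alpha_u Temperature (K) above which the ocean is ice-free.
#' @param B0 Outgoing-flux constant (W m^-2), the flux emitted at `T_opt`.
#' @param B1 Outgoing-flux slope (W K^-1 m^-2).
#' @param T_opt Optimal vegetation growth temperature (K).
#' @param k Growth-curve width parameter (yr^-1 K^-2); vegetation growth is
#'   positive only for `|T - T_opt| < sqrt(1/k)`.
#' @param gamma Vegetation death rate (yr^-1).  This is the main bifurcation
#'   parameter of the model.
#'
#' @return An object of class `climate_params` (a validated named list).
#' @examples
#' p <- climate_params(gamma = 0.02)
#' p$Q0
#' @export
climate_params <- function(C_T = 500, Q0 = 342.5, p = 0.3,
                           alpha_v = 0.1, alpha_g = 0.4,
                           alpha_max = 0.85, alpha_min = 0.25,
                           T_alpha_l = 263, T_alpha_u = 300,
                           B0 = 200, B1 = 2.5,
                           T_opt = 283, k = 0.004, gamma = 0.02) {
  par <- list(C_T = C_T, Q0 = Q0, p = p,
              alpha_v = alpha_v, alpha_g = alpha_g,
              alpha_max = alpha_max, alpha_min = alpha_min,
              T_alpha_l = T_alpha_l, T_alpha_u = T_alpha_u,
              B0 = B0, B1 = B1, T_opt = T_opt, k = k, gamma = gamma)
  validate_climate_params(par)
  structure(par, class = "climate_params")
}

validate_climate_params <- function(par) {
  num1 <- function(nm) {
    x <- par[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("parameter '%s' must be a single finite number", nm),
           call. = FALSE)
  }
  for (nm in names(par)) num1(nm)
  chk <- function(ok, msg) if (!ok) stop("invalid climate_params: ", msg,
                                         call. = FALSE)
  chk(par$alpha_v < par$alpha_g, "alpha_v < alpha_g is required")
  chk(par$alpha_min < par$alpha_max, "alpha_min < alpha_max is required")
  chk(par$T_alpha_l < par$T_alpha_u, "T_alpha_l < T_alpha_u is required")
  for (nm in c("alpha_v", "alpha_g", "alpha_max", "alpha_min"))
    chk(par[[nm]] >= 0 && par[[nm]] <= 1,
        sprintf("%s must lie in [0, 1]", nm))
  chk(par$p >= 0 && par$p <= 1, "p must lie in [0, 1]")
  for (nm in c("C_T", "Q0", "B1", "k", "gamma"))
    chk(par[[nm]] > 0, sprintf("%s must be > 0", nm))
  invisible(par)
}

# fixed order used by the C++ integrators
param_vector <- function(params) {
  stopifnot(inherits(params, "climate_params"))
  unlist(params[c("C_T", "Q0", "p", "alpha_v", "alpha_g",
                  "alpha_max", "alpha_min", "T_alpha_l", "T_alpha_u",
                  "B0", "B1", "T_opt", "k", "gamma")])
}

#' @export
print.climate_params <- function(x, ...) {
  cat("Climate-vegetation model parameters\n")
  cat(sprintf("  energy balance: C_T=%g W yr/K/m^2, Q0=%g W/m^2, B0=%g, B1=%g\n",
              x$C_T, x$Q0, x$B0, x$B1))
  cat(sprintf("  albedos: land p=%g, alpha_v=%g, alpha_g=%g, ocean %g..%g over [%g, %g] K\n",
              x$p, x$alpha_v, x$alpha_g, x$alpha_max, x$alpha_min,
              x$T_alpha_l, x$T_alpha_u))
  cat(sprintf("  vegetation: T_opt=%g K, k=%g /yr/K^2, gamma=%g /yr\n",
              x$T_opt, x$k, x$gamma))
  invisible(x)
}

#' Construct a model state
#'
#' A phase point of the model: global mean temperature `T` (kelvin) and
#' vegetated land fraction `A`.
#'
#' @param T Global mean temperature in kelvin; finite and positive.
#' @param A Vegetated land fraction in `[0, 1]`.
#' @return A named numeric vector `c(T = , A = )`.
#' @export
climate_state <- function(T, A) {
  if (!is.finite(T) || T <= 0)
    stop("T must be finite and positive (kelvin)", call. = FALSE)
  if (!is.finite(A) || A < 0 || A > 1)
    stop("A must lie in [0, 1]", call. = FALSE)
  c(T = as.numeric(T), A = as.numeric(A))
}

as_state <- function(state) {
  if (is.list(state)) state <- unlist(state)
  if (length(state) != 2L)
    stop("state must have two components (T, A)", call. = FALSE)
  climate_state(state[[1L]], state[[2L]])
}
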