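#' Integrate the deterministic model
#'
#' Fixed-step 4th-order Runge-Kutta integration of the coupled
#' temperature/vegetation system.  The step is fixed (default 0.01 yr) so
#' that deterministic and stochastic runs share a time grid.  `A` is
#' clamped to `[0, 1]` after each step; for valid initial states the clamp
#' only absorbs machine-precision excursions.
#'
#' @param state0 Initial state, `c(T, A)`.
#' @param params A [climate_params()] object.
#' @param t_max Integration horizon (yr).
#' @param dt Time step (yr).
#' @param stride Record every `stride`-th step (thinning); the full `dt`
#'   is kept in the metadata.
#' @return A `climate_trajectory`.
#' @examples
#' p <- climate_params(gamma = 0.02)
#' tr <- integrate_ode(c(295, 0.8), p, t_max = 100)
#' @export
integrate_ode <- function(state0, params, t_max, dt = 0.01, stride = 1L) {
  state0 <- as_state(state0)
  stopifnot(dt > 0, t_max >= dt)
  n_steps <- as.integer(round(t_max / dt))
  stride <- as.integer(stride)
  if (n_steps %% stride != 0)
    stop("t_max/dt must be a multiple of stride", call. = FALSE)
  mat <- rk4_cpp(state0[["T"]], state0[["A"]], dt, n_steps, stride,
                 param_vector(params))
  new_trajectory(mat, params, dt, stride)
}

#' Jacobian of the drift field
#'
#' Analytic 2x2 matrix of partial derivatives of the deterministic drift.
#' The field is only piecewise smooth (ocean-albedo ramp breakpoints,
#' growth-support edges); at a seam the derivative of the segment the state
#' itself belongs to is used (the ramp slope applies for
#' `T_alpha_l < T <= T_alpha_u`, the growth-curve slope for
#' `beta(T) > 0`), matching the branch conventions of the model functions.
#'
#' @inheritParams drift
#' @return A 2x2 numeric matrix, rows d(dT/dt), d(dA/dt), columns d/dT, d/dA.
#' @export
jacobian <- function(state, params) {
  state <- as_state(state)
  T <- state[["T"]]; A <- state[["A"]]
  dao_dT <- if (T > params$T_alpha_l && T <= params$T_alpha_u)
    (params$alpha_min - params$alpha_max) /
      (params$T_alpha_u - params$T_alpha_l) else 0
  dalpha_dT <- (1 - params$p) * dao_dT
  dalpha_dA <- params$p * (params$alpha_v - params$alpha_g)
  b <- growth_rate(T, params)
  dbeta_dT <- if (b > 0) -2 * params$k * (T - params$T_opt) else 0
  matrix(c((-params$Q0 * dalpha_dT - params$B1) / params$C_T,
           -params$Q0 * dalpha_dA / params$C_T,
           dbeta_dT * A * (1 - A),
           b * (1 - 2 * A) - params$gamma),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("dT", "dA"), c("T", "A")))
}

classify_stability <- function(ev) {
  re <- Re(ev); im <- Im(ev)
  if (all(abs(im) < 1e-12)) {
    if (re[1] * re[2] < 0) return("saddle")
    if (all(re < 0)) return("stable-node")
    return("unstable-node")
  }
  if (max(re) < 0) "stable-focus" else "unstable-focus"
}

make_equilibrium <- function(T, A, branch, params) {
  ev <- eigen(jacobian(c(T, A), params), only.values = TRUE)$values
  structure(list(state = c(T = T, A = A), branch = branch,
                 eigenvalues = ev, stability = classify_stability(ev),
                 residual = drift(c(T, A), params)),
            class = "climate_equilibrium")
}

#' @export
print.climate_equilibrium <- function(x, ...) {
  cat(sprintf("%-16s T = %9.4f K  A = %.6f  [%s]  Re(lambda) = %.3e, %.3e\n",
              x$branch, x$state[["T"]], x$state[["A"]], x$stability,
              Re(x$eigenvalues[1]), Re(x$eigenvalues[2])))
  invisible(x)
}

#' @export
print.climate_equilibria <- function(x, ...) {
  cat(sprintf("%d equilibria (gamma = %g):\n", length(x),
              attr(x, "gamma")))
  for (e in x) print(e)
  invisible(x)
}

# Newton polish of a 1-D root with numerically differenced slope.
polish_root <- function(f, x, lower, upper, iter = 5L) {
  for (i in seq_len(iter)) {
    fx <- f(x)
    if (fx == 0) break
    h <- max(1e-9, abs(x) * 1e-9)
    dfx <- (f(x + h) - f(x - h)) / (2 * h)
    if (!is.finite(dfx) || dfx == 0) break
    xn <- x - fx / dfx
    if (!is.finite(xn) || xn <= lower || xn >= upper) break
    x <- xn
  }
  x
}

scan_roots <- function(f, grid) {
  v <- vapply(grid, f, numeric(1))
  roots <- numeric(0)
  for (i in seq_len(length(grid) - 1L)) {
    if (!is.finite(v[i]) || !is.finite(v[i + 1])) next
    if (v[i] == 0) { roots <- c(roots, grid[i]); next }
    if (sign(v[i]) != sign(v[i + 1])) {
      r <- stats::uniroot(f, c(grid[i], grid[i + 1]),
                          tol = .Machine$double.eps)$root
      roots <- c(roots, polish_root(f, r, grid[i], grid[i + 1]))
    }
  }
  if (length(grid) && is.finite(v[length(grid)]) && v[length(grid)] == 0)
    roots <- c(roots, grid[length(grid)])
  roots
}

#' Find all equilibria of the deterministic model
#'
#' Unions two one-dimensional root searches.  (a) The vegetation-free
#' branch `A = 0`: the energy balance `(1 - alpha(T, 0)) Q0 = R0(T)` is
#' solved segment by segment over the three ocean-albedo pieces (the
#' residual is only piecewise smooth, so brackets never straddle a ramp
#' breakpoint).  (b) The interior branch: the nontrivial vegetation
#' nullcline `A(T) = 1 - gamma/beta(T)` is substituted into the energy
#' balance.  Near the growth-support edges `A(T)` is extremely steep in
#' `T`, so this branch is parameterized by `A` instead,
#' `T(A) = T_opt +/- sqrt((1 - gamma/(1 - A))/k)`, one half-branch on each
#' side of the optimum, and the root search runs on a uniform `A` grid.
#' Duplicate roots within 1e-6 K are merged.  Each equilibrium is
#' classified by its Jacobian eigenvalues.
#'
#' @param params A [climate_params()] object.
#' @param T_range Temperature search interval (K) for the vegetation-free
#'   branch.
#' @return An object of class `climate_equilibria`: a list of
#'   `climate_equilibrium` entries (state, branch, eigenvalues, stability),
#'   sorted by temperature.
#' @examples
#' find_equilibria(climate_params(gamma = 0.02))
#' @export
find_equilibria <- function(params, T_range = c(230, 310)) {
  gamma <- params$gamma
  energy_residual <- function(T, A)
    (1 - planetary_albedo(T, A, params)) * params$Q0 -
      outgoing_radiation(T, params)

  eqs <- list()

  # (a) vegetation-free branch, per ocean-albedo segment
  cuts <- sort(unique(c(T_range, params$T_alpha_l, params$T_alpha_u)))
  cuts <- cuts[cuts >= T_range[1] & cuts <= T_range[2]]
  f0 <- function(T) energy_residual(T, 0)
  for (i in seq_len(length(cuts) - 1L)) {
    grid <- seq(cuts[i], cuts[i + 1], by = 0.1)
    if (grid[length(grid)] < cuts[i + 1]) grid <- c(grid, cuts[i + 1])
    for (r in scan_roots(f0, grid))
      eqs[[length(eqs) + 1L]] <- make_equilibrium(r, 0, "vegetation-free",
                                                  params)
  }

  # (b) interior branch, parameterized by A on each side of T_opt
  if (gamma < 1) {
    half_width <- sqrt(1 / params$k)
    Tof <- function(A, s) params$T_opt + s * sqrt((1 - gamma / (1 - A)) /
                                                    params$k)
    A_hi <- 1 - gamma  # beta(T) = 1 at most, so A(T) <= 1 - gamma
    A_grid <- seq(0, A_hi - 1e-12, length.out = 4001L)
    for (s in c(-1, 1)) {
      fI <- function(A) energy_residual(Tof(A, s), A)
      for (rA in scan_roots(fI, A_grid)) {
        Tr <- Tof(rA, s)
        if (Tr >= T_range[1] && Tr <= T_range[2])
          eqs[[length(eqs) + 1L]] <-
            make_equilibrium(Tr, 1 - gamma / growth_rate(Tr, params),
                             "interior", params)
      }
    }
  }

  # merge duplicates within 1e-6 K, sort by temperature
  Ts <- vapply(eqs, function(e) e$state[["T"]], numeric(1))
  keep <- !duplicated(round(Ts / 1e-6))
  eqs <- eqs[keep][order(Ts[keep])]
  structure(eqs, class = "climate_equilibria", gamma = gamma)
}

# warm interior equilibrium = interior root with the highest temperature
warm_interior <- function(eqs) {
  interior <- Filter(function(e) e$branch == "interior" &&
                       e$stability != "saddle", eqs)
  if (!length(interior)) return(NULL)
  interior[[which.max(vapply(interior, function(e) e$state[["T"]],
                             numeric(1)))]]
}

saddle_of <- function(eqs) {
  s <- Filter(function(e) e$stability == "saddle", eqs)
  if (!length(s)) return(NULL)
  s[[1L]]
}

#' Detect the warm limit cycle
#'
#' Integrates from the (unstable) warm interior equilibrium perturbed by
#' `1e-3` in both components, discards a settling transient, and extracts
#' the oscillation period from successive local maxima of `T`.  Returns a
#' cycle summary, or no cycle when the oscillation amplitude has decayed
#' below `1e-6` K (stable focus), or an escape report if the trajectory
#' leaves to the cold basin.
#'
#' @param params A [climate_params()] object.
#' @param t_settle Transient discarded before measuring (yr).  The warm
#'   focus is only weakly unstable (`Re(lambda)` of order 1e-3 to 1e-4
#'   per yr for the default calibration), so the relaxation cycle needs
#'   on the order of 1e4 yr to develop from a small perturbation; the
#'   default settle is sized accordingly.
#' @param t_obs Observation window (yr).
#' @param dt Integration step (yr).
#' @return A list with `status` (`"cycle"`, `"none"` or `"escaped"`) and,
#'   for a cycle, `period` (yr), `T_range` (K) and `A_range`.
#' @export
detect_limit_cycle <- function(params, t_settle = 20000, t_obs = 5000,
                               dt = 0.01) {
  eqs <- find_equilibria(params)
  w <- warm_interior(eqs)
  if (is.null(w))
    stop("no warm interior equilibrium for gamma = ", params$gamma,
         call. = FALSE)
  state0 <- c(w$state[["T"]] + 1e-3, min(1, w$state[["A"]] + 1e-3))
  tr <- integrate_ode(state0, params, t_max = t_settle + t_obs, dt = dt,
                      stride = 10L)
  obs <- tr$times > t_settle
  Tv <- tr$T[obs]; Av <- tr$A[obs]; tv <- tr$times[obs]
  if (min(Tv) < 260)
    return(list(status = "escaped", period = NA_real_,
                T_range = range(Tv), A_range = range(Av)))
  amp <- diff(range(Tv))
  if (amp < 1e-6)
    return(list(status = "none", period = NA_real_,
                T_range = range(Tv), A_range = range(Av)))
  # interior local maxima of T
  d <- diff(Tv)
  peak <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (length(peak) < 2L)
    return(list(status = "none", period = NA_real_,
                T_range = range(Tv), A_range = range(Av)))
  list(status = "cycle", period = mean(diff(tv[peak])),
       T_range = range(Tv), A_range = range(Av))
}

#' Stability scan over the vegetation death rate
#'
#' Evaluates the warm interior equilibrium and its Jacobian eigenvalues on
#' a grid of death rates `gamma`, and brackets the Andronov-Hopf
#' transition as the adjacent grid pair across which the real part of the
#' eigenvalues changes sign from positive to negative.  Optionally refines
#' the bracket by bisection on `Re(lambda)(gamma)`.
#'
#' @param params A [climate_params()] object (its `gamma` is ignored).
#' @param gamma_grid Ascending grid of death rates (yr^-1).
#' @param refine_tol If non-`NULL`, bisect the bracket down to this width.
#' @return A data frame with one row per `gamma` (`T`, `A`, `re`, `im`,
#'   `stability`; `NA` rows flag a missing interior equilibrium), with
#'   attributes `hopf_bracket` (length-2 numeric or `NULL`) and, when
#'   refined, `hopf_gamma`.
#' @export
scan_hopf <- function(params, gamma_grid, refine_tol = NULL) {
  stopifnot(!is.unsorted(gamma_grid))
  warm_re <- function(g) {
    pg <- params; pg$gamma <- g
    w <- warm_interior(find_equilibria(pg))
    if (is.null(w)) return(NULL)
    w
  }
  rows <- lapply(gamma_grid, function(g) {
    w <- warm_re(g)
    if (is.null(w))
      return(data.frame(gamma = g, T = NA_real_, A = NA_real_,
                        re = NA_real_, im = NA_real_,
                        stability = NA_character_))
    data.frame(gamma = g, T = w$state[["T"]], A = w$state[["A"]],
               re = max(Re(w$eigenvalues)),
               im = max(abs(Im(w$eigenvalues))),
               stability = w$stability)
  })
  tab <- do.call(rbind, rows)
  bracket <- NULL
  ok <- which(is.finite(tab$re))
  for (i in seq_len(length(ok) - 1L)) {
    a <- ok[i]; b <- ok[i + 1L]
    if (tab$re[a] > 0 && tab$re[b] < 0) { bracket <- c(tab$gamma[a],
                                                       tab$gamma[b]); break }
  }
  attr(tab, "hopf_bracket") <- bracket
  if (!is.null(bracket) && !is.null(refine_tol)) {
    lo <- bracket[1]; hi <- bracket[2]
    while (hi - lo > refine_tol) {
      mid <- (lo + hi) / 2
      w <- warm_re(mid)
      if (is.null(w)) break
      if (max(Re(w$eigenvalues)) > 0) lo <- mid else hi <- mid
    }
    attr(tab, "hopf_gamma") <- c(lo, hi)
  }
  tab
}

#' Compute the separatrix
#'
#' The separatrix between the warm and cold basins is the stable manifold
#' of the saddle equilibrium.  It is traced by reverse-time RK4
#' integration from the saddle displaced by `+/- 1e-6` along the stable
#' eigenvector, in both directions, until the trajectory leaves the box
#' `T` in `T_range`, `A` in `[0, 1]`.
#'
#' @param params A [climate_params()] object.
#' @param dt Step magnitude for the reverse-time integration (yr).
#' @param T_range Bounding temperatures (K).
#' @param max_steps Step cap per arm.
#' @return A matrix of class `separatrix` with columns `T_K`, `A`: the
#'   polyline through the saddle (one arm reversed, the saddle, the other
#'   arm).
#' @export
compute_separatrix <- function(params, dt = 0.01, T_range = c(230, 310),
                               max_steps = 200000L) {
  eqs <- find_equilibria(params)
  sad <- saddle_of(eqs)
  if (is.null(sad)) {
    stop("no saddle equilibrium found; equilibria are: ",
         paste(vapply(eqs, function(e)
           sprintf("(%.2f K, %.3f, %s)", e$state[["T"]], e$state[["A"]],
                   e$stability), character(1)), collapse = "; "),
         call. = FALSE)
  }
  J <- jacobian(sad$state, params)
  ed <- eigen(J)
  stable_idx <- which.min(Re(ed$values))
  v <- Re(ed$vectors[, stable_idx])
  v <- v / sqrt(sum(v^2))

  # drift without state validation: reverse-time RK4 stages may probe
  # slightly outside A in [0, 1], where the affine albedo extends smoothly
  draw <- function(st) {
    T <- st[1]; A <- st[2]
    a <- (1 - params$p) * ocean_albedo(T, params) +
      params$p * (params$alpha_v * A + params$alpha_g * (1 - A))
    c(((1 - a) * params$Q0 - outgoing_radiation(T, params)) / params$C_T,
      growth_rate(T, params) * A * (1 - A) - params$gamma * A)
  }
  trace_arm <- function(sgn) {
    x <- unname(sad$state) + sgn * 1e-6 * v
    pts <- matrix(NA_real_, nrow = max_steps, ncol = 2L)
    n <- 0L
    for (s in seq_len(max_steps)) {
      # one reverse-time RK4 step
      f <- function(st) -draw(st)
      k1 <- f(x); k2 <- f(x + 0.5 * dt * k1); k3 <- f(x + 0.5 * dt * k2)
      k4 <- f(x + dt * k3)
      x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (!all(is.finite(x))) break
      if (x[1] < T_range[1] || x[1] > T_range[2] ||
          x[2] < 0 || x[2] > 1) break
      n <- n + 1L
      pts[n, ] <- x
    }
    pts[seq_len(n), , drop = FALSE]
  }
  up <- trace_arm(+1)
  dn <- trace_arm(-1)
  out <- rbind(dn[rev(seq_len(nrow(dn))), , drop = FALSE],
               matrix(sad$state, ncol = 2),
               up)
  colnames(out) <- c("T_K", "A")
  structure(out, class = c("separatrix", class(out)), saddle = sad$state)
}

# bounding box of the warm attractor (point or cycle), padded by 2 K / 0.1 A
warm_attractor_box <- function(params, pad_T = 2, pad_A = 0.1) {
  eqs <- find_equilibria(params)
  w <- warm_interior(eqs)
  if (is.null(w)) stop("no warm interior equilibrium", call. = FALSE)
  if (startsWith(w$stability, "stable")) {
    Tr <- rep(w$state[["T"]], 2); Ar <- rep(w$state[["A"]], 2)
  } else {
    lc <- detect_limit_cycle(params)
    Tr <- lc$T_range; Ar <- lc$A_range
  }
  list(T = c(Tr[1] - pad_T, Tr[2] + pad_T),
       A = c(max(0, Ar[1] - pad_A), min(1, Ar[2] + pad_A)))
}

#' Classify the basin of attraction of an initial state
#'
#' Integrates the deterministic flow and labels the endpoint: `"cold"` if
#' the final temperature is within 1 K of the snowball equilibrium,
#' `"warm"` if the final state lies in a 2 K / 0.1 A neighbourhood of the
#' warm attractor (equilibrium point or limit-cycle bounding box),
#' `"undecided"` otherwise.
#'
#' @param state0 Initial state `c(T, A)`.
#' @param params A [climate_params()] object.
#' @param t_max Integration horizon (yr).
#' @param warm_box Optional precomputed warm-attractor box (as returned by
#'   the internal helper); pass it when classifying many points.
#' @param T_cold Snowball temperature (K); computed from the parameters
#'   when `NULL`.
#' @return One of `"warm"`, `"cold"`, `"undecided"`.
#' @export
basin_of <- function(state0, params, t_max = 3000, warm_box = NULL,
                     T_cold = NULL) {
  stopifnot(t_max > 0)
  if (is.null(T_cold))
    T_cold <- snowball_temperature(params)
  if (is.null(warm_box)) warm_box <- warm_attractor_box(params)
  tr <- integrate_ode(state0, params, t_max = t_max, dt = 0.01,
                      stride = 100L)
  n <- length(tr$times)
  Tf <- tr$T[n]; Af <- tr$A[n]
  if (abs(Tf - T_cold) < 1) return("cold")
  if (Tf >= warm_box$T[1] && Tf <= warm_box$T[2] &&
      Af >= warm_box$A[1] && Af <= warm_box$A[2]) return("warm")
  "undecided"
}

#' Snowball equilibrium temperature (closed form)
#'
#' On the vegetation-free, ice-covered branch the energy balance is
#' linear: `T = T_opt + ((1 - alpha(T,0)) Q0 - B0)/B1` with the planetary
#' albedo at its ice-covered constant.  Independent of the vegetation
#' death rate.
#'
#' @param params A [climate_params()] object.
#' @return Temperature in kelvin.
#' @export
snowball_temperature <- function(params) {
  alpha_cold <- (1 - params$p) * params$alpha_max + params$p * params$alpha_g
  params$T_opt + ((1 - alpha_cold) * params$Q0 - params$B0) / params$B1
}
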