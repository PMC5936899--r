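test_that("equilibria are fixed points of the integrator", {
  p <- p_gamma(0.02)
  tr <- integrate_ode(c(242.045, 0), p, t_max = 500, dt = 0.01,
                      stride = 100L)
  expect_lt(max(abs(tr$T - 242.045)), 1e-8)
  expect_true(all(tr$A == 0))
})

test_that("RK4 shows 4th-order step-size robustness and matches deSolve", {
  p <- p_gamma(0.02)
  end_state <- function(dt) {
    tr <- integrate_ode(c(295, 0.8), p, t_max = 1000, dt = dt,
                        stride = as.integer(1000 / dt))
    c(tr$T[length(tr$T)], tr$A[length(tr$A)])
  }
  e1 <- end_state(0.01); e2 <- end_state(0.005)
  expect_lt(abs(e1[1] - e2[1]), 1e-6)
  # independent adaptive solver as cross-check
  rhs <- function(t, y, parms) list(unname(drift(y, p)))
  sol <- deSolve::lsoda(c(T = 295, A = 0.8), seq(0, 200, by = 1), rhs,
                        NULL, rtol = 1e-10, atol = 1e-10)
  tr <- integrate_ode(c(295, 0.8), p, t_max = 200, dt = 0.01,
                      stride = 100L)
  expect_equal(tr$T, unname(sol[, "T"]), tolerance = 1e-6)
  expect_equal(tr$A, unname(sol[, "A"]), tolerance = 1e-6)
})

test_that("cold-basin initial conditions converge to the snowball state", {
  p <- p_gamma(0.02)
  tr <- integrate_ode(c(260, 0.5), p, t_max = 3000, dt = 0.01,
                      stride = 1000L)
  n <- length(tr$times)
  expect_equal(tr$T[n], 242.045, tolerance = 0.01)
  expect_lt(tr$A[n], 1e-6)
})

test_that("the warm limit cycle exists below the Hopf point and not above", {
  lc <- detect_limit_cycle(p_gamma(0.02))
  expect_equal(lc$status, "cycle")
  expect_gt(diff(lc$T_range), 1e-3)
  lc_stable <- detect_limit_cycle(p_gamma(0.1))
  expect_equal(lc_stable$status, "none")
})

test_that("the oscillation period decreases with the vegetation death rate", {
  p1 <- detect_limit_cycle(p_gamma(0.01))
  p2 <- detect_limit_cycle(p_gamma(0.02))
  expect_equal(p1$status, "cycle")
  expect_equal(p2$status, "cycle")
  expect_gt(p1$period, p2$period)
})

test_that("the Hopf scan brackets the stability change between 0.025 and 0.1", {
  tab <- scan_hopf(p_gamma(0.02), c(0.001, 0.01, 0.02, 0.025, 0.1, 0.35),
                   refine_tol = 1e-3)
  expect_true(all(tab$re[tab$gamma <= 0.025] > 0))
  expect_true(all(tab$re[tab$gamma >= 0.1] < 0))
  expect_equal(attr(tab, "hopf_bracket"), c(0.025, 0.1))
  refined <- attr(tab, "hopf_gamma")
  expect_lt(diff(refined), 1e-3 + 1e-12)
  expect_true(refined[1] >= 0.025 && refined[2] <= 0.1)
})

test_that("the separatrix passes through the saddle and splits the basins", {
  p <- p_gamma(0.02)
  sep <- compute_separatrix(p)
  sad <- attr(sep, "saddle")
  d <- sqrt((sep[, "T_K"] - sad[["T"]])^2 + (sep[, "A"] - sad[["A"]])^2)
  expect_lt(min(d), 1e-5)
  expect_lt(abs(sad[["T"]] - 279), 1.5)
  # displacements along the unstable eigenvector land in different basins
  J <- jacobian(sad, p)
  ed <- eigen(J)
  vu <- Re(ed$vectors[, which.max(Re(ed$values))])
  vu <- vu / sqrt(sum(vu^2))
  box <- vegclim:::warm_attractor_box(p)
  lab1 <- basin_of(sad + 1e-3 * vu, p, t_max = 8000, warm_box = box)
  lab2 <- basin_of(sad - 1e-3 * vu, p, t_max = 8000, warm_box = box)
  expect_setequal(c(lab1, lab2), c("warm", "cold"))
})

test_that("basin labels are consistent for unambiguous starting points", {
  p <- p_gamma(0.02)
  box <- vegclim:::warm_attractor_box(p)
  expect_equal(basin_of(c(242.05, 0), p, warm_box = box), "cold")
  expect_equal(basin_of(c(295, 0.8), p, warm_box = box), "warm")
  expect_equal(basin_of(c(260, 0.5), p, warm_box = box), "cold")
})
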