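test_that("ocean albedo follows the ramp with the published breakpoints", {
  p <- p_gamma(0.02)
  expect_equal(ocean_albedo(263, p), 0.85)
  expect_equal(ocean_albedo(250, p), 0.85)
  expect_equal(ocean_albedo(300.0001, p), 0.25)
  expect_equal(ocean_albedo(281.5, p), 0.55)
  # continuity at both breakpoints and monotone non-increasing
  expect_equal(ocean_albedo(263 + 1e-10, p), 0.85, tolerance = 1e-8)
  expect_equal(ocean_albedo(300, p), 0.25, tolerance = 1e-8)
  grid <- seq(230, 310, by = 0.05)
  expect_true(all(diff(ocean_albedo(grid, p)) <= 1e-12))
  expect_equal(ocean_albedo(grid, p),
               vapply(grid, oracle_ocean_albedo, numeric(1)))
})

test_that("planetary albedo is the published land/ocean mix", {
  p <- p_gamma(0.02)
  expect_equal(planetary_albedo(250, 0, p), 0.715)
  expect_equal(planetary_albedo(310, 1, p), 0.205)
  expect_equal(planetary_albedo(281.5, 0.5, p), 0.46)
  # affine decreasing in A; bounded for default parameters
  Ts <- seq(235, 305, length.out = 29)
  for (T in Ts) {
    a <- planetary_albedo(T, c(0, 0.5, 1), p)
    expect_true(all(diff(a) < 0))
    expect_equal(a[2], mean(a[c(1, 3)]))
  }
  grid <- expand.grid(T = Ts, A = seq(0, 1, by = 0.1))
  vals <- planetary_albedo(grid$T, grid$A, p)
  expect_true(all(vals >= 0.205 - 1e-12 & vals <= 0.715 + 1e-12))
  expect_error(planetary_albedo(280, 1.2, p), "\\[0, 1\\]")
  expect_error(planetary_albedo(280, -0.1, p), "\\[0, 1\\]")
})

test_that("outgoing radiation is linear in T with B0 at the optimum", {
  p <- p_gamma(0.02)
  expect_equal(outgoing_radiation(283, p), 200)
  expect_equal(outgoing_radiation(293, p), 225)
  # at the snowball temperature it balances the absorbed flux exactly
  expect_equal(outgoing_radiation(242.045, p), 97.6125)
  expect_equal(outgoing_radiation(242.045, p),
               (1 - planetary_albedo(242.045, 0, p)) * p$Q0)
})

test_that("vegetation growth rate is a clipped parabola around T_opt", {
  p <- p_gamma(0.02)
  expect_equal(growth_rate(283, p), 1)
  expect_equal(growth_rate(273, p), 0.6)
  expect_equal(growth_rate(299, p), 0)
  grid <- seq(230, 310, by = 0.1)
  g <- growth_rate(grid, p)
  expect_true(all(g >= 0))
  expect_equal(g, growth_rate(2 * p$T_opt - grid, p))  # symmetry
  expect_true(all(g[abs(grid - 283) >= sqrt(1 / 0.004)] == 0))
})

test_that("drift matches hand substitution and keeps A = 0 invariant", {
  p <- p_gamma(0.02)
  expect_equal(unname(drift(c(242.045, 0), p)), c(0, 0), tolerance = 1e-9)
  expect_identical(drift(c(283, 0), p)[["dA"]], 0)
  expect_equal(drift(c(283, 0.5), p)[["dA"]], 0.24)
  # dA/dt at A=1 is -gamma for every T
  for (T in c(240, 270, 283, 297, 305))
    expect_equal(drift(c(T, 1), p)[["dA"]], -p$gamma)
  # agreement with the independent oracle at assorted states
  for (st in list(c(250, 0.2), c(281.5, 0.7), c(299.5, 0.05)))
    expect_equal(unname(drift(st, p)),
                 oracle_drift(st[1], st[2], 0.02), tolerance = 1e-12)
})

test_that("parameter validation rejects unphysical configurations", {
  expect_error(climate_params(alpha_v = 0.5), "alpha_v < alpha_g")
  expect_error(climate_params(alpha_min = 0.9), "alpha_min < alpha_max")
  expect_error(climate_params(T_alpha_l = 301), "T_alpha_l < T_alpha_u")
  expect_error(climate_params(p = 1.2), "\\[0, 1\\]")
  expect_error(climate_params(gamma = -0.1), "> 0")
  expect_error(climate_params(Q0 = NA), "finite")
})
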