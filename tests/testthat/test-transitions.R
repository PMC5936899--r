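test_that("first-passage detection handles the unambiguous cases", {
  p <- p_gamma(0.02)
  warm <- integrate_ode(c(295, 0.8), p, t_max = 500, dt = 0.01,
                        stride = 10L)
  expect_true(is.na(detect_transition(warm, 260)))
  cold <- integrate_ode(c(242.045, 0), p, t_max = 10, dt = 0.01)
  expect_identical(detect_transition(cold, 260), 0)
})

test_that("a strongly forced warm state reaches the snowball neighbourhood", {
  p <- p_gamma(0.35)
  tr <- simulate_em(c(294.23, 0.293), p,
                    noise_config(0.7, seed = 1, t_max = 5000), stride = 10L)
  fp <- detect_transition(tr, 260)
  expect_false(is.na(fp))
  expect_lt(fp, 5000)
  expect_lt(min(tr$T), 260)
})

test_that("transition probability is zero without noise and at weak noise", {
  p01 <- p_gamma(0.01)
  start <- c(298.7, 0.09)
  tp0 <- transition_probability(p01, 0, n_runs = 10, state0 = start,
                                noise = noise_config(0, seed = 1,
                                                     t_max = 200))
  expect_identical(tp0$prob, 0)
  # well below the transition window: 5000-yr horizon, modest ensemble
  tp <- transition_probability(p01, 0.05, n_runs = 20, state0 = start,
                               noise = noise_config(0.05, seed = 100))
  expect_identical(tp$prob, 0)
})

test_that("Wilson intervals are valid and the sweep extracts a window", {
  ci <- vegclim:::wilson_interval(0, 20)
  expect_equal(ci[["lo"]], 0)
  expect_lt(ci[["hi"]], 0.2)
  ci <- vegclim:::wilson_interval(20, 20)
  expect_equal(ci[["hi"]], 1)
  p <- p_gamma(0.35)
  sw <- epsilon_sweep(p, c(0.45, 0.65, 0.85), n_runs = 20,
                      state0 = c(294.23, 0.293),
                      noise = noise_config(0, seed = 7))
  expect_true(all(sw$prob >= 0 & sw$prob <= 1))
  expect_true(all(sw$ci_lo <= sw$prob & sw$prob <= sw$ci_hi))
  # probability is monotone within the binomial uncertainty
  for (j in seq_len(length(sw$prob) - 1))
    expect_gte(sw$ci_hi[j + 1], sw$ci_lo[j])
  expect_false(is.na(sw$window[["lo"]]))
  expect_false(is.na(sw$window[["hi"]]))
  expect_lte(sw$window[["lo"]], sw$window[["hi"]])
})

test_that("temperature densities are normalized with support in range", {
  p <- p_gamma(0.35)
  trs <- simulate_ensemble(c(294.23, 0.293), p,
                           noise_config(0.3, seed = 40, t_max = 1500),
                           n_runs = 4, stride = 10L)
  d <- temperature_density(trs, burn_in = 500, bins = 60)
  expect_equal(sum(d$mass), 1, tolerance = 1e-12)
  expect_true(all(d$mass >= 0))
  mid <- (d$bin_edges[-1] + d$bin_edges[-61]) / 2
  expect_true(all(d$mass[mid < 230 | mid > 310] == 0))
  # noiseless run from the stable equilibrium: a single occupied bin
  tr0 <- simulate_em(c(294.2333, 0.2933), p,
                     noise_config(0, seed = 1, t_max = 1000), stride = 10L)
  d0 <- temperature_density(tr0, burn_in = 500, bins = 60)
  expect_equal(sum(d0$mass > 0), 1L)
})

test_that("noise shifts the temperature distribution down and broadens it", {
  p <- p_gamma(0.35)
  eq_T <- 294.2333
  mk <- function(eps, seed) {
    trs <- simulate_ensemble(c(294.2333, 0.2933), p,
                             noise_config(eps, seed = seed, t_max = 2000),
                             n_runs = 5, stride = 10L)
    temperature_density(trs, burn_in = 500, bins = 160,
                        pre_transition = TRUE)
  }
  d0 <- mk(0, 1); d1 <- mk(0.1, 50); d4 <- mk(0.4, 90)
  tab0 <- shift_statistics(list(d0, d1))
  expect_equal(tab0$mean_T[1], eq_T, tolerance = 0.1)
  tab <- shift_statistics(list(d1, d4))
  expect_lt(tab$mean_T[2], tab$mean_T[1])
  expect_gt(tab$width90[2], tab$width90[1])
  expect_true(attr(tab, "mean_decreasing"))
})
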