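test_that("total rates combine channels linearly and reject unknown channels", {
  p <- sensor_params(k_dil = 0.02, k_dr = 0.1,
                     per_channel_rates = list(green = c(0.02, 0.002),
                                              red = c(0.001, 0.015)))
  dark <- total_rates(p, c(green = 0, red = 0))
  expect_equal(dark$k1, 0)
  expect_equal(dark$k_tot, p$k_dil + p$k_dr)  # slowest transitions in the dark
  one <- total_rates(p, c(green = 3))
  expect_equal(one$k1, 3 * 0.02)
  expect_equal(one$k2, 3 * 0.002)
  both <- total_rates(p, c(green = 3, red = 7))
  g <- total_rates(p, c(green = 3)); r <- total_rates(p, c(red = 7))
  expect_equal(both$k1, g$k1 + r$k1)
  expect_equal(both$k2, g$k2 + r$k2)
  expect_error(total_rates(p, c(uv = 1)), "uv")
})

test_that("the step response matches its boundary conditions and a numeric integration", {
  expect_equal(step_response_y(0.3, 0.1, 0.2, 0), 0.3)
  expect_equal(step_response_y(0.3, 0.1, 0.2, 1e6), 0.5)
  expect_equal(step_response_y(0, 0.1, 0.2, log(2) / 0.2), 0.25)
  sol <- deSolve::lsoda(c(y = 0), c(0, log(2) / 0.2),
                        function(t, y, p) list(0.1 - 0.2 * y), NULL,
                        rtol = 1e-12, atol = 1e-13)
  expect_equal(step_response_y(0, 0.1, 0.2, log(2) / 0.2), as.numeric(sol[2, 2]),
               tolerance = 1e-10)
  expect_error(step_response_y(0, 0.1, 0, 1), "inconsistent")
})

test_that("piecewise-analytic propagation matches generic stiff integration", {
  set.seed(11)
  for (i in 1:10) {
    p <- random_sensor()
    prog <- random_program()
    tt <- seq(0, prog$t_end, by = 5)
    ya <- simulate_active_fraction(prog, p, y0 = runif(1, 0, 0.9), t_grid = tt)
    yo <- ode_active_fraction(prog, p, ya$y[1], tt)
    expect_lt(max(abs(ya$y - yo)), 1e-8)
  }
})

test_that("dark is absorbing without dark reversion and square waves reach a periodic orbit", {
  p <- sensor_params(k_dil = 0.02, k_dr = 0,
                     per_channel_rates = list(green = c(0.02, 0.002)))
  dark <- constant_program(c(green = 0), 200)
  tr <- simulate_active_fraction(dark, p, y0 = 0)
  expect_true(all(tr$y == 0))
  # square wave: per-period drift vanishes after many periods
  period <- 60
  times <- seq(0, 30 * period - 30, by = 30)
  ints <- rep(c(5, 0), 30)
  sq <- light_program(list(green = data.frame(time = times, intensity = ints)),
                      30 * period)
  tr <- simulate_active_fraction(sq, p, y0 = 0, t_grid = seq(0, 30 * period, by = period))
  drift <- abs(diff(tr$y))
  expect_lt(drift[25], 1e-6)
})

test_that("propagation is invariant to artificial breakpoints inside a constant segment", {
  p <- sensor_params(k_dil = 0.02, k_dr = 0.05,
                     per_channel_rates = list(green = c(0.02, 0.002)))
  a <- light_program(list(green = data.frame(time = 0, intensity = 4)), 100)
  b <- light_program(list(green = data.frame(time = c(0, 33.3, 71),
                                             intensity = c(4, 4, 4))), 100)
  tt <- seq(0, 100, by = 2.5)
  ya <- simulate_active_fraction(a, p, 0.1, tt)$y
  yb <- simulate_active_fraction(b, p, 0.1, tt)$y
  expect_lt(max(abs(ya - yb)), 1e-12)
})

test_that("the two-state system conserves, reduces to the y-ODE at pool steady state, and decays in the dark", {
  # conservation when production and dilution vanish
  p0 <- sensor_params(k_dil = 0, k_dr = 0.01, k_s = 0,
                      per_channel_rates = list(green = c(0.02, 0.002)))
  prog <- constant_program(c(green = 5), 120)
  ts <- simulate_two_state(prog, p0, c(2, 1), t_grid = seq(0, 120, 10))
  expect_lt(max(abs(ts$s_g + ts$s_a - 3)) / 3, 1e-10)

  # pool initialized at k_s/k_dil: the reduction is exact
  p <- sensor_params(k_dil = 0.02, k_dr = 0.05, k_s = 1,
                     per_channel_rates = list(green = c(0.02, 0.002)))
  tt <- seq(0, 240, 10)
  ts <- simulate_two_state(constant_program(c(green = 3), 240), p,
                           c(p$k_s / p$k_dil, 0), t_grid = tt)
  ya <- simulate_active_fraction(constant_program(c(green = 3), 240), p, 0,
                                 t_grid = tt)
  expect_lt(max(abs(ts$y - ya$y)), 1e-6)

  # dark decay of an all-active pool follows the k_dr + k_dil half-life
  dark <- constant_program(c(green = 0), 100)
  ts <- simulate_two_state(dark, p0, c(0, 1), t_grid = c(0, log(2) / (0.01 + 0)))
  expect_equal(ts$s_a[2], 0.5, tolerance = 1e-6)
})

test_that("steady-state fraction is monotone in the photoconversion rates", {
  base <- list(k_dil = 0.02, k_dr = 0.05)
  y_of <- function(k1, k2) {
    p <- sensor_params(base$k_dil, base$k_dr,
                       per_channel_rates = list(g = c(k1, k2)))
    steady_state_y(p, c(g = 1))
  }
  k1s <- seq(0.01, 0.05, by = 0.01)
  expect_true(all(diff(vapply(k1s, y_of, numeric(1), k2 = 0.01)) > 0))
  expect_true(all(diff(vapply(k1s, y_of, numeric(1), k1 = 0.03)) < 0))
  # time constant under light is faster than in the dark
  p <- sensor_params(base$k_dil, base$k_dr,
                     per_channel_rates = list(g = c(0.02, 0.01)))
  expect_lt(1 / total_rates(p, c(g = 5))$k_tot, 1 / (base$k_dil + base$k_dr))
})

test_that("dark-reversion half-life is ln 2 over k_dr", {
  expect_equal(dark_reversion_half_life(truth_rep$sensor), 5.5, tolerance = 1e-12)
  expect_equal(dark_reversion_half_life(truth_act$sensor), Inf)
})

test_that("active ratio clamps y near one with a message", {
  expect_equal(active_ratio(0.5), 1)
  expect_message(r <- active_ratio(1), "clamped")
  expect_lt(r, 1.01e12)
})
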