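# Small, fast fitting fixtures: a reduced design with the same four
# experiment classes, noiseless unless stated.
small_design <- characterization_design(
  dynamic_led = "red", background = c(red = 1.25),
  step_intensities = 20 / 4^(3:0),
  times = c(30, 60, 120, 200, 320, 480),
  spectral_leds = responsive_leds(truth_rep, 6),
  spectral_intensities = 0.05 * 400^((0:3) / 3),
  replicates = 1)

warm_start <- function(truth, dataset) {
  leds <- sort(unique(c(dataset$led_id, dataset$bg_led[!is.na(dataset$bg_led)])))
  c(list(k_dil = truth$sensor$k_dil, k_dr = truth$sensor$k_dr,
         tau = truth$output$tau, n = truth$output$n,
         a_hat = truth$output$a_hat, b_hat = truth$output$b_hat),
    stats::setNames(lapply(leds, function(l) truth$sensor$per_channel_rates[[l]][1]),
                    paste0("k1.", leds)),
    stats::setNames(lapply(leds, function(l) truth$sensor$per_channel_rates[[l]][2]),
                    paste0("k2.", leds)))
}

ds0 <- generate_characterization(truth_rep, small_design, seed = 5, noise_cv = 0)

test_that("a noiseless dataset started near the truth is recovered to 0.1%", {
  fit <- fit_global(ds0, mode = "repressing",
                    fixed = list(big_k = truth_rep$output$big_k),
                    start = warm_start(truth_rep, ds0), n_starts = 1)
  expect_true(fit$converged)
  expect_lt(fit$objective, 1e-12)   # model self-consistency at the optimum
  expect_lt(rel_err(fit$output$k_dil, truth_rep$sensor$k_dil), 1e-3)
  expect_lt(rel_err(fit$sensor$k_dr, truth_rep$sensor$k_dr), 1e-3)
  expect_lt(rel_err(fit$output$tau, truth_rep$output$tau), 1e-3)
  expect_lt(rel_err(fit$output$n, truth_rep$output$n), 1e-3)
  expect_lt(rel_err(fit$output$a_hat, truth_rep$output$a_hat), 1e-3)
  expect_lt(rel_err(fit$output$b_hat, truth_rep$output$b_hat), 1e-3)
  for (l in fit$leds) {
    expect_lt(rel_err(fit$k_hats[[l]][1], truth_rep$sensor$per_channel_rates[[l]][1]), 1e-3)
    expect_lt(rel_err(fit$k_hats[[l]][2], truth_rep$sensor$per_channel_rates[[l]][2]), 1e-3)
  }
})

test_that("a flat dataset is flagged as degenerate, not silently fit", {
  flat <- ds0
  flat$fluorescence <- 1000
  expect_warning(fit <- fit_global(flat, mode = "repressing"), "degenerate")
  expect_true(fit$degenerate)
})

test_that("the fit is invariant to row order and rescales with fluorescence units", {
  f1 <- fit_global(ds0, mode = "repressing",
                   fixed = list(big_k = truth_rep$output$big_k),
                   start = warm_start(truth_rep, ds0), n_starts = 1)
  set.seed(9)
  perm <- sample(nrow(ds0))
  f2 <- fit_global(ds0[perm, ], mode = "repressing",
                   fixed = list(big_k = truth_rep$output$big_k),
                   start = warm_start(truth_rep, ds0), n_starts = 1)
  expect_equal(f1$objective, f2$objective, tolerance = 1e-8)
  expect_equal(f1$output$n, f2$output$n, tolerance = 1e-6)

  scaled <- ds0
  scaled$fluorescence <- 10 * scaled$fluorescence
  ws <- warm_start(truth_rep, ds0)
  ws$a_hat <- ws$a_hat * 10; ws$b_hat <- ws$b_hat * 10
  f3 <- fit_global(scaled, mode = "repressing",
                   fixed = list(big_k = truth_rep$output$big_k),
                   start = ws, n_starts = 1)
  expect_equal(f3$output$a_hat / f1$output$a_hat, 10, tolerance = 1e-4)
  expect_equal(f3$output$b_hat / f1$output$b_hat, 10, tolerance = 1e-4)
  expect_equal(f3$output$n, f1$output$n, tolerance = 1e-4)
  expect_equal(f3$k_hats[[1]][1], f1$k_hats[[1]][1], tolerance = 1e-4)
})

test_that("a dataset missing an experiment class warns but fits", {
  sub <- ds0[ds0$class %in% c("spectral_fwd", "spectral_rev"), ]
  expect_warning(fit_global(sub, mode = "repressing",
                            fixed = list(big_k = truth_rep$output$big_k,
                                         tau = truth_rep$output$tau,
                                         k_dil = truth_rep$sensor$k_dil),
                            start = warm_start(truth_rep, sub), n_starts = 1),
                 "dynamic")
})

test_that("profiling K with the best-fit K attains the fit's own objective", {
  fit <- fit_global(ds0, mode = "repressing",
                    fixed = list(big_k = truth_rep$output$big_k),
                    start = warm_start(truth_rep, ds0), n_starts = 1)
  prof <- profile_k(ds0, fit, k_values = truth_rep$output$big_k)
  expect_lte(prof$objective[1], fit$objective + 1e-10)
})

test_that("output-only refitting recovers dual Hill parameters and rejects empty grids", {
  dual <- make_ground_truth("dual")
  grid <- generate_dual_grid(dual, seed = 3, noise_cv = 0)
  sensing <- list(a = dual$systems$a$sensor, b = dual$systems$b$sensor)
  refit <- refit_output_only(grid, sensing,
                             taus = c(a = dual$systems$a$output$tau,
                                      b = dual$systems$b$output$tau))
  for (sys in c("a", "b")) {
    tru <- dual$systems[[sys]]$output
    expect_lt(rel_err(refit[[sys]]$a_hat, tru$a_hat), 1e-3)
    expect_lt(rel_err(refit[[sys]]$b_hat, tru$b_hat), 1e-3)
    expect_lt(rel_err(refit[[sys]]$n, tru$n), 1e-3)
    expect_lt(rel_err(refit[[sys]]$big_k, tru$big_k), 1e-3)
  }
  expect_error(refit_output_only(grid[0, ], sensing), "empty")
  # a grid with missing cells still fits
  drop <- data.frame(green = grid$green[1:4], red = grid$red[1:4])
  grid2 <- generate_dual_grid(dual, seed = 3, noise_cv = 0, drop_cells = drop)
  expect_lt(nrow(grid2), nrow(grid))
  refit2 <- refit_output_only(grid2, sensing,
                              taus = c(a = 10, b = 6))
  expect_lt(rel_err(refit2$a$n, dual$systems$a$output$n), 1e-3)
})

test_that("noisy recovery: the reduced design still pins the global parameters", {
  ds <- generate_characterization(truth_rep, small_design, seed = 21, noise_cv = 0.05)
  fit <- fit_global(ds, mode = "repressing",
                    fixed = list(big_k = truth_rep$output$big_k),
                    start = warm_start(truth_rep, ds), n_starts = 1)
  expect_lt(rel_err(fit$output$k_dil, truth_rep$sensor$k_dil), 0.1)
  expect_lt(rel_err(fit$sensor$k_dr, truth_rep$sensor$k_dr), 0.1)
  # the single-replicate reduced design supports tau only coarsely
  expect_lt(rel_err(fit$output$tau, truth_rep$output$tau), 0.35)
})
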