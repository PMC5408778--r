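rng_act <- steady_state_range(truth_act, "green")

test_that("reference construction follows the stated waveform formulas", {
  ref <- reference_preset("dual_sines_mcherry", c(100, 1600))
  expect_equal(reference_frac(ref, 120), 0.8)              # 0.5 + 0.3 sin(pi/2)
  # on a 16-fold range, the 50% log-scale level sits at G_min * 4
  expect_equal(reference_level(build_reference(
    list(list(type = "hold", level = 0.5, duration = 10)), c(100, 1600)), 5), 400)
  # the shifted waveform equals the original evaluated 60 min earlier
  w <- reference_preset("waveform", c(100, 1600))
  ws <- reference_preset("waveform_shifted", c(100, 1600))
  tt <- seq(60, w$t_end, by = 7)
  expect_equal(reference_frac(ws, tt), reference_frac(w, tt - 60), tolerance = 1e-12)
  expect_error(build_reference(list(list(type = "ramp", from = 0, to = 1.4,
                                         duration = 100)), c(100, 1600)),
               "outside \\[0, 1\\]")
})

test_that("a constant dark-level reference designs an all-dark program with zero error", {
  ref <- build_reference(list(list(type = "hold", level = 0, duration = 240)), rng_act)
  prog <- design_program(ref, truth_act$sensor, truth_act$output, "green", refine = 0)
  expect_equal(max(prog$channels$green$intensity), 0)
  expect_lt(attr(prog, "rmse"), 1e-3)
})

test_that("compensating a zero-intensity external signal changes nothing", {
  ref <- build_reference(list(
    list(type = "ramp", from = 0.1, to = 0.6, duration = 120),
    list(type = "hold", level = 0.6, duration = 120)), rng_act)
  zero_ext <- constant_program(c(red = 0), 240)
  p1 <- design_program(ref, truth_act$sensor, truth_act$output, "green", refine = 1)
  p2 <- design_program(ref, truth_act$sensor, truth_act$output, "green",
                       external = zero_ext, refine = 1)
  expect_equal(p1$channels$green$intensity, p2$channels$green$intensity,
               tolerance = 1e-8)
})

test_that("the reported objective equals the tracking error recomputed from the program", {
  ref <- build_reference(list(
    list(type = "sin", offset = 0.5, amplitude = 0.25, period = 480,
         duration = 480)), rng_act)
  prog <- design_program(ref, truth_act$sensor, truth_act$output, "green",
                         refine = 1)
  t_eval <- seq(0, 480, by = 2)
  sim <- simulate_system(prog, truth_act$sensor, truth_act$output,
                         precondition = attr(prog, "precondition"),
                         t_grid = t_eval)
  expect_equal(attr(prog, "rmse"),
               rmse_log10(sim$g, reference_level(ref, t_eval)),
               tolerance = 1e-10)
  expect_lt(attr(prog, "rmse"), 0.05)
})

test_that("designed programs respect intensity bounds and 12-bit quantization", {
  ref <- build_reference(list(
    list(type = "ramp", from = 0, to = 0.9, duration = 160),
    list(type = "ramp", from = 0.9, to = 0.3, duration = 160)), rng_act)
  prog <- design_program(ref, truth_act$sensor, truth_act$output, "green",
                         constraints = list(i_max = 12), refine = 1)
  expect_true(all(prog$channels$green$intensity >= 0 &
                  prog$channels$green$intensity <= 12))
  q <- quantize_program(prog, c(green = 12))
  expect_true(all(q$channels$green$intensity >= 0 &
                  q$channels$green$intensity <= 12))
  gs <- program_to_grayscale(prog, c(green = 12))
  expect_true(all(gs$gs_level %in% 0:4095))
  # quantization moves the achieved tracking error only marginally
  t_eval <- seq(0, 320, 2)
  rq <- rmse_log10(simulate_system(q, truth_act$sensor, truth_act$output,
                                   precondition = attr(prog, "precondition"),
                                   t_grid = t_eval)$g,
                   reference_level(ref, t_eval))
  expect_lt(abs(rq - attr(prog, "rmse")), 0.01)
})

test_that("an unreachable reference is flagged infeasible with its clip fraction", {
  # demands a level above the system's achievable envelope
  ref <- build_reference(list(list(type = "hold", level = 1, duration = 240)),
                         c(rng_act[1], rng_act[2] * 50))
  prog <- design_program(ref, truth_act$sensor, truth_act$output, "green",
                         refine = 0)
  expect_false(attr(prog, "feasible"))
  expect_gt(attr(prog, "clip_fraction"), 0.5)
})

test_that("multiplexed design inverts constant references and compensates the red program", {
  dual <- make_ground_truth("dual")
  ra <- build_reference(list(list(type = "hold", level = 0.5, duration = 240)),
                        steady_state_range(dual$systems$a, "green"))
  rb <- build_reference(list(list(type = "hold", level = 0.5, duration = 240)),
                        steady_state_range(dual$systems$b, "red"))
  mx <- design_multiplexed(ra, rb, dual, refine = 1)
  expect_lt(mx$joint_rmse[["a"]], 0.02)
  expect_lt(mx$joint_rmse[["b"]], 0.05)
  # the compensated green differs from a red-blind design when red is on
  solo <- design_program(ra, dual$systems$a$sensor, dual$systems$a$output,
                         "green", refine = 0)
  expect_gt(max(abs(mx$a$channels$green$intensity -
                    solo$channels$green$intensity)), 1e-4)
  # swapped order runs and returns both programs
  mx2 <- design_multiplexed(ra, rb, dual, order = c("a", "b"), refine = 0)
  expect_s3_class(mx2$a, "light_program")
  expect_s3_class(mx2$b, "light_program")
})
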