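# Shared fixtures: small ground truths and an independent ODE oracle for the
# active-fraction dynamics (generic stiff integration chained over program
# breakpoints, never the analytic step solution).

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

truth_act <- make_ground_truth("ccasr_like")
truth_rep <- make_ground_truth("cph8_like")

# deSolve-based oracle for dy/dt = k1 - k_tot * y under a light program
ode_active_fraction <- function(program, params, y0, times,
                                rtol = 1e-12, atol = 1e-13) {
  bks <- program_breakpoints(program)
  y <- y0
  out <- numeric(length(times))
  for (i in seq_len(length(bks) - 1L)) {
    t0 <- bks[i]; t1 <- bks[i + 1L]
    ints <- vapply(names(program$channels),
                   function(nm) program_intensity(program, nm, t0), numeric(1))
    kk <- total_rates(params, ints)
    tt <- sort(unique(c(t0, times[times > t0 & times <= t1], t1)))
    sol <- deSolve::lsoda(c(y = y), tt,
                          function(t, y, p) list(p$k1 - p$k_tot * y),
                          parms = kk, rtol = rtol, atol = atol)
    sel <- sol[, 1L] %in% times
    out[match(sol[sel, 1L], times)] <- sol[sel, 2L]
    y <- sol[nrow(sol), 2L]
  }
  if (0 %in% times) out[times == 0] <- y0
  out
}

# random piecewise-constant single-channel program
random_program <- function(t_end = 240, max_segments = 6, i_max = 20,
                           channel = "green") {
  n <- sample.int(max_segments, 1L)
  times <- sort(c(0, runif(n - 1L, 0, t_end * 0.95)))
  ints <- runif(n, 0, i_max) * rbinom(n, 1L, 0.8)
  light_program(stats::setNames(list(data.frame(time = times, intensity = ints)),
                                channel), t_end)
}

random_sensor <- function() {
  sensor_params(k_dil = runif(1, 0.005, 0.05), k_dr = runif(1, 0, 0.2),
                per_channel_rates = list(green = c(runif(1, 1e-4, 0.05),
                                                   runif(1, 1e-4, 0.05))))
}
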