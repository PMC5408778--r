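# End-to-end simulation: light program -> photoconversion rates -> active
# fraction -> delayed Hill production -> output level. Plus steady-state
# dose-response sweeps and the log10 prediction-error metric.

# Exact active-fraction evaluation at arbitrary times from a segment table.
eval_active_fraction <- function(segs, y0, times) {
  y_at_start <- numeric(nrow(segs))
  ycur <- y0
  for (i in seq_len(nrow(segs))) {
    y_at_start[i] <- ycur
    ycur <- step_response_y(ycur, segs$k1[i], segs$k_tot[i], segs$t1[i] - segs$t0[i])
  }
  out <- numeric(length(times))
  idx <- findInterval(pmin(pmax(times, segs$t0[1L]), segs$t1[nrow(segs)]),
                      segs$t0, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(segs))
  for (i in unique(idx)) {
    sel <- idx == i
    tt <- pmin(pmax(times[sel], segs$t0[i]), segs$t1[i]) - segs$t0[i]
    out[sel] <- step_response_y(y_at_start[i], segs$k1[i], segs$k_tot[i], tt)
  }
  out
}

#' Simulate the complete light-to-expression system
#'
#' Composes the sensing and output models: the program's per-channel
#' intensities set the photoconversion rates, the active fraction is
#' propagated piecewise-analytically, the active ratio is delayed by tau and
#' mapped through the Hill function, and the output integrates first-order
#' production/dilution. Initial conditions are the steady state of the
#' preconditioning light environment.
#'
#' @param program A `light_program`.
#' @param sensor A `sensor_params`.
#' @param output An `output_params`.
#' @param precondition Named intensity vector describing the preconditioning
#'   environment (default: dark).
#' @param t_grid Output sampling times (min); defaults to `dt` spacing.
#' @param dt Internal dense-grid step (min, default 0.5). The signaling delay
#'   and expression integral are evaluated on this grid.
#' @return data.frame of class `expression_trajectory` with `time`, `g`,
#'   `kg`, `y`, `r` (the undelayed active ratio).
#' @export
simulate_system <- function(program, sensor, output, precondition = numeric(0),
                            t_grid = NULL, dt = 0.5) {
  y0 <- steady_state_y(sensor, precondition)
  r_pre <- active_ratio(y0)
  g0 <- steady_state_g(r_pre, output)
  bks <- program_breakpoints(program)
  # the production rate has kinks at tau and at every breakpoint + tau:
  # keeping them on the grid preserves the integrator's accuracy order
  dense <- sort(unique(c(seq(0, program$t_end, by = dt), program$t_end,
                         bks, output$tau, bks + output$tau)))
  dense <- dense[dense <= program$t_end + 1e-12]
  segs <- program_rate_segments(program, sensor)
  # exact delayed lookup: evaluate the analytic solution at t - tau directly
  kg_at <- function(tt) {
    td <- tt - output$tau
    y_del <- ifelse(td < 0, y0, eval_active_fraction(segs, y0, pmax(td, 0)))
    production_rate(active_ratio(y_del), output)
  }
  y <- eval_active_fraction(segs, y0, dense)
  kg <- kg_at(dense)
  mids <- (dense[-1L] + dense[-length(dense)]) / 2
  g <- integrate_expression(dense, kg, output$k_dil, g0, kg_mid = kg_at(mids))
  res <- data.frame(time = dense, g = g, kg = kg, y = y, r = active_ratio(y))
  if (!is.null(t_grid)) {
    res <- data.frame(time = t_grid,
                      g = stats::approx(dense, g, t_grid, rule = 2)$y,
                      kg = stats::approx(dense, kg, t_grid, rule = 2)$y,
                      y = stats::approx(dense, y, t_grid, rule = 2)$y,
                      r = stats::approx(dense, active_ratio(y), t_grid, rule = 2)$y)
  }
  class(res) <- c("expression_trajectory", "data.frame")
  res
}

#' Closed-form steady-state output for a constant light environment
#'
#' R* = k1 / (k2 + k_dil + k_dr) and G* = k_G(R*) / k_dil.
#'
#' @param sensor A `sensor_params`.
#' @param output An `output_params`.
#' @param intensities Named intensity vector.
#' @return List `r_star`, `g_star`.
#' @export
steady_state_system <- function(sensor, output, intensities = numeric(0)) {
  kk <- total_rates(sensor, intensities)
  denom <- kk$k2 + sensor$k_dil + sensor$k_dr
  r_star <- if (denom <= 0) 0 else kk$k1 / denom
  list(r_star = r_star, g_star = steady_state_g(r_star, output))
}

#' Steady-state intensity dose-response
#'
#' Sweeps a foreground channel over a ladder of intensities, optionally on
#' top of a fixed background channel (the reverse-photoconversion
#' characterization design), and returns the closed-form steady-state output
#' at each point.
#'
#' @param channel Foreground channel name.
#' @param intensities Nonnegative intensity ladder.
#' @param sensor A `sensor_params`.
#' @param output An `output_params`.
#' @param background Optional named vector, e.g. `c(green = 1.25)`.
#' @return data.frame `intensity`, `r_star`, `g_star`.
#' @export
dose_response <- function(channel, intensities, sensor, output,
                          background = NULL) {
  if (any(intensities < 0)) stop("intensities must be nonnegative")
  rows <- lapply(intensities, function(i) {
    env <- c(stats::setNames(i, channel),
             if (is.null(background)) numeric(0) else background)
    ss <- steady_state_system(sensor, output, env)
    data.frame(intensity = i, r_star = ss$r_star, g_star = ss$g_star)
  })
  do.call(rbind, rows)
}

#' Root-mean-square log10 prediction error
#'
#' The relative error metric used for model validation:
#' sqrt(mean(log10(pred/measured)^2)), in log10 decades. It is symmetric in
#' its arguments and invariant to a common positive rescaling of both.
#'
#' @param predicted,measured Positive vectors of equal length.
#' @return RMSE in decades.
#' @export
rmse_log10 <- function(predicted, measured) {
  if (length(predicted) != length(measured))
    stop("predicted and measured must have equal length")
  bad <- which(predicted <= 0 | measured <= 0)
  if (length(bad))
    stop(sprintf("nonpositive values at indices: %s",
                 paste(utils::head(bad, 10L), collapse = ", ")))
  sqrt(mean(log10(predicted / measured)^2))
}
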