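# Synthetic ground truth and characterization data. A ground truth fully
# specifies a light-sensing TCS: smooth photoconversion cross sections,
# a bank of Gaussian LED spectra with per-LED unit photoconversion rates
# derived by overlap integrals, sensor/output kinetic parameters, and a
# multiplicative log-normal noise model. Every other module is testable from
# these with no external data.

gaussian_mixture <- function(components) {
  force(components)
  function(lambda) {
    out <- numeric(length(lambda))
    for (i in seq_len(nrow(components))) {
      sdev <- components$fwhm[i] / (2 * sqrt(2 * log(2)))
      out <- out + components$amp[i] * exp(-(lambda - components$center[i])^2 / (2 * sdev^2))
    }
    out
  }
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                   rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

# Default cross-section shapes (min^-1 per micromol m^-2 s^-1, peak values).
# Main photochemical band plus a UV/blue Soret-like shoulder and a shallow
# broad base, as seen for bilin-binding photoreceptors; widths >= 70 nm keep
# the shapes within reach of a 5-20-knot cubic spline.
sigma_defaults <- function(system) {
  if (system == "ccasr_like") {
    list(
      # the ground-state red tail is kept weak: red light must predominantly
      # revert the sensor (push-pull orthogonality of the green/red pair)
      sigma_g = data.frame(amp = c(0.020, 0.010, 0.002),
                           center = c(535, 400, 600), fwhm = c(80, 100, 80)),
      sigma_a = data.frame(amp = c(0.016, 0.007, 0.008),
                           center = c(672, 545, 395), fwhm = c(70, 120, 100)))
  } else {
    list(
      sigma_g = data.frame(amp = c(0.022, 0.010, 0.006),
                           center = c(650, 380, 520), fwhm = c(70, 100, 160)),
      sigma_a = data.frame(amp = c(0.018, 0.008, 0.006),
                           center = c(705, 400, 560), fwhm = c(60, 100, 180)))
  }
}

#' Bank of Gaussian spectral LEDs
#'
#' 23 Gaussian emission spectra with centroids evenly spanning 369--958 nm
#' (FWHM 25 nm), plus named `green` (526 nm) and `red` (657 nm) LEDs used for
#' dynamic characterization, backgrounds, and program design. Each entry
#' carries its unit-intensity spectrum and a calibrated maximum intensity.
#'
#' @param n_spectral Number of spectral LEDs.
#' @param centroid_range Centroid span (nm).
#' @param fwhm LED full width at half maximum (nm).
#' @param max_intensity Calibrated full-scale intensity (micromol m^-2 s^-1).
#' @param grid Wavelength grid.
#' @return Named list of entries `list(unit, centroid, max_intensity)`.
#' @export
led_bank <- function(n_spectral = 23, centroid_range = c(369, 958), fwhm = 25,
                     max_intensity = 20, grid = common_grid()) {
  cents <- seq(centroid_range[1L], centroid_range[2L], length.out = n_spectral)
  ids <- sprintf("led_%03.0f", cents)
  bank <- stats::setNames(lapply(seq_along(cents), function(i) {
    sp <- gaussian_spectrum(cents[i], fwhm, grid = grid, label = ids[i])
    list(unit = normalize_to_unit_intensity(sp), centroid = cents[i],
         max_intensity = max_intensity)
  }), ids)
  for (extra in list(list(id = "green", c = 526), list(id = "red", c = 657))) {
    sp <- gaussian_spectrum(extra$c, fwhm, grid = grid, label = extra$id)
    bank[[extra$id]] <- list(unit = normalize_to_unit_intensity(sp),
                             centroid = extra$c, max_intensity = max_intensity)
  }
  bank
}

bank_rates <- function(bank, sigma_g_fun, sigma_a_fun) {
  stats::setNames(lapply(bank, function(e)
    c(unit_photoconversion_rate(sigma_g_fun, e$unit),
      unit_photoconversion_rate(sigma_a_fun, e$unit))), names(bank))
}

#' Construct a synthetic ground-truth system
#'
#' Fully specifies a light-sensing TCS from known parameters: cross sections
#' (Gaussian mixtures), an LED bank with overlap-derived unit photoconversion
#' rates, sensor kinetics, and delayed-Hill output parameters.
#'
#' Defaults emulate the two engineered E. coli systems: `"ccasr_like"` is an
#' activating system (ground/active bands near 535/672 nm, no detectable dark
#' reversion, 60-fold output range, growth dilution ln(2)/37.4 min^-1);
#' `"cph8_like"` is a repressing system (bands near 650/705 nm, dark-reversion
#' half-life 5.5 min, 210-fold range, dilution ln(2)/37.9 min^-1). `"dual"`
#' pairs the two in one cell with a recalibrated mCherry output (6-fold range,
#' reduced red sensitivity), sharing the LED bank.
#'
#' @param system `"ccasr_like"`, `"cph8_like"`, or `"dual"`.
#' @param config Named list of overrides (any of `k_dil`, `k_dr`, `tau`, `n`,
#'   `big_k`, `a_hat`, `b_hat`, `noise_cv`, `sigma_g`, `sigma_a`,
#'   `bank` arguments).
#' @param seed Master seed stored with the truth (generation itself is
#'   deterministic).
#' @return An object of class `ground_truth`: for single systems fields
#'   `sensor`, `output`, `sigma_g`, `sigma_a` (functions), `sigma_g_mix`,
#'   `sigma_a_mix` (component tables), `bank`, `noise_cv`, `mode`, `seed`;
#'   for `"dual"` a list with `systems$a` (sfGFP) and `systems$b` (mCherry),
#'   each of that shape, sharing `bank`.
#' @export
make_ground_truth <- function(system = c("ccasr_like", "cph8_like", "dual"),
                              config = list(), seed = 1) {
  system <- match.arg(system)
  if (!is.list(config)) stop("config must be a list")
  if (system == "dual") {
    bank <- do.call(led_bank, config[["bank"]] %||% list())
    a <- single_truth("ccasr_like", config[["a"]] %||% list(), bank, seed)
    # dual-context mCherry output: range collapses to ~6-fold and
    # half-repression needs ~5.2-fold more light (K scaled accordingly)
    b <- single_truth("cph8_like", config[["b"]] %||% list(), bank, seed)
    if (is.null((config[["b"]] %||% list())$a_hat)) {
      b$output$a_hat <- 5 * b$output$b_hat        # 6-fold range
      b$output$big_k <- b$output$big_k * 5.2      # half-repression needs 5.2x more light
    }
    # dual CcaSR range 56-fold
    if (is.null((config[["a"]] %||% list())$a_hat))
      a$output$a_hat <- 55 * a$output$b_hat
    out <- list(systems = list(a = a, b = b), bank = bank, seed = seed,
                noise_cv = config[["noise_cv"]] %||% 0.1)
    class(out) <- c("dual_ground_truth", "ground_truth")
    return(out)
  }
  bank <- do.call(led_bank, config[["bank"]] %||% list())
  out <- single_truth(system, config, bank, seed)
  class(out) <- "ground_truth"
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

single_truth <- function(system, config, bank, seed) {
  sig <- sigma_defaults(system)
  sigma_g_mix <- config[["sigma_g"]] %||% sig$sigma_g
  sigma_a_mix <- config[["sigma_a"]] %||% sig$sigma_a
  sigma_g <- gaussian_mixture(sigma_g_mix)
  sigma_a <- gaussian_mixture(sigma_a_mix)
  if (system == "ccasr_like") {
    k_dil <- config[["k_dil"]] %||% (log(2) / 37.4)
    k_dr <- config[["k_dr"]] %||% 0
    b_hat <- config[["b_hat"]] %||% (300 * k_dil)      # dark level ~300 MEFL
    a_hat <- config[["a_hat"]] %||% (59 * b_hat)       # 60-fold range
    out <- output_params(a_hat, b_hat, n = config[["n"]] %||% 2,
                         big_k = config[["big_k"]] %||% 0.35,
                         tau = config[["tau"]] %||% 10, k_dil = k_dil,
                         mode = "activating")
  } else {
    k_dil <- config[["k_dil"]] %||% (log(2) / 37.9)
    k_dr <- config[["k_dr"]] %||% (log(2) / 5.5)       # 5.5-min dark-reversion half-life
    b_hat <- config[["b_hat"]] %||% (100 * k_dil)      # fully repressed ~100 MECY
    a_hat <- config[["a_hat"]] %||% (209 * b_hat)      # 210-fold range
    # K calibrated so the brightest red drives near-complete repression,
    # reproducing the observed ~210-fold dose-response span
    out <- output_params(a_hat, b_hat, n = config[["n"]] %||% 1.5,
                         big_k = config[["big_k"]] %||% 0.02,
                         tau = config[["tau"]] %||% 6, k_dil = k_dil,
                         mode = "repressing")
  }
  sensor <- sensor_params(k_dil = k_dil, k_dr = k_dr,
                          per_channel_rates = bank_rates(bank, sigma_g, sigma_a))
  list(system = system, sensor = sensor, output = out,
       sigma_g = sigma_g, sigma_a = sigma_a,
       sigma_g_mix = sigma_g_mix, sigma_a_mix = sigma_a_mix,
       bank = bank, noise_cv = config[["noise_cv"]] %||% 0.1,
       mode = out$mode, seed = seed)
}

#' @export
print.ground_truth <- function(x, ...) {
  if (inherits(x, "dual_ground_truth")) {
    cat("<dual ground_truth: systems a (sfGFP, activating) + b (mCherry, repressing)>\n")
  } else {
    cat(sprintf("<ground_truth '%s' (%s): k_dil = %.4g, k_dr = %.4g, %d bank LEDs, noise CV %.2g>\n",
                x$system, x$mode, x$sensor$k_dil, x$sensor$k_dr,
                length(x$bank), x$noise_cv))
  }
  invisible(x)
}

#' Characterization experiment design
#'
#' Describes the four classes of training experiments: step increases from
#' dark (`step_up`), step decreases to dark after preconditioning
#' (`step_down`), steady-state intensity dose-responses to a set of spectral
#' LEDs (`spectral_fwd`), and the same sweep atop a fixed activating
#' background (`spectral_rev`).
#'
#' @param dynamic_led LED used for the step experiments.
#' @param step_intensities Step-change intensity levels (8 by default,
#'   factor-2 spaced up to 20 micromol m^-2 s^-1).
#' @param times Measurement times (min), unevenly spaced with denser early
#'   coverage; harvest at 480 min (8-h growth).
#' @param spectral_leds LED ids for the spectral sweeps.
#' @param spectral_intensities Intensity ladder spanning three orders of
#'   magnitude.
#' @param background Named vector: background channel and intensity for the
#'   reverse sweep.
#' @param replicates Biological replicates per condition.
#' @return A list of class `characterization_design`.
#' @export
characterization_design <- function(dynamic_led = "green",
                                    step_intensities = 20 / 2^(7:0),
                                    times = c(15, 30, 45, 60, 90, 120, 160,
                                              200, 260, 320, 400, 480),
                                    spectral_leds = NULL,
                                    spectral_intensities = 0.02 * 1000^((0:5) / 5),
                                    background = c(green = 1.25),
                                    replicates = 3) {
  background <- unlist(background)
  structure(list(dynamic_led = dynamic_led,
                 step_intensities = as.numeric(unlist(step_intensities)),
                 times = as.numeric(unlist(times)),
                 spectral_leds = if (is.null(spectral_leds)) NULL
                                 else as.character(unlist(spectral_leds)),
                 spectral_intensities = as.numeric(unlist(spectral_intensities)),
                 background = background, replicates = replicates),
            class = "characterization_design")
}

#' Default spectral-LED subset for a scaled-down design
#'
#' Picks `n` LEDs from the bank with centroids evenly covering the band where
#' both photostates absorb appreciably (each unit rate above a fraction
#' `threshold` of its across-bank maximum). Forward and reverse
#' photoconversion are only jointly measurable where both states couple to
#' the light, so characterization panels are drawn from this band.
#'
#' @param truth A `ground_truth`.
#' @param n Number of LEDs.
#' @param threshold Fraction of the per-state maximum rate.
#' @return Character vector of LED ids.
#' @export
responsive_leds <- function(truth, n = 12, threshold = 0.08) {
  ids <- grep("^led_", names(truth$bank), value = TRUE)
  k <- truth$sensor$per_channel_rates[ids]
  kmax1 <- max(vapply(k, `[`, numeric(1), 1L))
  kmax2 <- max(vapply(k, `[`, numeric(1), 2L))
  ok <- vapply(k, function(kk) kk[1L] > threshold * kmax1 &&
                               kk[2L] > threshold * kmax2, logical(1))
  ids <- ids[ok]
  ids[unique(round(seq(1, length(ids), length.out = n)))]
}

noisy <- function(x, cv) {
  if (cv <= 0) return(x)
  sdlog <- sqrt(log(1 + cv^2))
  x * exp(stats::rnorm(length(x), -sdlog^2 / 2, sdlog))
}

#' Generate a characterization dataset from a ground truth
#'
#' Simulates the truth through the full system model for every condition of
#' the design, samples at the design's time points (steady-state classes at
#' the 8-h harvest), and applies multiplicative log-normal noise per record.
#'
#' @param truth A single-system `ground_truth`.
#' @param design A `characterization_design`.
#' @param seed Seed for the noise draws.
#' @param noise_cv Coefficient of variation; defaults to the truth's.
#' @return data.frame with columns `class`, `led_id`, `intensity`, `bg_led`,
#'   `bg_intensity`, `time`, `fluorescence`, `replicate`.
#' @export
generate_characterization <- function(truth, design = characterization_design(),
                                      seed = 1, noise_cv = NULL) {
  if (inherits(truth, "dual_ground_truth"))
    stop("use generate_dual_grid() for dual truths")
  if (is.null(noise_cv)) noise_cv <- truth$noise_cv
  if (is.null(design$spectral_leds)) design$spectral_leds <- responsive_leds(truth)
  missing <- setdiff(c(design$dynamic_led, design$spectral_leds,
                       names(design$background)),
                     names(truth$bank))
  if (length(missing))
    stop(sprintf("design references LEDs absent from the bank: %s",
                 paste(missing, collapse = ", ")))
  rows <- list()
  add <- function(class, led, intensity, bg_led, bg_int, time, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      class = class, led_id = led, intensity = intensity,
      bg_led = bg_led, bg_intensity = bg_int, time = time, model = value)
  }
  horizon <- max(design$times)
  for (i in design$step_intensities) {
    prog <- constant_program(stats::setNames(i, design$dynamic_led), horizon)
    tr <- simulate_system(prog, truth$sensor, truth$output,
                          t_grid = design$times)
    add("step_up", design$dynamic_led, i, NA_character_, NA_real_,
        design$times, tr$g)
    prog0 <- constant_program(stats::setNames(0, design$dynamic_led), horizon)
    tr <- simulate_system(prog0, truth$sensor, truth$output,
                          precondition = stats::setNames(i, design$dynamic_led),
                          t_grid = design$times)
    add("step_down", design$dynamic_led, i, NA_character_, NA_real_,
        design$times, tr$g)
  }
  bg_led <- names(design$background)[1L]
  bg_int <- design$background[[1L]]
  for (led in design$spectral_leds) {
    dr <- dose_response(led, design$spectral_intensities, truth$sensor, truth$output)
    add("spectral_fwd", led, design$spectral_intensities, NA_character_, NA_real_,
        480, dr$g_star)
    dr <- dose_response(led, design$spectral_intensities, truth$sensor, truth$output,
                        background = design$background)
    add("spectral_rev", led, design$spectral_intensities, bg_led, bg_int,
        480, dr$g_star)
  }
  base <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(seq_len(design$replicates), function(r) {
    d <- base
    d$replicate <- r
    d
  }))
  out$fluorescence <- with_seed(seed, noisy(out$model, noise_cv))
  out$model <- NULL
  rownames(out) <- NULL
  out
}

#' Generate a dual-system steady-state grid
#'
#' Two-dimensional green x red steady-state dose-response of a dual truth,
#' for both outputs, with optional missing cells (as in real grids where some
#' intensity combinations are not collected).
#'
#' @param truth A `dual_ground_truth`.
#' @param green_intensities,red_intensities Intensity ladders.
#' @param seed Noise seed.
#' @param noise_cv CV of the multiplicative noise.
#' @param drop_cells Optional data.frame (`green`, `red`) of cells to omit.
#' @return data.frame `green`, `red`, `output` ("a" sfGFP / "b" mCherry),
#'   `fluorescence`.
#' @export
generate_dual_grid <- function(truth, green_intensities = 20 * 2^seq(-8, 0, length.out = 8),
                               red_intensities = 20 * 3^seq(-7, 0, length.out = 8),
                               seed = 1, noise_cv = NULL, drop_cells = NULL) {
  if (!inherits(truth, "dual_ground_truth")) stop("need a dual ground truth")
  if (is.null(noise_cv)) noise_cv <- truth$noise_cv
  grid <- expand.grid(green = green_intensities, red = red_intensities)
  if (!is.null(drop_cells)) {
    keep <- !(paste(grid$green, grid$red) %in% paste(drop_cells$green, drop_cells$red))
    grid <- grid[keep, , drop = FALSE]
  }
  rows <- lapply(c("a", "b"), function(sys) {
    s <- truth$systems[[sys]]
    g <- vapply(seq_len(nrow(grid)), function(i)
      steady_state_system(s$sensor, s$output,
                          c(green = grid$green[i], red = grid$red[i]))$g_star,
      numeric(1))
    data.frame(green = grid$green, red = grid$red, output = sys, model = g)
  })
  out <- do.call(rbind, rows)
  out$fluorescence <- with_seed(seed, noisy(out$model, noise_cv))
  out$model <- NULL
  rownames(out) <- NULL
  out
}

#' Per-LED unit photoconversion rate observations from a truth
#'
#' The true overlap-integral rates of the bank's spectral LEDs with
#' multiplicative log-normal noise and a reported standard error, the input
#' expected by the cross-section spline estimator.
#'
#' @param truth A single-system `ground_truth`.
#' @param state `"ground"` (k1_hat) or `"active"` (k2_hat).
#' @param noise_cv CV of the noise on each rate (default 5%, emulating
#'   regression standard errors).
#' @param seed Noise seed.
#' @return data.frame of class `rate_observations`: `led_id`, `k_hat`,
#'   `k_hat_se`, with the unit spectra as attribute `spectra`.
#' @export
rate_observations <- function(truth, state = c("ground", "active"),
                              noise_cv = 0.05, seed = 1) {
  state <- match.arg(state)
  ids <- grep("^led_", names(truth$bank), value = TRUE)
  idx <- if (state == "ground") 1L else 2L
  k_true <- vapply(ids, function(id) truth$sensor$per_channel_rates[[id]][idx],
                   numeric(1))
  k_obs <- with_seed(seed, noisy(k_true, noise_cv))
  se <- pmax(noise_cv, 1e-3) * pmax(k_obs, 1e-3 * max(k_obs))
  out <- data.frame(led_id = ids, k_hat = k_obs, k_hat_se = se)
  attr(out, "spectra") <- lapply(truth$bank[ids], function(e) e$unit)
  class(out) <- c("rate_observations", "data.frame")
  out
}

#' Broad-spectrum filtered-white validation sources
#'
#' Synthesizes challenging light sources unlike the Gaussian training LEDs:
#' a phosphor-white emission spectrum (blue pump plus broad yellow phosphor
#' band) seen through eight smooth colored filters (long/short-pass edges,
#' band-passes, a notch, and neutral density), as unit-intensity spectra.
#'
#' @param grid Wavelength grid.
#' @return Named list of `unit_spectrum` objects.
#' @export
validation_sources <- function(grid = common_grid()) {
  white <- led_spectrum(grid,
    gaussian_mixture(data.frame(amp = c(1.0, 0.75),
                                center = c(452, 560), fwhm = c(22, 120)))(grid),
    label = "white")
  edge <- function(l0, width = 15) 1 / (1 + exp(-(grid - l0) / width))
  filters <- list(
    longpass_500 = edge(500),
    shortpass_600 = 1 - edge(600),
    band_430_490 = edge(430) * (1 - edge(490)),
    band_480_560 = edge(480) * (1 - edge(560)),
    band_560_640 = edge(560) * (1 - edge(640)),
    band_600_700 = edge(600) * (1 - edge(700)),
    notch_500_600 = 1 - 0.85 * edge(500) * (1 - edge(600)),
    neutral_half = rep(0.5, length(grid)))
  out <- lapply(names(filters), function(nm) {
    sp <- apply_filter(white, filters[[nm]])
    sp$label <- nm
    normalize_to_unit_intensity(sp)
  })
  stats::setNames(out, names(filters))
}
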