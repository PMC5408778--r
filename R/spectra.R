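# LED emission spectra: containers, normalization, summary statistics, and the
# spectral overlap integrals that turn a light spectrum into photoconversion rates.

#' Common wavelength grid
#'
#' The shared wavelength grid on which spectra and cross sections are combined:
#' 300--1100 nm in 0.5-nm steps. It spans all spectral LEDs (centroids
#' 369--958 nm) and the 1050-nm anchor knot of the cross-section spline, and
#' matches the 0.5-nm increment of spectroradiometer exports.
#'
#' @param from,to,by Grid limits and step in nm.
#' @return Numeric vector of wavelengths (nm).
#' @export
common_grid <- function(from = 300, to = 1100, by = 0.5) {
  seq(from, to, by = by)
}

#' Trapezoidal quadrature
#'
#' @param x Strictly increasing abscissae.
#' @param y Values at `x`.
#' @return The trapezoid-rule integral.
#' @export
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Construct an LED emission spectrum
#'
#' @param wavelength Strictly increasing wavelengths (nm), nominally 0.5-nm steps.
#' @param power_density Spectral power density at each wavelength
#'   (micromol s^-1 nm^-1); must be nonnegative.
#' @param label Identifier text.
#' @return An object of class `led_spectrum` with fields `wavelength`,
#'   `power_density`, `label`.
#' @export
led_spectrum <- function(wavelength, power_density, label = "led") {
  wavelength <- as.numeric(wavelength)
  power_density <- as.numeric(power_density)
  if (length(wavelength) != length(power_density))
    stop("wavelength and power_density must have equal length")
  if (length(wavelength) < 1L) stop("empty spectrum")
  dw <- diff(wavelength)
  if (any(dw <= 0)) {
    bad <- which(dw <= 0)[1L] + 1L
    stop(sprintf("wavelengths must be strictly increasing; violation at row %d (%.6g nm)",
                 bad, wavelength[bad]))
  }
  neg <- which(power_density < 0)
  if (length(neg))
    stop(sprintf("negative power density at row %d (%.6g)", neg[1L], power_density[neg[1L]]))
  structure(list(wavelength = wavelength, power_density = power_density,
                 label = as.character(label)[1L]),
            class = "led_spectrum")
}

#' @export
print.led_spectrum <- function(x, ...) {
  st <- spectrum_stats(x)
  cat(sprintf("<led_spectrum '%s': %d points, %.1f-%.1f nm, peak %.1f nm, total %.4g umol/s>\n",
              x$label, length(x$wavelength), min(x$wavelength), max(x$wavelength),
              st$peak_wavelength, st$total_power))
  invisible(x)
}

#' Read an LED spectrum table
#'
#' Reads a two-column delimited text file (header
#' `wavelength_nm,power_umol_s_nm`, an .IRR-derived dialect) into an
#' [led_spectrum()]. Rows must have strictly increasing wavelengths and
#' nonnegative densities; the offending row is reported otherwise.
#'
#' @param path Path to the file.
#' @param grid Optional wavelength grid to resample onto (linear
#'   interpolation, zero outside the measured support).
#' @param label Label; defaults to the file name.
#' @param sep Field separator.
#' @return An `led_spectrum`.
#' @export
read_spectrum <- function(path, grid = NULL, label = NULL, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep)
  if (nrow(tab) == 0L) stop(sprintf("empty spectrum file: %s", path))
  if (ncol(tab) < 2L) stop(sprintf("expected two columns in %s", path))
  sp <- led_spectrum(tab[[1L]], tab[[2L]],
                     label = if (is.null(label)) basename(path) else label)
  if (!is.null(grid)) sp <- resample_spectrum(sp, grid)
  sp
}

#' Write an LED spectrum table
#'
#' @param spectrum An `led_spectrum`.
#' @param path Output path.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.csv(data.frame(wavelength_nm = spectrum$wavelength,
                              power_umol_s_nm = spectrum$power_density),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a wavelength grid
#'
#' Linear interpolation; zero outside the measured support.
#'
#' @param spectrum An `led_spectrum` (or unit spectrum).
#' @param grid Target wavelengths (nm).
#' @return Object of the same class on the new grid.
#' @export
resample_spectrum <- function(spectrum, grid = common_grid()) {
  field <- if (inherits(spectrum, "unit_spectrum")) "flux_density" else "power_density"
  y <- stats::approx(spectrum$wavelength, spectrum[[field]], xout = grid,
                     method = "linear", yleft = 0, yright = 0)$y
  out <- spectrum
  out$wavelength <- grid
  out[[field]] <- y
  out
}

#' Spectral flux density from LED power
#'
#' Converts a spectral power density into the spectral flux density incident
#' on a well-mixed culture: n_light(lambda) = P_light(lambda) / (pi r^2),
#' assuming negligible absorption so that the mean in-well intensity is the
#' total LED power divided by the well cross-sectional area.
#'
#' @param spectrum An `led_spectrum` (micromol s^-1 nm^-1).
#' @param well_radius Culture well radius in meters (default 7.5 mm, the
#'   24-well plate geometry; the multiplier is then about 5.659e3 m^-2).
#' @return A `flux_spectrum` with `flux_density` in micromol m^-2 s^-1 nm^-1
#'   and attribute `multiplier` = 1/(pi r^2).
#' @export
flux_density_from_power <- function(spectrum, well_radius = 7.5e-3) {
  if (!is.numeric(well_radius) || length(well_radius) != 1L || well_radius <= 0)
    stop("well_radius must be a single positive number (meters)")
  mult <- 1 / (pi * well_radius^2)
  structure(list(wavelength = spectrum$wavelength,
                 flux_density = spectrum$power_density * mult,
                 label = spectrum$label, multiplier = mult),
            class = "flux_spectrum")
}

#' Normalize a flux-density spectrum to unit total intensity
#'
#' Divides a spectral flux density by its total intensity so the result
#' integrates (trapezoid rule) to exactly 1; the spectrum then represents the
#' source shape at 1 micromol m^-2 s^-1 and scales linearly with intensity.
#'
#' @param flux A `flux_spectrum`, `led_spectrum`, or list with `wavelength`
#'   and a density field.
#' @return A `unit_spectrum` with fields `wavelength`, `flux_density`, `label`
#'   and attribute `intensity` (the original total intensity).
#' @export
normalize_to_unit_intensity <- function(flux) {
  field <- if (!is.null(flux$flux_density)) "flux_density" else "power_density"
  total <- trapz(flux$wavelength, flux[[field]])
  if (!is.finite(total) || total <= 0)
    stop("cannot normalize: total intensity is not positive")
  structure(list(wavelength = flux$wavelength,
                 flux_density = flux[[field]] / total,
                 label = flux$label, intensity = total),
            class = "unit_spectrum")
}

#' @export
print.unit_spectrum <- function(x, ...) {
  cat(sprintf("<unit_spectrum '%s': %d points, unit-intensity shape (source intensity %.4g)>\n",
              x$label, length(x$wavelength),
              if (is.null(x$intensity)) NA_real_ else x$intensity))
  invisible(x)
}

#' Summary statistics of an emission spectrum
#'
#' Computes the peak wavelength, intensity-weighted centroid, full width at
#' half maximum (by linear interpolation of the half-maximum crossings), and
#' total power. For multimodal spectra with more than two half-maximum
#' crossings the FWHM is the span between the outermost crossings and the
#' result is flagged.
#'
#' @param spectrum An `led_spectrum` (or unit spectrum).
#' @return A list of class `spectrum_stats`: `peak_wavelength`,
#'   `centroid_wavelength`, `fwhm`, `total_power`, `multimodal` flag.
#' @export
spectrum_stats <- function(spectrum) {
  w <- spectrum$wavelength
  p <- if (!is.null(spectrum$power_density)) spectrum$power_density else spectrum$flux_density
  total <- trapz(w, p)
  ipk <- which.max(p)
  centroid <- if (total > 0) trapz(w, w * p) / total else w[ipk]
  half <- p[ipk] / 2
  above <- p >= half
  # linearly interpolated crossings of the half-maximum level
  cross <- numeric(0)
  for (i in seq_len(length(w) - 1L)) {
    if (above[i] != above[i + 1L]) {
      f <- (half - p[i]) / (p[i + 1L] - p[i])
      cross <- c(cross, w[i] + f * (w[i + 1L] - w[i]))
    }
  }
  multimodal <- length(cross) > 2L
  fwhm <- if (length(cross) >= 2L) max(cross) - min(cross) else 0
  structure(list(peak_wavelength = w[ipk], centroid_wavelength = centroid,
                 fwhm = fwhm, total_power = total, multimodal = multimodal),
            class = "spectrum_stats")
}

#' Apply a transmission filter to a spectrum
#'
#' Pointwise product of an emission spectrum with a per-wavelength
#' transmission fraction, emulating a colored filter cap placed over a
#' white-light LED to synthesize broad, complex validation sources.
#'
#' @param spectrum An `led_spectrum`.
#' @param transmission Either a numeric vector on the spectrum grid or a list
#'   with `wavelength` and `transmission` (resampled as needed). Values must
#'   lie in \[0, 1\].
#' @return A filtered `led_spectrum`.
#' @export
apply_filter <- function(spectrum, transmission) {
  if (is.list(transmission)) {
    tr <- stats::approx(transmission$wavelength, transmission$transmission,
                        xout = spectrum$wavelength, yleft = 0, yright = 0)$y
  } else tr <- as.numeric(transmission)
  if (length(tr) != length(spectrum$wavelength))
    stop("transmission must match the spectrum grid")
  if (any(tr < -1e-12 | tr > 1 + 1e-12))
    stop("transmission values must lie in [0, 1]")
  led_spectrum(spectrum$wavelength, spectrum$power_density * pmin(pmax(tr, 0), 1),
               label = paste0(spectrum$label, "+filter"))
}

#' Unit photoconversion rate by spectral overlap
#'
#' The photoconversion rate per unit light intensity for one photoreceptor
#' state and one light source: the trapezoidal overlap integral of the
#' photoconversion cross section with the unit-intensity source shape,
#' k_hat = integral of sigma(lambda) * nhat_light(lambda) dlambda
#' (min^-1 per micromol m^-2 s^-1). At intensity I the rate is k = I * k_hat,
#' and rates from multiple simultaneous sources add.
#'
#' @param pcs Cross section: a function of wavelength, a `pcs_spline`, or a
#'   numeric vector on the spectrum grid.
#' @param unit_spectrum A `unit_spectrum` (integral 1).
#' @return Scalar unit photoconversion rate.
#' @export
unit_photoconversion_rate <- function(pcs, unit_spectrum) {
  w <- unit_spectrum$wavelength
  sig <- if (is.function(pcs)) pcs(w)
         else if (inherits(pcs, "pcs_spline")) pcs_eval(pcs, w)
         else as.numeric(pcs)
  if (length(sig) != length(w))
    stop("cross section and spectrum must share a wavelength grid")
  trapz(w, sig * unit_spectrum$flux_density)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert an intensity to a hardware grayscale level
#'
#' Maps an intensity linearly onto the 12-bit (0--4095) grayscale scale used
#' by LED driver hardware, rounding half away from zero. [grayscale_to_intensity()]
#' is the inverse mapping; the round trip is the identity on every level.
#'
#' @param intensity Intensity in micromol m^-2 s^-1 (vectorized).
#' @param max_intensity Calibrated full-scale intensity of the channel.
#' @param bit_depth Bits of grayscale resolution (default 12).
#' @param channel Channel name used in error messages.
#' @return Integer grayscale level(s) in `[0, 2^bit_depth - 1]`.
#' @export
intensity_to_grayscale <- function(intensity, max_intensity, bit_depth = 12L,
                                   channel = "channel") {
  if (max_intensity <= 0) stop("max_intensity must be positive")
  if (any(intensity < 0 | intensity > max_intensity))
    stop(sprintf("intensity out of range [0, %g] for %s", max_intensity, channel))
  top <- 2^bit_depth - 1
  as.integer(round_half_away(intensity / max_intensity * top))
}

#' @rdname intensity_to_grayscale
#' @param level Grayscale level(s).
#' @export
grayscale_to_intensity <- function(level, max_intensity, bit_depth = 12L) {
  top <- 2^bit_depth - 1
  if (any(level < 0 | level > top)) stop("grayscale level out of range")
  level / top * max_intensity
}

#' Gaussian emission spectrum
#'
#' Convenience constructor for a Gaussian-shaped LED spectrum on a grid,
#' parameterized by centroid and FWHM as reported by spectroradiometer
#' summaries.
#'
#' @param centroid Centroid wavelength (nm).
#' @param fwhm Full width at half maximum (nm).
#' @param total_power Total power (micromol s^-1).
#' @param grid Wavelength grid.
#' @param label Label.
#' @return An `led_spectrum`.
#' @export
gaussian_spectrum <- function(centroid, fwhm, total_power = 1,
                              grid = common_grid(), label = sprintf("led_%.0f", centroid)) {
  sdev <- fwhm / (2 * sqrt(2 * log(2)))
  dens <- stats::dnorm(grid, centroid, sdev)
  tot <- trapz(grid, dens)
  led_spectrum(grid, dens / tot * total_power, label = label)
}
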