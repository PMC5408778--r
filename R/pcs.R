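# Continuous photoconversion cross-section (PCS) estimation. A piecewise
# cubic spline sigma(lambda) is regressed against per-LED unit
# photoconversion rates so that its overlap integral with each LED's
# unit-intensity spectrum reproduces the observed rate: the integral
# conditions enter a weighted least-squares objective, while C2 continuity at
# interior knots and natural boundary conditions enter as linear equality
# constraints solved exactly via Lagrange multipliers (a KKT system). Knot
# count is chosen by leave-one-out cross-validation.

pcs_knots <- function(n_knots, knot_range = c(350, 800), anchor = 1050) {
  if (n_knots < 3) stop("need at least 3 knots")
  sort(c(seq(knot_range[1L], knot_range[2L], length.out = n_knots - 1L), anchor))
}

# Basis matrix on a wavelength grid: columns are local monomials
# ((lambda - t_i)/h_i)^p restricted to interval i, p = 0..3.
pcs_basis <- function(knots, grid) {
  m <- length(knots)
  h <- diff(knots)
  B <- matrix(0, length(grid), 4L * (m - 1L))
  iv <- findInterval(grid, knots, rightmost.closed = TRUE)
  for (i in seq_len(m - 1L)) {
    sel <- iv == i
    if (!any(sel)) next
    x <- (grid[sel] - knots[i]) / h[i]
    for (p in 0:3) B[sel, 4L * (i - 1L) + p + 1L] <- x^p
  }
  B
}

# Equality constraints C c = 0: C2 continuity at interior knots plus natural
# (zero second derivative) boundary conditions.
pcs_constraints <- function(knots) {
  m <- length(knots)
  h <- diff(knots)
  ni <- m - 2L
  C <- matrix(0, 3L * ni + 2L, 4L * (m - 1L))
  row <- 0L
  col <- function(i, p) 4L * (i - 1L) + p + 1L
  for (i in seq_len(ni)) {   # junction between interval i and i+1
    row <- row + 1L          # value
    C[row, col(i, 0:3)] <- 1
    C[row, col(i + 1L, 0L)] <- -1
    row <- row + 1L          # first derivative
    C[row, col(i, 1:3)] <- c(1, 2, 3) / h[i]
    C[row, col(i + 1L, 1L)] <- -1 / h[i + 1L]
    row <- row + 1L          # second derivative
    C[row, col(i, 2:3)] <- c(2, 6) / h[i]^2
    C[row, col(i + 1L, 2L)] <- -2 / h[i + 1L]^2
  }
  C[row + 1L, col(1L, 2L)] <- 1                 # sigma''(t_1) = 0
  C[row + 2L, col(m - 1L, 2:3)] <- c(2, 6)      # sigma''(t_m) = 0
  C
}

obs_spectra <- function(observations, spectra = NULL) {
  if (is.null(spectra)) spectra <- attr(observations, "spectra")
  if (is.null(spectra)) stop("observations carry no spectra; pass `spectra`")
  spectra[match(observations$led_id, names(spectra))]
}

#' Fit a photoconversion cross-section spline
#'
#' Weighted least squares of the overlap-integral conditions
#' k_hat_j = integral sigma(lambda) nhat_j(lambda) dlambda over a piecewise
#' cubic spline, with C2 continuity and natural boundary conditions imposed
#' exactly through Lagrange multipliers. One knot is pinned at 1050 nm and
#' the remaining `n_knots - 1` are evenly spaced on 350--800 nm. Weights are
#' 1/se^2. Negative excursions of the fitted spline are reported as a quality
#' flag, not forbidden.
#'
#' @param observations data.frame with `led_id`, `k_hat`, `k_hat_se`
#'   (e.g. from [rate_observations()]), carrying the per-LED unit spectra as
#'   attribute `spectra` (or pass `spectra`).
#' @param n_knots Total number of knots (the 1050-nm anchor included).
#' @param spectra Optional named list of `unit_spectrum` objects.
#' @param knot_range Span of the evenly spaced knots (nm).
#' @param anchor Fixed far-red/IR anchor knot (nm).
#' @param grid Wavelength grid for the integral conditions.
#' @return An object of class `pcs_spline`: `knots`, `coef` (one row of four
#'   local coefficients per interval), `support`, `residuals`, `weights`,
#'   `negative_excursion`, `kappa` (condition estimate of the KKT system).
#' @export
fit_pcs <- function(observations, n_knots, spectra = NULL,
                    knot_range = c(350, 800), anchor = 1050,
                    grid = common_grid()) {
  spectra <- obs_spectra(observations, spectra)
  if (any(observations$k_hat_se <= 0)) stop("k_hat_se must be positive")
  knots <- pcs_knots(n_knots, knot_range, anchor)
  B <- pcs_basis(knots, grid)
  # integral conditions: one row per LED, trapezoid weights times spectrum
  d <- diff(grid)
  tw <- c(d / 2, 0) + c(0, d / 2)
  A <- t(vapply(spectra, function(sp) {
    fl <- if (identical(sp$wavelength, grid)) sp$flux_density
          else stats::approx(sp$wavelength, sp$flux_density, grid,
                             yleft = 0, yright = 0)$y
    as.numeric(crossprod(B, tw * fl))
  }, numeric(ncol(B))))
  w <- 1 / observations$k_hat_se^2
  w <- w / mean(w)
  C <- pcs_constraints(knots)
  # Equality-constrained WLS: eliminate the continuity/boundary constraints
  # exactly through an orthogonal basis of their null space (the stable way
  # to solve the Lagrange system when weights span many orders of magnitude),
  # then backsolve the reduced weighted problem by SVD.
  qrC <- qr(t(C))
  if (qrC$rank < nrow(C))
    stop(sprintf("rank-deficient constraint system: %d constraints, rank %d",
                 nrow(C), qrC$rank))
  N <- qr.Q(qrC, complete = TRUE)[, (qrC$rank + 1L):ncol(B), drop = FALSE]
  M <- sqrt(w) * (A %*% N)
  sv <- svd(M)
  kap <- max(sv$d) / max(min(sv$d), 1e-300)
  keep <- sv$d > max(sv$d) * 1e-10
  if (!any(keep))
    stop(sprintf("degenerate regression system (condition ~ %.3g)", kap))
  z <- sv$v[, keep, drop = FALSE] %*%
    (crossprod(sv$u[, keep, drop = FALSE], sqrt(w) * observations$k_hat) / sv$d[keep])
  cf <- as.numeric(N %*% z)
  fitted <- as.numeric(A %*% cf)
  vals <- as.numeric(B %*% cf)
  structure(list(knots = knots, h = diff(knots),
                 coef = matrix(cf, ncol = 4L, byrow = TRUE),
                 support = range(knots),
                 fitted = fitted, residuals = observations$k_hat - fitted,
                 weights = w, led_id = observations$led_id,
                 negative_excursion = min(vals) < -1e-10 * max(abs(vals)),
                 kappa = kap),
            class = "pcs_spline")
}

#' Evaluate a fitted cross-section spline
#'
#' @param spline A `pcs_spline`.
#' @param lambda Wavelengths (nm). Outside the knot support the cross
#'   section is taken as zero.
#' @return sigma(lambda).
#' @export
pcs_eval <- function(spline, lambda) {
  out <- numeric(length(lambda))
  inside <- lambda >= spline$support[1L] & lambda <= spline$support[2L]
  if (any(inside)) {
    iv <- findInterval(lambda[inside], spline$knots, rightmost.closed = TRUE)
    iv <- pmin(pmax(iv, 1L), length(spline$knots) - 1L)
    x <- (lambda[inside] - spline$knots[iv]) / spline$h[iv]
    cf <- spline$coef[iv, , drop = FALSE]
    out[inside] <- cf[, 1L] + x * (cf[, 2L] + x * (cf[, 3L] + x * cf[, 4L]))
  }
  out
}

#' @export
print.pcs_spline <- function(x, ...) {
  cat(sprintf("<pcs_spline: %d knots on [%g, %g] nm%s>\n", length(x$knots),
              x$support[1L], x$support[2L],
              if (x$negative_excursion) ", negative excursions flagged" else ""))
  invisible(x)
}

#' Predict a unit photoconversion rate from a fitted cross section
#'
#' Overlap integral of the fitted spline with a new light source's
#' unit-intensity spectrum. Spectrum power outside the spline support
#' contributes zero cross section (flagged via attribute
#' `outside_support_fraction`).
#'
#' @param spline A `pcs_spline`.
#' @param unit_spectrum A `unit_spectrum`.
#' @return Predicted k_hat (min^-1 per micromol m^-2 s^-1).
#' @export
predict_rate <- function(spline, unit_spectrum) {
  w <- unit_spectrum$wavelength
  sig <- pcs_eval(spline, w)
  out <- trapz(w, sig * unit_spectrum$flux_density)
  outside <- w < spline$support[1L] | w > spline$support[2L]
  frac <- trapz(w, unit_spectrum$flux_density * outside)
  attr(out, "outside_support_fraction") <- frac
  out
}

#' Choose the knot count by leave-one-out cross-validation
#'
#' For each candidate knot count, each LED is held out in turn, the spline is
#' refit to the rest, and the held-out rate is predicted; the CV error is the
#' weighted mean squared held-out residual. Returns the knot count minimizing
#' it.
#'
#' @param observations As in [fit_pcs()].
#' @param knot_range Candidate knot counts (default 5--20; counts outside
#'   that default band are accepted with a warning).
#' @param spectra Optional named list of unit spectra.
#' @param ... Passed to [fit_pcs()].
#' @return List of class `loocv_result`: `best_n_knots`, `cv`
#'   (data.frame `n_knots`, `cv_error`).
#' @export
loocv_select <- function(observations, knot_range = 5:20, spectra = NULL, ...) {
  spectra <- obs_spectra(observations, spectra)
  n <- nrow(observations)
  if (n < 7L) stop("need at least 7 observations for cross-validation")
  if (min(knot_range) < 5 || max(knot_range) > 20)
    warning("knot counts outside the default 5-20 band")
  knot_range <- knot_range[knot_range <= n - 1L]
  w <- 1 / observations$k_hat_se^2
  cv <- vapply(knot_range, function(nk) {
    r2 <- vapply(seq_len(n), function(i) {
      f <- fit_pcs(observations[-i, , drop = FALSE], nk,
                   spectra = spectra[-i], ...)
      (observations$k_hat[i] - predict_rate(f, spectra[[i]]))^2
    }, numeric(1))
    sum(w * r2) / sum(w)
  }, numeric(1))
  best <- knot_range[which.min(cv)]
  structure(list(best_n_knots = best,
                 cv = data.frame(n_knots = knot_range, cv_error = cv)),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result: best n_knots = %d (cv error %.4g)>\n",
              x$best_n_knots, min(x$cv$cv_error)))
  invisible(x)
}
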