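# Global nonlinear regression of the full photoconversion model to
# characterization data, by damped least squares (Levenberg-Marquardt) on the
# relative error, sum(((G_data - G_model)/G_data)^2). Per-LED unit
# photoconversion rate pairs and the LED-independent parameters (Hill
# function, dilution, dark reversion, delay) are estimated jointly on a log
# scale; multistart guards against local minima.

# Fast single-step trajectory prediction: precondition at i_pre on one LED,
# switch to i_post at t = 0, sample the output at `times`.
predict_step <- function(khat, i_pre, i_post, k_dil, k_dr, out, times, dt = 0.5) {
  k1p <- i_pre * khat[1L]; k2p <- i_pre * khat[2L]
  ktp <- k1p + k2p + k_dil + k_dr
  y0 <- if (ktp > 0) k1p / ktp else 0
  k1 <- i_post * khat[1L]; k2 <- i_post * khat[2L]
  kt <- k1 + k2 + k_dil + k_dr
  yinf <- if (kt > 0) k1 / kt else 0
  dense <- sort(unique(c(seq(0, max(times), by = dt), times, out$tau)))
  dense <- dense[dense <= max(times)]
  kg_at <- function(tt) {
    td <- tt - out$tau
    y_del <- ifelse(td < 0, y0, y0 + (yinf - y0) * (1 - exp(-kt * pmax(td, 0))))
    production_rate(active_ratio(pmin(y_del, 1 - 1e-12)), out)
  }
  mids <- (dense[-1L] + dense[-length(dense)]) / 2
  g0 <- steady_state_g(active_ratio(min(y0, 1 - 1e-12)), out)
  g <- integrate_expression(dense, kg_at(dense), out$k_dil, g0, kg_mid = kg_at(mids))
  g[match(times, dense)]
}

# Model predictions for every row of a characterization dataset.
predict_dataset <- function(dataset, k_hats, k_dil, k_dr, out) {
  pred <- numeric(nrow(dataset))
  dyn <- dataset$class %in% c("step_up", "step_down")
  if (any(dyn)) {
    dd <- dataset[dyn, ]
    key <- paste(dd$class, dd$led_id, dd$intensity)
    for (k in unique(key)) {
      sel <- key == k
      row1 <- dd[which(sel)[1L], ]
      khat <- k_hats[[row1$led_id]]
      if (row1$class == "step_up") {
        i_pre <- 0; i_post <- row1$intensity
      } else {
        i_pre <- row1$intensity; i_post <- 0
      }
      times <- sort(unique(dd$time[sel]))
      g <- predict_step(khat, i_pre, i_post, k_dil, k_dr, out, times)
      pred[which(dyn)[sel]] <- g[match(dd$time[sel], times)]
    }
  }
  ss <- !dyn
  if (any(ss)) {
    dd <- dataset[ss, ]
    k1 <- vapply(seq_len(nrow(dd)), function(i) k_hats[[dd$led_id[i]]][1L], numeric(1)) * dd$intensity
    k2 <- vapply(seq_len(nrow(dd)), function(i) k_hats[[dd$led_id[i]]][2L], numeric(1)) * dd$intensity
    hasbg <- !is.na(dd$bg_led) & !is.na(dd$bg_intensity)
    if (any(hasbg)) {
      bg1 <- vapply(which(hasbg), function(i) k_hats[[dd$bg_led[i]]][1L], numeric(1))
      bg2 <- vapply(which(hasbg), function(i) k_hats[[dd$bg_led[i]]][2L], numeric(1))
      k1[hasbg] <- k1[hasbg] + bg1 * dd$bg_intensity[hasbg]
      k2[hasbg] <- k2[hasbg] + bg2 * dd$bg_intensity[hasbg]
    }
    r_star <- k1 / (k2 + k_dil + k_dr)
    pred[ss] <- steady_state_g(r_star, out)
  }
  pred
}

fit_par_names <- function(leds, fixed) {
  glob <- c("k_dil", "k_dr", "tau", "n", "big_k", "a_hat", "b_hat")
  glob <- setdiff(glob, names(fixed))
  c(as.vector(t(outer(leds, c("k1", "k2"), function(l, s) paste0(s, ".", l)))), glob)
}

theta_to_model <- function(theta, leds, fixed, mode) {
  v <- exp(unlist(theta))
  getp <- function(nm) if (nm %in% names(fixed)) fixed[[nm]] else v[[nm]]
  k_hats <- stats::setNames(lapply(leds, function(l)
    c(v[[paste0("k1.", l)]], v[[paste0("k2.", l)]])), leds)
  out <- output_params(a_hat = getp("a_hat"), b_hat = getp("b_hat"),
                       n = getp("n"), big_k = getp("big_k"),
                       tau = getp("tau"), k_dil = getp("k_dil"), mode = mode)
  list(k_hats = k_hats, k_dil = getp("k_dil"), k_dr = getp("k_dr"), out = out)
}

# Data-driven initial parameter guesses.
heuristic_start <- function(dataset, leds, mode, fixed) {
  gmin <- min(dataset$fluorescence); gmax <- max(dataset$fluorescence)
  k_dil0 <- if ("k_dil" %in% names(fixed)) fixed$k_dil else log(2) / 35
  k_dr0 <- if ("k_dr" %in% names(fixed)) fixed$k_dr else 0.05
  b_hat0 <- max(gmin * k_dil0, 1e-6)
  a_hat0 <- max((gmax - gmin) * k_dil0, 1e-6)
  K0 <- if ("big_k" %in% names(fixed)) fixed$big_k else 0.5
  start <- list(k_dil = k_dil0, k_dr = k_dr0, tau = 8, n = 1.5, big_k = K0,
                a_hat = a_hat0, b_hat = b_hat0)
  for (l in leds) {
    sub <- dataset[dataset$led_id == l & dataset$class %in% c("spectral_fwd", "step_up"), ]
    i50 <- NA_real_
    if (nrow(sub) >= 3L) {
      if (any(sub$class == "spectral_fwd")) {
        sub <- sub[sub$class == "spectral_fwd", ]
        agg <- stats::aggregate(fluorescence ~ intensity, sub, mean)
      } else {
        # dynamic LED: use the late-time response across step intensities
        sub <- sub[sub$time >= 0.7 * max(sub$time), ]
        agg <- stats::aggregate(fluorescence ~ intensity, sub, mean)
      }
      lo <- min(agg$fluorescence); hi <- max(agg$fluorescence)
      if (hi / max(lo, 1e-12) > 1.5) {
        mid <- sqrt(lo * hi)
        rising <- (mode == "activating")
        ord <- order(agg$intensity)
        f <- agg$fluorescence[ord]; ii <- agg$intensity[ord]
        crossed <- if (rising) f >= mid else f <= mid
        j <- which(crossed)[1L]
        i50 <- if (!is.na(j) && j > 1L) {
          x2 <- f[(j - 1L):j]; y2 <- log(ii[(j - 1L):j])
          exp(y2[1L] + (mid - x2[1L]) * diff(y2) / diff(x2))
        } else ii[1L]
      }
    }
    k10 <- if (is.finite(i50) && i50 > 0) K0 * (k_dil0 + k_dr0) / i50 else 1e-4
    start[[paste0("k1.", l)]] <- max(k10, 1e-6)
    start[[paste0("k2.", l)]] <- max(0.3 * k10, 1e-6)
  }
  start
}

#' Global fit of the photoconversion model to characterization data
#'
#' Minimizes the summed squared relative error between the data and model
#' simulations by Levenberg-Marquardt least squares, jointly estimating
#' per-LED unit photoconversion rate pairs and the LED-independent
#' parameters (Hill a_hat, b_hat, n, K, delay tau, dilution k_dil, dark
#' reversion k_dr). All parameters are fit on a log scale for positivity.
#' Because good start points are not known a priori, a seeded multistart
#' (data-driven heuristic start plus log-normal jitters) is used, with a
#' deterministic early stop once additional starts cease to improve the
#' objective.
#'
#' @param dataset Characterization data.frame (`class`, `led_id`,
#'   `intensity`, `bg_led`, `bg_intensity`, `time`, `fluorescence`,
#'   `replicate`); replicates enter as individual residuals.
#' @param mode Output logic, `"activating"` or `"repressing"`.
#' @param fixed Named list of parameters to freeze (e.g. `list(big_k = 0.5)`
#'   to fix K at a reference value).
#' @param start Optional named list of start values (natural scale); missing
#'   entries fall back to the data-driven heuristic.
#' @param n_starts Number of multistart attempts (default 8).
#' @param seed Seed for the start jitters.
#' @param control List: `maxiter` (LM iterations per start, default 200),
#'   `jitter_sd` (log-scale start jitter, default 0.5), `min_starts`
#'   (default 3) and `stall_tol` (default 0.01) for the early stop.
#' @return An object of class `fit_result`: `k_hats` (per-LED c(k1_hat,
#'   k2_hat)), `sensor` / `output` parameter objects, `estimates`,
#'   `std_errors` (natural scale, from the regression covariance),
#'   `objective`, `converged`, `degenerate`, `n_starts_used`.
#' @export
fit_global <- function(dataset, mode = c("activating", "repressing"),
                       fixed = list(), start = NULL, n_starts = 8, seed = 1,
                       control = list()) {
  mode <- match.arg(mode)
  ctl <- utils::modifyList(list(maxiter = 500, jitter_sd = 0.5,
                                min_starts = 4, stall_tol = 0.01), control)
  need <- c("class", "led_id", "intensity", "time", "fluorescence")
  if (!all(need %in% names(dataset))) stop("dataset is missing required columns")
  if (any(dataset$fluorescence <= 0)) stop("fluorescence values must be positive")
  classes <- unique(dataset$class)
  if (!any(c("step_up", "step_down") %in% classes))
    warning("dataset has no dynamic class; tau and k_dr will be weakly constrained")
  if (!any(c("spectral_fwd", "spectral_rev") %in% classes))
    warning("dataset has no spectral class; per-LED rates rest on dynamics only")
  if (stats::sd(dataset$fluorescence) < 1e-12 * mean(dataset$fluorescence)) {
    warning("all fluorescence values are equal: degenerate flat fit")
    return(structure(list(degenerate = TRUE, converged = FALSE,
                          objective = NA_real_), class = "fit_result"))
  }
  leds <- sort(unique(c(dataset$led_id, dataset$bg_led[!is.na(dataset$bg_led)])))
  pn <- fit_par_names(leds, fixed)
  s0 <- heuristic_start(dataset, leds, mode, fixed)
  if (!is.null(start)) s0 <- utils::modifyList(s0, start)
  theta0 <- log(unlist(s0[pn]))
  # generous physical box bounds on the log scale keep the damped steps sane
  bound_of <- function(nm, side) {
    base <- sub("\\..*$", "", nm)
    b <- switch(base,
                k1 = c(1e-10, 1e2), k2 = c(1e-10, 1e2),
                k_dil = c(1e-4, 1), k_dr = c(1e-8, 10),
                tau = c(1e-2, 400), n = c(0.2, 10), big_k = c(1e-6, 1e3),
                a_hat = c(1e-9, 1e9), b_hat = c(1e-9, 1e9))
    log(b[side])
  }
  lower <- vapply(pn, bound_of, numeric(1), side = 1L)
  upper <- vapply(pn, bound_of, numeric(1), side = 2L)
  theta0 <- pmin(pmax(theta0, lower), upper)
  resid_fun <- function(theta) {
    names(theta) <- pn
    m <- theta_to_model(theta, leds, fixed, mode)
    pred <- predict_dataset(dataset, m$k_hats, m$k_dil, m$k_dr, m$out)
    r <- (dataset$fluorescence - pred) / dataset$fluorescence
    r[!is.finite(r)] <- 1e6
    r
  }
  best <- NULL
  stall <- 0L
  used <- 0L
  jitters <- with_seed(seed, lapply(seq_len(n_starts), function(i)
    if (i == 1L) rep(0, length(theta0))
    else stats::rnorm(length(theta0), 0, ctl$jitter_sd)))
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(theta0 + jitters[[i]], lower), upper),
                         fn = resid_fun, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = ctl$maxiter, maxfev = 100000)),
      error = function(e) NULL)
    used <- i
    if (!is.null(fit)) {
      if (is.null(best) || fit$deviance < best$deviance * (1 - ctl$stall_tol)) {
        stall <- 0L
      } else stall <- stall + 1L
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
    } else stall <- stall + 1L
    if (i >= ctl$min_starts && stall >= 2L) break
  }
  if (is.null(best)) stop("all optimization starts failed")
  theta <- best$par
  names(theta) <- pn
  m <- theta_to_model(as.list(theta), leds, fixed, mode)
  est <- exp(theta)
  se_log <- tryCatch({
    covm <- solve(best$hessian) * best$deviance / (length(best$fvec) - length(theta))
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) rep(NA_real_, length(theta)))
  se <- est * se_log  # delta method from the log scale
  names(se) <- pn
  converged <- best$info %in% 1:4
  if (!converged)
    warning(sprintf("fit did not converge cleanly (info = %d): %s",
                    best$info, best$message))
  sensor <- sensor_params(k_dil = m$k_dil, k_dr = m$k_dr,
                          per_channel_rates = m$k_hats)
  structure(list(k_hats = m$k_hats, sensor = sensor, output = m$out,
                 estimates = c(est, unlist(fixed)), std_errors = se,
                 fixed = fixed, mode = mode, leds = leds,
                 objective = best$deviance, converged = converged,
                 info = best$info, message = best$message,
                 degenerate = FALSE, n_starts_used = used,
                 n_residuals = length(best$fvec)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<fit_result: degenerate flat dataset, no fit>\n")
    return(invisible(x))
  }
  cat(sprintf("<fit_result (%s): objective = %.6g over %d residuals, %s, %d start(s)>\n",
              x$mode, x$objective, x$n_residuals,
              if (x$converged) "converged" else "NOT converged", x$n_starts_used))
  print(x$output)
  cat(sprintf("  k_dr = %.4g min^-1, %d LED rate pairs\n", x$sensor$k_dr,
              length(x$k_hats)))
  invisible(x)
}

#' Profile the objective over the Hill half-maximal ratio K
#'
#' Refits all other free parameters at each fixed K (warm-started from the
#' reference fit) and reports the re-optimized objective, quantifying how
#' weakly K is determined: changes in K can be compensated by changes in the
#' photoconversion rates, so the profile is characteristically flat.
#'
#' @param dataset Characterization dataset used for `fit`.
#' @param fit A converged `fit_result`.
#' @param k_values K values to profile.
#' @param n_starts Starts per profile point (warm-started; default 1).
#' @param seed Seed for any jittered starts.
#' @return data.frame of class `k_profile`: `big_k`, `objective`,
#'   `objective_ratio` (relative to the minimum observed).
#' @export
profile_k <- function(dataset, fit, k_values, n_starts = 1, seed = 1) {
  if (isTRUE(fit$degenerate) || !length(fit$k_hats))
    stop("profile_k needs a non-degenerate fit")
  warm <- c(list(k_dil = fit$output$k_dil, k_dr = fit$sensor$k_dr,
                 tau = fit$output$tau, n = fit$output$n,
                 a_hat = fit$output$a_hat, b_hat = fit$output$b_hat),
            stats::setNames(lapply(fit$leds, function(l) fit$k_hats[[l]][1L]),
                            paste0("k1.", fit$leds)),
            stats::setNames(lapply(fit$leds, function(l) fit$k_hats[[l]][2L]),
                            paste0("k2.", fit$leds)))
  obj <- vapply(k_values, function(K) {
    # compensation direction: rescale all photoconversion rates with K
    w <- warm
    scale <- K / fit$output$big_k
    for (l in fit$leds) {
      w[[paste0("k1.", l)]] <- w[[paste0("k1.", l)]] * scale
      w[[paste0("k2.", l)]] <- w[[paste0("k2.", l)]] * scale
    }
    f <- fit_global(dataset, mode = fit$mode,
                    fixed = utils::modifyList(fit$fixed, list(big_k = K)),
                    start = w, n_starts = n_starts, seed = seed,
                    control = list(min_starts = 1))
    f$objective
  }, numeric(1))
  res <- data.frame(big_k = k_values, objective = obj,
                    objective_ratio = obj / min(obj))
  class(res) <- c("k_profile", "data.frame")
  res
}

#' Refit only the output Hill parameters on a dual-system grid
#'
#' Recalibration for a new cellular context: the photoconversion and kinetic
#' rates are properties of the photoreceptors themselves and stay frozen,
#' while the Hill parameters (a_hat, b_hat, n, K) of each output are
#' re-estimated against a two-dimensional green x red steady-state grid. The
#' two outputs fit independently; missing grid cells are simply absent rows.
#'
#' @param dual_dataset data.frame `green`, `red`, `output` ("a"/"b"),
#'   `fluorescence`.
#' @param fixed_sensing Named list (`a`, `b`) of frozen `sensor_params`
#'   (must include `green` and `red` channel rates).
#' @param modes Named character vector of output logic per system.
#' @param taus Signaling delays carried through unchanged (irrelevant at
#'   steady state).
#' @return Named list (`a`, `b`) of refit `output_params`, with per-system
#'   objectives as attribute `objective`.
#' @export
refit_output_only <- function(dual_dataset,
                              fixed_sensing,
                              modes = c(a = "activating", b = "repressing"),
                              taus = c(a = 10, b = 6)) {
  if (nrow(dual_dataset) == 0L) stop("empty dual grid")
  res <- list(); objs <- c()
  for (sys in names(fixed_sensing)) {
    sub <- dual_dataset[dual_dataset$output == sys, ]
    if (nrow(sub) == 0L) stop(sprintf("no rows for output '%s'", sys))
    sensor <- fixed_sensing[[sys]]
    kk1 <- sensor$per_channel_rates
    k1 <- sub$green * kk1$green[1L] + sub$red * kk1$red[1L]
    k2 <- sub$green * kk1$green[2L] + sub$red * kk1$red[2L]
    r_star <- k1 / (k2 + sensor$k_dil + sensor$k_dr)
    gmin <- min(sub$fluorescence); gmax <- max(sub$fluorescence)
    theta0 <- log(c(a_hat = (gmax - gmin) * sensor$k_dil,
                    b_hat = max(gmin * sensor$k_dil, 1e-9),
                    n = 1.5, big_k = stats::median(r_star[r_star > 0])))
    rf <- function(theta) {
      v <- exp(theta)
      out <- output_params(v[1L], v[2L], v[3L], v[4L], tau = taus[[sys]],
                           k_dil = sensor$k_dil, mode = modes[[sys]])
      (sub$fluorescence - steady_state_g(r_star, out)) / sub$fluorescence
    }
    fit <- minpack.lm::nls.lm(theta0, fn = rf,
                              control = minpack.lm::nls.lm.control(maxiter = 300))
    v <- exp(fit$par)
    res[[sys]] <- output_params(v[1L], v[2L], v[3L], v[4L], tau = taus[[sys]],
                                k_dil = sensor$k_dil, mode = modes[[sys]])
    objs[sys] <- fit$deviance
  }
  attr(res, "objective") <- objs
  res
}
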