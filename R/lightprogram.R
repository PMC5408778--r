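# Piecewise-constant multi-channel light programs: the input format for every
# simulation. Each channel holds its intensity from a breakpoint until the next.

#' Construct a light program
#'
#' A multi-channel piecewise-constant intensity schedule. Each channel is a
#' table of breakpoints `(time, intensity)`; the intensity holds from a
#' breakpoint until the next one (and until `t_end` after the last). Before a
#' channel's first breakpoint its intensity is zero.
#'
#' @param channels Named list of data.frames with columns `time` (min,
#'   strictly increasing) and `intensity` (micromol m^-2 s^-1, nonnegative),
#'   or a single data.frame with columns `channel`, `time`, `intensity`.
#' @param t_end Program duration (min).
#' @param i_max Optional named vector of per-channel intensity bounds.
#' @return An object of class `light_program`.
#' @export
light_program <- function(channels, t_end, i_max = NULL) {
  if (is.data.frame(channels)) {
    stopifnot(all(c("channel", "time", "intensity") %in% names(channels)))
    channels <- split(channels[c("time", "intensity")], channels$channel)
  }
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channels must be named")
  for (nm in names(channels)) {
    ch <- as.data.frame(channels[[nm]])
    if (!all(c("time", "intensity") %in% names(ch)))
      stop(sprintf("channel '%s' needs columns time and intensity", nm))
    if (nrow(ch) == 0L) stop(sprintf("channel '%s' has no breakpoints", nm))
    if (any(diff(ch$time) <= 0))
      stop(sprintf("channel '%s': breakpoint times must be strictly increasing", nm))
    if (any(ch$time < 0) || any(ch$time >= t_end + 1e-9))
      stop(sprintf("channel '%s': breakpoints must lie within [0, t_end)", nm))
    if (any(ch$intensity < 0))
      stop(sprintf("channel '%s': negative intensity", nm))
    if (!is.null(i_max) && nm %in% names(i_max) &&
        any(ch$intensity > i_max[[nm]] + 1e-9))
      stop(sprintf("channel '%s': intensity exceeds bound %g", nm, i_max[[nm]]))
    channels[[nm]] <- ch[c("time", "intensity")]
  }
  structure(list(channels = channels, t_end = as.numeric(t_end), i_max = i_max),
            class = "light_program")
}

#' Constant-light program
#'
#' @param intensities Named vector of constant intensities per channel.
#' @param t_end Duration (min).
#' @return A `light_program` with a single breakpoint per channel at t = 0.
#' @export
constant_program <- function(intensities, t_end = 480) {
  if (length(intensities) == 0L) {
    return(light_program(list(dark = data.frame(time = 0, intensity = 0)), t_end))
  }
  chs <- lapply(intensities, function(i) data.frame(time = 0, intensity = i))
  names(chs) <- names(intensities)
  light_program(chs, t_end)
}

#' @export
print.light_program <- function(x, ...) {
  cat(sprintf("<light_program: %d channel(s), t_end = %g min>\n",
              length(x$channels), x$t_end))
  for (nm in names(x$channels))
    cat(sprintf("  %s: %d breakpoints, intensity %.4g-%.4g\n", nm,
                nrow(x$channels[[nm]]), min(x$channels[[nm]]$intensity),
                max(x$channels[[nm]]$intensity)))
  invisible(x)
}

#' Channel intensity at given times
#'
#' @param program A `light_program`.
#' @param channel Channel name.
#' @param t Times (min).
#' @return Intensities at `t` (zero before the first breakpoint).
#' @export
program_intensity <- function(program, channel, t) {
  if (!channel %in% names(program$channels)) return(rep(0, length(t)))
  ch <- program$channels[[channel]]
  idx <- findInterval(t + 1e-12, ch$time)
  ifelse(idx == 0L, 0, ch$intensity[pmax(idx, 1L)])
}

#' Merge two light programs channel-wise
#'
#' Used to inject an external (fixed) light signal into a designed program:
#' intensities of shared channels add on the union of breakpoints.
#'
#' @param a,b `light_program` objects (same `t_end`).
#' @return A `light_program`.
#' @export
program_add <- function(a, b) {
  if (is.null(b)) return(a)
  if (is.null(a)) return(b)
  t_end <- max(a$t_end, b$t_end)
  nms <- union(names(a$channels), names(b$channels))
  chs <- lapply(nms, function(nm) {
    times <- sort(unique(c(0,
      if (nm %in% names(a$channels)) a$channels[[nm]]$time,
      if (nm %in% names(b$channels)) b$channels[[nm]]$time)))
    data.frame(time = times,
               intensity = program_intensity(a, nm, times) +
                           program_intensity(b, nm, times))
  })
  names(chs) <- nms
  light_program(chs, t_end)
}

#' All breakpoint times of a program
#'
#' @param program A `light_program`.
#' @return Sorted unique breakpoint times including 0 and `t_end`.
#' @export
program_breakpoints <- function(program) {
  sort(unique(c(0, unlist(lapply(program$channels, function(ch) ch$time)),
                program$t_end)))
}

#' Read / write light program tables
#'
#' Delimited tables `channel,time_min,intensity_umol_m2_s` (piecewise
#' constant; each value holds until the next breakpoint).
#'
#' @param path File path.
#' @param t_end Duration (min); defaults to the last breakpoint + 1 if absent.
#' @return A `light_program` / the path, invisibly.
#' @export
read_light_program <- function(path, t_end = NULL) {
  tab <- utils::read.csv(path)
  stopifnot(all(c("channel", "time_min", "intensity_umol_m2_s") %in% names(tab)))
  if (is.null(t_end)) t_end <- max(tab$time_min) + 1
  light_program(data.frame(channel = tab$channel, time = tab$time_min,
                           intensity = tab$intensity_umol_m2_s), t_end)
}

#' @rdname read_light_program
#' @param program A `light_program`.
#' @export
write_light_program <- function(program, path) {
  rows <- do.call(rbind, lapply(names(program$channels), function(nm)
    data.frame(channel = nm, time_min = program$channels[[nm]]$time,
               intensity_umol_m2_s = program$channels[[nm]]$intensity)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a program as 12-bit grayscale levels
#'
#' Quantizes each channel's intensities to hardware grayscale levels given
#' per-channel calibrated maxima.
#'
#' @param program A `light_program`.
#' @param max_intensity Named vector of per-channel full-scale intensities.
#' @param bit_depth Grayscale bit depth.
#' @return data.frame `channel,time_min,gs_level`.
#' @export
program_to_grayscale <- function(program, max_intensity, bit_depth = 12L) {
  do.call(rbind, lapply(names(program$channels), function(nm) {
    if (!nm %in% names(max_intensity))
      stop(sprintf("no max_intensity for channel '%s'", nm))
    data.frame(channel = nm, time_min = program$channels[[nm]]$time,
               gs_level = intensity_to_grayscale(program$channels[[nm]]$intensity,
                                                 max_intensity[[nm]], bit_depth,
                                                 channel = nm))
  }))
}

#' Re-quantize a program through the grayscale mapping
#'
#' Rounds every intensity to its nearest representable 12-bit level, the
#' program the hardware can actually play.
#'
#' @inheritParams program_to_grayscale
#' @return A `light_program` with quantized intensities.
#' @export
quantize_program <- function(program, max_intensity, bit_depth = 12L) {
  chs <- lapply(names(program$channels), function(nm) {
    lev <- intensity_to_grayscale(program$channels[[nm]]$intensity,
                                  max_intensity[[nm]], bit_depth, channel = nm)
    data.frame(time = program$channels[[nm]]$time,
               intensity = grayscale_to_intensity(lev, max_intensity[[nm]], bit_depth))
  })
  names(chs) <- names(program$channels)
  light_program(chs, program$t_end)
}
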