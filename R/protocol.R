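#' Build the automated swinging-flashlight stimulation timeline
#'
#' Constructs the default stimulus sequence used by the pupillometer: an
#' initial 5 s dark-adaptation period, a 1 s binocular conditioning pulse
#' followed by 3 s of darkness, then `n_cycles` cycles of monocular
#' stimulation, each a 1 s light pulse to one eye followed by 3 s of darkness.
#' The left eye is always stimulated first. With the defaults (3 cycles) the
#' protocol lasts 33 s and contains 6 monocular pulses (3 left, 3 right).
#'
#' @param sample_rate_hz Sampling rate of the recording the timeline will be
#'   aligned to, in samples per second. Default 90 (the headset eye tracker's
#'   native frame rate).
#' @param intensity_lux Illuminance of every light pulse, in lux. Default 125.
#' @param n_cycles Number of monocular stimulation cycles. Default 3.
#' @param cycle_order `"alternating"` (default) interleaves left and right
#'   pulses within each cycle (L, R, L, R, ...), the swinging-flashlight
#'   convention; `"blocked"` presents all left pulses before all right pulses.
#'   Total duration is identical either way.
#' @param pulse_duration_s,dark_duration_s,adaptation_s Epoch durations in
#'   seconds. Defaults 1, 3 and 5.
#'
#' @return A `protocol_timeline` object: a list with the epoch table
#'   (`$epochs`: onset, duration, type, stimulated eye, intensity, cycle
#'   index), `$sample_rate_hz`, `$total_duration_s` and the construction
#'   parameters. Epochs tile `[0, total_duration_s)` with no gaps or overlaps.
#'
#' @examples
#' tl <- default_timeline()
#' tl$total_duration_s            # 33
#' sum(tl$epochs$type == "light") # 7 pulses: 1 binocular + 6 monocular
#' @export
default_timeline <- function(sample_rate_hz = 90, intensity_lux = 125,
                             n_cycles = 3,
                             cycle_order = c("alternating", "blocked"),
                             pulse_duration_s = 1, dark_duration_s = 3,
                             adaptation_s = 5) {
  cycle_order <- match.arg(cycle_order)
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      sample_rate_hz <= 0) {
    stop("`sample_rate_hz` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(n_cycles) || length(n_cycles) != 1 || n_cycles < 1 ||
      n_cycles != round(n_cycles)) {
    stop("`n_cycles` must be a positive integer", call. = FALSE)
  }
  if (pulse_duration_s <= 0 || dark_duration_s <= 0 || adaptation_s <= 0) {
    stop("epoch durations must be positive", call. = FALSE)
  }

  eye_seq <- if (cycle_order == "alternating") {
    rep(c("left", "right"), n_cycles)
  } else {
    rep(c("left", "right"), each = n_cycles)
  }
  # one row per epoch: adaptation, binocular pulse + dark, then the cycles
  eye <- c("none", "both", "none",
           as.vector(rbind(eye_seq, "none")))
  type <- ifelse(eye == "none", "dark", "light")
  duration <- ifelse(type == "light", pulse_duration_s, dark_duration_s)
  duration[1] <- adaptation_s
  onset <- cumsum(c(0, duration[-length(duration)]))
  # cycle index: NA for adaptation, 0 for the binocular pulse, then per-eye
  # replicate number 1..n_cycles for monocular pulses
  cycle <- rep(NA_integer_, length(eye))
  cycle[eye == "both"] <- 0L
  for (e in c("left", "right")) {
    cycle[eye == e] <- seq_len(sum(eye == e))
  }

  epochs <- data.frame(
    onset_s = onset,
    duration_s = duration,
    type = type,
    eye = eye,
    intensity_lux = ifelse(type == "light", intensity_lux, 0),
    cycle = cycle,
    stringsAsFactors = FALSE
  )
  total <- sum(duration)
  stopifnot(isTRUE(all.equal(epochs$onset_s[-1],
                             (epochs$onset_s + epochs$duration_s)[-nrow(epochs)])))

  structure(
    list(epochs = epochs,
         sample_rate_hz = sample_rate_hz,
         intensity_lux = intensity_lux,
         n_cycles = as.integer(n_cycles),
         cycle_order = cycle_order,
         pulse_duration_s = pulse_duration_s,
         dark_duration_s = dark_duration_s,
         adaptation_s = adaptation_s,
         total_duration_s = total),
    class = "protocol_timeline"
  )
}

#' @export
print.protocol_timeline <- function(x, ...) {
  cat("Swinging-flashlight protocol timeline\n")
  cat(sprintf("  %d cycles (%s), %.0f lux, %.0f Hz sampling\n",
              x$n_cycles, x$cycle_order, x$intensity_lux, x$sample_rate_hz))
  cat(sprintf("  total duration %.1f s (%d samples), %d light epochs\n",
              x$total_duration_s, timeline_n_samples(x),
              sum(x$epochs$type == "light")))
  invisible(x)
}

#' Number of samples in a recording matching a timeline
#'
#' @param timeline A `protocol_timeline`.
#' @return Integer sample count, `round(total_duration_s * sample_rate_hz)`.
#' @export
timeline_n_samples <- function(timeline) {
  stopifnot(inherits(timeline, "protocol_timeline"))
  as.integer(round(timeline$total_duration_s * timeline$sample_rate_hz))
}

#' Derive per-pulse baseline and response analysis windows
#'
#' For every light epoch of the timeline, returns the time interval used to
#' measure the pre-stimulus baseline diameter and the interval searched for
#' the constriction trough. Intervals are half-open `[start, end)` in seconds
#' from recording start.
#'
#' Two baseline conventions are supported. `"adaptation"` anchors every
#' pulse's baseline to the dark-adapted state: the last `baseline_window_s`
#' of the initial dark-adaptation epoch, so constriction percentages are
#' expressed relative to the fully dark-adapted diameter. `"preceding"` uses
#' the last `baseline_window_s` of the dark epoch immediately before each
#' pulse; this tracks slow drift but is biased low when redilation from the
#' previous pulse is still incomplete when the next pulse arrives.
#'
#' @param timeline A `protocol_timeline`.
#' @param baseline_window_s Length of the baseline interval in seconds
#'   (default 0.5). Must not exceed the relevant dark epoch's duration.
#' @param response_window_s Length of the response interval, from pulse onset
#'   (default 2.5 s, long enough that a reflex with ~0.25 s latency always
#'   troughs inside it). Must fit within the pulse plus the following dark
#'   epoch.
#' @param baseline_mode `"preceding"` (default) or `"adaptation"`; see above.
#' @param baseline_margin_s Gap in seconds between the end of the baseline
#'   window and the end of its dark epoch (default 0). A zero-phase running
#'   mean of width `w` samples draws on samples up to `w/2` samples ahead,
#'   so on a smoothed trace the last `w/2` samples of a dark epoch already
#'   carry stimulus-locked constriction; setting the margin to that filter
#'   half-width keeps the baseline uncontaminated.
#'
#' @return A data frame with one row per light epoch: `epoch` (row index into
#'   `timeline$epochs`), `eye`, `cycle`, `baseline_start`, `baseline_end`,
#'   `response_start`, `response_end`.
#' @export
analysis_windows <- function(timeline, baseline_window_s = 0.5,
                             response_window_s = 2.5,
                             baseline_mode = c("preceding", "adaptation"),
                             baseline_margin_s = 0) {
  stopifnot(inherits(timeline, "protocol_timeline"))
  baseline_mode <- match.arg(baseline_mode)
  ep <- timeline$epochs
  light <- which(ep$type == "light")
  if (baseline_window_s <= 0 || response_window_s <= 0) {
    stop("analysis windows must have positive length", call. = FALSE)
  }
  if (baseline_margin_s < 0) {
    stop("`baseline_margin_s` must be non-negative", call. = FALSE)
  }

  out <- lapply(light, function(i) {
    if (baseline_mode == "adaptation") {
      dark <- 1L # the adaptation epoch is always first
    } else {
      dark <- i - 1L
    }
    if (dark < 1 || ep$type[dark] != "dark") {
      stop("light epoch has no preceding dark epoch", call. = FALSE)
    }
    if (baseline_window_s + baseline_margin_s > ep$duration_s[dark] + 1e-12) {
      stop(sprintf(
        "baseline window plus margin (%.3g s) exceeds the available dark epoch (%.3g s)",
        baseline_window_s + baseline_margin_s, ep$duration_s[dark]),
        call. = FALSE)
    }
    avail <- ep$duration_s[i] +
      if (i < nrow(ep) && ep$type[i + 1] == "dark") ep$duration_s[i + 1] else 0
    if (response_window_s > avail + 1e-12) {
      stop(sprintf(
        "response window (%.3g s) exceeds the pulse plus following dark epoch (%.3g s)",
        response_window_s, avail), call. = FALSE)
    }
    dark_end <- ep$onset_s[dark] + ep$duration_s[dark] - baseline_margin_s
    data.frame(
      epoch = i,
      eye = ep$eye[i],
      cycle = ep$cycle[i],
      baseline_start = dark_end - baseline_window_s,
      baseline_end = dark_end,
      response_start = ep$onset_s[i],
      response_end = ep$onset_s[i] + response_window_s,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Serialize a timeline to a plain configuration list
#'
#' @param timeline A `protocol_timeline`.
#' @return A named list of scalar construction parameters, suitable for YAML
#'   or JSON serialization; invert with [timeline_from_config()].
#' @export
timeline_to_config <- function(timeline) {
  stopifnot(inherits(timeline, "protocol_timeline"))
  timeline[c("sample_rate_hz", "intensity_lux", "n_cycles", "cycle_order",
             "pulse_duration_s", "dark_duration_s", "adaptation_s")]
}

#' @rdname timeline_to_config
#' @param config A list as produced by [timeline_to_config()]; missing
#'   entries fall back to the defaults of [default_timeline()].
#' @export
timeline_from_config <- function(config) {
  args <- list(
    sample_rate_hz = config$sample_rate_hz %||% 90,
    intensity_lux = config$intensity_lux %||% 125,
    n_cycles = config$n_cycles %||% 3,
    cycle_order = config$cycle_order %||% "alternating",
    pulse_duration_s = config$pulse_duration_s %||% 1,
    dark_duration_s = config$dark_duration_s %||% 3,
    adaptation_s = config$adaptation_s %||% 5
  )
  do.call(default_timeline, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
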