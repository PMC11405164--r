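#' Flag physiologically impossible diameters as missing
#'
#' Samples outside the plausible pupil-diameter range — blink artifacts and
#' large eye movements typically register as extreme values — are marked
#' missing, per eye independently. Defaults follow the device's cutoffs:
#' below 1 mm or above 9 mm.
#'
#' @param trace A [pupil_trace()].
#' @param lo_mm,hi_mm Lower and upper diameter cutoffs in mm (defaults 1, 9).
#' @return The trace with out-of-range samples marked `"missing"`. Idempotent.
#' @export
flag_artifacts <- function(trace, lo_mm = 1, hi_mm = 9) {
  stopifnot(inherits(trace, "pupil_trace"))
  if (!is.numeric(lo_mm) || !is.numeric(hi_mm) || lo_mm <= 0 || lo_mm >= hi_mm) {
    stop("cutoffs must satisfy 0 < lo_mm < hi_mm", call. = FALSE)
  }
  for (eye in c("left", "right")) {
    d <- trace[[paste0(eye, "_mm")]]
    v <- trace[[paste0("validity_", eye)]]
    out <- !is.na(d) & (d < lo_mm | d > hi_mm)
    d[out] <- NA_real_
    v[out] <- "missing"
    trace[[paste0(eye, "_mm")]] <- d
    trace[[paste0("validity_", eye)]] <- v
  }
  trace
}

# run-length summary of missing samples for one eye
missing_runs <- function(miss) {
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values],
             length = r$lengths[r$values])
}

#' Bridge missing-sample gaps with shape-preserving interpolation
#'
#' Interior runs of missing samples no longer than `max_gap_samples` are
#' replaced, per eye, by piecewise cubic Hermite (PCHIP) values through the
#' surrounding valid samples; PCHIP preserves monotonicity, so interpolated
#' values never overshoot their bracketing samples. Leading and trailing runs
#' (which have no bracketing knot on one side) are filled by nearest-valid
#' constant extension. A run longer than `max_gap_samples` in either eye
#' fails quality control: the trace is returned unmodified with
#' `quality$pass = FALSE`, signalling that the recording should be repeated.
#'
#' @param trace A [pupil_trace()], typically after [flag_artifacts()].
#' @param max_gap_samples Longest bridgeable missing run, in samples.
#'   Default 90 — one second at the native 90 Hz rate.
#' @return A list with `$trace` (gaps filled, validity `"interpolated"`) and
#'   `$quality`, a `quality_report`: `pass`, per-eye `longest_gap_samples`
#'   and `fraction_missing` (both computed before filling), and `reason`.
#' @export
interpolate_gaps <- function(trace, max_gap_samples = 90) {
  stopifnot(inherits(trace, "pupil_trace"))
  if (max_gap_samples < 1) {
    stop("`max_gap_samples` must be at least 1", call. = FALSE)
  }
  n <- length(trace$t)
  longest <- c(left = 0L, right = 0L)
  frac <- c(left = 0, right = 0)
  reasons <- character(0)
  pass <- TRUE

  for (eye in c("left", "right")) {
    miss <- trace[[paste0("validity_", eye)]] == "missing"
    frac[eye] <- mean(miss)
    if (sum(!miss) < 2) {
      pass <- FALSE
      reasons <- c(reasons, sprintf("%s eye has fewer than 2 valid samples", eye))
      longest[eye] <- if (any(miss)) max(missing_runs(miss)$length) else 0L
      next
    }
    runs <- missing_runs(miss)
    longest[eye] <- if (nrow(runs)) max(runs$length) else 0L
    if (longest[eye] > max_gap_samples) {
      pass <- FALSE
      reasons <- c(reasons, sprintf(
        "%s eye has a %d-sample missing run (limit %d)",
        eye, longest[eye], max_gap_samples))
    }
  }

  quality <- structure(
    list(pass = pass,
         longest_gap_samples = longest,
         fraction_missing = frac,
         max_gap_samples = max_gap_samples,
         reason = if (pass) "ok" else paste(reasons, collapse = "; ")),
    class = "quality_report")

  if (!pass) {
    return(list(trace = trace, quality = quality))
  }

  for (eye in c("left", "right")) {
    d <- trace[[paste0(eye, "_mm")]]
    v <- trace[[paste0("validity_", eye)]]
    miss <- v == "missing"
    if (!any(miss)) next
    valid_idx <- which(!miss)
    first_v <- valid_idx[1]
    last_v <- valid_idx[length(valid_idx)]
    # leading/trailing runs: constant extension from the nearest valid sample
    if (first_v > 1) d[seq_len(first_v - 1)] <- d[first_v]
    if (last_v < n) d[(last_v + 1):n] <- d[last_v]
    # interior runs: shape-preserving Hermite through the valid knots
    interior <- which(miss)
    interior <- interior[interior > first_v & interior < last_v]
    if (length(interior)) {
      d[interior] <- pracma::pchip(trace$t[valid_idx], d[valid_idx],
                                   trace$t[interior])
    }
    v[miss] <- "interpolated"
    trace[[paste0(eye, "_mm")]] <- d
    trace[[paste0("validity_", eye)]] <- v
  }
  list(trace = trace, quality = quality)
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("Trace quality: %s\n", if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  longest missing run: OS %d, OD %d samples (limit %d)\n",
              x$longest_gap_samples["left"], x$longest_gap_samples["right"],
              x$max_gap_samples))
  cat(sprintf("  fraction missing: OS %.3f, OD %.3f\n",
              x$fraction_missing["left"], x$fraction_missing["right"]))
  if (!x$pass) cat("  reason:", x$reason, "\n")
  invisible(x)
}

# centred running mean; nominal window [i - floor(w/2), i + w - 1 - floor(w/2)],
# truncated to a symmetric window about i where the nominal one would cross
# either edge (keeps the filter zero-phase at the boundaries)
running_mean <- function(x, w) {
  n <- length(x)
  if (w == 1 || n == 0) return(x)
  L <- floor(w / 2)
  R <- w - 1L - L
  i <- seq_len(n)
  lo <- i - L
  hi <- i + R
  edge <- lo < 1 | hi > n
  k <- pmin(i - 1L, n - i)
  lo[edge] <- (i - k)[edge]
  hi[edge] <- (i + k)[edge]
  cs <- cumsum(c(0, x))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Smooth a trace with a centred running-average filter
#'
#' Replaces each eye's series by a centred moving mean over
#' `window_samples` samples (default 100, the device's filter length). Near
#' the edges the window is truncated symmetrically about the current sample,
#' so the filter stays zero-phase and output length equals input length.
#' Requires a gap-free trace: run [interpolate_gaps()] first.
#'
#' @param trace A [pupil_trace()] with no missing samples.
#' @param window_samples Filter length in samples; 1 is the identity.
#' @return The smoothed trace. Output values always lie within the input's
#'   range.
#' @export
smooth_trace <- function(trace, window_samples = 100) {
  stopifnot(inherits(trace, "pupil_trace"))
  if (window_samples < 1 || window_samples != round(window_samples)) {
    stop("`window_samples` must be a positive integer", call. = FALSE)
  }
  if (any(trace$validity_left == "missing") ||
      any(trace$validity_right == "missing")) {
    stop("trace contains missing samples; run interpolate_gaps() before smoothing",
         call. = FALSE)
  }
  trace$left_mm <- running_mean(trace$left_mm, window_samples)
  trace$right_mm <- running_mean(trace$right_mm, window_samples)
  trace
}

#' Run the full preprocessing chain on a raw trace
#'
#' Default order: [flag_artifacts()] (diameter cutoffs), then
#' [interpolate_gaps()] (PCHIP bridging, quality gate), then
#' [smooth_trace()]. Interpolating before smoothing prevents the running
#' mean from spreading blink spikes into neighbouring samples;
#' `published_order = TRUE` instead smooths the raw series first and then
#' applies the cutoffs and interpolation, the literal published sequence.
#'
#' @param trace A raw [pupil_trace()].
#' @param lo_mm,hi_mm Diameter cutoffs, see [flag_artifacts()].
#' @param max_gap_samples Quality-gate gap limit, see [interpolate_gaps()].
#' @param window_samples Smoothing window, see [smooth_trace()].
#' @param published_order Use the smooth-first ordering. Default `FALSE`.
#' @return A list with `$trace` (cleaned; unmodified input when quality
#'   fails) and `$quality` (a `quality_report`).
#' @export
preprocess_trace <- function(trace, lo_mm = 1, hi_mm = 9,
                             max_gap_samples = 90, window_samples = 100,
                             published_order = FALSE) {
  if (published_order) {
    # smoothing requires a gap-free series; smooth only the present samples'
    # neighbourhoods by carrying tracker dropouts through untouched
    sm <- trace
    for (eye in c("left", "right")) {
      d <- sm[[paste0(eye, "_mm")]]
      ok <- !is.na(d)
      d[ok] <- running_mean(d[ok], window_samples)
      sm[[paste0(eye, "_mm")]] <- d
    }
    flagged <- flag_artifacts(sm, lo_mm, hi_mm)
    return(interpolate_gaps(flagged, max_gap_samples))
  }
  flagged <- flag_artifacts(trace, lo_mm, hi_mm)
  res <- interpolate_gaps(flagged, max_gap_samples)
  if (!res$quality$pass) {
    return(res)
  }
  res$trace <- smooth_trace(res$trace, window_samples)
  res
}
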