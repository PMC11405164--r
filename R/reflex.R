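#' Measure one pupillary light-reflex response
#'
#' The baseline diameter is the mean of the responding eye over the baseline
#' interval; the trough is the minimum over the response interval. The
#' constriction amplitude is the percentage change from baseline,
#' `100 * (baseline - trough) / baseline`, floored at zero when the pupil
#' dilated instead of constricting (the floor keeps downstream ratio scores
#' defined; the raw dilation is recorded in `dilated`).
#'
#' @param trace A preprocessed, quality-passing [pupil_trace()].
#' @param baseline_start,baseline_end,response_start,response_end Interval
#'   bounds in seconds, half-open `[start, end)`.
#' @param stimulated_eye,responding_eye `"left"`, `"right"` or (stimulated
#'   only) `"both"`.
#' @param cycle Replicate index carried through to the measurement record.
#' @return A one-row data frame: stimulated and responding eye, cycle,
#'   `baseline_mm`, `trough_mm`, `constriction_pct`, `dilated`.
#' @export
measure_epoch <- function(trace, baseline_start, baseline_end,
                          response_start, response_end,
                          stimulated_eye, responding_eye, cycle = NA_integer_) {
  stopifnot(inherits(trace, "pupil_trace"))
  d <- eye_series(trace, responding_eye)
  bi <- trace$t >= baseline_start & trace$t < baseline_end
  ri <- trace$t >= response_start & trace$t < response_end
  if (!any(bi) || !any(ri)) {
    stop("analysis interval contains no samples", call. = FALSE)
  }
  if (anyNA(d[bi]) || anyNA(d[ri])) {
    stop("trace has missing samples inside an analysis interval; preprocess first",
         call. = FALSE)
  }
  baseline <- mean(d[bi])
  trough <- min(d[ri])
  pct <- 100 * (baseline - trough) / baseline
  data.frame(stimulated_eye = stimulated_eye,
             responding_eye = responding_eye,
             cycle = cycle,
             baseline_mm = baseline,
             trough_mm = trough,
             constriction_pct = max(pct, 0),
             dilated = pct < 0,
             stringsAsFactors = FALSE)
}

#' Extract direct and consensual reflex amplitudes for a whole recording
#'
#' Measures every light epoch of the timeline for both responding eyes,
#' giving per-cycle direct (stimulated eye = responding eye) and consensual
#' (fellow eye) constriction percentages, then aggregates them per eye
#' across cycles. The binocular conditioning pulse is measured but excluded
#' from the direct/consensual aggregates and from RAPD scoring; it serves
#' light adaptation only.
#'
#' @param trace A preprocessed, quality-passing [pupil_trace()].
#' @param timeline The [default_timeline()] the recording followed.
#' @param baseline_window_s,response_window_s,baseline_mode,baseline_margin_s
#'   Passed to [analysis_windows()]. The pipeline default `baseline_mode =
#'   "adaptation"` expresses constriction relative to the dark-adapted
#'   state; [analyze_trace()] sets the margin to the smoothing filter's
#'   half-width.
#' @param aggregate `"mean"` (default) or `"median"` across cycles.
#' @return A `reflex_summary`: `$measurements` (one row per light epoch x
#'   responding eye), `$direct` and `$consensual` (per-eye aggregate,
#'   `sd_pct` and replicate count), `$n_cycles`, `$aggregate`.
#' @export
summarize_reflexes <- function(trace, timeline, baseline_window_s = 0.5,
                               response_window_s = 2.5,
                               baseline_mode = c("adaptation", "preceding"),
                               baseline_margin_s = 0,
                               aggregate = c("mean", "median")) {
  baseline_mode <- match.arg(baseline_mode)
  aggregate <- match.arg(aggregate)
  win <- analysis_windows(timeline, baseline_window_s, response_window_s,
                          baseline_mode = baseline_mode,
                          baseline_margin_s = baseline_margin_s)
  rows <- lapply(seq_len(nrow(win)), function(i) {
    w <- win[i, ]
    do.call(rbind, lapply(c("left", "right"), function(resp) {
      measure_epoch(trace,
                    w$baseline_start, w$baseline_end,
                    w$response_start, w$response_end,
                    stimulated_eye = w$eye, responding_eye = resp,
                    cycle = w$cycle)
    }))
  })
  meas <- do.call(rbind, rows)

  mono <- meas[meas$stimulated_eye %in% c("left", "right"), ]
  agg_fun <- if (aggregate == "mean") mean else stats::median
  per_eye <- function(direct) {
    do.call(rbind, lapply(c("left", "right"), function(eye) {
      sel <- if (direct) {
        mono$stimulated_eye == eye & mono$responding_eye == eye
      } else {
        mono$stimulated_eye != eye & mono$responding_eye == eye
      }
      x <- mono$constriction_pct[sel]
      data.frame(eye = eye, mean_pct = agg_fun(x),
                 sd_pct = stats::sd(x), n = length(x),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(
    list(measurements = meas,
         direct = per_eye(TRUE),
         consensual = per_eye(FALSE),
         n_cycles = timeline$n_cycles,
         aggregate = aggregate),
    class = "reflex_summary")
}

#' @export
print.reflex_summary <- function(x, ...) {
  cat("Pupillary light-reflex summary (", x$aggregate, " of ",
      x$n_cycles, " cycles)\n", sep = "")
  for (i in seq_len(nrow(x$direct))) {
    eye <- x$direct$eye[i]
    cat(sprintf("  %-5s direct %6.2f +/- %.2f %%   consensual %6.2f +/- %.2f %%\n",
                eye, x$direct$mean_pct[i], x$direct$sd_pct[i],
                x$consensual$mean_pct[x$consensual$eye == eye],
                x$consensual$sd_pct[x$consensual$eye == eye]))
  }
  invisible(x)
}

#' Screen for an efferent pupillary pathway defect
#'
#' An efferent (motor) defect attenuates one pupil's response regardless of
#' which eye is stimulated, whereas an afferent defect attenuates both
#' pupils' responses when the affected eye is stimulated. The screen
#' therefore compares, within each stimulation side, the two pupils'
#' constriction amplitudes: the flag is raised only when the same pupil is
#' the weaker responder under both left- and right-eye stimulation and both
#' within-side asymmetry ratios exceed `asymmetry_ratio`. A completely
#' non-reactive pupil (zero constriction in a denominator) always raises
#' the flag. Pure afferent patterns never do, and the rule is invariant to
#' uniform scaling of all responses.
#'
#' @param summary A [summarize_reflexes()] result.
#' @param asymmetry_ratio Minimum larger/smaller within-side ratio to count
#'   as asymmetric. Default 1.25.
#' @return Logical flag with attributes `reason`, `ratio_left_stim`,
#'   `ratio_right_stim` and `weaker_pupil` (per stimulation side).
#' @export
detect_efferent_defect <- function(summary, asymmetry_ratio = 1.25) {
  stopifnot(inherits(summary, "reflex_summary"))
  mono <- summary$measurements
  mono <- mono[mono$stimulated_eye %in% c("left", "right"), ]
  side <- lapply(c("left", "right"), function(stim) {
    v <- vapply(c("left", "right"), function(resp) {
      mean(mono$constriction_pct[mono$stimulated_eye == stim &
                                   mono$responding_eye == resp])
    }, numeric(1))
    if (min(v) <= 0) {
      return(list(ratio = Inf, weaker = names(v)[which.min(v)],
                  nonreactive = TRUE))
    }
    list(ratio = max(v) / min(v),
         weaker = if (v["left"] == v["right"]) "none"
                  else names(v)[which.min(v)],
         nonreactive = FALSE)
  })
  names(side) <- c("left", "right")

  if (side$left$nonreactive || side$right$nonreactive) {
    flag <- TRUE
    reason <- "non-reactive pupil"
  } else if (side$left$weaker != "none" &&
             side$left$weaker == side$right$weaker &&
             side$left$ratio > asymmetry_ratio &&
             side$right$ratio > asymmetry_ratio) {
    flag <- TRUE
    reason <- sprintf("%s pupil consistently weaker (ratios %.2f / %.2f)",
                      side$left$weaker, side$left$ratio, side$right$ratio)
  } else {
    flag <- FALSE
    reason <- "no efferent asymmetry"
  }
  structure(flag,
            reason = reason,
            ratio_left_stim = side$left$ratio,
            ratio_right_stim = side$right$ratio,
            weaker_pupil = c(left_stim = side$left$weaker,
                             right_stim = side$right$weaker))
}

#' Compute the RAPD score from a reflex summary
#'
#' The two-tailed score is the ratio of the right eye's mean direct
#' constriction to the left eye's (OD / OS); the one-tailed score folds it
#' about unity, stronger / weaker, so it is always at least 1, with the
#' weaker eye identified separately. Scoring is withheld (scores `NA`) when
#' the efferent screen flagged the recording, when trace quality failed, or
#' when the weaker eye's mean constriction is not positive.
#'
#' @param summary A [summarize_reflexes()] result.
#' @param quality Optional `quality_report` from preprocessing.
#' @param efferent Optional result of [detect_efferent_defect()]; computed
#'   from `summary` (threshold `asymmetry_ratio`) when omitted.
#' @param asymmetry_ratio Efferent-screen threshold, see
#'   [detect_efferent_defect()].
#' @return An `rapd_result`: `score_one_tailed`, `score_two_tailed`,
#'   `weaker_eye` (`"none"` on an exact tie), `efferent_flag`, `quality`,
#'   `direct_pct` (named per-eye means) and `reason`.
#' @export
rapd_score <- function(summary, quality = NULL, efferent = NULL,
                       asymmetry_ratio = 1.25) {
  stopifnot(inherits(summary, "reflex_summary"))
  if (is.null(efferent)) {
    efferent <- detect_efferent_defect(summary, asymmetry_ratio)
  }
  od <- summary$direct$mean_pct[summary$direct$eye == "right"]
  os <- summary$direct$mean_pct[summary$direct$eye == "left"]
  res <- list(score_one_tailed = NA_real_,
              score_two_tailed = NA_real_,
              weaker_eye = NA_character_,
              efferent_flag = isTRUE(as.logical(efferent)),
              efferent_reason = attr(efferent, "reason"),
              quality = quality,
              direct_pct = c(left = os, right = od),
              reason = "ok")
  if (!is.null(quality) && !quality$pass) {
    res$reason <- paste("quality failure:", quality$reason)
  } else if (res$efferent_flag) {
    res$reason <- paste("efferent defect suspected:", attr(efferent, "reason"))
  } else if (min(od, os) <= 0) {
    res$reason <- "weaker eye shows no constriction; score undefined"
  } else {
    r <- od / os
    res$score_two_tailed <- r
    res$score_one_tailed <- max(r, 1 / r)
    res$weaker_eye <- if (od == os) "none" else if (od < os) "right" else "left"
  }
  structure(res, class = "rapd_result")
}

#' @export
print.rapd_result <- function(x, ...) {
  cat("RAPD result\n")
  if (is.na(x$score_one_tailed)) {
    cat("  unscored:", x$reason, "\n")
  } else {
    cat(sprintf("  one-tailed score %.3f (weaker eye: %s); OD/OS ratio %.3f\n",
                x$score_one_tailed, x$weaker_eye, x$score_two_tailed))
  }
  cat(sprintf("  direct constriction: OS %.2f%%, OD %.2f%%\n",
              x$direct_pct["left"], x$direct_pct["right"]))
  invisible(x)
}

#' Run the full analysis pipeline on one raw trace
#'
#' Preprocesses the trace ([preprocess_trace()]), extracts reflex amplitudes
#' ([summarize_reflexes()]), screens for efferent defects and scores the
#' RAPD ([rapd_score()]). On a quality failure the result is returned
#' unscored with the quality report attached.
#'
#' @param trace A raw [pupil_trace()].
#' @param timeline The protocol [default_timeline()].
#' @param config A [default_config()]-shaped list of pipeline parameters.
#' @return An `rapd_result`, with the `reflex_summary` attached as
#'   `$summary` when scoring was reached.
#' @export
analyze_trace <- function(trace, timeline = default_timeline(),
                          config = default_config()) {
  pp <- config$preprocess
  res <- preprocess_trace(trace,
                          lo_mm = pp$lo_mm, hi_mm = pp$hi_mm,
                          max_gap_samples = pp$max_gap_samples,
                          window_samples = pp$window_samples,
                          published_order = isTRUE(pp$published_order))
  if (!res$quality$pass) {
    out <- list(score_one_tailed = NA_real_, score_two_tailed = NA_real_,
                weaker_eye = NA_character_, efferent_flag = FALSE,
                efferent_reason = NA_character_, quality = res$quality,
                direct_pct = c(left = NA_real_, right = NA_real_),
                reason = paste("quality failure:", res$quality$reason))
    return(structure(out, class = "rapd_result"))
  }
  rf <- config$reflex
  margin <- rf$baseline_margin_s
  if (is.null(margin)) {
    # back the baseline off the pulse onset by the smoothing half-width so
    # the zero-phase filter cannot pull stimulus-locked samples into it
    margin <- ceiling(pp$window_samples / 2) / timeline$sample_rate_hz
  }
  summary <- summarize_reflexes(res$trace, timeline,
                                baseline_window_s = rf$baseline_window_s,
                                response_window_s = rf$response_window_s,
                                baseline_mode = rf$baseline_mode,
                                baseline_margin_s = margin,
                                aggregate = rf$aggregate)
  out <- rapd_score(summary, quality = res$quality,
                    asymmetry_ratio = rf$efferent_ratio)
  out$summary <- summary
  out
}
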