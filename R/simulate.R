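#' Subject-level simulation parameters
#'
#' Bundles the physiological and sensor parameters of one simulated subject.
#' The default maximal constriction fraction (0.38) matches the mean direct
#' constriction of healthy controls at this stimulus intensity; latency and
#' time constants are typical pupillary-light-reflex kinetics. Afferent
#' gains scale both pupils' responses when the corresponding eye is
#' stimulated (an afferent defect); efferent gains scale one pupil's
#' response regardless of stimulation side (an efferent defect).
#'
#' @param baseline_mm Dark-adapted diameter in mm, per eye (recycled from a
#'   scalar). Default 6.
#' @param amplitude_frac Maximal constriction fraction A0 in (0, 1).
#'   Default 0.38.
#' @param latency_s Reflex latency in seconds. Default 0.25.
#' @param tau_constrict_s,tau_redilate_s Constriction and redilation time
#'   constants in seconds. Defaults 0.35 and 1.5.
#' @param afferent_gain,efferent_gain Named per-eye gains in (0, 1],
#'   `c(left = , right = )` (recycled from a scalar). Default 1.
#' @param hippus_amp_mm,hippus_freq_hz Amplitude (mm) and frequency (Hz) of
#'   the bilateral hippus sinusoid. Defaults 0.1 and 0.2.
#' @param noise_sd_mm Gaussian sensor-noise SD in mm. Default 0.05.
#' @param blink_rate_hz,blink_duration_s Poisson rate and duration of
#'   bilateral tracker dropouts. Defaults 0.1 and 0.2.
#' @param artifact_rate_hz Rate of injected extreme-diameter spike
#'   artifacts (0.5 / 9.5 mm single samples) exercising the cutoff filter.
#'   Default 0.
#' @param seed Integer seed making the subject's trace reproducible.
#' @return A `subject_params` list.
#' @export
subject_params <- function(baseline_mm = 6, amplitude_frac = 0.38,
                           latency_s = 0.25, tau_constrict_s = 0.35,
                           tau_redilate_s = 1.5,
                           afferent_gain = 1, efferent_gain = 1,
                           hippus_amp_mm = 0.1, hippus_freq_hz = 0.2,
                           noise_sd_mm = 0.05,
                           blink_rate_hz = 0.1, blink_duration_s = 0.2,
                           artifact_rate_hz = 0, seed = NULL) {
  eyes <- function(x, nm) {
    if (length(x) == 1) x <- c(left = x, right = x)
    if (is.null(names(x))) names(x) <- c("left", "right")
    if (!all(c("left", "right") %in% names(x))) {
      stop("`", nm, "` must be named left/right", call. = FALSE)
    }
    x[c("left", "right")]
  }
  afferent_gain <- eyes(afferent_gain, "afferent_gain")
  efferent_gain <- eyes(efferent_gain, "efferent_gain")
  baseline_mm <- eyes(baseline_mm, "baseline_mm")
  if (any(c(afferent_gain, efferent_gain) <= 0) ||
      any(c(afferent_gain, efferent_gain) > 1)) {
    stop("gains must lie in (0, 1]", call. = FALSE)
  }
  if (amplitude_frac <= 0 || amplitude_frac >= 1) {
    stop("`amplitude_frac` must lie in (0, 1)", call. = FALSE)
  }
  if (tau_constrict_s <= 0 || tau_redilate_s <= 0 || latency_s < 0) {
    stop("kinetic parameters must be positive", call. = FALSE)
  }
  structure(
    list(baseline_mm = baseline_mm, amplitude_frac = amplitude_frac,
         latency_s = latency_s, tau_constrict_s = tau_constrict_s,
         tau_redilate_s = tau_redilate_s,
         afferent_gain = afferent_gain, efferent_gain = efferent_gain,
         hippus_amp_mm = hippus_amp_mm, hippus_freq_hz = hippus_freq_hz,
         noise_sd_mm = noise_sd_mm,
         blink_rate_hz = blink_rate_hz, blink_duration_s = blink_duration_s,
         artifact_rate_hz = artifact_rate_hz, seed = seed),
    class = "subject_params")
}

#' Pupillary light-reflex response kernel
#'
#' Normalized constriction time course to a single light pulse: zero before
#' the latency; a saturating exponential rise with time constant
#' `tau_constrict_s` while the drive lasts (pulse duration plus latency);
#' then exponential decay with `tau_redilate_s` from the value reached at
#' drive end. Continuous everywhere; peak value `1 - exp(-pulse/tau_c)`.
#'
#' @param t Seconds since pulse onset (vectorized; values < 0 give 0).
#' @param pulse_duration_s Light-pulse duration in seconds.
#' @param params A [subject_params()] supplying latency and time constants.
#' @return Constriction as a fraction of the subject's maximum, in \[0, 1).
#' @export
plr_kernel <- function(t, pulse_duration_s, params) {
  lat <- params$latency_s
  tc <- params$tau_constrict_s
  tr <- params$tau_redilate_s
  drive_end <- pulse_duration_s + lat
  k <- numeric(length(t))
  rising <- t >= lat & t <= drive_end
  k[rising] <- 1 - exp(-(t[rising] - lat) / tc)
  decaying <- t > drive_end
  peak <- 1 - exp(-pulse_duration_s / tc)
  k[decaying] <- peak * exp(-(t[decaying] - drive_end) / tr)
  k
}

#' Simulate one subject's binocular pupil trace
#'
#' Each pupil's diameter follows
#' `baseline * (1 - afferent * efferent * A0 * drive(t))`, where the drive
#' at any instant is the largest of the per-pulse reflex kernels then
#' active (the binocular conditioning pulse contributes the larger of the
#' two eyes' afferent gains). A bilateral hippus sinusoid with seeded random
#' phase and independent Gaussian sensor noise are added; blink events
#' (Poisson process) drop both eyes' samples, and optional spike artifacts
#' inject out-of-range diameters.
#'
#' @param params A [subject_params()].
#' @param timeline A [default_timeline()].
#' @return A raw [pupil_trace()] aligned to the timeline.
#' @export
simulate_subject <- function(params, timeline = default_timeline()) {
  stopifnot(inherits(params, "subject_params"),
            inherits(timeline, "protocol_timeline"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- timeline_n_samples(timeline)
  rate <- timeline$sample_rate_hz
  t <- (seq_len(n) - 1) / rate
  pulses <- timeline$epochs[timeline$epochs$type == "light", ]

  trace_eye <- function(eye) {
    drive <- numeric(n)
    for (i in seq_len(nrow(pulses))) {
      p <- pulses[i, ]
      aff <- if (p$eye == "both") max(params$afferent_gain)
             else params$afferent_gain[[p$eye]]
      k <- aff * plr_kernel(t - p$onset_s, p$duration_s, params)
      drive <- pmax(drive, k)
    }
    params$baseline_mm[[eye]] *
      (1 - params$efferent_gain[[eye]] * params$amplitude_frac * drive)
  }
  left <- trace_eye("left")
  right <- trace_eye("right")

  if (params$hippus_amp_mm > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    hippus <- params$hippus_amp_mm *
      sin(2 * pi * params$hippus_freq_hz * t + phase)
    left <- left + hippus
    right <- right + hippus
  }
  if (params$noise_sd_mm > 0) {
    left <- left + stats::rnorm(n, 0, params$noise_sd_mm)
    right <- right + stats::rnorm(n, 0, params$noise_sd_mm)
  }
  if (params$artifact_rate_hz > 0) {
    n_art <- stats::rpois(1, params$artifact_rate_hz * max(t))
    if (n_art > 0) {
      idx <- sample.int(n, min(n_art, n))
      spikes <- sample(c(0.5, 9.5), length(idx), replace = TRUE)
      left[idx] <- spikes
      right[idx] <- spikes
    }
  }
  if (params$blink_rate_hz > 0) {
    n_blink <- stats::rpois(1, params$blink_rate_hz * max(t))
    if (n_blink > 0) {
      starts <- stats::runif(n_blink, 0, max(t))
      for (s in starts) {
        idx <- t >= s & t < s + params$blink_duration_s
        left[idx] <- NA_real_
        right[idx] <- NA_real_
      }
    }
  }
  pupil_trace(left_mm = left, right_mm = right, sample_rate_hz = rate, t = t)
}

#' Simulate a labeled case/control cohort with ground truth
#'
#' Cases have one affected eye (drawn uniformly) whose afferent gain is
#' drawn from a severity band — mild (grades 1-2): gain in
#' `[0.55, 0.85]`; at-least-moderate (grades 3-5): gain in `[0.2, 0.55]` —
#' so the implied true one-tailed score is `1/gain`. Controls carry only
#' physiological asymmetry: an interocular gain ratio uniform in
#' `[1, 1 + control_asymmetry_max]` with the weaker side randomized.
#' Nuisance parameters (baseline diameter, maximal amplitude, latency) are
#' jittered per subject around their defaults. Fully reproducible from the
#' seed.
#'
#' @param n_cases,n_controls Cohort sizes. Defaults 77 and 77.
#' @param grade_mix Named probabilities `c(mild = , moderate = )` for a
#'   case's severity band. Default `c(50, 27) / 77`.
#' @param control_asymmetry_max Maximum physiological interocular gain
#'   asymmetry in controls, as a proportion. Default 0.2.
#' @param seed Integer master seed.
#' @param timeline A [default_timeline()].
#' @param noise Logical: keep the default hippus/noise/blink nuisances
#'   (`TRUE`) or silence them for closed-form checks (`FALSE`).
#' @return A `simulated_cohort` list: `$traces` (named list of raw
#'   [pupil_trace()]s), `$truth` (data frame: `subject_id`, `label`,
#'   `grade`, `affected_eye`, `gain_left`, `gain_right`, `true_score`),
#'   `$params` (per-subject [subject_params()]), `$seed`.
#' @export
simulate_cohort <- function(n_cases = 77, n_controls = 77,
                            grade_mix = c(mild = 50 / 77, moderate = 27 / 77),
                            control_asymmetry_max = 0.2,
                            seed = 1, timeline = default_timeline(),
                            noise = TRUE) {
  if (n_cases < 0 || n_controls < 0) {
    stop("cohort sizes must be non-negative", call. = FALSE)
  }
  grade_mix <- grade_mix / sum(grade_mix)
  set.seed(seed)
  n <- n_cases + n_controls
  label <- c(rep("case", n_cases), rep("control", n_controls))
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)

  bands <- list(mild = c(0.55, 0.85), moderate = c(0.2, 0.55))
  subjects <- lapply(seq_len(n), function(i) {
    if (label[i] == "case") {
      band <- sample(names(bands), 1, prob = grade_mix[names(bands)])
      gain <- stats::runif(1, bands[[band]][1], bands[[band]][2])
      affected <- sample(c("left", "right"), 1)
      grade <- if (band == "mild") sample(1:2, 1) else sample(3:5, 1)
      aff <- c(left = 1, right = 1)
      aff[affected] <- gain
    } else {
      ratio <- stats::runif(1, 1, 1 + control_asymmetry_max)
      affected <- sample(c("left", "right"), 1) # weaker side, physiological
      grade <- 0L
      aff <- c(left = 1, right = 1)
      aff[affected] <- 1 / ratio
    }
    params <- subject_params(
      baseline_mm = stats::runif(1, 5.5, 6.5),
      amplitude_frac = min(max(stats::rnorm(1, 0.38, 0.03), 0.25), 0.5),
      latency_s = stats::runif(1, 0.2, 0.3),
      afferent_gain = aff,
      hippus_amp_mm = if (noise) 0.1 else 0,
      noise_sd_mm = if (noise) 0.05 else 0,
      blink_rate_hz = if (noise) 0.1 else 0,
      seed = subject_seeds[i])
    truth <- data.frame(
      subject_id = sprintf("S%03d", i),
      label = label[i],
      grade = grade,
      affected_eye = if (label[i] == "case") affected else "none",
      gain_left = aff[["left"]],
      gain_right = aff[["right"]],
      true_score = max(aff) / min(aff),
      stringsAsFactors = FALSE)
    list(params = params, truth = truth)
  })

  traces <- lapply(subjects, function(s) simulate_subject(s$params, timeline))
  truth <- do.call(rbind, lapply(subjects, `[[`, "truth"))
  names(traces) <- truth$subject_id
  structure(
    list(traces = traces, truth = truth,
         params = lapply(subjects, `[[`, "params"),
         seed = seed, timeline = timeline),
    class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d cases, %d controls (seed %d)\n",
              sum(x$truth$label == "case"), sum(x$truth$label == "control"),
              x$seed))
  invisible(x)
}

#' Score every trace of a simulated cohort through the analysis pipeline
#'
#' Runs [analyze_trace()] on each trace and joins the resulting one-tailed
#' scores with the cohort's ground-truth labels and grades, yielding the
#' labeled score table consumed by [evaluate_cohort()]. Unscorable subjects
#' (quality failure or efferent flag) carry `NA` scores.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param config Pipeline parameters, see [default_config()].
#' @return A data frame: `subject_id`, `score`, `label`, `grade`,
#'   `true_score`, `weaker_eye`, `quality_pass`, `efferent_flag`, `reason`.
#' @export
analyze_cohort <- function(cohort, config = default_config()) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  rows <- lapply(seq_along(cohort$traces), function(i) {
    res <- analyze_trace(cohort$traces[[i]], cohort$timeline, config)
    data.frame(
      subject_id = cohort$truth$subject_id[i],
      score = res$score_one_tailed,
      label = cohort$truth$label[i],
      grade = cohort$truth$grade[i],
      true_score = cohort$truth$true_score[i],
      weaker_eye = res$weaker_eye,
      quality_pass = is.null(res$quality) || res$quality$pass,
      efferent_flag = res$efferent_flag,
      reason = res$reason,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
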