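# Independent oracles and fixture builders shared across test files.

# Pair-counting AUROC: P(case > control) + 0.5 P(tie), by exhaustive
# enumeration of all case/control pairs.
brute_auroc <- function(score, label) {
  s_case <- score[label == "case"]
  s_ctrl <- score[label == "control"]
  tot <- 0
  for (a in s_case) {
    for (b in s_ctrl) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(s_case) * length(s_ctrl))
}

# Sliding mean restated as an explicit per-sample loop: nominal window of w
# samples placed floor(w/2) back from the current sample, shrunk to the
# largest symmetric window when it would cross an edge.
brute_running_mean <- function(x, w) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- i - floor(w / 2)
    hi <- lo + w - 1
    if (lo < 1 || hi > n) {
      k <- min(i - 1, n - i)
      lo <- i - k
      hi <- i + k
    }
    out[i] <- mean(x[lo:hi])
  }
  out
}

# flat 5 mm binocular trace of n samples at 90 Hz
flat_trace <- function(n = 300, value = 5, rate = 90) {
  pupil_trace(rep(value, n), rep(value, n), sample_rate_hz = rate)
}

# subject parameters with every stochastic nuisance silenced
noiseless_params <- function(...) {
  subject_params(hippus_amp_mm = 0, noise_sd_mm = 0, blink_rate_hz = 0, ...)
}

# reflex_summary with prescribed per-(stimulated, responding) constriction
# percentages, bypassing trace measurement; `grid` is a named list like
# list(left = c(left = 30, right = 30), right = c(left = 30, right = 30)),
# outer = stimulated eye, inner = responding eye.
fake_summary <- function(grid, n_cycles = 3) {
  rows <- list()
  for (stim in names(grid)) {
    for (resp in names(grid[[stim]])) {
      for (cyc in seq_len(n_cycles)) {
        rows[[length(rows) + 1]] <- data.frame(
          stimulated_eye = stim, responding_eye = resp, cycle = cyc,
          baseline_mm = 6, trough_mm = 6 * (1 - grid[[stim]][[resp]] / 100),
          constriction_pct = grid[[stim]][[resp]], dilated = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  meas <- do.call(rbind, rows)
  direct <- do.call(rbind, lapply(c("left", "right"), function(eye) {
    x <- meas$constriction_pct[meas$stimulated_eye == eye &
                                 meas$responding_eye == eye]
    data.frame(eye = eye, mean_pct = mean(x), sd_pct = sd(x), n = length(x))
  }))
  consensual <- do.call(rbind, lapply(c("left", "right"), function(eye) {
    x <- meas$constriction_pct[meas$stimulated_eye != eye &
                                 meas$responding_eye == eye]
    data.frame(eye = eye, mean_pct = mean(x), sd_pct = sd(x), n = length(x))
  }))
  structure(list(measurements = meas, direct = direct,
                 consensual = consensual, n_cycles = n_cycles,
                 aggregate = "mean"),
            class = "reflex_summary")
}

# random labeled score set with both classes guaranteed present
random_labeled_scores <- function(n = 20) {
  n_case <- sample(1:(n - 1), 1)
  data.frame(
    score = round(1 + rexp(n, 2), 2), # rounding forces some ties
    label = sample(c(rep("case", n_case), rep("control", n - n_case))),
    stringsAsFactors = FALSE)
}
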