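test_that("constriction percentage follows the baseline/trough arithmetic", {
  n <- 270 # 3 s at 90 Hz
  t <- (0:(n - 1)) / 90
  d <- rep(6, n)
  d[t >= 1] <- 4 # drop to 4 mm from t = 1 s
  tr <- pupil_trace(d, d, sample_rate_hz = 90)
  m <- measure_epoch(tr, 0, 1, 1, 3, "left", "left", cycle = 1)
  expect_equal(m$baseline_mm, 6)
  expect_equal(m$trough_mm, 4)
  expect_equal(m$constriction_pct, 100 * 2 / 6) # 33.33%

  flat <- flat_trace(270)
  m0 <- measure_epoch(flat, 0, 1, 1, 3, "left", "left")
  expect_equal(m0$constriction_pct, 0)

  d2 <- c(rep(4, 90), rep(6, 180)) # dilates above baseline instead
  dil <- pupil_trace(d2, d2, sample_rate_hz = 90)
  md <- measure_epoch(dil, 0, 1, 1, 3, "left", "left")
  expect_equal(md$constriction_pct, 0) # floored
  expect_true(md$dilated)

  expect_error(measure_epoch(flat, 10, 11, 1, 3, "left", "left"),
               "no samples")
})

test_that("summary has one measurement per pulse and eye, symmetric when eyes match", {
  tl <- default_timeline()
  tr <- simulate_subject(noiseless_params(seed = 1), tl)
  pp <- preprocess_trace(tr)
  s <- summarize_reflexes(pp$trace, tl, baseline_margin_s = 50 / 90)

  expect_equal(nrow(s$measurements), 14) # 7 light epochs x 2 responding eyes
  mono <- s$measurements[s$measurements$stimulated_eye != "both", ]
  expect_equal(nrow(mono), 12) # 6 monocular pulses x 2 eyes
  expect_equal(s$direct$n, c(3, 3)) # n_cycles replicates per eye

  # identical eyes give identical direct (and consensual) means
  expect_equal(s$direct$mean_pct[s$direct$eye == "left"],
               s$direct$mean_pct[s$direct$eye == "right"])
  expect_equal(s$consensual$mean_pct[1], s$consensual$mean_pct[2])
})

test_that("a unilateral afferent deficit halves the direct but not the consensual response", {
  tl <- default_timeline()
  p <- noiseless_params(afferent_gain = c(left = 1, right = 0.5), seed = 2)
  tr <- simulate_subject(p, tl)
  s <- summarize_reflexes(preprocess_trace(tr)$trace, tl,
                          baseline_margin_s = 50 / 90)
  dl <- s$direct$mean_pct[s$direct$eye == "left"]
  dr <- s$direct$mean_pct[s$direct$eye == "right"]
  expect_equal(dr / dl, 0.5, tolerance = 0.02)

  # consensual response of the right pupil during left-eye stimulation is
  # driven by the healthy left afferent: unattenuated
  mono <- s$measurements[s$measurements$stimulated_eye == "left" &
                           s$measurements$responding_eye == "right", ]
  expect_equal(mean(mono$constriction_pct), dl, tolerance = 0.02)
})

test_that("efferent screen separates efferent from afferent asymmetry patterns", {
  sym <- fake_summary(list(left = c(left = 30, right = 30),
                           right = c(left = 30, right = 30)))
  expect_false(as.logical(detect_efferent_defect(sym)))

  # right pupil weak under BOTH stimulation sides: efferent pattern
  eff <- fake_summary(list(left = c(left = 35, right = 10),
                           right = c(left = 35, right = 10)))
  flag <- detect_efferent_defect(eff)
  expect_true(as.logical(flag))
  expect_match(attr(flag, "reason"), "right pupil")

  # both pupils weak when the right eye is stimulated: afferent pattern
  aff <- fake_summary(list(left = c(left = 35, right = 35),
                           right = c(left = 12, right = 12)))
  expect_false(as.logical(detect_efferent_defect(aff)))

  # uniform scaling of all responses leaves the screen unchanged
  scaled <- fake_summary(list(left = c(left = 3.5, right = 1.0),
                              right = c(left = 3.5, right = 1.0)))
  expect_true(as.logical(detect_efferent_defect(scaled)))

  # a non-reactive pupil always raises the flag
  dead <- fake_summary(list(left = c(left = 30, right = 0),
                            right = c(left = 30, right = 0)))
  fd <- detect_efferent_defect(dead)
  expect_true(as.logical(fd))
  expect_match(attr(fd, "reason"), "non-reactive")

  # asymmetry below the threshold ratio does not trip the flag
  mild <- fake_summary(list(left = c(left = 30, right = 25),
                            right = c(left = 30, right = 25)))
  expect_false(as.logical(detect_efferent_defect(mild)))
  expect_true(as.logical(detect_efferent_defect(mild, asymmetry_ratio = 1.1)))
})

test_that("RAPD scores fold the OD/OS ratio about unity", {
  tie <- rapd_score(fake_summary(list(left = c(left = 30, right = 30),
                                      right = c(left = 30, right = 30))))
  expect_equal(tie$score_one_tailed, 1)
  expect_equal(tie$weaker_eye, "none")

  # worked values from representative direct reflexes
  right_weak <- rapd_score(fake_summary(
    list(left = c(left = 26.74, right = 26.74),
         right = c(left = 12.24, right = 12.24))))
  expect_equal(right_weak$score_two_tailed, 12.24 / 26.74, tolerance = 1e-12)
  expect_equal(right_weak$score_one_tailed, 26.74 / 12.24, tolerance = 1e-12)
  expect_equal(round(right_weak$score_one_tailed, 3), 2.185)
  expect_equal(right_weak$weaker_eye, "right")

  left_weak <- rapd_score(fake_summary(
    list(left = c(left = 6.63, right = 6.63),
         right = c(left = 34.43, right = 34.43))))
  expect_equal(round(left_weak$score_one_tailed, 3), 5.193)
  expect_equal(left_weak$weaker_eye, "left")
})

test_that("scores are withheld on efferent flags, quality failures and dead pupils", {
  eff <- rapd_score(fake_summary(list(left = c(left = 35, right = 10),
                                      right = c(left = 35, right = 10))))
  expect_true(eff$efferent_flag)
  expect_true(is.na(eff$score_one_tailed))

  ok_sum <- fake_summary(list(left = c(left = 30, right = 30),
                              right = c(left = 20, right = 20)))
  bad_quality <- structure(
    list(pass = FALSE, longest_gap_samples = c(left = 120, right = 0),
         fraction_missing = c(left = 0.1, right = 0), max_gap_samples = 90,
         reason = "left eye has a 120-sample missing run (limit 90)"),
    class = "quality_report")
  q <- rapd_score(ok_sum, quality = bad_quality)
  expect_true(is.na(q$score_one_tailed))
  expect_match(q$reason, "quality failure")

  dead <- rapd_score(fake_summary(list(left = c(left = 0, right = 0),
                                       right = c(left = 0, right = 0))))
  expect_true(is.na(dead$score_one_tailed))
})

test_that("swapping the eyes flips the weaker eye but preserves the one-tailed score", {
  tl <- default_timeline()
  p <- noiseless_params(afferent_gain = c(left = 1, right = 0.6), seed = 5)
  tr <- simulate_subject(p, tl)
  res <- analyze_trace(tr, tl)

  # relabel the eyes throughout: swap the two pupil traces AND which eye
  # each monocular pulse stimulates (with an afferent defect the two pupil
  # traces are identical, so the stimulus relabelling is what matters)
  swapped <- tr
  swapped$left_mm <- tr$right_mm
  swapped$right_mm <- tr$left_mm
  swapped$validity_left <- tr$validity_right
  swapped$validity_right <- tr$validity_left
  tl_sw <- tl
  tl_sw$epochs$eye <- c(left = "right", right = "left", both = "both",
                        none = "none")[tl$epochs$eye]
  res_sw <- analyze_trace(swapped, tl_sw)

  expect_equal(res_sw$score_one_tailed, res$score_one_tailed, tolerance = 1e-10)
  expect_equal(res$weaker_eye, "right")
  expect_equal(res_sw$weaker_eye, "left")
  expect_equal(res_sw$score_two_tailed, 1 / res$score_two_tailed,
               tolerance = 1e-10)
  # exact identity: one-tailed = max(r, 1/r)
  expect_identical(res$score_one_tailed,
                   max(res$score_two_tailed, 1 / res$score_two_tailed))
})
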