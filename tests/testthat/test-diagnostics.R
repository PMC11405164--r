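test_that("ROC curve and AUROC agree with hand-computed cases", {
  perfect <- data.frame(score = c(2, 3, 1, 1.5),
                        label = c("case", "case", "control", "control"))
  roc <- roc_curve(perfect)
  expect_equal(auroc(roc), 1)
  expect_true(any(roc$fpr == 0 & roc$sensitivity == 1))
  # sorted by threshold descending, from (0,0) to (1,1)
  expect_true(all(diff(roc$threshold) <= 0))
  expect_equal(c(roc$fpr[1], roc$sensitivity[1]), c(0, 0))
  expect_equal(c(roc$fpr[nrow(roc)], roc$sensitivity[nrow(roc)]), c(1, 1))

  chance <- data.frame(score = c(1, 2, 3, 1, 2, 3),
                       label = rep(c("case", "control"), each = 3))
  expect_equal(auroc(roc_curve(chance)), 0.5)

  mixed <- data.frame(score = c(1.2, 1.5, 2.0, 1.0, 1.3, 1.4),
                      label = rep(c("case", "control"), each = 3))
  expect_equal(auroc(roc_curve(mixed)), 7 / 9)

  expect_error(roc_curve(data.frame(score = 1:3,
                                    label = rep("case", 3))),
               "at least one case and one control")
})

test_that("trapezoidal AUROC equals pair counting on random score sets", {
  set.seed(501)
  for (i in 1:50) {
    ls <- random_labeled_scores(sample(6:30, 1))
    expect_equal(auroc(roc_curve(ls)), brute_auroc(ls$score, ls$label),
                 tolerance = 1e-12)
  }
})

test_that("AUROC matches pROC and survives monotone transforms and duplicates", {
  skip_if_not_installed("pROC")
  set.seed(502)
  for (i in 1:5) {
    ls <- random_labeled_scores(40)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = ls$label, predictor = ls$score,
      levels = c("control", "case"), direction = "<", quiet = TRUE)))
    expect_equal(auroc(roc_curve(ls)), ref, tolerance = 1e-12)

    # strictly monotone transform of the scores leaves the AUROC unchanged
    tr <- ls
    tr$score <- exp(2 * tr$score)
    expect_equal(auroc(roc_curve(tr)), auroc(roc_curve(ls)),
                 tolerance = 1e-12)

    # a duplicated record never adds ROC vertices
    dup <- rbind(ls, ls[1, ])
    v1 <- unique(roc_curve(ls)[, c("fpr", "sensitivity")])
    v2 <- unique(roc_curve(dup)[, c("fpr", "sensitivity")])
    expect_equal(nrow(v2), nrow(v1))
  }
})

test_that("Youden cutoff maximizes J with the sensitivity-favouring tie rule", {
  mixed <- data.frame(score = c(1.2, 1.5, 2.0, 1.0, 1.3, 1.4),
                      label = rep(c("case", "control"), each = 3))
  yc <- youden_cutoff(roc_curve(mixed))
  expect_equal(yc$threshold, 1.5)
  expect_equal(yc$sensitivity, 2 / 3)
  expect_equal(yc$specificity, 1)

  perfect <- data.frame(score = c(2, 3, 1, 1.5),
                        label = c("case", "case", "control", "control"))
  yp <- youden_cutoff(roc_curve(perfect))
  expect_equal(yp$J, 1)
  expect_equal(yp$threshold, 2) # smallest threshold achieving J = 1

  flat <- data.frame(score = rep(1.3, 6),
                     label = rep(c("case", "control"), 3))
  expect_equal(youden_cutoff(roc_curve(flat))$J, 0)
})

test_that("classification metrics match closed forms, including degenerate tables", {
  all_right <- classification_metrics(tp = 50, fp = 0, tn = 50, fn = 0)
  expect_equal(all_right$sensitivity, 100)
  expect_equal(all_right$specificity, 100)
  expect_equal(all_right$accuracy, 100)
  expect_equal(all_right$precision, 100)
  expect_equal(all_right$mcc, 1)

  indep <- classification_metrics(tp = 25, fp = 25, tn = 25, fn = 25)
  expect_equal(indep$mcc, 0)

  hand <- classification_metrics(tp = 3, fp = 1, tn = 4, fn = 2)
  expect_equal(hand$mcc, 10 / sqrt(4 * 5 * 5 * 6))
  expect_equal(hand$sensitivity, 100 * 3 / 5)
  expect_equal(hand$specificity, 100 * 4 / 5)
  expect_equal(hand$accuracy, 100 * 7 / 10)
  expect_equal(hand$precision, 100 * 3 / 4)

  # zero denominators resolve to 0 and are flagged
  deg <- classification_metrics(tp = 0, fp = 0, tn = 5, fn = 0)
  expect_equal(deg$sensitivity, 0)
  expect_equal(deg$precision, 0)
  expect_true(all(c("sensitivity", "precision", "mcc") %in% deg$degenerate))

  expect_error(classification_metrics(-1, 0, 1, 0), "non-negative")
})

test_that("MCC is symmetric under a joint swap of labels and predictions", {
  set.seed(503)
  for (i in 1:10) {
    cm <- sample(0:20, 4, replace = TRUE)
    if (sum(cm) == 0) cm[1] <- 1
    a <- classification_metrics(cm[1], cm[2], cm[3], cm[4])
    b <- classification_metrics(cm[3], cm[4], cm[1], cm[2]) # tn<->tp, fn<->fp
    expect_equal(a$mcc, b$mcc)
  }
})

test_that("severity stratification matches case counts with seeded control draws", {
  set.seed(504)
  df <- data.frame(
    subject_id = sprintf("s%03d", 1:154),
    score = 1 + rexp(154, 2),
    label = c(rep("case", 77), rep("control", 77)),
    grade = c(sample(1:2, 50, TRUE), sample(3:5, 27, TRUE), rep(0, 77)))

  st <- stratify_by_grade(df, seed = 9)
  expect_equal(nrow(st$mild), 100) # 50 mild cases + 50 controls
  expect_equal(sum(st$mild$label == "case"), 50)
  expect_equal(nrow(st$moderate), 54) # 27 + 27
  expect_equal(sum(st$moderate$label == "control"), 27)
  expect_identical(stratify_by_grade(df, seed = 9), st) # determinism
  expect_false(identical(stratify_by_grade(df, seed = 10), st))

  few_controls <- df[c(1:77, 78:100), ]
  expect_error(stratify_by_grade(few_controls, seed = 1), "fewer controls")

  all_mild <- df
  all_mild$grade[all_mild$label == "case"] <- 1
  expect_message(st2 <- stratify_by_grade(all_mild, seed = 1), "skipped")
  expect_null(st2$moderate)
})

test_that("low-score reallocation moves half the sub-quantile cases", {
  df <- data.frame(
    score = c(1.1, 1.1, 1.1, 1.1, 2.0, 2.5, 3.0, 4.0, 1.0, 1.1),
    label = c(rep("case", 8), "control", "control"),
    grade = c(rep(1, 8), 0, 0))
  # Q1 of the 8 case scores (type 7) = 1.1: the four tied cases fall at it
  out <- reorganize_low_scores(df, quantile = 0.25, seed = 3)
  expect_equal(attr(out, "n_low"), 4)
  expect_equal(attr(out, "n_moved"), 2)
  expect_equal(nrow(out), nrow(df)) # total subject count preserved
  expect_equal(sum(out$label == "case"), 6)
  expect_true(all(out$grade[out$label == "control"] == 0))
  # only sub-quantile cases ever move
  moved <- which(out$label != df$label)
  expect_true(all(df$score[moved] <= attr(out, "cutoff")))
  expect_identical(reorganize_low_scores(df, quantile = 0.25, seed = 3), out)

  # a single low case: floor(1/2) = 0 records move, input unchanged
  one <- data.frame(score = c(1.0, 5, 6, 7, 1.2),
                    label = c(rep("case", 4), "control"))
  out1 <- reorganize_low_scores(one, seed = 1)
  expect_equal(attr(out1, "n_moved"), 0)
  expect_equal(out1$label, one$label)
})

test_that("cohort evaluation emits the four standard analysis rows", {
  set.seed(505)
  n <- 60
  df <- data.frame(
    score = c(1 + rexp(n / 2, 1), 1 + abs(rnorm(n / 2, 0, 0.08))),
    label = rep(c("case", "control"), each = n / 2),
    grade = c(sample(1:2, 20, TRUE), sample(3:5, 10, TRUE), rep(0, n / 2)))
  ev <- evaluate_cohort(df, seed = 2)
  expect_equal(ev$analysis, c("overall", "mild", "moderate", "reorganized"))
  expect_true(all(ev$auroc >= 0 & ev$auroc <= 1))
  expect_true(all(ev$mcc >= -1 & ev$mcc <= 1))
  expect_identical(evaluate_cohort(df, seed = 2), ev)

  expect_warning(ev1 <- evaluate_cohort(df[, c("score", "label")], seed = 2),
                 "grade")
  expect_equal(ev1$analysis, "overall")
  expect_equal(ev1$auroc, ev$auroc[1])
})
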