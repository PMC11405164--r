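#' ROC curve for labeled RAPD scores
#'
#' Higher scores indicate worse RAPD, so a subject is called positive when
#' `score >= threshold`. Thresholds sweep the distinct observed scores plus
#' infinite sentinels, giving the full polyline from (0, 0) to (1, 1) in
#' (1 - specificity, sensitivity) space.
#'
#' @param scores A data frame with numeric `score` and `label`
#'   (`"case"`/`"control"`) columns, or a numeric vector (then supply
#'   `labels`).
#' @param labels Optional character/factor vector of labels when `scores`
#'   is a numeric vector.
#' @return A `roc_points` data frame, sorted by threshold descending:
#'   `threshold`, `sensitivity`, `specificity`, `fpr` (= 1 - specificity).
#' @export
roc_curve <- function(scores, labels = NULL) {
  ls <- as_labeled_scores(scores, labels)
  s_case <- ls$score[ls$label == "case"]
  s_ctrl <- ls$score[ls$label == "control"]
  if (length(s_case) == 0 || length(s_ctrl) == 0) {
    stop("ROC analysis needs at least one case and one control", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(ls$score), decreasing = TRUE), -Inf)
  sens <- vapply(thr, function(th) mean(s_case >= th), numeric(1))
  spec <- vapply(thr, function(th) mean(s_ctrl < th), numeric(1))
  structure(
    data.frame(threshold = thr, sensitivity = sens, specificity = spec,
               fpr = 1 - spec),
    class = c("roc_points", "data.frame"))
}

# normalize input to a data frame with score/label (and optional grade)
as_labeled_scores <- function(scores, labels = NULL) {
  if (is.numeric(scores)) {
    if (is.null(labels)) stop("supply `labels` with a score vector", call. = FALSE)
    scores <- data.frame(score = scores, label = as.character(labels),
                         stringsAsFactors = FALSE)
  }
  if (!all(c("score", "label") %in% names(scores))) {
    stop("labeled scores need `score` and `label` columns", call. = FALSE)
  }
  if (!all(scores$label %in% c("case", "control"))) {
    stop('labels must be "case" or "control"', call. = FALSE)
  }
  scores
}

#' Area under the ROC curve
#'
#' Trapezoidal area over the (1 - specificity, sensitivity) polyline. This
#' equals the rank-based pair-counting estimator
#' P(case score > control score) + 0.5 P(tie) exactly.
#'
#' @param roc A [roc_curve()] result, or anything [roc_curve()] accepts.
#' @param labels Passed through to [roc_curve()] if needed.
#' @return The AUROC, in \[0, 1\].
#' @export
auroc <- function(roc, labels = NULL) {
  if (!inherits(roc, "roc_points")) roc <- roc_curve(roc, labels)
  o <- order(roc$fpr, roc$sensitivity)
  x <- roc$fpr[o]
  y <- roc$sensitivity[o]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Youden-optimal operating threshold
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over the finite
#' thresholds of the curve. Ties are broken toward the smallest threshold,
#' i.e. toward higher sensitivity, since a missed RAPD is clinically
#' costlier than a false positive (set `tie = "largest"` to prefer
#' specificity).
#'
#' @param roc A [roc_curve()] result.
#' @param tie `"smallest"` (default) or `"largest"` threshold on ties.
#' @return A list: `threshold`, `sensitivity`, `specificity`, `J`.
#' @export
youden_cutoff <- function(roc, tie = c("smallest", "largest")) {
  stopifnot(inherits(roc, "roc_points"))
  tie <- match.arg(tie)
  fin <- roc[is.finite(roc$threshold), ]
  J <- fin$sensitivity + fin$specificity - 1
  best <- which(J == max(J))
  pick <- if (tie == "smallest") best[which.min(fin$threshold[best])]
          else best[which.max(fin$threshold[best])]
  list(threshold = fin$threshold[pick],
       sensitivity = fin$sensitivity[pick],
       specificity = fin$specificity[pick],
       J = J[pick])
}

#' Classification metrics from a 2x2 confusion table
#'
#' Sensitivity, specificity, accuracy and precision are returned as
#' percentages; the Matthews correlation coefficient (MCC) as a correlation
#' in \[-1, 1\]:
#' `mcc = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`.
#' Any metric with a zero denominator is set to 0 by convention and named in
#' `$degenerate`.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts; total must be positive.
#' @return A list: `sensitivity`, `specificity`, `accuracy`, `precision`
#'   (percent), `mcc`, `degenerate` (character vector of zero-denominator
#'   metrics).
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  total <- sum(counts)
  if (total == 0) stop("confusion table is empty", call. = FALSE)
  degenerate <- character(0)
  frac <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      return(0)
    }
    num / den
  }
  sens <- frac(tp, tp + fn, "sensitivity")
  spec <- frac(tn, tn + fp, "specificity")
  prec <- frac(tp, tp + fp, "precision")
  acc <- (tp + tn) / total
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) {
    degenerate <- c(degenerate, "mcc")
    0
  } else {
    (tp * tn - fp * fn) / mcc_den
  }
  list(sensitivity = 100 * sens, specificity = 100 * spec,
       accuracy = 100 * acc, precision = 100 * prec,
       mcc = mcc, degenerate = degenerate)
}

#' Confusion table at a score threshold
#'
#' @param scores,labels As in [roc_curve()].
#' @param threshold Positive call when `score >= threshold`.
#' @return Named counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at <- function(scores, threshold, labels = NULL) {
  ls <- as_labeled_scores(scores, labels)
  pos <- ls$score >= threshold
  case <- ls$label == "case"
  c(tp = sum(pos & case), fp = sum(pos & !case),
    tn = sum(!pos & !case), fn = sum(!pos & case))
}

#' Full diagnostic-accuracy report for a labeled score set
#'
#' Computes the ROC curve and AUROC, picks the Youden-optimal threshold and
#' reports the confusion metrics at that operating point.
#'
#' @param scores,labels As in [roc_curve()].
#' @return A `diagnostic_report` list: `n_case`, `n_control`, `roc`,
#'   `auroc`, `youden_cutoff`, `sensitivity`, `specificity`, `accuracy`,
#'   `precision` (percent), `mcc`.
#' @export
diagnostic_report <- function(scores, labels = NULL) {
  ls <- as_labeled_scores(scores, labels)
  roc <- roc_curve(ls)
  auc <- auroc(roc)
  yc <- youden_cutoff(roc)
  cm <- do.call(classification_metrics,
                as.list(confusion_at(ls, yc$threshold)))
  structure(
    list(n_case = sum(ls$label == "case"),
         n_control = sum(ls$label == "control"),
         roc = roc, auroc = auc, youden_cutoff = yc$threshold,
         sensitivity = cm$sensitivity, specificity = cm$specificity,
         accuracy = cm$accuracy, precision = cm$precision, mcc = cm$mcc),
    class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("Diagnostic report (%d cases, %d controls)\n",
              x$n_case, x$n_control))
  cat(sprintf("  AUROC %.3f; Youden cutoff %.3f\n", x$auroc, x$youden_cutoff))
  cat(sprintf("  sens %.1f%%  spec %.1f%%  acc %.1f%%  prec %.1f%%  MCC %.3f\n",
              x$sensitivity, x$specificity, x$accuracy, x$precision, x$mcc))
  invisible(x)
}

#' Split cases by RAPD severity with matched control subsamples
#'
#' Divides cases into mild (Bell grades 1-2) and at-least-moderate (grades
#' >= 3) strata and pairs each with a seeded uniform random subsample of
#' controls of matching size (without replacement; an error is raised if
#' controls are too few).
#'
#' @param scores A labeled score data frame with a `grade` column (0 for
#'   controls, 1-5 for cases).
#' @param seed Integer seed for the control subsampling.
#' @return A list with `mild` and `moderate` data frames (`NULL`, with a
#'   message, for an empty stratum).
#' @export
stratify_by_grade <- function(scores, seed) {
  if (!"grade" %in% names(scores)) {
    stop("stratification requires a `grade` column", call. = FALSE)
  }
  ls <- as_labeled_scores(scores)
  controls <- ls[ls$label == "control", ]
  set.seed(seed)
  one <- function(sel, name) {
    cases <- ls[ls$label == "case" & sel, ]
    if (nrow(cases) == 0) {
      message("no cases in the ", name, " stratum; evaluation skipped")
      return(NULL)
    }
    if (nrow(cases) > nrow(controls)) {
      stop("fewer controls than ", name,
           " cases; refusing to sample with replacement", call. = FALSE)
    }
    picked <- controls[sample.int(nrow(controls), nrow(cases)), ]
    rbind(cases, picked)
  }
  list(mild = one(ls$grade %in% c(1, 2), "mild"),
       moderate = one(ls$grade >= 3, "moderate"))
}

#' Reallocate sub-quartile case scores to the control group
#'
#' Cases whose physiological interocular asymmetry alone could explain their
#' score are candidates for clinical over-diagnosis. This re-analysis finds
#' the cases scoring at or below the given quantile of the case-score
#' distribution (linear-interpolation quantile, type 7), shuffles them with
#' the seeded generator, and relabels the first half (rounding down) as
#' controls; everything else is unchanged. Total subject count is preserved.
#'
#' @param scores A labeled score data frame.
#' @param quantile Case-score quantile defining "low". Default 0.25.
#' @param seed Integer seed for the shuffle.
#' @return The relabeled data frame, with attributes `cutoff` (the score
#'   quantile), `n_low` and `n_moved`.
#' @export
reorganize_low_scores <- function(scores, quantile = 0.25, seed = 1) {
  ls <- as_labeled_scores(scores)
  if (quantile <= 0 || quantile >= 1) {
    stop("`quantile` must be in (0, 1)", call. = FALSE)
  }
  case_idx <- which(ls$label == "case")
  if (length(case_idx) == 0) stop("no cases present", call. = FALSE)
  cutoff <- stats::quantile(ls$score[case_idx], quantile, type = 7,
                            names = FALSE)
  low <- case_idx[ls$score[case_idx] <= cutoff]
  n_moved <- 0L
  if (length(low) > 0) {
    set.seed(seed)
    shuffled <- low[sample.int(length(low))]
    n_moved <- length(low) %/% 2L
    if (n_moved > 0) {
      moved <- shuffled[seq_len(n_moved)]
      ls$label[moved] <- "control"
      if ("grade" %in% names(ls)) ls$grade[moved] <- 0L
    }
  }
  structure(ls, cutoff = cutoff, n_low = length(low), n_moved = n_moved)
}

#' Four-row diagnostic evaluation of a labeled cohort
#'
#' Reproduces the standard report layout: overall cohort, mild-RAPD stratum,
#' at-least-moderate stratum (each with matched control subsamples), and the
#' low-score-reallocation re-analysis. Strata require a `grade` column;
#' without it only the overall row is produced, with a warning.
#'
#' @param scores A labeled score data frame (`score`, `label`, optionally
#'   `grade`).
#' @param seed Integer seed driving control subsampling and reallocation.
#' @param quantile Reallocation quantile, see [reorganize_low_scores()].
#' @return A data frame with one row per analysis (`analysis`, `n_case`,
#'   `n_control`, `youden_cutoff`, `auroc`, `sensitivity`, `specificity`,
#'   `accuracy`, `precision`, `mcc`).
#' @export
evaluate_cohort <- function(scores, seed = 1, quantile = 0.25) {
  ls <- as_labeled_scores(scores)
  row <- function(name, df) {
    if (is.null(df)) return(NULL)
    r <- diagnostic_report(df)
    data.frame(analysis = name, n_case = r$n_case, n_control = r$n_control,
               youden_cutoff = r$youden_cutoff, auroc = r$auroc,
               sensitivity = r$sensitivity, specificity = r$specificity,
               accuracy = r$accuracy, precision = r$precision, mcc = r$mcc,
               stringsAsFactors = FALSE)
  }
  out <- list(row("overall", ls))
  if ("grade" %in% names(ls)) {
    strata <- stratify_by_grade(ls, seed = seed)
    out <- c(out, list(row("mild", strata$mild),
                       row("moderate", strata$moderate),
                       row("reorganized",
                           reorganize_low_scores(ls, quantile, seed = seed))))
  } else {
    warning("no `grade` column: severity strata and reallocation skipped")
  }
  do.call(rbind, out)
}
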