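#' Construct a binocular pupil-diameter trace
#'
#' A `pupil_trace` holds uniformly sampled left- and right-eye pupil
#' diameters in millimetres, with a per-sample, per-eye validity state
#' (`"valid"`, `"missing"` or `"interpolated"`). `NA` diameters are recorded
#' as missing. Eye naming follows clinical convention: OD = right eye,
#' OS = left eye.
#'
#' @param left_mm,right_mm Numeric vectors of pupil diameters in mm; `NA`
#'   marks a missing sample (e.g. tracker dropout during a blink).
#' @param sample_rate_hz Sampling rate in samples per second.
#' @param t Optional time vector in seconds; defaults to
#'   `(0:(n-1)) / sample_rate_hz`. Must be uniformly spaced at
#'   `1/sample_rate_hz` within `1e-6` s.
#' @param validity_left,validity_right Optional character vectors of validity
#'   states; inferred from `NA`s when omitted.
#'
#' @return A `pupil_trace` object.
#' @export
pupil_trace <- function(left_mm, right_mm, sample_rate_hz, t = NULL,
                        validity_left = NULL, validity_right = NULL) {
  n <- length(left_mm)
  if (length(right_mm) != n) {
    stop("left and right diameter vectors must have equal length",
         call. = FALSE)
  }
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("`sample_rate_hz` must be positive", call. = FALSE)
  }
  if (is.null(t)) {
    t <- (seq_len(n) - 1) / sample_rate_hz
  } else {
    if (length(t) != n) stop("`t` length mismatch", call. = FALSE)
    dt <- diff(t)
    if (n > 1 && any(abs(dt - 1 / sample_rate_hz) > 1e-6)) {
      stop("`t` must be uniformly spaced at 1/sample_rate_hz (tolerance 1e-6 s)",
           call. = FALSE)
    }
  }
  infer <- function(x, v) {
    if (is.null(v)) v <- ifelse(is.na(x), "missing", "valid")
    if (!all(v %in% c("valid", "missing", "interpolated"))) {
      stop("validity states must be valid/missing/interpolated", call. = FALSE)
    }
    v[is.na(x)] <- "missing"
    v
  }
  validity_left <- infer(left_mm, validity_left)
  validity_right <- infer(right_mm, validity_right)
  bad <- function(x, v) any(v != "missing" & (!is.finite(x) | x <= 0))
  if (bad(left_mm, validity_left) || bad(right_mm, validity_right)) {
    stop("non-missing diameters must be finite and positive", call. = FALSE)
  }
  structure(
    list(t = as.numeric(t),
         left_mm = as.numeric(left_mm), right_mm = as.numeric(right_mm),
         validity_left = validity_left, validity_right = validity_right,
         sample_rate_hz = sample_rate_hz),
    class = "pupil_trace"
  )
}

#' @export
print.pupil_trace <- function(x, ...) {
  n <- length(x$t)
  miss <- c(left = mean(x$validity_left == "missing"),
            right = mean(x$validity_right == "missing"))
  cat(sprintf("Binocular pupil trace: %d samples at %.0f Hz (%.1f s)\n",
              n, x$sample_rate_hz, n / x$sample_rate_hz))
  cat(sprintf("  missing: OS %.1f%%, OD %.1f%%; interpolated: OS %.1f%%, OD %.1f%%\n",
              100 * miss["left"], 100 * miss["right"],
              100 * mean(x$validity_left == "interpolated"),
              100 * mean(x$validity_right == "interpolated")))
  invisible(x)
}

#' @export
length.pupil_trace <- function(x) length(x$t)

eye_series <- function(trace, eye) {
  switch(eye,
         left = trace$left_mm, os = trace$left_mm,
         right = trace$right_mm, od = trace$right_mm,
         stop("unknown eye: ", eye, call. = FALSE))
}

eye_validity <- function(trace, eye) {
  switch(eye,
         left = trace$validity_left, os = trace$validity_left,
         right = trace$validity_right, od = trace$validity_right)
}

#' Read a pupil trace from delimited text
#'
#' Expects a comma-separated file with header `time_s,od_mm,os_mm`
#' (OD = right eye, OS = left eye), one row per sample; an empty field is a
#' missing sample. Optional `validity_od,validity_os` columns are honoured.
#' Sampling must be uniform within 1e-6 s.
#'
#' @param path File path.
#' @param sample_rate_hz Optional; inferred from the median time step when
#'   omitted.
#' @return A [pupil_trace()].
#' @export
read_pupil_trace <- function(path, sample_rate_hz = NULL) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse trace file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  need <- c("time_s", "od_mm", "os_mm")
  if (nrow(df) == 0 || !all(need %in% names(df))) {
    stop("trace file '", path,
         "' must have columns time_s,od_mm,os_mm and at least one row",
         call. = FALSE)
  }
  bad_num <- which(!vapply(df[need], is.numeric, logical(1)))
  if (length(bad_num)) {
    for (cn in need[bad_num]) {
      suppressWarnings(df[[cn]] <- as.numeric(df[[cn]]))
    }
  }
  if (is.null(sample_rate_hz)) {
    dt <- stats::median(diff(df$time_s))
    sample_rate_hz <- 1 / dt
  }
  pupil_trace(left_mm = df$os_mm, right_mm = df$od_mm,
              sample_rate_hz = sample_rate_hz, t = df$time_s,
              validity_left = df$validity_os, validity_right = df$validity_od)
}

#' Write a pupil trace as delimited text
#'
#' Emits the dialect read by [read_pupil_trace()]: `time_s,od_mm,os_mm`, one
#' row per sample, missing samples as empty fields; with `validity = TRUE`
#' appends `validity_od,validity_os` columns.
#'
#' @param trace A [pupil_trace()].
#' @param path Output file path.
#' @param validity Whether to include the validity columns. Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_pupil_trace <- function(trace, path, validity = FALSE) {
  stopifnot(inherits(trace, "pupil_trace"))
  df <- data.frame(time_s = trace$t,
                   od_mm = trace$right_mm,
                   os_mm = trace$left_mm)
  if (validity) {
    df$validity_od <- trace$validity_right
    df$validity_os <- trace$validity_left
  }
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
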