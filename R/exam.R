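#' Construct a single microperimetry exam
#'
#' One mesopic microperimetry test of one eye: a threshold sensitivity in
#' dB for every point of a stimulus grid, plus the metadata the analysis
#' needs (subject age for the normative model, the exam's false-positive
#' catch-trial rate for reliability screening, and the cohort label).
#'
#' Thresholds are validated against the device dynamic range of 0--36 dB;
#' out-of-range values are rejected, never clipped, so data problems
#' surface at ingest.
#'
#' @param subject_id Subject identifier string.
#' @param eye `"left"` or `"right"`.
#' @param exam_index Positive integer; 1 is the first of the repeated
#'   same-visit tests.
#' @param age Subject age in years (> 0).
#' @param grid The [mp_grid()] the exam was acquired on.
#' @param thresholds Numeric vector of threshold sensitivities in dB, one
#'   per grid point, in grid point order, each in \[0, 36\].
#' @param false_positive_rate Fraction of false-positive catch-trial
#'   responses, in \[0, 1\].
#' @param cohort `"healthy"` or `"iAMD"`.
#'
#' @return An object of class `mp_exam` (a named list of the fields above).
#' @export
#' @examples
#' g <- grid_study33()
#' mp_exam("S01", "right", 1, age = 67, grid = g,
#'         thresholds = rep(26, n_points(g)), false_positive_rate = 0.05,
#'         cohort = "iAMD")
mp_exam <- function(subject_id, eye, exam_index, age, grid, thresholds,
                    false_positive_rate, cohort = c("healthy", "iAMD")) {
  eye <- match.arg(eye, c("left", "right"))
  cohort <- match.arg(cohort)
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  exam_index <- as.integer(exam_index)
  if (is.na(exam_index) || exam_index < 1L) {
    stop("exam_index must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(age) || length(age) != 1L || !is.finite(age) || age <= 0) {
    stop("age must be a single positive number", call. = FALSE)
  }
  stopifnot(inherits(grid, "mp_grid"))
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != n_points(grid)) {
    stop(sprintf("expected %d thresholds for grid '%s', got %d",
                 n_points(grid), grid$name, length(thresholds)),
         call. = FALSE)
  }
  if (any(!is.finite(thresholds)) ||
      any(thresholds < 0) || any(thresholds > 36)) {
    bad <- which(!is.finite(thresholds) | thresholds < 0 | thresholds > 36)
    stop(sprintf(
      "thresholds outside the 0-36 dB device range at point index(es) %s",
      paste(bad - 1L, collapse = ", ")
    ), call. = FALSE)
  }
  if (!is.numeric(false_positive_rate) || length(false_positive_rate) != 1L ||
      is.na(false_positive_rate) ||
      false_positive_rate < 0 || false_positive_rate > 1) {
    stop("false_positive_rate must be a fraction in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      subject_id = subject_id, eye = eye, exam_index = exam_index,
      age = as.numeric(age), grid = grid, thresholds = thresholds,
      false_positive_rate = as.numeric(false_positive_rate), cohort = cohort
    ),
    class = "mp_exam"
  )
}

#' @export
print.mp_exam <- function(x, ...) {
  cat(sprintf(
    "<mp_exam %s/%s exam %d: %s, age %.1f, grid '%s' (%d pts), mean %.1f dB, FP %.0f%%>\n",
    x$subject_id, x$eye, x$exam_index, x$cohort, x$age, x$grid$name,
    length(x$thresholds), mean(x$thresholds), 100 * x$false_positive_rate
  ))
  invisible(x)
}

#' Screen exams for reliability by false-positive rate
#'
#' Keeps exams whose false-positive catch-trial rate is strictly below
#' `max_fp` (an exam sitting exactly on the limit is excluded), preserving
#' input order. Each exclusion is reported via [message()] so a run log
#' records which tests were dropped.
#'
#' @param exams List of [mp_exam()] objects.
#' @param max_fp Exclusion limit as a fraction in (0, 1\]. The default 0.33
#'   is the conventional reliability limit for microperimetry.
#' @return The retained sublist of `exams`.
#' @export
qc_filter <- function(exams, max_fp = 0.33) {
  stopifnot(is.list(exams),
            is.numeric(max_fp), length(max_fp) == 1L,
            max_fp > 0, max_fp <= 1)
  keep <- vapply(exams, function(e) {
    stopifnot(inherits(e, "mp_exam"))
    e$false_positive_rate < max_fp
  }, logical(1))
  for (e in exams[!keep]) {
    message(sprintf(
      "qc_filter: excluding %s/%s exam %d (false-positive rate %.2f >= %.2f)",
      e$subject_id, e$eye, e$exam_index, e$false_positive_rate, max_fp
    ))
  }
  exams[keep]
}
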