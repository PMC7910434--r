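#' An abnormality criterion for pointwise deviations
#'
#' A point is called abnormal when its deviation from the age-expected
#' normal threshold falls strictly below `-cutoff_db`, where
#' `cutoff_db = z * pointwise_sd`. The conventional choices are
#' `z = 1.65` (the 5% normative tail) and `z = 2` (the 2.5% tail); with
#' the default normative SD of 1.78 dB these give cutoffs of 2.937 and
#' 3.56 dB, conventionally quoted rounded to 2.9 and 3.6 dB.
#'
#' The unrounded cutoff is the default because it preserves the stated
#' tail probabilities exactly: a rounded 2.9 dB cutoff corresponds to a
#' 5.2% tail, slightly more liberal than the nominal "less than 5%".
#' Set `rounded = TRUE` to reproduce the quoted one-decimal cutoffs.
#'
#' @param z Positive number of normative SDs defining the cutoff.
#' @param pointwise_sd Normative pointwise SD in dB; defaults to the
#'   standard 1.78 dB.
#' @param rounded If `TRUE`, round the cutoff to one decimal before use.
#' @return An object of class `abnormality_criterion` with fields `z`,
#'   `cutoff_db`, `rounded`, `pointwise_sd` and a display `label`.
#' @export
#' @examples
#' abnormality_criterion(1.65)                  # cutoff 2.937 dB
#' abnormality_criterion(2, rounded = TRUE)     # cutoff 3.6 dB
abnormality_criterion <- function(z, pointwise_sd = 1.78, rounded = FALSE) {
  stopifnot(is.numeric(z), length(z) == 1L, is.finite(z), z > 0,
            is.numeric(pointwise_sd), pointwise_sd > 0,
            is.logical(rounded), length(rounded) == 1L)
  cutoff <- z * pointwise_sd
  if (rounded) cutoff <- round(cutoff, 1)
  structure(
    list(z = as.numeric(z), cutoff_db = cutoff, rounded = rounded,
         pointwise_sd = as.numeric(pointwise_sd),
         label = sprintf("z%g", z)),
    class = "abnormality_criterion"
  )
}

#' @export
print.abnormality_criterion <- function(x, ...) {
  cat(sprintf(
    "<abnormality_criterion: deviation < -%.3f dB (z = %g, SD %g%s)>\n",
    x$cutoff_db, x$z, x$pointwise_sd, if (x$rounded) ", rounded" else ""
  ))
  invisible(x)
}

#' The two standard abnormality criteria
#'
#' @param pointwise_sd Normative pointwise SD in dB.
#' @param rounded Use one-decimal rounded cutoffs.
#' @return Named list of two [abnormality_criterion()] objects, `z1.65`
#'   (5% tail) and `z2` (2.5% tail).
#' @export
default_criteria <- function(pointwise_sd = 1.78, rounded = FALSE) {
  list(
    z1.65 = abnormality_criterion(1.65, pointwise_sd, rounded),
    z2    = abnormality_criterion(2,    pointwise_sd, rounded)
  )
}

#' Score one exam against the normative model
#'
#' Computes, for every grid point, the calibration-adjusted threshold
#' (`measured + offset`), the age-expected normal threshold, their
#' difference (the deviation), and an abnormality flag per criterion
#' (deviation strictly below `-cutoff_db`).
#'
#' @param exam An [mp_exam()].
#' @param model A [normative_model()].
#' @param offset A [calibration_offset()] (or a bare number in dB);
#'   defaults to no adjustment.
#' @param criteria Non-empty named list of [abnormality_criterion()]
#'   objects; defaults to [default_criteria()].
#' @return A tibble with one row per grid point: exam identifiers
#'   (`subject_id`, `eye`, `exam_index`, `cohort`, `age`), `point_index`,
#'   `x`, `y`, `threshold_db` (as measured), `adjusted_threshold`,
#'   `expected`, `deviation`, and one logical column `abnormal_<label>`
#'   per criterion. The criteria used are attached as attribute
#'   `criteria`.
#' @export
#' @examples
#' g <- grid_study33()
#' ex <- mp_exam("P1", "right", 1, age = 62.2, grid = g,
#'               thresholds = rep(25.9, 33), false_positive_rate = 0.1,
#'               cohort = "iAMD")
#' sc <- score_exam(ex, normative_model(), calibration_offset(2.67))
#' summary(sc$deviation)  # ~ 0: adjusted thresholds match expectation
score_exam <- function(exam, model, offset = calibration_offset(0),
                       criteria = default_criteria(model$pointwise_sd)) {
  stopifnot(inherits(exam, "mp_exam"), inherits(model, "normative_model"))
  if (is.numeric(offset)) offset <- calibration_offset(offset)
  stopifnot(inherits(offset, "calibration_offset"))
  if (!is.list(criteria) || length(criteria) == 0L ||
      !all(vapply(criteria, inherits, logical(1), "abnormality_criterion"))) {
    stop("criteria must be a non-empty list of abnormality_criterion objects",
         call. = FALSE)
  }
  adjusted <- exam$thresholds + offset$offset
  expected <- expected_threshold(model, exam$age)
  deviation <- adjusted - expected
  out <- tibble::tibble(
    subject_id = exam$subject_id,
    eye = exam$eye,
    exam_index = exam$exam_index,
    cohort = exam$cohort,
    age = exam$age,
    point_index = exam$grid$points$point_index,
    x = exam$grid$points$x,
    y = exam$grid$points$y,
    threshold_db = exam$thresholds,
    adjusted_threshold = adjusted,
    expected = expected,
    deviation = deviation
  )
  for (cr in criteria) {
    out[[paste0("abnormal_", cr$label)]] <- deviation < -cr$cutoff_db
  }
  attr(out, "criteria") <- criteria
  out
}

#' Score a list of exams into one long table
#'
#' @inheritParams score_exam
#' @param exams List of [mp_exam()] objects.
#' @return Row-bound [score_exam()] tibbles.
#' @export
score_exams <- function(exams, model, offset = calibration_offset(0),
                        criteria = default_criteria(model$pointwise_sd)) {
  stopifnot(is.list(exams), length(exams) > 0L)
  out <- dplyr::bind_rows(
    lapply(exams, score_exam, model = model, offset = offset,
           criteria = criteria)
  )
  attr(out, "criteria") <- criteria
  out
}
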