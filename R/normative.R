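#' The age-linear normative threshold model
#'
#' The device's internal normative database summarises healthy mesopic
#' sensitivity as a linear function of age that is independent of location
#' within the grid: `expected dB = intercept + slope * age`, with a single
#' pointwise standard deviation valid at all ages and eccentricities. The
#' defaults are the published constants of that database
#' (32.3 dB, -0.06 dB/year, SD 1.78 dB).
#'
#' @param intercept Expected threshold at age 0, dB.
#' @param slope Change in expected threshold per year of age, dB/year.
#' @param pointwise_sd Normative between-subject SD of a single point's
#'   threshold, dB (> 0).
#' @return An object of class `normative_model`.
#' @export
#' @examples
#' m <- normative_model()
#' expected_threshold(m, age = 65)
normative_model <- function(intercept = 32.3, slope = -0.06,
                            pointwise_sd = 1.78) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(slope), length(slope) == 1L,
            is.numeric(pointwise_sd), length(pointwise_sd) == 1L)
  if (!is.finite(pointwise_sd) || pointwise_sd <= 0) {
    stop("pointwise_sd must be a positive number", call. = FALSE)
  }
  structure(
    list(intercept = as.numeric(intercept), slope = as.numeric(slope),
         pointwise_sd = as.numeric(pointwise_sd)),
    class = "normative_model"
  )
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf(
    "<normative_model: expected dB = %g %+g * age, pointwise SD %g dB>\n",
    x$intercept, x$slope, x$pointwise_sd
  ))
  invisible(x)
}

#' Age-expected normal threshold
#'
#' @param model A [normative_model()].
#' @param age Age(s) in years; every value must be positive.
#' @return Expected threshold(s) in dB, vectorised over `age`.
#' @export
expected_threshold <- function(model, age) {
  stopifnot(inherits(model, "normative_model"))
  age <- as.numeric(age)
  if (length(age) == 0L || any(!is.finite(age)) || any(age <= 0)) {
    stop("age must be positive", call. = FALSE)
  }
  model$intercept + model$slope * age
}

#' A device calibration offset
#'
#' A single constant in dB added to every measured threshold before
#' deviation scoring. A positive offset means the device under study reads
#' lower than the normative model predicts, so measured values are shifted
#' up to put them on the normative scale.
#'
#' @param offset Offset in dB.
#' @param n_eyes Number of healthy eyes the offset was estimated from
#'   (`NA` for an externally supplied constant).
#' @param source Free-text provenance note.
#' @return An object of class `calibration_offset`.
#' @seealso [estimate_offset()]
#' @export
calibration_offset <- function(offset, n_eyes = NA_integer_,
                               source = "fixed") {
  stopifnot(is.numeric(offset), length(offset) == 1L, is.finite(offset))
  structure(
    list(offset = as.numeric(offset), n_eyes = as.integer(n_eyes),
         source = as.character(source)),
    class = "calibration_offset"
  )
}

#' @export
print.calibration_offset <- function(x, ...) {
  cat(sprintf("<calibration_offset: %+.3f dB (%s%s)>\n", x$offset, x$source,
              if (is.na(x$n_eyes)) "" else sprintf(", n = %d eyes", x$n_eyes)))
  invisible(x)
}

#' Estimate the device calibration offset from healthy eyes
#'
#' For each healthy eye, the grid-mean measured threshold of each of its
#' exams is averaged into one per-eye mean; the eye's offset is the
#' age-expected normal threshold minus that mean. The cohort offset is the
#' unweighted mean of the per-eye offsets. Because the normative model is
#' linear in age, for balanced designs (equal exam counts per eye) this
#' equals the expected threshold at the cohort mean age minus the grand
#' mean of the grid means.
#'
#' @param model A [normative_model()].
#' @param healthy_exams Non-empty list of [mp_exam()] objects from healthy
#'   eyes. Exams labelled with any other cohort trigger a warning but are
#'   still used (the caller asked for them).
#' @return A [calibration_offset()] with `n_eyes` set to the number of
#'   distinct eyes contributing.
#' @export
#' @examples
#' g <- grid_study33()
#' ex <- mp_exam("C1", "left", 1, age = 62.2, grid = g,
#'               thresholds = rep(25.9, 33), false_positive_rate = 0,
#'               cohort = "healthy")
#' estimate_offset(normative_model(), list(ex))  # 2.668 dB
estimate_offset <- function(model, healthy_exams) {
  stopifnot(inherits(model, "normative_model"), is.list(healthy_exams))
  if (length(healthy_exams) == 0L) {
    stop("estimate_offset needs at least one healthy exam", call. = FALSE)
  }
  lab <- vapply(healthy_exams, function(e) e$cohort, character(1))
  if (any(lab != "healthy")) {
    warning(sprintf("%d exam(s) not labelled 'healthy' included in offset estimation",
                    sum(lab != "healthy")), call. = FALSE)
  }
  tab <- tibble::tibble(
    subject_id = vapply(healthy_exams, function(e) e$subject_id, character(1)),
    eye = vapply(healthy_exams, function(e) e$eye, character(1)),
    age = vapply(healthy_exams, function(e) e$age, numeric(1)),
    grid_mean = vapply(healthy_exams, function(e) mean(e$thresholds), numeric(1))
  )
  per_eye <- dplyr::summarise(
    dplyr::group_by(tab, .data$subject_id, .data$eye),
    age = mean(.data$age),
    eye_mean = mean(.data$grid_mean),
    .groups = "drop"
  )
  offsets <- expected_threshold(model, per_eye$age) - per_eye$eye_mean
  calibration_offset(mean(offsets), n_eyes = nrow(per_eye),
                     source = "estimated from healthy cohort")
}
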