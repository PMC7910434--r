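#' Per-eye, per-exam endpoint summary
#'
#' Reduces the pointwise scores of one exam to the outcome quantities a
#' trial would use: the abnormal-point count under the given criterion,
#' the mean (calibration-adjusted) threshold and mean deviation over the
#' whole grid and over abnormal points only, and the within-grid SD of
#' thresholds. Abnormal-restricted means are undefined — returned as `NA`
#' with `has_abnormal = FALSE` — when the exam has no abnormal point;
#' such eyes are excluded from abnormal-restricted cohort aggregates, not
#' zero-filled.
#'
#' @param scores A [score_exam()] tibble for a single exam (a full grid).
#' @param criterion An [abnormality_criterion()]. Abnormality is
#'   recomputed from the stored deviations, so the criterion need not be
#'   one of those used at scoring time.
#' @return A one-row tibble with columns `subject_id`, `eye`,
#'   `exam_index`, `cohort`, `z`, `cutoff_db`, `n_points`, `n_abnormal`,
#'   `frac_abnormal`, `mean_threshold_all`, `mean_threshold_abnormal`,
#'   `mean_deviation_all`, `mean_deviation_abnormal`, `within_grid_sd`
#'   (sample SD, n-1), `has_abnormal`.
#' @export
summarize_eye <- function(scores, criterion) {
  stopifnot(is.data.frame(scores), inherits(criterion, "abnormality_criterion"))
  if (nrow(scores) == 0L) {
    stop("summarize_eye: empty score table", call. = FALSE)
  }
  key <- unique(scores[, c("subject_id", "eye", "exam_index")])
  if (nrow(key) != 1L) {
    stop("summarize_eye expects the scores of exactly one exam", call. = FALSE)
  }
  abn <- scores$deviation < -criterion$cutoff_db
  k <- sum(abn)
  tibble::tibble(
    subject_id = key$subject_id,
    eye = key$eye,
    exam_index = key$exam_index,
    cohort = scores$cohort[1],
    z = criterion$z,
    cutoff_db = criterion$cutoff_db,
    n_points = nrow(scores),
    n_abnormal = k,
    frac_abnormal = k / nrow(scores),
    mean_threshold_all = mean(scores$adjusted_threshold),
    mean_threshold_abnormal = if (k > 0) mean(scores$adjusted_threshold[abn]) else NA_real_,
    mean_deviation_all = mean(scores$deviation),
    mean_deviation_abnormal = if (k > 0) mean(scores$deviation[abn]) else NA_real_,
    within_grid_sd = stats::sd(scores$adjusted_threshold),
    has_abnormal = k > 0
  )
}

#' Summarise every exam in a long score table
#'
#' Applies [summarize_eye()] to each (subject, eye, exam) group for each
#' criterion.
#'
#' @param scores A [score_exams()] tibble covering one or more exams.
#' @param criteria Named list of [abnormality_criterion()] objects;
#'   defaults to the criteria attached to `scores`, else
#'   [default_criteria()].
#' @return Row-bound [summarize_eye()] tibbles, one row per exam per
#'   criterion.
#' @export
summarize_eyes <- function(scores, criteria = NULL) {
  stopifnot(is.data.frame(scores), nrow(scores) > 0L)
  if (is.null(criteria)) criteria <- attr(scores, "criteria")
  if (is.null(criteria)) criteria <- default_criteria()
  groups <- split(
    scores,
    interaction(scores$subject_id, scores$eye, scores$exam_index, drop = TRUE)
  )
  dplyr::bind_rows(lapply(criteria, function(cr) {
    dplyr::bind_rows(lapply(groups, summarize_eye, criterion = cr))
  }))
}

#' Trial eligibility of one eye
#'
#' An eye qualifies for a trial requiring at least `min_abnormal` abnormal
#' points when every supplied exam (default) — or any exam, with
#' `require_all_exams = FALSE` — reaches that count.
#'
#' @param outcomes [summarize_eye()] rows for the exams of one eye under
#'   one criterion (at least one row).
#' @param min_abnormal Minimum abnormal-point count, >= 1; default 5.
#' @param require_all_exams If `TRUE` (default), every exam must qualify.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' oc <- tibble::tibble(n_abnormal = c(6, 3))
#' check_eligibility(oc, 5)                          # FALSE
#' check_eligibility(oc, 5, require_all_exams = FALSE)  # TRUE
check_eligibility <- function(outcomes, min_abnormal = 5,
                              require_all_exams = TRUE) {
  stopifnot(is.data.frame(outcomes), is.numeric(min_abnormal),
            length(min_abnormal) == 1L, min_abnormal >= 1)
  if (nrow(outcomes) == 0L) {
    stop("check_eligibility: no exam outcomes supplied", call. = FALSE)
  }
  ok <- outcomes$n_abnormal >= min_abnormal
  if (require_all_exams) all(ok) else any(ok)
}

#' Cohort-level endpoint summary and eligibility screen
#'
#' Aggregates per-exam eye outcomes into the descriptive statistics a
#' study report tabulates, per criterion and exam: mean, sample SD and
#' range of the abnormal-point count; the percentage of abnormal points
#' both pooled (total abnormal / total tested) and as the mean of per-eye
#' fractions (the two conventions differ whenever counts vary across
#' eyes, so both are reported); mean and SD of the abnormal-restricted
#' mean threshold and mean deviation over the eyes that have at least one
#' abnormal point (eyes without any are counted in `n_no_abnormal` and
#' excluded from these two aggregates only); and mean and SD of the
#' whole-grid mean deviation. Eligibility at `min_abnormal` abnormal
#' points is tallied per exam and under the stricter rule requiring every
#' exam of an eye to qualify.
#'
#' @param outcomes A [summarize_eyes()] tibble (one row per exam per
#'   criterion, any number of eyes).
#' @param min_abnormal Minimum abnormal-point count for eligibility.
#' @return An object of class `cohort_summary`: a list with tibbles
#'   `by_exam` and `eligibility` plus the `min_abnormal` used. In
#'   `eligibility`, `rule` is either `"exam<k>"` (qualify in that exam)
#'   or `"all_exams"`, and `pct_excluded = 100 * (1 - n_eligible /
#'   n_eyes)`.
#' @export
summarize_cohort <- function(outcomes, min_abnormal = 5) {
  stopifnot(is.data.frame(outcomes), nrow(outcomes) > 0L)
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else NA_real_
  by_exam <- dplyr::summarise(
    dplyr::group_by(outcomes, .data$z, .data$exam_index),
    n_eyes = dplyr::n(),
    n_abnormal_mean = mean(.data$n_abnormal),
    n_abnormal_sd = sd0(.data$n_abnormal),
    n_abnormal_min = min(.data$n_abnormal),
    n_abnormal_max = max(.data$n_abnormal),
    pct_abnormal_pooled = 100 * sum(.data$n_abnormal) / sum(.data$n_points),
    pct_abnormal_mean_frac = 100 * mean(.data$frac_abnormal),
    n_no_abnormal = sum(!.data$has_abnormal),
    mean_threshold_abnormal_mean = mean(.data$mean_threshold_abnormal[.data$has_abnormal]),
    mean_threshold_abnormal_sd = sd0(.data$mean_threshold_abnormal[.data$has_abnormal]),
    mean_deviation_abnormal_mean = mean(.data$mean_deviation_abnormal[.data$has_abnormal]),
    mean_deviation_abnormal_sd = sd0(.data$mean_deviation_abnormal[.data$has_abnormal]),
    mean_deviation_all_mean = mean(.data$mean_deviation_all),
    mean_deviation_all_sd = sd0(.data$mean_deviation_all),
    n_eligible = sum(.data$n_abnormal >= min_abnormal),
    pct_eligible = 100 * mean(.data$n_abnormal >= min_abnormal),
    .groups = "drop"
  )

  elig_exam <- dplyr::mutate(
    by_exam[, c("z", "exam_index", "n_eyes", "n_eligible", "pct_eligible")],
    rule = sprintf("exam%d", .data$exam_index)
  )
  per_eye <- dplyr::summarise(
    dplyr::group_by(outcomes, .data$z, .data$subject_id, .data$eye),
    eligible_all = all(.data$n_abnormal >= min_abnormal),
    .groups = "drop"
  )
  elig_all <- dplyr::summarise(
    dplyr::group_by(per_eye, .data$z),
    n_eyes = dplyr::n(),
    n_eligible = sum(.data$eligible_all),
    pct_eligible = 100 * mean(.data$eligible_all),
    rule = "all_exams",
    .groups = "drop"
  )
  eligibility <- dplyr::bind_rows(
    elig_exam[, c("z", "rule", "n_eyes", "n_eligible", "pct_eligible")],
    elig_all[, c("z", "rule", "n_eyes", "n_eligible", "pct_eligible")]
  )
  eligibility$pct_excluded <- 100 - eligibility$pct_eligible

  structure(
    list(by_exam = by_exam, eligibility = eligibility,
         min_abnormal = min_abnormal),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary: eligibility at >= %d abnormal points>\n",
              x$min_abnormal))
  cat("\n$by_exam\n"); print(x$by_exam, ...)
  cat("\n$eligibility\n"); print(x$eligibility, ...)
  invisible(x)
}
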