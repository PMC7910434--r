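#' Bland-Altman agreement between two paired measurements
#'
#' Computes the mean paired difference (first minus second), its sample
#' SD, and the 95% limits of agreement `mean_diff +/- 1.96 * sd_diff`.
#' Two scalar widths are reported because published "limits of agreement
#' = x dB" statements are ambiguous: `span` is the distance between the
#' two limits (`2 * 1.96 * sd_diff`) and `half_width` its half
#' (`1.96 * sd_diff`).
#'
#' @param x,y Numeric vectors of equal length >= 2: the first and second
#'   measurement of each unit. Pairs with a missing member are dropped.
#' @return An object of class `bland_altman`: list with `n`, `mean_diff`,
#'   `sd_diff`, `loa_lower`, `loa_upper`, `span`, `half_width`, and the
#'   per-pair `mean` and `diff` vectors (for plotting).
#' @seealso [plot_bland_altman()]
#' @export
#' @examples
#' ba <- bland_altman(c(26, 24, 25), c(25.5, 24.5, 24))
#' ba$span
bland_altman <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("bland_altman: x and y must have equal length", call. = FALSE)
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) {
    stop("bland_altman needs at least 2 complete pairs", call. = FALSE)
  }
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  structure(
    list(
      n = length(d), mean_diff = m, sd_diff = s,
      loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
      span = 2 * 1.96 * s, half_width = 1.96 * s,
      mean = (x + y) / 2, diff = d
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman: n = %d, mean diff %+.2f dB, 95%% LoA [%.2f, %.2f], span %.2f dB>\n",
    x$n, x$mean_diff, x$loa_lower, x$loa_upper, x$span
  ))
  invisible(x)
}

#' Pair eye-level outcomes across two repeated exams
#'
#' Joins per-exam eye outcomes (one criterion at a time) into one row per
#' eye with `value_1` and `value_2`, the chosen outcome in the first and
#' second exam. With `min_abnormal` set, only eyes reaching that
#' abnormal-point count in both exams are kept, mirroring the eligibility
#' screen applied before repeatability analyses of abnormal-restricted
#' outcomes (whose value is undefined for eyes without abnormal points).
#'
#' @param outcomes A [summarize_eyes()] tibble containing a single `z`
#'   (filter first if scoring used several criteria).
#' @param value Name of the outcome column to pair, e.g.
#'   `"mean_threshold_all"` or `"mean_threshold_abnormal"`.
#' @param exams Length-2 integer vector of exam indices; default `c(1, 2)`.
#' @param min_abnormal Optional minimum abnormal-point count required in
#'   both exams.
#' @return Tibble with `subject_id`, `eye`, `value_1`, `value_2`.
#' @export
paired_eye_outcomes <- function(outcomes, value, exams = c(1L, 2L),
                                min_abnormal = NULL) {
  stopifnot(is.data.frame(outcomes), value %in% names(outcomes),
            length(exams) == 2L)
  if (length(unique(outcomes$z)) != 1L) {
    stop("paired_eye_outcomes: filter the outcomes to a single criterion (z) first",
         call. = FALSE)
  }
  o1 <- outcomes[outcomes$exam_index == exams[1], ]
  o2 <- outcomes[outcomes$exam_index == exams[2], ]
  p <- dplyr::inner_join(
    tibble::tibble(subject_id = o1$subject_id, eye = o1$eye,
                   value_1 = o1[[value]], n_abnormal_1 = o1$n_abnormal),
    tibble::tibble(subject_id = o2$subject_id, eye = o2$eye,
                   value_2 = o2[[value]], n_abnormal_2 = o2$n_abnormal),
    by = c("subject_id", "eye")
  )
  if (!is.null(min_abnormal)) {
    p <- p[p$n_abnormal_1 >= min_abnormal & p$n_abnormal_2 >= min_abnormal, ]
  }
  p[, c("subject_id", "eye", "value_1", "value_2")]
}

#' Pair pointwise thresholds across two repeated exams
#'
#' One row per (eye, grid point) with the calibration-adjusted threshold
#' in each exam, for pointwise repeatability analyses.
#'
#' @param scores A [score_exams()] tibble.
#' @param exams Length-2 integer vector of exam indices; default `c(1, 2)`.
#' @param value Score column to pair; default `"adjusted_threshold"`.
#' @return Tibble with `subject_id`, `eye`, `point_index`, `value_1`,
#'   `value_2`.
#' @export
paired_points <- function(scores, exams = c(1L, 2L),
                          value = "adjusted_threshold") {
  stopifnot(is.data.frame(scores), value %in% names(scores),
            length(exams) == 2L)
  s1 <- scores[scores$exam_index == exams[1], ]
  s2 <- scores[scores$exam_index == exams[2], ]
  dplyr::inner_join(
    tibble::tibble(subject_id = s1$subject_id, eye = s1$eye,
                   point_index = s1$point_index, value_1 = s1[[value]]),
    tibble::tibble(subject_id = s2$subject_id, eye = s2$eye,
                   point_index = s2$point_index, value_2 = s2[[value]]),
    by = c("subject_id", "eye", "point_index")
  )
}

#' Cohen's d effect size between two groups
#'
#' `d = (mean(a) - mean(b)) / s_pooled` with sample SDs. The default
#' pooling is the equal-weight form `sqrt((sd_a^2 + sd_b^2) / 2)` used by
#' common online effect-size calculators; `pooling = "weighted"` uses the
#' df-weighted pooled SD. The sign is preserved: a more depressed group
#' `a` gives negative `d`.
#'
#' @param a,b Numeric vectors, each with at least 2 finite values.
#' @param pooling `"equal"` (default) or `"weighted"`.
#' @return The signed effect size (a plain number).
#' @export
#' @examples
#' cohens_d(c(0, 2), c(4, 6))  # -2.828
cohens_d <- function(a, b, pooling = c("equal", "weighted")) {
  pooling <- match.arg(pooling)
  a <- as.numeric(a); b <- as.numeric(b)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("cohens_d needs at least 2 values per group", call. = FALSE)
  }
  va <- stats::var(a); vb <- stats::var(b)
  s <- switch(pooling,
    equal = sqrt((va + vb) / 2),
    weighted = sqrt(((length(a) - 1) * va + (length(b) - 1) * vb) /
                      (length(a) + length(b) - 2))
  )
  if (s == 0) {
    stop("cohens_d: pooled SD is zero", call. = FALSE)
  }
  (mean(a) - mean(b)) / s
}

#' Bland-Altman scatter plot
#'
#' Mean-versus-difference scatter with the mean difference (solid line)
#' and the 95% limits of agreement (dashed lines). Requires ggplot2.
#'
#' @param ba A [bland_altman()] result.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba, title = NULL) {
  stopifnot(inherits(ba, "bland_altman"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_bland_altman requires the ggplot2 package", call. = FALSE)
  }
  df <- tibble::tibble(mean = ba$mean, diff = ba$diff)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$mean_diff, linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(
      x = "Mean of the two tests (dB)",
      y = "Difference, first - second test (dB)",
      title = title,
      subtitle = sprintf("mean diff %+.2f dB, 95%% LoA [%.2f, %.2f]",
                         ba$mean_diff, ba$loa_lower, ba$loa_upper)
    ) +
    ggplot2::theme_minimal()
}
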