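# Fixture builders and independent naive oracles used across tests.
# The oracles deliberately use direct loops / two-pass formulas so they
# share no code path with the package implementation they check.

std_grid <- grid_study33()

# Build an exam whose scored deviations (at the given offset) equal
# `deviations` exactly.
make_exam_dev <- function(deviations, age = 62.2, offset = 0,
                          model = normative_model(), subject_id = "S1",
                          eye = "right", exam_index = 1, cohort = "iAMD",
                          fp = 0.1) {
  thr <- expected_threshold(model, age) + deviations - offset
  mp_exam(subject_id, eye, exam_index, age, std_grid, thr, fp,
          cohort = cohort)
}

# A healthy exam with a constant threshold surface.
make_healthy_exam <- function(age, grid_mean, subject_id = "C1",
                              eye = "left", exam_index = 1) {
  mp_exam(subject_id, eye, exam_index, age, std_grid,
          rep(grid_mean, n_points(std_grid)), 0.05, cohort = "healthy")
}

random_exam <- function(subject_id = "R1", exam_index = 1, cohort = "iAMD") {
  dev <- pmax(pmin(stats::rnorm(33, -2, 3), 6), -20)
  make_exam_dev(dev, age = stats::runif(1, 50, 85),
                subject_id = subject_id, exam_index = exam_index,
                cohort = cohort)
}

naive_eye_summary <- function(scores, cutoff) {
  n <- 0L; k <- 0L
  s_thr <- 0; s_dev <- 0; s_thr_ab <- 0; s_dev_ab <- 0
  for (i in seq_len(nrow(scores))) {
    n <- n + 1L
    s_thr <- s_thr + scores$adjusted_threshold[i]
    s_dev <- s_dev + scores$deviation[i]
    if (scores$deviation[i] < -cutoff) {
      k <- k + 1L
      s_thr_ab <- s_thr_ab + scores$adjusted_threshold[i]
      s_dev_ab <- s_dev_ab + scores$deviation[i]
    }
  }
  ss <- 0
  m <- s_thr / n
  for (i in seq_len(nrow(scores))) {
    ss <- ss + (scores$adjusted_threshold[i] - m)^2
  }
  list(
    n_points = n, n_abnormal = k,
    mean_threshold_all = m,
    mean_deviation_all = s_dev / n,
    mean_threshold_abnormal = if (k > 0) s_thr_ab / k else NA_real_,
    mean_deviation_abnormal = if (k > 0) s_dev_ab / k else NA_real_,
    within_grid_sd = sqrt(ss / (n - 1))
  )
}

naive_bland_altman <- function(x, y) {
  d <- numeric(0)
  for (i in seq_along(x)) d <- c(d, x[i] - y[i])
  m <- sum(d) / length(d)
  ss <- 0
  for (di in d) ss <- ss + (di - m)^2
  s <- sqrt(ss / (length(d) - 1))
  list(mean_diff = m, sd_diff = s,
       loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
       span = 2 * 1.96 * s)
}
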