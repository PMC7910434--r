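m <- normative_model()
c165 <- abnormality_criterion(1.65)
c200 <- abnormality_criterion(2)

test_that("eye summaries handle constant and mixed grids", {
  # all 33 points depressed by exactly 5 dB
  oc <- summarize_eye(score_exam(make_exam_dev(rep(-5, 33)), m), c165)
  expect_equal(oc$n_abnormal, 33)
  expect_equal(oc$frac_abnormal, 1)
  expect_equal(oc$mean_deviation_abnormal, -5)
  expect_equal(oc$mean_deviation_all, -5)
  expect_equal(oc$within_grid_sd, 0)
  expect_true(oc$has_abnormal)

  # 10 points at -4 dB, 23 at 0
  oc2 <- summarize_eye(
    score_exam(make_exam_dev(c(rep(-4, 10), rep(0, 23))), m), c165)
  expect_equal(oc2$n_abnormal, 10)
  expect_equal(oc2$mean_deviation_abnormal, -4)
  expect_equal(oc2$mean_deviation_all, -40 / 33, tolerance = 1e-12)
  # the same 10 points are below the stricter cutoff too
  expect_equal(summarize_eye(
    score_exam(make_exam_dev(c(rep(-4, 10), rep(0, 23))), m), c200
  )$n_abnormal, 10)
})

test_that("an eye with no abnormal points has undefined restricted means", {
  oc <- summarize_eye(score_exam(make_exam_dev(rep(-1, 33)), m), c165)
  expect_equal(oc$n_abnormal, 0)
  expect_false(oc$has_abnormal)
  expect_true(is.na(oc$mean_threshold_abnormal))
  expect_true(is.na(oc$mean_deviation_abnormal))
  # whole-grid fields are still defined
  expect_equal(oc$mean_deviation_all, -1)
})

test_that("eye summaries refuse empty or mixed-exam inputs", {
  sc <- score_exam(make_exam_dev(rep(0, 33)), m)
  expect_error(summarize_eye(sc[0, ], c165), "empty")
  sc2 <- score_exam(make_exam_dev(rep(0, 33), exam_index = 2), m)
  expect_error(summarize_eye(rbind(sc, sc2), c165), "one exam")
})

test_that("eligibility follows the minimum-count rule across exams", {
  oc <- function(k) tibble::tibble(n_abnormal = k)
  expect_true(check_eligibility(oc(c(5, 5)), 5))
  expect_false(check_eligibility(oc(c(0, 0)), 5))
  expect_false(check_eligibility(oc(c(0, 0)), 5, require_all_exams = FALSE))
  expect_false(check_eligibility(oc(c(6, 3)), 5))
  expect_true(check_eligibility(oc(c(6, 3)), 5, require_all_exams = FALSE))
  expect_error(check_eligibility(oc(integer(0)), 5), "no exam")
  expect_error(check_eligibility(oc(5), 0))
})

test_that("cohort aggregation excludes zero-abnormal eyes from restricted means only", {
  ks <- c(0, 2, 6, 12)
  scores <- dplyr::bind_rows(lapply(seq_along(ks), function(i) {
    score_exam(make_exam_dev(c(rep(-4, ks[i]), rep(0, 33 - ks[i])),
                             subject_id = sprintf("S%d", i)), m)
  }))
  cs <- summarize_cohort(summarize_eyes(scores, list(z1.65 = c165)),
                         min_abnormal = 5)
  be <- cs$by_exam
  expect_equal(be$n_eyes, 4)
  expect_equal(be$n_abnormal_mean, 5)
  expect_equal(be$n_abnormal_sd, sd(ks))
  expect_equal(be$n_abnormal_min, 0)
  expect_equal(be$n_abnormal_max, 12)
  expect_equal(be$n_no_abnormal, 1)
  # restricted aggregates over the 3 eyes that have abnormal points
  expect_equal(be$mean_deviation_abnormal_mean, -4)
  expect_equal(be$mean_deviation_abnormal_sd, 0)
  # all eyes count in the whole-grid aggregate and the denominator
  expect_equal(be$mean_deviation_all_mean, mean(-4 * ks / 33))
  expect_equal(be$n_eligible, 2)
  expect_equal(be$pct_eligible, 50)
  # both percent-abnormal conventions
  expect_equal(be$pct_abnormal_pooled, 100 * sum(ks) / (4 * 33))
  expect_equal(be$pct_abnormal_mean_frac, 100 * mean(ks / 33))
})

test_that("a cohort of identical eyes collapses to zero spread", {
  scores <- dplyr::bind_rows(lapply(1:3, function(i) {
    score_exam(make_exam_dev(c(rep(-5, 8), rep(0, 25)),
                             subject_id = sprintf("T%d", i)), m)
  }))
  be <- summarize_cohort(summarize_eyes(scores, list(z1.65 = c165)))$by_exam
  expect_equal(be$n_abnormal_sd, 0)
  expect_equal(be$n_abnormal_min, be$n_abnormal_max)
  expect_equal(be$mean_deviation_abnormal_sd, 0)
})

test_that("the both-exams eligibility rule is stricter than per-exam", {
  # eye A qualifies in both exams, eye B only in exam 1
  mk <- function(id, k1, k2) {
    dplyr::bind_rows(
      score_exam(make_exam_dev(c(rep(-5, k1), rep(0, 33 - k1)),
                               subject_id = id, exam_index = 1), m),
      score_exam(make_exam_dev(c(rep(-5, k2), rep(0, 33 - k2)),
                               subject_id = id, exam_index = 2), m)
    )
  }
  scores <- dplyr::bind_rows(mk("A", 7, 9), mk("B", 6, 2))
  el <- summarize_cohort(summarize_eyes(scores, list(z1.65 = c165)))$eligibility
  expect_equal(el$n_eligible[el$rule == "exam1"], 2)
  expect_equal(el$n_eligible[el$rule == "exam2"], 1)
  expect_equal(el$n_eligible[el$rule == "all_exams"], 1)
  expect_equal(el$pct_excluded[el$rule == "all_exams"], 50)
})
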