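m <- normative_model()

test_that("eye and cohort summaries agree with a naive re-computation", {
  set.seed(1001)
  criteria <- default_criteria()
  all_oc <- list()
  for (i in 1:100) {
    sc <- score_exam(random_exam(subject_id = sprintf("R%03d", i)), m)
    for (cr in criteria) {
      oc <- summarize_eye(sc, cr)
      ref <- naive_eye_summary(sc, cr$cutoff_db)
      expect_equal(oc$n_abnormal, ref$n_abnormal)
      expect_equal(oc$mean_threshold_all, ref$mean_threshold_all)
      expect_equal(oc$mean_deviation_all, ref$mean_deviation_all)
      expect_equal(oc$mean_threshold_abnormal, ref$mean_threshold_abnormal)
      expect_equal(oc$mean_deviation_abnormal, ref$mean_deviation_abnormal)
      expect_equal(oc$within_grid_sd, ref$within_grid_sd)
      all_oc[[length(all_oc) + 1L]] <- oc
    }
  }
  oc_tab <- dplyr::bind_rows(all_oc)
  cs <- summarize_cohort(oc_tab, min_abnormal = 5)
  # naive cohort aggregation, per criterion
  for (zv in unique(oc_tab$z)) {
    sub <- oc_tab[oc_tab$z == zv, ]
    row <- cs$by_exam[cs$by_exam$z == zv, ]
    expect_equal(row$n_abnormal_mean, sum(sub$n_abnormal) / nrow(sub))
    expect_equal(row$mean_deviation_abnormal_mean,
                 mean(sub$mean_deviation_abnormal[sub$n_abnormal > 0]))
    expect_equal(row$n_no_abnormal, sum(sub$n_abnormal == 0))
    expect_equal(row$n_eligible, sum(sub$n_abnormal >= 5))
  }
})

test_that("abnormal counts are monotone in z and in the offset", {
  set.seed(1002)
  zs <- c(1, 1.65, 2, 2.5)
  offsets <- c(-1, 0, 1, 2.67)
  for (i in 1:25) {
    ex <- random_exam()
    counts_z <- vapply(zs, function(z) {
      summarize_eye(score_exam(ex, m), abnormality_criterion(z))$n_abnormal
    }, numeric(1))
    expect_true(all(diff(counts_z) <= 0))
    counts_off <- vapply(offsets, function(o) {
      summarize_eye(score_exam(ex, m, calibration_offset(o)),
                    abnormality_criterion(1.65))$n_abnormal
    }, numeric(1))
    expect_true(all(diff(counts_off) <= 0))
  }
})

test_that("Bland-Altman agrees with a naive two-pass computation", {
  set.seed(1003)
  for (i in 1:20) {
    n <- sample(3:60, 1)
    x <- rnorm(n, 25, 2); y <- rnorm(n, 25, 2)
    ba <- bland_altman(x, y)
    ref <- naive_bland_altman(x, y)
    expect_equal(ba$mean_diff, ref$mean_diff)
    expect_equal(ba$sd_diff, ref$sd_diff)
    expect_equal(ba$loa_lower, ref$loa_lower)
    expect_equal(ba$loa_upper, ref$loa_upper)
    expect_equal(ba$span, ref$span)
  }
})

test_that("the restricted-mean deviation always sits below the cutoff", {
  set.seed(1004)
  cr <- abnormality_criterion(1.65)
  for (i in 1:50) {
    oc <- summarize_eye(score_exam(random_exam(), m), cr)
    if (oc$n_abnormal >= 1) {
      expect_lte(oc$mean_deviation_abnormal, -cr$cutoff_db)
    } else {
      expect_true(is.na(oc$mean_deviation_abnormal))
    }
    expect_gte(oc$n_abnormal, 0)
    expect_lte(oc$n_abnormal, oc$n_points)
  }
})

test_that("scored healthy simulations have centred deviations and nominal tails", {
  # moderate n here; the precise tail check runs in the acceptance suite
  cfg <- simulation_config(n_healthy = 400, n_iamd = 0, n_exams = 1,
                           measurement_noise_sd = 1.78, seed = 1005)
  co <- simulate_cohort(cfg)
  sc <- score_exams(co$exams, cfg$model, calibration_offset(cfg$device_offset))
  expect_equal(mean(sc$deviation), 0, tolerance = 0.05)
  frac165 <- mean(sc$abnormal_z1.65)
  frac200 <- mean(sc$abnormal_z2)
  se165 <- sqrt(pnorm(-1.65) * (1 - pnorm(-1.65)) / nrow(sc))
  se200 <- sqrt(pnorm(-2) * (1 - pnorm(-2)) / nrow(sc))
  expect_lt(abs(frac165 - pnorm(-1.65)), 4 * se165)
  expect_lt(abs(frac200 - pnorm(-2)), 4 * se200)
})
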