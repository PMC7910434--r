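test_that("the generator is deterministic and order-independent", {
  cfg <- simulation_config(n_healthy = 3, n_iamd = 3, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(
    lapply(a$exams, function(e) e$thresholds),
    lapply(b$exams, function(e) e$thresholds)
  )
  expect_identical(a$truth_points, b$truth_points)
  # a single eye's stream depends only on (seed, index)
  e5 <- simulate_eye(cfg, "iAMD", "X", index = 5L)
  e5b <- simulate_eye(cfg, "iAMD", "X", index = 5L)
  expect_identical(e5[[1]]$thresholds, e5b[[1]]$thresholds)
  # a different seed changes the data
  expect_false(identical(
    simulate_cohort(simulation_config(n_healthy = 3, n_iamd = 3,
                                      seed = 10))$truth_points,
    a$truth_points
  ))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123); r1 <- runif(3)
  set.seed(123)
  invisible(simulate_cohort(simulation_config(n_healthy = 2, n_iamd = 1)))
  expect_identical(runif(3), r1)
})

test_that("the noiseless healthy limit reproduces the normative surface", {
  cfg <- simulation_config(n_healthy = 1, n_iamd = 0, device_offset = 0,
                           measurement_noise_sd = 0, seed = 3)
  ex <- simulate_eye(cfg, "healthy", "H1", index = 1L)
  tr <- attr(ex, "truth")
  expected <- expected_threshold(cfg$model, tr$age)
  expect_equal(ex[[1]]$thresholds, rep(round(expected, 1), 33))
  expect_equal(tr$true_sensitivity, rep(expected, 33))
  expect_equal(tr$n_affected, 0)
})

test_that("exam metadata stays within its contracts", {
  co <- simulate_cohort(simulation_config(n_healthy = 4, n_iamd = 4,
                                          seed = 21))
  fp <- vapply(co$exams, function(e) e$false_positive_rate, numeric(1))
  expect_true(all(fp >= 0 & fp <= 0.2))
  thr <- unlist(lapply(co$exams, function(e) e$thresholds))
  expect_true(all(thr >= 0 & thr <= 36))
  expect_true(all(vapply(co$exams, function(e) e$age, numeric(1)) > 0))
  # both exams of an eye share age, eye side and cohort
  by_eye <- split(co$exams,
                  vapply(co$exams, function(e) e$subject_id, character(1)))
  for (pair in by_eye) {
    expect_equal(pair[[1]]$age, pair[[2]]$age)
    expect_equal(pair[[1]]$eye, pair[[2]]$eye)
  }
})

test_that("empty cohorts are allowed", {
  co <- simulate_cohort(simulation_config(n_healthy = 0, n_iamd = 0))
  expect_length(co$exams, 0)
  expect_equal(nrow(co$truth_eyes), 0)
})

test_that("lesions respect count, depth sign and spatial mode", {
  cfg <- simulation_config(n_iamd = 10, n_healthy = 0,
                           n_affected_mean = 8, n_affected_sd = 0, seed = 13)
  co <- simulate_cohort(cfg)
  expect_true(all(co$truth_eyes$n_affected == 8))
  expect_true(all(co$truth_points$depth <= 0))
  expect_true(all(co$truth_points$depth[!co$truth_points$affected] == 0))
  # cluster mode: affected points span a contiguous arc in angular order
  g <- cfg$grid
  ord <- order(g$points$angle, g$points$eccentricity)
  for (sid in unique(co$truth_points$subject_id)) {
    tp <- co$truth_points[co$truth_points$subject_id == sid, ]
    pos <- sort(match(tp$point_index[tp$affected], tp$point_index[ord]))
    gaps <- diff(c(pos, pos[1] + 33))
    expect_equal(sum(gaps > 1), if (length(pos) < 33) 1 else 0)
  }
})

test_that("heavy truncation at the device floor triggers a warning", {
  cfg <- simulation_config(n_iamd = 5, n_healthy = 0, depth_mean = -28,
                           depth_sd = 0, n_affected_mean = 20,
                           n_affected_sd = 0, seed = 5)
  expect_warning(simulate_cohort(cfg), "truncated")
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(measurement_noise_sd = -1))
  expect_error(simulation_config(n_affected_mean = 40), "grid size")
  expect_error(simulation_config(depth_mean = 2), "depression")
  expect_error(simulation_config(n_exams = 0))
})

test_that("flagged counts track the analytic tail probabilities", {
  # 12 affected points at exactly -6 dB, noise SD 1: the expected flag
  # count per eye is sum over points of Phi((-cutoff - depth) / sigma)
  cfg <- simulation_config(n_iamd = 300, n_healthy = 0, n_exams = 1,
                           n_affected_mean = 12, n_affected_sd = 0,
                           depth_mean = -6, depth_sd = 0,
                           measurement_noise_sd = 1, seed = 88)
  co <- simulate_cohort(cfg)
  m <- cfg$model
  off <- calibration_offset(cfg$device_offset)
  sc <- score_exams(co$exams, m, off)
  oc <- summarize_eyes(sc, list(abnormality_criterion(1.65)))
  cut <- 1.65 * 1.78
  analytic <- 12 * pnorm((-cut + 6) / 1) + 21 * pnorm(-cut / 1)
  # MC SE of the mean count at 300 eyes is ~0.013; 0.1 is ample
  expect_equal(mean(oc$n_abnormal), analytic, tolerance = 0.1 / analytic)
})
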