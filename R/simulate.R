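#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure of same-visit
#' repeated mesopic microperimetry in healthy and intermediate-AMD eyes.
#' Each eye gets a true per-point sensitivity surface drawn once — the
#' age-expected normal threshold, lowered by a global device offset
#' (which the calibration stage is meant to recover) and, in iAMD eyes,
#' by focal lesion depressions — and each exam adds independent Gaussian
#' measurement noise per point, with truncation to the device range.
#'
#' Defaults encode the study conditions: cohort sizes 22 healthy / 25
#' iAMD; ages 62.2 +/- 4.4 (healthy) and 67.7 +/- 7.1 (iAMD) years; a
#' 2.67 dB device offset; two exams per eye. The measurement noise SD
#' (1.732 dB) is calibrated so the pointwise test-retest 95%
#' limits-of-agreement span is `2 * 1.96 * sqrt(2) * sd ~ 9.6` dB. The
#' lesion model places on average 12 (SD 9) affected points per iAMD eye
#' with per-point depression depth -5 +/- 1.5 dB, in a contiguous angular
#' sector by default (focal drusen-like damage) or scattered at random;
#' these defaults give roughly a third of points abnormal, a whole-grid
#' mean deviation near -2 dB and a within-grid SD near 2.4 dB.
#'
#' @param n_healthy,n_iamd Eyes per cohort (>= 0).
#' @param age_mean_healthy,age_sd_healthy,age_mean_iamd,age_sd_iamd Age
#'   distributions in years (normal, truncated to \[40, 95\]).
#' @param device_offset dB subtracted from every simulated true
#'   sensitivity (the device reads low by this amount).
#' @param measurement_noise_sd Per-point, per-exam noise SD in dB (>= 0).
#' @param n_exams Repeated same-visit exams per eye (>= 1).
#' @param n_affected_mean,n_affected_sd Distribution of the number of
#'   lesion-affected points per iAMD eye (normal, rounded, truncated to
#'   \[0, grid size\]).
#' @param depth_mean,depth_sd Per-point lesion depression in dB
#'   (`depth_mean` <= 0; draws are capped at 0 so a lesion never raises
#'   sensitivity).
#' @param spatial `"cluster"` (contiguous angular sector) or `"random"`
#'   (scattered points).
#' @param fp_max False-positive rates are drawn uniformly on
#'   \[0, `fp_max`\].
#' @param range Device dynamic range used for truncation, dB.
#' @param seed Master seed; each eye's random stream is derived
#'   deterministically from (seed, eye index), so a dataset is
#'   reproducible bit-for-bit and independent of generation order.
#' @param model The [normative_model()] the truths are drawn from.
#' @param grid The [mp_grid()] to simulate on.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_healthy = 22, n_iamd = 25,
                              age_mean_healthy = 62.2, age_sd_healthy = 4.4,
                              age_mean_iamd = 67.7, age_sd_iamd = 7.1,
                              device_offset = 2.67,
                              measurement_noise_sd = 9.6 / (2 * 1.96 * sqrt(2)),
                              n_exams = 2,
                              n_affected_mean = 12, n_affected_sd = 9,
                              depth_mean = -5, depth_sd = 1.5,
                              spatial = c("cluster", "random"),
                              fp_max = 0.2,
                              range = c(0, 36),
                              seed = 1L,
                              model = normative_model(),
                              grid = grid_study33()) {
  spatial <- match.arg(spatial)
  stopifnot(
    n_healthy >= 0, n_iamd >= 0,
    age_sd_healthy >= 0, age_sd_iamd >= 0,
    age_mean_healthy > 0, age_mean_iamd > 0,
    measurement_noise_sd >= 0, n_exams >= 1,
    n_affected_sd >= 0, depth_sd >= 0,
    fp_max >= 0, fp_max <= 1,
    length(range) == 2L, range[1] < range[2],
    inherits(model, "normative_model"), inherits(grid, "mp_grid")
  )
  if (n_affected_mean < 0 || n_affected_mean > n_points(grid)) {
    stop("n_affected_mean must lie within the grid size", call. = FALSE)
  }
  if (depth_mean > 0) {
    stop("depth_mean is a depression and must be <= 0 dB", call. = FALSE)
  }
  structure(
    list(
      n_healthy = as.integer(n_healthy), n_iamd = as.integer(n_iamd),
      age_mean_healthy = age_mean_healthy, age_sd_healthy = age_sd_healthy,
      age_mean_iamd = age_mean_iamd, age_sd_iamd = age_sd_iamd,
      device_offset = device_offset,
      measurement_noise_sd = measurement_noise_sd,
      n_exams = as.integer(n_exams),
      n_affected_mean = n_affected_mean, n_affected_sd = n_affected_sd,
      depth_mean = depth_mean, depth_sd = depth_sd,
      spatial = spatial, fp_max = fp_max, range = as.numeric(range),
      seed = as.integer(seed), model = model, grid = grid
    ),
    class = "simulation_config"
  )
}

# Deterministic per-eye stream seed from (master seed, eye index); a
# single LCG step keeps the result in the 32-bit integer range.
derive_eye_seed <- function(master, index) {
  as.integer((1103515245 * ((as.numeric(master) + 7919 * index) %% 65521) +
                12345) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

#' Simulate the repeated exams of one eye
#'
#' Draws the eye's true sensitivity surface once, then produces
#' `config$n_exams` exams by adding independent per-point measurement
#' noise, rounding thresholds to the device's one-decimal output
#' precision and truncating to the dynamic range. The random stream is
#' derived from `(config$seed, index)`, so the same eye is reproducible
#' regardless of how many other eyes are generated around it.
#'
#' @param config A [simulation_config()].
#' @param cohort `"healthy"` or `"iAMD"`; lesions are only drawn for
#'   iAMD eyes.
#' @param subject_id Subject identifier for the generated exams.
#' @param index Integer identifying this eye's random stream.
#' @return A list of [mp_exam()] objects with attribute `truth`: a list
#'   with `age`, `eye`, `true_sensitivity` (per point), `affected`
#'   (logical per point), `depth` (per point, 0 where unaffected),
#'   `n_affected` and `n_clipped` (points truncated at the range bounds,
#'   summed over exams).
#' @export
simulate_eye <- function(config, cohort = c("healthy", "iAMD"),
                         subject_id = "S1", index = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  cohort <- match.arg(cohort)
  npts <- n_points(config$grid)
  with_seed(derive_eye_seed(config$seed, index), {
    age <- if (cohort == "healthy") {
      rnorm_trunc(1, config$age_mean_healthy, config$age_sd_healthy, 40, 95)
    } else {
      rnorm_trunc(1, config$age_mean_iamd, config$age_sd_iamd, 40, 95)
    }
    eye <- sample(c("left", "right"), 1)
    depth <- numeric(npts)
    affected <- logical(npts)
    if (cohort == "iAMD") {
      k <- round(stats::rnorm(1, config$n_affected_mean, config$n_affected_sd))
      k <- max(0L, min(npts, as.integer(k)))
      if (k > 0) {
        idx <- if (config$spatial == "cluster") {
          ord <- order(config$grid$points$angle,
                       config$grid$points$eccentricity)
          start <- sample(npts, 1)
          ord[((start - 1 + seq_len(k) - 1) %% npts) + 1]
        } else {
          sample(npts, k)
        }
        affected[idx] <- TRUE
        depth[idx] <- pmin(0, stats::rnorm(k, config$depth_mean,
                                           config$depth_sd))
      }
    }
    truth <- expected_threshold(config$model, age) - config$device_offset +
      depth
    n_clipped <- 0L
    exams <- lapply(seq_len(config$n_exams), function(i) {
      raw <- truth + stats::rnorm(npts, 0, config$measurement_noise_sd)
      n_clipped <<- n_clipped +
        sum(raw < config$range[1] | raw > config$range[2])
      thr <- round(pmin(config$range[2], pmax(config$range[1], raw)), 1)
      mp_exam(
        subject_id = subject_id, eye = eye, exam_index = i,
        age = round(age, 1), grid = config$grid, thresholds = thr,
        false_positive_rate = round(stats::runif(1, 0, config$fp_max), 3),
        cohort = cohort
      )
    })
    attr(exams, "truth") <- list(
      age = age, eye = eye, true_sensitivity = truth, affected = affected,
      depth = depth, n_affected = sum(affected), n_clipped = n_clipped
    )
    exams
  })
}

#' Simulate a full two-cohort dataset
#'
#' Generates `n_healthy` healthy and `n_iamd` iAMD eyes under the given
#' configuration and collects the ground truth needed for
#' parameter-recovery checks. Warns when more than 1% of simulated
#' point measurements had to be truncated at the device range, since
#' floor/ceiling effects bias deviation estimates.
#'
#' @param config A [simulation_config()].
#' @return An object of class `mp_cohort`: list with `exams` (flat list
#'   of [mp_exam()]), `truth_eyes` (tibble: `subject_id`, `eye`,
#'   `cohort`, `age`, `device_offset`, `n_affected`, `mean_depth` over
#'   affected points, `NA` if none), `truth_points` (tibble:
#'   `subject_id`, `eye`, `point_index`, `true_sensitivity`, `affected`,
#'   `depth`) and the `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_healthy = 3, n_iamd = 2,
#'                                             seed = 7))
#' length(cohort$exams)  # (3 + 2) eyes x 2 exams
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  plan <- tibble::tibble(
    cohort = rep(c("healthy", "iAMD"), c(config$n_healthy, config$n_iamd)),
    subject_id = c(sprintf("H%03d", seq_len(config$n_healthy)),
                   sprintf("P%03d", seq_len(config$n_iamd))),
    index = seq_len(config$n_healthy + config$n_iamd)
  )
  exams <- list()
  truth_eyes <- vector("list", nrow(plan))
  truth_points <- vector("list", nrow(plan))
  total_clipped <- 0L
  for (i in seq_len(nrow(plan))) {
    ex <- simulate_eye(config, cohort = plan$cohort[i],
                       subject_id = plan$subject_id[i], index = plan$index[i])
    tr <- attr(ex, "truth")
    exams <- c(exams, ex)
    truth_eyes[[i]] <- tibble::tibble(
      subject_id = plan$subject_id[i], eye = tr$eye, cohort = plan$cohort[i],
      age = tr$age, device_offset = config$device_offset,
      n_affected = tr$n_affected,
      mean_depth = if (tr$n_affected > 0) mean(tr$depth[tr$affected]) else NA_real_
    )
    truth_points[[i]] <- tibble::tibble(
      subject_id = plan$subject_id[i], eye = tr$eye,
      point_index = config$grid$points$point_index,
      true_sensitivity = tr$true_sensitivity,
      affected = tr$affected, depth = tr$depth
    )
    total_clipped <- total_clipped + tr$n_clipped
  }
  n_meas <- nrow(plan) * config$n_exams * n_points(config$grid)
  if (n_meas > 0 && total_clipped / n_meas > 0.01) {
    warning(sprintf(
      "%.1f%% of simulated measurements truncated at the device range; deviation estimates may be biased",
      100 * total_clipped / n_meas
    ), call. = FALSE)
  }
  structure(
    list(exams = exams,
         truth_eyes = dplyr::bind_rows(truth_eyes),
         truth_points = dplyr::bind_rows(truth_points),
         config = config),
    class = "mp_cohort"
  )
}

#' @export
print.mp_cohort <- function(x, ...) {
  cat(sprintf(
    "<mp_cohort: %d exams (%d healthy + %d iAMD eyes x %d exams), grid '%s', seed %d>\n",
    length(x$exams), x$config$n_healthy, x$config$n_iamd, x$config$n_exams,
    x$config$grid$name, x$config$seed
  ))
  invisible(x)
}
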