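pipeline_defaults <- function() {
  list(
    seed = 1L,
    input_csv = NULL,
    simulation = list(),
    model = list(intercept = 32.3, slope = -0.06, pointwise_sd = 1.78),
    offset = "estimate",
    criteria = list(z = c(1.65, 2), rounded = FALSE),
    qc = list(max_fp = 0.33),
    eligibility = list(min_abnormal = 5, require_all_exams = TRUE),
    agreement = list(exams = c(1, 2))
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full abnormal-point outcome pipeline
#'
#' Composes the whole analysis: read (or simulate) exams, screen them by
#' false-positive rate, estimate the device calibration offset from the
#' healthy cohort (or use a fixed one), score every exam against the
#' normative model, summarise per eye and per cohort, screen trial
#' eligibility, and compute test-retest agreement (Bland-Altman for
#' whole-grid means, abnormal-point means and pointwise thresholds) and
#' Cohen's d of abnormal-point deviations against the healthy eyes'
#' whole-grid deviations.
#'
#' @param config Either a path to a YAML configuration file or a named
#'   list. Recognised fields (all optional): `seed`; `input_csv` (path to
#'   an exam table; when absent a cohort is simulated); `simulation`
#'   (arguments for [simulation_config()]); `model` (`intercept`,
#'   `slope`, `pointwise_sd`); `offset` (`"estimate"` or a number in dB);
#'   `criteria` (`z` vector, `rounded` flag); `qc` (`max_fp`);
#'   `eligibility` (`min_abnormal`, `require_all_exams`); `agreement`
#'   (`exams`, the pair of exam indices to compare).
#' @param out_dir Directory for the output artifacts; created if needed.
#'   Written files: `exams.csv` (when simulated), `truth_eyes.csv`
#'   (simulation ground truth), `points.csv` (per-point scores),
#'   `eyes.csv` (per-exam eye outcomes), `cohort_by_exam.csv`,
#'   `eligibility.csv`, `agreement.csv`, `effect_sizes.csv`,
#'   `run_log.txt`. Outputs are deterministic given the configuration.
#' @return Invisibly, a list with all intermediate objects (`exams`,
#'   `offset`, `scores`, `outcomes`, `cohort` summary, `agreement`,
#'   `effect_sizes`, `paths`).
#' @export
run_pipeline <- function(config = list(), out_dir = ".") {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- merge_config(pipeline_defaults(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    sprintf("mpoutcomes %s", as.character(utils::packageVersion("mpoutcomes"))),
    sprintf("seed: %s", cfg$seed)
  )
  paths <- list()

  model <- stage("model", do.call(normative_model, cfg$model))
  criteria <- stage("criteria", {
    crits <- lapply(cfg$criteria$z, abnormality_criterion,
                    pointwise_sd = model$pointwise_sd,
                    rounded = isTRUE(cfg$criteria$rounded))
    names(crits) <- vapply(crits, function(cr) cr$label, character(1))
    crits
  })
  for (cr in criteria) {
    log_lines <- c(log_lines, sprintf(
      "criterion: z = %g, cutoff = %.4f dB, rounded = %s",
      cr$z, cr$cutoff_db, cr$rounded
    ))
  }

  sim <- NULL
  exams <- stage("input", {
    if (!is.null(cfg$input_csv)) {
      log_lines <- c(log_lines, sprintf("input: %s", cfg$input_csv))
      read_exams(cfg$input_csv, grid_study33())
    } else {
      sim_args <- cfg$simulation
      sim_args$seed <- cfg$seed
      sim <- simulate_cohort(do.call(simulation_config, sim_args))
      log_lines <- c(log_lines, sprintf(
        "input: simulated cohort (%d healthy + %d iAMD eyes, %d exams each)",
        sim$config$n_healthy, sim$config$n_iamd, sim$config$n_exams
      ))
      paths$exams <- file.path(out_dir, "exams.csv")
      write_exams(sim$exams, paths$exams)
      paths$truth_eyes <- file.path(out_dir, "truth_eyes.csv")
      utils::write.csv(sim$truth_eyes, paths$truth_eyes, row.names = FALSE)
      sim$exams
    }
  })

  n_before <- length(exams)
  exams <- stage("qc_filter",
                 suppressMessages(qc_filter(exams, cfg$qc$max_fp)))
  log_lines <- c(log_lines, sprintf(
    "qc_filter: %d of %d exams retained (false-positive rate < %g)",
    length(exams), n_before, cfg$qc$max_fp
  ))

  offset <- stage("offset", {
    if (identical(cfg$offset, "estimate")) {
      healthy <- Filter(function(e) e$cohort == "healthy", exams)
      if (length(healthy) == 0L) {
        stop("no healthy exams to estimate the calibration offset from; supply offset as a number")
      }
      estimate_offset(model, healthy)
    } else {
      calibration_offset(as.numeric(cfg$offset))
    }
  })
  log_lines <- c(log_lines, sprintf("calibration offset: %+.4f dB (%s)",
                                    offset$offset, offset$source))

  scores <- stage("score_exam",
                  score_exams(exams, model, offset, criteria))
  outcomes <- stage("summarize_eye", summarize_eyes(scores, criteria))
  cohorts <- stage("summarize_cohort", {
    lapply(split(outcomes, outcomes$cohort), summarize_cohort,
           min_abnormal = cfg$eligibility$min_abnormal)
  })

  agreement <- stage("bland_altman", {
    pair <- as.integer(cfg$agreement$exams)
    rows <- list()
    iamd_out <- outcomes[outcomes$cohort == "iAMD", ]
    for (zv in unique(outcomes$z)) {
      oz <- iamd_out[iamd_out$z == zv, ]
      if (nrow(oz) == 0L) next
      p_all <- paired_eye_outcomes(oz, "mean_threshold_all", exams = pair)
      p_abn <- paired_eye_outcomes(oz, "mean_threshold_abnormal",
                                   exams = pair,
                                   min_abnormal = cfg$eligibility$min_abnormal)
      for (lev in list(list(name = "eye_mean_all", p = p_all),
                       list(name = "eye_mean_abnormal", p = p_abn))) {
        if (nrow(lev$p) >= 2L) {
          ba <- bland_altman(lev$p$value_1, lev$p$value_2)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            level = lev$name, z = zv, n = ba$n, mean_diff = ba$mean_diff,
            sd_diff = ba$sd_diff, loa_lower = ba$loa_lower,
            loa_upper = ba$loa_upper, span = ba$span,
            half_width = ba$half_width
          )
        }
      }
    }
    pp <- paired_points(scores[scores$cohort == "iAMD", ], exams = pair)
    if (nrow(pp) >= 2L) {
      ba <- bland_altman(pp$value_1, pp$value_2)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        level = "pointwise", z = NA_real_, n = ba$n, mean_diff = ba$mean_diff,
        sd_diff = ba$sd_diff, loa_lower = ba$loa_lower,
        loa_upper = ba$loa_upper, span = ba$span, half_width = ba$half_width
      )
    }
    dplyr::bind_rows(rows)
  })

  effect_sizes <- stage("cohens_d", {
    healthy_dev <- outcomes$mean_deviation_all[
      outcomes$cohort == "healthy" & outcomes$z == outcomes$z[1]
    ]
    rows <- list()
    if (length(healthy_dev) >= 2L) {
      iamd_out <- outcomes[outcomes$cohort == "iAMD", ]
      for (zv in unique(iamd_out$z)) {
        for (ei in sort(unique(iamd_out$exam_index))) {
          dev <- iamd_out$mean_deviation_abnormal[
            iamd_out$z == zv & iamd_out$exam_index == ei & iamd_out$has_abnormal
          ]
          if (length(dev) >= 2L) {
            rows[[length(rows) + 1L]] <- tibble::tibble(
              z = zv, exam_index = ei, n_iamd = length(dev),
              n_healthy = length(healthy_dev),
              d = cohens_d(dev, healthy_dev)
            )
          }
        }
      }
    }
    dplyr::bind_rows(rows)
  })

  write_one <- function(obj, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(obj, p, row.names = FALSE)
    p
  }
  paths$points <- write_one(scores, "points.csv")
  paths$eyes <- write_one(outcomes, "eyes.csv")
  paths$cohort_by_exam <- write_one(
    dplyr::bind_rows(lapply(names(cohorts), function(nm) {
      dplyr::mutate(cohorts[[nm]]$by_exam, cohort = nm, .before = 1)
    })), "cohort_by_exam.csv")
  paths$eligibility <- write_one(
    dplyr::bind_rows(lapply(names(cohorts), function(nm) {
      dplyr::mutate(cohorts[[nm]]$eligibility, cohort = nm, .before = 1)
    })), "eligibility.csv")
  if (nrow(agreement) > 0L) {
    paths$agreement <- write_one(agreement, "agreement.csv")
  }
  if (nrow(effect_sizes) > 0L) {
    paths$effect_sizes <- write_one(effect_sizes, "effect_sizes.csv")
  }
  log_lines <- c(log_lines, sprintf(
    "eligibility: >= %d abnormal points, require_all_exams = %s",
    cfg$eligibility$min_abnormal, isTRUE(cfg$eligibility$require_all_exams)
  ))
  paths$log <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, paths$log)

  invisible(list(
    exams = exams, simulation = sim, model = model, offset = offset,
    criteria = criteria, scores = scores, outcomes = outcomes,
    cohorts = cohorts, agreement = agreement, effect_sizes = effect_sizes,
    config = cfg, paths = paths
  ))
}
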