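#' Flatten exams to the long CSV schema
#'
#' One row per tested point with header
#' `subject_id,eye,exam_index,age,cohort,point_index,x_deg,y_deg,threshold_db,false_positive_rate`.
#'
#' @param exams List of [mp_exam()] objects.
#' @return A tibble in the exam-table schema.
#' @export
exams_to_table <- function(exams) {
  stopifnot(is.list(exams), length(exams) > 0L)
  dplyr::bind_rows(lapply(exams, function(e) {
    stopifnot(inherits(e, "mp_exam"))
    tibble::tibble(
      subject_id = e$subject_id, eye = e$eye, exam_index = e$exam_index,
      age = e$age, cohort = e$cohort,
      point_index = e$grid$points$point_index,
      x_deg = round(e$grid$points$x, 6), y_deg = round(e$grid$points$y, 6),
      threshold_db = e$thresholds,
      false_positive_rate = e$false_positive_rate
    )
  }))
}

#' Write exams to CSV
#'
#' Thresholds are written at the device's one-decimal output precision;
#' all other numeric fields keep full precision. UTF-8, '.' decimal
#' separator, no quoting.
#'
#' @param exams List of [mp_exam()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_exams()]
#' @export
write_exams <- function(exams, path) {
  tab <- exams_to_table(exams)
  tab$threshold_db <- sprintf("%.1f", tab$threshold_db)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

exam_table_columns <- c(
  "subject_id", "eye", "exam_index", "age", "cohort", "point_index",
  "x_deg", "y_deg", "threshold_db", "false_positive_rate"
)

#' Read exams from CSV
#'
#' Parses and validates an exam table against a grid: every
#' (subject, eye, exam) group must cover each grid point exactly once,
#' exam-level fields must be constant within a group, and thresholds must
#' lie in the 0-36 dB device range. Violations are reported with the
#' offending exam and data row numbers.
#'
#' @param path CSV file in the [write_exams()] schema.
#' @param grid The [mp_grid()] the exams were acquired on.
#' @return List of validated [mp_exam()] objects, thresholds ordered by
#'   grid point index.
#' @export
read_exams <- function(path, grid) {
  stopifnot(inherits(grid, "mp_grid"))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(exam_table_columns, names(tab))
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  tab$.row <- seq_len(nrow(tab)) + 1L  # data rows, counting the header
  groups <- split(tab, interaction(tab$subject_id, tab$eye, tab$exam_index,
                                   drop = TRUE))
  want <- sort(grid$points$point_index)
  exams <- lapply(groups, function(g) {
    id <- sprintf("%s/%s exam %s", g$subject_id[1], g$eye[1], g$exam_index[1])
    dup <- g$point_index[duplicated(g$point_index)]
    if (length(dup) > 0L) {
      stop(sprintf("%s: duplicate point index(es) %s in %s", path,
                   paste(unique(dup), collapse = ", "), id), call. = FALSE)
    }
    absent <- setdiff(want, g$point_index)
    extra <- setdiff(g$point_index, want)
    if (length(absent) > 0L || length(extra) > 0L) {
      stop(sprintf(
        "%s: %s does not cover grid '%s'%s%s", path, id, grid$name,
        if (length(absent)) paste0("; missing point(s) ",
                                   paste(absent, collapse = ", ")) else "",
        if (length(extra)) paste0("; unknown point(s) ",
                                  paste(extra, collapse = ", ")) else ""
      ), call. = FALSE)
    }
    for (col in c("age", "cohort", "false_positive_rate")) {
      if (length(unique(g[[col]])) != 1L) {
        stop(sprintf("%s: %s varies within %s (rows %s)", path, col, id,
                     paste(range(g$.row), collapse = "-")), call. = FALSE)
      }
    }
    bad <- which(!is.finite(g$threshold_db) | g$threshold_db < 0 |
                   g$threshold_db > 36)
    if (length(bad) > 0L) {
      stop(sprintf("%s: threshold outside 0-36 dB in %s at row(s) %s", path,
                   id, paste(g$.row[bad], collapse = ", ")), call. = FALSE)
    }
    g <- g[order(g$point_index), ]
    mp_exam(
      subject_id = as.character(g$subject_id[1]), eye = g$eye[1],
      exam_index = g$exam_index[1], age = g$age[1], grid = grid,
      thresholds = g$threshold_db,
      false_positive_rate = g$false_positive_rate[1], cohort = g$cohort[1]
    )
  })
  names(exams) <- NULL
  # stable order: by subject, eye, exam
  ord <- order(vapply(exams, function(e) e$subject_id, character(1)),
               vapply(exams, function(e) e$eye, character(1)),
               vapply(exams, function(e) e$exam_index, integer(1)))
  exams[ord]
}
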