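# Canonical interchange formats: wide per-subject CSV with a `time` column
# and one column per channel/layer (ch01_oxy ... ch24_oxy, ch01_deoxy ...),
# a subjects CSV, and a JSON/YAML schedule.

layer_columns <- function(n_channels, layers) {
  unlist(lapply(layers, function(l) sprintf("ch%02d_%s", seq_len(n_channels), l)))
}

#' Write a recording to wide CSV
#'
#' Columns: \code{time} then \code{ch01_<layer>} ... for each layer
#' (\code{oxy}/\code{deoxy} or \code{od760}/\code{od840}). Values are
#' written at full precision (round-trips exactly).
#'
#' @param r A \code{nirs_recording}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(r, path) {
  layers <- names(r$data)
  df <- data.frame(time = r$start_time + (seq_len(r$n_samples) - 1L) / r$sampling_rate)
  for (l in layers) {
    m <- t(r$data[[l]])
    colnames(m) <- sprintf("ch%02d_%s", seq_len(r$n_channels), l)
    df <- cbind(df, m)
  }
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a recording from wide CSV
#'
#' Verifies a uniform time grid (maximum jitter below 1e-6 s), the expected
#' channel columns for the declared unit, and the absence of missing
#' samples.
#'
#' @param path CSV file path.
#' @param unit \code{"hb_mM_mm"} or \code{"optical_density"}.
#' @param subject_id Subject id to attach (default: file name sans
#'   extension).
#' @param n_channels Expected channel count (default 24).
#' @return A \code{nirs_recording}.
#' @export
read_recording <- function(path, unit = HB_UNIT,
                           subject_id = sub("\\.[^.]*$", "", basename(path)),
                           n_channels = 24) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  unit <- match.arg(unit, c(HB_UNIT, OD_UNIT))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("montage mismatch: no time column")
  tt <- df$time
  if (length(tt) < 2L) stop("irregular sampling: fewer than 2 samples")
  dt <- diff(tt)
  if (max(dt) - min(dt) > 1e-6 || any(dt <= 0))
    stop("irregular sampling: non-uniform time grid")
  fs <- 1 / stats::median(dt)
  layers <- if (unit == HB_UNIT) HB_LAYERS else OD_LAYERS
  want <- layer_columns(n_channels, layers)
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols))
    stop(sprintf("montage mismatch: missing channel column(s) %s",
                 paste(utils::head(missing_cols, 3L), collapse = ", ")))
  if (anyNA(df[want])) stop("missing sample: NaN/NA cell in channel data")
  data <- lapply(layers, function(l) {
    m <- t(as.matrix(df[layer_columns(n_channels, l)]))
    dimnames(m) <- NULL
    m
  })
  names(data) <- layers
  nirs_recording(subject_id, data, sampling_rate = fs, unit = unit,
                 start_time = tt[1L])
}

#' Read a task schedule from JSON or YAML
#'
#' The file holds a list of blocks, each with fields \code{condition},
#' \code{onset}, \code{duration} (seconds). Validation (overlap, ordering)
#' is applied on construction.
#'
#' @param path File path; format chosen by extension (\code{.json} vs
#'   \code{.yaml}/\code{.yml}).
#' @return A \code{task_schedule}.
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  else yaml::read_yaml(path)
  if (is.data.frame(raw)) {
    blocks <- raw
  } else {
    if (!is.null(raw$blocks)) raw <- raw$blocks
    blocks <- do.call(rbind, lapply(raw, function(b)
      data.frame(condition = b$condition, onset = b$onset,
                 duration = b$duration, stringsAsFactors = FALSE)))
  }
  if (is.null(blocks) || nrow(blocks) == 0L)
    stop("schedule must contain at least one block")
  task_schedule(blocks$condition, blocks$onset, blocks$duration)
}

#' Write a task schedule to JSON
#' @param s A \code{task_schedule}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_schedule <- function(s, path) {
  jsonlite::write_json(as.data.frame(s), path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read the subjects covariate CSV
#'
#' Expected columns: subject_id, group, age, fiq, ygtss, scwc1..3,
#' medicated, comorbid (the last three optional).
#'
#' @param path CSV file path.
#' @return A \code{subject_table}.
#' @export
read_subjects <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "fiq", "scwc1", "scwc2", "scwc3")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("subjects table missing column(s): %s",
                 paste(miss, collapse = ", ")))
  subject_table(df$subject_id, df$group, df$age, df$fiq,
                ygtss = if ("ygtss" %in% names(df)) df$ygtss else NA_real_,
                scwc1 = df$scwc1, scwc2 = df$scwc2, scwc3 = df$scwc3,
                medicated = if ("medicated" %in% names(df)) df$medicated else NA,
                comorbid = if ("comorbid" %in% names(df)) df$comorbid else NA)
}

#' Write the subjects covariate CSV
#' @param subjects A \code{subject_table}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_subjects <- function(subjects, path) {
  utils::write.csv(as.data.frame(subjects), path, row.names = FALSE)
  invisible(path)
}

#' Read an analysis configuration from YAML
#' @param path YAML file with any of the \code{\link{analysis_config}}
#'   fields; absent fields take their defaults.
#' @return An \code{analysis_config}.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(analysis_config, raw[intersect(names(raw),
    names(formals(analysis_config)))])
}

#' Load a study dataset from a directory
#'
#' Reads \code{subjects.csv}, \code{schedule.json}, and one
#' \code{<subject_id>.csv} recording per subject, as written by
#' \code{\link{write_study}}.
#'
#' @param dir Directory path.
#' @param unit Recording unit to parse.
#' @return A \code{study_dataset}.
#' @export
read_study <- function(dir, unit = HB_UNIT) {
  subjects <- read_subjects(file.path(dir, "subjects.csv"))
  schedule <- read_schedule(file.path(dir, "schedule.json"))
  recs <- lapply(subjects$subject_id, function(id)
    read_recording(file.path(dir, paste0(id, ".csv")), unit = unit,
                   subject_id = id))
  names(recs) <- subjects$subject_id
  study_dataset(subjects, recs, schedule)
}

#' Write a study dataset to a directory
#' @param d A \code{study_dataset}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(d, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_subjects(d$subjects, file.path(dir, "subjects.csv"))
  write_schedule(d$schedule, file.path(dir, "schedule.json"))
  for (id in names(d$recordings))
    write_recording(d$recordings[[id]], file.path(dir, paste0(id, ".csv")))
  invisible(dir)
}
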