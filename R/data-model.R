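# Unit conventions used throughout:
#   time in seconds, sample i (0-based) lives at t = start_time + i / fs;
#   block windows are half-open [onset, onset + duration);
#   hemoglobin signals are concentration x pathlength changes in mM*mm.

HB_UNIT <- "hb_mM_mm"
OD_UNIT <- "optical_density"
HB_LAYERS <- c("oxy", "deoxy")
OD_LAYERS <- c("od760", "od840")

#' Multi-channel fNIRS recording
#'
#' A recording holds one matrix (channels x samples) per signal layer: for
#' hemoglobin units the layers are \code{oxy} and \code{deoxy} (mM*mm); for
#' optical-density units they are \code{od760} and \code{od840}
#' (dimensionless, one per wavelength).
#'
#' @param subject_id Subject identifier string.
#' @param data Named list of numeric matrices (channels x samples), all the
#'   same shape. Names must be \code{c("oxy","deoxy")} for unit
#'   \code{"hb_mM_mm"} or \code{c("od760","od840")} for
#'   \code{"optical_density"}.
#' @param sampling_rate Sampling rate in Hz (default 10).
#' @param unit Either \code{"hb_mM_mm"} or \code{"optical_density"}.
#' @param start_time Time of the first sample in seconds (default 0).
#' @return An object of class \code{nirs_recording}.
#' @export
nirs_recording <- function(subject_id, data, sampling_rate = 10,
                           unit = HB_UNIT, start_time = 0) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  unit <- match.arg(unit, c(HB_UNIT, OD_UNIT))
  want <- if (unit == HB_UNIT) HB_LAYERS else OD_LAYERS
  if (!is.list(data) || !setequal(names(data), want))
    stop(sprintf("data must be a named list with layers: %s",
                 paste(want, collapse = ", ")))
  data <- data[want]
  dims <- lapply(data, dim)
  if (any(vapply(data, function(m) !is.matrix(m) || !is.numeric(m), TRUE)))
    stop("each layer must be a numeric matrix (channels x samples)")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all layers must have identical dimensions")
  if (any(vapply(data, function(m) anyNA(m) || any(!is.finite(m)), TRUE)))
    stop("missing sample")
  structure(
    list(subject_id = subject_id, data = data,
         n_channels = nrow(data[[1L]]), n_samples = ncol(data[[1L]]),
         sampling_rate = sampling_rate, unit = unit,
         start_time = start_time),
    class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf("<nirs_recording> subject %s: %d channels x %d samples @ %g Hz (%s), t0 = %g s\n",
              x$subject_id, x$n_channels, x$n_samples, x$sampling_rate,
              x$unit, x$start_time))
  invisible(x)
}

#' Recording duration in seconds
#' @param r A \code{nirs_recording}.
#' @return Duration covered by the samples, \code{n_samples / fs}, seconds.
#' @export
recording_duration <- function(r) r$n_samples / r$sampling_rate

#' Block-design task schedule
#'
#' An ordered set of non-overlapping condition blocks. Conditions are
#' \code{"baseline_word"} (word reading) and \code{"activation_color_word"}
#' (incongruent color-word naming).
#'
#' @param condition Character vector of block conditions.
#' @param onset Numeric vector of block onsets, seconds, strictly increasing.
#' @param duration Numeric vector of block durations, seconds, all positive.
#' @return A data.frame of class \code{task_schedule} with columns
#'   \code{condition}, \code{onset}, \code{duration}.
#' @export
task_schedule <- function(condition, onset, duration) {
  if (length(condition) == 0L) stop("schedule must contain at least one block")
  stopifnot(length(condition) == length(onset),
            length(onset) == length(duration))
  condition <- match.arg(condition,
                         c("baseline_word", "activation_color_word"),
                         several.ok = TRUE)
  if (any(duration <= 0)) stop("block durations must be positive")
  if (is.unsorted(onset, strictly = TRUE))
    stop("block onsets must be strictly increasing")
  ends <- onset + duration
  if (any(ends[-length(ends)] > onset[-1L] + 1e-12))
    stop("schedule overlap: blocks share a time interval")
  structure(
    data.frame(condition = condition, onset = onset, duration = duration,
               stringsAsFactors = FALSE),
    class = c("task_schedule", "data.frame"))
}

#' Canonical Stroop color-word block schedule
#'
#' Three cycles of 45 s word reading (baseline) alternating with 45 s
#' incongruent color-word naming (activation), closed by a final 45 s
#' word-reading block: seven blocks in total, beginning and ending with the
#' baseline condition.
#'
#' @param lead_in Seconds of recording before the first block onset
#'   (default 15). The protocol does not fix this; it only has to leave room
#'   for the pre-task baseline window.
#' @param block_s Block duration in seconds (default 45).
#' @return A \code{task_schedule} with 7 blocks.
#' @export
default_stroop_schedule <- function(lead_in = 15, block_s = 45) {
  conds <- rep(c("baseline_word", "activation_color_word"), length.out = 7L)
  onsets <- lead_in + block_s * (0:6)
  task_schedule(conds, onsets, rep(block_s, 7L))
}

#' End time of the last block
#' @param s A \code{task_schedule}.
#' @return Seconds.
#' @export
schedule_end <- function(s) max(s$onset + s$duration)

#' Activation blocks of a schedule
#' @param s A \code{task_schedule}.
#' @return The rows with condition \code{"activation_color_word"}.
#' @export
activation_blocks <- function(s) s[s$condition == "activation_color_word", , drop = FALSE]

#' Subject covariate table
#'
#' Builds the per-subject covariate data.frame used by the demographic and
#' correlation analyses. \code{ygtss} (tic severity) applies to the case
#' group only and is \code{NA} for controls, never imputed.
#'
#' @param subject_id Character vector.
#' @param group Character vector, \code{"case"} or \code{"control"}.
#' @param age Years, positive.
#' @param fiq Full-scale IQ scores.
#' @param ygtss Tic severity scores (case group only; NA otherwise).
#' @param scwc1,scwc2,scwc3 Stroop color-word correct-answer counts for the
#'   three task cycles, non-negative integers.
#' @param medicated,comorbid Optional logical flags.
#' @return A data.frame of class \code{subject_table}.
#' @export
subject_table <- function(subject_id, group, age, fiq, ygtss = NA_real_,
                          scwc1, scwc2, scwc3,
                          medicated = NA, comorbid = NA) {
  group <- match.arg(group, c("case", "control"), several.ok = TRUE)
  if (any(age <= 0)) stop("age must be positive")
  sc <- cbind(scwc1, scwc2, scwc3)
  if (any(sc < 0, na.rm = TRUE)) stop("SCWC counts must be non-negative")
  structure(
    data.frame(subject_id = subject_id, group = group, age = age, fiq = fiq,
               ygtss = ygtss, scwc1 = scwc1, scwc2 = scwc2, scwc3 = scwc3,
               medicated = medicated, comorbid = comorbid,
               stringsAsFactors = FALSE),
    class = c("subject_table", "data.frame"))
}

#' Complete study dataset
#'
#' @param subjects A \code{subject_table}.
#' @param recordings Named list of \code{nirs_recording}, one per subject,
#'   names matching \code{subjects$subject_id}.
#' @param schedule A \code{task_schedule} shared by all subjects.
#' @return An object of class \code{study_dataset}.
#' @export
study_dataset <- function(subjects, recordings, schedule) {
  structure(list(subjects = subjects, recordings = recordings,
                 schedule = schedule),
            class = "study_dataset")
}

#' Analysis configuration
#'
#' Window lengths and statistical thresholds of the block analysis.
#'
#' @param pre_baseline_s Pre-task baseline window, seconds (default 10).
#' @param post_baseline_s Post-task baseline window, seconds (default 25).
#' @param moving_avg_s Moving-average window, seconds (default 5).
#' @param fdr_q Benjamini-Hochberg false-discovery-rate level (default 0.05).
#' @param alpha_marks Strict-inequality thresholds for the significance
#'   marks dagger/star/double-star (default 0.1, 0.05, 0.01).
#' @return A list of class \code{analysis_config}.
#' @export
analysis_config <- function(pre_baseline_s = 10, post_baseline_s = 25,
                            moving_avg_s = 5, fdr_q = 0.05,
                            alpha_marks = c(0.1, 0.05, 0.01)) {
  if (pre_baseline_s <= 0 || post_baseline_s <= 0 || moving_avg_s <= 0)
    stop("window lengths must be positive")
  if (fdr_q <= 0 || fdr_q >= 1) stop("fdr_q must be in (0, 1)")
  stopifnot(length(alpha_marks) == 3L, all(diff(alpha_marks) < 0))
  structure(list(pre_baseline_s = pre_baseline_s,
                 post_baseline_s = post_baseline_s,
                 moving_avg_s = moving_avg_s, fdr_q = fdr_q,
                 alpha_marks = alpha_marks),
            class = "analysis_config")
}

#' Validate a study dataset
#'
#' Checks dataset-level invariants: every subject has exactly one recording,
#' and each recording is long enough to hold the last activation epoch plus
#' the post-task baseline window.
#'
#' @param d A \code{study_dataset}.
#' @param cfg An \code{analysis_config} (for the post-baseline margin).
#' @return Character vector of findings; empty when the dataset is valid.
#' @export
validate_dataset <- function(d, cfg = analysis_config()) {
  findings <- character()
  ids <- d$subjects$subject_id
  for (id in ids) {
    r <- d$recordings[[id]]
    if (is.null(r)) {
      findings <- c(findings, sprintf("subject %s: no recording", id))
      next
    }
    need <- schedule_end(d$schedule) + cfg$post_baseline_s
    have <- r$start_time + recording_duration(r)
    if (have < need - 1e-9)
      findings <- c(findings,
                    sprintf("subject %s: recording ends at %g s but %g s needed for the post-task baseline",
                            id, have, need))
    first_act <- min(activation_blocks(d$schedule)$onset)
    if (r$start_time > first_act - cfg$pre_baseline_s + 1e-9)
      findings <- c(findings,
                    sprintf("subject %s: recording starts too late for the pre-task baseline", id))
  }
  extra <- setdiff(names(d$recordings), ids)
  if (length(extra))
    findings <- c(findings,
                  sprintf("recording without subject row: %s", extra))
  findings
}
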