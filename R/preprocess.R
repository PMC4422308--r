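# Signal chain for block analysis, applied in this fixed order:
#   MBLL (if OD input) -> moving average -> epoch extraction ->
#   integral-mode baseline correction -> repetition average ->
#   activation-window statistic.
# Filtering precedes epoching so the smoothing window never mixes data
# across epoch boundaries differently between repetitions.

#' Centered moving-average filter
#'
#' Smooths each row of \code{x} with a centered boxcar of
#' \code{2*floor(window_s*fs/2)+1} samples (51 samples for a 5 s window at
#' 10 Hz). Near the edges the window shrinks to the available samples, so
#' output length equals input length and a constant series passes
#' unchanged.
#'
#' @param x Numeric vector or channels x samples matrix.
#' @param window_s Window length in seconds (> 0).
#' @param fs Sampling rate, Hz.
#' @return Filtered object of the same shape.
#' @export
moving_average <- function(x, window_s, fs) {
  if (window_s <= 0) stop("moving-average window must be positive")
  if (is.null(dim(x))) return(drop(moving_average(matrix(x, nrow = 1L), window_s, fs)))
  h <- floor(window_s * fs / 2)
  n <- ncol(x)
  if (h == 0L || n == 1L) return(x)
  # running sums via cumulative sums per row; truncated window at edges
  cs <- cbind(0, t(apply(x, 1L, cumsum)))
  idx <- seq_len(n)
  hi <- pmin(idx + h, n)
  lo <- pmax(idx - h, 1L)
  out <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    matrix(hi - lo + 1, nrow = nrow(x), ncol = n, byrow = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Apply the moving average to every layer of a recording
#' @param r A \code{nirs_recording}.
#' @param window_s Window length, seconds.
#' @return Filtered \code{nirs_recording}.
#' @export
filter_recording <- function(r, window_s) {
  r$data <- lapply(r$data, moving_average, window_s = window_s,
                   fs = r$sampling_rate)
  r
}

#' Single activation epoch
#'
#' A channels x samples slice covering
#' \code{[onset - pre, onset + duration + post)} around one activation
#' block.
#'
#' @param data Channels x samples matrix.
#' @param onset,duration Activation block timing, seconds.
#' @param pre,post Baseline margins, seconds.
#' @param fs Sampling rate, Hz.
#' @return Object of class \code{nirs_epoch}.
#' @export
nirs_epoch <- function(data, onset, duration, pre, post, fs) {
  n_expect <- round((pre + duration + post) * fs)
  stopifnot(is.matrix(data), ncol(data) == n_expect)
  structure(list(data = data, onset = onset, duration = duration,
                 pre = pre, post = post, fs = fs),
            class = "nirs_epoch")
}

epoch_windows <- function(e) {
  n <- ncol(e$data)
  n_pre <- round(e$pre * e$fs)
  n_post <- round(e$post * e$fs)
  n_task <- n - n_pre - n_post
  list(pre = seq_len(n_pre),
       task = n_pre + seq_len(n_task),
       post = n - n_post + seq_len(n_post))
}

#' Extract activation epochs from a recording
#'
#' One epoch per activation block, each spanning the pre-task baseline, the
#' task block, and the post-task baseline. Windows are half-open in time;
#' samples are indexed 0-based at \code{t = start_time + i/fs}.
#'
#' @param r A \code{nirs_recording} in hemoglobin units.
#' @param s A \code{task_schedule}.
#' @param cfg An \code{analysis_config}.
#' @param layer Which signal layer to epoch (default \code{"oxy"}).
#' @return List of \code{nirs_epoch}, one per activation block.
#' @export
extract_epochs <- function(r, s, cfg = analysis_config(), layer = "oxy") {
  if (r$unit != HB_UNIT)
    stop("extract_epochs expects a hemoglobin-unit recording; convert first")
  acts <- activation_blocks(s)
  if (nrow(acts) == 0L) stop("schedule has no activation blocks")
  fs <- r$sampling_rate
  m <- r$data[[layer]]
  lapply(seq_len(nrow(acts)), function(k) {
    onset <- acts$onset[k]; dur <- acts$duration[k]
    i0 <- round((onset - cfg$pre_baseline_s - r$start_time) * fs)
    n <- round((cfg$pre_baseline_s + dur + cfg$post_baseline_s) * fs)
    if (i0 < 0 || i0 + n > ncol(m))
      stop(sprintf("epoch out of bounds: activation block at %g s needs samples outside the recording",
                   onset))
    nirs_epoch(m[, i0 + seq_len(n), drop = FALSE], onset, dur,
               cfg$pre_baseline_s, cfg$post_baseline_s, fs)
  })
}

#' Integral-mode baseline correction
#'
#' Per channel, computes the mean over the pre-task baseline window and the
#' mean over the post-task baseline window, anchors these values at the
#' time midpoints of the two windows, and subtracts the straight line
#' through the anchors from the whole epoch. Afterwards both baseline
#' windows have mean zero by construction, and any linear drift in the
#' input is removed exactly.
#'
#' @param e A \code{nirs_epoch}.
#' @return A \code{corrected_epoch}: the epoch plus per-channel anchor
#'   values \code{m_pre}, \code{m_post} and anchor sample positions.
#' @export
integral_correct <- function(e) {
  w <- epoch_windows(e)
  if (length(w$pre) == 0L || length(w$post) == 0L)
    stop("zero-length baseline window")
  x <- seq_len(ncol(e$data)) - 1      # sample index, 0-based
  m_pre <- rowMeans(e$data[, w$pre, drop = FALSE])
  m_post <- rowMeans(e$data[, w$post, drop = FALSE])
  x_pre <- mean(w$pre - 1)
  x_post <- mean(w$post - 1)
  slope <- (m_post - m_pre) / (x_post - x_pre)
  # line value at sample x: m_pre + slope * (x - x_pre), per channel
  baseline <- outer(slope, x - x_pre) + m_pre
  out <- e
  out$data <- e$data - baseline
  out$pre_anchor <- list(x = x_pre, value = m_pre)
  out$post_anchor <- list(x = x_post, value = m_post)
  class(out) <- c("corrected_epoch", "nirs_epoch")
  out
}

#' Average corrected epochs pointwise
#' @param epochs Non-empty list of \code{corrected_epoch} of equal shape.
#' @return A \code{corrected_epoch} holding the arithmetic mean.
#' @export
average_epochs <- function(epochs) {
  if (length(epochs) == 0L) stop("cannot average an empty epoch list")
  shapes <- vapply(epochs, function(e) paste(dim(e$data), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) stop("epochs differ in shape")
  out <- epochs[[1L]]
  out$data <- Reduce(`+`, lapply(epochs, `[[`, "data")) / length(epochs)
  out
}

#' Activation-window channel statistic
#'
#' Mean of the corrected signal over the activation window
#' \code{[onset, onset+duration)}, per channel. Because the corrected
#' baseline windows average to zero, this equals the task-minus-baseline
#' difference the channel comparison table summarizes.
#'
#' @param e A \code{corrected_epoch}.
#' @return Numeric vector, one value per channel (mM*mm).
#' @export
task_statistic <- function(e) {
  w <- epoch_windows(e)
  rowMeans(e$data[, w$task, drop = FALSE])
}

#' Per-subject channel statistics through the full chain
#'
#' Runs moving-average filtering, epoch extraction, integral correction per
#' activation block, repetition averaging, and the activation-window
#' statistic for one recording.
#'
#' @param r A \code{nirs_recording} (OD input is converted first).
#' @param s A \code{task_schedule}.
#' @param cfg An \code{analysis_config}.
#' @param ext Extinction table for OD conversion.
#' @return Numeric vector of per-channel statistics (mM*mm).
#' @export
subject_channel_statistics <- function(r, s, cfg = analysis_config(),
                                       ext = extinction_table()) {
  e <- subject_average_epoch(r, s, cfg, ext)
  task_statistic(e)
}

#' Repetition-averaged corrected epoch for one subject
#' @inheritParams subject_channel_statistics
#' @return A \code{corrected_epoch} averaged over activation blocks.
#' @export
subject_average_epoch <- function(r, s, cfg = analysis_config(),
                                  ext = extinction_table()) {
  r <- recording_to_hb(r, ext)
  r <- filter_recording(r, cfg$moving_avg_s)
  eps <- extract_epochs(r, s, cfg)
  average_epochs(lapply(eps, integral_correct))
}

#' Group grand-average waveform
#'
#' Pointwise mean and standard error across subjects of the
#' repetition-averaged corrected epochs.
#'
#' @param epochs Non-empty list of \code{corrected_epoch}, one per subject,
#'   equal shapes.
#' @return List with \code{mean} and \code{se} (channels x samples
#'   matrices; \code{se} is NA with a single subject), plus \code{n} and
#'   the epoch time axis \code{time} (seconds relative to block onset).
#' @export
grand_average <- function(epochs) {
  if (length(epochs) == 0L) stop("cannot grand-average an empty group")
  n <- length(epochs)
  mats <- lapply(epochs, `[[`, "data")
  m <- Reduce(`+`, mats) / n
  if (n > 1L) {
    ss <- Reduce(`+`, lapply(mats, function(x) (x - m)^2))
    se <- sqrt(ss / (n - 1L)) / sqrt(n)
  } else {
    se <- m * NA_real_
  }
  e1 <- epochs[[1L]]
  time <- (seq_len(ncol(m)) - 1L) / e1$fs - e1$pre
  list(mean = m, se = se, n = n, time = time)
}
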