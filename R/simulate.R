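# Synthetic two-group block-design fNIRS study generator.
#
# Each subject's oxy-Hb channel signal is
#   A_sc * (activation boxcar convolved with a double-gamma HRF)
#   + linear drift + physiological sinusoids + white noise + motion spikes,
# with A_sc = A_c + N(0, sd_c^2) drawn per subject and channel. Amplitudes
# are expressed on the task-statistic scale: they are divided by the
# attenuation the analysis chain applies to a unit-amplitude response, so
# the expected activation-window statistic of channel c equals A_c.

#' Reference per-channel group effect profiles
#'
#' Default per-channel task-response amplitudes for the two simulated arms,
#' emulating the published per-channel group means and standard errors of
#' a pediatric Tourette-versus-control prefrontal Stroop study (24
#' channels, n = 10 per group; the attenuated left-DLPFC response of the
#' case arm sits around channels 7-13). Two entries of the source table are
#' garbled in print (channel 5 SE, channel 24 case mean) and are restored
#' to the magnitude range of their columns.
#'
#' @return Data.frame with columns \code{channel, case_mean, case_se,
#'   control_mean, control_se} (mM*mm, SE at n = 10).
#' @export
reference_effect_profiles <- function() {
  data.frame(
    channel = 1:24,
    case_mean = c(0.0024, -0.0078, 0.0211, 0.0093, 0.0186, -0.0136,
                  -0.0283, -0.0054, 0.0044, -0.0035, -0.0035, -0.0202,
                  -0.0332, 0.0039, -0.0019, -0.0083, 0.0151, 0.0131,
                  -0.0208, 0.0018, 0.0183, -0.0134, -0.0219, -0.0164),
    case_se = c(0.0214, 0.0157, 0.0123, 0.0220, 0.0149, 0.0140,
                0.0145, 0.0211, 0.0169, 0.0210, 0.0210, 0.0368,
                0.0116, 0.0231, 0.0228, 0.0213, 0.0138, 0.0197,
                0.0281, 0.0320, 0.0301, 0.0202, 0.0264, 0.0227),
    control_mean = c(0.0199, 0.0290, 0.0485, 0.0228, 0.0308, -0.0016,
                     0.0393, 0.0190, 0.0342, 0.0454, 0.0454, 0.0387,
                     0.0188, 0.0319, 0.0470, 0.0340, 0.0283, 0.0651,
                     0.0379, 0.0089, 0.0458, 0.0426, 0.0348, 0.0341),
    control_se = c(0.0148, 0.0216, 0.0147, 0.0132, 0.0133, 0.0095,
                   0.0137, 0.0117, 0.0111, 0.0079, 0.0079, 0.0126,
                   0.0099, 0.0051, 0.0090, 0.0055, 0.0056, 0.0146,
                   0.0144, 0.0127, 0.0103, 0.0167, 0.0165, 0.0112))
}

#' Group effect profile
#'
#' Per-channel task-response amplitudes (on the task-statistic scale,
#' mM*mm) and between-subject amplitude SDs for one simulated arm.
#'
#' @param amplitude Numeric vector of per-channel amplitudes.
#' @param sd Numeric vector (or scalar) of between-subject SDs, >= 0.
#' @return List of class \code{group_effect_profile}.
#' @export
group_effect_profile <- function(amplitude, sd) {
  sd <- rep_len(sd, length(amplitude))
  if (any(sd < 0)) stop("between-subject SDs must be non-negative")
  structure(list(amplitude = amplitude, sd = sd),
            class = "group_effect_profile")
}

default_effect_profiles <- function() {
  ref <- reference_effect_profiles()
  list(case = group_effect_profile(ref$case_mean, ref$case_se * sqrt(10)),
       control = group_effect_profile(ref$control_mean,
                                      ref$control_se * sqrt(10)))
}

#' Physiological and instrumental noise model
#'
#' @param white_sd White-noise SD per sample, mM*mm (default 0.02).
#' @param drift_slope_sd SD of the per-subject/channel linear drift slope,
#'   mM*mm per second (default 5e-4).
#' @param sinusoids Data.frame \code{freq} (Hz), \code{amp} (mM*mm);
#'   defaults cover Mayer waves (~0.1 Hz), respiration (~0.25 Hz) and the
#'   cardiac pulse (~1.1 Hz), each with a random phase per channel.
#' @param spike_rate_per_min Motion-spike Poisson rate (default 2).
#' @param spike_amp_sd SD of the signed spike amplitudes, mM*mm
#'   (default 0.1).
#' @param spike_decay_s Exponential decay constant of a spike, s
#'   (default 1).
#' @return List of class \code{noise_model}.
#' @export
noise_model <- function(white_sd = 0.02, drift_slope_sd = 5e-4,
                        sinusoids = data.frame(
                          freq = c(0.10, 0.25, 1.10),
                          amp = c(0.010, 0.008, 0.005)),
                        spike_rate_per_min = 2, spike_amp_sd = 0.1,
                        spike_decay_s = 1) {
  if (white_sd < 0 || drift_slope_sd < 0 || spike_amp_sd < 0 ||
      spike_rate_per_min < 0)
    stop("noise parameters must be non-negative")
  structure(list(white_sd = white_sd, drift_slope_sd = drift_slope_sd,
                 sinusoids = sinusoids,
                 spike_rate_per_min = spike_rate_per_min,
                 spike_amp_sd = spike_amp_sd, spike_decay_s = spike_decay_s),
            class = "noise_model")
}

#' Simulation configuration
#'
#' @param n_per_group Subjects per arm (default 10, >= 2).
#' @param schedule A \code{task_schedule} (default the canonical Stroop
#'   alternation).
#' @param effects List with \code{case} and \code{control}
#'   \code{group_effect_profile}s; default: the reference profiles with
#'   between-subject SD = published SE * sqrt(10).
#' @param noise A \code{noise_model}.
#' @param hrf_peak_s,hrf_undershoot_s,hrf_undershoot_ratio Double-gamma
#'   response parameters (defaults 6 s, 16 s, 1/6).
#' @param fs Sampling rate, Hz (default 10).
#' @param duration_s Recording length, seconds; default schedule end plus
#'   30 s so the post-task baseline always fits.
#' @param emit_unit \code{"hb_mM_mm"} (default) or \code{"optical_density"}.
#' @param calibrate If TRUE (default), amplitudes are interpreted on the
#'   task-statistic scale (divided by the analysis-chain attenuation of a
#'   unit response); if FALSE they scale the convolved regressor directly.
#' @param deoxy_ratio Deoxy task response as a (negative) fraction of the
#'   oxy response (default -1/3).
#' @param analysis_cfg \code{analysis_config} used for calibration.
#' @param seed Mandatory integer root seed.
#' @return List of class \code{simulation_config}.
#' @export
simulation_config <- function(n_per_group = 10,
                              schedule = default_stroop_schedule(),
                              effects = default_effect_profiles(),
                              noise = noise_model(),
                              hrf_peak_s = 6, hrf_undershoot_s = 16,
                              hrf_undershoot_ratio = 1 / 6,
                              fs = 10,
                              duration_s = schedule_end(schedule) + 30,
                              emit_unit = HB_UNIT,
                              calibrate = TRUE,
                              deoxy_ratio = -1 / 3,
                              analysis_cfg = analysis_config(),
                              seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  stopifnot(length(effects$case$amplitude) == length(effects$control$amplitude))
  if (any(noise$sinusoids$freq >= fs / 2))
    stop("sinusoid frequencies must lie below the Nyquist rate")
  structure(list(n_per_group = n_per_group, schedule = schedule,
                 effects = effects, noise = noise,
                 hrf_peak_s = hrf_peak_s,
                 hrf_undershoot_s = hrf_undershoot_s,
                 hrf_undershoot_ratio = hrf_undershoot_ratio,
                 fs = fs, duration_s = duration_s, emit_unit = emit_unit,
                 calibrate = calibrate, deoxy_ratio = deoxy_ratio,
                 analysis_cfg = analysis_cfg, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Canonical double-gamma hemodynamic response kernel
#'
#' Difference of two gamma-shaped bumps (peak minus scaled undershoot),
#' normalized so the kernel maximum is exactly 1; zero at t = 0 and
#' decaying to zero at large t.
#'
#' @param t_grid Uniform non-negative time grid, seconds.
#' @param peak_s Response peak time (default 6 s).
#' @param undershoot_s Undershoot peak time (default 16 s).
#' @param undershoot_ratio Undershoot depth relative to the peak
#'   (default 1/6).
#' @return Numeric kernel values on \code{t_grid}.
#' @export
canonical_hrf <- function(t_grid, peak_s = 6, undershoot_s = 16,
                          undershoot_ratio = 1 / 6) {
  if (any(t_grid < 0)) stop("t_grid must be non-negative")
  if (length(t_grid) > 2) {
    dt <- diff(t_grid)
    if (max(dt) - min(dt) > 1e-9) stop("t_grid must be uniform")
  }
  bump <- function(t, m) ifelse(t <= 0, 0, exp(m * log(t / m) + (m - t)))
  h <- bump(t_grid, peak_s) - undershoot_ratio * bump(t_grid, undershoot_s)
  h / max(h)
}

# Activation boxcar convolved with the HRF, on the recording grid.
task_regressor <- function(cfg) {
  n <- round(cfg$duration_s * cfg$fs)
  t <- (seq_len(n) - 1L) / cfg$fs
  box <- rep(0, n)
  acts <- activation_blocks(cfg$schedule)
  for (k in seq_len(nrow(acts)))
    box[t >= acts$onset[k] & t < acts$onset[k] + acts$duration[k]] <- 1
  klen <- round(40 * cfg$fs)        # 40 s kernel support
  kern <- canonical_hrf((seq_len(klen) - 1L) / cfg$fs,
                        cfg$hrf_peak_s, cfg$hrf_undershoot_s,
                        cfg$hrf_undershoot_ratio)
  kern <- kern / sum(kern)   # unit gain: a sustained boxcar plateaus at 1
  out <- stats::filter(c(rep(0, klen), box), kern, method = "convolution",
                       sides = 1)
  as.numeric(out[klen + seq_len(n)])
}

#' Analysis-chain attenuation of a unit-amplitude response
#'
#' Runs a noiseless unit-amplitude convolved response through the full
#' analysis chain (moving average, epoching, integral correction,
#' repetition average, activation-window mean) and returns the resulting
#' statistic. Dividing requested amplitudes by this factor makes the
#' expected task statistic equal the requested value.
#'
#' @param cfg A \code{simulation_config}.
#' @return Scalar attenuation factor.
#' @export
attenuation_factor <- function(cfg) {
  reg <- task_regressor(cfg)
  r <- nirs_recording("unit", list(oxy = matrix(reg, nrow = 1L),
                                   deoxy = matrix(0 * reg, nrow = 1L)),
                      sampling_rate = cfg$fs, unit = HB_UNIT)
  unname(subject_channel_statistics(r, cfg$schedule, cfg$analysis_cfg))
}

# Deterministic child seed for (root seed, stream counter); keeps every
# subject reproducible independently of generation order.
child_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 10007 + counter) %% 2147483647)
}

rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

#' Simulate one subject's recording
#'
#' Deterministic given \code{(cfg$seed, group, subject_index)}.
#'
#' @param group \code{"case"} or \code{"control"}.
#' @param cfg A \code{simulation_config}.
#' @param subject_index 1-based subject index within the group.
#' @param regressor Optional precomputed \code{task_regressor(cfg)}.
#' @param attenuation Optional precomputed \code{attenuation_factor(cfg)}.
#' @return A \code{nirs_recording} in \code{cfg$emit_unit} units.
#' @export
simulate_subject <- function(group, cfg, subject_index,
                             regressor = task_regressor(cfg),
                             attenuation = attenuation_factor(cfg)) {
  group <- match.arg(group, c("case", "control"))
  prof <- cfg$effects[[group]]
  nch <- length(prof$amplitude)
  n <- length(regressor)
  t <- (seq_len(n) - 1L) / cfg$fs
  offset <- if (group == "case") 0L else 1000L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(child_seed(cfg$seed, offset + subject_index))
  amp <- prof$amplitude + stats::rnorm(nch, 0, prof$sd)
  gain <- if (cfg$calibrate) amp / attenuation else amp
  oxy <- outer(gain, regressor)
  deoxy <- cfg$deoxy_ratio * oxy
  nm <- cfg$noise
  if (nm$drift_slope_sd > 0)
    oxy <- oxy + outer(stats::rnorm(nch, 0, nm$drift_slope_sd), t)
  for (k in seq_len(nrow(nm$sinusoids))) {
    phase <- stats::runif(nch, 0, 2 * pi)
    oxy <- oxy + nm$sinusoids$amp[k] *
      sin(outer(rep(2 * pi * nm$sinusoids$freq[k], nch), t) + phase)
  }
  if (nm$white_sd > 0)
    oxy <- oxy + matrix(stats::rnorm(nch * n, 0, nm$white_sd), nch, n)
  if (nm$spike_rate_per_min > 0) {
    n_spk <- stats::rpois(1, nm$spike_rate_per_min * cfg$duration_s / 60)
    if (n_spk > 0) {
      times <- stats::runif(n_spk, 0, cfg$duration_s)
      for (te in times) {
        a <- stats::rnorm(nch, 0, nm$spike_amp_sd)
        tail_idx <- which(t >= te)
        decay <- exp(-(t[tail_idx] - te) / nm$spike_decay_s)
        oxy[, tail_idx] <- oxy[, tail_idx] + outer(a, decay)
      }
    }
  }
  if (nm$white_sd > 0)
    deoxy <- deoxy + matrix(stats::rnorm(nch * n, 0, nm$white_sd / 2), nch, n)
  id <- sprintf("%s%02d", if (group == "case") "case" else "ctrl",
                subject_index)
  rec <- nirs_recording(id, list(oxy = oxy, deoxy = deoxy),
                        sampling_rate = cfg$fs, unit = HB_UNIT)
  if (cfg$emit_unit == OD_UNIT) rec <- recording_to_od(rec) else rec
}

simulate_covariates <- function(cfg) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(child_seed(cfg$seed, 999999L))
  np <- cfg$n_per_group
  mk <- function(group) {
    case <- group == "case"
    scwc_m <- if (case) c(26.8, 26.1, 27.2) else c(42.7, 40.2, 37.7)
    scwc_s <- if (case) c(11.14, 10.21, 12.74) else c(9.78, 8.77, 8.11)
    subject_table(
      subject_id = sprintf("%s%02d", if (case) "case" else "ctrl",
                           seq_len(np)),
      group = rep(group, np),
      age = round(rtruncnorm(np, if (case) 9.20 else 9.50,
                             if (case) 2.25 else 2.12, 6, 15), 1),
      fiq = round(rtruncnorm(np, if (case) 99.8 else 97.3,
                             if (case) 15.32 else 9.90, 50, 150)),
      ygtss = if (case) round(rtruncnorm(np, 18.0, 6.75, 0, 50))
              else NA_real_,
      scwc1 = round(rtruncnorm(np, scwc_m[1], scwc_s[1], 0, Inf)),
      scwc2 = round(rtruncnorm(np, scwc_m[2], scwc_s[2], 0, Inf)),
      scwc3 = round(rtruncnorm(np, scwc_m[3], scwc_s[3], 0, Inf)),
      medicated = if (case) stats::runif(np) < 0.3 else NA,
      comorbid = if (case) stats::runif(np) < 0.5 else NA)
  }
  rbind(mk("case"), mk("control"))
}

#' Simulate a complete two-group study
#'
#' Generates covariates and one recording per subject for both arms;
#' \code{\link{validate_dataset}} of the result is empty for every seed.
#'
#' @param cfg A \code{simulation_config}.
#' @return A \code{study_dataset}.
#' @export
simulate_study <- function(cfg) {
  subjects <- simulate_covariates(cfg)
  reg <- task_regressor(cfg)
  att <- attenuation_factor(cfg)
  recs <- list()
  for (grp in c("case", "control"))
    for (i in seq_len(cfg$n_per_group)) {
      r <- simulate_subject(grp, cfg, i, regressor = reg, attenuation = att)
      recs[[r$subject_id]] <- r
    }
  study_dataset(subjects, recs, cfg$schedule)
}
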