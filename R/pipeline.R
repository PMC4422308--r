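# End-to-end orchestration: simulate -> analyze -> report, with flat-file
# outputs and a JSON run manifest so identical inputs reproduce identical
# tables.

file_sha <- function(path) {
  # dependency-light content fingerprint: size plus a polynomial hash of
  # the bytes, enough to detect input drift between runs
  bytes <- readBin(path, "raw", file.info(path)$size)
  ints <- as.integer(bytes)
  h <- 0
  for (chunk in split(ints, ceiling(seq_along(ints) / 4096)))
    h <- (h * 31 + sum(chunk * (seq_along(chunk) %% 97 + 1))) %% 2147483647
  sprintf("%d-%d", length(bytes), h)
}

pkg_version <- function() {
  as.character(utils::packageVersion("fnirsblock"))
}

#' Simulate a study and write it to disk
#'
#' Writes the full dataset in the package's interchange formats plus a
#' manifest recording the configuration and seed.
#'
#' @param cfg A \code{simulation_config}.
#' @param out_dir Output directory.
#' @return The \code{study_dataset}, invisibly.
#' @export
run_simulate <- function(cfg, out_dir) {
  d <- simulate_study(cfg)
  write_study(d, out_dir)
  manifest <- list(
    kind = "simulation",
    seed = cfg$seed,
    n_per_group = cfg$n_per_group,
    emit_unit = cfg$emit_unit,
    fs = cfg$fs,
    duration_s = cfg$duration_s,
    package_version = pkg_version(),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(d)
}

#' Run the full analysis on a study dataset
#'
#' Validates the dataset, runs the per-subject signal chain, and writes the
#' output bundle: \code{channel_table.csv}, \code{demographics.csv},
#' \code{correlations.csv}, per-group grand-average waveform CSVs, the
#' topographic t-map grid, and a run manifest with input fingerprints.
#' Identical inputs and configuration reproduce identical tables.
#'
#' @param d A \code{study_dataset} (or a directory path readable by
#'   \code{\link{read_study}}).
#' @param cfg An \code{analysis_config}.
#' @param out_dir Output directory.
#' @param unit Recording unit when \code{d} is a directory path.
#' @return Invisible list of the computed tables.
#' @export
run_analyze <- function(d, cfg = analysis_config(), out_dir,
                        unit = HB_UNIT) {
  input_dir <- NULL
  if (is.character(d)) { input_dir <- d; d <- read_study(d, unit = unit) }
  findings <- validate_dataset(d, cfg)
  if (length(findings))
    stop(paste(c("dataset validation failed:", findings), collapse = "\n  "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  groups <- split(d$subjects$subject_id, d$subjects$group)
  epochs <- lapply(d$recordings, subject_average_epoch, s = d$schedule,
                   cfg = cfg)
  stats_mat <- t(vapply(epochs, task_statistic,
                        numeric(d$recordings[[1L]]$n_channels)))
  case_mat <- stats_mat[groups$case, , drop = FALSE]
  ctrl_mat <- stats_mat[groups$control, , drop = FALSE]

  channel_tab <- build_channel_table(case_mat, ctrl_mat, cfg)
  demo_tab <- build_demographics_table(d$subjects)
  corr_tab <- build_correlation_table(d$subjects)

  ga <- lapply(groups, function(ids) grand_average(epochs[ids]))
  df <- nrow(case_mat) + nrow(ctrl_mat) - 2L
  tmap <- interpolate_tmap(channel_tab$t)

  num <- function(x) format(x, digits = 15, scientific = TRUE, trim = TRUE)
  utils::write.csv(channel_tab, file.path(out_dir, "channel_table.csv"),
                   row.names = FALSE)
  utils::write.csv(demo_tab, file.path(out_dir, "demographics.csv"),
                   row.names = FALSE)
  utils::write.csv(corr_tab, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)
  for (grp in names(ga)) {
    g <- ga[[grp]]
    wide <- data.frame(time = g$time, t(g$mean))
    names(wide) <- c("time", sprintf("ch%02d", seq_len(nrow(g$mean))))
    utils::write.csv(num(wide),
                     file.path(out_dir, sprintf("grand_average_%s.csv", grp)),
                     row.names = FALSE, quote = FALSE)
    wide_se <- data.frame(time = g$time, t(g$se))
    names(wide_se) <- names(wide)
    utils::write.csv(num(wide_se),
                     file.path(out_dir, sprintf("grand_average_%s_se.csv", grp)),
                     row.names = FALSE, quote = FALSE)
  }
  write_tmap(tmap, file.path(out_dir, "topomap.csv"))
  sub_stats <- data.frame(subject_id = rownames(stats_mat), stats_mat)
  names(sub_stats) <- c("subject_id",
                        sprintf("ch%02d", seq_len(ncol(stats_mat))))
  utils::write.csv(num(sub_stats),
                   file.path(out_dir, "subject_statistics.csv"),
                   row.names = FALSE, quote = FALSE)

  manifest <- list(
    kind = "analysis",
    config = unclass(cfg),
    n_case = nrow(case_mat), n_control = nrow(ctrl_mat),
    df = df,
    display_levels = as.list(threshold_levels(df)),
    fdr_threshold = attr(channel_tab, "fdr_threshold"),
    package_version = pkg_version())
  if (!is.null(input_dir)) {
    files <- list.files(input_dir, full.names = TRUE)
    manifest$input_hashes <- stats::setNames(
      lapply(files, file_sha), basename(files))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(channel_table = channel_tab, demographics = demo_tab,
                 correlations = corr_tab, grand_averages = ga,
                 topomap = tmap, subject_statistics = stats_mat))
}

#' Render a human-readable summary of an analysis bundle
#'
#' @param bundle_dir Directory written by \code{\link{run_analyze}}.
#' @param file Connection or path for the text output (default stdout).
#' @return Invisibly, the lines printed.
#' @export
run_report <- function(bundle_dir, file = stdout()) {
  need <- file.path(bundle_dir, "channel_table.csv")
  if (!file.exists(need)) stop(sprintf("missing bundle file: %s", need))
  ch <- utils::read.csv(need)
  lines <- c("== Channel comparison (case vs control) ==",
             sprintf("%d channels; FDR-rejected: %s", nrow(ch),
                     if (any(ch$fdr)) paste(ch$channel[ch$fdr], collapse = ", ")
                     else "none"),
             sprintf("Ch %2d: case %+.4f  control %+.4f  t=%+.2f p=%.4f %s%s",
                     ch$channel, ch$mean_case, ch$mean_control, ch$t, ch$p,
                     ch$mark, ifelse(ch$fdr, " [FDR]", "")))
  demo_path <- file.path(bundle_dir, "demographics.csv")
  if (file.exists(demo_path)) {
    dm <- utils::read.csv(demo_path)
    lines <- c(lines, "", "== Demographics / behavior ==",
               sprintf("%-6s case %7.2f (%5.2f)  control %7.2f (%5.2f)  p=%s",
                       dm$variable, dm$mean_case, dm$sd_case,
                       dm$mean_control, dm$sd_control,
                       ifelse(is.na(dm$p), "-", sprintf("%.3f", dm$p))))
  }
  corr_path <- file.path(bundle_dir, "correlations.csv")
  if (file.exists(corr_path)) {
    co <- utils::read.csv(corr_path)
    lines <- c(lines, "", "== Covariate correlations (Spearman) ==",
               sprintf("%-7s %-5s ~ %-5s rho=%+.3f p=%.3f %s",
                       co$group, co$scwc, co$covariate, co$rho, co$p, co$mark))
  } else {
    lines <- c(lines, "", "(no correlations table in bundle)")
  }
  writeLines(lines, con = file)
  invisible(lines)
}
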