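# direct O(n*w) convolution oracle for the truncated centered moving average
naive_moving_average <- function(x, half) {
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - half):min(n, i + half)]), 0)
}

test_that("moving average matches a direct convolution oracle", {
  set.seed(21)
  x <- rnorm(200)
  expect_equal(moving_average(x, 5, 10), naive_moving_average(x, 25),
               tolerance = 1e-12)
  # 51-sample plateau of height 1/51 from an interior unit impulse
  imp <- rep(0, 200); imp[100] <- 1
  y <- moving_average(imp, 5, 10)
  expect_equal(y[75:125], rep(1 / 51, 51), tolerance = 1e-12)
  expect_equal(y[c(74, 126)], c(0, 0))
})

test_that("moving average passes DC and interior linear trends", {
  expect_equal(moving_average(rep(3.5, 100), 5, 10), rep(3.5, 100))
  t <- (0:499) / 10
  ramp <- 0.2 + 1.3 * t
  y <- moving_average(ramp, 5, 10)
  expect_equal(y[26:475], ramp[26:475], tolerance = 1e-10)
})

test_that("moving average handles matrices row-wise and rejects bad windows", {
  set.seed(22)
  m <- matrix(rnorm(300), nrow = 3)
  got <- moving_average(m, 2, 10)
  expect_equal(got[2, ], moving_average(m[2, ], 2, 10))
  expect_equal(dim(got), dim(m))
  expect_error(moving_average(m, 0, 10), "positive")
})

test_that("epoch extraction yields 800-sample epochs for the canonical run", {
  cfg <- analysis_config()
  s <- default_stroop_schedule(lead_in = 15)
  r <- make_recording(matrix(0, nrow = 2, ncol = 3600))
  eps <- extract_epochs(r, s, cfg)
  expect_length(eps, 3L)
  for (e in eps) expect_equal(ncol(e$data), (10 + 45 + 25) * 10)
  one <- task_schedule(c("baseline_word", "activation_color_word"),
                       c(15, 60), c(45, 45))
  expect_length(extract_epochs(r, one, cfg), 1L)
})

test_that("epochs outside the recording are rejected by block", {
  cfg <- analysis_config()
  s <- default_stroop_schedule(lead_in = 15)
  # ends 290 s in: 5 s after the last activation block, inside the post window
  r <- make_recording(matrix(0, nrow = 2, ncol = 2900))
  expect_error(extract_epochs(r, s, cfg), "epoch out of bounds.*240")
})

test_that("integral correction zeroes baselines and removes linear drift", {
  cfg <- analysis_config()
  fs <- 10
  n <- 800
  const <- nirs_epoch(matrix(7.7, 2, n), 60, 45, 10, 25, fs)
  cc <- integral_correct(const)
  expect_equal(max(abs(cc$data)), 0)
  # arbitrary linear drift, different per channel
  t <- (0:(n - 1)) / fs
  drift <- rbind(0.4 - 0.03 * t, -1.1 + 0.21 * t)
  cd <- integral_correct(nirs_epoch(drift, 60, 45, 10, 25, fs))
  expect_lt(max(abs(cd$data)), 1e-9)
  # baseline-window means are zero after correction
  set.seed(31)
  noisy <- integral_correct(nirs_epoch(matrix(rnorm(2 * n), 2, n),
                                       60, 45, 10, 25, fs))
  expect_lt(max(abs(rowMeans(noisy$data[, 1:100]))), 1e-10)
  expect_lt(max(abs(rowMeans(noisy$data[, 551:800]))), 1e-10)
})

test_that("a boxcar confined to the task window passes through correction", {
  fs <- 10; n <- 800; h <- 0.42
  m <- matrix(0, 1, n); m[1, 101:550] <- h
  ce <- integral_correct(nirs_epoch(m, 60, 45, 10, 25, fs))
  expect_equal(ce$data, m, tolerance = 1e-12)
  expect_equal(unname(task_statistic(ce)), h, tolerance = 1e-12)
})

test_that("epoch averaging is the pointwise mean", {
  fs <- 10; n <- 800
  mk <- function(v) integral_correct(nirs_epoch(
    matrix(0, 1, n) + rbind(c(rep(0, 100), rep(v, 450), rep(0, 250))),
    60, 45, 10, 25, fs))
  e1 <- mk(1); e2 <- mk(2); e3 <- mk(3)
  expect_equal(average_epochs(list(e1))$data, e1$data)
  neg <- e1; neg$data <- -e1$data
  expect_equal(max(abs(average_epochs(list(e1, neg))$data)), 0)
  expect_equal(unname(task_statistic(average_epochs(list(e1, e2, e3)))), 2,
               tolerance = 1e-12)
  expect_error(average_epochs(list()), "empty")
})

test_that("grand average reduces correctly for tiny groups", {
  fs <- 10; n <- 800
  set.seed(33)
  base <- integral_correct(nirs_epoch(matrix(rnorm(n), 1, n), 60, 45, 10, 25, fs))
  g1 <- grand_average(list(base))
  expect_equal(g1$mean, base$data)
  expect_true(all(is.na(g1$se)))
  mirrored <- base; mirrored$data <- -base$data
  g2 <- grand_average(list(base, mirrored))
  expect_equal(max(abs(g2$mean)), 0)
  expect_equal(g2$n, 2L)
  expect_error(grand_average(list()), "empty")
})

test_that("simulated control grand average rises during the task window", {
  cfg <- quiet_config(seed = 2, amp = rep(0.05, 24), sd = 0.005,
                      n_per_group = 3)
  d <- simulate_study(cfg)
  ids <- d$subjects$subject_id[d$subjects$group == "control"]
  epochs <- lapply(d$recordings[ids], subject_average_epoch, s = d$schedule)
  g <- grand_average(epochs)
  task_mean <- mean(g$mean[, 101:550])
  pre_mean <- mean(g$mean[, 1:100])
  expect_gt(task_mean, pre_mean + 0.02)
})

test_that("the chain is linear in the input and immune to global drift", {
  cfg <- analysis_config()
  s <- default_stroop_schedule()
  set.seed(35)
  m <- matrix(rnorm(4 * 3600, sd = 0.05), nrow = 4)
  r <- make_recording(m)
  stat <- subject_channel_statistics(r, s, cfg)
  r3 <- make_recording(3 * m)
  expect_equal(subject_channel_statistics(r3, s, cfg), 3 * stat,
               tolerance = 1e-10)
  t <- (0:3599) / 10
  drifted <- make_recording(m + matrix(rep(0.5 - 0.002 * t, each = 4), nrow = 4))
  expect_lt(max(abs(subject_channel_statistics(drifted, s, cfg) - stat)), 1e-8)
})
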