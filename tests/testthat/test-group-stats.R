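test_that("pooled t-test handles identical and degenerate groups", {
  x <- c(1, 2, 3, 4)
  r <- t_two_sample(x, x)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_equal(r$df, 6)
  expect_error(t_two_sample(rep(1, 3), rep(2, 3)), "degenerate variance")
  z <- t_two_sample(rep(1, 3), rep(1, 3))
  expect_equal(c(z$t, z$p), c(0, 1))
  expect_error(t_two_sample(1, c(1, 2)), "at least 2")
})

test_that("two-tailed p agrees with direct t-density integration", {
  set.seed(41)
  x <- rnorm(8) + 1
  y <- rnorm(9)
  r <- t_two_sample(x, y)
  dens <- function(u) (1 + u^2 / r$df)^(-(r$df + 1) / 2)
  norm_const <- integrate(dens, -Inf, Inf)$value
  tail <- integrate(dens, abs(r$t), Inf)$value / norm_const
  expect_equal(r$p, 2 * tail, tolerance = 1e-7)
})

test_that("t from raw data and from its summary statistics coincide", {
  set.seed(42)
  x <- rnorm(10, 0.5, 1.2)
  y <- rnorm(12, 0, 0.8)
  raw <- t_two_sample(x, y)
  summ <- t_from_summary(mean(x), sd(x), 10, mean(y), sd(y), 12, "sd")
  expect_equal(raw$t, summ$t, tolerance = 1e-12)
  expect_equal(raw$p, summ$p, tolerance = 1e-12)
  # SE form: SD recovered as SE * sqrt(n)
  se_form <- t_from_summary(mean(x), sd(x) / sqrt(10), 10,
                            mean(y), sd(y) / sqrt(12), 12, "se")
  expect_equal(se_form$t, raw$t, tolerance = 1e-12)
  # cross-check against the base equal-variance t-test
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(raw$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(raw$p, ref$p.value, tolerance = 1e-12)
})

test_that("group-label swap negates t and preserves p", {
  set.seed(43)
  x <- rnorm(7); y <- rnorm(9, 0.4)
  a <- t_two_sample(x, y); b <- t_two_sample(y, x)
  expect_equal(a$t, -b$t)
  expect_identical(a$p, b$p)
})

test_that("t-test p agrees with a 1e5-draw permutation oracle", {
  set.seed(44)
  x <- rnorm(10, 0.5)
  y <- rnorm(10)
  obs <- t_two_sample(x, y)
  z <- c(x, y)
  B <- 1e5
  idx <- matrix(replicate(B, sample.int(20L, 10L)), nrow = 10L)
  ss_tot <- sum(z^2); s_all <- sum(z)
  m1 <- colSums(matrix(z[idx], 10L)) / 10
  m2 <- (s_all - 10 * m1) / 10
  sp2 <- (ss_tot - 10 * m1^2 - 10 * m2^2) / 18
  t_perm <- (m1 - m2) / sqrt(sp2 * (1 / 10 + 1 / 10))
  p_perm <- mean(abs(t_perm) >= abs(obs$t) - 1e-12)
  expect_lt(abs(obs$p - p_perm), 0.02)
})

test_that("BH step-up matches hand enumeration and p.adjust", {
  r <- bh_fdr(c(0.001, 0.02, 0.03, 0.9), q = 0.05)
  expect_equal(r$rejected, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(r$threshold, 0.03)
  expect_equal(bh_fdr(rep(1, 10), 0.05)$rejected, rep(FALSE, 10))
  expect_equal(bh_fdr(numeric(0), 0.05)$rejected, logical(0))
  set.seed(45)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    mine <- bh_fdr(p, 0.05)$rejected
    expect_identical(mine, p.adjust(p, "BH") <= 0.05)
  }
})

test_that("BH rejection set never shrinks when a p-value decreases", {
  set.seed(46)
  for (i in 1:20) {
    p <- runif(12)
    before <- bh_fdr(p, 0.05)$rejected
    j <- sample(12, 1)
    p2 <- p; p2[j] <- p[j] * runif(1)
    after <- bh_fdr(p2, 0.05)$rejected
    # every hypothesis rejected before stays rejected
    expect_true(all(after[before]))
  }
})

test_that("significance marks follow the strict thresholds", {
  expect_equal(significance_mark(c(0.005, 0.07, 0.5, 0.02)),
               c("**", "+", "NS", "*"))
  # strict inequality at the boundaries
  expect_equal(significance_mark(c(0.01, 0.05, 0.1)), c("*", "+", "NS"))
})

test_that("Spearman correlation is rank-based with average ties", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_cor(x, exp(x))$rho, 1)
  expect_equal(spearman_cor(x, exp(x))$p, 0)
  expect_equal(spearman_cor(x, rev(x))$rho, -1)
  # tied data against the direct rank-formula oracle and cor.test
  xt <- c(1, 2, 2, 3, 5, 5, 5, 8)
  yt <- c(3, 1, 4, 4, 6, 2, 7, 7)
  r <- spearman_cor(xt, yt)
  ref <- suppressWarnings(cor.test(xt, yt, method = "spearman",
                                   exact = FALSE))
  expect_equal(r$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  expect_error(spearman_cor(rep(2, 5), 1:5), "zero rank variance")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("critical t values are monotone and approach the normal limit", {
  expect_gt(critical_t(18, 0.01), critical_t(18, 0.05))
  expect_gt(critical_t(5, 0.05), critical_t(30, 0.05))
  expect_lt(abs(critical_t(1e4, 0.05) - qnorm(0.975)), 0.005)
  expect_error(critical_t(18, 1.2), "alpha")
})

test_that("channel table wires means, tests, marks and FDR together", {
  set.seed(47)
  case <- matrix(rnorm(30, 0), 10, 3)
  ctrl <- matrix(rnorm(30, c(2, 0, 0)), 10, 3)
  ctrl[, 1] <- rnorm(10, 2, 0.5)
  tab <- build_channel_table(case, ctrl)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$df, rep(18, 3))
  expect_equal(tab$mean_case, colMeans(case))
  expect_equal(tab$se_case, apply(case, 2, sd) / sqrt(10))
  direct <- t_two_sample(case[, 1], ctrl[, 1])
  expect_equal(tab$t[1], direct$t, tolerance = 1e-12)
  expect_equal(tab$p[1], direct$p, tolerance = 1e-12)
  expect_identical(tab$fdr, bh_fdr(tab$p, 0.05)$rejected)
  expect_identical(tab$mark, significance_mark(tab$p))
  # single-channel montage degenerates to a single BH test
  one <- build_channel_table(case[, 1, drop = FALSE], ctrl[, 1, drop = FALSE])
  expect_equal(nrow(one), 1L)
  expect_identical(one$fdr, one$p <= 0.05)
  expect_error(build_channel_table(case[1, , drop = FALSE], ctrl), "at least 2")
})

test_that("null draws rarely produce FDR rejections", {
  set.seed(48)
  prof <- reference_effect_profiles()
  hits <- 0L
  for (b in 1:100) {
    a <- draw_channel_stats(prof$control_mean, prof$control_se)
    b2 <- draw_channel_stats(prof$control_mean, prof$control_se)
    hits <- hits + as.integer(any(build_channel_table(a, b2)$fdr))
  }
  # P(any BH rejection) = 0.05 under the complete null; 13/100 is > 3 SD
  expect_lte(hits, 13L)
})

test_that("the strongest reference channels dominate the comparison", {
  set.seed(49)
  prof <- reference_effect_profiles()
  tsum <- numeric(24)
  for (b in 1:200) {
    tab <- build_channel_table(
      draw_channel_stats(prof$case_mean, prof$case_se),
      draw_channel_stats(prof$control_mean, prof$control_se))
    tsum <- tsum + abs(tab$t)
  }
  expect_setequal(order(tsum, decreasing = TRUE)[1:2], c(7L, 13L))
})

test_that("demographics table reproduces group summaries and tests", {
  set.seed(50)
  subj <- subject_table(
    sprintf("s%02d", 1:8),
    rep(c("case", "control"), each = 4),
    age = c(9, 10, 8, 11, 9, 10, 8, 11),
    fiq = c(100, 95, 105, 98, 101, 96, 104, 99),
    ygtss = c(15, 20, 18, 22, NA, NA, NA, NA),
    scwc1 = c(20, 25, 22, 28, 40, 45, 38, 44),
    scwc2 = c(21, 26, 23, 29, 39, 42, 37, 41),
    scwc3 = c(22, 27, 24, 30, 38, 41, 36, 40))
  dm <- build_demographics_table(subj)
  expect_setequal(dm$variable, c("age", "fiq", "scwc1", "scwc2", "scwc3",
                                 "ygtss"))
  # identical group values give p = 1
  expect_equal(dm$p[dm$variable == "age"], 1)
  sc <- dm[dm$variable == "scwc1", ]
  ref <- t_two_sample(subj$scwc1[1:4], subj$scwc1[5:8])
  expect_equal(sc$p, ref$p)
  expect_true(is.na(dm$p[dm$variable == "ygtss"]))
  expect_error(build_demographics_table(subj[c(1, 5), ]), "at least 2")
})

test_that("correlation table covers both groups and marks findings", {
  set.seed(51)
  cfg <- quiet_config(seed = 99)
  subj <- simulate_study(cfg)$subjects
  ct <- build_correlation_table(subj)
  expect_setequal(unique(ct$group), c("case", "control"))
  expect_true(all(ct$rho >= -1 & ct$rho <= 1))
  # ygtss correlations only exist in the case group
  expect_false(any(ct$covariate == "ygtss" & ct$group == "control"))
  # monotone-transform invariance of the underlying statistic
  r1 <- spearman_cor(subj$age, subj$scwc1)
  r2 <- spearman_cor(rank(subj$age)^3, subj$scwc1)
  expect_equal(r1$rho, r2$rho)
})
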