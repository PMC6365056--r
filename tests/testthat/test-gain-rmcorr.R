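test_that("the gain curve is the logistic derivative with peak kA/4 at S0", {
  gp <- gain_params(A = 10, k = 2, S0 = 1, alpha0 = 30, alpha_scale = 5)
  alpha_star <- gp$alpha0 - gp$alpha_scale * gp$S0  # maps onto S = S0
  g <- gain_curve(alpha_star, gp)
  expect_equal(g$gain, gp$k * gp$A / 4, tolerance = 1e-12)
  expect_equal(g$output, gp$A / 2, tolerance = 1e-12)
  # peak location: the gain elsewhere is lower
  grid <- gain_curve(seq(5, 55, by = 0.5), gp)
  expect_lt(max(grid$gain), gp$k * gp$A / 4 + 1e-9)
  # larger amplitude at fixed slope: uniformly larger gain
  g_big <- gain_curve(seq(5, 55, by = 0.5), gain_params(A = 15, k = 2,
                                                        S0 = 1))
  g_small <- gain_curve(seq(5, 55, by = 0.5), gain_params(A = 10, k = 2,
                                                          S0 = 1))
  expect_true(all(g_big$gain > g_small$gain))
  # lower alpha maps onto higher endogenous input
  expect_gt(gain_curve(10, gp)$input, gain_curve(40, gp)$input)
})

test_that("overlapping bins follow the core-plus-half-width construction", {
  alpha <- sort(runif(100, 5, 40))
  ab <- assign_bins(alpha, n_bins = 10)
  sizes <- lengths(ab$bins)
  expect_equal(sizes, c(15, rep(20, 8), 15))
  # every trial belongs to at least one bin
  expect_setequal(unique(unlist(ab$bins)), seq_along(alpha))
  # strictly increasing alpha: strictly increasing medians
  expect_true(all(diff(ab$median_alpha) > 0))
  # order invariance
  set.seed(2)
  o <- sample(100)
  ab2 <- assign_bins(alpha[o])
  expect_equal(ab2$median_alpha, ab$median_alpha)
  expect_equal(sort(o[ab2$bins[[1]]]), sort(ab$bins[[1]]))
  # rank-based: affine rescaling leaves memberships unchanged
  ab3 <- assign_bins(3 * alpha + 7)
  expect_equal(lapply(ab3$bins, sort), lapply(ab$bins, sort))
  expect_error(assign_bins(runif(15)), "too few")
})

test_that("bin summaries reproduce a brute-force oracle and the noiseless gain", {
  cfg <- study_config(n_subjects = 1, blocks_per_condition = 1, seed = 12)
  sp <- sample_subject_params(1, seed = 12, gamma_noise_sd = 0)
  tab <- simulate_study(cfg, sp, seed = 12)
  b <- bin_summaries(tab, refit = "none")
  expect_equal(nrow(b), 20)  # 10 bins x 2 conditions
  for (cond in c("liberal", "conservative")) {
    ct <- tab[tab$condition == cond, ]
    ab <- assign_bins(ct$alpha)
    for (k in c(1, 5, 10)) {
      ref_gamma <- mean(gain_curve(ct$alpha[ab$bins[[k]]],
                                   sp[[1]]$gain[[cond]])$gain)
      got <- b$mean_gamma[b$condition == cond & b$bin == k]
      expect_equal(got, ref_gamma, tolerance = 1e-9)
      ref_alpha <- median(ct$alpha[ab$bins[[k]]])
      expect_equal(b$median_alpha[b$condition == cond & b$bin == k],
                   ref_alpha)
    }
  }
  # gain-generated data show an interior maximum at the group level
  gmat <- with(b[b$condition == "liberal", ], mean_gamma[order(bin)])
  expect_gt(which.max(gmat), 1)
  expect_lt(which.max(gmat), 10)
})

test_that("the Gaussian contrast weights sum to zero and score as defined", {
  w <- gaussian_contrast_weights()
  expect_identical(sum(w), 0)
  expect_length(w, 10)
  # flat profiles score exactly zero for every subject
  binned <- expand.grid(subject = 1:5, condition = "liberal", bin = 1:10)
  binned$mean_gamma <- 3.7
  scores <- vapply(1:5, function(s) {
    prof <- binned[binned$subject == s, ]
    sum(w * prof$mean_gamma[order(prof$bin)])
  }, 0)
  expect_equal(scores, rep(0, 5))
  # a profile equal to the weights scores sum(w^2)
  binned2 <- expand.grid(subject = 1:6, condition = "liberal", bin = 1:10)
  binned2$mean_gamma <- w[binned2$bin] + rnorm(60, 0, 1e-6)
  res <- gaussian_contrast_test(binned2)
  expect_equal(res$mean_score, sum(w^2), tolerance = 1e-3)
  expect_gt(res$F, 1e6)
  expect_lt(res$p, 1e-10)
})

test_that("the condition-by-bin interaction tests the profile difference", {
  set.seed(8)
  w <- gaussian_contrast_weights()
  binned <- expand.grid(subject = 1:8, condition = c("liberal",
                                                     "conservative"),
                        bin = 1:10)
  bump <- exp(-((1:10) - 5.5)^2 / 4)
  binned$mean_gamma <- ifelse(binned$condition == "liberal", 2, 1) *
    bump[binned$bin] + rnorm(nrow(binned), 0, 0.05)
  res <- gaussian_contrast_test(binned)
  expect_setequal(res$effect, c("liberal", "conservative", "interaction"))
  expect_lt(res$p[res$effect == "interaction"], 0.01)
  expect_gt(res$mean_score[res$effect == "liberal"],
            res$mean_score[res$effect == "conservative"])
  expect_error(gaussian_contrast_test(binned[binned$bin != 3, ]),
               "incomplete")
})

test_that("within-subject SEM removes additive subject offsets", {
  base <- expand.grid(subject = 1:6, condition = c("a", "b"), bin = 1:3)
  set.seed(3)
  base$y <- rnorm(nrow(base))
  shifted <- base
  shifted$y <- base$y + 10 * base$subject     # big additive offsets
  s1 <- within_subject_sem(base, "y")
  s2 <- within_subject_sem(shifted, "y")
  expect_equal(s1$sem, s2$sem, tolerance = 1e-12)
  # identical subjects: zero error bars
  const <- expand.grid(subject = 1:4, condition = "a", bin = 1:3)
  const$y <- const$bin * 2.0
  expect_equal(within_subject_sem(const, "y", cells = "bin")$sem,
               rep(0, 3), tolerance = 1e-12)
  # matches a brute-force Cousineau recomputation on a 3 x 2 toy
  toy <- expand.grid(subject = 1:3, condition = c("a", "b"))
  toy$y <- c(1, 4, 7, 3, 5, 6)
  got <- within_subject_sem(toy, "y", cells = "condition")
  cent <- toy$y - ave(toy$y, toy$subject) + mean(toy$y)
  ref <- tapply(cent, toy$condition, function(v) sd(v) / sqrt(3))
  expect_equal(got$sem, as.numeric(ref[as.character(got$condition)]))
  expect_error(within_subject_sem(toy[-1, ], "y", cells = "condition"),
               "balanced")
})

test_that("rmcorr reports the ANCOVA common slope with df = N k - N - 1", {
  set.seed(4)
  n_sub <- 14; k <- 10
  subject <- rep(1:n_sub, each = k)
  x <- rnorm(n_sub * k)
  y <- 0.5 * x + rep(rnorm(n_sub, sd = 3), each = k) + rnorm(n_sub * k, 0.3)
  res <- rmcorr(x, y, subject)
  expect_equal(res$df, 14 * 10 - 14 - 1)   # 125
  expect_gt(res$r, 0)
  # (near-)perfect within-subject linearity: r -> 1
  y2 <- x + rep(c(10, 20, 30), each = k)[seq_along(x)] +
    rnorm(length(x), sd = 1e-3)
  res2 <- rmcorr(x, y2, subject)
  expect_equal(res2$r, 1, tolerance = 1e-4)
  # 3-subject toy against hand-computed ANCOVA sums of squares
  xs <- c(1, 2, 3, 2, 4, 6, 1, 1, 4)
  ys <- c(2, 3, 5, 1, 2, 2, 8, 7, 9)
  ss <- rep(1:3, each = 3)
  cx <- xs - ave(xs, ss); cy <- ys - ave(ys, ss)
  b <- sum(cx * cy) / sum(cx^2)
  ss_x <- b^2 * sum(cx^2)
  ss_err <- sum((cy - b * cx)^2)
  ref_r <- sign(b) * sqrt(ss_x / (ss_x + ss_err))
  res3 <- rmcorr(xs, ys, ss)
  expect_equal(res3$r, ref_r, tolerance = 1e-12)
  expect_equal(res3$df, 9 - 3 - 1)
  # degenerate: no within-subject variance in x
  expect_error(rmcorr(rep(1:3, each = 3), ys, ss), "variance")
})

test_that("Cook's-distance refit drops gross outliers and counts df", {
  set.seed(6)
  n_sub <- 8; k <- 10
  subject <- rep(1:n_sub, each = k)
  x <- rnorm(n_sub * k)
  y <- 0.8 * x + rep(rnorm(n_sub), each = k) + rnorm(n_sub * k, sd = 0.3)
  clean <- cooks_refit(x, y, subject)
  base <- rmcorr(x, y, subject)
  if (clean$n_excluded == 0) {
    expect_equal(clean$r, base$r)
    expect_equal(clean$df, base$df)
  }
  y_out <- y; y_out[5] <- y[5] + 40
  res <- cooks_refit(x, y_out, subject)
  expect_true(5 %in% res$excluded)
  spoiled <- rmcorr(x, y_out, subject)
  expect_gt(res$r, spoiled$r)          # refit moves toward the clean value
  expect_equal(res$df, n_sub * k - res$n_excluded - n_sub - 1)
})

test_that("joint regression attributes gamma to the generating bias parameter", {
  set.seed(7)
  n_sub <- 14; k <- 10
  subject <- rep(1:n_sub, each = k)
  db <- rnorm(n_sub * k)
  sp <- rnorm(n_sub * k)               # orthogonal in expectation
  gamma <- 2 * db + rep(rnorm(n_sub), each = k) + rnorm(n_sub * k, sd = 0.5)
  res <- joint_bias_regression(gamma, db, sp, subject)
  expect_equal(res$df2, rep(n_sub * k - n_sub - 2, 2))  # 124 for 14 x 10
  Fdb <- res$partial_F[res$predictor == "drift_bias"]
  Fsp <- res$partial_F[res$predictor == "starting_point"]
  expect_gt(Fdb, 50)
  expect_lt(Fsp, 10)
  expect_error(joint_bias_regression(gamma, db, db, subject), "collinear")
})

test_that("the theta/gamma within-subject test isolates the gamma effect", {
  set.seed(11)
  n_sub <- 14; k <- 10
  subject <- rep(1:n_sub, each = k)
  theta <- rnorm(n_sub * k)
  gamma <- rnorm(n_sub * k)
  db <- 1.5 * gamma + rnorm(n_sub * k, sd = 0.4)
  res <- theta_gamma_anova(db, theta, gamma, subject)
  expect_equal(res$df2, rep(n_sub - 1, 3))
  expect_lt(res$p[res$effect == "gamma"], 1e-4)
  expect_gt(res$p[res$effect == "theta"], 0.01)
  # consistent relabelling of subjects leaves F unchanged
  relab <- c(8:14, 1:7)[subject]
  res2 <- theta_gamma_anova(db, theta, gamma, relab)
  expect_equal(sort(res2$F), sort(res$F), tolerance = 1e-10)
})
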