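test_that("the design is exact: block counts, alternation, proportions", {
  cfg <- study_config(n_subjects = 2, blocks_per_condition = 2,
                      trials_per_block = 240, p_target = 0.75, seed = 5)
  subs <- sample_subject_params(2, seed = 5)
  tab <- generate_behavior(cfg, subs)
  counts <- table(tab$subject, tab$block, tab$stimulus)
  expect_true(all(counts[, , "target"] == 180))
  expect_true(all(counts[, , "nontarget"] == 60))
  # conditions alternate within subject; first condition counterbalanced
  s1 <- unique(tab[tab$subject == 1, c("block", "condition")])
  expect_equal(s1$condition, rep(c("liberal", "conservative"), 2))
  s2 <- unique(tab[tab$subject == 2, c("block", "condition")])
  expect_equal(s2$condition, rep(c("conservative", "liberal"), 2))
  # totals reproduce the configured design
  expect_equal(nrow(tab), 2 * 4 * 240)
})

test_that("degenerate designs are rejected", {
  expect_error(study_config(p_target = 1), "strictly")
  expect_error(study_config(p_target = 0), "strictly")
  expect_error(study_config(trials_per_block = 239, p_target = 0.75),
               "integer")
  expect_error(study_config(n_subjects = 0), "subject")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- study_config(n_subjects = 1, blocks_per_condition = 1, seed = 9)
  subs <- sample_subject_params(1, seed = 9)
  a <- simulate_study(cfg, subs, seed = 3)
  b <- simulate_study(cfg, subs, seed = 3)
  d <- simulate_study(cfg, subs, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a$rt, d$rt))
})

test_that("neural scalars carry the condition structure", {
  cfg <- study_config(n_subjects = 4, blocks_per_condition = 3, seed = 2)
  subs <- sample_subject_params(4, seed = 2)
  tab <- simulate_study(cfg, subs, seed = 2)
  m <- aggregate(cbind(alpha, theta) ~ condition, tab, mean)
  lib <- m[m$condition == "liberal", ]
  con <- m[m$condition == "conservative", ]
  expect_lt(lib$alpha, con$alpha)   # liberal alpha suppressed
  expect_gt(lib$theta, con$theta)   # liberal theta elevated
  expect_true(all(tab$alpha > 0))
  expect_true(all(is.finite(tab$gamma_mod)))
})

test_that("noiseless coupling makes gamma the exact gain-curve value", {
  cfg <- study_config(n_subjects = 1, blocks_per_condition = 1, seed = 6)
  sp <- sample_subject_params(1, seed = 6, gamma_noise_sd = 0)
  tab <- simulate_study(cfg, sp, seed = 6)
  for (cond in c("liberal", "conservative")) {
    sub <- tab[tab$condition == cond, ]
    expect_equal(sub$gamma_mod,
                 gain_curve(sub$alpha, sp[[1]]$gain[[cond]])$gain,
                 tolerance = 1e-12)
  }
})

test_that("subject parameter constraints hold by construction", {
  subs <- sample_subject_params(20, seed = 31)
  for (sp in subs) {
    expect_lt(sp$alpha_meanlog[["liberal"]],
              sp$alpha_meanlog[["conservative"]])
    expect_gte(sp$gain$liberal$A, sp$gain$conservative$A)
    expect_identical(sp$ddm$liberal$z_frac, sp$ddm$conservative$z_frac)
  }
})

test_that("raw epochs carry the injected oscillations", {
  raw <- generate_raw_trials(n_trials = 2, n_channels = 3, fs = 256,
                             seed = 8, noise_amp = 0)
  expect_equal(dim(raw$data), c(2, 3, length(raw$times)))
  expect_true(min(raw$times) <= -1 && max(raw$times) >= 1.25)
  # amplitude doubling quadruples band power (power ~ amplitude^2)
  r1 <- generate_raw_trials(n_trials = 1, n_channels = 2, fs = 256,
                            seed = 3, noise_amp = 0,
                            alpha_amp_conservative = 1,
                            condition = "conservative")
  r2 <- generate_raw_trials(n_trials = 1, n_channels = 2, fs = 256,
                            seed = 3, noise_amp = 0,
                            alpha_amp_conservative = 2,
                            condition = "conservative")
  bandpow <- function(r) {
    x <- r$data[1, 1, r$times < 0]
    f <- seq(0, r$fs, length.out = length(x) + 1)[seq_along(x)]
    px <- abs(fft(x))^2
    sum(px[f >= 8 & f <= 12])
  }
  expect_equal(bandpow(r2) / bandpow(r1), 4, tolerance = 0.05)
  expect_error(generate_raw_trials(fs = 128), "fs")
  expect_error(generate_raw_trials(fs = 260, ssvep_hz = 200), "aliasing")
})

test_that("a square drive spreads power into its first harmonic", {
  raw <- generate_raw_trials(n_trials = 1, n_channels = 2, fs = 256,
                             seed = 4, noise_amp = 0, alpha_amp_liberal = 0,
                             drive = "square")
  x <- raw$data[1, 1, raw$times >= 0]
  f <- seq(0, raw$fs, length.out = length(x) + 1)[seq_along(x)]
  px <- abs(fft(x))^2
  p25 <- sum(px[abs(f - 25) < 2])
  p50 <- sum(px[abs(f - 50) < 2])
  expect_gt(p25, p50)                 # fundamental dominates
  expect_gt(p50, 0.05 * p25)          # first harmonic clearly present
  raw2 <- generate_raw_trials(n_trials = 1, n_channels = 2, fs = 256,
                              seed = 4, noise_amp = 0,
                              alpha_amp_liberal = 0, drive = "sine")
  x2 <- raw2$data[1, 1, raw2$times >= 0]
  px2 <- abs(fft(x2))^2
  expect_lt(sum(px2[abs(f - 50) < 2]) / sum(px2[abs(f - 25) < 2]), 1e-3)
})

test_that("trial tables round-trip through CSV", {
  cfg <- study_config(n_subjects = 1, blocks_per_condition = 1, seed = 1)
  tab <- simulate_study(cfg, sample_subject_params(1, seed = 1), seed = 1)
  path <- tempfile(fileext = ".csv")
  write_trials(tab, path)
  back <- read_trials(path)
  expect_equal(back$rt, tab$rt, tolerance = 1e-9)
  expect_identical(back$condition, tab$condition)
  unlink(path)
})
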