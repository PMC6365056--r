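raw_from_matrix <- function(x, fs, times, nch = 1) {
  arr <- array(0, dim = c(nrow(x), nch, ncol(x)))
  for (ch in seq_len(nch)) arr[, ch, ] <- x
  list(data = arr, fs = fs, times = times,
       channels = paste0("ch", seq_len(nch)))
}

test_that("a pure tone peaks at its frequency bin and scales as amplitude^2", {
  fs <- 256
  times <- seq(-1, 1.25, by = 1 / fs)
  x <- matrix(sin(2 * pi * 25 * times), nrow = 1)
  cube <- tfr(raw_from_matrix(x, fs, times), tfr_config("lowfreq_hann"))
  spec <- apply(cube$power[1, 1, , , drop = FALSE], 3, mean)
  expect_equal(cube$freqs[which.max(spec)], 25)
  cube2 <- tfr(raw_from_matrix(2 * x, fs, times),
               tfr_config("lowfreq_hann"))
  spec2 <- apply(cube2$power[1, 1, , , drop = FALSE], 3, mean)
  expect_equal(max(spec2) / max(spec), 4, tolerance = 1e-6)
})

test_that("multitaper averaging cuts the estimator variance ~ 1/K", {
  fs <- 256
  times <- seq(-0.5, 0.5, by = 1 / fs)
  set.seed(42)
  n_ep <- 300
  x <- matrix(rnorm(n_ep * length(times)), nrow = n_ep)
  raw <- raw_from_matrix(x, fs, times)
  pick <- function(cfg) {
    cube <- tfr(raw, cfg)
    # one interior bin/time to avoid edge effects
    cube$power[, 1, 3, ceiling(length(cube$times) / 2)]
  }
  v_mt <- var(pick(tfr_config("highfreq_multitaper")))
  v_h <- var(pick(tfr_config("highfreq_multitaper", n_tapers = 1,
                             smoothing_hz = 8)))
  ratio <- v_h / v_mt
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 10)
})

test_that("taper counts incompatible with the bandwidth are rejected", {
  expect_error(tfr_config("highfreq_multitaper", n_tapers = 8),
               "taper")
  # 2 * 0.4 s * 8 Hz - 1 = 5.4 -> five tapers are admissible
  expect_equal(tfr_config("highfreq_multitaper")$n_tapers, 5L)
})

test_that("baseline modulation is the percent change from condition baselines", {
  fs <- 64
  times <- seq(-0.5, 0.5, by = 1 / fs)
  nt <- length(times)
  cube <- structure(list(
    power = array(1, dim = c(4, 1, 2, nt)),
    freqs = c(10, 20), times = times, channels = "ch1",
    config = NULL, alignment = "stimulus_locked"), class = "tfr_cube")
  # trials 3-4 double their power after onset
  cube$power[3:4, , , times > 0] <- 2
  m <- baseline_modulation(cube)
  expect_equal(max(abs(m$power[1, , , ])), 0)
  expect_equal(unique(as.vector(m$power[3, 1, , times > 0.01])), 100)
  # condition-specific baselines: permuting labels changes the result the
  # way recomputed baselines dictate
  cond <- c("a", "a", "b", "b")
  m2 <- baseline_modulation(cube, condition = cond)
  expect_equal(unique(as.vector(m2$power[3, 1, , times > 0.01])), 100)
  cube$power[3:4, , , times <= 0] <- 2   # baseline for b now 2
  m3 <- baseline_modulation(cube, condition = cond)
  expect_equal(unique(as.vector(m3$power[3, 1, , times > 0.01])), 0)
})

test_that("zero baseline power is an error naming the bin", {
  fs <- 64
  times <- seq(-0.5, 0.5, by = 1 / fs)
  cube <- structure(list(
    power = array(0, dim = c(2, 1, 1, length(times))),
    freqs = 10, times = times, channels = "ch1"), class = "tfr_cube")
  expect_error(baseline_modulation(cube), "baseline power")
})

test_that("trial alpha pools the band and flags outliers like a two-pass oracle", {
  fs <- 64
  times <- seq(-1, 0.5, by = 1 / fs)
  n_tr <- 40
  cube <- structure(list(
    power = array(rep(1:n_tr, times = 2 * 3 * length(times)) * 0 +
                    rep(seq_len(n_tr), 2 * 3 * length(times)),
                  dim = c(n_tr, 2, 3, length(times))),
    freqs = c(8, 10, 12), times = times,
    channels = c("Oz", "POz")), class = "tfr_cube")
  base <- rnorm(n_tr, 10, 1)
  for (i in seq_len(n_tr)) cube$power[i, , , ] <- base[i]
  cube$power[5, , , ] <- 30  # gross outlier
  res <- trial_alpha(cube, channels = c("Oz", "POz"))
  expect_equal(res$alpha, ifelse(seq_len(n_tr) == 5, 30, base),
               tolerance = 1e-12)
  # brute-force two-pass mean/sd exclusion
  a <- res$alpha
  keep_ref <- abs(a - mean(a)) <= 3 * sd(a)
  expect_identical(res$keep, keep_ref)
  expect_false(res$keep[5])
  expect_error(trial_alpha(cube, channels = "nope"), "pool")
})

test_that("trial gamma isolates modulation inside its window", {
  fs <- 64
  times <- seq(-0.5, 1, by = 1 / fs)
  freqs <- seq(40, 100, by = 10)
  cube <- structure(list(
    power = array(0, dim = c(3, 1, length(freqs), length(times))),
    freqs = freqs, times = times, channels = "ch1",
    baseline = list(window = c(-0.4, 0))), class = "tfr_cube")
  expect_equal(trial_gamma(cube, channels = 1), c(0, 0, 0))
  # burst confined to 0.2-0.6 s, 60-100 Hz on trial 2
  cube$power[2, 1, freqs >= 60, times >= 0.2 & times <= 0.6] <- 50
  g <- trial_gamma(cube, channels = 1)
  expect_gt(g[2], 0)
  expect_equal(g[c(1, 3)], c(0, 0))
  # linear in burst power
  cube2 <- cube
  cube2$power <- cube$power * 2
  expect_equal(trial_gamma(cube2, channels = 1)[2], 2 * g[2])
  # burst outside the window leaves the scalar at zero
  cube3 <- cube
  cube3$power[] <- 0
  cube3$power[2, 1, freqs >= 60, times > 0.7] <- 50
  expect_equal(trial_gamma(cube3, channels = 1)[2], 0)
})

test_that("the ERP filter passes DC, kills 25 Hz, and averages noise down", {
  fs <- 256
  times <- seq(-0.5, 1, by = 1 / fs)
  nt <- length(times)
  dc <- raw_from_matrix(matrix(1, 1, nt), fs, times)
  interior <- abs(times) < 0.3   # away from filtfilt edge transients
  expect_equal(mean(erp(dc, 1)$erp[interior]), 1, tolerance = 1e-3)
  tone <- raw_from_matrix(matrix(sin(2 * pi * 25 * times), 1), fs, times)
  e <- erp(tone, 1)$erp
  mid <- abs(times) < 0.3
  atten <- sqrt(mean(e[mid]^2)) / sqrt(0.5)
  expect_lt(20 * log10(atten), -20)
  set.seed(9)
  for (n in c(4, 16)) {
    noisy <- raw_from_matrix(matrix(rnorm(n * nt), n), fs, times)
    v <- var(erp(noisy, 1)$erp)
    assign(paste0("v", n), v)
  }
  expect_equal(v4 / v16, 4, tolerance = 1.5)
  expect_error(erp(dc, 1, lowpass = 200), "Nyquist")
})

test_that("total spectral power tracks time-domain variance (Parseval-ish)", {
  fs <- 256
  times <- seq(-0.5, 0.5, by = 1 / fs)
  set.seed(5)
  x <- matrix(rnorm(20 * length(times), sd = 2), nrow = 20)
  cube <- tfr(raw_from_matrix(x, fs, times),
              tfr_config("prestim_1s", freq_range = c(1, 127),
                         freq_bin = 1))
  # white noise: flat PSD at sigma^2 / (fs / 2) per Hz, one-sided
  psd <- mean(cube$power)
  expect_equal(psd, 4 / (fs / 2) , tolerance = 0.3)
})
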