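#' Time-frequency analysis configuration
#'
#' Three preset modes mirror the analysis settings: \code{lowfreq_hann}
#' (sliding 0.4 s window, 50 ms steps, single Hann taper, 3--35 Hz on a 1 Hz
#' bin grid), \code{highfreq_multitaper} (same sliding window, five DPSS
#' tapers at a nominal +/- 8 Hz smoothing bandwidth, 36--100 Hz on a 2 Hz
#' grid) and \code{prestim_1s} (a single 1 s window centred 0.5 s before
#' trial onset, 1--35 Hz on a 0.5 Hz grid, single taper). Frequency grids
#' finer than the window's native resolution are reached by zero-padding the
#' FFT (declared in the returned metadata).
#'
#' @param mode one of "lowfreq_hann", "highfreq_multitaper", "prestim_1s".
#' @param window_s,step_s,freq_range,freq_bin,n_tapers,smoothing_hz override
#'   the mode presets if supplied.
#' @return a \code{tfr_config} object.
#' @export
tfr_config <- function(mode = c("lowfreq_hann", "highfreq_multitaper",
                                "prestim_1s"),
                       window_s = NULL, step_s = NULL, freq_range = NULL,
                       freq_bin = NULL, n_tapers = NULL,
                       smoothing_hz = NULL) {
  mode <- match.arg(mode)
  preset <- switch(mode,
    lowfreq_hann = list(window_s = 0.4, step_s = 0.05,
                        freq_range = c(3, 35), freq_bin = 1,
                        n_tapers = 1L, smoothing_hz = 4.5),
    highfreq_multitaper = list(window_s = 0.4, step_s = 0.05,
                               freq_range = c(36, 100), freq_bin = 2,
                               n_tapers = 5L, smoothing_hz = 8),
    prestim_1s = list(window_s = 1.0, step_s = NA_real_,
                      freq_range = c(1, 35), freq_bin = 0.5,
                      n_tapers = 1L, smoothing_hz = NA_real_))
  cfg <- list(mode = mode,
              window_s = window_s %||% preset$window_s,
              step_s = step_s %||% preset$step_s,
              freq_range = freq_range %||% preset$freq_range,
              freq_bin = freq_bin %||% preset$freq_bin,
              n_tapers = as.integer(n_tapers %||% preset$n_tapers),
              smoothing_hz = smoothing_hz %||% preset$smoothing_hz)
  if (cfg$n_tapers > 1) {
    # DPSS feasibility: 2 * window * half-bandwidth - 1 >= n_tapers
    if (2 * cfg$window_s * cfg$smoothing_hz - 1 < cfg$n_tapers)
      stop("taper count inconsistent with time-bandwidth product")
  }
  structure(cfg, class = "tfr_config")
}

# Discrete prolate spheroidal sequences via the symmetric tridiagonal
# eigenproblem; returns an n x k matrix of unit-energy tapers.
.dpss <- function(n, w, k) {
  t <- 0:(n - 1)
  d <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  e <- t[-1] * (n - t[-1]) / 2
  M <- diag(d)
  for (i in seq_len(n - 1)) {
    M[i, i + 1] <- e[i]
    M[i + 1, i] <- e[i]
  }
  ev <- eigen(M, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  # sign convention: symmetric tapers positive mean, antisymmetric positive
  # initial slope
  for (j in seq_len(k)) {
    s <- sum(tapers[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) tapers[, j] <- -tapers[, j]
    } else if (tapers[2, j] - tapers[1, j] < 0) tapers[, j] <- -tapers[, j]
  }
  sweep(tapers, 2, sqrt(colSums(tapers^2)), "/")
}

.hann <- function(n) {
  h <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  h / sqrt(sum(h^2))
}

#' Sliding-window time-frequency power estimation
#'
#' Short-time Fourier power per trial, channel, frequency bin and window
#' centre. Single-taper modes use a Hann window; the multitaper mode
#' averages power over orthogonal DPSS tapers. Power is scaled as
#' \code{2 |X|^2 / fs} with unit-energy tapers (one-sided PSD convention).
#'
#' @param raw list with \code{data} (trials x channels x time array),
#'   \code{fs} and \code{times} (as returned by
#'   \code{\link{generate_raw_trials}}).
#' @param config a \code{\link{tfr_config}}.
#' @return a \code{tfr_cube}: list with \code{power} (trials x channels x
#'   freqs x times array), \code{freqs}, \code{times} (window centres),
#'   \code{channels}, \code{config}, \code{nfft} (padding declared),
#'   \code{alignment}.
#' @export
tfr <- function(raw, config = tfr_config("lowfreq_hann")) {
  stopifnot(is.array(raw$data), length(dim(raw$data)) == 3)
  fs <- raw$fs
  times <- raw$times
  if (max(config$freq_range) > fs / 2)
    stop("requested frequency above Nyquist")
  ns <- round(config$window_s * fs)
  if (ns > length(times)) stop("window does not fit inside the epoch")
  nfft <- max(ns, round(fs / config$freq_bin))
  freqs <- seq(config$freq_range[1], config$freq_range[2],
               by = config$freq_bin)
  fft_freqs <- seq(0, fs, length.out = nfft + 1)[seq_len(nfft)]
  fidx <- vapply(freqs, function(f) which.min(abs(fft_freqs - f)), 0L)
  half <- (ns - 1) / 2
  centers <- if (config$mode == "prestim_1s") {
    -0.5
  } else {
    lo <- times[1] + half / fs
    hi <- times[length(times)] - half / fs
    seq(lo, hi, by = config$step_s)
  }
  start_idx <- vapply(centers, function(ct)
    as.integer(which.min(abs(times - ct)) - floor(ns / 2)), 0L)
  start_idx <- pmin(pmax(start_idx, 1L), length(times) - ns + 1L)
  tapers <- if (config$n_tapers > 1)
    .dpss(ns, config$smoothing_hz / fs, config$n_tapers)
  else matrix(.hann(ns), ncol = 1)
  ntr <- dim(raw$data)[1]; nch <- dim(raw$data)[2]
  pow <- array(0, dim = c(ntr, nch, length(freqs), length(centers)))
  seg_rows <- outer(seq_len(ns) - 1L, start_idx, `+`)  # ns x ncenters
  for (tr in seq_len(ntr)) for (ch in seq_len(nch)) {
    x <- raw$data[tr, ch, ]
    segs <- matrix(x[seg_rows], nrow = ns)
    acc <- 0
    for (k in seq_len(ncol(tapers))) {
      tap_seg <- segs * tapers[, k]
      padded <- rbind(tap_seg,
                      matrix(0, nrow = nfft - ns, ncol = ncol(tap_seg)))
      X <- stats::mvfft(padded)
      acc <- acc + 2 * abs(X[fidx, , drop = FALSE])^2 / fs
    }
    pow[tr, ch, , ] <- acc / ncol(tapers)
  }
  structure(list(power = pow, freqs = freqs, times = centers,
                 channels = raw$channels %||% paste0("ch", seq_len(nch)),
                 config = config, nfft = nfft,
                 alignment = raw$alignment %||% "stimulus_locked"),
            class = "tfr_cube")
}

#' Percent power modulation relative to a condition-specific baseline
#'
#' For each frequency bin and channel, the baseline is the mean power over
#' the baseline window and over all trials of the same condition; the
#' modulation is \code{(x - b) / b * 100}.
#'
#' @param cube a \code{tfr_cube}.
#' @param condition per-trial condition labels (a single condition is
#'   assumed when NULL).
#' @param baseline_window two-element window in seconds (default
#'   c(-0.4, 0)).
#' @return a \code{tfr_cube} with power replaced by percent modulation and a
#'   \code{baseline} field recording the window.
#' @export
baseline_modulation <- function(cube, condition = NULL,
                                baseline_window = c(-0.4, 0)) {
  stopifnot(inherits(cube, "tfr_cube"))
  bidx <- which(cube$times >= baseline_window[1] &
                cube$times <= baseline_window[2])
  if (!length(bidx)) stop("baseline window is outside the epoch")
  ntr <- dim(cube$power)[1]
  condition <- condition %||% rep("all", ntr)
  stopifnot(length(condition) == ntr)
  mod <- cube$power
  for (cond in unique(condition)) {
    tr <- which(condition == cond)
    # baseline: mean over baseline times and the condition's trials
    b <- apply(cube$power[tr, , , bidx, drop = FALSE], c(2, 3), mean)
    if (any(b <= 0)) {
      bad <- which(b <= 0, arr.ind = TRUE)[1, ]
      stop(sprintf("zero baseline power (channel %d, %g Hz)",
                   bad[1], cube$freqs[bad[2]]))
    }
    for (i in tr)
      mod[i, , , ] <- (cube$power[i, , , ] -
                         as.vector(b)) / as.vector(b) * 100
  }
  out <- cube
  out$power <- mod
  out$baseline <- list(window = baseline_window, per_condition = TRUE)
  out
}

# mean over a band x window x channel pool, one scalar per trial
.pool_scalar <- function(cube, channels, window, band) {
  chidx <- if (is.character(channels)) match(channels, cube$channels)
           else channels
  chidx <- chidx[!is.na(chidx)]
  if (!length(chidx)) stop("empty electrode pool")
  tidx <- which(cube$times >= window[1] & cube$times <= window[2])
  fidx <- which(cube$freqs >= band[1] & cube$freqs <= band[2])
  if (!length(tidx)) stop("window outside epoch")
  if (!length(fidx)) stop("band outside frequency grid")
  apply(cube$power[, chidx, fidx, tidx, drop = FALSE], 1, mean)
}

#' Trial-level pre-stimulus alpha scalar
#'
#' Mean raw (un-baselined) 8--12 Hz power over a pre-stimulus window and an
#' electrode pool, one scalar per trial, plus an exclusion mask flagging
#' trials more than \code{exclude_sd} standard deviations from the mean.
#'
#' @param cube raw-power \code{tfr_cube}.
#' @param channels electrode pool (labels or indices); defaults to the
#'   posterior pool.
#' @param window pre-stimulus window in seconds (default c(-0.8, -0.2),
#'   staying half a window from trial onset).
#' @param band frequency band in Hz (default c(8, 12)).
#' @param exclude_sd exclusion threshold in standard deviations (default 3).
#' @return list: \code{alpha} (per-trial scalar), \code{keep} (logical
#'   mask, FALSE for excluded trials).
#' @export
trial_alpha <- function(cube, channels = posterior_electrodes(),
                        window = c(-0.8, -0.2), band = c(8, 12),
                        exclude_sd = 3) {
  a <- .pool_scalar(cube, channels, window, band)
  keep <- abs(a - mean(a)) <= exclude_sd * sd(a)
  if (all(!is.finite(a))) stop("alpha scalars are not finite")
  list(alpha = a, keep = keep)
}

#' Trial-level post-stimulus gamma modulation scalar
#'
#' Mean baseline-normalised 59--100 Hz modulation over 0.2--0.6 s after
#' trial onset and an electrode pool, one scalar per trial.
#'
#' @param cube baseline-normalised \code{tfr_cube} (see
#'   \code{\link{baseline_modulation}}).
#' @param channels electrode pool.
#' @param window post-stimulus window in seconds (default c(0.2, 0.6)).
#' @param band frequency band in Hz (default c(59, 100)).
#' @return per-trial gamma modulation scalars (percent).
#' @export
trial_gamma <- function(cube, channels = posterior_electrodes(),
                        window = c(0.2, 0.6), band = c(59, 100)) {
  if (is.null(cube$baseline))
    warning("trial_gamma expects a baseline-normalised cube")
  .pool_scalar(cube, channels, window, band)
}

#' Default electrode pools
#'
#' Label-driven pooling: eleven occipito-parietal electrodes for
#' stimulus-related activity, four frontal electrodes for midfrontal theta,
#' and C4 for the motor ERP. Override by passing explicit labels or indices
#' to the scalar extractors.
#'
#' @return character vector of electrode labels.
#' @export
posterior_electrodes <- function()
  c("Oz", "POz", "Pz", "PO3", "PO4", "P1", "P2", "P3", "P4", "P5", "P6")

#' @rdname posterior_electrodes
#' @export
frontal_electrodes <- function() c("Fz", "Cz", "FC1", "FC2")

#' Event-related potential
#'
#' Zero-phase low-pass filters each trial (4th-order Butterworth applied
#' forward and backward) and averages across trials.
#'
#' @param raw list with \code{data} (trials x channels x time), \code{fs},
#'   \code{times}.
#' @param channel channel index or label.
#' @param lowpass cutoff frequency in Hz (default 8; must be below
#'   Nyquist).
#' @return list with \code{erp} (averaged waveform) and \code{times}.
#' @export
erp <- function(raw, channel = 1, lowpass = 8) {
  fs <- raw$fs
  if (lowpass >= fs / 2) stop("low-pass cutoff must be below Nyquist")
  ch <- if (is.character(channel)) match(channel, raw$channels) else channel
  if (is.na(ch)) stop("unknown channel")
  bf <- signal::butter(4, lowpass / (fs / 2), type = "low")
  ntr <- dim(raw$data)[1]
  filt <- vapply(seq_len(ntr), function(tr)
    as.numeric(signal::filtfilt(bf, raw$data[tr, ch, ])),
    numeric(dim(raw$data)[3]))
  list(erp = rowMeans(filt), times = raw$times)
}
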