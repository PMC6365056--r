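#' Study configuration for the synthetic generator
#'
#' Encodes the task design: blocks of a fixed trial count with an exact
#' target proportion (180 targets and 60 nontargets per 240-trial block at
#' the default 0.75), liberal and conservative blocks alternating, uniform
#' inter-trial intervals and a fixed response deadline.
#'
#' @param n_subjects number of subjects.
#' @param blocks_per_condition blocks per condition per subject (blocks
#'   alternate between conditions).
#' @param trials_per_block trials per block (default 240).
#' @param p_target target proportion per block (default 0.75; must give an
#'   integer target count per block and lie strictly inside (0, 1) so both
#'   stimulus classes occur).
#' @param iti_range uniform inter-trial-interval range in seconds.
#' @param response_deadline response window in seconds after (non)target
#'   onset.
#' @param dt Euler step for behaviour generation (seconds).
#' @param seed default master seed for generation.
#' @return a \code{study_config} object.
#' @export
study_config <- function(n_subjects = 16L, blocks_per_condition = 8L,
                         trials_per_block = 240L, p_target = 0.75,
                         iti_range = c(0.3, 2.2), response_deadline = 0.84,
                         dt = 1e-3, seed = 1L) {
  if (n_subjects < 1) stop("need at least one subject")
  if (p_target <= 0 || p_target >= 1)
    stop("p_target must lie strictly in (0, 1): both stimulus classes ",
         "must occur for signal-detection measures to be defined")
  n_tgt <- trials_per_block * p_target
  if (abs(n_tgt - round(n_tgt)) > 1e-9)
    stop("trials_per_block * p_target must be an integer (exact design)")
  if (response_deadline <= 0) stop("response deadline must be positive")
  structure(list(n_subjects = as.integer(n_subjects),
                 blocks_per_condition = as.integer(blocks_per_condition),
                 trials_per_block = as.integer(trials_per_block),
                 p_target = p_target, iti_range = iti_range,
                 response_deadline = response_deadline, dt = dt,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Per-subject generating parameters
#'
#' One subject's generating parameters for both conditions: diffusion
#' parameters per condition, a condition-shifted log-normal for pre-stimulus
#' alpha power (liberal median below conservative), a sigmoidal response-gain
#' curve per condition (liberal amplitude at or above conservative), frontal
#' theta means (liberal above conservative) and scalar noise levels.
#'
#' @param ddm_liberal,ddm_conservative \code{\link{ddm_params}} per
#'   condition.
#' @param alpha_meanlog_liberal,alpha_meanlog_conservative log-median of the
#'   alpha distribution per condition (log a.u.).
#' @param alpha_sdlog log-sd of the alpha distribution.
#' @param gain_liberal,gain_conservative \code{\link{gain_params}} per
#'   condition.
#' @param theta_mean_liberal,theta_mean_conservative frontal theta mean per
#'   condition (a.u.).
#' @param theta_sd trial-level theta noise sd.
#' @param gamma_noise_sd trial-level gamma-modulation noise sd (percent
#'   units); 0 gives the noiseless coupling.
#' @return a \code{subject_params} object.
#' @export
subject_params <- function(ddm_liberal, ddm_conservative,
                           alpha_meanlog_liberal = log(17),
                           alpha_meanlog_conservative = log(20),
                           alpha_sdlog = 0.35,
                           gain_liberal = gain_params(A = 12),
                           gain_conservative = gain_params(A = 8),
                           theta_mean_liberal = 2.0,
                           theta_mean_conservative = 1.6,
                           theta_sd = 0.4,
                           gamma_noise_sd = 10) {
  stopifnot(inherits(ddm_liberal, "ddm_params"),
            inherits(ddm_conservative, "ddm_params"),
            alpha_sdlog > 0, theta_sd >= 0, gamma_noise_sd >= 0)
  if (alpha_meanlog_liberal >= alpha_meanlog_conservative)
    stop("liberal alpha median must lie below conservative (by construction)")
  if (gain_liberal$A < gain_conservative$A)
    stop("liberal gain amplitude must be >= conservative (by construction)")
  structure(list(
    ddm = list(liberal = ddm_liberal, conservative = ddm_conservative),
    alpha_meanlog = c(liberal = alpha_meanlog_liberal,
                      conservative = alpha_meanlog_conservative),
    alpha_sdlog = alpha_sdlog,
    gain = list(liberal = gain_liberal, conservative = gain_conservative),
    theta_mean = c(liberal = theta_mean_liberal,
                   conservative = theta_mean_conservative),
    theta_sd = theta_sd, gamma_noise_sd = gamma_noise_sd),
    class = "subject_params")
}

#' Draw a population of subject parameter sets
#'
#' Subjects are drawn around the group-level generating values: drift rates
#' v (liberal 2.39, conservative 3.06), drift biases db (liberal 2.08,
#' conservative -0.04), a shared relative starting point of 0.24, boundary
#' separation near 1 and non-decision times near 0.3 s (liberal slightly
#' shorter), with between-subject jitter.
#'
#' @param n_subjects number of subjects.
#' @param seed integer seed.
#' @param v_lib,v_cons,db_lib,db_cons,z_frac,a group means of the diffusion
#'   parameters.
#' @param t_nd_lib,t_nd_cons group-mean non-decision times.
#' @param sd_v,sd_db,sd_z,sd_a between-subject jitter sds.
#' @param A_lib,A_cons group-mean gain amplitudes (percent units).
#' @param A_cv between-subject coefficient of variation of the gain
#'   amplitude.
#' @param gamma_noise_sd trial-level gamma noise sd passed through.
#' @return list of \code{\link{subject_params}} of length
#'   \code{n_subjects}.
#' @export
sample_subject_params <- function(n_subjects, seed = 1L,
                                  v_lib = 2.39, v_cons = 3.06,
                                  db_lib = 2.08, db_cons = -0.04,
                                  z_frac = 0.24, a = 1.0,
                                  t_nd_lib = 0.28, t_nd_cons = 0.32,
                                  sd_v = 0.4, sd_db = 0.35, sd_z = 0.03,
                                  sd_a = 0.08, A_lib = 12, A_cons = 8,
                                  A_cv = 0.25, gamma_noise_sd = 10) {
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      zf <- min(max(z_frac + rnorm(1, 0, sd_z), 0.08), 0.9)
      ai <- max(a + rnorm(1, 0, sd_a), 0.4)
      Al <- max(A_lib * (1 + rnorm(1, 0, A_cv)), 1)
      Ac <- min(max(A_cons * (1 + rnorm(1, 0, A_cv)), 0.5), Al)
      subject_params(
        ddm_liberal = ddm_params(v = v_lib + rnorm(1, 0, sd_v), a = ai,
                                 z_frac = zf,
                                 db = db_lib + rnorm(1, 0, sd_db),
                                 t_nd = t_nd_lib),
        ddm_conservative = ddm_params(v = v_cons + rnorm(1, 0, sd_v), a = ai,
                                      z_frac = zf,
                                      db = db_cons + rnorm(1, 0, sd_db),
                                      t_nd = t_nd_cons),
        gain_liberal = gain_params(A = Al),
        gain_conservative = gain_params(A = Ac),
        gamma_noise_sd = gamma_noise_sd)
    })
  })
}

# trial skeleton: exact stimulus counts per block, alternating conditions
.trial_skeleton <- function(config, subject_id, first_condition) {
  conds <- c("liberal", "conservative")
  if (first_condition == "conservative") conds <- rev(conds)
  n_blocks <- 2L * config$blocks_per_condition
  n_tgt <- as.integer(round(config$trials_per_block * config$p_target))
  rows <- lapply(seq_len(n_blocks), function(b) {
    stim <- sample(rep(c("target", "nontarget"),
                       c(n_tgt, config$trials_per_block - n_tgt)))
    data.frame(subject = subject_id, block = b,
               condition = conds[(b - 1L) %% 2L + 1L],
               stimulus = stim,
               iti = runif(config$trials_per_block,
                           config$iti_range[1], config$iti_range[2]))
  })
  do.call(rbind, rows)
}

#' Generate task behaviour for a synthetic study
#'
#' Builds the full trial table: per-block exact stimulus counts (not
#' binomial draws), conditions alternating across blocks (first condition
#' counterbalanced across subjects), and choices/RTs simulated from each
#' subject's condition-specific diffusion parameters.
#'
#' @param config a \code{\link{study_config}}.
#' @param subjects list of \code{\link{subject_params}}, one per subject.
#' @param seed integer seed (defaults to the config seed).
#' @return trial table data.frame: subject, block, condition, stimulus,
#'   choice, rt, iti.
#' @export
generate_behavior <- function(config, subjects, seed = config$seed) {
  stopifnot(inherits(config, "study_config"))
  if (length(subjects) != config$n_subjects)
    stop("need one subject_params per subject")
  tabs <- lapply(seq_len(config$n_subjects), function(i) {
    first <- if (i %% 2L == 1L) "liberal" else "conservative"
    skel <- with_seed(child_seed(seed, paste0("skeleton", i)),
                      .trial_skeleton(config, i, first))
    skel$choice <- NA_character_
    skel$rt <- NA_real_
    for (cond in c("liberal", "conservative"))
      for (stim in c("target", "nontarget")) {
        idx <- which(skel$condition == cond & skel$stimulus == stim)
        sim <- ddm_simulate(subjects[[i]]$ddm[[cond]], stim, length(idx),
                            dt = config$dt,
                            deadline = config$response_deadline,
                            seed = child_seed(seed,
                                              paste0("beh", i, cond, stim)))
        skel$choice[idx] <- sim$choice
        skel$rt[idx] <- sim$rt
      }
    skel
  })
  do.call(rbind, tabs)
}

#' Add trial-level neural scalars to a trial table
#'
#' Draws per-trial pre-stimulus alpha power from a condition-shifted
#' log-normal (positive support by construction; liberal median below
#' conservative), gamma modulation as the subject's condition-specific
#' response-gain curve evaluated at the trial's alpha plus zero-mean noise,
#' and frontal theta as a condition mean plus noise (liberal above
#' conservative).
#'
#' @param trials trial table from \code{\link{generate_behavior}} (or a
#'   skeleton with subject/condition columns).
#' @param subjects list of \code{\link{subject_params}}.
#' @param seed integer seed.
#' @return the trial table with columns alpha, gamma_mod, theta appended.
#' @export
generate_neural_scalars <- function(trials, subjects, seed = 1L) {
  trials$alpha <- NA_real_
  trials$gamma_mod <- NA_real_
  trials$theta <- NA_real_
  for (i in unique(trials$subject)) {
    sp <- subjects[[i]]
    for (cond in c("liberal", "conservative")) {
      idx <- which(trials$subject == i & trials$condition == cond)
      if (!length(idx)) next
      with_seed(child_seed(seed, paste0("scalars", i, cond)), {
        alpha <- rlnorm(length(idx), sp$alpha_meanlog[[cond]], sp$alpha_sdlog)
        gm <- gain_curve(alpha, sp$gain[[cond]])$gain +
          rnorm(length(idx), 0, sp$gamma_noise_sd)
        th <- sp$theta_mean[[cond]] + rnorm(length(idx), 0, sp$theta_sd)
        trials$alpha[idx] <- alpha
        trials$gamma_mod[idx] <- gm
        trials$theta[idx] <- th
      })
    }
  }
  trials
}

#' Simulate a complete coupled synthetic study
#'
#' Full generative chain in the order the analysis assumes it arose: trial
#' skeleton with exact stimulus counts, neural scalars (alpha -> gamma via
#' the response-gain curve, theta), then behaviour whose trial-level drift
#' bias is the subject's condition drift bias plus a coupling coefficient
#' times the subject-and-condition-centred gamma modulation. With a positive
#' coupling, trials with stronger gamma accumulate evidence more liberally,
#' which the bin-wise drift-bias refit and repeated-measures correlation
#' should recover.
#'
#' @param config a \code{\link{study_config}}.
#' @param subjects list of \code{\link{subject_params}} (drawn via
#'   \code{\link{sample_subject_params}} when NULL).
#' @param seed master seed (defaults to the config seed).
#' @param coupling drift-bias units per percent of (centred) gamma
#'   modulation.
#' @return trial table with behaviour and scalar columns.
#' @export
simulate_study <- function(config = study_config(), subjects = NULL,
                           seed = config$seed, coupling = 0.15) {
  if (is.null(subjects))
    subjects <- sample_subject_params(config$n_subjects,
                                      seed = child_seed(seed, "subjects"))
  skel <- do.call(rbind, lapply(seq_len(config$n_subjects), function(i) {
    first <- if (i %% 2L == 1L) "liberal" else "conservative"
    with_seed(child_seed(seed, paste0("skeleton", i)),
              .trial_skeleton(config, i, first))
  }))
  tab <- generate_neural_scalars(skel, subjects,
                                 seed = child_seed(seed, "scalars"))
  tab$choice <- NA_character_
  tab$rt <- NA_real_
  for (i in seq_len(config$n_subjects)) {
    sp <- subjects[[i]]
    for (cond in c("liberal", "conservative"))
      for (stim in c("target", "nontarget")) {
        idx <- which(tab$subject == i & tab$condition == cond &
                     tab$stimulus == stim)
        if (!length(idx)) next
        cidx <- which(tab$subject == i & tab$condition == cond)
        gbar <- mean(tab$gamma_mod[cidx])
        pars <- sp$ddm[[cond]]
        dbt <- pars$db + coupling * (tab$gamma_mod[idx] - gbar)
        sim <- ddm_simulate(pars, stim, length(idx), dt = config$dt,
                            deadline = config$response_deadline,
                            seed = child_seed(seed,
                                              paste0("beh", i, cond, stim)),
                            db_trial = dbt)
        tab$choice[idx] <- sim$choice
        tab$rt[idx] <- sim$rt
      }
  }
  tab
}

# 1/f-shaped unit-variance background noise, built in the frequency domain
# (amplitude 1/sqrt(f), random phases, Hermitian-symmetric spectrum)
.pink_noise <- function(n, fs) {
  nf <- floor(n / 2) + 1L
  f <- seq(0, fs / 2, length.out = nf)
  amp <- c(0, 1 / sqrt(f[-1]))
  spec <- amp * exp(1i * runif(nf, 0, 2 * pi))
  full <- if (n %% 2L == 0L) c(spec, Conj(rev(spec[2:(nf - 1L)])))
          else c(spec, Conj(rev(spec[2:nf])))
  x <- Re(fft(full, inverse = TRUE)) / n
  x / sd(x)
}

#' Generate raw synthetic EEG-like epochs
#'
#' Epochs span -1.0 to +1.25 s around trial onset. Designated posterior
#' channels carry a periodic 25 Hz drive after stimulus onset (a square
#' pulse train by default, whose non-sinusoidal shape also produces power at
#' the first harmonic) plus a pre-stimulus 8--12 Hz oscillation whose
#' amplitude depends on condition; designated frontal channels carry a
#' 2--6 Hz component; all channels ride on 1/f-shaped background noise.
#'
#' @param config a \code{\link{study_config}} (deadline/ITI carried in
#'   metadata).
#' @param n_trials number of epochs.
#' @param n_channels total channel count (first two thirds posterior, rest
#'   frontal; labels returned).
#' @param fs sampling rate in Hz (>= 256).
#' @param condition "liberal" or "conservative" (sets the pre-stimulus alpha
#'   amplitude: suppressed under liberal).
#' @param ssvep_hz drive frequency (default 25, i.e. a 40 ms frame period).
#' @param ssvep_amp,alpha_amp_liberal,alpha_amp_conservative,theta_amp
#'   component amplitudes (a.u.).
#' @param noise_amp 1/f background amplitude.
#' @param drive "square" (pulse train, harmonic-rich) or "sine".
#' @param seed integer seed.
#' @return list: \code{data} (trials x channels x time array), \code{fs},
#'   \code{times}, \code{channels}, \code{groups} (posterior/frontal channel
#'   indices), \code{seed}, \code{config}.
#' @export
generate_raw_trials <- function(config = study_config(), n_trials = 10L,
                                n_channels = 6L, fs = 256,
                                condition = c("liberal", "conservative"),
                                ssvep_hz = 25, ssvep_amp = 1,
                                alpha_amp_liberal = 0.5,
                                alpha_amp_conservative = 1,
                                theta_amp = 0.8, noise_amp = 0.5,
                                drive = c("square", "sine"), seed = 1L) {
  condition <- match.arg(condition)
  drive <- match.arg(drive)
  if (fs < 256) stop("fs must be at least 256 Hz")
  # highest injected frequency: first harmonic of the drive for the square
  f_max <- if (drive == "square") 2 * ssvep_hz else ssvep_hz
  if (fs < 2 * f_max)
    stop("fs below twice the highest injected frequency (aliasing)")
  times <- seq(-1.0, 1.25, by = 1 / fs)
  nt <- length(times)
  n_post <- min(max(1L, as.integer(ceiling(2 * n_channels / 3))),
                n_channels)
  groups <- list(posterior = seq_len(n_post),
                 frontal = if (n_post < n_channels)
                   seq.int(n_post + 1L, n_channels) else integer(0))
  alpha_amp <- if (condition == "liberal") alpha_amp_liberal else
    alpha_amp_conservative
  post_mask <- times >= 0
  pre_mask <- times < 0
  drive_sig <- if (drive == "square") {
    # periodic pulse train (25% duty): one brief frame-locked transient per
    # 40 ms cycle, rich in harmonics of the drive frequency
    ph <- (times %% (1 / ssvep_hz)) * ssvep_hz
    2 * (ph < 0.25) - 0.5
  } else sin(2 * pi * ssvep_hz * times)
  arr <- array(0, dim = c(n_trials, n_channels, nt))
  with_seed(seed, {
    for (tr in seq_len(n_trials)) {
      alpha_phase <- runif(1, 0, 2 * pi)
      theta_f <- runif(1, 2, 6)
      theta_phase <- runif(1, 0, 2 * pi)
      for (ch in seq_len(n_channels)) {
        sig <- noise_amp * .pink_noise(nt, fs)
        if (ch %in% groups$posterior) {
          sig <- sig + ssvep_amp * drive_sig * post_mask +
            alpha_amp * sin(2 * pi * 10 * times + alpha_phase) * pre_mask
        } else {
          sig <- sig + theta_amp * sin(2 * pi * theta_f * times + theta_phase)
        }
        arr[tr, ch, ] <- sig
      }
    }
  })
  labels <- c(paste0("P", seq_len(n_post)),
              paste0("F", seq_len(n_channels - n_post)))
  list(data = arr, fs = fs, times = times, channels = labels,
       groups = groups, condition = condition, seed = seed, config = config)
}

#' Write / read a trial table as CSV
#'
#' @param trials trial table data.frame.
#' @param path file path.
#' @return \code{read_trials} returns the trial table.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
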