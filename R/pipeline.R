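#' Run the full synthetic-study analysis pipeline
#'
#' Executes the stages in order on one synthetic study: simulate the
#' coupled study, signal-detection summaries, diffusion-model fits of the
#' three bias variants with BIC comparison, overlapping alpha binning with
#' bin-wise summaries and drift-bias/starting-point refits, the Gaussian
#' contrast tests, repeated-measures correlation between gamma modulation
#' and drift bias with the Cook's-distance robustness refit, the joint
#' regression of gamma on both bias parameters, and the
#' theta-controlled gamma test. Each stage draws from its own named seed
#' substream so stages can be re-run in isolation. Results are returned as
#' one list and optionally written as CSV/JSON under \code{out_dir}.
#'
#' @param config a \code{\link{study_config}}.
#' @param subjects optional list of \code{\link{subject_params}}.
#' @param seed master seed (defaults to the config seed).
#' @param coupling gamma-to-drift-bias coupling passed to
#'   \code{\link{simulate_study}}.
#' @param restarts optimisation restarts per diffusion fit.
#' @param maxit simplex iteration cap per restart (see \code{\link{ddm_fit}}).
#' @param n_perm permutations for the behavioural paired tests.
#' @param fit_subjects how many subjects to carry through the
#'   diffusion-fit stages (NULL = all; smaller values give a faster,
#'   partial run).
#' @param out_dir optional output directory for tables and the JSON
#'   summary.
#' @return list with elements \code{trials}, \code{sdt}, \code{sdt_tests},
#'   \code{fits} (per subject), \code{model_comparison}, \code{binned},
#'   \code{contrast}, \code{rmcorr} (per condition), \code{joint} (per
#'   condition), \code{theta_gamma} (per condition), \code{config},
#'   \code{seed}.
#' @export
run_study <- function(config = study_config(), subjects = NULL,
                      seed = config$seed, coupling = 0.15, restarts = 6L,
                      n_perm = 10000L, fit_subjects = NULL,
                      out_dir = NULL, maxit = 800L) {
  trials <- simulate_study(config, subjects = subjects, seed = seed,
                           coupling = coupling)
  sdt <- sdt_table(trials)

  wide <- function(col) {
    lib <- sdt[sdt$condition == "liberal", ]
    con <- sdt[sdt$condition == "conservative", ]
    con <- con[match(lib$subject, con$subject), ]
    list(lib = lib[[col]], con = con[[col]])
  }
  crit <- wide("criterion"); dpr <- wide("dprime")
  sdt_tests <- list(
    criterion = perm_test_paired(crit$lib, crit$con, n_perm = n_perm,
                                 seed = child_seed(seed, "perm_c")),
    dprime = perm_test_paired(dpr$lib, dpr$con, n_perm = n_perm,
                              seed = child_seed(seed, "perm_d")))

  subs <- sort(unique(trials$subject))
  if (!is.null(fit_subjects)) subs <- head(subs, fit_subjects)
  variants <- c("fixed", "starting_point", "drift_bias")
  fits <- lapply(subs, function(s) {
    st <- trials[trials$subject == s, ]
    fs <- lapply(variants, function(v)
      ddm_fit(st, v, deadline = config$response_deadline,
              restarts = restarts, maxit = maxit,
              seed = child_seed(seed, paste0("fit", s, v))))
    names(fs) <- variants
    fs
  })
  names(fits) <- paste0("subject", subs)
  model_comparison <- do.call(rbind, lapply(seq_along(subs), function(i) {
    cmp <- compare_models(fits[[i]])
    cmp$subject <- subs[i]
    cmp
  }))

  sub_trials <- trials[trials$subject %in% subs, ]
  binned <- bin_summaries(sub_trials, refit = "both",
                          deadline = config$response_deadline,
                          restarts = restarts, maxit = maxit,
                          seed = child_seed(seed, "bins"))
  contrast <- gaussian_contrast_test(binned)

  per_cond <- function(f) {
    out <- lapply(c("liberal", "conservative"), function(cond) {
      b <- binned[binned$condition == cond, ]
      f(b)
    })
    names(out) <- c("liberal", "conservative")
    out
  }
  rm_res <- per_cond(function(b) {
    base <- rmcorr(b$mean_gamma, b$drift_bias, b$subject)
    robust <- cooks_refit(b$mean_gamma, b$drift_bias, b$subject)
    list(r = base$r, df = base$df, p = base$p, robust = robust)
  })
  joint <- per_cond(function(b)
    joint_bias_regression(b$mean_gamma, b$drift_bias, b$starting_point,
                          b$subject))
  tg <- per_cond(function(b)
    theta_gamma_anova(b$drift_bias, b$mean_theta, b$mean_gamma, b$subject))

  res <- list(trials = trials, sdt = sdt, sdt_tests = sdt_tests,
              fits = fits, model_comparison = model_comparison,
              binned = binned, contrast = contrast, rmcorr = rm_res,
              joint = joint, theta_gamma = tg, config = config,
              seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials(trials, file.path(out_dir, "trials.csv"))
    utils::write.csv(sdt, file.path(out_dir, "sdt.csv"), row.names = FALSE)
    utils::write.csv(model_comparison,
                     file.path(out_dir, "model_comparison.csv"),
                     row.names = FALSE)
    utils::write.csv(binned, file.path(out_dir, "binned.csv"),
                     row.names = FALSE)
    summary <- list(
      seed = seed,
      sdt_tests = lapply(sdt_tests, function(x) x[c("p", "statistic")]),
      contrast = contrast,
      rmcorr = lapply(rm_res, function(x) x[c("r", "df", "p")]),
      joint = joint, theta_gamma = tg)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
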