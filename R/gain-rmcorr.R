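#' Sigmoidal response-gain parameters
#'
#' The response-gain model maps total synaptic input S (stimulus-driven
#' plus endogenous) to population output through a logistic
#' \deqn{O(S) = A / (1 + e^{-k (S - S0)})}
#' whose first derivative (the response gain)
#' \deqn{g(S) = k\,O\,(A - O)/A}
#' is bell-shaped with peak \code{k A / 4} at \code{S = S0}. Endogenous
#' input decreases monotonically with pre-stimulus alpha power (lower alpha
#' = higher excitability); the default mapping is linear,
#' \code{S = (alpha0 - alpha) / alpha_scale}.
#'
#' @param A amplitude (upper asymptote of the sigmoid; condition-specific).
#' @param k slope (1 / input units).
#' @param S0 midpoint in input units.
#' @param alpha0,alpha_scale linear alpha-to-input mapping parameters.
#' @return a \code{gain_params} object.
#' @export
gain_params <- function(A, k = 1.5, S0 = 2.3, alpha0 = 30, alpha_scale = 5) {
  stopifnot(A > 0, k > 0, alpha_scale > 0)
  structure(list(A = A, k = k, S0 = S0, alpha0 = alpha0,
                 alpha_scale = alpha_scale), class = "gain_params")
}

#' Response-gain curve over alpha
#'
#' Evaluates the sigmoid output and its first derivative (the gain) at the
#' inputs mapped from the supplied alpha values.
#'
#' @param alpha alpha power values (a.u.).
#' @param params a \code{\link{gain_params}}.
#' @return list with \code{input} (mapped S), \code{output} (sigmoid O) and
#'   \code{gain} (first derivative).
#' @export
gain_curve <- function(alpha, params) {
  stopifnot(inherits(params, "gain_params"), all(is.finite(alpha)))
  S <- (params$alpha0 - alpha) / params$alpha_scale
  O <- params$A * plogis(params$k * (S - params$S0))
  list(input = S, output = O, gain = params$k * O * (params$A - O) / params$A)
}

#' Overlapping alpha bins
#'
#' Sorts the trial alpha values ascending and forms \code{n_bins} core bins
#' of (near-)equal count, then extends each bin's membership half a core
#' width into each neighbouring bin (edge bins extend inward only), so that
#' adjacent bin ranges overlap by 50 percent. Binning is rank-based, hence
#' invariant to affine rescaling of alpha and to trial order.
#'
#' @param alpha per-trial alpha scalars (exclusion mask already applied).
#' @param n_bins number of bins (default 10).
#' @return an \code{alpha_binning}: list with \code{bins} (trial index
#'   vectors into \code{alpha}), \code{median_alpha}, \code{n}, and
#'   \code{core_size}.
#' @export
assign_bins <- function(alpha, n_bins = 10L) {
  n <- length(alpha)
  if (n < 2L * n_bins)
    stop("too few trials to define ", n_bins, " overlapping bins")
  ord <- order(alpha)                 # stable rank order
  # near-equal core bin sizes
  core_edges <- round(seq(0, n, length.out = n_bins + 1L))
  half <- floor((n / n_bins) / 2)
  bins <- vector("list", n_bins)
  med <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    lo <- max(core_edges[b] + 1L - half, 1L)
    hi <- min(core_edges[b + 1L] + half, n)
    bins[[b]] <- ord[lo:hi]
    med[b] <- median(alpha[bins[[b]]])
  }
  structure(list(bins = bins, median_alpha = med, n = n,
                 core_size = diff(core_edges), n_bins = n_bins),
            class = "alpha_binning")
}

#' Bin-wise summaries per subject and condition
#'
#' Assigns each subject-by-condition's trials to overlapping alpha bins and
#' summarises each bin: median alpha, mean gamma modulation, mean theta,
#' and (optionally) the bin-wise drift bias and starting point from profile
#' refits of the diffusion model (non-bias parameters held at each
#' subject's condition-level estimates from the drift-bias fit, and the
#' starting point analogously from the starting-point fit).
#'
#' @param trials trial table with subject, condition, stimulus, choice, rt,
#'   alpha, gamma_mod and (optionally) theta columns.
#' @param n_bins number of alpha bins (default 10).
#' @param refit "none", "db" (bin-wise drift bias only) or "both" (also
#'   bin-wise starting point from the starting-point model).
#' @param deadline,binning,restarts,seed,maxit fitting settings (see
#'   \code{\link{ddm_fit}}).
#' @return data.frame: subject, condition, bin, n_trials, median_alpha,
#'   mean_gamma, mean_theta, drift_bias, starting_point.
#' @export
bin_summaries <- function(trials, n_bins = 10L,
                          refit = c("none", "db", "both"),
                          deadline = 0.84, binning = quantile_binning(),
                          restarts = 6L, seed = 1L, maxit = 800L) {
  refit <- match.arg(refit)
  subjects <- sort(unique(trials$subject))
  out <- list()
  for (s in subjects) {
    st <- trials[trials$subject == s, ]
    fit_db <- fit_sp <- NULL
    if (refit != "none") {
      fit_db <- ddm_fit(st, "drift_bias", binning = binning,
                        deadline = deadline, restarts = restarts,
                        seed = child_seed(seed, paste0("db", s)),
                        maxit = maxit)
      if (refit == "both")
        fit_sp <- ddm_fit(st, "starting_point", binning = binning,
                          deadline = deadline, restarts = restarts,
                          seed = child_seed(seed, paste0("sp", s)),
                          maxit = maxit)
    }
    for (cond in unique(st$condition)) {
      ct <- st[st$condition == cond, ]
      ab <- assign_bins(ct$alpha, n_bins = n_bins)
      for (b in seq_len(n_bins)) {
        bt <- ct[ab$bins[[b]], ]
        db <- sp <- NA_real_
        if (!is.null(fit_db))
          db <- ddm_refit_bias(bt, fit_db$params[[cond]], "db",
                               binning = binning, deadline = deadline)
        if (!is.null(fit_sp))
          sp <- ddm_refit_bias(bt, fit_sp$params[[cond]], "z_frac",
                               binning = binning, deadline = deadline)
        out[[length(out) + 1L]] <- data.frame(
          subject = s, condition = cond, bin = b, n_trials = nrow(bt),
          median_alpha = ab$median_alpha[b],
          mean_gamma = mean(bt$gamma_mod),
          mean_theta = if ("theta" %in% names(bt)) mean(bt$theta)
                       else NA_real_,
          drift_bias = db, starting_point = sp)
      }
    }
  }
  do.call(rbind, out)
}

#' Gaussian contrast weights
#'
#' The ten-bin contrast encoding a unit-standard-deviation Gaussian shape;
#' the values sum to zero.
#' @return numeric vector of length 10.
#' @export
gaussian_contrast_weights <- function()
  c(-1000, -991, -825, 295, 2521, 2521, 295, -825, -991, -1000)

#' Gaussian-contrast test of the inverted-U profile
#'
#' Per subject, the contrast score is the weighted sum of the ten bin
#' values; each condition's score vector is tested against zero with a
#' one-sample test reported as \code{F(1, N - 1) = t^2} (the single-df
#' contrast of the repeated-measures ANOVA), and the condition-by-bin
#' interaction is the same test applied to liberal-minus-conservative
#' profiles.
#'
#' @param binned output of \code{\link{bin_summaries}} (complete 10-bin
#'   profiles per subject and condition).
#' @param value column to test (default "mean_gamma").
#' @param weights contrast weights (default
#'   \code{\link{gaussian_contrast_weights}}).
#' @return data.frame with rows per condition plus "interaction": F, df1,
#'   df2, p, mean_score.
#' @export
gaussian_contrast_test <- function(binned, value = "mean_gamma",
                                   weights = gaussian_contrast_weights()) {
  n_bins <- length(weights)
  scores <- function(df) {
    subs <- sort(unique(df$subject))
    vapply(subs, function(s) {
      prof <- df[df$subject == s, ]
      prof <- prof[order(prof$bin), ]
      if (nrow(prof) != n_bins || any(!is.finite(prof[[value]])))
        stop("incomplete bin profile for subject ", s)
      sum(weights * prof[[value]])
    }, 0)
  }
  one_test <- function(sc, label) {
    if (length(sc) < 2) stop("contrast test needs at least 2 subjects")
    tt <- t.test(sc)
    data.frame(effect = label, F = unname(tt$statistic)^2, df1 = 1,
               df2 = length(sc) - 1, p = tt$p.value, mean_score = mean(sc))
  }
  conds <- sort(unique(binned$condition))
  rows <- lapply(conds, function(cond)
    one_test(scores(binned[binned$condition == cond, ]), cond))
  if (length(conds) == 2) {
    s1 <- scores(binned[binned$condition == conds[1], ])
    s2 <- scores(binned[binned$condition == conds[2], ])
    if (!identical(names(s1), names(s2)))
      stop("conditions cover different subjects")
    rows[[length(rows) + 1L]] <- one_test(s1 - s2, "interaction")
  }
  do.call(rbind, rows)
}

#' Within-subject standard errors (subject means removed)
#'
#' Error bars for within-subject designs: each subject's mean across all
#' cells is removed before computing the per-cell SEM across subjects, so
#' additive subject offsets do not inflate the error bars.
#'
#' @param binned data.frame with subject column and cell identifiers.
#' @param value value column name.
#' @param cells character vector of cell-identifying columns (default
#'   condition and bin).
#' @return data.frame of cells with \code{sem}.
#' @export
within_subject_sem <- function(binned, value = "mean_gamma",
                               cells = c("condition", "bin")) {
  key <- interaction(binned[cells], drop = TRUE)
  counts <- table(binned$subject, key)
  if (any(counts != 1))
    stop("design must be balanced: one value per subject and cell")
  smean <- tapply(binned[[value]], binned$subject, mean)
  centred <- binned[[value]] - smean[as.character(binned$subject)] +
    mean(binned[[value]])
  sem <- tapply(centred, key, function(v) sd(v) / sqrt(length(v)))
  out <- unique(binned[cells])
  out$sem <- as.numeric(sem[as.character(interaction(out[cells],
                                                     drop = TRUE))])
  rownames(out) <- NULL
  out
}

#' Repeated-measures correlation
#'
#' The common within-subject association between paired measures: an
#' analysis-of-covariance with subject as factor and a common slope.
#' \code{r} carries the slope's sign and magnitude
#' \code{sqrt(SS_measure / (SS_measure + SS_error))}; degrees of freedom are
#' \code{N_obs - N_subjects - 1} (\code{N k - N - 1} for balanced data) and
#' the p-value comes from the common slope's F(1, df).
#'
#' @param x,y paired observations.
#' @param subject subject identifier per observation.
#' @return list with \code{r}, \code{df}, \code{p}, \code{slope} and the
#'   underlying \code{lm} fit.
#' @export
rmcorr <- function(x, y, subject) {
  stopifnot(length(x) == length(y), length(x) == length(subject))
  subject <- factor(subject)
  if (nlevels(subject) < 2) stop("need at least 2 subjects")
  if (any(table(subject) < 2)) stop("need >= 2 observations per subject")
  fit <- lm(y ~ subject + x)
  if (anyNA(coef(fit))) stop("zero within-subject variance in x")
  a <- anova(fit)
  ss_x <- a["x", "Sum Sq"]
  ss_err <- a["Residuals", "Sum Sq"]
  df <- a["Residuals", "Df"]
  slope <- unname(coef(fit)["x"])
  r <- sign(slope) * sqrt(ss_x / (ss_x + ss_err))
  Fv <- a["x", "F value"]
  list(r = r, df = df, p = pf(Fv, 1, df, lower.tail = FALSE),
       slope = slope, fit = fit)
}

#' Robustness refit after removing influential observations
#'
#' Computes Cook's distance for every observation of the rmcorr model,
#' removes observations exceeding \code{factor} times the average distance,
#' and recomputes the correlation; the degrees of freedom shrink by the
#' number of removed observations.
#'
#' @param x,y,subject as in \code{\link{rmcorr}}.
#' @param factor multiple of the mean Cook's distance beyond which an
#'   observation is excluded (default 5).
#' @return list with the refitted \code{r}, \code{df}, \code{p},
#'   \code{excluded} (indices) and \code{n_excluded}.
#' @export
cooks_refit <- function(x, y, subject, factor = 5) {
  base <- rmcorr(x, y, subject)
  cd <- cooks.distance(base$fit)
  excl <- which(cd > factor * mean(cd))
  if (!length(excl)) {
    return(list(r = base$r, df = base$df, p = base$p,
                excluded = integer(0), n_excluded = 0L))
  }
  keep <- setdiff(seq_along(x), excl)
  left <- table(factor(subject)[keep])
  if (any(left == 0))
    stop("exclusion removed all observations of a subject")
  re <- rmcorr(x[keep], y[keep], subject[keep])
  list(r = re$r, df = re$df, p = re$p, excluded = as.integer(excl),
       n_excluded = length(excl))
}

#' Joint regression of gamma on both bias parameters
#'
#' Subject-centred multiple regression of gamma modulation on the bin-wise
#' drift bias and starting point together, reporting each predictor's
#' partial F (type-III, equal to the squared t of its coefficient with the
#' other predictor in the model).
#'
#' @param gamma,drift_bias,starting_point bin-level vectors.
#' @param subject subject identifier per observation.
#' @param cor_tol absolute within-subject correlation between the
#'   predictors above which a collinearity error is raised.
#' @return data.frame with one row per predictor: partial_F, df1, df2, p.
#' @export
joint_bias_regression <- function(gamma, drift_bias, starting_point,
                                  subject, cor_tol = 0.999) {
  subject <- factor(subject)
  X <- model.matrix(~ subject + drift_bias + starting_point)
  if (qr(X)$rank < ncol(X)) stop("collinear predictors (rank-deficient)")
  cen <- function(v) v - tapply(v, subject, mean)[as.character(subject)]
  if (abs(cor(cen(drift_bias), cen(starting_point))) > cor_tol)
    stop("collinear predictors (within-subject correlation ~ 1)")
  fit <- lm(gamma ~ subject + drift_bias + starting_point)
  sm <- summary(fit)$coefficients
  dfr <- fit$df.residual
  preds <- c("drift_bias", "starting_point")
  data.frame(predictor = preds,
             partial_F = sm[preds, "t value"]^2,
             df1 = 1, df2 = dfr,
             p = 2 * pt(abs(sm[preds, "t value"]), dfr, lower.tail = FALSE))
}

#' Within-subject test of gamma and theta effects on drift bias
#'
#' Regresses each subject's bin-wise drift bias on theta, gamma and their
#' interaction, then tests the coefficient of each term against zero across
#' subjects (one-sample test, reported as F(1, N - 1) = t^2): the gamma
#' effect controlling for theta, the theta effect controlling for gamma,
#' and their interaction.
#'
#' @param drift_bias,theta,gamma bin-level vectors.
#' @param subject subject identifier per observation.
#' @return data.frame with one row per effect: F, df1, df2, p.
#' @export
theta_gamma_anova <- function(drift_bias, theta, gamma, subject) {
  subject <- factor(subject)
  subs <- levels(subject)
  if (length(subs) < 2) stop("need at least 2 subjects")
  coefs <- t(vapply(subs, function(s) {
    i <- subject == s
    if (sum(i) < 4) stop("need >= 4 bins per subject")
    th <- scale(theta[i])[, 1]
    gm <- scale(gamma[i])[, 1]
    if (!all(is.finite(th)) || !all(is.finite(gm)))
      stop("constant theta or gamma within subject ", s)
    coef(lm(drift_bias[i] ~ th + gm + th:gm))[-1]
  }, numeric(3)))
  effects <- c(theta = "th", gamma = "gm", interaction = "th:gm")
  rows <- lapply(names(effects), function(nm) {
    v <- coefs[, effects[[nm]]]
    tt <- t.test(v)
    data.frame(effect = nm, F = unname(tt$statistic)^2, df1 = 1,
               df2 = length(v) - 1, p = tt$p.value)
  })
  do.call(rbind, rows)
}
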