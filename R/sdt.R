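#' Hit and false-alarm rates
#'
#' Hit rate is the proportion of target-present responses among target
#' trials; false-alarm rate the proportion of target-present responses among
#' nontarget trials.
#'
#' @param trials data.frame with columns \code{stimulus}
#'   ("target"/"nontarget") and \code{choice} ("press"/"none").
#' @return list with \code{h}, \code{fa}, and the counts
#'   \code{n_target}, \code{n_nontarget}, \code{n_hit}, \code{n_fa}.
#' @export
response_rates <- function(trials) {
  tgt <- trials$stimulus == "target"
  n_target <- sum(tgt); n_nontarget <- sum(!tgt)
  if (n_target == 0) stop("no target trials: hit rate undefined")
  if (n_nontarget == 0) stop("no nontarget trials: false-alarm rate undefined")
  n_hit <- sum(tgt & trials$choice == "press")
  n_fa <- sum(!tgt & trials$choice == "press")
  list(h = n_hit / n_target, fa = n_fa / n_nontarget,
       n_target = n_target, n_nontarget = n_nontarget,
       n_hit = n_hit, n_fa = n_fa)
}

#' Signal-detection summary: d-prime and criterion
#'
#' \deqn{d' = Z(H) - Z(FA)} \deqn{c = -\frac{1}{2}[Z(H) + Z(FA)]}
#' with Z the inverse standard normal distribution. Positive criterion
#' values reflect a conservative bias. Rates of exactly 0 or 1 are corrected
#' by the log-linear rule, replacing a count of k out of n by
#' (k + 0.5) / (n + 1) for that rate only; the correction is flagged in the
#' output and can be disabled.
#'
#' @param rates output of \code{\link{response_rates}} (or a list with the
#'   same fields).
#' @param correct apply the extreme-rate correction (default TRUE).
#' @return list with \code{h}, \code{fa} (post-correction), \code{dprime},
#'   \code{criterion}, counts and \code{correction_applied}.
#' @export
sdt_summary <- function(rates, correct = TRUE) {
  stopifnot(rates$n_target > 0, rates$n_nontarget > 0)
  h <- rates$h; fa <- rates$fa
  corrected <- FALSE
  fix <- function(rate, k, n) {
    if (rate %in% c(0, 1)) {
      corrected <<- TRUE
      (k + 0.5) / (n + 1)
    } else rate
  }
  if (correct) {
    h <- fix(h, rates$n_hit, rates$n_target)
    fa <- fix(fa, rates$n_fa, rates$n_nontarget)
  }
  if (h <= 0 || h >= 1 || fa <= 0 || fa >= 1)
    stop("rates at 0 or 1 require the extreme-rate correction")
  zh <- qnorm(h); zfa <- qnorm(fa)
  list(h = h, fa = fa, dprime = zh - zfa, criterion = -0.5 * (zh + zfa),
       n_target = rates$n_target, n_nontarget = rates$n_nontarget,
       correction_applied = corrected)
}

#' Per subject-by-condition signal-detection table
#'
#' Pools each subject's trials across sessions/blocks within condition and
#' returns one row per subject-by-condition with rates, d-prime and
#' criterion.
#'
#' @param trials trial table with columns subject, condition, stimulus,
#'   choice.
#' @param correct extreme-rate correction flag passed to
#'   \code{\link{sdt_summary}}.
#' @return data.frame: subject, condition, h, fa, dprime, criterion,
#'   n_target, n_nontarget, correction_applied.
#' @export
sdt_table <- function(trials, correct = TRUE) {
  combos <- unique(trials[, c("subject", "condition")])
  combos <- combos[order(combos$subject, combos$condition), ]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- trials[trials$subject == combos$subject[i] &
                  trials$condition == combos$condition[i], ]
    s <- sdt_summary(response_rates(sub), correct = correct)
    data.frame(subject = combos$subject[i], condition = combos$condition[i],
               h = s$h, fa = s$fa, dprime = s$dprime,
               criterion = s$criterion, n_target = s$n_target,
               n_nontarget = s$n_nontarget,
               correction_applied = s$correction_applied)
  })
  do.call(rbind, rows)
}
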