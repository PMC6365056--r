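#' Simulate go/no-go drift-diffusion trials
#'
#' Euler--Maruyama simulation of the diffusion between an absorbing lower
#' bound (0, implicit target-absent decision) and upper bound (\code{a},
#' target-present decision). Per-step increment is
#' \code{(sign(stimulus) * v + db) * dt + s * sqrt(dt) * N(0, 1)}. An upper
#' crossing yields a press with \code{rt = crossing time + t_nd}, censored to
#' a no-response when \code{rt} exceeds the response deadline (mirroring the
#' task's response window); a lower crossing, or no crossing within the
#' deadline, yields a no-response.
#'
#' @param params a \code{\link{ddm_params}} object.
#' @param stimulus "target" or "nontarget" (scalar).
#' @param n number of trials.
#' @param dt Euler step in seconds (<= 1e-3 recommended; use 1e-4 for
#'   oracle-grade accuracy).
#' @param deadline response deadline in seconds (rt above it counts as
#'   no-response); may be \code{Inf} for uncensored simulation.
#' @param t_max cap on simulated decision time when \code{deadline} is
#'   infinite (default 20 s; residual mass beyond it is negligible for any
#'   reasonable parameter set).
#' @param seed optional integer seed applied locally.
#' @param db_trial optional per-trial drift-bias vector overriding
#'   \code{params$db} trial by trial (length \code{n}).
#' @return data.frame with columns \code{choice} ("press"/"none") and
#'   \code{rt} (seconds, \code{NA} iff choice is "none").
#' @export
ddm_simulate <- function(params, stimulus = c("target", "nontarget"), n,
                         dt = 1e-3, deadline = 0.84, t_max = 20,
                         seed = NULL, db_trial = NULL) {
  stimulus <- match.arg(stimulus)
  stopifnot(inherits(params, "ddm_params"), n >= 0)
  if (dt <= 0) stop("'dt' must be positive")
  if (is.finite(deadline) && deadline <= params$t_nd)
    stop("'deadline' must exceed the non-decision time")
  sim_cap <- if (is.finite(deadline)) deadline - params$t_nd else t_max
  z <- params$z_frac * params$a
  run <- function() {
    if (is.null(db_trial)) {
      mu <- ddm_drift(params, stimulus)
      .ddm_sim_cpp(as.integer(n), mu, params$a, z, params$s, dt, sim_cap)
    } else {
      stopifnot(length(db_trial) == n, all(is.finite(db_trial)))
      sign <- if (stimulus == "target") 1 else -1
      .ddm_sim_vec_cpp(sign * params$v + db_trial, params$a, z, params$s,
                       dt, sim_cap)
    }
  }
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  rt <- res$dtime + params$t_nd
  press <- res$bound == 1L & (!is.finite(deadline) | rt <= deadline)
  data.frame(choice = ifelse(press, "press", "none"),
             rt = ifelse(press, rt, NA_real_))
}
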