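#' Drift-diffusion model parameters
#'
#' Bundles the parameters of the constant-drift diffusion used throughout:
#' evidence accumulates from a starting point \code{z = z_frac * a} between an
#' implicit lower bound at 0 (target-absent decision, no overt response) and
#' an upper bound at \code{a} (target-present decision, button press). The
#' drift on a trial is \code{+v + db} for targets and \code{-v + db} for
#' nontargets: \code{v} is the stimulus-driven drift rate and \code{db} a
#' stimulus-independent drift bias pushing accumulation toward one bound.
#' Crossing times are shifted by the non-decision time \code{t_nd} (sensory
#' encoding plus motor execution). The diffusion noise scale \code{s} is fixed
#' at 1 by convention; all parameter magnitudes are interpreted under that
#' scaling.
#'
#' @param v drift rate (evidence units per second).
#' @param a boundary separation (> 0).
#' @param z_frac relative starting point in (0, 1).
#' @param db drift bias (evidence units per second).
#' @param t_nd non-decision time in seconds (>= 0).
#' @param s diffusion noise scale (> 0, fixed during fitting).
#' @return an object of class \code{ddm_params} (named list).
#' @export
ddm_params <- function(v, a = 1, z_frac = 0.5, db = 0, t_nd = 0.3, s = 1) {
  stopifnot(is.finite(v), is.finite(a), is.finite(z_frac), is.finite(db),
            is.finite(t_nd), is.finite(s))
  if (a <= 0) stop("boundary separation 'a' must be positive")
  if (z_frac <= 0 || z_frac >= 1) stop("'z_frac' must lie strictly in (0, 1)")
  if (t_nd < 0) stop("'t_nd' must be non-negative")
  if (s <= 0) stop("noise scale 's' must be positive")
  structure(list(v = v, a = a, z_frac = z_frac, db = db, t_nd = t_nd, s = s),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf(
    "ddm_params: v=%.3f a=%.3f z_frac=%.3f db=%.3f t_nd=%.3f s=%.3f\n",
    x$v, x$a, x$z_frac, x$db, x$t_nd, x$s))
  invisible(x)
}

# Signed total drift for a stimulus class.
ddm_drift <- function(params, stimulus) {
  sign <- ifelse(stimulus == "target", 1, -1)
  sign * params$v + params$db
}
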