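#' Analytic press probability of the go/no-go diffusion
#'
#' Probability that the diffusion with total drift \code{mu} started at
#' \code{z} between absorbing bounds 0 and \code{a} is absorbed at the upper
#' bound (ignoring any deadline):
#' \deqn{P = (1 - e^{-2 \mu z / s^2}) / (1 - e^{-2 \mu a / s^2})}
#' with the limit \code{z / a} as \code{mu -> 0}.
#'
#' @param mu total drift (stimulus drift plus drift bias).
#' @param a boundary separation.
#' @param z absolute starting point (0 < z < a).
#' @param s diffusion noise scale.
#' @return upper-absorption probability.
#' @export
ddm_press_prob <- function(mu, a, z, s = 1) {
  stopifnot(a > 0, z > 0, z < a, s > 0)
  k <- 2 * mu / s^2
  small <- abs(k * a) < 1e-9
  p <- ifelse(small, z / a, expm1(-k * z) / expm1(-k * a))
  p
}

# Zero-drift unit-bound first-passage density at the LOWER bound, relative
# start w in (0,1), normalized time tau = t / a_tilde^2. Series selection and
# truncation follow the standard small-time / large-time error bounds: the
# representation needing fewer terms for the requested tolerance is used.
.fpt0 <- function(tau, w, tol = 1e-10, max_terms = 1000L) {
  out <- numeric(length(tau))
  pos <- which(tau > 0)
  if (!length(pos)) return(out)
  tau_p <- tau[pos]
  # terms needed, per the usual truncation bounds
  ks <- ifelse(2 * sqrt(2 * pi * tau_p) * tol < 1,
               2 + sqrt(-2 * tau_p * log(2 * sqrt(2 * pi * tau_p) * tol)),
               2)
  ks <- pmax(ks, sqrt(tau_p) + 1)
  kl <- ifelse(pi * tau_p * tol < 1,
               sqrt(-2 * log(pi * tau_p * tol) / (pi^2 * tau_p)),
               1 / (pi * sqrt(tau_p)))
  kl <- pmax(kl, 1 / (pi * sqrt(tau_p)))
  use_small <- ks < kl
  if (max(ceiling(ifelse(use_small, ks, kl))) > max_terms)
    stop("first-passage series: tolerance not achievable within max_terms")
  if (any(use_small)) {
    tt <- tau_p[use_small]
    K <- max(ceiling((max(ks[use_small]) - 1) / 2))
    kk <- seq.int(-K, K)
    # f0 = (2*pi*tau)^{-1/2} tau^{-1} sum_k (w + 2k) exp(-(w + 2k)^2 / (2 tau))
    M <- outer(tt, kk, function(t1, k1) {
      wk <- w + 2 * k1
      wk * exp(-wk^2 / (2 * t1))
    })
    out[pos[use_small]] <- rowSums(M) / sqrt(2 * pi * tt^3)
  }
  if (any(!use_small)) {
    tt <- tau_p[!use_small]
    K <- max(ceiling(max(kl[!use_small])))
    kk <- seq_len(K)
    M <- outer(tt, kk, function(t1, k1)
      k1 * exp(-k1^2 * pi^2 * t1 / 2) * sin(k1 * pi * w))
    out[pos[!use_small]] <- pi * rowSums(M)
  }
  pmax(out, 0)
}

#' First-passage-time density through the upper boundary
#'
#' Density of the decision time for upper-bound (press) absorptions of the
#' diffusion with constant total drift \code{mu}, bounds 0 and \code{a},
#' start \code{z} and noise \code{s}. Computed from the classic dual series
#' representation for the Wiener first-passage density (small-time and
#' large-time expansions, whichever needs fewer terms at the requested
#' tolerance), using the reflection that maps an upper-bound passage onto a
#' lower-bound passage with negated drift and mirrored start.
#'
#' @param t vector of decision times (seconds, > 0; density is 0 at t <= 0).
#' @param mu total drift.
#' @param a boundary separation.
#' @param z absolute starting point.
#' @param s diffusion noise scale.
#' @param tol series truncation tolerance.
#' @param max_terms maximum series terms before giving up.
#' @return density values (not including non-decision time).
#' @export
fpt_upper <- function(t, mu, a, z, s = 1, tol = 1e-10, max_terms = 1000L) {
  stopifnot(a > 0, z > 0, z < a, s > 0)
  # reflect: upper passage of (mu, z) == lower passage of (-mu, a - z);
  # rescale to unit noise
  at <- a / s
  v <- -mu / s
  w <- (a - z) / a
  tau <- t / at^2
  f0 <- .fpt0(tau, w, tol = tol, max_terms = max_terms)
  dens <- (1 / at^2) * exp(-v * at * w - v^2 * t / 2) * f0
  dens[t <= 0] <- 0
  dens
}

# Cumulative upper-passage mass M(t) = P(upper crossing with decision time
# <= t) at the given breakpoints: composite 16-point Gauss-Legendre
# quadrature of the first-passage density with panels capped at `h` seconds
# so the sharp early peak is resolved (compiled hot path).
ddm_upper_mass <- function(breaks, mu, a, z, s = 1, h = 0.05,
                           tol = 1e-10, max_terms = 1000L) {
  b <- sort(breaks)
  stopifnot(all(b >= 0), all(is.finite(b)))
  m <- .ddm_upper_mass_cpp(b, mu, a, z, s, h, tol, as.integer(max_terms))
  unname(m[match(breaks, b)])
}
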