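# Four-state RaM gating reduced to one differential-algebraic equation.
#
# Under the rapid-equilibrium assumption the paired states R/O and I1/I2
# collapse into two super-states, RO and I1I2 = 1 - RO. Ca2+ partitions
# each super-state instantaneously via Hill curves (f_Ca on RO, g_Ca on
# I1I2), so the only slow variable is RO, governed by the two-state master
# equation
#
#   dRO/dt = k_in(ca) (1 - RO) - k_out(ca) RO
#   k_out(ca) = k_O_I1 f_Ca + k_R_I2 (1 - f_Ca)
#   k_in(ca)  = k_I1_O g_Ca + k_I2_R (1 - g_Ca)
#
# i.e. each super-state leaves through whichever conformational route its
# instantaneous Ca2+-bound fraction feeds. At constant ca this is linear
# with time constant tau = 1/(k_in + k_out) and steady state
# RO_inf = k_in/(k_in + k_out), giving the analytic propagator used for all
# piecewise-constant protocols.

#' Hill binding fraction, overflow-safe
#'
#' Fraction of sites with Ca2+ bound, ca^n / (ca^n + K^n). Evaluated as a
#' logistic in log-concentration, \code{plogis(n (log ca - log K))}, so that
#' the steep cooperativity used here (n = 24) neither overflows nor
#' underflows anywhere in 0..1e7 nM, and \code{ca == K} returns exactly 0.5.
#' By definition the zero-ligand limit is 0.
#'
#' @param ca free Ca2+ concentration, nM (vectorized, >= 0).
#' @param K half-saturation threshold, nM (> 0).
#' @param n Hill coefficient (>= 1).
#' @return binding fraction(s) in [0, 1].
#' @export
hillFraction <- function(ca, K, n) {
  if (!is.numeric(ca) || any(!is.finite(ca)) || any(ca < 0))
    stop("'ca' must be finite and >= 0")
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
    stop("'K' must be a single finite value > 0")
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    stop("'n' must be a single finite value >= 1")
  out <- numeric(length(ca))
  pos <- ca > 0
  out[pos] <- stats::plogis(n * (log(ca[pos]) - log(K)))
  out[ca == K] <- 0.5
  out
}

#' Effective transition rates out of and into the RO super-state
#'
#' Assembles the convex combinations of conformational rates weighted by
#' the instantaneous Ca2+-bound fractions: the RO pool exits via O -> I1
#' from its bound fraction f_Ca and via R -> I2 from its unbound fraction;
#' the inhibited pool returns via I1 -> O (bound, g_Ca) and I2 -> R
#' (unbound).
#'
#' @param ca free Ca2+ concentration, nM (vectorized).
#' @param p a \code{ram_params} object.
#' @return list with components \code{out} and \code{into}, both 1/s.
#' @export
transitionRates <- function(ca, p) {
  f <- hillFraction(ca, p$K_O, p$n)
  g <- hillFraction(ca, p$K_I, p$n)
  list(out  = p$k_O_I1 * f + p$k_R_I2 * (1 - f),
       into = p$k_I1_O * g + p$k_I2_R * (1 - g))
}

#' Time derivative of the RO super-state fraction
#'
#' @param RO fraction of RaM in the rest+open super-state, in [0, 1].
#' @param ca free Ca2+ concentration, nM.
#' @param p a \code{ram_params} object.
#' @return dRO/dt in 1/s; zero exactly at \code{steadyStateRO(ca, p)}.
#' @export
dROdt <- function(RO, ca, p) {
  if (any(RO < 0 | RO > 1)) stop("'RO' must lie in [0, 1]")
  k <- transitionRates(ca, p)
  k$into * (1 - RO) - k$out * RO
}

#' Steady-state RO fraction at fixed Ca2+
#'
#' \code{k_in / (k_in + k_out)}; monotonically non-increasing in ca (high
#' Ca2+ drives the pool into the inhibited states).
#'
#' @inheritParams dROdt
#' @return steady-state fraction(s) in [0, 1].
#' @export
steadyStateRO <- function(ca, p) {
  k <- transitionRates(ca, p)
  k$into / (k$into + k$out)
}

#' Relaxation time constant at fixed Ca2+
#'
#' \code{1 / (k_in + k_out)}: the single exponential time scale of
#' RO <-> I1I2 interconversion at that Ca2+ level.
#'
#' @inheritParams dROdt
#' @return time constant(s), s.
#' @export
timeConstant <- function(ca, p) {
  k <- transitionRates(ca, p)
  1 / (k$into + k$out)
}

#' Analytic RO time course at constant Ca2+
#'
#' The linear relaxation \code{RO_inf + (RO0 - RO_inf) exp(-t / tau)}.
#'
#' @param t time(s) since the start of the constant-Ca2+ interval, s (>= 0).
#' @param RO0 initial RO fraction.
#' @param ca free Ca2+ concentration held constant over [0, t], nM.
#' @param p a \code{ram_params} object.
#' @return RO fraction(s) at the requested times.
#' @export
roAnalytic <- function(t, RO0, ca, p) {
  if (any(t < 0)) stop("'t' must be >= 0")
  if (RO0 < 0 || RO0 > 1) stop("'RO0' must lie in [0, 1]")
  ro_inf <- steadyStateRO(ca, p)
  tau <- timeConstant(ca, p)
  ro_inf + (RO0 - ro_inf) * exp(-t / tau)
}

#' Split the super-state fractions into the four underlying states
#'
#' Applies the rapid-equilibrium partition: R = (1 - f_Ca) RO,
#' O = f_Ca RO, I1 = g_Ca (1 - RO), I2 = (1 - g_Ca)(1 - RO). The four
#' fractions sum to one by construction.
#'
#' @inheritParams dROdt
#' @return data.frame with columns R, O, I1, I2.
#' @export
stateFractions <- function(RO, ca, p) {
  f <- hillFraction(ca, p$K_O, p$n)
  g <- hillFraction(ca, p$K_I, p$n)
  i12 <- 1 - RO
  data.frame(R = (1 - f) * RO, O = f * RO,
             I1 = g * i12, I2 = (1 - g) * i12)
}

#' Time for RO to recover to a fraction of its steady state
#'
#' Closed form from the analytic propagator: starting at \code{RO0}, RO
#' reaches \code{frac * RO_inf} after
#' \code{tau * log((RO_inf - RO0) / (RO_inf (1 - frac)))}. With the default
#' fully-inhibited start (RO0 = 0) and 95% threshold this is tau * log(20):
#' about 78 s for heart at 50 nM and 0.03 s for liver, the tissue contrast
#' the model is built around.
#'
#' @param p a \code{ram_params} object.
#' @param ca recovery Ca2+ level, nM (must lie below steady state support,
#'   i.e. \code{frac * RO_inf} must be reachable from \code{RO0}).
#' @param RO0 starting RO fraction (default 0, fully inhibited).
#' @param frac recovery threshold as a fraction of RO_inf (default 0.95).
#' @return recovery time, s.
#' @export
recoveryTime <- function(p, ca, RO0 = 0, frac = 0.95) {
  ro_inf <- steadyStateRO(ca, p)
  if (frac * ro_inf <= RO0)
    return(0)
  timeConstant(ca, p) * log((ro_inf - RO0) / (ro_inf * (1 - frac)))
}
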