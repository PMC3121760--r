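# Voltage-dependent, saturable, unidirectional Ca2+ influx through open RaM
# and its closed-form time integral over a constant-Ca2+ segment.

#' Membrane environment for electrodiffusive Ca2+ entry
#'
#' Physical constants and the (fixed) inner-membrane potential driving
#' Ca2+ into the matrix. The default 190 mV corresponds to mitochondria at
#' rest (state-2 respiration); the potential is held constant per
#' simulation, with no feedback of uptake on the potential.
#'
#' @param delta_psi inner-membrane potential, mV (matrix negative taken as
#'   positive driving force). Default 190.
#' @param temperature absolute temperature, K. Default 298.
#' @param voltage_form optional replacement for the default barrier model:
#'   a function \code{function(delta_psi, env)} returning the dimensionless
#'   influx multiplier. The default (NULL) uses a single centered Eyring
#'   barrier under the constant-field assumption,
#'   \code{exp(z F dPsi / (2 R T))}. Alternative barrier shapes fit uptake
#'   data equally well and differ only by a rescaling of X_RaM.
#' @return an object of class \code{membrane_env} with fixed constants
#'   z = +2, F = 96.480 J mol^-1 mV^-1, R = 8.314 J mol^-1 K^-1.
#' @export
membraneEnv <- function(delta_psi = 190, temperature = 298,
                        voltage_form = NULL) {
  if (!is.numeric(temperature) || temperature <= 0)
    stop("'temperature' must be > 0")
  if (!is.null(voltage_form) && !is.function(voltage_form))
    stop("'voltage_form' must be NULL or a function(delta_psi, env)")
  structure(
    list(delta_psi = as.numeric(delta_psi),
         temperature = as.numeric(temperature),
         z_Ca = 2, F = 96.480, R_gas = 8.314,
         voltage_form = voltage_form),
    class = "membrane_env")
}

#' @export
print.membrane_env <- function(x, ...) {
  cat(sprintf(
    "Membrane environment: dPsi = %g mV, T = %g K (z = +%g)%s\n",
    x$delta_psi, x$temperature, x$z_Ca,
    if (is.null(x$voltage_form)) ", centered Eyring barrier"
    else ", custom voltage form"))
  invisible(x)
}

#' Dimensionless voltage multiplier on unidirectional influx
#'
#' For the default single centered Eyring barrier under the Goldman
#' constant-field assumption the inward rate is scaled by
#' \code{exp(z F dPsi / (2 R T))}: unity at zero field, monotonically
#' increasing with potential, about 1.63e3 at 190 mV and 298 K.
#'
#' @param env a \code{membrane_env} object.
#' @return the multiplier (dimensionless, > 0).
#' @export
voltageFactor <- function(env) {
  if (!is.null(env$voltage_form)) return(env$voltage_form(env$delta_psi, env))
  exp(env$z_Ca * env$F * env$delta_psi / (2 * env$R_gas * env$temperature))
}

#' Instantaneous unidirectional Ca2+ influx via RaM
#'
#' \code{X_RaM * O * ca/(ca + K_Ca) * voltageFactor(env)} where
#' \code{O = f_Ca * RO} is the open fraction. Transport is saturable in
#' Ca2+ and strictly unidirectional: at physiological potential the
#' outward flux is negligible and is set identically to zero, so the flux
#' is non-negative for all inputs.
#'
#' @param ca free extramitochondrial Ca2+, nM (>= 0, vectorized).
#' @param RO rest+open super-state fraction, in [0, 1].
#' @param p a \code{ram_params} object.
#' @param env a \code{membrane_env} object.
#' @return influx, nmol mg^-1 s^-1.
#' @export
ramFlux <- function(ca, RO, p, env) {
  if (any(RO < 0 | RO > 1)) stop("'RO' must lie in [0, 1]")
  f <- hillFraction(ca, p$K_O, p$n)
  p$X_RaM * f * RO * (ca / (ca + p$K_Ca)) * voltageFactor(env)
}

#' Closed-form net uptake over one constant-Ca2+ segment
#'
#' Because the open fraction is the only time-dependent factor in the flux,
#' the cumulative uptake over a segment of length \code{duration} at fixed
#' \code{ca} integrates analytically:
#' \deqn{y = X_{RaM} \frac{ca}{ca + K_{Ca}} V f_{Ca}
#'   \left[ RO_\infty \Delta t +
#'   (RO_0 - RO_\infty)\,\tau\,(1 - e^{-\Delta t/\tau}) \right]}
#' with V the voltage multiplier. The first bracket term is the steady
#' leak through the residual open fraction; the second is the fast
#' transient that empties the initially available RO pool, saturating on
#' the tau time scale (about 10 ms at saturating Ca2+).
#'
#' @param ca Ca2+ level held constant over the segment, nM.
#' @param RO0 RO fraction at segment start.
#' @param duration segment length, s (>= 0).
#' @param p a \code{ram_params} object.
#' @param env a \code{membrane_env} object.
#' @return list with \code{uptake} (nmol/mg, >= 0) and \code{RO_end}
#'   (fraction at segment end from the analytic propagator).
#' @export
netUptakeSegment <- function(ca, RO0, duration, p, env) {
  if (duration < 0) stop("'duration' must be >= 0")
  list(uptake = uptakeAtTime(duration, ca, RO0, p, env),
       RO_end = roAnalytic(duration, RO0, ca, p))
}

# Cumulative uptake t seconds into a constant-ca segment (vectorized in t).
# Shared by netUptakeSegment and trajectory sampling.
uptakeAtTime <- function(t, ca, RO0, p, env) {
  f <- hillFraction(ca, p$K_O, p$n)
  ro_inf <- steadyStateRO(ca, p)
  tau <- timeConstant(ca, p)
  amp <- p$X_RaM * (ca / (ca + p$K_Ca)) * voltageFactor(env) * f
  amp * (ro_inf * t + (RO0 - ro_inf) * tau * (1 - exp(-t / tau)))
}
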