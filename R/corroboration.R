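# Coupled matrix/buffer Ca2+ system for corroborating the gating model
# against caged-Ca2+ pulse-train experiments on single mitochondria:
# RaM influx plus uniporter influx into a buffered matrix with first-order
# H+/Ca2+-exchanger efflux, driven by a square-wave photorelease source
# with first-order washout of buffer Ca2+.

#' Parameters of the matrix/buffer corroboration model
#'
#' Defaults are the published corroboration set: CHE efflux rate 350/s,
#' basal matrix and buffer Ca2+ 90 nM, matrix buffering strength 1000,
#' washout rate 0.99/s, uniporter activity 2e5 nM/s with 10 uM affinity
#' (stored in nM).
#'
#' @param k_CHE first-order Ca2+ efflux rate via the H+/Ca2+ exchanger, 1/s.
#' @param ca_x_min basal matrix free Ca2+, nM.
#' @param beta_Ca dimensionless matrix Ca2+ buffering strength (ratio of
#'   total to free Ca2+ changes).
#' @param k_washout first-order rate of Ca2+ diffusion away from the
#'   photorelease site, 1/s.
#' @param ca_e_min basal buffer free Ca2+, nM.
#' @param X_CU uniporter activity, nM/s.
#' @param K_CU uniporter Ca2+ affinity, nM (default 1e4 nM = 10 uM).
#' @param ram_scale conversion of RaM flux (nmol mg^-1 s^-1) into a matrix
#'   concentration rate (nM/s). The source traces are uncalibrated, so
#'   this bridge is a free scale; the default 800 makes peak RaM flux at
#'   500 nM comparable to the uniporter flux there.
#' @param cu_exponent Hill exponent of the uniporter saturation (default
#'   1; an exponent of 2 is plausible from the uniporter literature and is
#'   exposed here as an option).
#' @return an object of class \code{corro_params}.
#' @export
corroParams <- function(k_CHE = 350, ca_x_min = 90, beta_Ca = 1000,
                        k_washout = 0.99, ca_e_min = 90,
                        X_CU = 2e5, K_CU = 1e4,
                        ram_scale = 800, cu_exponent = 1) {
  vals <- c(k_CHE = k_CHE, ca_x_min = ca_x_min, beta_Ca = beta_Ca,
            k_washout = k_washout, ca_e_min = ca_e_min, X_CU = X_CU,
            K_CU = K_CU, ram_scale = ram_scale, cu_exponent = cu_exponent)
  for (f in names(vals))
    if (!is.numeric(vals[[f]]) || !is.finite(vals[[f]]) || vals[[f]] <= 0)
      stop(sprintf("'%s' must be a single finite value > 0", f))
  structure(as.list(vals), class = "corro_params")
}

#' @export
print.corro_params <- function(x, ...) {
  cat("Matrix/buffer corroboration parameters:\n")
  cat(sprintf("  k_CHE = %g /s  beta_Ca = %g  k_washout = %g /s\n",
              x$k_CHE, x$beta_Ca, x$k_washout))
  cat(sprintf("  basal Ca2+: matrix %g nM, buffer %g nM\n",
              x$ca_x_min, x$ca_e_min))
  cat(sprintf("  uniporter: X_CU = %g nM/s, K_CU = %g nM (exponent %g)\n",
              x$X_CU, x$K_CU, x$cu_exponent))
  cat(sprintf("  RaM flux bridge: %g nM per nmol/mg\n", x$ram_scale))
  invisible(x)
}

#' Square-wave photorelease pulse train
#'
#' Each event delivers \code{amplitude} nM of Ca2+ to the buffer as a
#' square wave of height \code{amplitude / pulse_width} lasting
#' \code{pulse_width}, repeated every \code{period} seconds. With widths
#' far below the washout time constant the achieved buffer peak is close
#' to \code{amplitude} above its pre-pulse level.
#'
#' @param amplitude Ca2+ delivered per event, nM.
#' @param pulse_width square-wave width, s (0 < width < period).
#' @param period event spacing, s.
#' @param n_events number of events (>= 1); zero amplitude is allowed and
#'   leaves the system at its pulse-free fixed point.
#' @return an object of class \code{pulse_train}.
#' @export
pulseTrain <- function(amplitude, pulse_width, period, n_events) {
  if (amplitude < 0) stop("'amplitude' must be >= 0")
  if (!(period > pulse_width && pulse_width > 0))
    stop("need period > pulse_width > 0")
  if (n_events < 1) stop("'n_events' must be >= 1")
  structure(list(amplitude = as.numeric(amplitude),
                 pulse_width = as.numeric(pulse_width),
                 period = as.numeric(period),
                 n_events = as.integer(n_events)),
            class = "pulse_train")
}

#' Uniporter Ca2+ influx
#'
#' Saturable uniporter flux
#' \code{X_CU ca^h / (ca^h + K_CU^h)} with the configured Hill exponent h
#' (default 1): about 9.52e3 nM/s at 500 nM buffer Ca2+ with defaults.
#'
#' @param ca_e buffer free Ca2+, nM (>= 0, vectorized).
#' @param cp a \code{corro_params} object.
#' @return influx, nM/s.
#' @export
cuFlux <- function(ca_e, cp) {
  if (any(ca_e < 0)) stop("'ca_e' must be >= 0")
  out <- numeric(length(ca_e))
  pos <- ca_e > 0
  out[pos] <- cp$X_CU *
    stats::plogis(cp$cu_exponent * (log(ca_e[pos]) - log(cp$K_CU)))
  out
}

#' Right-hand side of the matrix/buffer system
#'
#' State is (ca_x, ca_e, RO). Matrix Ca2+ gains the (scaled) RaM and
#' uniporter influxes and loses first-order CHE efflux, all attenuated by
#' the buffering strength; buffer Ca2+ sees only the square-wave source
#' and first-order washout (mitochondrial fluxes are negligible for the
#' buffer, whose volume dwarfs a single mitochondrion); RO follows the
#' gating equation at the instantaneous buffer Ca2+, since the external
#' level is no longer piecewise constant.
#'
#' @param t time, s.
#' @param state numeric vector or list with ca_x, ca_e (nM) and RO.
#' @param cp a \code{corro_params} object.
#' @param p a \code{ram_params} object (liver in the published scenarios).
#' @param env a \code{membrane_env} object.
#' @param train a \code{pulse_train} (or NULL for no pulses).
#' @return numeric vector of derivatives (d ca_x, d ca_e, d RO) per second.
#' @export
corroRHS <- function(t, state, cp, p, env, train = NULL) {
  ca_x <- max(state[[1]], 0); ca_e <- max(state[[2]], 0)
  RO <- min(max(state[[3]], 0), 1)
  j_ram <- cp$ram_scale * ramFlux(ca_e, RO, p, env)
  j_cu <- cuFlux(ca_e, cp)
  d_ca_x <- (j_ram + j_cu - cp$k_CHE * (ca_x - cp$ca_x_min)) / cp$beta_Ca
  j_pulse <- 0
  if (!is.null(train) && train$amplitude > 0) {
    k <- floor(t / train$period)
    if (k >= 0 && k < train$n_events &&
        (t - k * train$period) < train$pulse_width)
      j_pulse <- train$amplitude / train$pulse_width
  }
  d_ca_e <- j_pulse - cp$k_washout * (ca_e - cp$ca_e_min)
  d_RO <- dROdt(RO, ca_e, p)
  c(d_ca_x, d_ca_e, d_RO)
}

#' Integrate the matrix/buffer system over a pulse train
#'
#' Stiff-capable adaptive integration (lsoda) carried out piecewise
#' between square-wave edges, so each integrated interval has a smooth
#' right-hand side and no pulse is stepped over. Output is sampled densely
#' enough to resolve the pulse widths, and the state just before each
#' pulse onset is recorded exactly from the interval endpoints.
#'
#' @param train a \code{pulse_train}.
#' @param cp a \code{corro_params} object.
#' @param p a \code{ram_params} object.
#' @param env a \code{membrane_env} object.
#' @param t_end end time, s (default: one period past the last event).
#' @param state0 initial state (default: basal buffer Ca2+, gating steady
#'   state there, and the matrix level balancing the basal leak fluxes).
#' @param n_out approximate number of output samples per smooth interval.
#' @param rtol,atol integration tolerances.
#' @return an object of class \code{corro_sim}: \code{trajectory}
#'   (data.frame t, ca_e, ca_x, RO), \code{pre_pulse_RO} (RO immediately
#'   before each event) and \code{recovery_ratio}
#'   (pre-pulse RO relative to the first event).
#' @export
simulateCorroboration <- function(train, cp = corroParams(),
                                  p = ramParamSet("liver"),
                                  env = membraneEnv(),
                                  t_end = NULL, state0 = NULL,
                                  n_out = 40L, rtol = 1e-8, atol = 1e-10) {
  if (is.null(t_end)) t_end <- train$n_events * train$period
  if (is.null(state0)) {
    ro0 <- steadyStateRO(cp$ca_e_min, p)
    ca_x0 <- cp$ca_x_min +
      (cuFlux(cp$ca_e_min, cp) +
       cp$ram_scale * ramFlux(cp$ca_e_min, ro0, p, env)) / cp$k_CHE
    state0 <- c(ca_x = ca_x0, ca_e = cp$ca_e_min, RO = ro0)
  }
  edges <- sort(unique(c(
    0, t_end,
    rep(seq_len(train$n_events) - 1L, each = 2L) * train$period +
      c(0, train$pulse_width))))
  edges <- edges[edges >= 0 & edges <= t_end]
  traj <- NULL
  state <- state0
  pre_pulse <- numeric(0)
  onsets <- (seq_len(train$n_events) - 1L) * train$period
  for (i in seq_len(length(edges) - 1L)) {
    a <- edges[i]; b <- edges[i + 1L]
    if (a %in% onsets) pre_pulse <- c(pre_pulse, state[["RO"]])
    times <- seq(a, b, length.out = max(5L, n_out))
    # the square wave is constant within each interval: freeze it from the
    # interval midpoint so the integrator never straddles an edge
    mid <- (a + b) / 2
    k <- floor(mid / train$period)
    on <- train$amplitude > 0 && k < train$n_events &&
      (mid - k * train$period) < train$pulse_width
    jp <- if (on) train$amplitude / train$pulse_width else 0
    sol <- deSolve::lsoda(state, times, function(t, y, parms) {
      d <- corroRHS(t, y, cp, p, env, train = NULL)
      d[2] <- d[2] + jp
      list(d)
    }, parms = NULL, rtol = rtol, atol = atol)
    state <- stats::setNames(as.numeric(sol[nrow(sol), -1]),
                             c("ca_x", "ca_e", "RO"))
    traj <- rbind(traj, sol[if (is.null(traj)) TRUE else -1, , drop = FALSE])
  }
  if (length(pre_pulse) < train$n_events && t_end >= max(onsets))
    pre_pulse <- c(pre_pulse, state[["RO"]])[seq_len(train$n_events)]
  traj <- as.data.frame(traj)
  names(traj) <- c("t", "ca_x", "ca_e", "RO")
  structure(
    list(trajectory = traj[, c("t", "ca_e", "ca_x", "RO")],
         pre_pulse_RO = pre_pulse,
         recovery_ratio = pre_pulse / pre_pulse[1],
         train = train, params = cp),
    class = "corro_sim")
}

#' @export
print.corro_sim <- function(x, ...) {
  cat(sprintf(
    "Matrix/buffer simulation: %d pulse(s) of %g nM every %g s\n",
    x$train$n_events, x$train$amplitude, x$train$period))
  cat("  inter-pulse RO recovery ratios:",
      paste(sprintf("%.3g", x$recovery_ratio), collapse = ", "), "\n")
  invisible(x)
}

#' Published-style pulse-train scenarios
#'
#' Two caged-Ca2+ photorelease regimes: the high-frequency scenario uses
#' 5.5 ms UV pulses producing ~5 uM buffer peaks at 1 s spacing (RaM
#' recovers less and less between successive pulses because buffer Ca2+
#' never falls below the inhibition threshold); the low-frequency scenario
#' uses 0.5 ms pulses producing ~450 nM peaks at 10 s spacing (buffer
#' Ca2+ washes out below threshold between events, so RaM fully recovers
#' before every pulse). Pulse spacings are not published; these defaults
#' bracket the washout time constant on either side.
#'
#' @param name "high_freq" or "low_freq".
#' @param cp a \code{corro_params} object.
#' @param p a \code{ram_params} object (liver by default, as published).
#' @param env a \code{membrane_env} object.
#' @param ... further arguments to \code{\link{simulateCorroboration}}.
#' @return a \code{corro_sim} object.
#' @export
simulateScenario <- function(name = c("high_freq", "low_freq"),
                             cp = corroParams(),
                             p = ramParamSet("liver"),
                             env = membraneEnv(), ...) {
  name <- match.arg(name)
  train <- switch(name,
    high_freq = pulseTrain(amplitude = 5000 - cp$ca_e_min,
                           pulse_width = 0.0055, period = 1,
                           n_events = 10L),
    low_freq = pulseTrain(amplitude = 450 - cp$ca_e_min,
                          pulse_width = 0.0005, period = 10,
                          n_events = 5L))
  simulateCorroboration(train, cp, p, env, ...)
}
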