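# Piecewise-constant Ca2+ pulse protocols and the experiment-family scans
# (sustained pulse, interpulse-duration scan, interpulse-height scan,
# multiple-short-pulses versus one long pulse).

#' Pulse-protocol description
#'
#' A piecewise-constant, right-continuous extramitochondrial Ca2+ waveform:
#' an equilibration level (prepulse), \code{n_pulses} pulses of equal
#' height and duration separated by interpulse intervals, and an optional
#' postpulse tail. This is the waveform class used by the source rapid-
#' uptake experiments, where the apparatus held Ca2+ fixed within each
#' phase.
#'
#' @param pulse_height pulse Ca2+ level, nM.
#' @param pulse_duration pulse length, s.
#' @param prepulse_height equilibration Ca2+ level before the first pulse,
#'   nM (default 50, well below both gating thresholds).
#' @param interpulse_height Ca2+ level between pulses, nM.
#' @param interpulse_duration time between pulses, s.
#' @param n_pulses number of pulses (>= 1).
#' @param postpulse_height Ca2+ level after the last pulse, nM.
#' @param postpulse_duration tail length, s (default 0: no tail segment).
#' @param prepulse_equilibration if TRUE (default) the simulation starts
#'   from the gating steady state at the prepulse level, mimicking the
#'   preincubation of the source experiments; if FALSE it starts fully
#'   rested (RO = 1).
#' @return an object of class \code{pulse_protocol}.
#' @export
pulseProtocol <- function(pulse_height, pulse_duration,
                          prepulse_height = 50,
                          interpulse_height = 50, interpulse_duration = 0,
                          n_pulses = 1L,
                          postpulse_height = prepulse_height,
                          postpulse_duration = 0,
                          prepulse_equilibration = TRUE) {
  conc <- c(prepulse_height = prepulse_height, pulse_height = pulse_height,
            interpulse_height = interpulse_height,
            postpulse_height = postpulse_height)
  for (f in names(conc))
    if (!is.numeric(conc[[f]]) || conc[[f]] < 0)
      stop(sprintf("'%s' must be >= 0", f))
  dur <- c(pulse_duration = pulse_duration,
           interpulse_duration = interpulse_duration,
           postpulse_duration = postpulse_duration)
  for (f in names(dur))
    if (!is.numeric(dur[[f]]) || dur[[f]] < 0)
      stop(sprintf("'%s' must be >= 0", f))
  if (n_pulses < 1) stop("'n_pulses' must be >= 1")
  structure(
    list(prepulse_height = as.numeric(prepulse_height),
         pulse_height = as.numeric(pulse_height),
         pulse_duration = as.numeric(pulse_duration),
         interpulse_height = as.numeric(interpulse_height),
         interpulse_duration = as.numeric(interpulse_duration),
         n_pulses = as.integer(n_pulses),
         postpulse_height = as.numeric(postpulse_height),
         postpulse_duration = as.numeric(postpulse_duration),
         prepulse_equilibration = isTRUE(prepulse_equilibration)),
    class = "pulse_protocol")
}

#' @export
print.pulse_protocol <- function(x, ...) {
  cat(sprintf(
    "Pulse protocol: %d x %g s at %g nM (prepulse %g nM%s)\n",
    x$n_pulses, x$pulse_duration, x$pulse_height, x$prepulse_height,
    if (x$prepulse_equilibration) ", equilibrated" else ""))
  if (x$n_pulses > 1L)
    cat(sprintf("  interpulse: %g s at %g nM\n",
                x$interpulse_duration, x$interpulse_height))
  if (x$postpulse_duration > 0)
    cat(sprintf("  postpulse: %g s at %g nM\n",
                x$postpulse_duration, x$postpulse_height))
  invisible(x)
}

#' Expand a protocol into ordered constant-Ca2+ segments
#'
#' @param protocol a \code{pulse_protocol}.
#' @return data.frame with columns \code{ca} (nM), \code{duration} (s) and
#'   \code{kind} ("pulse", "interpulse" or "postpulse"); pulses and
#'   interpulses alternate, ending on the final pulse, followed by the
#'   postpulse tail when its duration is positive.
#' @export
buildSegments <- function(protocol) {
  stopifnot(inherits(protocol, "pulse_protocol"))
  np <- protocol$n_pulses
  ca <- rep(c(protocol$pulse_height, protocol$interpulse_height),
            length.out = 2L * np - 1L)
  dur <- rep(c(protocol$pulse_duration, protocol$interpulse_duration),
             length.out = 2L * np - 1L)
  kind <- rep(c("pulse", "interpulse"), length.out = 2L * np - 1L)
  if (protocol$postpulse_duration > 0) {
    ca <- c(ca, protocol$postpulse_height)
    dur <- c(dur, protocol$postpulse_duration)
    kind <- c(kind, "postpulse")
  }
  data.frame(ca = ca, duration = dur, kind = kind)
}

#' Simulate a pulse protocol with the analytic propagator
#'
#' Chains constant-Ca2+ segments: within each segment the RO fraction
#' follows the closed-form relaxation and the cumulative uptake its
#' closed-form integral; RO is continuous across segment boundaries (only
#' the Ca2+ level jumps). Per-pulse uptake summaries exclude interpulse
#' and postpulse segments, matching how the source experiments quantified
#' uptake per pulse.
#'
#' @param protocol a \code{pulse_protocol}.
#' @param p a \code{ram_params} object.
#' @param env a \code{membrane_env} object (default \code{membraneEnv()}).
#' @param points_per_segment trajectory sampling density (default 25).
#' @return an object of class \code{ram_uptake_sim}: a list with
#'   \code{segments} (segment table with per-segment uptake and RO
#'   endpoints), \code{pulse_uptake} (vector, one entry per pulse),
#'   \code{total_pulse_uptake}, \code{total_uptake} (all segments),
#'   \code{final_RO}, and \code{trajectory} (data.frame time_s, ca_nM, RO,
#'   cumulative_uptake_nmol_per_mg).
#' @export
simulateProtocol <- function(protocol, p, env = membraneEnv(),
                             points_per_segment = 25L) {
  seg <- buildSegments(protocol)
  ro <- if (protocol$prepulse_equilibration)
    steadyStateRO(protocol$prepulse_height, p) else 1
  n <- nrow(seg)
  seg$uptake <- numeric(n)
  seg$RO_start <- numeric(n)
  seg$RO_end <- numeric(n)
  t0 <- 0
  cum <- 0
  tt <- 0; cc <- protocol$prepulse_height; rr <- ro; uu <- 0
  for (i in seq_len(n)) {
    seg$RO_start[i] <- ro
    res <- netUptakeSegment(seg$ca[i], ro, seg$duration[i], p, env)
    seg$uptake[i] <- res$uptake
    seg$RO_end[i] <- res$RO_end
    if (seg$duration[i] > 0) {
      ts <- seq(0, seg$duration[i], length.out = points_per_segment)
      tt <- c(tt, t0 + ts)
      cc <- c(cc, rep(seg$ca[i], length(ts)))
      rr <- c(rr, roAnalytic(ts, ro, seg$ca[i], p))
      uu <- c(uu, cum + uptakeAtTime(ts, seg$ca[i], ro, p, env))
    }
    cum <- cum + res$uptake
    ro <- res$RO_end
    t0 <- t0 + seg$duration[i]
  }
  pulse_uptake <- seg$uptake[seg$kind == "pulse"]
  structure(
    list(protocol = protocol,
         segments = seg,
         pulse_uptake = pulse_uptake,
         total_pulse_uptake = sum(pulse_uptake),
         total_uptake = sum(seg$uptake),
         final_RO = ro,
         trajectory = data.frame(
           time_s = tt, ca_nM = cc, RO = rr,
           cumulative_uptake_nmol_per_mg = uu)),
    class = "ram_uptake_sim")
}

#' @export
print.ram_uptake_sim <- function(x, ...) {
  cat(sprintf(
    "RaM protocol simulation: %d segment(s), total pulse uptake %.4g nmol/mg\n",
    nrow(x$segments), x$total_pulse_uptake))
  cat(sprintf("  per-pulse uptake: %s\n",
              paste(sprintf("%.4g", x$pulse_uptake), collapse = ", ")))
  cat(sprintf("  final RO: %.4g\n", x$final_RO))
  invisible(x)
}

#' Scan specification over one protocol variable
#'
#' Parameterizes the experiment families of the rapid-uptake studies:
#' sweeping pulse duration, interpulse duration, interpulse height or the
#' number of pulses around a base protocol, one independent freshly
#' equilibrated simulation per grid point.
#'
#' @param scan_variable one of "pulse_duration", "interpulse_duration",
#'   "interpulse_height", "n_pulses".
#' @param grid non-empty ascending vector of values for that variable.
#' @param base_protocol a \code{pulse_protocol} supplying all other fields.
#' @return an object of class \code{scan_spec}.
#' @export
scanSpec <- function(scan_variable = c("pulse_duration",
                                       "interpulse_duration",
                                       "interpulse_height", "n_pulses"),
                     grid, base_protocol) {
  scan_variable <- match.arg(scan_variable)
  if (length(grid) < 1L) stop("'grid' must be non-empty")
  if (is.unsorted(grid)) stop("'grid' must be sorted ascending")
  stopifnot(inherits(base_protocol, "pulse_protocol"))
  structure(list(scan_variable = scan_variable, grid = as.numeric(grid),
                 base_protocol = base_protocol),
            class = "scan_spec")
}

#' Run a protocol scan
#'
#' One \code{\link{simulateProtocol}} call per grid value. Interpulse scans
#' report the second pulse's uptake (the recovery/inhibition readout of the
#' two-pulse experiments); the other scans report total pulse uptake.
#'
#' @param spec a \code{scan_spec}.
#' @param p a \code{ram_params} object.
#' @param env a \code{membrane_env} object.
#' @return data.frame with columns \code{value} (the scanned variable),
#'   \code{uptake} (nmol/mg) and \code{readout} ("second_pulse" or
#'   "total_pulse").
#' @export
runScan <- function(spec, p, env = membraneEnv()) {
  stopifnot(inherits(spec, "scan_spec"))
  second <- spec$scan_variable %in% c("interpulse_duration",
                                      "interpulse_height")
  uptake <- vapply(spec$grid, function(v) {
    proto <- spec$base_protocol
    if (spec$scan_variable == "n_pulses") {
      proto$n_pulses <- as.integer(v)
    } else {
      proto[[spec$scan_variable]] <- v
    }
    sim <- simulateProtocol(proto, p, env)
    if (second) {
      if (length(sim$pulse_uptake) < 2L)
        stop("interpulse scans need a base protocol with n_pulses >= 2")
      sim$pulse_uptake[2L]
    } else {
      sim$total_pulse_uptake
    }
  }, numeric(1))
  data.frame(value = spec$grid, uptake = uptake,
             readout = if (second) "second_pulse" else "total_pulse")
}

#' Reference protocol grid emulating the classic experiment families
#'
#' Builds the battery of pulse protocols used throughout the package for
#' parameter-recovery studies: single sustained 5 s pulses across a range
#' of heights spanning the open threshold, two-pulse designs scanning the
#' interpulse duration (recovery kinetics) at a sub-threshold interpulse
#' level, and two-pulse designs scanning the interpulse height
#' (inhibition threshold) at a fixed interpulse duration. The heart grid
#' uses the 209/98 nM pulse/interpulse levels of the classic two-pulse
#' heart experiments with interpulse durations up to 180 s; the liver grid
#' uses a 170 nM pulse and sub-second interpulse durations matching
#' liver's fast recovery.
#'
#' Each protocol appears \code{replicates} times. The default of 6
#' replicate runs per condition reflects the information content of the
#' source experiments, whose continuous uptake records contributed on the
#' order of a hundred sampled points per tissue rather than one number per
#' condition.
#'
#' @param tissue "heart" or "liver".
#' @param replicates replicate runs per condition (default 6).
#' @return a list of \code{pulse_protocol} objects.
#' @export
referenceProtocols <- function(tissue = c("heart", "liver"),
                               replicates = 6L) {
  tissue <- match.arg(tissue)
  if (tissue == "heart") {
    heights <- c(120, 150, 170, 190, 209, 230, 250, 300, 400, 500)
    two <- function(...) pulseProtocol(pulse_height = 209,
                                       pulse_duration = 5,
                                       interpulse_height = 98,
                                       n_pulses = 2L, ...)
    ip_durations <- c(0.5, 1, 2, 5, 10, 15, 20, 30, 45, 60, 90, 120, 180)
    ip_heights <- c(50, 80, 98, 110, 125, 150, 175, 200, 250)
    ip_fix <- 60
  } else {
    heights <- c(110, 130, 150, 170, 190, 210, 250, 300, 400, 500)
    two <- function(...) pulseProtocol(pulse_height = 170,
                                       pulse_duration = 5,
                                       interpulse_height = 50,
                                       n_pulses = 2L, ...)
    ip_durations <- c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1, 2, 5)
    ip_heights <- c(50, 80, 98, 110, 125, 150, 175, 200, 250)
    ip_fix <- 2
  }
  grid <- c(lapply(heights, function(h)
      pulseProtocol(pulse_height = h, pulse_duration = 5)),
    lapply(ip_durations, function(d) two(interpulse_duration = d)),
    lapply(ip_heights, function(h) {
      pr <- two(interpulse_duration = ip_fix)
      pr$interpulse_height <- h
      pr
    }))
  rep(grid, times = replicates)
}
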