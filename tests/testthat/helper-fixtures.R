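# Shared fixtures: published parameter sets, their balance-closed versions
# (the truth sets for recovery experiments), and the default membrane
# environment.

heart <- ramParamSet("heart")
liver <- ramParamSet("liver")
heart_bal <- enforceDetailedBalance(heart)
liver_bal <- enforceDetailedBalance(liver)
env0 <- membraneEnv()

# numerically integrate the gating equation at constant ca (independent of
# the analytic propagator under test)
integrateRO <- function(t_out, RO0, ca, p, rtol = 1e-11, atol = 1e-13) {
  sol <- deSolve::lsoda(c(RO = RO0), t_out,
                        function(t, y, parms) list(dROdt(y[[1]], ca, p)),
                        parms = NULL, rtol = rtol, atol = atol)
  sol[, "RO"]
}

# trapezoid-free quadrature of the flux along the analytic RO course
quadratureUptake <- function(ca, RO0, duration, p, env) {
  stats::integrate(function(t) ramFlux(ca, roAnalytic(t, RO0, ca, p), p, env),
                   0, duration, rel.tol = 1e-12, abs.tol = 0,
                   subdivisions = 2000L)$value
}
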