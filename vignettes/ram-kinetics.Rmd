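---
title: "Modeling the rapid mode of mitochondrial calcium uptake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the rapid mode of mitochondrial calcium uptake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramkin)
```

## The model

Isolated mitochondria take up Ca²⁺ in two very different regimes: the
classical uniporter, a high-capacity channel that only becomes effective at
micromolar Ca²⁺, and the *rapid mode* (RaM), a transient, high-conductance
pathway triggered already at nanomolar Ca²⁺ and then self-inhibited until
the external level falls back below roughly 100–150 nM. `ramkin`
implements a minimal four-state gating model of RaM — rest (R), open (O)
and two inhibited conformations (I₁, I₂) arranged in a cycle — together
with the uptake flux through the open state, protocol simulation,
parameter estimation and an integrated matrix/buffer model used for
qualitative corroboration against single-mitochondrion pulse experiments.

### Rapid-equilibrium reduction

Ca²⁺ binding to the external trigger sites is assumed to equilibrate at
least two orders of magnitude faster than the conformational transitions,
so the pairs R/O and I₁/I₂ collapse into two super-states, `RO` and
`I1I2 = 1 − RO`. Within each super-state, Ca²⁺ partitions the pool
instantaneously through steep Hill curves

$$f_{Ca} = \frac{[Ca^{2+}]^n}{[Ca^{2+}]^n + K_O^n}, \qquad
  g_{Ca} = \frac{[Ca^{2+}]^n}{[Ca^{2+}]^n + K_I^n},$$

with a shared cooperativity of $n = 24$: binding is effectively
switch-like around the open trigger threshold $K_O$ (224 nM heart, 196 nM
liver) and the inhibited-lock threshold $K_I$ (110 nM). The only slow
variable is then `RO`, obeying the two-state master equation

$$\frac{dRO}{dt} = k_{in}(1 - RO) - k_{out}\,RO,$$

where each super-state exits through whichever conformational route its
instantaneous bound fraction feeds:

$$k_{out} = k_{O \to I_1} f_{Ca} + k_{R \to I_2} (1 - f_{Ca}), \qquad
  k_{in} = k_{I_1 \to O} g_{Ca} + k_{I_2 \to R} (1 - g_{Ca}).$$

This convex-combination form is the unique two-state reduction whose time
constant $\tau = 1/(k_{in} + k_{out})$ and steady state
$RO_\infty = k_{in}/(k_{in}+k_{out})$ reproduce every published
consequence we can check: the ~26 s heart recovery time constant at low
Ca²⁺, the ~10 ms time constant at saturating Ca²⁺, and the τ and
steady-state surfaces over the (Ca²⁺, t) plane. At constant Ca²⁺ the
equation is linear, and the propagator
$RO(t) = RO_\infty + (RO_0 - RO_\infty)e^{-t/\tau}$ is exact — which is
why pulse protocols, where the apparatus holds Ca²⁺ fixed within each
phase, are simulated by chaining closed-form segments with no ODE solver
and no discretization error.

```{r}
heart <- ramParamSet("heart")
liver <- ramParamSet("liver")
# the slow/fast tissue contrast in one line each
recoveryTime(heart, 50)   # ~78 s to 95% recovery at 50 nM
recoveryTime(liver, 50)   # ~0.03 s
```

### Thermodynamic consistency

The four transition rates form a cycle; at equilibrium the product of
rates around the cycle must be equal in both directions (microscopic
reversibility), otherwise the scheme would quietly pump using an
unmodeled energy source. With the Hill-equilibrated binding steps folded
in, the constraint is

$$k_{O \to I_1}\,k_{I_2 \to R}\,K_I^{\,n} =
  k_{I_1 \to O}\,k_{R \to I_2}\,K_O^{\,n}.$$

`enforceDetailedBalance()` solves this exactly for one designated
dependent rate — by default $k_{I_1 \to O}$, the rate derived rather than
fitted in the published sets — and the fitter re-applies it at every
candidate parameter vector, so the constraint holds at every optimizer
iterate. Because the published sets are printed with 2–3 significant
digits, they sit slightly off the constraint surface (cycle residual
3–6% in log units); the constructors therefore accept a |ln residual| up
to 0.1 for sets flagged `balanced`, while internally constructed sets
must close to 10⁻¹². All cycle arithmetic is carried out in log space:
with $n = 24$, $K^n$ spans hundreds of orders of magnitude across the
nM–mM range, and the Hill fraction itself is evaluated as a logistic in
log-concentration (`plogis(n(log ca − log K))`), which neither overflows
nor underflows anywhere in 0–10⁷ nM and returns exactly 0.5 at
`ca == K`.

```{r}
# the liver I1->O rate implied by the other published liver values
enforceDetailedBalance(liver, "k_I1_O")$k_I1_O   # printed as 0.009
```

### Uptake flux

Transport through the open fraction $O = f_{Ca}\,RO$ is saturable,
strictly unidirectional (at physiological potential the outward flux is
negligible and set to zero) and driven by the membrane potential through
a single centered Eyring barrier under the constant-field assumption:

$$J_{RaM} = X_{RaM}\, O\, \frac{[Ca^{2+}]}{[Ca^{2+}] + K_{Ca}}
  \exp\!\left(\frac{z F \Delta\Psi}{2RT}\right).$$

ΔΨ is fixed at 190 mV (resting, state-2 respiration) and never fed back
from uptake. The barrier shape is a swappable strategy
(`membraneEnv(voltage_form = ...)`): alternative shapes (trapezoidal,
Goldman-type) fit uptake data equally well and differ only by a
rescaling of $X_{RaM}$, so nothing downstream depends on the choice.
Because $O(t)$ is the only time-dependent factor, the uptake over a
constant-Ca²⁺ segment integrates in closed form into a fast
pool-emptying transient, saturating on the τ time scale (~10 ms at
saturating Ca²⁺, 95% complete by $\tau\ln 20 \approx 30$ ms for heart),
plus a slow steady leak through the residual open fraction
$RO_\infty$. The liver benchmark — a sustained 170 nM pulse from a
50 nM-equilibrated state — gives 0.052 nmol/mg from the fast component
and 0.077 nmol/mg including 40 s of slow leak, bracketing the published
≈0.08 nmol/mg.

## Protocols and scans

`pulseProtocol()` describes the piecewise-constant waveforms of the
classic stopped-flow experiments (prepulse equilibration level, n pulses
with interpulse gaps, optional postpulse tail); edges are ideal steps —
the instrument's finite mixing time is not modeled, consistent with the
source protocols treating Ca²⁺ as fixed per phase. The default initial
condition is the gating steady state at the prepulse level, matching the
preincubation of the experiments. Per-pulse uptake summaries exclude
interpulse and postpulse segments, which is how the source experiments
quantified uptake per pulse. "Recovery time" is operationalized as the
time to reach 95% of $RO_\infty$ (the literature quotes ranges, not a
definition); the closed form is $\tau \ln 20$ for a fully inhibited
start. `runScan()` parameterizes the four experiment families (sustained
pulse, interpulse-duration scan, interpulse-height scan, pulse-number
scan), one freshly equilibrated simulation per grid point; interpulse
scans report the second pulse's uptake, the recovery/inhibition readout
of the two-pulse designs.

```{r}
base <- pulseProtocol(pulse_height = 209, pulse_duration = 5,
                      interpulse_height = 98, n_pulses = 2)
runScan(scanSpec("interpulse_duration", c(1, 15, 60, 180), base), heart)
```

## Parameter estimation

`fitRaM()` minimizes the variance-weighted least-squares objective
$f(p) = \sum_{ij} (y_{ij}(p) - \hat y_{ij})^2/\sigma_{ij}^2$ over all
datasets jointly, with fixed parameters pinned, shared parameters taking
one value across tissues, and the dependent rate eliminated by detailed
balance at every evaluation. Confidence intervals come from the inverse
Fisher information matrix: the sensitivity matrix is normalized on both
sides — outputs by the experimental standard deviation, parameters by
their best value — exactly the double normalization needed to keep
$S^\top S$ conditioned across parameters spanning eight orders of
magnitude; the 95% half-width is $\delta_l = 1.96\sqrt{C_{ll}}$ and the
absolute interval $p^*_l(1 \pm \delta_l)$, with a negative lower bound
replaced by $10^{-3} p^*_l$ (rates are positive; a Gaussian interval
crossing zero only says the data cannot resolve how small the rate is).
Cramér–Rao widths underestimate the true uncertainty, so the package's
coverage test checks an 80% floor rather than the nominal 95%.

Choices the source material leaves open, decided here once:

* **Optimizer.** Seeded multi-start local search on log-scaled
  parameters: a Nelder–Mead walk followed by an L-BFGS-B polish within
  bounds. The $n = 24$ Hill thresholds carve canyon-shaped objectives
  whose cliffs defeat a gradient line search started off-canyon (it
  jumps clear across onto the zero-uptake plateau); the simplex walk is
  immune to this and the polish then converges quadratically inside the
  canyon. Five starts by default (the supplied start plus seeded ±20%
  log-perturbations), best kept; deterministic given the seed.
* **Sensitivities.** Central finite differences with relative step
  10⁻⁶.
* **Unidentifiability.** Parameters loading on null directions of
  $S^\top S$ are reported, excluded from the covariance (Moore–Penrose
  pseudo-inverse), and their interval rows set to NA.

### The synthetic-data generator

The raw uptake observations behind the published fits live in the source
papers' figures and are not reproduced here; fitting is exercised
against `synthesizeDataset()`, which simulates a protocol battery and
applies seeded multiplicative Gaussian noise
($obs = y(1+\varepsilon)$, $\varepsilon \sim N(0, cv^2)$, default
cv = 5%) with variance $(cv\, y)^2$ floored at $(0.005\ \text{nmol/mg})^2$
— an absolute assay detection floor, so sub-threshold records carry
realistic rather than unbounded weight. Three generator conventions
matter and are fixed once:

* **Truth sets.** Recovery experiments use the *balance-closed* versions
  of the published parameter sets
  (`enforceDetailedBalance(ramParamSet("heart"))`). The published fits
  enforced reversibility strictly and printed rounded values; a
  printed set is off the constraint surface by rounding, and since the
  estimator searches only on the surface, using a printed set as truth
  would build a ~1.5-unit irreducible objective into every "zero-noise"
  experiment.
* **Design.** `referenceProtocols()` is the standing experiment battery:
  10 sustained-pulse heights spanning the open threshold, 13 (heart) or
  9 (liver) interpulse durations spanning the recovery time scale, and
  9 interpulse heights spanning both thresholds, each condition run in
  6 replicates. The replication reflects the information content of the
  source experiments, whose continuous uptake records contributed on
  the order of a hundred sampled points per tissue; under this design
  the $k_{I_2 \to R}$ estimator has a sampling sd of ~3–4% at 5% noise.
* **What it does not emulate.** Real uptake traces have correlated
  within-curve noise, instrument dead time, and efflux-pathway
  corrections; the generator's records are independent. Passing
  recovery tests therefore demonstrate estimator correctness under the
  stated error model, not robustness to the full error structure of the
  original measurements.

## The matrix/buffer corroboration model

To compare against caged-Ca²⁺ photorelease experiments on single
mitochondria, a deliberately minimal coupled system is integrated
(`simulateCorroboration()`): matrix free Ca²⁺ gains RaM and uniporter
influx and loses first-order H⁺/Ca²⁺-exchanger efflux, all attenuated by
a buffering factor β; buffer Ca²⁺ sees only the square-wave photorelease
source and first-order washout (the buffer volume dwarfs a
mitochondrion, so mitochondrial fluxes are omitted from its balance);
and RO follows the gating equation at the instantaneous buffer Ca²⁺,
since the external level is no longer piecewise constant. The uniporter
is a saturable Michaelis term with 10 µM affinity (a Hill exponent of 2
is plausible from the uniporter literature and exposed as
`cu_exponent`; the default is 1). Integration uses lsoda piecewise
between square-wave edges so the stiff solver never straddles a pulse.

Two bridges are free because the source traces are uncalibrated, and
both are config-exposed with defaults chosen once:

* `ram_scale` converts the RaM flux (nmol mg⁻¹ s⁻¹) into a matrix
  concentration rate (nM/s); the default 800 makes peak RaM flux at
  500 nM comparable to the uniporter flux there (~10⁴ nM/s).
* Pulse timing is not published. Each event delivers its amplitude as a
  square wave of height amplitude/width; the high-frequency scenario
  uses 5.5 ms pulses reaching ~5 µM at 1 s spacing, the low-frequency
  scenario 0.5 ms pulses reaching ~450 nM (the midpoint of the reported
  400–500 nM) at 10 s spacing. The spacings bracket the ~1 s washout
  time constant: at 1 s spacing buffer Ca²⁺ never falls below the
  inhibition threshold and RaM recovery collapses after the first
  pulse, while at 10 s spacing the buffer clears below threshold and
  liver RaM (recovery < 1 s) resets fully before every pulse. This is
  the qualitative contrast the corroboration is meant to show; the
  original fluorescence traces themselves are uncalibrated and not
  reproduced.

```{r, fig.width = 6, fig.height = 3}
lo <- simulateScenario("low_freq")
round(lo$recovery_ratio, 3)
plot(RO ~ t, lo$trajectory, type = "l", xlab = "time (s)",
     ylab = "fraction in RO")
```

## Numerical notes and limitations

* Hill fractions and cycle residuals in log space throughout; `ca == K`
  returns exactly 0.5; zero-ligand limit is exactly 0.
* The analytic propagator is used wherever Ca²⁺ is piecewise constant;
  the package's tests hold it to 10⁻⁸ against adaptive integration over
  [0, 300 s] and the closed-form uptake to 10⁻⁸ relative against
  quadrature.
* Invalid parameter candidates inside the optimizer map to a large
  finite penalty (10¹⁰) rather than an exception, keeping bound
  searches in-domain.
* Test-suite problem sizes: recovery fits use the 192-record reference
  battery; the coverage study uses 100 seeded replicates of the
  32-condition battery with single-start fits initialized at truth.
* Out of scope by design: the five-state biphasic-recovery heart
  variant, effector regulation (ruthenium red, spermine, adenine
  nucleotides), stochastic single-channel gating, ΔΨ dynamics and
  bioenergetic coupling, Mg²⁺ competition, and spatial Ca²⁺
  microdomains. Heart RaM's observed biphasic recovery (a quarter of
  the pool resetting liver-fast) is therefore *not* captured: the
  four-state model yields single-exponential recovery.
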