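---
title: "Modeling and identifying a whole-cell malonyl-CoA biosensor"
author: "MalonylSensor authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and identifying a whole-cell malonyl-CoA biosensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MalonylSensor)
```

## The problem

A FapR-based whole-cell biosensor reports intracellular malonyl-CoA as
red fluorescence: malonyl-CoA binds the FapR repressor, relieving
repression of an RFP gene, so wells of a kinetic microplate run emit
fluorescence that tracks both the culture's biomass and its malonyl-CoA
production rate. To use such a sensor quantitatively — for screening
candidate production pathways or for closing a feedback loop around
them — one needs a calibrated dynamic model: how much fluorescence per
unit biomass a given production rate yields (the gain), and how fast the
readout follows the culture (the time constants). This package provides
that model chain end to end: a mechanistic cascade simulator, the family
of approximate linear filter models, their discretization and
least-squares identification from plate data, and the plate-level
response analyses built on the fitted parameters.

## The mechanistic cascade

Biomass $X(t)$ (OD600) drives three first-order balances, for the
metabolite $M$, the FapR--malonyl-CoA complex $C$, and the reporter $R$:

$$\frac{dM}{dt} = v_m X - v_g \frac{dX}{dt} - \gamma_m M, \qquad
\frac{dC}{dt} = k_f F M - k_r C, \qquad
\frac{dR}{dt} = \kappa C - \gamma_r R.$$

Here $v_m$ is the construct- and induction-specific production rate,
$v_g$ an optional consumption term proportional to biomass formation,
$F$ the (constant) FapR level set by arabinose, $K_d = k_r/k_f$ the
repressor's dissociation constant (2.4 uM by default), $\kappa$ the
promoter strength and $\gamma_m$, $\gamma_r$ first-order decay rates.
Chaining the three equilibria under constant biomass gives the
steady-state sensitivity

$$\frac{R}{X} = \frac{\kappa F v_m}{K_d\, \gamma_m\, \gamma_r},$$

implemented as `steadyStateGain()` and verified against the ODE
simulation to 1e-6 relative in the tests. Because each stage is linear,
the cascade acts as three first-order filters in series, and the
steady-state ratio is exactly the DC gain of that filter chain — which
motivates the approximate models below. $v_g$ is not identifiable from
the data this pipeline targets and defaults to 0; the term is
implemented and switchable.

```{r}
sp <- SensorParams(vm = 0.1)
steadyStateGain(sp)
```

## The approximate filter models

Between biomass and fluorescence we fit transfer functions with one
derivative (zero) constant $\tau_z$, a gain $K$, and one to three
integral (pole) constants $\tau_{p,i}$:

$$\frac{R(s)}{X(s)} =
  \frac{K\,(1 - \tau_z s)}{\prod_{i=1}^{n}(1 + \tau_{p,i}\, s)},
  \qquad n \in \{1, 2, 3\}.$$

The second-order form ($n = 2$) is the reference model: on real screens
the third-order fit is not always achievable, while the first-order one
visibly underfits. Time constants are reported in minutes and sorted
descending, so $\tau_1$ is the slow (reporter-dominated) constant —
typically hundreds of minutes — and $\tau_2$ the faster metabolite
constant, around ten minutes.

## Identification by bilinear discretization and lagged least squares

Sampling every $T_s$ minutes, the transfer function is discretized with
the bilinear (Tustin) substitution

$$s \leftarrow \frac{2}{T_s}\,\frac{z - 1}{z + 1},$$

expanding into the ARX difference equation
$R[k] = \sum_i a_i R[k-i] + \sum_j b_j X[k-j]$, fitted by ordinary least
squares on the lagged samples with no intercept (the first `order`
samples are dropped so every row is complete). The substitution maps
$s = 0$ to $z = 1$, so the DC gain is preserved exactly — the expanded
coefficients are DC-normalized so this holds to machine precision even
when $\tau \gg T_s$ — and stability is preserved in both directions.
Fitted coefficients are mapped back through the inverse substitution:
AR-polynomial roots $z_i$ give poles
$s_i = (2/T_s)(z_i - 1)/(z_i + 1)$ and $\tau_{p,i} = -1/s_i$; the gain
is the DC gain; $\tau_z$ comes from the numerator root away from
$z = -1$ (the image of $s = \infty$). Root estimates are polished with
two Newton steps, which matters when poles cluster.

The numerator is fitted unconstrained (order + 1 coefficients) even
though the continuous model has only two numerator degrees of freedom;
surplus numerator roots are reported as unmodeled dynamics in the
validity flags. Negative, unstable or complex estimates are never
coerced into time constants: the continuous parameters are absent and
the flags (`stable`, `realPoles`, `positiveGain`, `extraZeros`) explain
why, gating downstream analyses.

```{r}
m2 <- TransferModel(K = 250.84, tauP = c(290.11, 12.69), tauZ = 5)
tm <- seq(0, by = 12, length.out = 240)
x <- logisticGrowth(GrowthParams(X0 = 0.05, Xmax = 1.2, mu = 0.01,
                                 lag = 0), tm)
r <- simulateDiscreteARX(bilinearDiscretize(m2, Ts = 12), x)
identifySensor(r, x, order = 2, Ts = 12)
```

For data generated by the discrete model itself the round trip is exact
to floating-point precision; for data from the continuous ODEs the
bilinear approximation error shrinks as $O(T_s^2)$, which the tests
verify by fitting the same continuous run at $T_s$ = 24, 12 and 6 min.

## What the synthetic plates emulate

`generatePlate()` produces 96-well kinetic runs with the structure the
analysis assumes, and is the package's test bed:

* **Growth** is logistic with a lag phase. Defaults (X0 = 0.05,
  Xmax = 1.2, mu = 0.01/min, lag = 60 min) emulate an overnight minimal-
  medium culture diluted 20-fold: a ~70-min doubling time and a plateau
  just above OD 1.
* **Induction** maps are Hill functions. IPTG (screened at 0.01, 0.1,
  0.3, 0.6, 1 and 10 mM) sets $v_m$ with half-saturation at 0.3 mM —
  inside the screened range, so the dose series spans the curve;
  arabinose can optionally set $F$. No mechanistic dose law is claimed;
  the maps are monotone saturating plumbing connecting dose to rate.
* **Sampling** is one reading per 12 min, 120 readings (24 h).
* **Noise** is multiplicative Gaussian (sigma = 0.02 by default, a
  typical plate-reader relative error), clipped at zero: reader noise
  scales with signal. An optional per-well lognormal jitter on $v_m$
  (`wellCV`) emulates clone-to-clone variation and is off by default so
  that sigma = 0 reproduces the noise-free cascade exactly.
* **Default sensor constants** place the reporter pole near 290 min
  ($\gamma_r$), the metabolite pole near 13 min ($\gamma_m$) and binding
  much faster ($k_r = 2.4$/min), so the simulated cascade genuinely
  behaves like the second-order reference model with physiological time
  constants.
* The **stationary-phase derepression artifact** (arabinose runs out,
  FapR drops, fluorescence jumps) is available as an opt-in scenario
  (`depletionOD`) implemented as a step decrease of $F$ when the culture
  crosses a set OD. Within this linear cascade the FapR level enters the
  response multiplicatively, so the step changes the late-time gain; the
  repressor logic that makes the real artifact an *increase* is outside
  the linear chain, and the scenario should be read as "late kinetics
  change past this OD", not as a signed prediction.

What passing tests on these plates do **not** show: real screens add
background fluorescence of the medium, burden mutations sweeping
through populations, growth arrest at high induction, and plasmid
copy-number effects. None of these are generated, so conclusions from
synthetic runs transfer only to the dynamical and statistical structure
listed above.

## Response analyses

Readouts are anchored to growth phase: `readoutAtOD()` interpolates
fluorescence at the *first* upward crossing of OD 0.6 (later crossings
after dips are ignored), which sidesteps the stationary-phase artifact.
`normalizeRfpOd()` masks samples below an OD floor (0.05) instead of
dividing by near-zero biomass. Dose-response curves summarize readouts
per concentration; `paramInductionCorrelation()` correlates fitted
parameters with log10(dose), the natural axis for a series spanning
three decades. Substrate effects use Welch's unequal-variance t-test
(the direction of the mean difference is reported, since supplementation
can help or hurt); no multiple-testing correction is applied across
constructs or doses, matching per-comparison reporting — noted here
deliberately. Reproducibility uses the coefficient of variation with the
sample (n-1) standard deviation, appropriate at small replicate counts.

One calibration note: Welch's test is conservative at very small group
sizes (its Satterthwaite approximation gives a measured size near 0.02
at n = 3 and alpha = 0.05), a known property of the test rather than an
implementation artifact. The null-calibration test therefore uses six
replicates per group — a realistic within-plate replication — where the
measured size is close to nominal.

## Numerical choices

* ODE integration is `deSolve::lsoda` (adaptive, stiff-capable) at
  rtol 1e-8 for the cascade — $k_f F$ can be much faster than every
  other rate — and rtol 1e-10 for the linear filter simulations used as
  identification references.
* dX/dt is taken analytically from the logistic model whenever growth
  parameters are available, else by central differences.
* The lag regression uses `lm.fit`; exact collinearity is accepted only
  when the pivoted solution reproduces the response perfectly
  (overparameterized noise-free data), otherwise an identifiability
  error is raised.
* An undersampling advisory fires when $T_s \ge 2\min(\tau_p)$.
  Coincident poles are permitted; the closed-form step response switches
  to the repeated-root formula.
* An all-zero response series short-circuits to the zero model (zero
  coefficients, zero residual) rather than tripping the collinearity
  check.

## Problem sizes

The bundled tests and the acceptance script run on desk-scale problems
chosen to exercise every code path: 240-sample round trips for
parameter recovery, 36-well plates (2 synthetic constructs x 6 doses x
3 replicates, 120 time points) for the correlation and clustering
properties, and 1000 Monte-Carlo nulls for test calibration. All
simulated inputs are generated in code from seeds; no stored fixtures
are used.

## Configuration format

The pipeline configuration and the generator's parameter sidecar are
YAML: a single established, human-editable structured-text format with
a mature R parser, covering the same needs (nested sections, typed
scalars, comments) as any other config dialect. The complete default
file ships at `inst/extdata/default-config.yaml`; user files override
only the keys they state.

## Known limitations

* The linear cascade cannot represent saturation of the sensor at high
  malonyl-CoA, repressor-logic sign effects, or growth arrest under
  induction — parameter estimates from wells showing those phenomena
  should be gated on the validity flags and inspected.
* $\tau_z$ recovered from freely-fitted numerators is the root nearest
  the real axis; when noise scatters the numerator roots the estimate is
  diagnostic, not quantitative.
* The gain confounds $\kappa F v_m / (K_d \gamma_m \gamma_r)$; absolute
  malonyl-CoA quantification requires an external calibration and is out
  of scope — all outputs stay in fluorescence units.
* Fitted fast time constants absorb both the metabolite pole and the
  (nearly instantaneous) binding pole; on cascade-generated data the
  recovered $\tau_2$ is therefore an effective constant, smaller than
  $1/\gamma_m$.
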