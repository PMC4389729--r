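# MalonylSensor

Dynamic modeling and identification of a whole-cell malonyl-CoA
biosensor from microplate kinetic screens.

## What this is for

Whole-cell biosensors couple an intracellular metabolite to an optical
readout: here, malonyl-CoA binds the *Bacillus subtilis* repressor FapR,
derepressing an RFP gene, so a growing *E. coli* culture fluoresces in
proportion to both its biomass and its malonyl-CoA production. Used for
pathway screening or feedback control, such a sensor needs calibration:
its **gain** (fluorescence per unit biomass per unit production rate)
and its **time constants** (how fast the readout tracks the culture).
This package is for synthetic biologists and modelers who run 96-well
kinetic screens (OD600 + fluorescence every few minutes) and want those
parameters estimated, per well and per construct, with honest validity
flags — plus a seeded synthetic-plate generator to validate the whole
chain.

## The model

Biomass `X(t)` drives a three-stage linear cascade — metabolite `M`,
repressor complex `C`, reporter `R`:

    dM/dt = vm·X − vg·dX/dt − γm·M
    dC/dt = kf·F·M − kr·C
    dR/dt = κ·C − γr·R

whose steady-state sensitivity is `R/X = κ·F·vm/(Kd·γm·γr)` with
`Kd = kr/kf` (2.4 µM for FapR). Between `X` and `R` the package fits
transfer models with one zero and one to three poles,

    R(s)/X(s) = K(1 − τz·s) / Π(1 + τp_i·s),

the two-pole form being the reference model. Identification discretizes
the model with the bilinear (Tustin) substitution
`s ← (2/Ts)(z−1)/(z+1)` at the sampling period `Ts` (12 min by default),
fits the resulting ARX difference equation by lagged least squares, and
maps the coefficients back to `K`, `τz`, `τp` — with flags instead of
coerced values whenever the fitted poles are complex, unstable or
negative.

## Worked example

Round-trip identification — simulate the discretized reference model
along a logistic growth curve, then recover its parameters:

```r
library(MalonylSensor)
m2 <- TransferModel(K = 250.84, tauP = c(290.11, 12.69), tauZ = 5)
tm <- seq(0, by = 12, length.out = 240)              # 48 h at 12 min
x  <- logisticGrowth(GrowthParams(X0 = 0.05, Xmax = 1.2, mu = 0.01,
                                  lag = 0), tm)
r  <- simulateDiscreteARX(bilinearDiscretize(m2, Ts = 12), x)
identifySensor(r, x, order = 2, Ts = 12)
#> SensorFit on 238 samples: R^2 = 1  resid var = 2.842e-27
#>   flags: stable=TRUE realPoles=TRUE positiveGain=TRUE extraZeros=FALSE
#>   TransferModel order 2 : K = 250.84  tauZ = 5 min, tauP = 290.11, 12.69 min
```

The fit recovers the gain (250.84 fluorescence/OD) and both integral
time constants (290.11 and 12.69 min — a slow reporter pole and a fast
metabolite pole) exactly, with clean diagnostics.

A synthetic screen end to end — generate a plate (6 IPTG doses × 3
replicates), identify every well, and summarize:

```r
plate <- generatePlate(defaultPlateDesign("matCmatB", replicates = 3),
                       seed = 42,
                       time = seq(0, by = 12, length.out = 120))
fits  <- identifyPlate(plate, order = 2)
ro    <- plateReadouts(plate)                  # fluorescence at OD 0.6
doseResponse(ro$fluorescence_at_od, ro$iptg_mM)
#>    dose   mean     sd n
#> 1  0.01  4.691 0.1717 3
#> 2  0.10 17.573 0.3086 3
#> 3  0.30 31.991 0.5455 3
#> 4  0.60 40.960 1.2664 3
#> 5  1.00 47.131 1.3043 3
#> 6 10.00 58.630 2.6013 3
paramInductionCorrelation(fits)$correlations
#>   parameter       r  p_value  n
#> 1         K  0.9798 1.29e-12 18
#> 2     tau_1 -0.0397 8.76e-01 18
#> 3     tau_2 -0.3243 1.89e-01 18
#> 4     tau_z  0.1182 6.41e-01 18
```

The OD-anchored readout rises monotonically with dose (a saturating
dose-response), the fitted gain correlates strongly with log-dose, and
the time constants do not — the signature of a responsive sensor with
induction-independent dynamics.

A thin CLI wrapping the same functions ships at
`inst/scripts/malonyl-sensor` (subcommands `simulate`, `identify`,
`analyze`, `report`; YAML config, see
`inst/extdata/default-config.yaml`).

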