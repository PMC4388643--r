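# itckin — enzyme kinetics from isothermal titration calorimetry

Many enzyme substrates produce no usable optical signal — lignosulfonic
acid, a polydisperse lignin derivative attacked by fungal laccases, is a
canonical example. Since essentially every reaction produces or consumes
heat, an isothermal titration calorimeter (ITC) can serve as a universal
rate detector. `itckin` implements the full two-experiment ITC kinetics
workflow for researchers characterizing such enzymes, plus the
conventional spectrophotometric initial-rate workflow for chromogenic
substrates (ABTS, 2,6-DMP), and a seeded calorimeter simulator for
validation.

The core inference, for a fixed-volume overflow cell of volume *V*:

1. **Calibration** (single-injection method): a substrate bolus is
   converted completely; the apparent molar enthalpy is
   *ΔH*app = ∫(dQ/dt) dt / ([S]total · V), in cal/mol.
2. **Rates** (multiple-injection method): Rate = d[P]/dt =
   (1 / (V·ΔHapp)) · dQ/dt converts the instantaneous thermal power to a
   reaction rate, and [S]t = [S]total − ∫(dQ/dt)dt / (ΔHapp·V) converts
   cumulative heat to residual substrate.
3. **Fitting**: the (S, rate) pairs are fitted to
   Rate = Vmax·S/(Km + S) by Levenberg–Marquardt in log-parameter space,
   yielding Km, Vmax, kcat = Vmax/[E]0, the efficiency kcat/Km, and
   (given a molecular weight) the specific activity in U/mg. A
   Lineweaver–Burk linearization is reported as a diagnostic.

In between sit the unglamorous but decisive steps: baseline estimation and
subtraction, Tian deconvolution of the instrument response
(P_true = P_meas + τ·dP/dt), peak/heat integration, post-injection
settling exclusion, and normalization for the enzyme dilution caused by
the titration itself.

## Worked example

Simulate both instrument protocols with the packaged ground truth
(kcat 0.234 s⁻¹, Km 56.7 µM, ΔH −25,040 cal/mol, 1.39 µM enzyme in a
200 µL cell; 2 × 5 µL of 0.1 mM substrate for calibration, 30 × 1 µL of
1 mM for the titration) and run the full analysis chain:

```r
library(itckin)
report <- run_itc_pipeline(simulate = TRUE, sim_args = list(noise_sd = 0))
report
#> == Calorimetric enzyme kinetics report ==
#> Apparent enthalpy: -25037 cal/mol (2 injections, -2.504e-05 cal over 1e-09 mol)
#> Rate curve: 421 points (94 retained); S 4.09-22.3 uM, rate 0.0216-0.0791 uM/s
#> Michaelis-Menten fit (n = 94): Vmax = 0.33191 +/- 0.00038 uM/s, Km = 58.23 +/- 0.088 uM
#>   RSS 1.084e-07; converged in 3 iterations
#>   kcat = 0.2388 s^-1, kcat/Km = 0.0041 s^-1 uM^-1 (reported: 0.004)
#> Ground truth (simulated): Vmax 0.3253 uM/s, Km 56.7 uM, dH -25040 cal/mol
```

Reading the output: the calibration experiment recovers the generating
enthalpy (−25,037 vs −25,040 cal/mol, 0.01%); the titration yields 94
usable (S, rate) points after excluding settling and deconvolution-edge
windows; and the fit recovers Km within 3% and the efficiency at its
reported rounding (0.004 s⁻¹µM⁻¹). `write_report(report, dir)` writes a
human-readable report, a machine-readable key/value file, and a plot-ready
rate-curve table.

The spectrophotometric side mirrors a kinetics-table row:

```r
traces <- simulate_absorbance(kcat = 3382, Km = 65, E0 = 3e-5,
                              substrate_concs = c(10, 25, 50, 100, 200, 400, 1000),
                              assay = standard_assay("abts"), noise_sd = 0)
run_spectro_pipeline(traces, E0 = 3e-5, MW = 67700)
```

Measured data enter the same way through `read_thermogram()`,
`read_injection_schedule()` and `read_absorbance_trace()` (delimited text
with a commented unit header). A thin CLI wrapper with `simulate`,
`report` and `spectro` subcommands is installed at
`system.file("scripts", "itckin", package = "itckin")`.

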