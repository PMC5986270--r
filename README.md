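# protonflux

Quantitative analysis of proton-coupled membrane transport for cell
physiologists: from raw ratiometric-dye or pH-microelectrode recordings to
calibrated pH traces, transport rates, buffer capacities and proton fluxes —
plus the ¹⁸O isotope-exchange carbonic anhydrase (CA) assay and a
nuclei-counting proliferation readout. The package targets the analysis
chain used in studies of monocarboxylate transporters (MCT1/MCT4), which
cotransport lactate with H⁺, and of carbonic anhydrase II acting as a
"proton antenna" that facilitates that transport.

Every estimator is paired with a seeded synthetic-data generator that
records its ground truth, so the whole chain can be validated end to end.

## What it computes

**Ratiometric calibration.** A nigericin staircase clamps intracellular pH
to known values; per-step steady states are extracted by exponential
regression and fitted with a Boltzmann sigmoid

```
R(pH) = (A1 − A2) / (1 + exp((pH − x0)/dx)) + A2
```

whose exact algebraic inverse, `pH = x0 + dx·ln((A1 − A2)/(R − A2) − 1)`,
converts every recorded ratio to pH (`fit_boltzmann()`, `ratio_to_ph()`).

**Electrode calibration.** A two-solution (pH 7.0 / 6.4) linear calibration
`pH = intercept + slope·V_e` for ion-sensitive microelectrodes
(`calibrate_electrode()`, `voltage_to_ph()`), with
`[H⁺] = 10^(−pH) × 10⁹ nM` (`ph_to_proton()`).

**Transport rates and proton flux.** The maximum rate of pH (or [H⁺])
change during substrate application/withdrawal is extracted by sliding- or
fixed-window linear regression (`extract_rate()`). A terminal
5% CO₂ / 10 mM HCO₃⁻ pulse gives the intrinsic buffer capacity
`β_i = Δ[HCO₃⁻]_i / ΔpH_i` (mM per pH unit) via Henderson–Hasselbalch
(`buffer_capacity()`), and the proton flux is
`J_H = (ΔpH/Δt) × β_i` in mM/min (`proton_flux()`); `quantify_events()`
orchestrates a full per-cell recording.

**¹⁸O-exchange CA activity.** From the m/z 45/47/49 abundance series,
`log enrichment = log₁₀(49 × 100 / (49 + 47 + 45))`; its linear slope
before and after lysate addition gives the uncatalyzed and catalyzed
depletion rates, and `units = |cat|/|uncat| − 1` (one unit = 100%
stimulation of the uncatalyzed depletion; `log_enrichment()`, `ca_units()`,
`ca_assay()`).

**Proliferation readout.** Threshold (30–255), Euclidean-distance-transform
watershed, size/circularity particle filtering and conversion to nuclei/mm²
(`segment_nuclei()`, `count_particles()`, `nuclei_density()`), plus the
2^(−ΔΔCt) expression ratio and band-normalisation helpers.

## Worked example

```r
library(protonflux)

# simulate one recording: 3 and 10 mM lactate pulses, then a terminal
# 5% CO2 / 10 mM HCO3- pulse (4 Hz electrode-style sampling)
sim <- gen_lactate_experiment(J_max = 3, K_m = 5, beta_true = 20,
                              tau_s = 60, noise_sd = 0.002,
                              sample_hz = 4, seed = 1)
protocol <- ApplicationProtocol(data.frame(
  solute = c("lactate", "lactate", "CO2"),
  concentration = c(3, 10, 5),
  start = c(300, 900, 1500), end = c(600, 1200, 1800)))

quantify_events(sim$trace, protocol, window_s = 15)
#>   event  solute concentration   direction   slope    r2 window_start window_end
#> 1     1 lactate             3 application -0.0560 0.829          301        316
#> 2     1 lactate             3  withdrawal  0.0515 0.755          606        621
#> 3     2 lactate            10 application -0.0860 0.901          900        915
#> 4     2 lactate            10  withdrawal  0.0880 0.927         1204       1219
#>   beta_i  J_H
#> 1     20 1.12
#> 2     20 1.03
#> 3     20 1.72
#> 4     20 1.76
```

Each row is one phase of one solution-change event: the regression slope in
pH/min, its r², the winning window, the buffer capacity recovered from the
CO₂ pulse (here 20.0 mM/pH, the generating value) and the proton flux
`J_H = |slope| × β_i` in mM/min. The generator's true fluxes were 1.12
(3 mM) and 2.00 mM/min (10 mM): the 3 mM flux is recovered on the nose,
while the 10 mM estimate (1.72) shows the expected downward bias of a
finite regression window on an exponentially relaxing response — windows of
about one sixth of the response time constant keep that bias below ~10%.

```r
# enzyme units from an 18O-exchange recording simulated with U_true = 5
iso <- gen_isotope_series(theta_uncat = 1e-3, U_true = 5, seed = 1)
ca_assay(iso$series, addition_time_s = 300)
#> <CAActivityResult> 5.048 U (63.1 U/ml at 0.08 ml); rates: uncat -0.05202, cat -0.3146 LE/min

# intracellular concentration after injecting 27.6 nl of 400 mM stock
# into an oocyte (0.35 ul effective free volume), one significant figure
signif(injection_concentration(27.6, 400, 0.35), 1)
#> [1] 30
```

A command-line wrapper is installed with the package
(`system.file("exec/protonflux", package = "protonflux")`) with subcommands
`calibrate`, `quantify`, `ca-activity`, `count-nuclei` and `simulate`.

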