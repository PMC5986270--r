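---
title: "Methods and design of protonflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of protonflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonflux)
```

# The measurement problem

Monocarboxylate transporters (MCTs) move lactate and H⁺ together across the
plasma membrane, so their transport activity can be read out as the rate of
intracellular acidification when lactate is applied and of alkalinisation
when it is withdrawn. Cytosolic carbonic anhydrase II can facilitate this
transport non-catalytically, acting as a "proton antenna" that exchanges H⁺
with the transporter faster than bulk diffusion can. Testing that idea
quantitatively requires a chain of conversions, each with its own
calibration and its own failure modes:

1. raw signal (fluorescence ratio or electrode potential) → intracellular pH,
2. pH → proton concentration where the logarithmic scale would mislead,
3. trace + application protocol → transport rate (a windowed regression slope),
4. CO₂/HCO₃⁻ pulse → intrinsic buffer capacity β_i,
5. rate × β_i → proton flux J_H in mM/min,
6. isotope abundances → carbonic anhydrase activity in enzyme units,
7. stained images → nuclei per mm² (a proliferation readout).

`protonflux` implements this chain as composable, unit-tagged operations.
Every stage is exercised against synthetic data whose ground truth is
recorded at generation time.

# Traces and unit discipline

All time series are `Trace` objects: seconds-based, strictly increasing
(possibly irregular) time, finite values, and a `kind` tag (`ratio`,
`potential_mV`, `pH`, `proton_nM`, `log_enrichment`). Operations that are
only meaningful on one scale refuse other kinds rather than guessing;
conversions (`ratio_to_ph()`, `voltage_to_ph()`, `ph_to_proton()`) change
the tag explicitly. Time is stored in seconds throughout; rates are
converted to per-minute at the reporting boundary because fluxes are
conventionally quoted in mM/min while acquisition is clocked in seconds.
Regression-based operations never assume uniform sampling.

# Ratiometric calibration

## The sigmoid and its inverse

A ratiometric pH dye such as SNARF-5F maps pH to an emission ratio through
a sigmoid. We use the four-parameter Boltzmann form

$$R(\mathrm{pH}) = \frac{A_1 - A_2}{1 + e^{(\mathrm{pH} - x_0)/dx}} + A_2,$$

with $A_1$ the acidic-limit ratio, $A_2$ the alkaline-limit ratio, $x_0$
the centre and $dx$ the width, both in pH units. Printed renderings of this
formula are often typographically mangled; the form above is the one that
is algebraically consistent with the inversion actually used on the data,

$$\mathrm{pH} = x_0 + dx \cdot \ln\!\left(\frac{A_1 - A_2}{R - A_2} - 1\right),$$

and with the reading of $A_1$/$A_2$ as initial/final values. The width
$dx$ is a pH-scale quantity (the fit is ratio against pH), even though
fitting software sometimes labels the analogous parameter a "time
constant". The pair of maps is an exact bijection on the open interval
between the asymptotes; the tests hold the round trip to 1e-10.

Ratios at or just beyond an asymptote occur in real data because noise can
graze the saturated ends. Values within an absolute tolerance of 1e-9 of
the boundary are clamped just inside the domain and reported via a
`clamped` attribute; anything further out raises a domain error naming the
offending sample, since it indicates a wrong calibration rather than
noise.

## Fitting

`fit_boltzmann()` is a Levenberg–Marquardt least-squares fit
(`minpack.lm::nlsLM`) restarted over a small grid of initial widths, with
data-driven starting values (acid-limit ratio, alkaline-limit ratio, median
pH). It requires at least 4 distinct pH values spanning at least one pH
unit, and refuses flat data (unidentifiable sigmoid). Worth knowing: four
parameters estimated from five calibration points are only marginally
identified when noise sits directly on the points. In the intended pipeline
the calibration points are *steady-state estimates*, each obtained by
exponential regression over a few hundred staircase samples, which
suppresses the per-point noise by more than an order of magnitude; the 5%
parameter-recovery property holds on that path, and that is the path the
test suite asserts it on.

## Steady states

`steady_state_value()` fits $y(t) = y_{ss} + (y_0 - y_{ss})e^{-t/\tau}$
(time re-zeroed to the segment start, so the estimate is shift-invariant)
and returns the asymptote. Two guards matter in practice:

* if the optimiser fails, the mean of the final quartile of the segment is
  returned instead, and the `method` attribute records the fallback;
* if the fitted $\tau$ exceeds twice the segment span, the data cannot
  distinguish the exponential from linear drift and the "asymptote" is
  unconstrained extrapolation — a fit to a *flat noisy plateau* routinely
  produces absurd asymptotes this way. The plateau mean is used instead.

# Electrode recordings

The two-solution calibration (pH 7.0 and 6.4) gives the line
`pH = intercept + slope · V_e`; with exactly two points the interpolant,
with more an OLS fit. `ph_to_proton()` applies
$[\mathrm{H}^+] = 10^{-\mathrm{pH}} \times 10^9$ nM, used when a pH-scale
rate would misrepresent the underlying proton load (the same ΔpH at a more
acidic baseline means a larger Δ[H⁺]). Electrode drift enters a rate
estimate linearly: a drift of $d$ mV/min biases a pH-scale slope by exactly
$\mathrm{slope} \cdot d$ per minute, which the generator-based tests
confirm to numerical precision.

# Rate extraction

`extract_rate()` reports the ordinary least-squares slope over either a
fixed window anchored at the event edge or the sliding window of length
`window_s` (advancing one sample at a time) with maximal $|$slope$|$, ties
broken by the earliest window — the "maximum rate of change" readout. The
r² of a zero-variance segment is defined as 0.

The window length is a genuine analysis choice that the original
measurement convention leaves open, so it is a parameter, with defaults of
30 s for 0.4 Hz imaging traces and shorter windows for fast electrode
recordings. Two opposing biases govern the choice for a response that
relaxes exponentially with time constant $\tau$:

* a window of length $w$ *underestimates* the initial slope by a factor
  close to $e^{-w/2\tau}$ (about 9% at $w = \tau/5$), because the response
  curls away from the fitted line;
* short windows in noisy data *overestimate* it, because the
  maximum-over-windows statistic selects favourable noise.

Windows around $\tau/6$ to $\tau/5$ (with at least ~20 samples) keep both
effects inside ±10%, which is how the end-to-end flux-recovery tests
choose their windows (max(6 s, τ/6) at 4 Hz sampling). This is also why a
single-cell flux estimate should be read with its r², and why per-condition
means across cells are the quantity of interest, as in the underlying
experimental practice.

# Buffer capacity and proton flux

The intrinsic buffer capacity is measured from a terminal
5% CO₂ / 10 mM HCO₃⁻ pulse. With CO₂ freely equilibrating across the
membrane, the dissolved CO₂ is set by the superfusate,
$[\mathrm{CO_2}] = [\mathrm{HCO_3^-}]_o / 10^{\mathrm{pH}_o - pK'}$, and
the intracellular bicarbonate follows Henderson–Hasselbalch,
$[\mathrm{HCO_3^-}]_i = [\mathrm{CO_2}] \cdot 10^{\mathrm{pH}_i - pK'}$.
Because the rest of the experiment runs nominally CO₂-free, the pre-pulse
intracellular bicarbonate is taken as 0 mM and the bicarbonate formed
during the pulse equals its in-pulse steady-state value. Then

$$\beta_i = \frac{\Delta[\mathrm{HCO_3^-}]_i}{|\Delta \mathrm{pH}_i|}
\quad \text{(mM per pH unit)}, \qquad
J_H = \left|\frac{\Delta \mathrm{pH}}{\Delta t}\right| \cdot \beta_i
\quad \text{(mM/min)}.$$

Printed method summaries sometimes show the β_i ratio upside down while
still quoting mM units; the orientation above is the standard definition
and the only one that makes $J_H$ come out in mM/min, so it is the one
implemented. The CO₂-dependent buffer component β_CO₂ is deliberately
omitted, matching the nominally CO₂-free experimental design. A pulse that
moves pH by less than 0.01 raises an error rather than dividing by a
noise-scale ΔpH. $pK'$ defaults to 6.1, the physiological-chemistry
convention near room temperature, and is configurable through
`SolutionSpec`. The flux identity $J_H = |\mathrm{rate}| \times \beta_i$
holds exactly by construction of `FluxResult`.

The injection-dilution helper computes the intracellular concentration of
an injected compound as $(V_{inj} C_{inj})/(V_{free} + V_{inj})$. Whether
the injected volume belongs in the denominator is numerically moot at
oocyte scale (29.2 vs 31.5 mM before rounding for the canonical 27.6 nl /
400 mM / 0.35 µl example — both are 30 mM at one significant figure, the
reporting precision); we include it because mass balance says the final
volume contains the injectate.

# The ¹⁸O-exchange assay

Doubly labelled ¹³C¹⁸O¹⁸O (m/z 49) loses its ¹⁸O through repeated
CO₂/HCO₃⁻ interconversion, passing through ¹³C¹⁸O¹⁶O (m/z 47) to
¹³C¹⁶O¹⁶O (m/z 45). The enrichment statistic is

$$\mathrm{LE} = \log_{10}\!\left(\frac{100 \cdot a_{49}}{a_{49} + a_{47} + a_{45}}\right),$$

with log base 10 so that pure m/z 49 gives LE = 2 (the percent scale). LE
is invariant to overall abundance scaling, so detector gain cancels. In a
first-order cascade with per-¹⁸O-atom exchange rate θ
($\dot a_{49} = -2\theta a_{49}$, $\dot a_{47} = 2\theta a_{49} - \theta
a_{47}$, $\dot a_{45} = \theta a_{47}$), the total is conserved and LE
decays *exactly* linearly with slope $-2\theta/\ln 10$ per second — a
closed form that doubles as a cross-validation of the generator and the
statistic, asserted to 1e-6 in the tests.

Enzyme units follow the 100%-stimulation definition:
`units = |cat_rate| / |uncat_rate| − 1`, with the uncatalyzed rate fitted
on the pre-addition window of the same recording and the catalyzed rate on
the 10 minutes after lysate addition. Units are also normalised per ml
using the lysate volume, default 0.08 ml (a batch of 20 oocytes lysed in
80 µl); whether one normalises by lysate or cuvette volume is a lab
convention the original account leaves unstated, so the volume is an
explicit parameter rather than a constant. A catalyzed rate slower than
the uncatalyzed one yields negative raw units; the result is floored at 0
and flagged, since negative catalysis is assay failure, not enzymology.

# Nuclei counting

The proliferation readout mirrors the classic interactive pipeline:
threshold the 8-bit channel at 30–255, split fused nuclei with a watershed
on the Euclidean distance transform, count particles with a
size/circularity filter, and convert to nuclei/mm² via the pixel size.
Implementation choices:

* connected components are 8-connected (diagonally touching pixels merge);
  the 4-connected labelling of the underlying library is corrected by a
  union–find pass over diagonal adjacencies;
* the watershed's peak detection (`peak_tolerance`, `peak_ext`) controls
  over-segmentation; the defaults (tolerance 1, ext 1) cleanly split disk
  pairs whose centres are ~1.5 radii apart without fragmenting single
  nuclei;
* circularity is $4\pi A / P^2$, clamped to 1, with the perimeter
  estimated by the 4-direction Crofton (integral-geometry) formula, which
  is accurate to ~1–5% for smooth convex digital shapes — naive
  boundary-pixel counts overestimate perimeters of digital disks by ~25%
  and would misclassify genuinely round objects;
* no reference implementation's watershed is reproduced bit-for-bit;
  accuracy claims are made against planted ground truth (disjoint images
  must be counted exactly; at 30% touching pairs the watershed count must
  be within ±1 of the planted count).

The 2^(−ΔΔCt) expression ratio, the loading-normalised band intensity and
the signals-per-nucleus ratio are included as the small, exactly testable
formulas they are.

# Synthetic data: what it does and does not show

The generators emulate the *statistical structure* of each experiment with
recorded ground truth:

* **Calibration staircases** — piecewise mono-exponential approach (τ
  default 20 s) to the sigmoid value of each clamped pH step, Gaussian
  ratio noise (σ default 0.01), 0.4 Hz sampling, five steps pH 6.0–8.0 of
  300 s each.
* **Lactate experiments** — during application of concentration $c$ the
  initial pH slope is $-(J_{max} c/(c + K_m))/\beta$ with $K_m$ = 5 mM
  (the MCT1-scale affinity), relaxing exponentially (τ default 60 s)
  toward a quasi-steady pH; withdrawal mirrors back to baseline; a
  terminal CO₂ pulse acidifies to the pH at which the
  Henderson–Hasselbalch bicarbonate load equals β times the displacement —
  i.e. exactly the steady state a closed buffer of strength β would show,
  so `buffer_capacity()` has a well-defined truth to recover. Gaussian pH
  noise, σ default 0.005.
* **Electrode recordings** — the same pH kinetics mapped through the
  inverse electrode line, with optional linear drift and mV noise, plus
  the two prepended calibration plateaus.
* **Isotope series** — the closed-form cascade above, θ stepping from
  θ_uncat to θ_uncat(1 + U_true) at lysate addition, with optional Poisson
  counting noise at a scale of 10⁴ counts.
* **Nuclei images** — disks with Gaussian radius jitter; a requested
  fraction of nuclei form touching pairs at centre distance 0.75 of the
  summed radii, the rest are rejection-sampled to be disjoint; Gaussian
  intensity texture; 0.65 µm pixels (a 10× objective on a typical camera).

Noise magnitudes are not taken from any published statistics (none are
available); they are set so the analyses are visibly noisy but
recoverable. Consequently, passing tests demonstrate *estimator
correctness* — inverse consistency, oracle equality, bias bounds under the
stated noise — not robustness to everything real recordings do:
photobleaching and dye leakage, electrode drift nonlinearity, perfusion
dead-time, intracellular pH gradients, irregular nucleus shapes and
intensity inhomogeneity are all outside the generators' vocabulary. The
mono-exponential cell response is a stand-in, not a transporter model, and
the first-order cascade deliberately ignores the species-specific
hydration/dehydration chemistry of the full ¹⁸O-exchange system.

# Problem sizes and determinism

The validation suite runs at desk scale by choice: staircases of 5 × 300 s
at 0.4 Hz; flux-recovery grids of 2 amplitudes × 3 time constants × 2
noise levels × 8 simulated cells at 4 Hz; isotope records of 900 s at
1 Hz; images of 512² px with 20–25 nuclei (plus one 1581² px density
check). All stochastic tests fix their seeds; every generator is a pure
function of its parameters and seed, so regeneration is bit-identical.

# Known limitations

* The maximal-slope estimator is biased for exponentially relaxing
  responses (see above); window choice trades this against noise
  selection. This is inherent to the windowed-regression readout, not to
  the implementation, and is why recovery claims are stated at ±10%.
* `buffer_capacity()` assumes a clean pre-pulse plateau; apply it only
  after the cell has recovered from preceding events (about 5τ).
* The watershed accuracy claim is calibrated for disk-like nuclei at
  moderate overlap; heavily confluent fields will undercount.
* Calibration parameters from few noisy points are marginally identified;
  prefer steady-state-averaged calibration points and inspect the fit
  residual that `fit_boltzmann()` attaches.
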