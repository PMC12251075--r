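---
title: "Inline spectroscopic monitoring of multi-pump infusions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inline spectroscopic monitoring of multi-pump infusions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowspec)
```

## The measurement problem

In critical-care infusion, several drugs join a saline carrier at a stopcock
manifold and flow through a single catheter lumen. The concentration each
solute actually reaches at the delivery point depends on every pump's flow
rate and on the transport lag through the shared line — neither of which is
directly observable at the bedside. The method modelled here measures those
concentrations inline: a Z-flow cell (10 mm optical path, 26 µL volume) sits
in the common pathway, dual LEDs illuminate it, and a compact spectrometer
(350–700 nm) records transmission continuously. Two food dyes stand in for
drugs: Erioglaucine (EG, blue, absorbing near 631 nm, stock 25 µg/mL) and
Tartrazine (TZ, yellow, absorbing near 424 nm, stock 100 µg/mL).

`flowspec` implements the full measurement chain and, because no physical
rig is attached, couples it to a digital twin of the infusion line so the
whole method is testable end-to-end at desk scale.

## Forward optical model

Absorbance follows the Beer–Lambert law, additive over solutes:

$$A(\lambda) = \sum_i \varepsilon_i(\lambda)\, c_i\, L, \qquad
  I/I_0 = 10^{-A},$$

with $\varepsilon$ in mL µg$^{-1}$ mm$^{-1}$, $c$ in µg/mL and $L$ in mm.
The true dye spectra are available only as single-peaked curves, so each is
synthesized as a Gaussian (`make_dye_spectrum()`): EG peaking at 631 nm
(width 40 nm), TZ at 424 nm (width 45 nm). Peak absorptivities default to
0.0048 and 0.0012 mL µg$^{-1}$ mm$^{-1}$ so that each stock concentration
gives $A \approx 1.2$ ($I/I_0 \approx 6\%$) at its own peak over the 10 mm
path — a strongly attenuating, informative calibration range.

Cross-absorption is the one spectral feature that matters for unmixing and
the one least constrained by the available record: the Gaussian tails are
numerically negligible 200 nm away, so each default spectrum carries an
explicit flat baseline floor of 1% of its peak absorptivity
(`default_dyes(cross_fraction = 0.01)`). This keeps the off-diagonal terms
of the unmixing matrix nonzero and exercised; setting `cross_fraction = 0`
recovers (numerically) independent channels.

The detector applies multiplicative Gaussian noise, SD 0.5% of signal, per
wavelength and sample, clipped at zero. No noise model is stated for the
real spectrometer; 0.5% is a typical short-integration CCD figure and is
configurable (`detector_config()`). Intensities "at" 424 or 631 nm are means
over a ±1 nm band (configurable), since single-pixel versus band readout is
not specified for the original system.

## Calibration curves

Concentration-versus-transmission calibrations come in two fitted forms
(`fit_calibration()`):

* **single exponential** $I/I_0 = a\,10^{-bC} + c$ with $a>0$, $b>0$,
  $c \ge 0$. The exact equation used by the original system is in
  unavailable supplementary material; this form was chosen because it nests
  pure Beer–Lambert behaviour ($a=1$, $c=0$, $b=\varepsilon L$) and allows
  a baseline offset (stray light, detector floor).
* **linear**, for narrow concentration ranges.

The exponential fit is nonlinear least squares (port algorithm, bounded
below) with a deterministic start: $a = 1$, $c = \tfrac12\min(I/I_0)$, and
$b$ from a log-linear regression of $I/I_0 - c$ on $C$. `nls` is run with
`scaleOffset = 1` so noiseless (zero-residual) data converges rather than
erroring. Fits whose predicted curve is not strictly decreasing over the
data range are refused (`nonmonotone_calibration`): such a curve has no
unique inverse. Inversion (`invert_calibration()`) is closed-form and is
the exact mathematical inverse of prediction on the valid range;
measurements outside the curve's predicted range are refused rather than
extrapolated.

Normalization assumes a dye-free (saline) blank recorded per run defines
$I_0$; whether the original system re-blanks per run is unknown, and the
simulated detector normalizes against the true blank by construction.

## Two-dye unmixing

At the two measurement wavelengths the forward model is linear in
absorbance space:

$$A_w = -\log_{10} I_w = \sum_d K_{wd}\, C_d, \qquad
  K_{wd} = \varepsilon_d(\lambda_w)\, L.$$

`build_cross_matrix()` assembles $K$ (rows 424/631 nm, columns TZ/EG) and
refuses condition numbers above $10^8$ (`degenerate_spectra`) — dyes whose
spectra cannot be told apart at the chosen wavelengths. Recovery
(`recover_concentrations()`) is then an exact 2×2 solve; no iteration, no
calibration-curve approximation. The inversion algorithm of the original
system is unstated; the absorbance-space solve was chosen because it is
exact under the Beer–Lambert model, and the single-exponential curves are
retained for the single-dye path and baseline-offset estimation. The
construction generalizes to $n$ wavelengths × $n$ dyes, though only the
two-dye configuration is exercised by default.

Noise can push a recovered concentration slightly negative. Values within
0.5% of the stock concentration below zero are clipped to 0; anything more
negative raises `inconsistent_intensities` — at that magnitude the
intensities contradict the spectral model rather than reflecting noise.

## The infusion-line digital twin

Pump schedules are piecewise-constant per-pump flow rates
(`pump_schedule()`). At the manifold junction, ideal mixing gives
$C_i = Q_i C_{0,i} / Q_{tot}$, so at steady state the normalized
concentration equals the flow fraction: $C/C_0 = Q_i/Q_{tot}$.

Between junction and flow cell lies the line dead volume. Its physical
magnitude for a clinical manifold + catheter is not reported anywhere in
the available record, so it is a required configuration field with a
documented default of 1.0 mL. Transport is modelled as **tanks-in-series**
(default $n = 5$ equal well-mixed volumes): the chain reproduces the
qualitative dead-volume lag (time scale $V/Q_{tot}$), is monotone in its
step response, and has the junction concentration as its exact fixed point
for any $n$. $n = 1$ is a single mixing chamber; a **plug-flow** option
provides the pure-delay limit for analytic tests. Integration is an
explicit update at the detector interval with a stability guard
(`unstable_timestep` when the step exceeds half a tank residence time) —
adequate because residence times (tens of seconds and up) far exceed the
0.2–1 s sampling interval.

The balance under the outflow accumulates mass as $\rho \int Q_{tot}\,dt$
(computed in closed form from the schedule), with additive noise and
round-half-even quantization at the stated 0.01 mg sensitivity
(`balance_readout()`). Density is fixed at 1.0 g/mL: dye mass fractions are
at most $10^{-4}$, so dilute-aqueous density is exact to far better than
any other error source. Trial-to-trial variation is independent noise seeds
only; an optional pump-rate error is deliberately not defaulted on, since
the validation experiments hold pump programming fixed.

## Derived quantities

* **Total flow from the balance** (`total_flow_from_balance()`):
  $Q_{tot} \approx \Delta m / (\rho\,\Delta t)$, centered differences over
  a 30 s default window — wide enough that 0.01 mg quantization is
  negligible at mL/h flows.
* **Saline fraction** (`saline_fraction()`): with each solute exclusively
  in one syringe, flow fractions sum to one, so
  $C/C_0|_{sal} = 1 - C/C_0|_{EG} - C/C_0|_{TZ}$. Results below $-0.01$
  raise `mass_balance_violation`: during dead-volume transients the
  measured dye fractions lag the instantaneous flows and the closure
  genuinely fails — the error is a feature, marking the regime where the
  inference is invalid. (The underlying conservation statement is for an
  incompressible liquid; volume additivity is assumed throughout.)
* **Per-stream flows** (`stream_flows()`): $Q_i = (C/C_0)_i\, Q_{tot}$,
  saline taking the remainder, so the three always sum to $Q_{tot}$
  exactly.
* **Steady-state statistics** (`steady_state_stats()`): across $\ge 2$
  trials, per-time cross-trial mean and SEM $= s/\sqrt{n}$; repeatability
  is the maximum SEM over the analysis window and accuracy the maximum
  absolute difference between expected and mean. The original averaging
  window is unstated; the default is the last 5 minutes of each phase,
  after the transient has decayed.

## Validation presets

`experiment_preset()` encodes the three validation schedules verbatim
(rates in mL/h for saline/EG/TZ):

| Experiment | Interval | Rates | EG fraction | TZ fraction |
|---|---|---|---|---|
| exp_a | 0–60 min | 1.5 / 0.5 / 1 | 0.167 | 0.33 |
| exp_b | 0–15 min | 7 / 3 / 3 | 0.23 | 0.23 |
|       | 15–35 min | 3 / 7 / 3 | 0.54 | 0.23 |
| exp_c | 0–15 min | 7 / 3 / 3 | 0.23 | 0.23 |
|       | 15–35 min | 3 / 3 / 7 | 0.23 | 0.54 |

Stored fractions are checked against $Q_{dye}/Q_{tot}$ at load time.
Display rounding follows the table's own convention (three decimals below
0.2, two above). `run_experiment()` chains simulation → unmixing →
statistics, three trials by default, deterministic under a master seed from
which per-trial noise seeds are derived.

`fast = TRUE` divides all schedule times and the dead volume by 10. The
dimensionless lag $V/(Q\,t)$ is preserved exactly, so transient shape in
normalized time and every steady-state quantity are unchanged while a full
three-experiment run completes in about a second.

## What a green test does and does not establish

The generator emulates: Beer–Lambert optics with configurable
cross-absorption, multiplicative detector noise, dead-volume lag from a
saline-filled start, balance quantization, and the exact validation
schedules. It does **not** emulate: the true (untabulated) dye spectra,
the real rig's noise spectrum and drift, pump start-up mechanics or
compliance, laminar dispersion or turbulence at the junction, or the
unreported physical dead volume. Consequently the simulated steady-state
fractions, closure and flow back-calculation are genuine checks of the
*method*, while published accuracy/repeatability magnitudes and transient
shapes characterize the physical rig and are deliberately not reproduction
targets here.

## Limitations

* Two dyes, two wavelengths by default; $n>2$ unmixing is implemented but
  unvalidated against any reference system.
* Solutes must absorb strongly; weakly absorbing drugs would need a dye
  admixture, which this model treats as exact co-location.
* Each solute must be exclusive to one syringe; pre-mixed syringes break
  the flow-fraction identity.
* The transport model is a lumped approximation; it matches lag time
  scales, not detailed residence-time distributions.
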