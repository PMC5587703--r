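---
title: "Modelling within-breath arterial oxygen oscillations from a single alveolar compartment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling within-breath arterial oxygen oscillations from a single alveolar compartment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alvosc)
```

## The physiological question

Continuous intra-arterial oxygen sensing shows that arterial PO~2~ (PaO~2~)
is not constant within the respiratory cycle: it rises during inspiration and
falls during expiration, even in the healthy, uninjured lung. In lung-injury
models such oscillations are usually attributed to cyclical atelectasis — a
within-breath variation of shunt as dependent lung collapses and reopens. The
model implemented here shows that no varying shunt is needed: a single
well-mixed alveolar compartment with *constant* oxygen uptake, ventilated
tidally, already produces oscillations of the observed size, because oxygen
is delivered only during inspiration while the pulmonary circulation removes
it continuously.

`alvosc` packages that model together with the measurement rules used on
continuous PaO~2~ traces and a quantitative-CT aeration analysis, plus seeded
generators that emulate the study's inputs, so the whole pipeline runs and is
tested without experimental data.

## The compartment model

The lung is a single gas compartment of volume

$$V_A(t) = V_{A0} + V_{\mathrm{above\ EELV}}(t), \qquad
  V_{A0} = (\mathrm{EELV} - V_D)\,\mathrm{per\ kg} \times \mathrm{mass},$$

where EELV is the end-expiratory lung volume (the FRC at the applied PEEP)
and $V_D$ the series dead space. The alveolar O~2~ fraction $F_A$ obeys the
mass balance

$$\frac{d(F_A V_A)}{dt} =
  \begin{cases}
    F_{in}(t)\,\dot V(t) - \dot VO_2 & \text{inspiration} \\
    -F_A\,|\dot V(t)| - \dot VO_2 & \text{expiration,}
  \end{cases}$$

with alveolar PO~2~ $P_A = F_A (P_B - P_{H_2O})$. The first $V_D$ ml of each
inspiration re-enter at the end-expiratory alveolar composition (series
dead space, first-in/last-out); the remainder enters at FIO~2~. Expired gas
leaves at alveolar composition, so during expiration the dilution term
cancels and

$$\frac{dP_A}{dt} = -\frac{\dot VO_2 (P_B - P_{H_2O})}{V_A(t)},$$

which is also the closed-form breath-hold prediction
(`predict_breath_hold_decline()`): with the volume frozen, alveolar PO~2~
falls linearly at a rate inversely proportional to lung volume. This single
expression links the tidal simulation, the breath-hold experiments, and the
`estimate_vo2()` regression (decline rate against $(P_B-P_{H_2O})/V_A$
through the origin).

Only oxygen is tracked. CO~2~ and N~2~ exchange, the respiratory-quotient
volume deficit, haemoglobin-desaturation kinetics below ~100 mmHg, regional
V/Q heterogeneity and recruitment dynamics are all outside the model. Uptake
$\dot VO_2$ is treated as removal of O~2~ partial volume at BTPS;
`stpd_to_btps()` converts a metabolic (STPD) uptake when needed.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| mass | 29 | kg | reference animal |
| eelv_per_kg | 22.3 | ml/kg | measured FRC at PEEP 5 cmH~2~O |
| vd_per_kg | 3 | ml/kg | series dead-space estimate |
| vo2 | calibrated | ml/s BTPS | see below |
| pb, ph2o | 760, 47 | mmHg | barometric / water vapour |
| shunt | 0 | — | constant within the breath when non-zero |
| transit_delay | 2 | s | lung-to-sensor transport |
| sensor_tau | 2 | s | first-order smoothing of the arterial signal |
| compliance, resistance | 50, 0.01 | ml/cmH~2~O, cmH~2~O·s/ml | see below |

**VO~2~ calibration.** The study never reports its oxygen uptake directly,
but it reports the end-expiratory breath-hold decline (6.9 mmHg/s at an
alveolar volume of $(22.3-3)\times 29 = 559.7$ ml). `gas_params()` therefore
defaults to the algebraic inversion
$\dot VO_2 = 6.9 \times 559.7 / 713 \approx 5.42$ ml/s BTPS. With that single
calibration the model predicts the declines measured at the two inflation
volumes (+10 and +20 ml/kg) without further fitting:

```{r decline}
p <- gas_params(mass = 29)
predict_breath_hold_decline(p, alveolar_volume_at_eelv(p) + c(0, 290, 580))
```

**Mechanics.** The study reports airway pressures but not compliance or
resistance. We chose C = 50 ml/cmH~2~O and R = 0.01 cmH~2~O·s/ml: the
expiratory time constant is 0.5 s (lungs essentially empty within the
shortest expiratory time studied, 1 s), the peak airway pressure of a
10 ml/kg breath at PEEP 5 is 12.0 cmH~2~O (below the 13.6 cmH~2~O ceiling
maintained in the experiments), and the simulated mean airway pressures fall
in the reported 5–9 cmH~2~O range. These are ordinary values for a ~30 kg
pig.

**Arterial transmission.** The arterial channel is the alveolar signal after
(optional) constant-shunt venous admixture through the oxygen-content model
(Severinghaus dissociation curve; venous PO~2~ a parameter, default
40 mmHg, since cardiac output is not modelled), a 2 s transit delay, and a
first-order low-pass of time constant 2 s representing transport mixing and
sensor response. A first-order filter attenuates a sinusoid of period $T$ by
$1/\sqrt{1 + (2\pi\tau/T)^2}$ — at RR 12 ($T = 5$ s, $\tau = 2$ s) the gain
is 0.37, so arterial amplitudes are roughly a third of alveolar ones at that
rate and larger at RR 6. Shunt defaults to zero: the point of the model is
that none is needed.

## Ventilator waveforms

`simulate_volume_trace()` concatenates single-compartment breaths. Volume
control delivers constant inspiratory flow $V_T/T_i$; pressure control
applies a square pressure target (0.1 s linear rise) and the volume follows
the RC charging curve; expiration is passive and exponential against PEEP in
both modes. `pc_pressure_for_vt()` inverts the charging curve so both modes
deliver the same tidal volume, as the experiments did. Periodic steady state
of the waveform is declared when the end-expiratory volume changes by less
than 0.5% of V~T~ between the final two breaths.

Numerical choices: the default grid is dt = 0.01 s (≥ 50 samples in the
shortest phase studied, Te = 1 s at I:E 4:1 and RR 12; dt ≥ τ/5 is rejected).
Pressure-control inspiration uses an exponential-integrator step with
midpoint drive (exact for piecewise-constant pressure), and the O~2~
integrator is a fixed-step discrete balance whose inflow/outflow follows the
sign of the volume change, so phase-switch samples carry gas consistently —
the discrete per-breath O~2~ budget then telescopes to
$\dot VO_2 \times$ period at steady state to ~10^-6^ relative, and the
frozen-volume decline matches the closed form to well under 1%.

The O~2~ store washes in with a time constant of roughly
$V_A / (\text{fresh-gas alveolar ventilation}) \approx 15$ s at the default
settings. Simulations start at $F_A = 0.9\,\mathrm{FIO_2}$ and run 240 s by
default; all steady-state statistics use the trailing 120 s window, leaving
a ≥ 8-time-constant transient to decay.

## Measurement rules on PaO~2~ traces

* `oscillation_stats()`: mean and per-breath peak-to-trough amplitudes over
  the trailing 2-min window; breaths are segmented from airway-pressure
  onsets when that channel exists, otherwise from PaO~2~ troughs with ≥ 1
  mmHg prominence and a minimum spacing of half the expected period.
* `steepest_decline()`: the steepest OLS slope over every sliding 5-s
  window, excluding any window containing a sample below 100 mmHg (below
  which haemoglobin desaturation flattens the decline). OLS over the window
  is used rather than a two-point difference because it is robust to sensor
  noise; the estimator is verified against an exhaustive window scan.
* `is_steady_state()`: consecutive non-overlapping 60-s means differing by
  ≤ 5 mmHg/min.
* `bland_altman()`: bias, SD of differences, 1.96-SD limits of agreement,
  CI of the bias via $t_{n-1}\,s/\sqrt{n}$ and of each limit via the
  standard $t_{n-1}\,s\sqrt{3/n}$ approximation.
* `normalize_decline()`: the body-mass correction is configurable (linear in
  mass, or none) because the original normalization formula is not public.

## Quantitative CT

Voxels are quantitated by the linear mixing model — gas fraction
$\max(0, \min(1, -\mathrm{HU}/1000))$, tissue density 1.0 g/ml (configurable
to 1.04) — and classified into the standard aeration bands: overinflated
[−1000, −901], normal [−900, −501], poor [−500, −101], atelectatic
[−100, +100] HU. Masked voxels outside [−1000, +100] are flagged and counted
in the nearest band, never dropped. Reports give per-class tissue mass, gas
volume and tissue-mass fractions; `lung_volume()` returns both the total
(gas + tissue) and the gas-only volume, since either may be meant by a
"CT lung volume".

## What the synthetic data emulate — and what they do not

The generators reproduce the *structure* of the study's data under known
ground truth:

* `make_breath_hold_dataset()`: 18 holds (3 volumes × 6 repeats) ordered by
  a de Bruijn B(3,2)-based cycle so every ordered volume pair occurs — a
  balanced stand-in for the original (unpublished) sequence table. Traces
  are the linear-decline model plus the arterial transform and Gaussian
  sensor noise (default SD 1 mmHg; the sensor's true noise figure is
  unpublished).
* `make_ct_phantom()`: per-band uniform HU draws with voxel counts solved
  from the band-mean tissue fractions so tissue-mass fractions hit their
  targets within 1 point. Default voxels are 0.2 ml so the default 52×52
  masked slice holds ~540 ml.
* `make_tidal_ct_series()`: inflation must grow the lung region — on a fixed
  grid, adding gas to a voxel necessarily removes computed tissue — so each
  inflated frame shifts selected poorly-aerated voxels by exactly −400 HU
  (into the normal band, each losing 0.4 voxel-volumes of tissue) and
  recruits an equal number of rim voxels at −600 HU (each carrying exactly
  that tissue). Tissue mass is conserved to machine precision, injected gas
  equals the prescribed profile to one voxel, atelectatic voxels are
  untouched by default, and an optional cyclical-atelectasis mode exists as
  a contrast case.

What passing tests on these data show is that the *pipeline* is correct:
estimators recover generator ground truth, conservation laws hold, and the
directional effects of ventilator settings match the in-vivo tables. They do
not show that the model fits any particular animal: real traces carry
non-Gaussian sensor artefacts, cardiogenic oscillations and slow drifts; real
CT has texture, beam hardening and partial-volume effects; and the in-vivo
means and amplitudes (and the reported 31% overestimate of measured declines)
can only be reproduced against the original recordings, which are not
deposited.

## Reproducing the protocol

`run_tidal_study()` mirrors the experimental design: 16 conditions (2 modes ×
4 I:E ratios × {RR 12 with V~T~ 10 ml/kg, RR 6 with V~T~ 20 ml/kg}), FIO~2~
calibrated once per condition set on its volume-control anchor (target mean
PaO~2~ 130 mmHg) and held across the set, each condition summarised over the
trailing 2-min steady-state window. `run_breath_hold_study()` runs the
18-hold sequence and reports measured rates per volume. Both are
seed-deterministic.

```{r study, eval = FALSE}
tab <- run_tidal_study(run_config())
tab[tab$rr == 6, c("mode", "ie_ratio", "mean_pao2", "amplitude_mean")]
```

## Known limitations

Single compartment, linear mechanics, no spontaneous effort, no CO~2~, no
pressure–volume hysteresis, shunt constant within the breath, and an
arterial transform with two free constants (delay, smoothing) that are not
identifiable from the published aggregates. The breath-hold model freezes
the alveolar volume (constant-pressure hold with open airway) and is invalid
once PO~2~ approaches zero; analysis below 100 mmHg is excluded by design.
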