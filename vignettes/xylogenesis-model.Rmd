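---
title: "Simulating wood formation: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating wood formation: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xylosim)
```

## The problem

Conifer growth rings show a conserved anatomy: wide, thin-walled,
low-density earlywood; a transition to narrow, thick-walled latewood with a
density peak near the ring boundary; and high temperature sensitivity of
that peak (the basis of maximum-latewood-density palaeothermometry). None
of this is well explained by models that treat single wood properties in
isolation. `xylosim` implements a process model in which these features are
emergent: cells develop along independent radial files under the joint
control of temperature-dependent growth kinetics, daylength-driven
developmental zones, dormancy phenology, and — critically — the spatial
distribution of carbohydrates diffusing inward from the phloem.

## State and daily cycle

Each radial file is an ordered sequence of cells from the phloem inward.
A cell carries its radial length `L_r` (axial and tangential lengths are
fixed at 2680 and 50.1 µm), birth length, a growth factor `eps`, a division
length `L_r_d`, wall mass `M`, and cytoplasmic carbohydrate concentration
`theta`. One day is one time step:

1. **Zone classification.** A cell's developmental phase follows the
   distance of its centre from the inner phloem edge relative to the day's
   proliferation (`z_p`), enlargement-only (`z_e`) and wall-thickening
   (`z_t`) zone widths. Status moves only forward (proliferating →
   enlarging → thickening → mature).
2. **Enlargement** (non-dormant proliferation/enlargement zones):
   `dL = L_r (e^{eps·mu} − 1)` with Boltzmann–Arrhenius
   `mu(T) = mu0·e^{(Ea/k)(1/T0 − 1/T)}` (`mu0 = 0.0570` d⁻¹ at
   `T0 = 283.15` K, `Ea = 0.374` eV).
3. **Division** (proliferation zone): triggered at `L_r ≥ L_r_d`, with
   `L_r_d = f·L_r_b + chi_b(2 − f + Z)`; `f = 0.48` places size control
   between a pure sizer and a pure adder. Division is asymmetric
   (`Z_a ~ N(0, 0.105)`, clamped at ±0.49); each daughter's `eps`
   compensates its birth-size deviation. The file's outermost cell is the
   bifacial initial; its second daughter becomes phloem with probability
   0.315 and then leaves the tracked system.
4. **Wall demand.** Saturated deposition is proportional to lumen volume
   with steeper kinetics (`Eaw = 1.43` eV): `dM_max = omega·V_l·Arr(T)`.
   Proliferating/enlarging cells deposit only primary wall, capped by the
   headroom `rho·V_wp − M` of a 0.8 µm shell (recomputed after growth, so
   enlarging cells regain headroom daily); thickening cells deposit
   secondary wall without cap; dormant zones deposit nothing.
5. **Transport equilibrium.** With demands fixed, concentrations satisfy
   `theta_{i−1} − theta_i = eta·Σ_{j≥i} dM_j(theta_j)` with boundary
   `theta_0 = theta_p = 95` mg ml⁻¹ and an impermeable wall behind the
   innermost living cell. The scalar unknown — the innermost living cell's
   concentration — is solved by Brent's method; realized `dM` is then
   deposited. Mature cells are outside the domain.

At the last day of the year, cells outside the proliferation zone are
finalized into the annual ring (innermost = earliest formed = ring start);
proliferation-zone cells and the initial carry over.

## Zones, daylength and dormancy

Zone widths are linear in daylength, `z_k = a_k + b_k·dl`, fitted for days
from DOY 185 onward. Regime rules: the proliferation width before DOY 185
is pinned at its DOY-185 value (its seasonal maximum) and, during dormancy,
at its DOY-231 value; the wall-thickening width uses the regression on all
days. For the enlargement-only zone before DOY 185 we use the temporal
extension `z_e = 1257 − 5.01·DOY`: the printed coefficient pair is
continuous with the daylength regime at DOY 185
(`1257 − 5.01·185 = 330 ≈ −744 + 51.7·dl(185)`), which identifies its
predictor as day-of-year; interpreting it as a daylength regression instead
would produce an ~800 µm discontinuity at DOY 185 and implausibly large
earlywood cells. No width may exceed its value at 24 h daylength — required
north of the Arctic circle, where polar day begins around DOY 150 and the
temporal extension (~505 µm) meets the daylength regime's ceiling
(496.8 µm) almost exactly. Ordering `z_t ≥ z_e ≥ z_p` is enforced by
raising outer widths to inner ones, inner zones being the more directly
observed. Daylength itself is geometric (solar declination
`23.44°·sin` of the orbital angle, hour-angle cosine clamped for polar
day/night); no refraction term is applied, and accuracy well within ±0.5 h
suffices since zone widths are linear in daylength.

Dormancy of the proliferation and enlargement-only zones begins on DOY 231.
Release uses a chilling-conditioned thermal-time rule,
`dd_req = 15 + 4401.8·e^{−0.042·cd}`: chill days (`t < 0` °C) accumulate in
the autumn/winter window from DOY 306 until the forcing window opens, and
degree-days (`max(t, 0)`) accumulate from DOY 32; release occurs on the
first day in the first half of the year (DOY ≤ 182) whose preceding
degree-day sum meets the requirement. We read the two windows as
sequential — chilling then forcing — because the concurrent alternative
(chilling continuing into spring) collapses the requirement to ~26 °C·d and
releases dormancy in mid-April, inconsistent with observed boreal cambial
reactivation in late May; the sequential reading yields release around DOY
130–145 at the study latitude. A day at exactly 0 °C counts toward neither
sum. Only one release can occur per year, never in the second half.

## Initialization, carry-over and ensembles

Each file starts from 100 provisional cells of length `chi_b(1 + Z_a)` that
divide once; one daughter from each division is kept, and daughters are
retained while their centres fall inside the day-1 (dormant) proliferation
zone — about 14–18 cells at 64.35° N. Each retained cell receives `eps` and
`L_r_d` draws, a complete primary wall (`M = rho·V_wp`; cambial cells have
finished primary walls, and the model text does not specify an initial
mass), and phloem-level `theta`. An ensemble (default 100 files; the
scenario experiments in this package use 15–25 for tractability) runs each
file on an independent RNG stream derived from one master seed, making
every result bit-reproducible.

## Scenarios

`scenario_config()` encodes the experiment hooks: a fixed kinetic
temperature (dormancy forcing untouched), zone widths frozen at a chosen
DOY (20 June for the named experiments), removal of autumn dormancy,
carbohydrate saturation (`dM = dM_max`, solver bypassed), and additive
temperature anomalies targeted at the enlargement rate, the thickening
rate, or only the cells of the proliferation or enlargement zone. Anomalies
never touch the dormancy forcing unless explicitly requested, matching the
design of the temperature experiments.

## Synthetic climate

The built-in generator emulates boreal-Sweden forcing: a seasonal cosine
(annual mean 1 °C, half-amplitude 14 K, warmest near DOY 200) plus AR(1)
daily noise (φ = 0.7, innovation SD 3 K, stationary SD ≈ 4.2 K), 365-day
years, started from the stationary distribution. This reproduces the
first-order statistics that drive the model — summer means near 13–15 °C,
long sub-zero winters supplying ~85–90 chill days, spring warming through
April–May — but not everything about real forcing: no synoptic-scale warm
spells beyond daily AR(1) persistence, no skewness, no elevation or
maritime effects, and no interannual trends. Tests passing under this
generator therefore demonstrate the mechanisms and their orderings, not
site-level reproduction of any observed year. With real daily temperature
CSVs (`read_forcing()`) the same machinery runs unchanged.

## Numerical choices

- **Transport.** The equilibrium is found by a residual sweep: given a
  trial innermost concentration, demands and inter-cell drops are
  reconstructed outward and compared with the phloem boundary value. The
  residual is monotone in the trial value and brackets in `[0, theta_p]`.
  After `stats::uniroot()` (Brent) locates the root, a bisection in
  compiled code collapses the bracket to adjacent doubles: the sweep
  amplifies perturbations of the innermost concentration (each cell
  contributes a factor > 1), so polishing is needed to hold the boundary
  residual below 10⁻⁸ mg ml⁻¹. Conservation (influx = Σ deposition) then
  holds to 10⁻⁹ mg d⁻¹. An independent damped fixed-point iteration on the
  full concentration vector serves as a cross-check in the test suite
  (agreement ≤ 10⁻⁶ over randomized demand sets).
- **Division.** The second daughter's length is computed as `L − s_a`, so
  length conservation is exact to the bit; wall mass is partitioned
  proportionally (`M_b = M − M_a`). Division-length draws are floored at
  the birth length so a pathological noise draw defers division by a day
  instead of creating an inverted target. A cell divides at most once per
  day; at realistic temperatures daily growth is far below the division
  increment, so this is not binding.
- **Update order** is growth → division → transport, because wall demands
  are evaluated on post-growth geometry; the daily timestep makes the
  residual ordering freedom immaterial.
- **Degenerate inputs.** Zone widths are floored at 0; a cell reaching
  `M/rho > V_c` aborts the run (it would indicate an integration bug — one
  day of saturated deposition cannot occlude a lumen below ~30 °C with the
  default kinetics, which the suite checks); rings formed in years without
  dormancy release are empty and valid.

## Problem sizes

The packaged checks use 25-file ensembles over 12 years for the emergent
anatomy (≈ 2000 cells per year), 25-file paired 5-year ensembles for the
temperature-response experiment, and 15-file ensembles for the scenario
orderings; these sizes give profile bins of 20–70 cells and stable ensemble
means while keeping a full run of the suite under a few minutes. The
ensemble size of the original experiments (100 files) is available by
setting `n_files = 100`.

## Known limitations

- Phloem anatomy, turgor, water and nutrient limitation, and axial or
  tangential growth are outside the model's scope; temperature is the only
  environmental driver of cell kinetics.
- The phloem carbohydrate concentration is constant; there is no
  whole-plant carbon balance or seasonal source dynamics, and no diffusion
  between radial files.
- The division-inhibiting signal implied by meristem size-control theory is
  represented implicitly through the sizer–adder rule and the asymmetry
  growth factor, not as an explicit concentration field.
- Under the synthetic forcing the emergent earlywood plateau sits near
  0.30 g cm⁻³, somewhat below the ~0.4 g cm⁻³ seen in observed profiles;
  the ring's total mass is supply-limited by the carbohydrate gradient, and
  earlywood density is acutely sensitive to the near-zero concentrations
  reaching the thickening zone in early summer, when many enlarging cells
  intervene between it and the phloem. The latewood peak, terminal decline,
  scenario orderings and temperature responses are robust to this.
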