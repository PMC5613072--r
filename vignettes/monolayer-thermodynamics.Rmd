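---
title: "Monolayer thermodynamics with monofilm: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monolayer thermodynamics with monofilm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monofilm)
```

## The physical problem

A Langmuir monolayer is a one-molecule-thick film of amphiphiles spread at
the air/water interface and compressed by movable barriers while the
surface pressure $\pi$ (mN/m) is recorded against the mean molecular area
$A$ (Å²/molecule). For membrane lipids — sphingomyelin (SM),
phosphatidylcholines such as POPC, cholesterol and its ring-oxidized
derivatives such as 7-ketocholesterol — the $\pi$–$A$ isotherm and a small
set of derived quantities summarize the film's packing and the
interactions between its components:

* the **compression modulus** $C_s^{-1} = -A\,\mathrm{d}\pi/\mathrm{d}A$,
  whose magnitude distinguishes gaseous, liquid-expanded (LE),
  liquid-condensed (LC) and solid (S) film states;
* the **lift-off area**, the largest area at which $\pi$ rises measurably
  above zero;
* the **limiting area**, the $\pi = 0$ intercept of the last rectilinear
  segment of the isotherm;
* the **collapse pressure** $\pi_{coll}$ at which the 2D film fails into
  3D structures;
* for mixed films, the **excess area**
  $A^{exc} = A_{12} - (A_1 X_1 + A_2 X_2)$ and the **excess Gibbs energy
  of mixing** (Pagano–Gershfeld)
  $$\Delta G^{exc} = N_A \int_0^{\pi} A^{exc}\,\mathrm{d}\pi,$$
  negative values indicating attractive, film-stabilizing interactions;
* the **critical packing parameter** $s = V/(a\,l_c)$ (Israelachvili),
  mapping molecular geometry onto shape classes that rationalize which
  lipid pairs pack favourably.

Monolayers at 30–35 mN/m mimic the lateral packing of one bilayer
leaflet (the monolayer–bilayer correspondence), so 30 mN/m is the
package's default reporting pressure for $\Delta G^{exc}$; scans are
routinely also evaluated at 5–35 mN/m since interactions are
pressure-dependent.

## Data model and units

Units are fixed in the schema: areas in Å²/molecule, pressures in mN/m,
temperatures in °C, energies in J/mol. An `isotherm` is an ordered
compression run (areas strictly decreasing after normalization) with at
least 10 points, a composition summing to 1 within $10^{-9}$, and
pressures no lower than $-0.5$ mN/m — values below that exceed plausible
Wilhelmy-plate drift and are rejected. Input order is auto-detected,
exact duplicate areas (barrier jitter) are averaged, and negative
pressures within the drift band are retained but clipped to 0 for
integration. Files use a plain CSV dialect
(`area_A2,pressure_mN_m`) with a `#`-prefixed metadata header; the writer
emits 17 significant digits so `write(read(f))` is byte-identical.

## Numerical choices

**Pre-collapse branch.** All interpolation and integration act on the
points up to and including the *first* occurrence of the global pressure
maximum; a collapse plateau repeats the maximum, so its onset terminates
the branch. Post-collapse points are kept in the object for collapse-mode
detection.

**Smoothing.** Pressure smoothing is a Savitzky–Golay-style local
polynomial fit computed in the *area* coordinate rather than in sample
index, with windows that shrink one-sidedly at the record ends. Fitting
in $A$ keeps the exact-reproduction property for polynomial data on
non-uniform area grids, which uniform-spacing convolution filters do not
guarantee. The default (window 11, order 2) is conservative for
$\ge 200$-point isotherms and preserves the plateau curvature needed for
transition detection; spline differentiation is deliberately avoided as
it over-smooths plateaus.

**Differentiation.** $C_s^{-1}$ uses centered finite differences on the
(optionally smoothed) branch. On noise-free equation-of-state data with
500+ points the result agrees with the analytic derivative to well below
1% (the test suite and `scripts/acceptance.R` measure ~0.01%).

**Regridding.** $A(\pi)$ uses monotone piecewise-cubic (PCHIP)
interpolation on the maximal strictly-increasing branch; the returned
areas are therefore non-increasing in $\pi$. An initial zero-pressure
foot is collapsed onto its last point so that $A(\pi \to 0)$ is the
lift-off-side area, and grid pressures up to 0.5 mN/m below the lowest
recorded branch pressure are answered with that area (flat extension
below the noise floor); the integrand's contribution there is negligible
by construction. Anything further out of range is an error naming the
offending pressure.

**Integration.** $\Delta G^{exc}$ uses the trapezoid rule on a uniform
pressure grid with 0.1 mN/m steps from exactly $\pi = 0$. Isotherm data
are tabulated, not functional, so no adaptive quadrature is used. The
unit bridge is $N_A \times 10^{-23}$ J = 6.02214076 J/mol per
Å²·mN/m·molecule⁻¹.

**Thresholds and tie-breaks.**

* Lift-off: crossing of $\max(3\sigma_\pi, 0.1\ \mathrm{mN/m})$
  sustained for 5 consecutive points, refined by linear interpolation.
  For a film whose isotherm is exactly linear this detector sits
  $0.1/\text{slope}$ Å² below the zero-pressure intercept — the only
  situation in which "lift-off ≥ limiting area" can be violated, and by
  a known, bounded amount.
* Limiting area: the longest sliding window (≥ 15% of the rising branch,
  pressures above 0.1 mN/m) with $R^2 \ge 0.999$, negative slope and
  ≥ 1 mN/m pressure span; among ties the most condensed window wins, and
  the OLS line is extrapolated to $\pi = 0$.
* State bands (the label convention gives no numeric boundaries, so these
  are the package's documented choice, consistent with the standard
  reference assignments 150 → LC, 300 → S, 160 → LC, 830 → S):
  G below 12.5, LE 12.5–50, an LE/LC band 50–100 reported as LC with a
  borderline flag, LC 100–250, S above 250 mN/m; boundary values belong
  to the lower band.
* Collapse: a pressure drop > 0.3 mN/m after the maximum ("drop"), or a
  sustained $|\mathrm{d}\pi/\mathrm{d}A| \le 0.05$ plateau at the
  pressure maximum after the modulus maximum ("plateau"); if both fire,
  the lower onset wins; a slope-ratio "kink" detector is a fallback.
  Restricting the plateau search to the neighbourhood of the pressure
  maximum is what keeps LE/LC transition plateaus from masquerading as
  collapse.
* Transitions: sub-threshold (12.5 mN/m) modulus minima strictly between
  two above-threshold maxima; runs touching the branch ends (gaseous
  foot, collapse) never qualify.
* Shape bands: cone $s \le 1/3$, truncated cone to 0.95, cylinder
  $1 \pm 0.05$, inverted truncated cone to 3, inverted cone beyond;
  boundary to the lower band. Mapping shape words to numeric bands is a
  convention, flagged as such to users; no default $V, a, l_c$ values
  ship for real lipids — preset geometries would be invention, so users
  supply their own.
* The $\Delta G^{exc}$ minimum is reported at measured compositions only;
  parabolic refinement exists behind `refine = TRUE` but is off by
  default because composition grids are coarse and the refined value
  suggests more precision than the data carry.
* Miscibility: the collapse-pressure range across ≥ 3 compositions must
  exceed 0.6 mN/m (three times the collapse-detection uncertainty) for a
  "miscible" verdict; interior collapses that all coincide with one
  endpoint's value within that band give "immiscible-indication";
  anything else is "inconclusive".

## The synthetic generator

Raw laboratory isotherms for these lipids are not generally available as
deposited data, so the package ships an equation-of-state generator whose
output has closed-form ground truth for every analysis stage:

* **volmer**: $\pi = k_BT/(A-\omega) - \pi_{coh}$ — expanded films; the
  modulus oracle is $C_s^{-1} = A\,k_BT/(A-\omega)^2$.
* **linear_condensed**: $\pi = \text{slope}\,(\omega - A)$ — condensed
  films with constant $\mathrm{d}\pi/\mathrm{d}A$.
* **piecewise_LE_plateau_LC**: Volmer LE branch, first-order transition
  plateau, linear condensed branch — sphingomyelin-like films.

Collapse is rendered either as a hard plateau at $\pi_{coll}$ or as a 10%
pressure drop over 2 Å² followed by a flat. Mixtures blend the endpoint
equations of state additively and add a Margules-type excess
$A^{exc}(\pi, X) = X(1-X)\,[\alpha_0 + \alpha_1(1-2X)]\,g(\pi)$ with
$g$ constant or linearly decaying, so
$\Delta G^{exc}$ has the closed form implemented in
`analytic_excess_gibbs()`. Member collapse pressures interpolate linearly
between the endpoints (miscible-film behaviour).

**Preset calibration.** The five shipped pure presets are calibrated only
to the printed characteristic points of the four reference films:
lift-off anchored so $\pi$ crosses the 0.1 mN/m detection threshold at
exactly 91 (brain SM) and 78 Å² (egg SM); transition plateau at 5 mN/m
ending at 55 Å²; condensed-branch slopes set so the modulus maximum is
150 / 300 / 830 / 160 mN/m for brain SM / egg SM / Chol-like / 7KC-like
films; collapse plateaus at 69 / 69 / 46 / 46 mN/m (POPC-like: 50).
Every other parameter (area ranges, plateau placement, cohesion
pressures) is an illustrative free choice. Two caveats are worth
stating plainly. First, the POPC-like preset is a linear film chosen to
reproduce the *absence of a transition* and the 50 mN/m collapse — no
simple one-branch EOS keeps the modulus in the LE band all the way to
collapse, so this preset's modulus scale (≈ 90 mN/m, borderline LE/LC)
is not a claim about real POPC. Second, the synthetic condensed branches
place the modulus maximum just above the transition rather than just
below collapse as real films often do; detector tests do not depend on
that location.

The mixture presets encode the qualitative interaction pattern of the
sterol/phospholipid systems: `Chol-POPC` has a symmetric attractive
excess ($\alpha_0 = -8$ Å²) and `7KC-POPC` exactly half that amplitude,
so the recovered interaction-strength ratio is 2; `Chol-SM`/`7KC-SM` are
asymmetric ($\alpha_1 = 2.5\,\alpha_0$), placing the continuous minimum
at $X \approx 0.27$ (grid argmin 0.3, the 2:1 lipid:sterol
stoichiometry) and the sign change at $X = 0.7$; the pseudo-binary
ternary presets (`Chol-POPC:SM`, `7KC-POPC:SM`, endpoint 1 a 1:1
POPC/SM blend) change sign at $X = 0.8$. Ternary films are treated
strictly pseudo-binarily — a fixed-ratio blend becomes one endpoint via
`as_pseudo_component()` and the scan runs over the sterol mole fraction;
no Gibbs-triangle analysis is attempted.

**Noise model.** The instrument model is Gaussian: per-point pressure
noise with $\sigma_\pi = 0.05$ mN/m by default (five times the 0.01 mN/m
sensor resolution, allowing for drift) and an area calibration offset
with $\sigma_A = 1$ Å² (half the ±2 Å² replicate-reproducibility
envelope; with $\sigma_A = 1$, ~95% of replicates fall inside ±2 Å²,
which the test suite verifies on 200 seeded replicates). Only bounds,
not distributions, are available for real instruments; Gaussian is the
documented choice. For a *single* film each simulated replicate draws
its own offset. For a *mixture series* the offset is drawn once and
shared by all members: the members of one composition series are
measured in one session with the same spreading solutions and trough
calibration, so the dominant area error is common-mode — and
$A^{exc} = A_{12} - X_1A_1 - X_2A_2$ is exactly invariant under
common-mode shifts because the mole fractions sum to 1. That invariance
is the practical reason excess quantities are robust observables, and it
is why the noisy-replicate recovery of $\Delta G^{exc}$ (median error
well under 10 J/mol at 30 mN/m in the acceptance measurements) is
limited only by the pressure noise. If per-member independent offsets
were physically appropriate instead, a ±1 Å² independent error on all
three areas would propagate to an irreducible
$\mathcal{O}(200\ \mathrm{J/mol})$ uncertainty at 30 mN/m — worth
remembering when comparing series recorded in different sessions.

**What the generator does not emulate.** Relaxation and hysteresis,
barrier-speed effects, pH effects, nucleation before collapse, BAM
texture, and genuinely non-Margules excess shapes. Passing tests on
synthetic data therefore demonstrate that the *numerics* (derivative,
interpolation, quadrature, detectors) are correct and that the pipeline
recovers known ground truth under a realistic noise model — not that any
particular real film obeys these equations of state.

## Problem sizes and determinism

The shipped analyses use 500-point pure isotherms, 400-point mixture
members, 0.1 mN/m integration steps, 100 seeded replicates for recovery
and noise studies and 200 for the reproducibility envelope — sizes at
which every oracle comparison is comfortably resolved. All generators
are pure functions of (parameters, seed); mixture-series members draw
their noise sequentially from the master seed, so a series is
reproducible as a whole.

## Worked example

```{r example, eval = FALSE}
library(monofilm)

## a sphingomyelin-like film and its descriptors
iso <- simulate_preset("SM-brain")
describe_isotherm(iso)

## a sterol/sphingomyelin mixing study with instrument noise
ser <- simulate_mixture_preset("Chol-SM", x2 = seq(0, 1, 0.1),
                               noise = c(0.05, 1), seed = 1)
scan <- gibbs_composition_scan(ser, pi_target = 30,
                               smooth = list(window = 11, polyorder = 2))
scan$argmin_x   # 0.3: the 2:1 lipid:sterol stoichiometry
miscibility_from_collapse(ser)$verdict  # "miscible"

## molecular shape from geometry
shape_assessment(new_component("Chol", "sterol",
                               geometry = list(V = 400, a = 19,
                                               l_c = 17.5)))
```

## Known limitations

* The descriptor thresholds (state bands, lift-off threshold, collapse
  tolerances) are conventions; alternative conventions shift labels for
  films near band boundaries, which is why borderline cases carry flags.
* `limiting_area()` requires a genuinely rectilinear condensed segment;
  on continuously curved films (pure Volmer) it raises a
  `no-linear-segment` error rather than returning an extrapolation of a
  badly fitting line.
* Real $\Delta G^{exc}$ magnitudes for specific lipid systems cannot be
  validated against synthetic data; only signs, minima locations, ranges
  and programmed ratios are meaningful checks here.
* Pseudo-binary treatment hides any composition dependence *within* the
  fixed-ratio blend; it answers the question "what does adding sterol to
  this matrix do", nothing more.
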