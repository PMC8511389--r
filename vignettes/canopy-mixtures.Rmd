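---
title: "Simulating binary wheat cultivar mixtures: model, emulation and sensitivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating binary wheat cultivar mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canomix)
```

## What this package computes

`canomix` re-creates, at desk scale, an in-silico experiment on balanced
binary mixtures of winter wheat cultivars: an individual-based canopy
simulator in which plants compete for diffuse light and adjust their
tillering, wrapped in the statistical machinery needed to learn from it —
maximin latin-hypercube designs, Kriging (Gaussian-process) emulation of the
stochastic simulator, variance-based Sobol sensitivity indices, and
Efficient Global Optimization of stand performance.

A simulated stand is summarized by three outputs:

* `n_ears` — mean number of ears per plant at maturity (each surviving axis
  bears exactly one ear; the main stem never dies, so `n_ears >= 1`);
* `l_perc` — mean fraction of incident PAR intercepted by the stand, averaged
  daily from day 100 after sowing to stand maturity;
* `f_tot` — total plot fitness, the sum over surviving axes of the
  photothermal quotient `F_axis = PAR_i45 / T_m45` (mean daily PAR
  intercepted by the axis over the 45 days preceding flowering, divided by
  the mean temperature over the same window, in mol °Cd⁻¹) — a standard
  linear proxy for wheat grain number.

A binary mixture is encoded by the stand mean (`ref`) and the between-
cultivar difference (`diff`) of five architectural parameters; the two
cultivars get `ref ± diff/2`:

| parameter | meaning | ref range | diff range | plant scale |
|---|---|---|---|---|
| `H_MS`  | final main-stem height (cm)            | 65–135  | ±50  | 40–160  |
| `phi_B` | blade insertion angle from the stem (°) | 30–50   | ±40  | 10–70   |
| `LmaxB` | longest main-stem blade (cm)           | 16–27   | ±16  | 8–35    |
| `GAI_c` | GAI threshold stopping tiller emission | 0.4–0.7 | ±0.6 | 0.1–1   |
| `PAR_t` | PAR threshold for tiller survival      | 0.3–0.5 | ±0.2 | 0.2–0.6 |

Overyielding compares a mixture to its components:
`OY = out_mix / ((out_pure1 + out_pure2)/2)`. The package runs the two pure
references under the *same master seed* as the mixture, which makes the
zero-differential identity exact: a "mixture" of two identical cultivars
reproduces its pure stands bit for bit and `OY = 1` to machine precision,
not just in expectation.

## The stand simulator

### Development

Development follows thermal time (base temperature 0 °C). Plants emerge
after a random delay drawn uniformly on [80, 150] °Cd; main-stem leaves
appear every phyllochron (110 °Cd, 11 leaves), each blade expanding linearly
over two phyllochrons. Stems elongate linearly between 900 and 1500 °Cd
after plant emergence, flowering is at 1650 °Cd and maturity at 2350 °Cd;
after flowering all green area senesces linearly to zero at maturity. A
rank-`r` primary tiller carries the main-stem blade profile with `r` fewer
leaves, delayed to its own emergence, and a final height reduced by 5% per
rank (floored at 50%): taller, earlier axes overtop later ones, and their
longer stems also carry more sheath/internode surface.

Blade allometry: leaf `n` of `N` has final length
`LmaxB (0.4 + 0.6 n/N)`, width `0.08 ×` length and area `0.74 ×` length ×
width, so the whole profile — and with it the stand's green area — is
strictly increasing in `LmaxB`. Blade area sits in the canopy layer of the
leaf's ligule (inserted at fraction `n/N` of current stem height); the
sheath/internode cylinder (diameter 0.4 cm) is spread uniformly along the
stem. The exact blade-shape and curvature equations of full 3-D wheat FSPMs
are out of scope; this allometry keeps the monotonicities that drive the
experiment.

### Light competition

The 3-D ray-tracing radiative model of the reference experiment is replaced
by a horizontally layered turbid medium — the major, deliberate fidelity gap
of this package. The plot (default 110 plants at 200 plants m⁻², a 10 × 11
grid with 7.07 cm spacing) is the repeating cell of an infinite periodic
canopy, so there are no border effects; all neighbour distances are
minimum-image. Green area is binned into 2 cm layers. For each of 16 sky
directions (a TURTLE-style equal-solid-angle discretization of the
hemisphere weighted by the standard-overcast radiance `(1 + 2 cos θ)/3`
times `cos θ`), layers are swept from the top: layer `l` has optical depth
`Σ_axes k_a A_al / (S cos θ)` with `S` the ground area and
`k_a = sin(phi_B)` the genotype's extinction coefficient (flatter blades
project more area); the absorbed flux `I_l (1 − e^(−depth))` is shared
among axes in proportion to `k_a A_al`. Interception plus transmission
equals incident light to 1e-9 relative — tested daily.

What the layered model preserves: the competitive asymmetries the
experiment manipulates (leaf area via `LmaxB`, vertical dominance via
`H_MS` and tiller height, angle via `phi_B`). What it loses: horizontal
heterogeneity within a layer (a plant does not shade its *neighbourhood*
more than distant plants), row/diagonal effects and sunfleck geometry.
Conclusions about spatial arrangement cannot be read off this model;
directional trait effects can.

### Tillering plasticity

Three rules regulate tillering:

1. *Emission*: a rank-`r` tiller may emerge once the main stem has `r + 3`
   leaves, with empirical probability `p_r` (defaults 0.95, 0.85, 0.70,
   0.50, 0.30, 0.10 for ranks 1–6); one uniform draw per plant and rank,
   taken at first eligibility.
2. *Cessation*: each day, every plant perceives the green area index within
   0.15 m (minimum-image disc, ≈14 neighbours at default density). Once
   this surrounding GAI reaches the genotype's `GAI_c`, the plant stops
   emitting tillers permanently.
3. *Regression*: from the start of stem elongation, an active tiller whose
   7-day running mean of intercepted PAR per unit green area per degree-day
   falls below the genotype's `PAR_t` switches to a distinct *regressing*
   state, loses its green area linearly over 5 days, and is then dead. The
   main stem is exempt, so every plant bears at least one ear.

A unit note on the regression signal: the package expresses intercepted PAR
per green area in mol m⁻² °Cd⁻¹. On this scale a well-lit axis under a
seasonal incident PAR of 5–55 mol m⁻² d⁻¹ sees values of order 0.5–2 and a
shaded tiller 0.1–0.4, so the explored `PAR_t` range [0.2, 0.6] is a live
threshold separating the two. Expressing the same quantity per cm² would put
all axes at ~1e-4 and make any threshold in that printed range kill every
tiller; the per-m² convention is the only dimensionally consistent reading
of the explored range and is used throughout.

### Randomness and seed-matching

All stochastic elements (cultivar placement, emergence delays, tiller
draws) are drawn up front from named substreams of one master seed
(`sub_seed`); the daily loop is deterministic. This is what makes the OY
seed-matching contract exact, makes campaign results independent of worker
count, and makes a saved run record replayable bit for bit.

## Emulation and sensitivity

Because even a desk-scale simulator is too slow to sample a 10-D space
densely, all sensitivity and optimization work runs on Kriging metamodels,
never on the raw simulator. The emulator uses an anisotropic Matérn 5/2
correlation with a constant trend; inputs are normalized to the unit
hypercube and outputs standardized. Length-scales (and, by default, a
nugget absorbing the simulator's stochastic noise) are estimated by
maximizing the concentrated log marginal likelihood with seeded multi-start
L-BFGS-B (5 restarts; length-scales bounded in [0.01, 100], nugget ratio in
[1e-8, 1], a 1e-10 diagonal jitter for numerical stability). A
zero-variance response returns a flagged constant model rather than an
error, so degenerate campaign outputs do not kill a pipeline.

Sobol indices use the Saltelli A/B/AB_i pick-freeze scheme with the Jansen
estimators for both the first-order (MSI) and total-order (TSI) index —
chosen for their lower variance for TSI. Uncertainty is reported as the
spread over 10 independent replications of the whole scheme rather than a
bootstrap: simpler, honest about Monte-Carlo error, and negative small
estimates are deliberately *not* clipped so that this error stays visible.
The overyielding of an output is emulated compositionally:
`OY(ref, diff) = mix(ref, diff) / mean(pure(ref + diff/2), pure(ref − diff/2))`
with the 10-D mixture metamodel in the numerator and the 5-D pure-stand
metamodel evaluated at both derived cultivars in the denominator.

Optimization follows the classic EGO loop for maximizing `f_tot`: refit the
metamodel on all runs so far, draw a fresh seeded LHS candidate pool,
evaluate the Expected Improvement
`EI = (μ − best) Φ(u) + σ φ(u)`, `u = (μ − best)/σ`, and run the simulator
at the argmax (first index on ties). Hyperparameters are refitted at every
iteration; "best" is the best *observed* output, with simulator noise
absorbed into the nugget — the simplest defensible convention for a
stochastic code. When the objective is made deterministic by fixing the
simulation seed (as in the package's own optimization checks), the correct
emulator is instead the interpolating model (`nugget = 0`): there is no
noise to absorb, and a spurious nugget only flattens the Expected
Improvement surface. Failures at a chosen point are recorded, skipped and
not counted as iterations.

Designs are maximin latin hypercubes obtained by drawing a configurable
number (default 20) of seeded random LHS candidates and keeping the one
with the largest minimum pairwise distance — deterministic given the seed
and sufficient at these design sizes, in place of exchange/annealing
algorithms. Dimension order is fixed as per-parameter (ref, diff) pairs and
serialized in headers to prevent silent misalignment.

## Problem sizes and what the tests show

The reference experiment ran 5,000 mixture and 1,000 pure simulations of
110-plant plots and enriched with 50 EGO runs against 10,000-candidate
pools. This package's analyses and tests run the same pipeline at reduced
sizes chosen to keep a full rerun on a laptop comfortable: 24-plant plots
(12 for the EGO property runs) over a 330-day synthetic season, 64–96-point
mixture designs with 3 replicate seeds, Sobol at `n_base` 2048–4096 × 10
replications, EGO with 6–15 iterations over pools of a few hundred.

Passing tests therefore show that the *machinery* is right — exact
zero-differential overyielding, light conservation, LHS stratification,
closed-form Sobol and EI oracles, directionally correct leaf-size effects
(`n_ears` falls and `l_perc` rises with `LmaxB`) — not that the simplified
light model reproduces the reference experiment's published index values;
those derive from full 3-D ray tracing and are out of reach by design.

The synthetic climate emulates a smooth multi-site average (annual mean
11 °C, amplitude 8 °C, sowing day-of-year 295, PAR 5–55 mol m⁻² d⁻¹,
AR(1) temperature noise with coefficient 0.7, lognormal PAR noise
σ = 0.1). It has no weather fronts, frost events or inter-annual
variability; conclusions about year-to-year stability of mixtures are
outside what these runs can support.

## Known limitations

* Layered turbid-medium light: no horizontal heterogeneity, no explicit
  organ geometry.
* Primary tillers only, no secondary tillering, no plant mortality, no
  nitrogen or water limitation (also absent from the reference model).
* The fitness proxy stops at the photothermal quotient; there is no grain
  filling.
* The tiller height factor (1 − 0.05 × rank) and the sheath-cylinder
  lateral area are simple stand-ins for organ-level kinetics; they provide
  the qualitative mechanism (taller tillers carry more non-blade area and
  regress more easily) without claiming its exact magnitude.

## A worked zero-differential check

```{r oy-check, eval = FALSE}
climate <- generate_climate(330, seed = 1)
spec <- mixture_spec(ref = c(90, 40, 21, 0.55, 0.35), diff = rep(0, 5))
mixture_overyielding(spec, climate, seed = 1, n_plants = 24)
#>   output   out_mix out_pure1 out_pure2 oy
#> 1 n_ears 1.1250000 1.1250000 1.1250000  1
#> 2 l_perc 0.7931493 0.7931493 0.7931493  1
#> 3  f_tot 0.3590507 0.3590507 0.3590507  1
```

The three outputs agree across the mixture and both pure references because
the genotypes are identical and the seeds are matched; `scripts/acceptance.R`
recomputes exactly this quantity.
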