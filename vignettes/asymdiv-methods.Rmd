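---
title: "Modelling mother-restricted division under a limiting vacuolar resource"
author: "asymdiv package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mother-restricted division under a limiting vacuolar resource}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymdiv)
```

# The biological problem

When budding yeast are moved from rich medium to one lacking an essential
transition metal (zinc, iron or copper), population growth switches from
exponential to linear: division becomes restricted to the mother cells
that were born in rich conditions, while their daughters are born small,
receive almost none of the vacuole, and arrest in G1. The interpretation
modelled here is that the vacuole carries a stored, non-replenishable
pool of the limiting metal; by keeping that pool in one progenitor
instead of diluting it two-fold at every division, the population as a
whole completes more divisions before the pool is exhausted.

`asymdiv` implements that picture end to end: a closed-form capacity
model, a stochastic agent-based population simulator with presets for the
studied genotypes and media, a synthetic dual-channel time-lapse
renderer, the end-to-beginning lineage-reconstruction algorithm used for
such movies, and the growth/size/asymmetry/survival statistics.

# The limiting-resource capacity model

A progenitor enters the poor environment with a vacuolar pool $Z_0$ of
the limiting resource; division is impossible below the critical level
$Z_c$, and each division consumes $\Delta Z$.

* **Symmetric partitioning** halves the pool at every division, so after
  $k$ cycles each descendant holds $Z_0/2^k$. Division stops after
  $\lfloor \log_2(Z_0/Z_c) \rfloor$ cycles and the population can grow at
  most by the factor $N_s = Z_0/Z_c$.
* **Asymmetric retention** keeps the whole pool in the progenitor, which
  can generate $N_{as} = (Z_0 - Z_c)/\Delta Z$ daughters; with
  $\Delta Z = 0$ division can proceed indefinitely.

Asymmetric retention therefore wins exactly when $\Delta Z$ is small
relative to $Z_c$; `preferredStrategy()` evaluates the crossing point,
and both capacities are tested against brute-force depletion loops.

```{r capacity}
capacityTable(z0 = 16, zc = 1, dz = c(0.1, 1))
```

# The population simulator

`simulatePopulation()` is an event-driven, per-cell simulation. Each cell
carries a size (volume proxy), a vacuolar pool, and a lineage record; the
regime (a `RegimeParams` object) fixes the mean cycle time, the partition
fraction $f$ retained by the mother at division, the regeneration rate of
the pool from the medium, the Start size threshold, and the
`ResourceParams`. Regimes with a medium shift switch the cycle time,
partition fraction, daughter size fraction and regeneration rate from
rich-phase values to post-shift values at `shiftTime`.

The rules, in order:

1. **Division viability.** A cycle can start only when the pool covers
   the critical level *plus* the upcoming division cost,
   $R \ge Z_c + \Delta Z$: a division that would leave the mother below
   $Z_c$ is not attempted. This makes a fully retaining progenitor
   ($f = 1$, no regeneration) complete exactly
   $\lfloor (Z_0 - Z_c)/\Delta Z \rfloor$ divisions, matching the
   closed-form capacity, and it is why arrested mothers end with pools
   just above $Z_c$ rather than at zero.
2. **Start (size) gate.** Growth to the critical size requires
   $R \ge Z_c$ — a starved cell cannot grow — and division cannot
   complete before the critical size is reached. The drawn cycle time
   covers G1, so for well-fed cells the size gate is never the slower
   process; accounting G1 inside the drawn inter-division time is what
   lets a population of cells with mean cycle time $\tau$ double every
   $\tau$ minutes, rather than $\tau$ plus a daughter-maturation delay.
3. **Cycle duration.** Lognormal with the regime mean and CV (default
   0.15; lognormal guarantees positivity), multiplied by the slowdown
   $\max(1, \mathrm{ref}/R)^{\gamma}$ with $\gamma = 1$. For wild-type
   regimes the reference is $Z_c$, so cells at a healthy pool never slow
   down. The *whi5* preset references the initial pool $Z_0$ instead:
   without the Start checkpoint, cycle rate tracks the diluted pool from
   the first division, which is what makes *whi5* cycles lengthen
   generation after generation while wild-type mothers keep a constant
   rate. (Coupling the slowdown to $Z_c$ alone cannot produce this:
   cells eligible to divide always have $R \ge Z_c$, so their slowdown
   would always be 1.)
4. **Division.** The mother keeps $f \cdot R - \Delta Z$ (clipped at
   zero), the bud receives $(1 - f) R$, and the daughter's size is
   `daughterSizeFraction` of the mother's. Resource conservation at
   every unclipped division is tested to $10^{-9}$.
5. **Founder phase.** Founders complete their first division after a
   uniform fraction of a cycle, emulating the desynchronised age
   structure of a culture loaded into a flow cell. Without this, the
   synchronised early divisions bias the fitted doubling time upward.

Randomness is keyed per (master seed, cell id, draw index), so identical
seeds give bit-identical trees and extending a run never perturbs the
history of existing cells.

## Regime presets

| preset | cycle (min) | $f$ | regen | $Z_0$ | notes |
|---|---|---|---|---|---|
| `rich` | 103 | 0.5 | fast | 9 | exponential growth |
| `low_metal` | 120 (pre: 103) | 0.98 | 0 post-shift | 10 | 8 post-shift divisions per full-pool progenitor; daughters born at 0.65 of the mother size |
| `preadapted` | 150 | 0.98 | 0 | 6.5 | 4–5 divisions |
| `semi_low` | 150 | 0.5 | slow | 9 | slower but exponential |
| `whi5` | 120 | 0.5 | 0 | 9 | Start threshold ×0.7, slowdown referenced to $Z_0$ |
| `whi5_rich` | 103 | 0.5 | fast | 9 | normal rate, cells 30% smaller |
| `vac17` | 180 | 1.0 | 0 | 9 | no vacuole transport to the bud; linear from the outset |
| `zrc1cot1` | 150 (pre: 103) | 0.98 | 0 | 5 | smaller stored pool, earlier transition |

Choices made once and not revisited: the partition fraction $f$ is not
reported as a number in the imaging literature this emulates; 0.98 makes
the late daughter share a few percent — visible but far below $Z_c$. The
low-metal pool $Z_0 = Z_c + 9\Delta Z$ is sized so that, under the
division-viability rule, a full-pool progenitor completes exactly eight
post-shift divisions. The shift is placed at 180 min: divisions before
it partition the vacuole symmetrically, those after it asymmetrically,
so the asymmetry onset matches the observed ~3 h mark, and "early
daughters can still divide" is emergent — cells born before the shift
carry replenished pools. Regeneration in rich medium (0.5 units/min)
refills a half pool within minutes, an order-of-magnitude choice the
configuration exposes.

## Stress events

`applyStress()` implodes each exposed cell independently with its class
probability (class = mother/daughter at stress onset) and assigns
survivors of recoverable stresses a class recovery delay. The presets
encode osmotic stress (30% of daughters vs 8% of mothers imploding),
zinc shock (mothers resume promptly, daughters 4 h later) and rapamycin
(most mothers die, daughters mostly recover; the exact probabilities,
0.75 and 0.15, are qualitative choices as only the ordering is
reported).

# The synthetic movies

`renderMovie()` turns a simulated tree into exactly the cues the
reconstruction uses, and nothing more: a cytoplasm (bright-field proxy)
channel for segmentation, a nuclear channel whose signal appears in the
bud at nuclear separation (12 min before birth by default), a bud-neck
ring that is bright from bud emergence and drops by `budneckContrast` at
birth, and a ground-truth label mask used only by tests. Geometry is a
planar layer of non-overlapping discs: founders on a grid, every
daughter at the first free angle clockwise from the mother's previous
bud site. Centres sit on pixels and each disc uses the radius whose
rasterised pixel count best matches the intended area, keeping labelled
areas within 5% of the size they encode. Overcrowding raises an error
naming the frame rather than silently overlapping cells.

# Lineage reconstruction

The analysis follows the end-to-beginning design: segment only the final
frame, then track backwards.

* **Segmentation**: threshold the cytoplasm channel (3×3 box-smoothed
  when noisy; background level and spread estimated by median and MAD,
  with a quarter-dynamic-range floor so noiseless input works) and split
  touching cells by seeded region growing from nuclear peaks. Unborn
  buds have no nucleus and are absorbed by their mother's segment.
* **Backwards tracking**: each final segment is propagated to earlier
  frames by overlap (previous labels restricted to the earlier frame's
  foreground seed a new propagation). A label without foreground support
  terminates — a daughter's track ends where its bud appears — and no
  track can exist that is absent from the final frame.
* **Event calling**: nuclear separation is the first frame the track's
  peak nuclear intensity exceeds background + 5 sd (the peak, not the
  region mean, so large cells do not dilute their own nucleus).
  The mother is chosen among the nearest nucleated neighbours as the one
  whose shared-neck trace (3-frame median-smoothed) shows the largest
  fractional drop within 30 min at or after nuclear separation; the drop
  must reach 50% to call the birth, otherwise the event is kept flagged
  with no birth. The 30 min window is applied one-sided (birth at or
  after separation), configurable.
* **Tree building**: founders are tracks present and nucleated at frame
  1; every confirmed birth adds a daughter; a cell is a mother once it
  mothers one confirmed birth. Sizes are tracked areas divided by the
  area scale; no volume conversion is attempted.

On noiseless renders the round trip is exact: tree isomorphic to the
generator's, births within one 6-min frame, classification error zero.
At pixel noise up to 20% of the signal amplitude the tests require the
topology to survive and classification to stay above 95%.

# Growth and asymmetry statistics

* `fitExponential()` is ordinary least squares on $\log_2$ counts (variance
  stabilising; the doubling time is the inverse slope). `fitLinear()`
  fits raw counts; its automatic window takes the longest suffix
  reaching $r^2 \ge 0.98$, starting no earlier than 120 min after any
  shift (the post-shift transition is excluded).
* `classifyGrowthMode()` compares the two $r^2$ on the common
  transition-excluded window; a margin under 0.01 is ambiguous. $r^2$ is
  defined as $1 - SS_{res}/SS_{tot}$ on the fitted scale and set to 0
  for constant series, so degenerate inputs compare as ambiguous.
* `interdivisionStats()` aggregates successive division-time differences
  per mother by post-shift rank; `cycleTimesByGeneration()` groups cycle
  durations by the generation of cells born after the shift, the cohort
  whose pools are set purely by dilution. The highest observed
  generation is right-censored (only its fastest cycles finish before
  the horizon), so monotonicity checks exclude it.
* `sizeDistributions()` uses medians (robust to the lognormal cycle
  noise) and defines the gap as $1 - \mathrm{med}(daughter)/
  \mathrm{med}(mother)$. Age correction aligns all births and reads
  sizes at the common (median) age, removing the age-driven component:
  on a fixture where both classes share one growth law the corrected gap
  is zero while the raw gap is not.
* `vacuoleFraction()` reports the partition of the pool as it is split
  (before the division loss is consumed), so mother and daughter
  fractions sum to one and recover the regime's $f$ exactly.
* `stressSurvival()` tallies per class with binomial standard errors.

# What the synthetic data do and do not show

The generator reproduces the *structure* of the experiments — count
dynamics per class, per-generation cycle times, size and vacuole
asymmetry, differential survival — under idealised conditions: cells
never move or detach, intensities are piecewise-constant plus Gaussian
noise, segmentation cues are unambiguous, and the vacuole is a single
well-mixed scalar pool. Passing the round-trip tests therefore validates
the algorithmic chain (simulation → rendering → tracking → statistics),
not the biology of real movies: real bright-field segmentation, focus
drift, photobleaching, crowding-induced occlusion and replicative aging
are all outside scope, as are explicit zinc transporter kinetics and
colony geometry effects.

# Problem sizes

The shipped tests and the acceptance script use 8 single-founder
colonies (10 h) for the exponential regime, 30 founders run to arrest
(~33 h) for the low-metal regimes, a 65-cell colony on a 384×384 px
field for the noiseless round trip, a 25-cell colony at 20% noise for
the robustness check, 500 cells per class for stress tallies, and 20
paired seeds for the wild-type/whi5 comparison. These sizes give
run-to-run spreads comfortably inside each tolerance (e.g. the fitted
doubling time varies by ~±2 min across master seeds).

# Known limitations

* The partition fraction, regeneration rates and stress probabilities
  other than the osmotic pair are order-of-magnitude or
  qualitative-ordering choices; only their observable consequences
  (division counts, cycle times, survival ordering) are constrained.
* The pre-adapted regime is a parameter preset, not a mechanistic model
  of pre-adaptation.
* `cellSizeAt()` for reconstructed trees reads areas at the nearest
  frame; sizes are in arbitrary units throughout (no pixel scale is
  assumed).
* The simulator has no spatial interactions; crowding exists only as a
  layout constraint in the renderer.
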