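---
title: "A mechano-logical model of the C. elegans germ line"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechano-logical model of the C. elegans germ line}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germsim)
```

## The model

`germsim` simulates one hermaphrodite gonad arm in 3D from the end of the L2
larval stage through adult homeostasis. Two coupled layers drive the tissue:

* **Cell mechanics.** Every germ cell is a deformable sphere. Overlapping
  spheres repel with a linear overlap spring, `F = k * delta` along the
  centre line, where `delta` is the overlap depth; motion is overdamped,
  `dx/dt = F / drag` (no inertia), integrated with forward Euler. Cells are
  confined to a tube of radius `r(t)` around the path traced by the
  migrating distal tip cell (DTC), and cells distal to and within the
  U-turn are additionally kept to a single layer lining the tube wall,
  leaving a hollow core that represents the rachis.

* **Cell logic.** Each cell carries a hierarchical statechart with five
  orthogonal regions — the GLP-1 (Notch) receptor, LAG-1, the GLD-1/GLD-2
  pathways, the cell cycle, and sex determination — updated every step
  against a frozen per-cell context (clock, arclength distance to the DTC,
  compressed-volume fraction, radius, life stage). Transitions whose guard
  is true fire immediately; daughters inherit the parent's configuration at
  division.

The biological hypotheses encoded in the chart:

* Within 35 µm of the DTC the receptor becomes Bound; at or beyond 70 µm
  the signal becomes Absent, LAG-1 switches off and the GLD pathways
  activate. Between the thresholds the receptor keeps its previous state,
  and Absent is terminal: meiotic entry is irreversible.
* Cells leave mitosis only when they are in G1 with GLD active at ≥ 70 µm
  from the DTC, so cells past G1 at signal loss divide exactly once more.
  A fixed-length G1 and a fixed meiotic S precede meiotic prophase, and
  meiotic cells grow steadily to a 4 µm radius cap.
* Cell-cycle phases G1 and G2 are sampled per entry from `N(mu, (s*mu)^2)`
  with `s = 0.1`; S and M are fixed at their means. Phase means scale a
  3 h total in larvae and an 8 h total in adults, ramping linearly from
  mid-L4 to adulthood.
* Adult cells compressed below 70% of rest volume pause the cycle: the G2
  timer freezes until the compression relaxes (contact inhibition). The
  compressed volume subtracts, for each overlapping neighbour, the
  spherical cap cut off by the radical plane of the two spheres.
* On reaching 200 µm from the DTC a cell commits: sperm-fated strictly
  before 32.5 hours post-hatch (hph), oocyte-fated otherwise. Sperm-fated
  cells divide twice after short delays, producing four terminal sperm.
  Oocyte-fated cells grow and are mature at a 10 µm radius; while immature
  and within 250 µm of the DTC, adult oocyte-fated cells die with
  probability `P` per hour (converted to a per-step geometric hazard
  `1 - (1 - P)^dt`, so the outcome is step-size invariant). Cells that
  reach the proximal gonad (≥ 250 µm from the DTC) are committed to
  becoming gametes.
* A mature oocyte within one oocyte diameter of the proximal end is
  ovulated together with one sperm; with no sperm left, oocytes accumulate.

The boundary grows with the DTC: a prescribed per-stage migration rate, a
U-turn at a prescribed time (wherever the DTC happens to be), and a pause
rule — the DTC only advances while a germ cell is within one cell diameter
of it. During late L4 the turn itself is displaced away from the centre of
the animal ("stretching"), doubling the proximal limb; cells in the
proximal limb advect affinely with the stretch, cells in the turn translate
rigidly, and cells in the return limb keep their physical position.

## Parameters

Measured, printed quantities (marked `[paper-fixed]` in configuration
dumps): the 35/70/200/250 µm thresholds, 32.5 hph, 3 h and 8 h cycle
totals, `s = 0.1`, the 70% arrest fraction, the 4 µm and 10 µm radius caps,
16 founder cells, four sperm per spermatocyte, and the one-cell-diameter
DTC gap (CD = 70/13 ≈ 5.38 µm, from the printed equivalence of 70 µm with
~13 cell diameters; base mitotic radius 2.7 µm).

Everything else is free configuration with defaults chosen once to give a
realistic organ; the main ones, with rationale:

* **Stage times** (`t_start` 15, `t_L4` 25, `t_adult` 34.5 hph; turn at
  26 hph). The sperm/oocyte time threshold is a hard constraint: cells must
  be 200 µm from the DTC before 32.5 hph or no sperm ever form. At the
  fixed 3 h larval cycle starting from 16 cells, gonad length reaches
  200 µm only in late L4, so late L4 must precede 32.5 hph. These defaults
  give a sperm cohort of in vivo order (~100-150 sperm) and place
  adulthood at ~34.5 hph.
* **Phase split** (G1 5%, S 50%, G2 35%, M 10% of the stage total): G1 is
  very short in this system; only the total is constrained.
* **Gonad radius schedule** `r(t)`: 5 µm (L3 start) → 6 µm (L4) → 11.5 µm
  (adult), linear between. These radii give 8-10 cells per circumferential
  row and mid-L3 first meiotic entry, both as observed in vivo.
* **Migration rates** 7 / 9 / 11 µm/h (L3 / early L4 / late L4), adult 0;
  **stretch** 22 µm/h from mid-L4 to adulthood, which doubles the proximal
  limb over the window.
* **Mechanics**: stiffness `k = 20` force/µm, drag 1 force·h/µm (only
  `k/drag` is identifiable), step `dt = 0.01` h. Fixed meiotic G1 0.5 h,
  meiotic S 3 h; meiotic growth 0.05 µm/h, oocyte growth 0.5 µm/h;
  apoptosis `P = 0.03`/h (about half of oogenic cells die before reaching
  protection at the simulated proximal transit rate, as in vivo; this is
  also the free parameter that balances meiotic-arm inflow and outflow, so
  the adult proliferative pool holds steady); sperm-division delay 1 h; terminal sperm radius
  1.5 µm (spermatids are far smaller than germ cells; at the full base
  radius a realistic sperm cohort would fill half the gonad and jam the
  proximal arm).

## Numerical choices

* **Statechart semantics.** Orthogonal regions update independently
  against the frozen start-of-step snapshot, so cross-region signals
  (receptor → LAG-1 → GLD) propagate one step per layer and the update
  order cannot matter. When several guards out of a state are true, the
  first transition in definition order fires; chained transitions run to
  quiescence with a limit of 8 hops per region per step (exceeding it
  signals a mis-specified chart).
* **Division timing.** The division event is emitted on entry into M.
  Daughters inherit the parent's configuration — including M, with a fresh
  timer — then complete M before G1, so consecutive division events of a
  lineage are separated by one full G1+S+G2+M cycle and realized cycle
  lengths average the stage total.
* **Initial states.** The 16 founders start in a uniformly random cycle
  position (phase weighted by expected duration, elapsed time uniform
  within the phase), receptor Unbound, LAG-1 Active, GLD Inactive, sex
  Precursor. Distal founders bind the receptor within one step.
* **Boundary conventions.** Strict senses as printed: Bound below 35 µm,
  Absent at ≥ 70 µm, commitment at ≥ 200 µm, sperm strictly before
  32.5 hph (a tie is an oocyte), arrest strictly below 70%, protection at
  ≥ 250 µm.
* **Mechanics substepping.** Within one simulation step the position
  update subdivides adaptively so no cell moves further than 0.45 of its
  own radius per force evaluation; transient force spikes (fresh division
  overlaps, crowded oocytes) cost extra force evaluations instead of
  instability. The direct `integrate_positions()` API instead aborts when
  a step would exceed half the smallest radius.
* **Compressed volume.** Radical-plane caps ignore cap-cap intersections;
  the approximation is validated against Monte Carlo integration on
  disjoint-cap configurations and errs conservative (reports less
  remaining volume) when caps overlap. The fraction is floored at 5% of
  rest volume.
* **Degenerate geometry.** Coincident sphere centres repel along a
  deterministic unit vector hashed from the id pair; cells projected
  exactly onto the path axis are displaced along a fixed perpendicular.
  Projection ties at the turn resolve to the smaller arclength.
* **Distance to the DTC** is always arclength along the path
  (`dtc_arclength - s`), never the 3D chord, so thresholds work around the
  turn.

## Metrics

Rows are arclength bins of one cell diameter from the DTC (row 0 abuts
it). The proliferative zone ends at the first row containing two or more
meiotic cells (committed cells count as meiotic from `NonProliferative`
onward); the mitotic index is the M-phase fraction within the zone. The
internuclear distance index divides the micron distance to the boundary by
a row count obtained by clustering the zone cells' sorted distances at
gaps above the mean gap. That count is invariant under a uniform axial
compression while the micron distance scales with it, which makes the
index a direct compression readout.

## What the simulation does and does not reproduce

Runs with the default preset reproduce, qualitatively and at realistic
scale: 16 founders expanding to several hundred cells; first meiotic entry
in mid-L3 at exactly ≥ 70 µm; a proliferative zone of ~13 rows at the end
of larval development; a sperm cohort formed before 32.5 hph whose count
falls steadily once ovulation begins; oogenesis with apoptosis of a
fraction of oocyte-fated cells; a stable adult proliferative pool under
contact inhibition (and an unchecked increase without it); a shorter adult
gonad when stretching is disabled; and cell movement toward the DTC during
L3 that reverses in the adult.

Known limitations, documented deliberately:

* **Early-adult filling transient.** The tube radius ramps up during late
  L4 faster than cells fill the new volume, so for the first ~15-20 adult
  hours the distal arm densifies and the mean zone-cell velocity is still
  distalward; the reversal is measured once the zone has equilibrated
  (late adulthood). In vivo the radial growth is accompanied by cell
  growth not modelled here.
* **Distal mixing.** Cells that commit to meiosis just beyond 70 µm can be
  jostled back into the zone by divisions on their distal side and, with
  no directed flow to extract them, slowly accumulate there; the
  first-two-meiotic-row statistic therefore decays over long adult runs
  even while the proliferative pool itself is stable. The turn region is
  similarly crowded (a cluster rather than a single file of growing
  oocytes).
* Absolute cell-count trajectories during development depend on measured
  migration-rate and dimension schedules that are free configuration here;
  only their qualitative shape is reproduced.
* No aging effects, no second gonad arm, no mutant charts (though
  `germline_chart()` makes chart edits straightforward), no local
  narrowing of the tube at the tip or turn, and no molecular dynamics of
  the GLP-1 pathway beyond threshold logic.

## Problem sizes used by the test-suite

The test suite exercises full runs at the scale the model was built for:
one default development-plus-adult run to 70 hph (~600-750 cells), one
no-stretch comparison to 47 hph, and two no-feedback runs to 44 hph,
shared across test blocks; statistical checks use 1000 isolated cycling
cells, 10^5-draw distribution checks, and 10^6-point Monte Carlo volume
validation. These sizes keep every documented property measurable while a
complete check runs in minutes on one core.

## A worked example

```{r example, eval = FALSE}
library(germsim)

cfg <- preset("default", seed = 1)
sim <- run_simulation(cfg, until = 40)
print(sim)
census(sim)

mx <- compute_metrics(sim)
tail(mx[, c("time_hph", "total", "proliferative", "sperm", "oocyte",
            "prolif_zone_rows_CD", "mitotic_index")])

# every printed decision boundary, recovered from the chart by bisection
germline_thresholds()
```
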