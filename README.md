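# germsim

A 3D agent-based simulator of *Caenorhabditis elegans* germline development
and adult homeostasis, combining center-based cell mechanics with per-cell
hierarchical statecharts ("mechano-logical" modelling).

## The problem

The *C. elegans* hermaphrodite germ line is a standard system for studying
stem-cell niches: the distal tip cell (DTC) leads the growth of a U-shaped
gonad arm and signals nearby germ cells (via GLP-1/Notch) to keep
proliferating, while cells further away enter meiosis, choose a sperm or
oocyte fate, grow, die, or are ovulated. How these decision rules interact
with physical crowding inside the growing organ is hard to dissect at the
bench. `germsim` simulates the whole arm — from 16 founder cells at the end
of L2 through days of adulthood — so that hypotheses such as *mechanical
feedback on the cell cycle* (contact inhibition) and *gonadal stretching
during late L4* can be tested in silico, with full lineage tracking and
quantitative readouts.

## The model in brief

* Germ cells are overdamped soft spheres: overlapping cells repel with a
  linear spring `F = k * delta`, positions follow `dx/dt = F / drag`, and
  all cells stay inside a tube of radius `r(t)` around the path traced by
  the migrating DTC; a hollow core along the distal arm and turn represents
  the rachis. The DTC migrates at prescribed stage rates, pauses whenever it
  is more than one cell diameter ahead of the nearest germ cell, turns at a
  prescribed time, and in late L4 the turn is displaced outward, stretching
  the proximal arm to twice its length.
* Each cell runs a statechart with orthogonal regions for the GLP-1
  receptor (Bound < 35 µm from the DTC; Absent ≥ 70 µm; hysteretic in
  between), LAG-1, the GLD pathways, the cell cycle (G1/S/G2/M with
  normally distributed G1 and G2, `s = 0.1`, totals 3 h larval / 8 h
  adult; mitosis exit only in G1 with GLD active at ≥ 70 µm; a division
  event on every M entry), and sex determination (commitment at 200 µm
  from the DTC — sperm-fated strictly before 32.5 hours post-hatch;
  sperm-fated cells divide twice into four sperm; oocyte-fated cells grow
  to maturity at a 10 µm radius, with a per-hour apoptosis hazard while
  immature and unprotected). Adult cells compressed below 70% of their
  rest volume — computed by subtracting radical-plane spherical caps for
  each overlapping neighbour — pause the cycle in G2.
* Ovulation removes a mature oocyte at the proximal end together with one
  sperm; lineage labels are inherited at division for clonal analysis.

## Worked example

```r
library(germsim)

cfg <- preset("default", seed = 1)
sim <- run_simulation(cfg, until = 40)
print(sim)
#> germline simulation at 40.00 hph: 828 cells (85 proliferative,
#> 450 meiotic, 160 sperm, 133 oocyte); gonad 304.2 um

germline_thresholds()
#>         glp1_bound_um        glp1_absent_um       sex_decision_um
#>                35.002                69.999               200.002
#>        sperm_time_hph     g2_arrest_percent  apoptosis_protect_um
#>                32.500                69.984               249.998
#> meiotic_radius_cap_um      oocyte_mature_um
#>                 4.000                10.000
```

The run grows 16 founders into a ~300 µm gonad arm with a proliferative
zone held near the distal tip, a sperm cohort committed before 32.5 hph,
and oocytes maturing toward the proximal end. `germline_thresholds()`
probes a single cell's statechart by bisection and recovers every decision
boundary of the model: receptor binding at 35 µm, signal loss at 70 µm,
sex determination at 200 µm, the 32.5 hph sperm/oocyte deadline, cycle
arrest below 70% rest volume, apoptosis protection from 250 µm, and the
4 µm / 10 µm growth caps.

Other entry points: `compute_metrics()` (census, zone lengths in cell
diameters and µm, mitotic index, internuclear distance index per
snapshot), `label_cells_at()` + `clonality_summary()` +
`trajectory_export()` (lineage work), `preset()` for the named scenarios
(`no_stretch_fast_dtc`, `no_stretch_pausing`, `no_feedback_fixed_death`),
`write_run_outputs()` for CSV/VTK artefacts, and a thin CLI at
`inst/cli/germsim.R` (`run`, `metrics`, `presets` subcommands).

See `vignettes/germline-model.Rmd` for the full model description,
parameter rationale and known limitations.

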