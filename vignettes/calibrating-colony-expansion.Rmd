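---
title: "Calibrating a lattice model of cell colony expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating a lattice model of cell colony expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`colonycal` simulates and calibrates an exclusion-process model of a cell
colony spreading in a circular barrier assay. Cells are agents on a square
lattice with spacing $\Delta$ (default 18 µm, a typical cell-nucleus
diameter), at most one agent per site. A 24-well plate well of diameter
15.6 mm maps to an $867 \times 867$ lattice, and the assay's seeding
barrier to a disc of radius 3.25 mm (180 sites) at the lattice centre, in
which the initial cells are placed uniformly at random.

Each time step of duration $\tau$ applies a random sequential update:

1. **Motility sweep.** $N(t)$ agents are drawn uniformly *with
   replacement*. A drawn agent moves with probability
   $P_m (1 - q)^a$, where $a \in \{0, \dots, 4\}$ is its number of
   occupied von Neumann neighbours at the moment of selection and
   $q \in [0, 1]$ is the cell-to-cell adhesion strength. The target is one
   of the four neighbour sites with probability $1/4$; moves onto occupied
   or off-lattice sites abort silently.
2. **Proliferation sweep.** Another $N(t)$ draws; a drawn agent deposits a
   daughter with probability $P_p$ under the same target rule.

The macroscopic parameters are the cell diffusivity
$D = P_m \Delta^2 / (4\tau)$ (µm²/h), the adhesion strength $q$
(dimensionless), and the proliferation rate $\lambda = P_p / \tau$ (per
hour, doubling time $\log_e 2 / \lambda$). `lattice_params()` converts
$(D, q, \lambda)$ into per-step parameters, always choosing an integral
step count $b = T/\tau$: for $D \ge \Delta^2/4$ it pins $P_m = 1$ and
shrinks $\tau$, otherwise it keeps $\tau = 1$ h and lowers $P_m$.
Diffusivity grids in multiples of $\Delta^2/4 = 81$ µm²/h therefore give
exact integer step counts at $P_m = 1$.

Design choices where the update scheme was genuinely open:

* Both sweeps sample with replacement, so an agent may be selected several
  times per step while another is skipped.
* The proliferation sweep fixes its number of draws at $N(t)$ from the
  sweep's start, but daughters join the sampling pool immediately (plain
  list-append semantics). Over a 48 h run at realistic rates
  ($P_p \le 0.035$) the alternative — excluding newborns until the next
  step — differs by far less than replicate variability.
* Adhesion modulates motility only; proliferation is not reduced by
  $(1-q)^a$.
* The lattice boundary behaves as permanently occupied. Colonies seeded at
  3.25 mm cannot reach the 7.8 mm boundary within 48 h, so this is a
  well-defined convention rather than an observable effect. A `periodic`
  flag instead wraps the boundary, which is how the spatially uniform
  growth check below is run.
* Disc membership for seeding is boundary-inclusive on site centres. Our
  180-site disc contains 101,765 sites; counting conventions in the
  literature give values within ±0.05% of $\pi \cdot 180^2$, and the
  seeding occupancies for 20,000 and 30,000 cells (19.7% and 29.5%) are
  insensitive to the convention.

## The four observation statistics

All extractors take a point pattern (a tibble of centroid coordinates in
µm, origin at the colony centre) and are applied identically to
pseudo-experimental and simulated colonies — for calibration what matters
is that both sides of the comparison pass through the same pipeline.

* **Leading-edge radius** (`measure_radius()`): the pattern is rasterised
  at one pixel per lattice site, morphologically closed with a disc
  element of radius 54 µm ($3\Delta$), hole-filled, reduced to its largest
  connected component, and summarised as the equivalent radius
  $R = \sqrt{A/\pi}$ of the enclosed area $A$. The closing radius is a
  convention: it bridges gaps up to ${\sim}108$ µm, so the detected edge
  tracks the dense core and discards the diffuse halo of escaped single
  cells. Detected radii carry a small systematic bias from this choice
  (the freshly seeded 3.25 mm disc detects at ${\sim}3.22$ mm), which
  cancels in the normalised error because observation and simulation are
  detected identically.
* **Transect density profile** (`transect_density_profile()`): a strip
  through the centre, 98 sections of 160 µm by 260 µm, each count
  converted to a non-dimensional density by the carrying capacity
  $K = 1/\Delta^2$ (kept exactly as $1/324$ µm⁻²). Because 160 and 260 µm
  are not multiples of the 18 µm lattice, a full lattice reads back
  section densities of 0.93–1.05 rather than exactly 1; the bias is
  identical on both sides of any comparison. `average_half_profiles()`
  folds profiles about the centre and averages all replicate halves (three
  replicates give six half-profiles).
* **Isolated-cell percentage** (`isolated_fraction()`,
  `clustering_regions()`): a cell is isolated iff no other centroid lies
  within 18 µm, boundary-inclusive, so on-lattice isolation is exactly
  "no von Neumann neighbour" while diagonal neighbours
  ($18\sqrt{2}$ µm) remain isolated. The colony-level statistic averages
  six 500 µm × 2000 µm regions tiled 3-across × 2-down about the centre.
  Any fixed central layout is equivalent for the statistically uniform
  core; the tests confirm the statistic falls monotonically with $q$.
* **Subregion density** (`subregion_density()`): counts in four
  230 µm × 230 µm boxes centred at $(\pm 500, \pm 500)$ µm, non-
  dimensionalised by $K$. These feed the logistic growth fit.

## Calibration

All four comparisons use one normalised least-squares form,
$\mathrm{Error} = \sum_i (E_i - S_i)^2 / \sum_i E_i^2$, evaluated at the
two post-seeding observation times (24 h and 48 h), never at $t = 0$.
`sweep_error_surface()` evaluates the chosen statistic over a $(D, q)$
grid with proliferation suppressed ($\lambda = 0$, the
proliferation-inhibited arm of the assay), averaging 3 simulated
replicates per cell for radii, 5 for profiles and 20 for clustering.
Profiles are compared over the full 98 sections at both times (the folded
half-profiles are for display).

The estimation logic reflects which data types are informative:

* The leading-edge and profile surfaces have a wide shallow valley — many
  $(D, q)$ combinations match the observed expansion to within the
  one-pixel detection resolution, so neither statistic identifies the
  pair. The package's tests demonstrate this on synthetic data by counting
  grid cells whose error falls below $(18\,\mu m / 3.3\,\mathrm{mm})^2$,
  a threshold grounded in the detector's resolution rather than in the
  sampled surface minimum: with replicate variability coming from the
  model alone, simulated radii are reproducible to a few µm, the error
  floor is ${\sim}10^{-6}$, and the surface minimum is an extreme order
  statistic — multiples of it select almost nothing even on a plainly
  flat valley.
* The clustering surface varies strongly along $q$ and weakly along $D$.
  `estimate_q()` marginalises over $D$ and returns the $q$ whose marginal
  error is within a tolerance factor (default 2) of the minimum, plus a
  variance-ratio diagnostic quantifying the $q$-versus-$D$ sensitivity.
* Given $q$, `conditional_D_range()` reads the admissible $D$ span off
  the leading-edge surface row, treating errors below a resolution floor
  as ties with the row minimum (`calibrate_colony()` supplies the
  one-pixel floor automatically). `calibrate_colony()` chains the two
  stages.
* The proliferation rate comes from the non-suppressed arm:
  `fit_proliferation_rate()` fixes $c(0)$ at the observed $t = 0$ mean
  density and minimises the normalised error of the logistic solution
  $c(t) = c(0) e^{\lambda t} / (1 + c(0)(e^{\lambda t} - 1))$ on a
  $10^{-4}$ h⁻¹ grid refined by golden-section search. The reported
  uncertainty range is the set of rates within twice the minimum error —
  a declared convention for a one-dimensional error curve, not a
  confidence interval with frequentist coverage.

`predict_expansion()` closes the loop: it forward-simulates fitted
parameters (3 replicates for radii, 5 for profiles) and reports the
normalised errors against held observations.

## The synthetic-data generator

`generate_observation_set()` plays the role of the experimental campaign:
it simulates replicate assays at known true parameters and applies the
extractors above, so recovery of the truth exercises the whole pipeline
end to end. Default geometry is the real assay's (20,000 or 30,000 cells,
3.25 mm disc, observations at 0, 24, 48 h, three replicates).

What it emulates: the replicate structure, lattice-scale crowding, the
adhesion-driven decline in isolated cells, and logistic density growth in
the colony core. What it does not: measurement noise in cell detection
and edge tracing, optical artefacts, biological heterogeneity between
wells, or sub-cellular adhesion mechanics. Passing recovery tests
therefore shows the estimation machinery is self-consistent under the
model's own stochasticity — typically much smaller than experimental
noise — and says nothing about model misspecification on real images.
`generate_logistic_counts()` adds optional multiplicative noise
(`noise_cv`) for stress-testing the rate fit; it is off by default
everywhere else.

## Problem sizes and runtime

The simulation core is written in C++ (driven by R's RNG, so `set.seed()`
governs every result). Full-geometry runs cost well under a second each,
which keeps the test-suite sweeps — a $10 \times 6$ leading-edge grid at
3 replicates and a $4 \times 6$ clustering grid at 20 replicates —
in the minutes range. Behavioural tests that need many realisations
(adhesion monotonicity) run on a scaled-down arena: a 220-site lattice
with a 1.44 mm disc seeded at the same ${\sim}20\%$ occupancy. Free-space
diffusion is checked against $\mathrm{MSD} = 4Dt$ over $10^4$ independent
walks, and the proliferation mechanism against the logistic mean-field
limit on a periodic $100 \times 100$ lattice at high motility (the
mean-field approximation needs fast mixing relative to division; at
$P_m/P_p \approx 286$ agreement is within 0.03 absolute density).

## Known limitations

* The edge-detection recipe (closing radius, hole fill, largest
  component) is a convention; detected radii for strongly adhesive,
  highly motile colonies are sensitive to how aggressively the diffuse
  halo is linked to the core, and other recipes shift 48 h radii by a few
  percent. Calibration is insensitive because both sides share the
  recipe, but absolute radii should be read with that caveat.
* Section binning (160 µm and 260 µm on an 18 µm lattice) carries a few
  percent of discretisation bias, identical on both comparison sides.
* The model is strictly two-dimensional, with no cell death, chemotaxis,
  or off-lattice motion; agents are monodisperse and the lattice is
  regular.
* The $\lambda$ uncertainty range and the surface tolerance factor are
  reading conventions, not calibrated coverage statements.
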