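---
title: "Modelling clonal pattern formation during bacterial surface colonization under flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling clonal pattern formation during bacterial surface colonization under flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmCA)
```

## The model

`biofilmCA` simulates two neutrally labelled bacterial strains (blue and
red) colonizing the floor of a laminar-flow channel. Space is a square
lattice of lateral length `L` sites (default 60; one site is 1 um across,
the footprint of a single cell, so the default lattice represents one
60 um x 60 um microscope field of view). Each site is empty or holds one
cell. Both lattice axes are periodic: a cell swept past the downstream
edge re-enters upstream, standing in for exchange between adjacent fields
of view and removing the anisotropy a directional flow would otherwise
imprint on the boundaries.

The two strains differ in nothing but their colour label. Their shared
traits are:

* **adhesiveness** `sigma` in [0, 1] — resistance to being displaced by
  neighbours or stripped by flow. `sigma = 1` mimics a constitutive
  extracellular-matrix producer, `sigma = 0` a non-producer;
* **founder density** `rho0` — the fraction of sites occupied at time
  zero. Founders are placed uniformly at random, each independently blue
  or red with probability 1/2 (a 1:1 mixture on average).

The environment contributes the **flow intensity** `f` in [0, 1], a
non-dimensional stand-in for the laminar shear: it scales both the
detachment pressure on exposed cells and the maximum distance `f * L` a
detached cell is carried downstream before it can re-attach.

Each discrete time step performs two stochastic sub-steps on
independently chosen occupied cells, birth first:

1. **Birth and shoving.** With probability `p_b` a random cell divides.
   The newborn takes a uniformly chosen empty site in the parent's Moore
   neighbourhood (the 8 surrounding sites, periodic wrap). If the
   neighbourhood is full the newborn challenges one uniformly chosen
   resident neighbour: with probability `p_s = (1 - sigma)/2` the
   resident is displaced and the newborn takes its site, otherwise the
   newborn is the loser. Either way the losing cell moves to a uniformly
   chosen empty site around the resident's original position, or — if
   that neighbourhood is also full — is removed with the outflow. A shove
   is never propagated further: crowding is relieved by releasing one
   cell into the passing flow rather than by a displacement cascade.
2. **Detachment and relocation.** A random cell is tested against the
   flow. A cell whose directly upstream neighbour site is occupied is
   drafting-protected and never detaches. An exposed cell detaches with
   probability `p_d = f * (1 - sigma)`; it is carried `dx` sites
   downstream, `dx` uniform on `{0, ..., floor(f L)}`, and `dy` sites
   across, `dy` uniform on `{-dx, ..., dx}`, landing with periodic wrap.
   The origin is vacated before landing, so the degenerate `dx = dy = 0`
   draw re-attaches the cell in place. An occupied landing site means the
   cell is lost with the outflow.

A run stops once 95% of sites are occupied (`occupancy_threshold`): near
full coverage almost every birth only triggers shoves that no longer
change the large-scale pattern, and the experimental runs the model
mirrors were likewise stopped at near-complete coverage by eye.

```{r single-run}
cfg <- simulation_config(L = 60, sigma = 1, rho0 = 0.01, f = 1, seed = 42)
run <- run_to_confluence(cfg)
run
```

### Parameter choices

* `p_b` (default 1): the per-step birth-attempt probability. Because one
  detachment test accompanies every step regardless, `p_b` sets the
  relative frequency of detachment tests to birth attempts, and final
  patterns do depend on that ratio: lowering `p_b` raises the number of
  detachment events per birth and strengthens flow-driven effects such
  as the weak-flow adhesion payoff. The default of one guaranteed birth
  attempt per step is the fastest choice and is the package's fixed
  reference condition; the dependence is exposed through the
  configuration for sensitivity analysis.
* `max_steps` (default 1e7): a safety bound; at `L = 60` every
  configuration we have run terminates within a few times 1e4 steps.
* Founder count is `round(rho0 * L^2)` (half-up): a density prescribes
  only an expectation, and a deterministic count keeps ensembles at a
  fixed density strictly comparable.
* The relocation bound `f * L` is floored when fractional and the draw
  includes both endpoints.
* **Extinction**: at `sigma = 0` under strong flow a sparse population
  can be completely swept away. Such runs are flagged `EXTINCT`,
  excluded from correlation-length ensembles, and counted.

## Quantifying lineage segregation

The final pattern is summarised by the radially averaged two-point
autocorrelation of the colour field,

$$C(r) = \frac{\langle c(R)\,c(R+r)\rangle - \langle c(R)\rangle\langle
c(R+r)\rangle}{\langle c^2(R)\rangle - \langle c(R)\rangle^2},$$

with `c` equal to 1 or 2 on occupied sites. Empty sites are excluded from
every average — patterns are analysed at 95% or more coverage, where the
distinction between excluding and imputing them is negligible, and
exclusion is the only convention under which `c` keeps a clean meaning.
Pairs of occupied sites are averaged in unit-width annuli
`[k - 0.5, k + 0.5)` of Euclidean pair distance. The `r = 0` bin holds
only self-pairs, so `C(0) = 1` exactly; per-bin covariances are
normalised by the global colour variance. The **clonal correlation
length** `xi` is the first zero of `C(r)`, located by linear
interpolation between the bracketing bins; it tracks the typical clonal
cluster size in the field of view.

```{r xi}
profile <- autocorrelation(run$lattice)
correlation_length(profile)
```

Numerical conventions worth stating:

* `r_max` defaults to `L/2`; bins beyond that are dominated by a handful
  of long-distance pairs. A profile that never crosses zero within
  `r_max` is **censored** at `xi = r_max` (this includes monoclonal
  patterns, whose correlation never decays); censored values are counted
  but excluded from ensemble moments.
* Boundary mode for the *analysis* defaults to `bounded` (pairs confined
  to the frame) even though the *dynamics* are periodic: an experimental
  field of view is a bounded window, and the same convention is applied
  to simulated patterns for comparability. Periodic minimal-image
  distances are available via the pattern's `boundary` attribute.
* With the global-variance normalisation the per-bin values can in
  principle exceed 1 marginally in strongly colour-unbalanced patterns;
  on balanced patterns and all fixtures used here they stay in [-1, 1].
* A fast C++ pair-enumeration path is used everywhere; an independent
  plain-R brute-force implementation (`autocorrelation_reference()`) is
  kept as the test oracle, and the suite asserts bin-wise agreement to
  1e-12.

### What the fixtures calibrate

`generate_reference_pattern()` provides patterns with known correlation
structure: checkerboards (in periodic mode the 4 axial opposite-colour
and 4 diagonal same-colour neighbour pairs cancel exactly, so
`C(1) = 0`), stripes, blocks, random fields and Voronoi tessellations of
random founders (the ideal each-founder-claims-its-territory limit). Two
calibration facts matter when reading `xi` values:

* For an alternating stripe pattern of width `w` the radially averaged
  correlation is `1 - 4r/(pi w)` at short range, so the first zero sits
  at `(pi/4) w ~ 0.785 w`, not at `w`: radial averaging mixes the
  along-stripe direction into every annulus. `xi` is proportional to the
  imposed length scale but carries this geometric factor; the suite
  freezes the brute-force values (1.45, 3.23, 3.95, 8.36 for
  `w = 2, 4, 5, 10` on a 60 x 60 lattice).
* For a fully random 1:1 pattern every bin beyond 0 fluctuates around
  zero, so the first crossing has a geometric-like tail: the median over
  seeds is ~1.1, but individual realizations occasionally exceed 2.
  Calibration statements about random fields are therefore made about
  the median.

## Ensembles, sweeps and distributions

`run_ensemble()` repeats `run_to_confluence()` with per-replicate seeds
derived deterministically from a base seed, measures `xi` per replicate,
and flags censored/extinct runs. `ensemble_summary()` reports mean,
sample standard deviation, median and adjusted Fisher-Pearson skewness
(the convention under which |skewness| between 0.5 and 1 is moderate and
above 1 strong). `run_sweep()` fills an (f, rho0, sigma) grid and, where
both `sigma` endpoints are present, reports the adhesion payoff
`delta_xi = mean xi(sigma = 1) - mean xi(sigma = 0)`;
`variability_surface()` adds percentile-bootstrap intervals around
`sd(xi)`.

```{r ensemble}
xis <- run_ensemble(simulation_config(sigma = 1, rho0 = 0.01, f = 1),
                    n_reps = 20, base_seed = 1)
ensemble_summary(xis)
```

Correlation-length distributions are compared with an adaptive kernel
density estimate (`adaptive_kde()`): a Gaussian KDE whose bandwidth
varies across the data (Abramson's square-root law), chosen because xi
distributions are asymmetric with a fat tail on one side. A pilot
fixed-bandwidth estimate with Silverman's bandwidth `h0` is evaluated at
the sample points; local bandwidths are
`h_i = h0 * (f_pilot(x_i)/g)^(-1/2)` with `g` the geometric mean of the
pilot values, and mass below zero is folded back by reflection since
`xi > 0`. The default evaluation grid extends five of the widest local
bandwidths past the largest sample so the estimate integrates to 1
within 1e-3. `compare_distributions()` runs the KDE per density group
and reports pairwise overlap coefficients (integral of the pointwise
minimum).

## Model behaviour at desk scale

The reference ensembles behind the package's qualitative claims use
`L = 60` with 200 replicates for trend statements and 500 for sign
statements, with bootstrap intervals reported so users can judge (and
scale up) the Monte-Carlo error; the original study conditions used
ensembles of 5e4 to 2e6 realizations, which only narrows the intervals.
At these sizes the simulations reproduce:

* **Density dependence under strong flow** (`f = 1`): for adhesive
  strains (`sigma = 1`) the mean `xi` falls monotonically as `rho0`
  grows through 1e-3 ... 1e-1 — sparser founders claim larger
  territories. For non-adhesive strains (`sigma = 0`), over the density
  range in which such populations are viable (1e-2 ... 1e-1; under
  strong flow sparse non-adhesive populations are mostly washed out),
  the relative range of mean `xi` is less than half that of the adhesive
  curve: continual detachment and relocation decouples the final pattern
  from the initial condition.
* **The sign structure of the adhesion payoff**: `delta_xi > 0` at
  (`f = 1`, `rho0 = 1e-3`) — under strong flow and sparse colonization,
  investing in adhesion yields larger clonal domains, a payoff of ~+9
  sites that 500 replicates resolve decisively — and `delta_xi < 0` at
  (`f = 0.125`, `rho0 = 1e-1`): under weak flow, relocations are
  short-ranged and act as local dispersal that relieves crowding inside
  clusters of non-adhesive cells, while dense adhesive populations
  freeze the well-mixed initial pattern in place. The "high density"
  anchor is 1e-1 cells/um^2, the top of the colonization density range
  the model is calibrated for; far above it (e.g. `rho0 = 0.8`) the run
  is essentially over at initialization and the payoff collapses to
  zero. At this package's reference conditions the weak-flow reversal
  is consistently negative in its point estimate but small relative to
  the per-run spread of `xi`, so a 500-replicate bootstrap interval can
  straddle zero; resolving its sign at 95% confidence takes ensembles
  one to two orders of magnitude larger (routine at the original
  study's scale, where tens of thousands of realizations were
  averaged). The magnitude also grows as `p_b` decreases (see above),
  i.e. as detachment turnover per birth rises.
* The one-sided Spearman test is used for the monotone trend (5 density
  anchors give an exact one-sided p of 1/120 under a perfect ordering).

Two caveats on what these desk-scale checks do and do not show. The
generator emulates the study conditions (square field, 1:1 random
founder mixture, neutral labels, one cell per site); it does not emulate
features of real micrographs such as irregular cell footprints,
segmentation noise, uneven illumination or cross-tile cell exchange, so
passing tests validate the model implementation and analysis chain, not
agreement with any particular experimental data set. And with 200-500
replicates the Monte-Carlo error on mean `xi` is a few percent of its
value; all assertions are made with margins (Spearman p-values,
bootstrap CIs) that account for it.

## Known limitations

* The automaton is strictly 2D and single-layer: no 3D biofilm growth,
  nutrient fields, cell death or active motility.
* The flow enters only through the scalar `f`; no hydrodynamics is
  computed, and the drafting rule is a one-site upstream shadow.
* Image ingestion (`pattern_from_image()`) is deliberately minimal —
  per-channel thresholds and an argmax — and is not a cell segmenter.
* At extreme colour imbalance the global-variance normalisation of
  `C(r)` can nominally leave [-1, 1]; correlation lengths remain
  well-defined (the first-zero estimator only needs the sign).
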