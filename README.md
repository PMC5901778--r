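# biofilmCA

Who ends up next to whom when bacteria colonize a surface under flow?
When two neutrally labelled strains seed the floor of a laminar-flow
channel and grow to confluence, the final mosaic of clonal patches is set
by three things: how densely the surface was seeded, how strongly cells
adhere (e.g. through constitutive extracellular-matrix production), and
how hard the flow works to strip exposed cells and carry them downstream.
`biofilmCA` implements a probabilistic cellular automaton of this process
together with the spatial statistics used to quantify the resulting
lineage segregation. It is aimed at microbial ecologists and biofilm
modellers who want to regenerate and extend the model's predictions, or
to run the same pattern analysis on their own two-colour data.

## The model in brief

Two strains (colour labels only) compete for sites of an `L x L` periodic
lattice (default `L = 60`, one site = one cell = 1 um). Per time step, on
independently chosen occupied cells:

* **Birth.** With probability `p_b` a random cell divides into a random
  empty Moore-neighbourhood site. If the neighbourhood is full, one shove
  against a random resident neighbour is resolved: the resident is
  displaced with probability

  `p_s = (1 - sigma) / 2`

  (`sigma` = adhesiveness in [0, 1]); the losing cell moves next to the
  resident's site or, if that neighbourhood is also full, is removed with
  the outflow. Shoves never cascade.
* **Detachment.** A random cell with an *empty* upstream neighbour (cells
  behind an occupied site are drafting-protected) detaches with
  probability

  `p_d = f (1 - sigma)`

  and is relocated `dx ~ U{0, ..., floor(f L)}` sites downstream and
  `dy ~ U{-dx, ..., dx}` across, with periodic wrap; an occupied landing
  site means loss with the outflow.

Runs stop at 95% coverage. The final pattern is summarised by the
radially averaged two-point autocorrelation of the colour field `c`
(1 or 2 on occupied sites, empty sites excluded),

`C(r) = [<c(R) c(R+r)> - <c(R)><c(R+r)>] / [<c^2(R)> - <c(R)>^2]`,

binned in unit annuli of pair distance, and by the **clonal correlation
length** `xi`: the first zero of `C(r)` (linear interpolation; censored
at `r_max` when there is no crossing). `xi` tracks the typical clonal
cluster size.

## Worked example

```r
library(biofilmCA)

cfg <- simulation_config(L = 60, sigma = 1, rho0 = 0.01, f = 1, seed = 42)
run <- run_to_confluence(cfg)
run
#> colonization_run: THRESHOLD after 11092 steps | occupancy 0.950 |
#>   births 3384, shove removals 7708, detachments 0, relocation removals 0

correlation_length(autocorrelation(run$lattice))
#> correlation length xi = 15.860

xis <- run_ensemble(simulation_config(sigma = 1, rho0 = 0.03, f = 1),
                    n_reps = 30, base_seed = 1)
ensemble_summary(xis)
#> ensemble: n=30 mean=10.674 sd=4.166 median=9.365 skewness=2.183 | censored 0, extinct 0
```

A fully adhesive (`sigma = 1`) population seeded at 1% density under
strong flow (`f = 1`) records no detachments (adhesive cells cannot be
stripped) and freezes 36 founder territories into clonal domains with
`xi ~ 15` um; denser seeding shrinks the domains (`xi ~ 11` um at 3%).
The shove-removal count shows how crowding is relieved near confluence.

Sweeps difference the two adhesion strategies across conditions:

```r
sw <- run_sweep(f_values = c(0.125, 1), rho0_values = c(1e-3, 1e-1),
                sigma_values = c(0, 1), n_reps = 200, base_seed = 1)
sw$delta_xi   # mean xi(sigma=1) - mean xi(sigma=0) per (f, rho0)
```

`delta_xi > 0` under strong flow and sparse seeding (adhesion pays off in
larger clonal clusters), `delta_xi < 0` under weak flow at high density
(short-range relocations let non-adhesive strains coarsen instead).

A thin command-line front end over the same functions ships in
`inst/cli/biofilmca.R` (subcommands `simulate`, `ensemble`, `sweep`,
`analyze`, `kde`). Patterns serialize as headerless CSV integer grids
(0 empty / 1 blue / 2 red, rows = transverse coordinate) with a JSON
metadata sidecar; `load_pattern()`/`save_pattern()` round-trip them
bit-exactly.

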