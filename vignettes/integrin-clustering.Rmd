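---
title: "Modelling integrin clustering on nanoporous gold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling integrin clustering on nanoporous gold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Nanoporous gold (NPG) is a sponge-like pure-gold material made by dealloying
a gold-silver alloy. Cells adhere to it noticeably worse than to flat gold,
and the effect strengthens as the pores get smaller — the opposite of what
most nanotopographies do. `npgclust` implements a computational model of the
receptor-scale mechanism: integrins diffusing in the cell membrane must
activate, bind extracellular-matrix (ECM) ligands, and associate laterally
into clusters before a focal adhesion (FA) can assemble, and the pore size
of the substrate modulates the binding and association energetics of those
reactions.

## The reaction ladder

Each integrin occupies one rung of a four-state ladder,

INACTIVE ⇌ ACTIVE ⇌ BOUND ⇌ ASSOCIATED,

with three reversible reactions whose equilibrium constants are set by
energies in units of kT:

* **Activation** (inside-out signalling): `k_a+ / k_a- = exp(-E_a)` with
  `E_a = 3 kT`. The substrate plays no role here, so `E_a` is constant.
* **Binding** to an ECM ligand: `k_b+ / k_b- = exp(+E_b)` with
  `E_b = alpha * c * B / r_p + A * c`, where `r_p` is the pore size in nm,
  `c` the local gold concentration, `A = 3.5`, `B = -12 kT nm`, and `alpha`
  scales how strongly the substrate couples into binding. Because `B < 0`,
  small pores *reduce* the binding energy.
* **Association** of a bound integrin with a bound or associated
  4-neighbour: `k_c+ / k_c- = exp(+E_c)` with
  `E_c = beta * c * r_p / r_max + C`, `C = 5.2 kT`, `r_max = 150 nm`.
  Alternatively `E_c` can be pinned at `6.2 kT` (the value the pore-size
  model takes at `r_p = r_max`), the reading in which the substrate affects
  only binding.

Forward rates are `k_a+ = k_b+ = 10 /s` and `k_c+ = 1 /s`; reverse rates
follow from the ratios above. Flat gold is represented by the sentinel
`r_p = Inf`: the pore term of `E_b` vanishes (leaving `A * c`) and `E_c`
takes its `r_max` value, so flat gold and the largest modelled pore size are
nearly equivalent — by construction for association, and within 0.08 kT for
binding. Both energies stay inside the admissible 0-10 kT band for all
`r_p` in [20, 150], `c` in [0, 1] and the scenario intensities.

```{r}
library(npgclust)
binding_energy(20, 1)       # 2.90 kT
association_energy(75, 1)   # 5.70 kT
scenario_params("strong_coupling") # alpha = 2.5, beta = 2
```

The four scenario presets are `baseline` (alpha = beta = 1),
`constant_association` (E_c fixed at 6.2 kT), `weak_coupling`
(alpha = beta = 0.5) and `strong_coupling` (alpha = 2.5, beta = 2).

## The Monte Carlo engine

The membrane is a 6 x 6 µm patch divided into 100 x 100 sites (60 nm
spacing) with periodic boundaries; each site carries exactly one ECM ligand
and holds at most one integrin. 1000 integrins start INACTIVE at random
distinct sites. Time advances in fixed steps of `dt = 10 ms`. Within each
step every integrin is visited once, in a freshly shuffled order.

**Within-step kinetics.** A visited integrin propagates its reaction ladder
through the full 10 ms by first-reaction sampling: draw an exponential
waiting time at the total rate of its currently eligible channels, fire a
channel proportionally to its rate, and repeat until the step budget is
exhausted. This is the exact solution of the competing-Poisson-channel
problem at any `dt`. The distinction matters here: the inactivation rate is
`k_a- = 10 e^3 ≈ 201 /s`, so `k dt ≈ 2` and schemes that allow at most one
event per step (with probability either `k dt` or `1 - exp(-k dt)`)
distort the stationary occupancies by a factor large enough to shift the
apparent activation energy by ~0.8 kT. With exact within-step kinetics the
time-averaged active fraction of an activation-only run recovers
`1 / (1 + e^3)` and the logit of that fraction recovers `E_a = 3 kT`; the
test suite checks both, and a 2 x 2-lattice configuration chain is checked
against an exactly enumerated Markov-chain stationary distribution.
`step_probability()` (`p = 1 - exp(-k dt)`) remains the correct
single-event probability and is exported for rate-to-probability reasoning.

**Diffusion.** An integrin that fired no reaction during its step and is
not associated attempts one hop to a uniformly chosen 4-neighbour; the hop
is rejected if the target site is occupied (single occupancy is what makes
adjacency-based association meaningful). Bound-but-unassociated integrins
carry their bound state with them — ligands are uniform, one per site, so a
ligand is always available at the destination. Associated integrins are
immobilised. The hop attempt probability is configurable (`hop_prob`,
default 1 per step); no diffusion coefficient is stated for the membrane,
so one attempt per step defines the model's time-length coupling.

**Association moves.** A BOUND integrin with at least one BOUND or
ASSOCIATED 4-neighbour may fire the association channel. If none of its
neighbours is yet associated, one uniformly chosen bound neighbour is
recruited along with it, so clusters nucleate pairwise; otherwise it joins
the adjacent cluster. Disassociation (ASSOCIATED -> BOUND) fires at
`k_c- = k_c+ exp(-E_c)` independently of neighbour count. After every step
an orphan-cleanup pass demotes any associated integrin left without an
associated 4-neighbour (iterated to its unique fixpoint), which keeps the
associated set equal to a union of lattice-connected clusters of size >= 2.

**Equilibration and measurement.** A run stops when the least-squares slope
of the associated count over a trailing window (default 5000 steps) falls
below a relative tolerance of 1e-3 per 1000 steps, or is flagged
non-equilibrated at `max_steps` (default 2e5). The associated *count*
plateaus within ~1e4 steps, but the cluster-*size* distribution relaxes on
the disassociation timescale `1/k_c-` (5e4-5e5 steps at these energies), so
`sim_config(min_steps = ...)` can impose a floor before the detector may
stop the run; the sweep studies use a 2e5-step floor. Because the
top-decile FA area is a heavy-tailed statistic of the few largest clusters,
a single end-state snapshot is noisy; `measure_clusters()` therefore
time-averages ~20 snapshots taken 5000 steps apart along the equilibrated
trajectory, the standard Monte Carlo estimator.

## Cluster statistics

Clusters are connected components of associated integrins under 4-neighbour
adjacency on the periodic lattice — the same neighbourhood the engine uses.
The FA "area" of a cluster is its integrin count. The headline statistic
averages the areas of the top `ceiling(0.10 * n_clusters)` clusters (stable
order under ties), so any non-empty cluster set contributes at least one
cluster. `sweep_scenarios()` runs the scenario x pore-size grid
(20, 50, 75, 100, 150 nm and flat gold) with replicate seeds
`base_seed + replicate - 1` and returns a tidy per-run table;
`summarize_sweep()` aggregates means and standard errors and
`autoplot()` draws the bar charts.

```{r}
sweep <- sweep_scenarios(
  scenarios = c("baseline", "strong_coupling"),
  pore_sizes_nm = c(20, 150), n_replicates = 10,
  config_args = list(n_integrins = 360, n_rows = 60, n_cols = 60,
                     max_steps = 2e5, min_steps = 2e5))
summarize_sweep(sweep)
autoplot(sweep, metric = "n_clustered")
```

With the default energetics the model reproduces the qualitative substrate
effects: fewer clustered integrins and smaller top-decile FAs at 20 nm than
at 150 nm under `baseline`; flat gold statistically indistinguishable from
150 nm; and a stronger pore-size effect under `strong_coupling` than under
`weak_coupling`. The test suite asserts exactly these comparisons (at the
scaled-down sizes below) rather than any absolute cluster counts, which are
not published quantities.

## The substrate generator

`generate_npg_field()` is the synthetic stand-in for dealloyed NPG
surfaces. It evolves a conserved two-phase field by the Cahn-Hilliard
equation — the canonical model of spinodal decomposition, which produces
the bicontinuous ligament-and-pore morphology characteristic of dealloyed
metals — using a semi-implicit Fourier-spectral scheme (double-well bulk
energy `c^2 (1-c)^2`, implicit biharmonic term, unconditionally stable in
practice at `dt_ch = 0.5`). Evolution conserves the mean composition to
1e-6 and dissipates the discrete Ginzburg-Landau free energy.

No physical coefficients are stated for the substrate model, so the
physical scale is attached by calibration: the field coarsens until its
characteristic length — half the wavelength `2*pi/k1` of the first moment
`k1` of the radially averaged structure factor — reaches a resolution floor
(8 px by default), is binarised at 0.5 (the symmetric double-well
midpoint) and lightly smoothed, and the pixel size is then fixed so the
measured length equals the requested pore size exactly. Larger pore sizes
(50-150 nm) reuse the calibrated 20 nm parent via `rescale_field()`, which
multiplies the pixel size and touches no pixel values — exactly a magnified
print of the same morphology, mirroring how the larger-pore substrates were
defined as enlargements of the 20 nm model.

The mean composition defaults to 0.5: dealloying removes nearly all silver,
and the observed pore and ligament widths of real NPG track each other
almost 1:1, which a symmetric bicontinuous field reproduces. The 3:7
gold:silver ratio of the pre-dealloying alloy describes the alloy
chemistry, not the post-dealloying solid fraction, so it is *not* used as
the composition; it remains configurable for exploration.

**Gold-concentration modes.** Whether `c` in the energy model is a scalar
substrate property or a spatial field is genuinely open. The package
implements both. `c_mode = "uniform"` (the default for sweeps) sets `c = 1`
everywhere — dealloyed NPG is pure gold, and this reading makes the stated
flat-gold/150 nm equivalence hold. `c_mode = "field"` samples each 60 nm
lattice site as the mean of the substrate-field pixels it covers
(`map_substrate_to_lattice()`; the generated fields are periodic and are
tiled across the 6 µm membrane), so integrins over pores see `c ≈ 0` and
lose both binding and association support there.

What the generator does *not* emulate: three-dimensional pore connectivity,
dealloying kinetics and surface chemistry (including the surface
hyperpolarisation hypothesised to act on cells), SEM imaging noise, and the
skew of real pore-size distributions. Passing tests on these fields
therefore validate the model logic on idealised bicontinuous morphologies,
not agreement with any particular micrograph.

## Morphometry

`granulometry_size()` measures the local width of a binary phase as the
inscribed-disk diameter at the regional maxima of the Euclidean distance
transform (adjacent maxima merged, edge-crossing disks excluded — the usual
exclude-edge-particles convention), matching common ImageJ local-thickness
practice; per-feature sizes are reported with mean ± s.e.m.
(sd / sqrt(n)). Pore and ligament are dual phases: `invert_phase()` swaps
them. On the binarised calibrated fields this width agrees with the
spectral characteristic length to within 25% — the two metrics differ by
definition (local width vs dominant wavelength), so exact agreement is not
expected.

Cell-shape circularity is `4*pi*A/L^2` on exact area and perimeter, which
keeps the closed forms exact (circle 1, square pi/4, machine precision);
pixel-mask estimation (`mask_circularity()`) is provided separately and
documented as approximate, since edge-count perimeters of smooth shapes are
biased. `fit_pore_ligament()` is an ordinary least-squares fit of ligament
width on pore width; on the five packaged reference means
(`npg_size_table()`) it gives R² ≈ 0.9957. The reference characterisation
reports R² = 0.9973 on the underlying raw measurements (N > 50 per
substrate), which are not published; the fit on the five means is not
forced to match it.

## Problem sizes and numerical choices

* Trend studies in the test suite run at 60 x 60 sites with 360 integrins
  (the same 10% occupancy as the full 100 x 100 / 1000 system), a 2e5-step
  equilibration floor and a 1e5-step measurement phase with 20 snapshots;
  closed-form calibration checks run activation-only or binding-only
  systems for 2e5 steps. The full-size defaults remain on `sim_config()`.
* Substrate tests use 64-128 px fields; the generator default is 256 px
  (~32 characteristic lengths across the box at the 8 px floor).
* All randomness flows through R's RNG: a `sim_config(seed = )` makes
  placement, trajectory and measurement bit-identical.
* Ties in the top-decile selection are broken by stable sort; the ceiling
  rule guarantees a non-empty selection whenever clusters exist.
* Degenerate inputs fail loudly: uniform fields have no characteristic
  length, single-phase images cannot be sized, n < 3 or zero-variance
  regressions are errors, and over-capacity placements are rejected.

## Limitations

* No force-dependent (catch/slip-bond) kinetics and no explicit adaptor
  proteins (talin, vinculin): the model addresses the substrate's effect on
  clustering energetics only.
* Association stability is independent of neighbour count (the equilibrium
  ratio fixes only `k_c+ / k_c-`), so there is no line-tension-driven
  Ostwald ripening; late-stage coarsening proceeds mainly through the
  extinction and re-accretion of small clusters and is slow at these
  energies. Cluster-size comparisons are therefore made at matched, stated
  horizons with time-averaged estimators.
* The true stationary state at these energies has nearly all integrins
  associated on every substrate; the biologically relevant differences are
  quasi-steady-state properties on the 1e5-1e6 step scale, which is what
  the sweeps sample.
* `c_mode = "field"` couples substrate geometry to the lattice at 60 nm
  resolution; sub-site gold structure is averaged out.
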