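---
title: "A hybrid multiscale model of tumour invasion and metastasis"
author: "metastasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid multiscale model of tumour invasion and metastasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metastasim)
```

## The model

`metastasim` simulates carcinoma invasion as a genuinely hybrid system: the
collectively behaving cell populations are continuum density fields, while
the invasive, individually migrating cells are discrete stochastic agents,
and mass moves between the two representations through exactly conservative
operators.

**Density phase.** Five scalar fields live on a uniform cell-centred grid
over a cuboid tissue domain (default $[-0.05, 0.05]^3$ cm):

* $c^E$ — epithelial-like cancer cells (ECCs). They spread by *degenerate
  porous-medium diffusion*, $\nabla\!\cdot\!(D_E\, c^E \nabla c^E)$: the
  mobility vanishes with the density, so a compactly supported tumour keeps
  a sharp front and a finite invasion speed, unlike linear (heat-equation)
  diffusion whose solutions are instantly positive everywhere. They also
  drift up the matrix gradient (haptotaxis, coefficient $\chi_E$) and
  proliferate logistically against the volume occupied by all cell phases
  and the matrix.
* $c^F$ — cancer-associated fibroblasts (CAFs): same transport structure,
  but drifting *down* the matrix gradient (matrix-remodelling behaviour),
  with proliferation boosted by the factor $(1 + c^E)$ and first-order
  death.
* $b$ — TGF-β, produced by CAFs, diffusing linearly and decaying; it is
  the signal that gates EMT.
* $m$ — matrix metalloproteinases (MMPs), produced by CAFs and ECCs,
  diffusing linearly and decaying.
* $v$ — extracellular matrix (ECM), immobile; produced by CAFs and
  degraded both by the MMP–ECC complex ($\lambda_v^E\, m\, c^E\, v$) and
  under the footprints of solitary cells ($\lambda_v^M \sum_p
  \mathcal{X}_{K_p} v$).

**Agent phase.** Mesenchymal-like cancer cells (MCCs) are point masses
$(\mathbf{x}^p, m^p)$ evolving by an Euler–Maruyama-type update
$$ \mathbf{X}_{n+1} = \mathbf{X}_n +
   \mu(\nabla v(\mathbf{X}_n))\,\tau + \sigma \mathbf{Z}_n , $$
with a *saturated* haptotactic drift $\mu(z) = A \arctan(z/A)$,
$A = 2V_\mathrm{thr}/\pi$, so the drift speed never exceeds the maximum
cell speed $V_\mathrm{thr}$ (default 2.16 cm/d), and compound-Poisson jump
noise: in a step of length $\tau$ a reorientation jump occurs with
probability $1 - e^{-\lambda\tau}$, drawn as an isotropic direction times a
half-Gaussian magnitude of scale $\sqrt\tau$. After each update the implied
velocity is rescaled onto $V_\mathrm{thr}$ if the combined drift and jump
exceed it, and positions are mirror-reflected into the domain.

**Phase transitions.** The domain is tiled by partition blocks the size of
a biological cell, coarser than the computational grid. The
density-to-cells operator emits one agent per block carrying the block's
integrated mass at its barycentre; the cells-to-density operator spreads
each agent's mass over the blocks its footprint cube overlaps,
proportionally to the overlap volume (clipped and renormalised at walls).
Both directions, and their round trips, conserve mass to round-off — the
structural backbone of the model.

**Phenotype switching.** EMT is a Poisson process per partition block with
intensity $\zeta(b)\tau$, where $\zeta(b) = L / (1 + e^{-k(b - b_T)})$ is a
shifted logistic switch in the local TGF-β density, active only where the
epithelial density reaches the gate $C_\mathrm{ref}$; each event converts
one cell quantum $m_\mathrm{cell}$ of density into a new agent. MET is a
fixed-rate Poisson clock per agent (probability $1 - e^{-r\tau}$ per step);
reverting agents are deposited back onto $c^E$. Because TGF-β initially
surrounds but does not penetrate the tumour, EMT fires on the tumour rim —
blocks that mix interior density with exterior signal.

**Metastasis network.** An organism is a set of equal cuboid organs coupled
all-to-all by a circulatory graph. Agents intravasate with a Poisson rate,
become circulating tumour cells (CTCs), survive transit with probability
$p_\mathrm{survive}$ (default 0.1%), and survivors extravasate into an
organ drawn uniformly among those connected to the origin (no self-return
by default), arriving as agents at a uniform random interior position.
Blood-flow directionality, CTC dormancy and realistic organ geometry are
deliberately out of scope.

## Numerical scheme

The published account of the model states the equations but not the
discretisation, so the scheme here is the package's own design, chosen for
exact discrete conservation:

* finite-volume fluxes on a cell-centred grid with homogeneous Neumann
  walls (zero boundary flux, ghost-cell mirroring), so every transport term
  telescopes to zero total mass change;
* arithmetic-mean interface mobility for the porous-medium flux
  $D\,\bar c\,\Delta c/h$ — degenerate at zero, which keeps compact
  supports compact (at most one cell per step per side, verified in the
  tests against the closed-form Barenblatt self-similar solution);
* first-order upwinding for haptotaxis (monotone, conservative);
* explicit forward Euler in time with a stability-controlled step:
  0.4 times the minimum of the diffusive limit $h^2/(2\,\mathrm{dim}\,
  D_\mathrm{max})$, the advective limit $h/u_\mathrm{max}$ and the inverse
  of the fastest local relative reaction rate, capped at `dt_max`
  (default $10^{-2}$ d);
* operator ordering per global step, fixed for reproducibility: density
  transport + reactions → EMT → MET → agent migration → intravasation →
  transit resolution (CTCs resolve one global step after entry);
* negative values created by round-off are clipped to zero and the clipped
  mass is logged; the per-step audit balances total cancer mass against
  the logged proliferation, clipping and CTC deaths.

Positions are physical (cm), masses in g, densities in g cm⁻³, time in
days. All randomness flows through R's global RNG: `set.seed()` before a
run (or the `seed` entry of a configuration) makes every result — field
trajectories, agent paths, event logs — bit-reproducible. We chose the
global-stream convention over an explicit generator object because it is
the idiom of R simulation code and keeps every function signature clean.

## Parameters

Defaults follow the published parameterisation of the system (units of
days and cm): $D_E = 8.64\times10^{-8}$ cm²/d, $D_F = 10 D_E$,
$D_b = D_m = 10^3 D_E$, $\chi_E = \chi_F = 10^{-3}$ cm²/d,
$\rho_c^E = 1.2$/d, $\rho_c^F = 10^{-3}$/d, production rates
$\rho_b^F = \rho_m^F = \rho_v^F = 10^{-3}$, decay rates $\lambda_F =
\lambda_b = \lambda_m = 2.62\times10^{-2}$/d, matrix degradation 1.8383,
$\sigma = 30$ cm d$^{-1/2}$, EMT ceiling $L = 5\times10^{-3}$/d with
steepness $k = 10^6$ and threshold $b_T = 10^{-3}$ g cm⁻³, MET rate
0.1/d, $V_\mathrm{thr} = 2.16$ cm/d, matrix bounds $v_\mathrm{max} = 1.06$
and $v_\mathrm{min} = 0.9\, v_\mathrm{max}$ g cm⁻³.

Gaps the source leaves open are filled once, as package defaults, all
overridable through `model_params()`:

* `rho_mE` (MMP production by ECCs) has no published value; set equal to
  `rho_mF`.
* The published table gives a single matrix degradation rate; both
  `lambda_vM` and `lambda_vE` default to it.
* The MMP equation prints the epithelial diffusion coefficient in one
  place and defines a dedicated $D_m$ in another; we treat the former as a
  typo and use $D_m$ (switchable via `mmp_diffusion = "D_E"`).
* `C_ref` (EMT density gate) defaults to 0.5 g cm⁻³, half the logistic
  carrying-capacity scale.
* `m_cell` (mass per EMT event) defaults to $C_\mathrm{ref}$ times the
  partition-block volume, making the emitted agents cell-sized.
* The compound-Poisson reorientation rate is not published; default
  `lam_cpp = 50`/d, i.e. several reorientations per day, consistent with a
  persistent random walk. This is the single most influential free
  parameter of the agent dynamics and is prominently configurable.
* The intravasation rate is not published; default `lam_intra = 0.1`/d,
  the same order as MET.
* The drift saturation is applied to the gradient *magnitude* with the
  direction preserved (a componentwise variant is available), so the speed
  bound holds in any dimension.
* "Reflective" walls are mirror reflections; the alternative reading
  (return to the last interior position) is available as
  `boundary = "last_position"`.
* The published velocity drift coefficient $\mu_v = 100$ cm²/d has no slot
  in the saturated drift law (which is fully determined by
  $V_\mathrm{thr}$); it is carried as an inert configuration field.

## The four studies

```{r presets, eval = FALSE}
run1 <- run_experiment(experiment_preset(1))  # haptotaxis flow
run2 <- run_experiment(experiment_preset(2))  # cancer cell islands
run3 <- run_experiment(experiment_preset(3))  # merging microtumours
run4 <- run_experiment(experiment_preset(4))  # multi-organ metastasis
```

1. **Haptotaxis flow** — a density-3 spherical tumour (radius 0.01 cm) in
   a *directional* matrix increasing linearly towards one corner; only
   epithelial diffusion, EMT and agent migration are active. Demonstrates
   rim-localised EMT and agents drifting up-gradient.
2. **Cancer cell islands** — full dynamics in a *hierarchical random*
   matrix: an 8³ standard-normal lattice is repeatedly doubled in
   resolution by multilinear interpolation plus level-halving Gaussian
   noise (so the coarse structure persists), then mapped to
   $[v_\mathrm{min}, v_\mathrm{max}]$; at the native configuration the
   refinement reaches 64³. Escaped agents revert by MET and seed epithelial
   islands.
3. **Growing and merging microtumours** — two density-1 spheres offset
   along the diagonal, EMT disabled: pure density-phase dynamics.
4. **Multiple organ metastasis** — four organs, tumour in organ 1 only;
   intravasation, transit survival and uniform extravasation connect them.

Desk-scale defaults (32³, or 24³ for the four-organ study, horizons of a
few hundredths of a day) keep a run in seconds; the native resolutions and
horizons are plain configuration overrides. The tests and the acceptance
script use these desk scales throughout.

## What the synthetic environment does and does not capture

The generators reproduce the *statistical structure* of the published
initial conditions: exact 30% fibroblast coverage with $U(0, 0.001)$
densities, TGF-β $U(0, 0.01)$ strictly outside the tumour and zero inside,
MMP $U(0, 10^{-4})$ everywhere, and the two matrix constructions above.
They do not emulate image-derived tissue anatomy, vascular geometry,
anisotropic fibre orientation, or any feedback between initial randomness
and cell state — so a passing suite demonstrates the solver and the
stochastic machinery on the model's own terms, not agreement with
biological imaging data.

## Known limitations

* With the published parameter set, the matrix density $v \in [0.954,
  1.06]$ g cm⁻³ saturates the logistic capacity: the competition factor
  $(1 - c^E - c^M - c^F - v)$ is negative wherever tumour density is
  appreciable, so epithelial mass *decays* slowly on desk-scale horizons
  and matrix degradation (at rate $\sim \rho_m \lambda_v^E$) is far too
  slow to free capacity within a day. Net tumour growth therefore does not
  occur under the printed values; the island-versus-single-mass comparison
  (`compare_island_growth()`) is accordingly reported as growth *factors*
  normalised by each discretised initial state at matched seeds. The
  `normalize_carrying_capacity` flag rescales the matrix by
  $v_\mathrm{max}$ in the competition term but does not change this
  qualitative picture.
* Similarly, at the default EMT ceiling $L = 5\times10^{-3}$/d a tumour
  sheds agents very slowly; studies that want visible cascades on short
  horizons raise `L` (the demonstrations and tests do so explicitly).
* The EMT density gate interacts with resolution: a 0.01 cm ball needs
  roughly 32 cells per axis before rim partition blocks average above
  `C_ref`; below that the gate correctly reports no eligible blocks.
* One global time step is shared by all organs and set by the stiffest
  one; there is no sub-cycling.
* Snapshots and logs are plain CSV/JSON, chosen for portability and
  text-only reproducibility of runs.
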