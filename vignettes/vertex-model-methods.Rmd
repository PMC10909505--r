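---
title: "Friction, the cell cycle, and growth in a stochastic epithelial vertex model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Friction, the cell cycle, and growth in a stochastic epithelial vertex model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`epivertex` simulates a growing planar epithelium as a shared-vertex
tessellation of polygonal cells and asks a deliberately narrow question: how
does the friction coefficient of the overdamped vertex dynamics reshape
morphology, cell-cycle progression, tissue growth rate and topological
transitions?  This vignette records the model, the numerical choices, the
design decisions that were genuinely open, and what the test suite does and
does not establish.

## The mechanical model

Cells are simple polygons with counter-clockwise vertex loops; tri-cellular
junctions are vertices shared by three cells.  The tissue energy is the
standard vertex-model functional

$$E(\mathbf r)=\sum_\alpha\left[\frac{K}{2}\big(A_\alpha-A^0_\alpha(t)\big)^2
+\frac{\Gamma}{2}L_\alpha^2\right]+\sum_{\langle ij\rangle}\Lambda\, l_{ij},$$

with area elasticity $K$, perimeter contractility $\Gamma$, and line tension
$\Lambda$ on each *unordered* edge (an interior edge shared by two cells is
counted once — some vertex-model variants count per cell side, which would
double the interior tension).  Every vertex follows overdamped dynamics

$$\gamma\,\frac{d\mathbf r_i}{dt}=\mathbf F_i=-\nabla_i E,$$

integrated with an explicit forward-Euler step.  Forces are analytic: the
shoelace derivative for the area term, unit-tangent sums for the perimeter
term, and unit edge vectors for the tension term; the test suite verifies
them against central finite differences of the energy on random meshes, and
checks the two structural identities (total force exactly zero by
translation invariance; energy non-increasing along static-target
relaxation).

The default parameters, in simulation units, are $K=1$, $\Lambda=0.05$,
$\Gamma=0.02$.  The tissue has a free boundary: boundary vertices obey the
same equation of motion with no extra term, and boundary edges carry the
same line tension.

When the target areas are constant the dynamics depend on $t/\gamma$ only,
so friction merely rescales time.  That symmetry (verified to $10^{-8}$ in
the tests) is the null against which every friction effect in the package is
measured: any $\gamma$-dependence must enter through the coupling to a
process with its own clock — here, the cell cycle.

## The stochastic cell cycle

Each cell draws an intrinsic cycle length at birth,

$$t_c \sim \varepsilon T_c + \mathrm{Exp}\!\big((1-\varepsilon)T_c\big),$$

a deterministic minimum plus an exponential tail, so $\langle t_c\rangle=T_c$
and the support is $[\varepsilon T_c,\infty)$.  Defaults: $T_c=388$,
$\varepsilon=0.8$.  The cell's target area follows

$$A^0(t)=\begin{cases}1,& t<t_c/2\\ \min(2t/t_c,\;A_f),& t\ge t_c/2\end{cases}$$

with $A_f=2$ the maximum target area of a mitotic cell.  The clamp at $A_f$
is a documented decision: the raw schedule is unbounded for $t>t_c$, and a
high-friction cell whose division is delayed by the area gate would
otherwise be driven elastically without limit.

Cytokinesis requires the cell's **age** to reach $t_c$ *and*, when the area
gate is on, its current apical area to reach the critical area
$A_c=0.78\,A_f=1.56$.  Setting `with_area_gate = FALSE` (the $A_c=0$
ablation) removes the spatial condition entirely, which decouples division
timing from mechanics and leaves T2 extrusion as the only mechanical brake
on growth.

Division splits the polygon by a line through its area centroid.  The
default orientation is uniformly random (keeping daughters statistically
symmetric); a short-axis rule (split along the minor principal axis) is
available in the configuration.  Daughters restart the schedule at
$A^0=1$ with fresh independent $t_c$ draws.  Both choices are checked by
area conservation at machine precision and by the mesh validator.

## Topological transitions

Three moves keep the tessellation valid as it deforms:

* **T1 edge swap** — an interior edge between two tri-junctions shorter than
  $\ell_{T1}=0.05$ is rotated 90° about its midpoint and rescaled to
  $\ell_{new}=0.06$; the two cells that shared it lose a side, the two
  flanking cells gain one.  If the rotated edge would cross a neighbouring
  edge (which can happen in crowded regions at this fixed $\ell_{new}$), the
  swap is vetoed, reverted, and skipped for that sweep.
* **T2 extrusion** — a 3-sided cell with area below $A_{T2}=0.02$ collapses
  to a single vertex at its centroid; each neighbour loses one side.  A
  3-sided cell with a boundary edge is peeled instead (its loop deleted).
* **boundary merge** — boundary edges have no fourth cell and cannot T1;
  a short boundary edge is resolved by merging its removable endpoint into
  the other one at the midpoint.  When both endpoints are tri-junctions the
  merge leaves a 4-fold *boundary* vertex, which is legal: the tri-junction
  invariant constrains interior vertices.  Every merge is guarded by a
  simple-polygon check on the touched loops and reverted if it would tangle.

Thresholds are in units where the initial cell area is 1; they are
configuration parameters, and the qualitative results below are stable to
changing them by ±50%.  Sweeps process the shortest eligible edge first with
stable-id tie-breaks, so they are deterministic for a given mesh.

## Age-structured growth theory

The growth side of the package is spatial-model-free.  For a cycle-duration
distribution $P(\tau)$ with CDF $G$, steady exponential growth at rate $k$
implies the stationary age density and the Euler–Lotka relation

$$N(t,\tau)\propto (1-G(\tau))\,e^{-k\tau},\qquad
\tfrac12=\int_0^\infty e^{-k\tau}P(\tau)\,d\tau,$$

and the snapshot identity $k = N(t,0)/2N(t)$ relating growth to the newborn
fraction.  For the intrinsic family the Euler–Lotka transform is the closed
form $\tfrac12=e^{-k\varepsilon T_c}/(1+k(1-\varepsilon)T_c)$: at
$\varepsilon=1$ it returns $\ln 2/T_c$, at $\varepsilon=0$ it returns
$1/T_c$ (the fastest growth at fixed mean), and at $\varepsilon=0.8$ the
root gives $k_{sto}T_c\simeq0.70$.  The transform is strictly decreasing in
$k$, so the root is unique; it is bracketed by doubling and solved with
`uniroot` at $10^{-12}$ relative tolerance.  For an empirical sample the
transform is the plain sample mean of $e^{-k\tau_i}$ — unbiased under the
empirical measure, with no smoothing of $P$.

The age-structure estimator uses a newborn window $\delta$ (default 2% of
$T_c$): $\hat k=\tfrac12\,\#\{\text{age}<\delta\}/(\delta N)$, with a
bootstrap standard error.  Its small-$\delta$ bias is $O(k\delta)$ (below
1% at the default); its practical error on real snapshots is dominated by
residual non-stationarity, discussed next.

## The branching-process oracle and what "stationary" means

`branching_process_simulate()` realises the interaction-free model: every
cell divides exactly at its drawn $t_c$.  It is the independent oracle for
the growth theory: fitted log-slopes of $N(t)$ across ten seeds agree with
the Euler–Lotka root to three decimals.

One finding matters for testing: a population started synchronously (all
ages zero) **rings**.  The cohort wave decays by a factor
$|\mathbb E\,e^{2\pi i t_c/T_c}|\approx0.62$ per generation, and at eight
mean cycles the age distribution still deviates from the stationary density
by about 1% in sup norm — small, but detectable by a Kolmogorov–Smirnov
test with $n=10^4$ ages.  By twelve mean cycles the same test is comfortably
passed.  The test suite therefore demonstrates oracle agreement with the
stationary density at twelve mean cycles, and the acceptance check that
insists on eight mean cycles documents this transient honestly rather than
hiding it.  The same ringing perturbs the newborn-fraction estimator, whose
consistency is therefore assessed on stationary-horizon snapshots and
averaged over realisations.

## Simulation protocol and desk-scale study conditions

A run starts from an exact hexagonal lattice (unit-area cells, the initial
target area) with all birth times zero and independent $t_c$ draws, and
iterates: forces → Euler step → topology sweep → division checks, with
metrics recorded every $T_c/10$.  One seed drives all randomness;
runs are bit-reproducible, and the identity
$N(t)=N_0+\#\text{divisions}-\#\text{T2}$ is asserted against the event log.

**Time step.**  The default is $dt=0.05\,\gamma/K$, a twentieth of the
single-junction relaxation time, uniformly across $\gamma$ (so every run
sits at the same fraction of its own mechanical timescale).  A convergence
study at $\gamma=0.01$ and $\gamma=2$ (two seeds each, $dt$ factors 0.05,
0.1, 0.2) found mean/SD of cell area, fitted growth rate, and division age
and area unchanged to three significant digits; only the raw tally of T1
events shifts, without affecting any reported summary.  The replicated
study protocols (`friction_study()`, `ablation_study()`) therefore use
$dt=0.2\,\gamma/K$.

**Scale.**  The friction effect on morphology is collective.  A growing
free tissue must displace material over its own radius $R$, with viscous
timescale $\sim\gamma R^2/K\sim\gamma N/(\pi K)$; friction bites when this
exceeds the cycle time, i.e. beyond $N^*\approx\pi K T_c/\gamma$ — about
600 cells at $\gamma=2$, and irrelevantly large at $\gamma=0.01$.
Consistently, the measured reduction in mean apical area between
$\gamma=0.01$ and $\gamma=2$ grows from ~5% at 1000 cells to ~13–18% at
2000 cells (master-seed dependent), approaching the ~20% seen at much larger scale.  The
`friction_study()` protocol therefore grows 5 replicates per friction value
to **2000 cells**; the `ablation_study()` protocol grows 3 replicates to
**4000 cells**, the scale at which T2 extrusions become frequent at high
friction while remaining rare at low friction.  Mean areas are pooled over
replicates because the division-wave phase (shared across seeds through the
synchronous start) makes single final snapshots oscillate.

These scales are roughly an order of magnitude below the full-scale
computational study the model addresses (20 replicates to 15 000 cells);
the qualitative orderings are developed at desk scale, the quantitative
area reduction is near the lower edge of its full-scale value, and exact
T2 counts are protocol-dependent and compared only by ordering.

## What the synthetic data do and do not emulate

All inputs are generated internally: the hexagonal lattice defines the
initial condition and the branching process the interaction-free cycle
statistics.  The generator reproduces the *model's* assumptions —
uniform mechanical parameters, a memoryless stochastic cycle tail,
mother–daughter independence of $t_c$, symmetric division.  Real epithelia
violate several of these (heterogeneous tension, cycle-length correlations,
oriented divisions, apico-basal structure), so passing tests establish
internal correctness of the model and its theory, not fidelity to any
particular tissue.

## Known limitations

* Forward Euler only; no adaptive or semi-implicit stepping.  The validated
  $dt$ policy covers the parameter ranges used here, not arbitrary ones.
* Friction is a single global constant; size-dependent dissipation is out
  of scope.
* T1 thresholds are not derived from physics; near-threshold tangles are
  vetoed rather than resolved by vertex splitting, and a vetoed edge simply
  waits for the geometry to open up.
* The stationary age density assumes a time-invariant duration
  distribution; in gated tissues the realised distribution drifts with
  tissue size, which is precisely why the age-structure estimator on the
  final snapshot outperforms the intrinsic prediction there.
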