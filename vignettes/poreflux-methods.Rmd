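---
title: "Models and methods behind poreflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poreflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreflux)
```

poreflux quantifies water transport through membrane channels of the
aquaporin type from molecular dynamics trajectories, and classifies channels
into functional states when a ligand (for example a corticosteroid bound in
the extracellular vestibule) modulates permeation. This vignette explains
the models implemented, the tunable parameters and their defaults, the
synthetic-data generator used to validate every estimator, and the numerical
choices made where the design was genuinely open.

## Permeation counting

A permeation event is an end-to-end passage of a water molecule through a
cylindrical transmembrane section, canonically 30 Å long (the whole membrane
span) or 5 Å around the aromatic/arginine (ar/R) selectivity filter. The
state machine in `count_crossings()` records an event only when a particle
enters through one z-face of the cylinder and exits through the opposite
face while remaining inside the cylinder radius in between:

* leaving the cylinder wall radially resets the attempt — a molecule that
  wanders out into the membrane region and re-enters has not permeated;
* re-entry after a radial exit starts a fresh attempt, and entries through
  the cylinder wall never arm one;
* frame-to-frame z jumps larger than half the box are treated as periodic
  images, never as crossings.

Because the literature is ambiguous about whether short-section counts use
the same strict rule, `radial = FALSE` switches to a plain slab-crossing
rule that ignores the radius; the strict rule is the default. The counter
warns when the frame spacing is coarse relative to the section (rms z step
above half the section length), since sparse sampling undercounts.

## Osmotic permeability by collective diffusion

The dimensionless collective coordinate accumulates the axial displacements
of the waters inside the pore,

$$ n(t) = \sum_{\text{steps}} \frac{1}{L} \sum_{i \in \text{pore}} \Delta z_i, $$

with $L$ the section length and minimum-image $\Delta z_i$. At equilibrium
$n(t)$ performs a random walk, $\langle n^2(t) \rangle = 2 D_n t$, and the
single-channel osmotic permeability is

$$ p_f = v_w D_n, $$

with $v_w$ the volume of one water molecule. The default
$v_w = 2.989\times10^{-23}\,\mathrm{cm^3}$ (18.07 cm³/mol divided by
Avogadro's number) is configurable.

`pf_from_collective()` estimates $D_n$ as half the least-squares slope of
the mean square displacement of $n(t)$ computed over non-overlapping
restart segments of the path, with the fit window set to 20 % of the
segment length. By default the path is cut into one segment per ~200 stored
points (at least 10 segments): short segments keep the MSD at small lags
where it is estimated from many quasi-independent stretches, which reduced
the fitted-slope standard deviation on ideal Brownian paths from roughly
30 % (10 segments of 10⁴ points) to about 5 % (500 segments) at 10⁵ points
in our calibration runs, with no detectable bias — an ideal Brownian path
has a linear MSD at every lag, and the equilibrium collective coordinate is
close to one. A negative fitted slope (possible on very short, quiet
series) yields $p_f = 0$ with a warning rather than a negative
permeability.

## The Dk barrier correction

Thermal agitation of the water column inflates collective-diffusion
$p_f$ estimates even in channels that never conduct: the waters rattle, so
$n(t)$ diffuses, although no molecule crosses. The correction constant
penalizes free-energy barriers along the pore,

$$ D_k = \exp\!\left(-\Delta G_{\max}/k_BT\right), \qquad
   p_f^{\mathrm{corr}} = D_k \, p_f, $$

where $\Delta G_{\max}$ is the highest barrier of the occupancy-derived
profile within the section, relative to the bulk zero level and clamped at
zero so that barrier-free channels are untouched. This Boltzmann form is
the package's design choice: it is bounded in $(0, 1]$, leaves open
channels unchanged, decreases monotonically with barrier height, and scales
$p_f$ by exactly $e^{-1}$ for a barrier of $k_BT$ — the qualitative
behaviour required of the correction. Published variants of the constant
differ in normalization details; anyone needing a specific variant can
compute $D_k$ externally and multiply, since `apply_dk()` also reports the
barrier it found.

## Free-energy profiles from occupancy

`occupancy_profile()` divides the cylinder into 0.5 Å slices (configurable)
and time-averages the water count per slice; `gibbs_profile()` converts
densities to free energies,

$$ G(z) = -k_B T \,\ln\frac{\rho(z)}{\rho_{\mathrm{bulk}}}, $$

at the simulation temperature (default 310.15 K, $k_BT =
0.61633$ kcal/mol). Zero-occupancy slices are masked — reported as
undefined, never as $\pm\infty$ — and any operation that would consume a
masked slice inside its section (`barrier()`, `apply_dk()`) raises an
explicit error instead of propagating `NaN`. Which bulk region defines
$\rho_{\mathrm{bulk}}$ is an open choice; the default is all selected water
outside the cylinder per unit of the remaining box volume, and a fixed
literature value can be supplied instead. `barrier()` reports the maximum
over the section with ties broken toward the smallest z.

## Binding free energy and dissociation constant

Per-frame ligand binding free energies (computed upstream by an empirical
contact-based scorer and consumed here as a CSV time series) are summarized
by `summarize_binding()` and converted by

$$ K_D = \exp\!\left(\Delta G / RT\right) \ \mathrm{M}, \qquad
   R = 1.9872\times10^{-3}\ \mathrm{kcal\,mol^{-1}K^{-1}}. $$

Two conventions deserve a note. First, the sign: with binding free energies
reported as negative numbers, $K_D = \exp(+\Delta G/RT)$ is the convention
under which a favourable interaction gives a sub-molar $K_D$ and
$\Delta G = 0$ gives exactly 1 M; the reference values this package is
validated against (−9.22 kcal/mol ↦ ≈318 nM) satisfy it. Second, the
temperature: the conversion defaults to the simulation temperature
310.15 K, which reproduces those reference values; 298 K does not.
`Kd_mean` is $K_D$ of the mean $\Delta G$, not the mean of per-frame
$K_D$ values — the latter is dominated by the weakest frames.

## Structural observables

* **Hydrogen bonds** — geometric criterion: donor–acceptor distance
  ≤ 3.5 Å and H–donor–acceptor angle ≤ 30°, the common defaults of
  standard MD tooling; both are configurable. Hydrogens are attached to
  donors by topology: same residue, name starting with H, within 1.2 Å in
  the first frame. Donors without a resolvable hydrogen are excluded with a
  warning.
* **Minimum distances** — exact minimum over all inter-group pairs under
  the minimum-image convention, no cutoff truncation.
* **Pore radius** — a slice-wise inscribed-radius approximation: per slice,
  the minimum over atoms of (lateral distance to the pore axis − van der
  Waals radius), clamped at zero, averaged over frames. This is a
  simplified stand-in for sphere-propagation pore software and is labelled
  as such in its output; it suffices for comparative profiles, not for
  absolute pore dimensions in kinked channels.
* **RDF** — `g(r)` normalized by the ideal-gas expectation at the target's
  mean density, so a Poisson gas converges to 1; self-pairs are excluded
  from counts and normalization; `r_max` must stay below half the smallest
  box length.
* **Dipole moments** — $\mu = \sum_i q_i (r_i - r_{\mathrm{cog}})$ in
  Debye, with the selection's centre of geometry as reference so that
  non-neutral selections are well-defined (the reference is recorded with
  the result), plus the angle to +z.
* **Membrane potential** — charge density binned along z and
  double-integrated through the one-dimensional Poisson equation with
  vacuum permittivity, field and potential pinned to zero at the lower box
  edge (the convention of the standard z-potential tools); non-neutral
  totals warn with the residual.

## Statistics pipeline

Trajectories are cut into contiguous, non-overlapping 10 ns blocks anchored
at the start (trailing partial blocks dropped with a message), each channel
contributing independently: 250 ns × 4 channels gives 25 blocks per channel
and 100 repetitions per condition. A block is *functional* when 5 or more
waters cross the whole 30 Å section — threshold inclusive, chosen because
it separates both means and medians of open versus ligand-blocked
conditions.

`compare_groups()` implements the test-selection rule: Shapiro–Wilk
normality in every group and Levene homoscedasticity, both at α = 0.05
(neither the tests nor the α are sacred; both are arguments). All pass →
Student's t (two groups) or one-way ANOVA with Tukey's post hoc; otherwise
Mann–Whitney or pairwise Wilcoxon rank-sum with Bonferroni correction
(Kruskal–Wallis omnibus). Constant data in a group forces the rank branch,
since normality is untestable there. The chosen path is recorded in the
result, and the pairwise-Wilcoxon reading of the ">2 groups, non-parametric"
case matches the pairwise p-value displays this pipeline is meant to feed.

`contingency_chi2()` is Pearson's chi-square without continuity correction
by default (Yates available), with fixed table orientation and a hard error
on zero margins, where association is undefined. The
functional-state-versus-ligand-contact association is its canonical use.

`slice_dipole_correlation()` assigns frames to 10 Å z-slabs by the ligand's
centre of geometry and computes the Spearman rank correlation between
protein and ligand dipole-angle series per slab; slabs with fewer than 5
frames are reported as "insufficient data" rather than tested.

## The synthetic-data generator

No trajectory data are deposited with the study this methodology follows,
so validation rests on generators with known ground truth:

* `simulate_pore()` — overdamped Langevin point particles:
  $z \leftarrow z - \beta D\, U'(z)\,\Delta t + \sqrt{2D\Delta t}\,\xi$,
  free diffusion in x/y and in the reservoirs, all axes periodic. The
  imposed potential $U(z)$ acts only inside the pore radius. A reflective
  wall at the cylinder surface acts on particles within the pore z-section
  from both sides: a one-sided wall would break detailed balance and pile
  density into the pore, whereas with the two-sided wall the stationary
  density is exactly Boltzmann in $U(z)$ — the property the free-energy
  estimators are tested against. Defaults are chosen to emulate the study
  conditions: D = 230 Å²/ns (bulk water self-diffusion near 310 K), a 30 Å
  section in a periodic box, 310.15 K, 10 ns blocks. The integrator rejects
  time steps whose maximum drift per step exceeds the profile grid spacing.
  Identical seeds give bit-identical trajectories.
* `generate_collective_series()` — a Brownian path with exactly known
  $D_n$, the direct ground truth for the $p_f$ estimator.
* `generate_dipole_pair()` — a bivariate Gaussian copula mapped
  monotonically onto angles; the sample Spearman correlation converges to
  $(6/\pi)\arcsin(\rho/2)$.
* `generate_charge_slab()` — two opposite uniform charge sheets with the
  parallel-plate potential difference $\sigma d / \varepsilon_0$ as
  analytic truth.

What the generator does *not* emulate: explicit water structure and
hydrogen-bond networks, single-file transport correlations, electrostatics
in the dynamics, protein flexibility, or force-field detail. Passing tests
therefore demonstrate that the estimators recover known transport
coefficients, free-energy profiles and classifications from trajectories
with the right statistical structure — not that any particular biological
system behaves as the generator does. In particular the equality
$p_f = v_w D_n$ is validated on ideal collective paths; on real single-file
channels $D_n$ itself carries the single-file physics.

## Problem sizes and runtimes

The shipped tests validate estimator recovery at sizes chosen to keep
Monte-Carlo error well inside the asserted tolerances while running on one
CPU in minutes: 10⁵-step collective paths (20 seeds per diffusion constant
over two decades), ≈2×10⁶ particle-frames for the 2 kcal/mol barrier
recovery (±0.2 kcal/mol band), 1000-repeat null calibrations for both test
branches, an exhaustive sweep of all 2×2 tables with margins ≤ 20 against
the closed-form chi-square, and an end-to-end replica of two four-channel
conditions (flat versus 3 kcal/mol barrier, 50 ns at 0.01 ns frame
spacing) through counting, blocking, classification and association
testing.

## Known limitations

* XTC input is not supported (no R reader for the compressed GROMACS
  format); convert to DCD or multi-frame GRO first. DCD files carry no box
  here, so the topology box is replicated across frames.
* The pore-radius profile is the simplified inscribed-radius
  approximation described above.
* The selection grammar covers residue name/id, atom name, chain and
  boolean combinations — not distance-based or within-style selections.
* `compare_groups()` reports the Kruskal–Wallis omnibus p alongside
  Bonferroni-adjusted pairwise Wilcoxon p-values in the non-parametric
  multi-group branch; it does not implement mixed models or corrections
  beyond Bonferroni/Tukey.
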