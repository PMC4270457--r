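---
title: "Models and methods for ParA-mediated plasmid positioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for ParA-mediated plasmid positioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parspace)
```

# The biological problem

Low-copy-number bacterial plasmids carrying a *parABC* locus are positioned
at equally spaced sites over the nucleoid, which guarantees that each
daughter cell inherits at least one copy. The locus encodes ParA, a P-loop
ATPase whose ATP-bound dimer binds nucleoid DNA nonspecifically, and ParB,
which binds the plasmid's *parC* region and stimulates ParA-ATP hydrolysis,
releasing ParA from the nucleoid as cytoplasmic ParA-ADP. ParA-ADP matures
slowly (rate $k_W$) back into a DNA-binding-competent form, long enough for
cytoplasmic diffusion to erase any memory of where it unbound. parspace
implements the quantitative machinery for studying how these ingredients
self-organize into equal plasmid spacing: a closed-form gradient analysis,
two exact stochastic lattice simulators embodying rival transport
mechanisms, and the statistics used to confront either mechanism with
trajectory and image data.

# The analytic 1d gradient

`solve_steady_state()` solves the steady state of the minimal
reaction-diffusion picture: on a nucleoid of length $L$, ParA-ATP binds
uniformly at flux $R$ per unit length, diffuses with constant $D$, and is
released only at plasmid positions $x_1 < \dots < x_{n_p}$. On every
plasmid-free segment

$$ D \, A''(x) + R = 0, $$

with no-flux conditions $A'(0) = A'(L) = 0$, so $A$ is piecewise quadratic
with curvature $-R/D$. Perfectly absorbing plasmids impose $A(x_i) = 0$;
with a finite hydrolysis rate $k_B$ we impose flux balance
$J_i^- + J_i^+ = k_B A(x_i)$, a point-sink (radiation) condition whose
solution reduces to the absorbing case as $k_B \to \infty$ (the package's
reading of the finite-rate variant; the solver treats it as a tridiagonal
linear system in the plasmid concentrations). Plasmids are zero-width
points throughout.

The arrival fluxes carry the positional information: for a single plasmid,
$J^- = R x_1$ and $J^+ = R (L - x_1)$, so the imbalance
$J^+ - J^- = R (L - 2 x_1)$ always points toward the longer side, and the
total arrival over all plasmids is exactly $R L$ (everything bound must be
released at a plasmid). The fixed points of `flux_imbalance_relaxation()`
— a quasi-static iteration that moves each plasmid a damped step toward
its larger flux and re-solves the profile, justified by the separation of
timescales between ParA diffusion and plasmid motion — are the
equal-spacing positions $x_i = (2 i - 1) L / (2 n_p)$, with inter-plasmid
spacing $L / n_p$ (hence slope 1/2 of spacing against nucleoid length for
two plasmids). The relaxation step defaults to $L/2000$ with convergence
declared at a maximal per-sweep displacement below $10^{-9} L$; the damping
scales the step by the displacement $|J^+ - J^-|/(2R)$ that would balance
an isolated plasmid, which makes the iteration contract smoothly instead
of hopping across the fixed point.

# The stochastic engine

Both simulators run an exact Gillespie direct-method kernel: waiting times
are exponential in the total propensity, channels fire proportionally to
their propensity, and propensities are updated incrementally after every
event. The compiled kernels aggregate channels per lattice column in a
binary sum tree (logarithmic selection and update); the generic R-level
`run_ssa()` exposes the same semantics for arbitrary reaction sets.
Scheduled events interleave deterministically at their exact times, which
is licensed by the memorylessness of exponential waiting times:

* **Growth**: the lattice is extended by two empty columns inserted at one
  uniformly random position; indices to the right shift by two, and the
  cytoplasmic ParA-ADP pool is replenished so total ParA returns to the
  target density (2400 dimers per µm of long axis by default). New protein
  enters through the ADP pool because newly synthesized ParA must mature
  through the slow $k_W$ step before it can bind DNA; a fixed-count mode
  (`density_per_um = NA`) is available for the alternative reading.
* **Duplication**: a uniformly chosen plasmid gains a colocalized copy
  with zero bound ParA.
* **Output**: state snapshots every 5 s by convention; each snapshot also
  audits exact ParA mass conservation and aborts on any violation.

All lattice boundaries are reflecting: nucleoid-bound species have nowhere
else to go, matching the no-flux edges of the analytic model. Negative
propensities and count underflows abort with the reaction identity.
Reproducibility is per run seed; the R wrappers seed R's RNG and the
kernels draw from it, so identical inputs give identical event sequences.

# The diffusion/immobilization model

One-dimensional lattice, site size $dx = 5$ nm. Nucleoid-bound ParA-ATP
hops at $D_A/dx^2$ per direction ($D_A = 10^{-2}$ µm²/s — deliberately ten
times slower than the plasmid, else it could hardly immobilize one); free
plasmids hop at $D_P/dx^2$ ($D_P = 10^{-1}$ µm²/s) until two or more
ParA-ATP are bound, which sets the plasmid diffusion constant to zero. Up
to 35 ParA-ATP bind a co-localized plasmid at $k_{AB} = 100$ s⁻¹ per
molecule; bound ParA-ATP is hydrolyzed at $k_B = 68.5$ s⁻¹ per molecule
into cytoplasmic ParA-ADP; maturation runs at $k_W = 1/15$ s⁻¹ and
nucleoid binding at $k_{on} = 50$ s⁻¹ to a uniformly random site. A
spontaneous-hydrolysis channel $k_{off}$ exists but defaults to zero (it
does not change the behaviour). Mobile ParA-ATP passes freely through
plasmid-occupied sites in this model, and multiple plasmids may share a
site (duplication requires it); they bind ParA independently. The standard
initial condition places a quarter of total ParA as cytoplasmic ParA-ADP,
11 ParA-ATP pre-bound per plasmid (initial anchoring), and the rest
uniformly at random on the nucleoid.

`duplication_assay()` measures how far daughters separate: each replicate
relaxes a single mid-nucleoid plasmid on a fixed 3 µm nucleoid for 60 s
(long enough for the local ParA depletion zone around the anchored plasmid
to form), duplicates it, and records the maximal additional inter-plasmid
separation within a 20 s window (sampled every 0.5 s). The headline
statistic is the fraction of replicates reaching 0.8 µm. The assay
geometry (3 µm, mid-nucleoid start) is a package choice logged in the run
configuration; separation is measured from the duplication instant.

# The directed-motion polymer model

Thin 2d strip lattice ($dx = 5$ nm; strip width $S$ = 30 nm short-polymer
/ 25 nm long-polymer, i.e. 6 or 5 rows). Mobile ParA-ATP hops 4-ways at
$D_A/dx^2$ ($D_A = 1$ µm²/s). Two mobile molecules on long-axis-adjacent
sites of one row nucleate an immobile polymer of two subunits at $k_p$;
elongation adds a mobile molecule sitting immediately beyond a tip (same
row, long axis only) at $k_p$; each subunit depolymerizes back to mobile
at $k_{dp}$. Short polymers use $k_p = 800$ s⁻¹, $k_{dp} = 10$ s⁻¹; long
polymers $10^6$ and $10^{-4}$. The plasmid occupies one full-width column,
hops at $D_P/dx^2$ ($D_P = 3\times10^{-4}$ µm²/s, the experimentally
bounded value) only when no polymeric subunit occupies its own or either
adjacent column (otherwise it is tethered), and is stepped onto an
adjacent column at $k_{dm} = 0.8$ s⁻¹ per polymeric subunit there, each
step consuming that subunit to cytoplasmic ParA-ADP — a burnt-bridge-like
retraction-following motion. Polymeric and mobile ParA-ATP in a plasmid
column are hydrolyzed at $k_B = 68.5$ s⁻¹ and $k_{mB} = 40$ s⁻¹
respectively ($k_B \gg k_{dm}$ so a column is cleared before the plasmid
moves on).

**Hard-wall semantics.** In the wild type a plasmid column is a hard wall
to mobile ParA-ATP: molecules may hop *into* the column — where the
ParB-*parC* complex hydrolyzes them — but not out, so nothing diffuses
past and the plasmid is the dominant ParA sink, as the gradient analysis
requires. This is the reading under which equal spacing emerges; making
the column fully impenetrable removes the sink, and free two-way passage
lets ParA equilibrate around the plasmid, and both abolish positioning.
In the perturbed-nucleoid variants (`dm_variant_params("perturbed_*")`),
which emulate a disordered nucleoid, the wall is off: boundary hops run in
both directions at 10% (short) or 100% (long) of the normal rate, and
$k_{mB}$ drops ten-fold to 4 s⁻¹ so ParA can pass without being
hydrolyzed; the perturbed-long variant narrows the strip to 10 nm.

**Polymer bookkeeping.** Depolymerization of an interior subunit splits a
polymer; since polymers have at least two subunits by the nucleation
definition, a surviving isolated subunit is reclassified as mobile at its
site. Directed steps may move a plasmid onto another plasmid's column
(daughters can colocalize after duplication), and no rate-sharing rule is
applied when two plasmids flank one subunit.

`model_asymmetry_series()` reproduces the asymmetry readout applied to
microscopy data: per 5 s sample, nucleoid-bound ParA strictly left/right
of the plasmid divided by the side length gives densities $I_L, I_R$;
cytoplasmic ParA is uniformly distributed and so adds equally to both
densities (effectively only raising the denominator); the reported series
is $|I_L - I_R|/(I_L + I_R)$.

# Desk-scale (coarsened) simulation conditions

The full-resolution models (dx = 5 nm, 2400 ParA dimers per µm) cost on
the order of $10^{11}$ events per cell cycle and are impractical for
routine runs, so the simulators expose a `coarse` factor: site size
becomes `coarse * dx`, hop rates rescale automatically through $D/dx^2$,
and the strip collapses to `round(S/dx)` rows (one row at the desk
scales). Coarsening interacts with copy number: polymeric occupancy is 0/1
per site, so a coarsened lattice at full density saturates with polymer
and the flux competition that drives positioning disappears into a
uniformly polymerized sea. The positioning regime requires the
nucleoid-bound inventory to be an order-one fraction of lattice sites.
The package's standard desk conditions are therefore:

* directed-motion runs: `coarse = 6` (30 nm sites) at 300 dimers/µm —
  equal spacing, mid-nucleoid repositioning from an edge start, quarter
  positions for two plasmids and the spacing-versus-length slope of 0.5
  all hold there, as the test suite verifies;
* diffusion/immobilization runs: `coarse = 10` (50 nm sites) at the full
  2400 dimers/µm (this model has no occupancy cap, so density can stay at
  its measured value).

These are scaled-down study conditions, not calibrated fits: copy-number
noise is larger than at full scale, and quantities tied to absolute
molecule counts (e.g. polymer subunit counts per structure) are reported
in coarse-lattice units. The acceptance computations average 16 seeds per
condition, 1200 s per run with a 300 s burn-in for the spacing slope, and
120 duplication replicates for the separation assay; replication was sized
so the Monte-Carlo error of the slope estimate (seed-to-seed spread) is
well inside its stated tolerance.

# Trajectory statistics

`compute_msd()` pools every overlapping-window planar squared displacement
at each lag across all foci and cells (each trajectory contributes many
short lags, so short-lag means are precise); pairs spanning missing frames
still count at their actual lag. `fit_subdiffusion()` fits

$$ \langle r^2(\tau) \rangle = 4 D \tau^{\alpha} + \beta $$

by Levenberg-Marquardt least squares with weights $1/\mathrm{SEM}^2$
(residuals scaled by $1/\mathrm{SEM}(\tau)$), excluding $\tau = 0$. The
planar prefactor is fixed at 4 and $\beta$ is *not* multiplied by it:
$\beta$ absorbs the static localization error, since an i.i.d. error of
variance $\sigma^2$ per coordinate inflates the planar MSD by $4\sigma^2$
uniformly in $\tau$ (the cross term averages away); $\alpha$ is invariant
to the prefactor convention. Starting values come from the end-to-end
log-log slope. Note the overlapping-window SEMs understate the error of
*differences* between lags (displacements are correlated); the package's
own tests therefore validate diffusion laws on independent,
non-overlapping windows.

`required_diffusivity()` encodes the one-line screening argument: a
displacement $d$ within time $t$ under free 1d diffusion needs
$D \ge d^2 / 2t$; 3-4 µm in 10 min gives $D$ of order $10^{-2}$ µm²/s,
two orders above the measured subdiffusive bound, which is what rules out
a diffusion/immobilization transport step for the observed rapid
segregation.

`detect_segregation_events()` scans per-cell focus pairs for the rapid
segregation definition — initial separation at most 0.3 µm (merged foci
count as zero), an additional 0.8 µm of separation within 20 s (60 s in
the relaxed variant) — reporting at most one event per pair at its
earliest qualifying start. `max_msd_resampling_test()` compares the mean
per-trajectory maximal squared displacement of an event set against
equally sized uniform draws (without replacement) from the full dataset,
with the add-one empirical p-value $(1 + \#\{null \ge obs\})/(1 + n)$ so
p is never zero. The per-trajectory maxima are exposed alongside, since
"larger maximal MSDs" could also be read per trajectory.

# Localization statistics

Nucleoid edges are the outermost half-maximum crossings of the linear
profile, linearly interpolated between bracketing samples; nucleoid length
is their separation and the number of above-half runs is reported for
post-replication two-lobed nucleoids. Focus positions are normalized to
the edge interval, sorted and rank-labeled $1..n_p$ — the same labeling
applied to `random_position_null()`, whose label-$k$ distribution is the
$k$-th uniform order statistic with mean $k/(n_p+1)$: rank labeling alone
creates apparent spatial order, which is exactly the null this function
documents.

The asymmetry measure integrates intensity from each pole to the focus
(trapezoidal, per unit length, so it is sampling-density independent and
exactly zero for a uniform profile) and reports
$|I_L - I_R|/(I_L + I_R) \in [0,1]$, invariant under intensity scaling. A
focus at a pole is rejected (zero side length). `mind_reference()`
generates the comparison distribution for a pole-to-pole oscillator:
asymmetry $= a\,|\sin t|$ with phases uniform over one period and
amplitude 0.6 by default (large-cell value), giving mean $2a/\pi$; the
absolute value is taken because the asymmetry statistic is nonnegative by
definition.

`select_focus_planes()` picks the 9 consecutive z planes maximizing the
summed per-plane maximum intensity (ties to the lowest start), which
handles per-cell focus differences and z misalignment automatically.
`first_harmonic_score()` anchors a half-sine of amplitude $I_{max}(z)$
between the per-plane half-maximum edges and averages the squared
residual normalized to the cell-wide maximum; normalizing the residual
*before* squaring follows the stated normalization to $I_{maxcell}$, and
the amplitude choice makes the score depend on shape, not expression
level. Because the anchors sit at half-maximum positions (where any real
profile is at half its peak while the harmonic is zero), even an exactly
half-sine-shaped profile retains a small edge residual (~0.04); the score
separates shape classes — a flat plateau scores $1.5 - 4/\pi \approx
0.23$ and helically modulated profiles more — rather than attaining an
absolute zero. Degenerate planes (coincident edges, empty planes) are
skipped with a warning.

`colocalize()` computes per-cell Pearson correlation over all grid points
(undefined and flagged for a zero-variance channel) and Manders overlap
curves: $M_A(T)$ is the fraction of channel A's intensity where channel
B, normalized to its own cell maximum, exceeds $T$, and symmetrically
$M_B$; $M(0) = 1$ by construction and both curves are non-increasing in
$T$. Summaries across cells (mean, SEM) are left to the caller, matching
the per-cell definitions.

# Synthetic data

`generate_fbm_tracks()` synthesizes planar fractional Brownian motion by
circulant embedding (Davies-Harte), which is covariance-exact — the
recovery tests need unbiased generation, so approximate kernels were not
an option. Each coordinate has Hurst exponent $\alpha/2$ scaled so the
ensemble planar MSD is $4 D \tau^{\alpha}$; optional reflecting
confinement folds coordinates into a box (an approximation: folding
distorts the fBm increment correlations near the walls), then N(0, σ²)
localization noise is added per coordinate and positions are rounded to
the 0.066 µm pixel grid. Defaults are the combined-dataset scales
($\alpha = 0.73$, $D = 9.7\times10^{-4}$ µm² s⁻ᵅ, σ = 0.02 µm, the value
whose $4\sigma^2$ matches the fitted static offset).

`generate_cell_stack()` emulates the two-channel per-cell image input: a
nucleoid channel with a flat or half-sine envelope between the nucleoid
edges, optionally helically modulated as
$1 + a \cos(2\pi x/\lambda + \phi(z))$ with phase advancing across planes
(the minimal structure the first-harmonic score must distinguish from a
smooth nucleoid); a second channel nested inside the nucleoid support
with a tunable mixing weight toward the first channel's shape; Gaussian
punctate foci; z attenuation outside a designated in-focus band; and
scaled-Poisson noise plus a baseline. Ground truth (edges, foci, band) is
returned with every stack. The generators are seed-deterministic.

What the generators do *not* emulate: photophysics (bleaching, blinking),
cell segmentation errors, drift beyond i.i.d. localization noise,
anisotropic PSFs, and the glassy heterogeneity of real cytoplasm. Passing
recovery tests on these fixtures therefore validates the estimators'
correctness, not their robustness to every real-data artifact.

# Known limitations

* The exact finite-hydrolysis closed form of the gradient model is
  asserted only through its absorbing limit and flux balance; the point
  sink is the minimal reading consistent with both.
* The discrete hard-wall semantics of the directed-motion model cannot be
  pinned down uniquely from the verbal model description; the implemented
  trap reading is the one that preserves the sink property the analytic
  model requires (see above).
* Desk-scale runs trade copy number and lattice resolution for speed;
  absolute molecule-count observables are not comparable to full-scale
  values, only the geometric/positional observables are.
* Subdiffusion is fitted, never mechanistically discriminated (fBm vs
  CTRW vs confinement) — the statistics deliberately stop at the
  exponent, coefficient and offset.
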