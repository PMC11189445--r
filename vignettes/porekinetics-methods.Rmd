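---
title: "Methods: pore profiling, permeation kinetics and gating analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pore profiling, permeation kinetics and gating analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porekinetics)
```

porekinetics quantifies how a cation channel's pore geometry, ion
permeation kinetics, solvation environment and helix conformations change
between gating states, and fits the voltage dependence of activation.
This vignette documents the models and conventions behind each stage, the
parameters that matter, and what the synthetic ground-truth generators do
and do not establish about real data.

## The pore-aligned frame

All axial quantities are expressed in a frame anchored at the
mass-weighted centre of the bundle-crossing lower gate — by default the
heavy atoms of residues 394–398, set at Z = 0 Å — with +z pointing toward
the selectivity filter (residues 358–361), i.e. the extracellular side.
Masses are standard atomic masses; hydrogens are excluded by the default
selections because cryo-EM coordinate models rarely include them (the
gate centroid is switchable to Cα-only via the selection expression).
As a robustness check the frame also computes the principal axis of the
combined gate+filter selection; a deviation above 5° from the
centroid-difference axis raises a warning, since for a roughly
four-fold-symmetric channel the two should agree closely.

Residue numbers are always the author numbering of the deposited model;
nothing is renumbered.  Alternate conformers are collapsed to the
highest-occupancy copy, ties keeping the first listed — a deterministic
rule, so repeated reads give identical models.

## Inscribed-sphere pore profiling

At each z-slice the profiler reports the radius of the largest sphere
centred in the slice plane that touches no atom,

$$ r(z) \;=\; \max_{c \,\in\, \text{plane}} \; \min_i \left( \lVert c - x_i \rVert - R_i \right), $$

the solvent-accessible pathway convention: a reported "diameter" is twice
this inscribed radius, not an atom-centre distance.  The maximization
uses simulated annealing (default 2000 steps, geometric cooling 0.995,
fixed seed 0, all echoed in output metadata), seeded from the previous
slice's centre while marching outward from the gate plane in both
directions.  Two numerical safeguards matter:

* the probe centre may move at most `max_shift` (2.5 Å) from the previous
  slice's centre.  Without this, the objective rises again *outside* the
  channel wall, and a stochastic search can tunnel through the
  single-atom-thick shell of a narrow constriction and report bulk
  solvent.  The constraint also enforces continuity of the centre path.
* slices with no atoms within 15 Å are reported capped at `max_radius`
  (15 Å) and flagged unconverged — these are bulk solvent, not pore.

Every reported radius is a *certificate*: re-evaluating
$\min_i(\lVert c-x_i\rVert - R_i)$ at the reported centre reproduces it
exactly, which the test suite checks slice by slice.  On ring-built
fixtures with analytically known profiles the annealed profile agrees
with the closed form to better than 0.01 Å, and it can only improve on a
0.05 Å grid search up to that tolerance.

Atomic radii default to the classic simple profiling set (C 1.85, N 1.75,
O 1.65, S 2.00, P 2.10, H 1.00 Å); an Amber-flavoured alternative
(Rmin/2 values) ships alongside because sub-Ångström constriction
diameters depend on the set, and the set name is recorded in the profile
metadata.  Per-residue gate diameters take the nearest local constriction
within ±2 Å of the residue's side-chain centroid projection — a window
chosen to tolerate the axial spread of a rotameric ring of side chains;
it is configurable.

## Ion permeation counting and conductance

Ion trajectories are unwrapped along z per ion (no frame-to-frame jump
may exceed half the box) *before* projection into the pore frame;
otherwise periodic re-imaging aliases a single traversal into spurious
back-and-forth crossings.  When a topology is present the gate centre of
mass is recomputed per frame so the z = 0 anchor co-moves with the
channel.

Complete permeation events are counted by a three-compartment state
machine (above / inside / below the pore).  The outer thresholds default
to ±18 Å — the approximate membrane interfaces — with a 2 Å hysteresis:
entering the pore requires crossing the threshold offset inward, leaving
uses the outer threshold.  This makes the count invariant to jitter
smaller than half the hysteresis, which the tests exercise.  Only full
traversals from one outer compartment to the other count; re-entries and
traversals still in progress at the trace end count nothing.  Time
reversal of a trace preserves the count and flips every direction.  For
periodic Brownian-dynamics traces the compartments are tiled every domain
length along the unwrapped coordinate.

Conductance is \(g = N e / (T\,|V|)\) per replica with \(e\) the
elementary charge; the worked example — events {5, 4, 6} over 500 ns at
500 mV — gives per-replica 3.204, 2.563, 3.845 pS and mean 3.20 pS.  The
replicate spread defaults to the *population* standard deviation
(0.52 pS for the example) because that convention reproduces the
customary "±0.5" rounding for three replicas; sample SD (0.64) and SEM
(0.37) are available, and the convention is always echoed in the output
since published "±" values rarely name theirs.

## Free energy, hydration, coordination, hydrogen bonds

The axial potential of mean force is the Boltzmann inversion
\(F(z) = -kT\,\ln(\rho(z)/\rho_{\mathrm{ref}})\) of the binned in-cylinder
ion density, with \(kT = 0.5922\) kcal/mol at 298 K and F averaged to
zero over a stated reference window.  Empty bins are masked, never
imputed, and the reference cancels any multiplicative rescaling of the
density exactly.  By default no applied-field correction is made — the
direct inversion of applied-field data is the common practice this
mirrors — but a linear correction \(qV(z-z_{\mathrm{ref}})/\mathrm{span}\)
is available, because a field-tilted inversion is not an equilibrium free
energy and the uncorrected profile should be read as an effective
landscape under bias.

Hydration profiles count water oxygens (HOH/WAT/TIP3/SOL/SPC residue
conventions) inside a 12 Å axial cylinder per z-bin; a bin whose mean
count falls below 1 is flagged dry, expressing transient
wetting/dewetting.  Coordination numbers use a 3.5 Å K–O first-shell
cutoff, near the first maximum–minimum structure of the K–water RDF; the
"waters lost" at a site is the bulk-window mean minus the site-window
mean.  Hydrogen bonds use the common geometric criterion — donor–acceptor
heavy-atom distance ≤ 3.5 Å and D–H⋯A angle ≥ 150° when the hydrogen is
present, distance-only (with a warning) when it is not.  Each bond is
credited to both partner groups, so a closed ring of four mutually
donating hydroxyls averages 2.0 bonds per side chain (1 donated + 1
accepted).  Because published per-side-chain bond counts depend strongly
on the unstated criterion behind them, ours is a documented convention,
not an attempt to reproduce any particular printed value.

## Conformational metrics

Superposition is the Kabsch SVD construction with uniform weights and a
proper rotation; atoms pair by (chain, resid, name) and mismatches are
an error naming the offenders.  Trajectory RMSD/RMSF default to aligning
on the transmembrane backbone ranges 140–166, 173–195, 209–242, 253–287,
297–324 and 369–401; RMSF uses a two-pass mean/variance (a one-pass sum
of squares loses precision catastrophically for near-static
coordinates), and per-atom values are additionally averaged across
symmetry-equivalent chains by (resid, name).

Helix segment axes come from the least-variance direction of the
*second differences* of consecutive Cα positions: for a regular helix the
axial rise is linear in residue index, so second differences lie exactly
in the plane perpendicular to the axis.  This estimator is insensitive
to partial turns, which bias a raw PCA of the Cα cloud by several
degrees for 10–15-residue segments; it recovers generator bends to well
under 1° and is invariant under rigid motion and uniform scaling.  The
segment split for a bend measurement is the caller's choice (there is no
automatic kink detection); the generator returns suitable segments with
its ground truth.

Helicity is assigned per residue: an α hydrogen bond
(O(i)⋯N(i+4) or O(i−4)⋯N(i) ≤ 3.5 Å) *and* φ ∈ [−100°, −30°] *and*
ψ ∈ [−80°, −5°]; residues missing a criterion (chain termini) are judged
on the rest, and residues missing backbone atoms are marked
indeterminate and excluded from runs.  Using either of the i±4 bonds
keeps residues near a helix's last intact turn helical, so a generated
k-residue extended tail is recovered as exactly k non-helical residues
(a 7-residue tail ≈ 1.94 helical turns at 3.6 residues/turn).

## The activation-curve fit

Normalized tail-current conductances are fitted to the single Boltzmann
\(G/G_{\max} = 1/(1+\exp((V-V_{1/2})/k))\) by Levenberg–Marquardt least
squares, with \(G_{\max}\) fixed at 1 after normalization (a free
amplitude is available for raw tails).  Auto-initialisation takes
\(V_{1/2}\) as the voltage nearest G = 0.5 and k = 8 mV.  On the
standard −20 to −110 mV (10 mV decrement) grid the fit recovers noiseless
parameters exactly, is equivariant under voltage-axis shifts, and shows
a \(V_{1/2}\) bias below 0.05 mV under 2% Gaussian noise.

## What the synthetic generators emulate — and what they do not

Every analysis stage has a generator returning data *plus* its ground
truth:

* **Ring pores** place ≥12 pseudo-atoms per ring (sparser rings are
  refused) so the inscribed radius with an axial centre is exactly
  \(\min_k \sqrt{R_k^2+(z-z_k)^2} - r_{\mathrm{atom}}\); at a ring plane
  this is \(R_k - r_{\mathrm{atom}}\).
* **Brownian ion traces** integrate overdamped Langevin dynamics
  \(z \leftarrow z + (D F/kT)\,dt + \sqrt{2 D dt}\,\eta\) on a periodic
  domain, with the field force \(qV/\mathrm{span}\) applied inside the
  membrane span and an optional piecewise-linear potential.  Defaults
  mirror an applied-field permeation design: −500 mV, 500 ns, a
  ~36 Å span in a 140 Å domain, 298 K, and D = 196 Å²/ns (bulk K⁺ — a
  documented stand-in, not a fitted value).  500 mV across the span
  corresponds to 11.53 kcal/mol for a +1e ion.  The integrator refuses
  time steps above \(0.01\,\mathrm{span}^2/D\).  The returned
  drift-based crossing expectation \(\bar v T/L\) (with
  \(\bar v = D q V \,/\, kT L\), the in-span drift averaged over the
  domain) is exact only when the force is (nearly) uniform over the
  domain or weak compared to kT; with a strong field confined to a
  sub-span, transport becomes diffusion-limited outside the field region
  and falls below the naive average — so the flux-recovery checks use a
  field spanning essentially the whole domain, the regime the closed
  form describes, and compare the *net* (inward minus outward) detected
  crossings.  Ions are non-interacting: multi-ion filter correlations
  are an analysis target, never a generator feature.
* **Kinked helices** are built by natural-extension placement with
  standard backbone geometry (φ = −57°, ψ = −47°, ω = 180°; extended
  tails at φ = −120°, ψ = 130°), the post-kink segment rigidly rotated
  by the requested bend about an axis perpendicular to the pre-kink axis.
* **Solvation snapshots** place an exact number of first-shell water
  oxygens on a Fibonacci sphere, the remaining cylinder waters outside
  the shell, and decoys outside the cylinder.
* **Activation curves** evaluate the Boltzmann with Gaussian noise
  clipped to [−0.05, 1.05].

All generators are bit-reproducible under a fixed seed.  Passing the
recovery checks demonstrates that each estimator is *correct on data
obeying its model assumptions*; it does not establish accuracy on real
membrane simulations, where ions interact with protein, lipid and each
other, water is explicit, sampling is far from exhaustive, and the true
landscape is unknown.  In particular, absolute conductances and barrier
heights from real applied-field trajectories carry sampling and
finite-size uncertainties these fixtures cannot emulate.

## Problem sizes and numerical choices

The recovery studies use sizes chosen to make Monte-Carlo error small
relative to each tolerance: 20 independent Brownian simulations of
2 × 500 ns for flux recovery (2 SE ≈ 1 crossing against means near 38);
10⁶ Metropolis samples (proposal SD 3 Å, thinning 2 — settings picked
for chain mixing) for barrier recovery within 0.1 kcal/mol; 10⁴ frames
for the RMSF closed form within 2%; 100 noisy curves for the
\(V_{1/2}\) bias bound of 0.5 mV.  Slice steps default to 0.25 Å.
Degenerate inputs fail loudly rather than silently: empty models,
unstable time steps, flat activation data, sub-minimum helix segments
and all-masked densities are errors, and degenerate residue ranges or
unknown chains warn and select nothing.

## Known limitations

* The deposited-model checks (gate diameters of the Closed/Intermediate/
  Open structures) need the user to supply the coordinate files; they are
  not redistributed.  Sub-Ångström agreement depends on the radius set,
  which is why both sets are reported.
* No explicit-solvent or membrane simulation is performed anywhere; the
  Brownian generator abstracts the applied-field design only.
* Trajectory input covers DCD, multi-model PDB, multi-frame GRO and a
  plain-text ion-trace TSV dialect; compressed XTC is not decoded.
* Secondary structure beyond the α-helix criterion, automatic kink
  detection, WHAM/umbrella estimators and map-level (MRC) data are out
  of scope.
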