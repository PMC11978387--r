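---
title: "Post-docking analytics for antibody-antigen complexes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-docking analytics for antibody-antigen complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

Antibody-antigen docking pipelines produce large pose sets whose native
scoring functions discriminate good from bad models poorly. This package
implements the analytics that sit *after* pose generation: standardizing
model confidences into comparable certainty values, deriving ipTM from
aligned-error probability distributions, combining confidence and physics
scores into an equal-weight composite for re-ranking, scoring poses against
native complexes with DockQ, characterizing interfaces (accessibility-based
region classes, stickiness, packing density, surface complementarity), and
the evaluation machinery (top-N success rates, bootstrap intervals,
success/failure discriminants). It deliberately does not run any modeling,
docking or neural-network inference.

## Model certainty

AI-guided antibody modeling tools report a per-model predicted error (or a
B-factor-style confidence). Errors from different tools live on different
scales, so each tool's errors are pooled across all systems and z-scored
with the **population** standard deviation (divide by *n*); the sign is then
flipped so that a smaller predicted error means a larger certainty:

$$\mathrm{certainty} = -\frac{e - \bar e}{\sigma_e}.$$

The population-sd convention (rather than the sample *n − 1* form) is fixed
and documented so every downstream threshold is deterministic; with it, a
self-standardized population has mean 0 and sd 1 to machine precision.
`certainty_by_tool()` enforces the per-tool pooling — certainties from
different tools are never standardized together, because their error scales
are incommensurable. Tools that report no confidence cannot be assigned a
certainty and must be excluded upstream.

## ipTM from aligned-error probabilities

Single-chain predictor checkpoints do not emit ipTM directly, but it can be
computed from the binned aligned-error probabilities. For residues $i, j$
and error bins with centers $b_k$:

$$\mathrm{pTM} = \max_i \; \mathrm{mean}_{j \in M} \sum_k p_{ijk}
\frac{1}{1 + (b_k / d_0(N))^2},$$

where the mask $M$ is either all pairs (pTM) or only cross-chain pairs
(ipTM), and $d_0(N) = \max\{1.24 (N - 15)^{1/3} - 1.8,\; 1\}$ is the usual
TM-score normalization. Two choices here were genuinely open:

* **Residue scope for $d_0$.** We use the full complex length $N$ (not the
  interface size); this matches how TM-type scores are normally normalized
  and keeps the score independent of the interface definition.
* **Point-estimate PAE input.** Confidence JSON that carries only a PAE
  matrix (no probability bins) is accepted by treating each value as a
  delta distribution on its nearest default bin (0.5-Å bins, centers 0.25
  to 31.75). This is exact when the matrix was itself produced by taking
  binned expectations of sharp distributions, and a documented
  approximation otherwise.

The implementation collapses the bin axis with one matrix product; tests
hold it to an explicit triple-loop reference within 1e-9.

## The equal-weight composite

Poses are re-ranked by

$$\mathrm{composite} = Z_{\mathrm{pLDDT}} + Z_{\mathrm{pTM}} +
Z_{\mathrm{ipTM}} + Z_{\mathrm{phys}},$$

with each raw metric standardized across the pose population of one
antibody-antigen system. Equal weights are a deliberate guard against
overfitting; no renormalization is applied. Details that the formula leaves
open, and the choices made:

* **Physics-score orientation.** Engines disagree on sign conventions
  (energies: lower is better; shape scores: higher is better). A per-engine
  flag orients the raw score before standardization so a favorable score
  always maps to a positive z; defaults are lower-is-better for `propose`,
  higher-is-better for `zdock`.
* **Standardization scope.** Physics scores are standardized per engine by
  default (pooling across engines must be requested explicitly), because
  engine score scales are unrelated.
* **Zero-spread metrics.** If every pose shares one value of a metric, that
  metric carries no ranking information and contributes z = 0 rather than
  raising a degenerate-population error; rescoring an all-identical pose
  set then falls through to the tie-break.
* **Tie-breaking.** Descending total, then descending $Z_{\mathrm{ipTM}}$
  (the interface-weighted term), then pose id — fully deterministic.

Standardization makes the ranking invariant to shifting any raw metric by a
constant, which the tests exercise directly.

## DockQ scoring

Pose quality against the native complex uses the standard DockQ
combination

$$\mathrm{DockQ} = \tfrac13\left(f_{nat} +
\frac{1}{1 + (i\mathrm{RMS}/1.5)^2} +
\frac{1}{1 + (L\mathrm{RMS}/8.5)^2}\right)$$

with the published constants: 5 Å heavy-atom cutoff for native contacts,
10 Å for the interface-residue set, backbone = N, CA, C, O. The antibody is
the receptor and the antigen the ligand for LRMS (the antigen is the rigid
mobile body in the docking protocol this package serves); multi-chain
antigens are treated as one body. Class thresholds are application-driven:
acceptable (≥ 0.23, sufficient for epitope mapping), medium (≥ 0.49, the
bar for antibody design), high (≥ 0.80). Residues are corresponded across
models by (chain role, author residue number, insertion code) — models of
the same molecule share numbering, and no sequence alignment is attempted.

## Superposition and ensemble diagnostics

Superposition is closed-form least squares (Kabsch via SVD) with a
reflection guard, fitted by default on framework backbone atoms.
Framework/CDR partitions come from fixed Chothia-style windows (H1 26-32,
H2 52-56, H3 95-102; L1 24-34, L2 50-56, L3 89-97) with the scheme exposed
as a parameter — derived quantities such as H3 length and the per-region
ensemble RMSDs depend on it, and no claim is made that these windows match
any particular external annotation run. The ensemble report computes
free-RMSD as the mean over all unordered model pairs per region, bound-RMSD
per model against a bound reference, and the per-region minimum as best
bound-RMSD; region RMSDs are measured *without refitting* after the
framework fit, so they reflect genuine loop displacement.

## The interface property panel

**SASA.** Shrake-Rupley sphere sampling with a deterministic golden-spiral
point set (960 points/atom by default, probe 1.4 Å, Bondi radii).
Determinism was preferred over random resampling so that every downstream
threshold (notably "ΔSA > 0") is reproducible bit-for-bit; the fixed
global orientation of the point lattice means areas are exact under
translation and wobble by up to a few percent under rotation, which is the
quadrature anisotropy, not noise. Closed-form single-sphere and two-sphere
references hold to ≤ 1% at 960 points.

**Region classes.** Relative accessibility (rSA) is area divided by a
fully-exposed Gly-X-Gly reference (Tien et al. 2013 theoretical values,
shipped as a versioned CSV). Each residue is classified from its complexed
and uncomplexed rSA: interior and surface for residues whose area does not
change on binding (below/above 25%), and support, rim, core for residues
that lose area. Three boundary rules had to be fixed: burial is tested on
raw area with a 1e-6 Å² tolerance (absorbing quadrature noise); a residue
at exactly 25% with no burial is surface, with burial rim; and a residue
meeting both the support and core conditions is core, core being the more
specific refinement. Each side is classified against its own uncomplexed
state, obtained by rigid separation.

**Stickiness.** Per-region sums of the 20-residue interface-propensity
scale of Levy (2012), shipped as CSV; duplicated residues count each time,
and sums are additive over disjoint regions by construction.

**Global density (GD).** The covariance eigenvalues of the interface atom
cloud define an equivalent uniform ellipsoid (semi-axis
$a_i = \sqrt{5\lambda_i}$); GD divides the atom count by the area of the
ellipse of the two largest axes, $N / (\pi a b)$. The originating
description mentions an ellipsoid *volume* but divides by an ellipse
*area*; we implement the printed division rule and expose the
atoms-per-volume variant behind `mode = "volume"`. GD is exactly invariant
to rigid transforms and obeys the $s^{-2}$ coordinate-scaling law, both
asserted to 1e-9. A uniform filled disk gives $N / (\pi R^2 \cdot 5/4)$
under this convention, which the Monte-Carlo oracle reproduces.

**Surface complementarity (SC).** Each side's surface is tessellated as a
dot surface over its interface atoms: accessibility is decided with the
probe-expanded sphere (a solvent test), but the element itself sits on the
vdW sphere — a contact surface. This matters: solvent-accessible surfaces
of two touching sides interpenetrate by up to two probe radii, destroying
the local facing geometry, while contact surfaces meet. Every element is
paired with its nearest opposing element and scored by the anti-alignment
of outward normals, $-(\hat n_a \cdot \hat n_b)$, weighted by element area
times a Gaussian distance decay with half-maximum at 1.0 Å; the index is
the decayed-area-weighted mean averaged over both sides, bounded in
[−1, 1]. Normalizing by the *decayed* area means back-facing patches (far
from the partner) barely dilute the index. All constants are arguments.
This is a self-contained index for comparing interfaces within this
package; it does not aim to reproduce any specific external SC program's
numbers.

## Benchmark machinery

`enumerate_manifest()` is plain arithmetic over the run dimensions and is
the source of the pose budgets (81 systems × 3 tools × 4 models × 2
engines × 100 poses = 194,400; one tool's ensembles on one engine =
32,400; the template-free budget of 5 seeds × 5 models = 25).
Ambiguities resolved in the evaluation layer:

* **Bootstrap.** 200 iterations by default, resampling the per-unit
  success indicators with replacement; the reported interval is the 2.5-97.5
  percentile interval (the underlying "error bar" definition was not
  fixed by the protocol this mirrors). The resampling unit is whatever
  indicator vector the caller passes — models or systems — since the
  stratification was left open.
* **Discriminants.** Success-vs-failure comparisons use the Welch
  (unequal-variance) two-sample t-test and a Cohen's-d style pooled-sd
  standardized difference; stars encode p < .05 / .01 / .001. Groups with
  fewer than two members skip the property with a warning rather than
  fabricating a p-value.
* **Confidence-guided selection.** `certainty_filter()` drops models below
  a certainty threshold; systems losing all models leave the denominator,
  which is precisely the mechanism that lets the success rate over
  *remaining* systems rise with stringency. A minimum representation of 5%
  of systems flags data points for suppression, avoiding abrupt
  small-sample artifacts. `threshold_sweep()` packages the whole curve.

## The synthetic generator

Every test input is generated in code. The toy complex is an idealized
extended backbone (3.8 Å CA spacing, N/C/O plus a CB pseudo-side-chain)
with contacts engineered by pointing the CB atoms of designated residues
across the chain gap; exactly `interface_size` residue pairs touch within
`contact_distance`, the heavy chain carries a Chothia-numbered H3 window
(insertions at 100 for lengths above 8), and a ≤ 0.05 Å seeded jitter
breaks exact degeneracies while leaving ≥ 0.3 Å of margin around every
contact decision. Decoys rigidly rotate and translate the antigen on a
graded schedule spanning all four DockQ classes, with the true DockQ of
each decoy recorded by the quality module itself. Confidence bundles draw
each metric as a deterministic monotone link of an effective quality
$\rho q + (1-\rho) u$ with independent uniform noise $u$: at $\rho = 1$
every metric ranks poses exactly as true DockQ, at $\rho = 0$ metrics are
quality-independent. Truncated-Gaussian bin profiles keep every PAE row a
proper distribution.

What the toys do *not* emulate: real side-chain packing, loop closure,
realistic docking-score landscapes, or any particular engine's score
distribution. Passing tests therefore demonstrate the correctness and the
qualitative mechanisms of the analytics (e.g. that composite re-ranking
beats naive selection when confidence carries signal at ρ = 0.8, and that
certainty thresholding monotonically improves success on the retained
systems), not quantitative performance on crystallographic data.

## Problem sizes and determinism

The shipped checks run at desk scale by choice: toy complexes of ~40
residues, 100-decoy sets, 100 seeded re-ranking trials, 20-replicate
threshold sweeps over 30-system tables, 960-point SASA quadrature (480 for
the slab complementarity fixtures, 240 inside the panel's SC step). Every
stochastic operation takes an explicit seed, and the acceptance script
derives all of its streams from a single `--seed` argument, so runs are
exactly reproducible.

## Known limitations

* Chain-role heuristics expect `H`/`L` chain ids; anything else needs
  explicit `chain_roles`.
* Residue correspondence is numbering-based; renumbered models of the same
  molecule are out of scope by design.
* SASA under rotation is stable only to the quadrature anisotropy (a few
  percent at default density); increase `sphere_points` where tighter
  rotational stability matters.
* The SC index is package-internal; compare values only within one
  parameter set.
* The GD ellipse convention follows the printed division rule; the
  volume-based alternative is available but produces numbers on a
  different scale.
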