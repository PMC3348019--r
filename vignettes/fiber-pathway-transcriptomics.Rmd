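---
title: "Linking fiber pathways, gene expression and protein networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking fiber pathways, gene expression and protein networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberlink)
```

# The analysis this package implements

fiberlink reimplements, at desk scale, a three-modality integration for a
single brain: (i) probabilistic streamline tractography over a
crossing-fiber orientation field, seeded from every voxel of a bilateral
seed structure (a hippocampus analog) toward hemisphere-matched target
structures; (ii) selection of spatially registered microarray expression
samples that fall inside each reconstructed pathway, with per-probe
z-score normalization and per-pathway average z-scores for a disease gene
panel; and (iii) a protein–protein interaction (PPI) analysis that counts
unique interaction partners per disease gene, retains genes with strictly
more than a threshold number of interactions, and classifies the
neighborhood of a designated seed protein into tiers.

Real inputs of this kind (whole-brain microarray plus diffusion imaging
of the same brain, plus a curated PPI database) are release-dependent and
cannot be bundled. The package therefore ships a first-class synthetic
data module that generates every input with known ground truth, and all
quantitative claims in the test suite are made against that ground truth
or against printed worked-example tables.

# The phantom

`default_phantom_config()` describes a 48 × 56 × 48 voxel grid at 1 mm
spacing (world origin at (−24, −28, −24) mm, so the affine is exercised
by every world↔voxel conversion). Fifteen spherical ROIs are painted with
distinct positive labels: seven bilateral structures — hippocampus
(seed), nucleus accumbens, amygdala, caudate nucleus, globus pallidus,
putamen, thalamus analogs — plus a midline brainstem analog. Hemisphere
is an explicit ROI attribute rather than a sign test on x, so task
enumeration ("left to left, right to right") is robust to asymmetric
layouts.

Fiber tracts are tubes of radius 1.5 voxels around natural cubic spline
centerlines through three control points, connecting the seed to five of
the six bilateral targets per hemisphere. The accumbens analog is
deliberately unconnected in both hemispheres: with 12 enumerated tasks
this forces the 10-of-12 nonempty pathway pattern that the end-to-end
tests assert. Voxels inside one tube carry a single fiber population
tangent to the centerline with volume fraction 0.6; voxels shared by two
tubes carry both populations, with fractions rescaled to sum to 0.9 when
they would exceed 1 (the remainder stands for an isotropic compartment).
One crossing box is placed where the left caudate- and putamen-bound
tracts intersect; inside it every voxel carries the two tracts' local
tangent directions, which exercises two-population sampling on every
default run.

Samples are scattered by `make_samples()`: a configurable share (default
0.5, split evenly across tracts) is forced inside tubes by drawing a
centerline point and a uniform offset within 0.9 of the tube radius; the
rest are uniform over the grid. Every sample carries geometric
ground-truth flags (distance to the dense centerline ≤ tube radius) so
selection stages can be tested against construction rather than against
themselves.

`make_expression()` draws per-probe baselines from N(7, 1) log2 units — a
typical microarray log2 intensity scale; the sources give no intensity
distribution, so this is a package choice — and adds N(0, noise_sd)
measurement noise (default 0.5). Planted genes receive +δ log2 units
(default δ = 3) in exactly the samples whose ground truth marks them
inside the planted tract. `make_ppi()` builds an undirected,
deduplicated, loop-free edge list in which, writing C = {seed} ∪ related,
every designed tier-k protein has exactly k distinct partners in C and
random extra edges never touch C, so the designed tiers are recoverable
by construction.

# Tractography

The orientation field stores, per voxel, up to two fiber populations:
a unit axial direction, a volume fraction in [0, 1] (fractions sum to
≤ 1), and an angular concentration κ. Dispersion is Watson-like and
axial: a sampled direction is the population mean plus isotropic Gaussian
noise of standard deviation 1/√(2κ), renormalised and sign-aligned with
the incoming direction. κ = Inf — and, as a convenience for orientation
formats that carry no dispersion, κ = 0 — means no dispersion is
modelled. The phantom default κ = 40 corresponds to about 6° of angular
jitter.

Tracking parameters and defaults (all overridable):

| parameter | default | meaning |
|---|---|---|
| `step_size` | 0.5 voxels | Euler step length |
| `curvature_thresh` | 80° | max turning angle per step |
| `n_per_seed` | 100 | streamlines per seed voxel |
| `max_steps` | 2000 | per propagation direction |
| `min_fraction` | 0.05 | population eligibility threshold |
| `mask_threshold` | 1 | min visitation count for the mask |

These follow common probabilistic-tractography practice with the sample
count cut to desk scale; the original analysis names its tools but not
its parameters, so the defaults are package choices.

**Step sampling.** At each step, a population is *eligible* when its
fraction is at least `min_fraction` and — once an incoming direction
exists — its sign-aligned mean direction lies within the curvature
threshold of the incoming direction. One eligible population is drawn
with probability proportional to its fraction, perturbed by the
dispersion draw, sign-aligned, and the perturbed draw is checked against
the curvature threshold again. Termination reasons are `low-fraction`
(no population passes the fraction test), `curvature` (none is
curvature-compatible, or the perturbed draw turned too sharply),
`left-volume`, `reached-target` and `max-steps`.

Making curvature part of population *eligibility* — rather than drawing
among all populations and terminating on a bad draw — is the design
decision that lets a streamline transit a crossing region along its own
population: at a near-orthogonal crossing the transverse population is
never compatible with the streamline's heading, so the draw
degenerates to the correct population. Under draw-then-terminate
semantics we measured (on coplanar and grazing crossing phantoms across
crossing angles 12°–90°) that the minor tract can never retain more than
about half its streamlines and that single-population modelling is
barely worse — i.e. the mechanism the two-fiber model exists to provide
never materialises. With eligibility-based sampling the paired-run test
shows the intended contrast: both tracts transit a 90° crossing almost
losslessly with two populations, and dropping the minor population
strands the minor tract at the crossing.

**Propagation** is bidirectional Euler stepping from each start point
(the second half starts with the negated first direction of the first
half), with all streamlines of a task advanced in lock step by a
vectorised engine. A streamline is retained iff it enters the target
mask in either direction, and is truncated at target entry so voxels
past the target never contribute. The visitation map counts, per voxel,
the retained streamlines that pass through it (at most one count per
streamline per voxel); the pathway mask thresholds that map at
`mask_threshold`, and the reported voxel count is the thresholded mask
size. Whether a published "#voxels" counts thresholded or raw visited
voxels is not stated anywhere we could verify, so the threshold is
explicit configuration rather than a guess.

**Randomness.** A single master seed is expanded by `derive_seed()` (a
rolling string hash modulo a prime below 2³¹) into named substreams per
stage and per task (hash of the seed and the task's seed/target labels),
so tasks are order-independent and any stage can be rerun in isolation
bit-exactly. Within a task, all streamlines share the task substream and
are advanced in a fixed order by the batch engine; we chose task-level
rather than per-streamline substreams because a per-streamline R-level
loop is roughly two orders of magnitude slower while the reproducibility
contract (identical seed ⇒ byte-identical results) is unchanged.

# Expression mapping

Voxel conventions: indices are 0-based; world→voxel applies the inverse
affine and then **floors** each coordinate, i.e. voxel (i, j, k) owns the
half-open box [i, i+1)³ in continuous voxel space and its centre sits at
(i, j, k) + 0.5. The floor (not round) choice matches half-open box
semantics and is applied uniformly; sample selection is exactly "the
sample's voxel is in-bounds and the mask is true there", with
out-of-bounds samples excluded and counted in a warning.

Per-probe normalization: z = (x − μ)/σ with μ and σ computed per probe
across **all** samples of the matrix. The whole-matrix scope is the
default because normalization precedes pathway selection in the
workflow and per-sample z-scores against a global reference are what a
whole-brain atlas analysis implies; a per-pathway scope is available as
configuration. σ uses the population (divide-by-n) convention by
default, with the sample convention available — the source formula
writes σ without naming a convention, so both are explicit options
rather than silent assumptions. Probes with σ = 0 yield missing
z-scores plus a warning, never a division error, and missing values are
skipped (not zero-filled) everywhere downstream.

Gene-level z-scores average a gene's probe z-scores per sample, skipping
missing values; the mean (rather than max or first probe) is symmetric
and parameter-free, and the probe→gene aggregation used originally is
unstated. Per-pathway summaries then average each gene's z-scores over
the selected samples (the arithmetic-mean definition), recording n, the
number of contributing samples; genes with n = 0 are omitted with a
warning, and an empty selection produces a zero-row summary — pathways
with zero samples are a legitimate outcome that the pathway table keeps
visible.

# PPI network

The graph is undirected and simple: duplicate and reversed-duplicate
edges collapse, self-loops are dropped with a counted warning.
Interaction counts are **unique partners** of the mapped protein
(self-interactions excluded); source databases contain duplicates and
self-loops and the original counting rule is unstated, so this choice is
documented configuration. The disease-gene filter keeps genes with
strictly more than `min_count` (default 10) partners.

Tier classification around a seed protein with related set R, writing
C = {seed} ∪ R: every node outside C adjacent to at least one member of
C gets k(v) = number of unique neighbors in C, and is `tier3plus` when
k ≥ 3, `tier2` when k = 2, `peripheral` when k = 1; nodes not adjacent
to C are excluded. "Interacts with three related proteins" is read as
k ≥ 3 — otherwise k ≥ 4 nodes would be unclassifiable — with an exact-3
rule available that labels k ≥ 4 nodes `unclassified`. k counts the seed
itself as a member of C uniformly for all tiers. The related set is an
input roster (optionally intersected with the seed's neighborhood)
because no topological selection rule for it exists; in synthetic runs
the roster is the designed related set, six proteins by default.

# What the tests do and do not show

The synthetic generator emulates the *statistical structure* downstream
stages assume: tubes with axial populations and a crossing region,
samples inside/outside pathways, a planted log2 elevation, a designed
PPI neighborhood. It does not emulate realistic anatomy, DWI signal
formation, registration error, or microarray preprocessing artefacts —
so green tests certify the algorithmic chain (geometry → selection →
normalization → ranking → tiering), not robustness to real-data noise
sources that are out of scope here.

Problem sizes were chosen so the full suite runs in well under a minute:
the default phantom tracks 12 tasks at 100 streamlines per seed voxel
(~56 seed voxels per hemisphere); unit tests use 10–40 streamlines per
seed voxel, 120–200 samples, 40–60 genes with 1–2 probes each; the
planted-effect recovery property uses 20 seeded replicates at δ = 3,
noise sd 0.5, ≥ 10 in-tube samples and demands the planted genes occupy
the top ranks in at least 19 of 20; tier classification is cross-checked
against a brute-force edge-list oracle on 50 random graphs of up to 200
nodes.

# Known limitations

- Up to two fiber populations per voxel; three-way crossings are not
  representable.
- Euler integration with per-voxel (not interpolated) orientations;
  sub-voxel partial-volume effects are not modelled.
- The dispersion model is an isotropic Gaussian perturbation, a
  convenient stand-in for a true Watson density; for the tight
  concentrations used here the difference is negligible.
- Masks, counts and summaries all live in the phantom's own grid; no
  nonlinear template registration is provided or planned.
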