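---
title: "Colour-based neurite identification: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colour-based neurite identification: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qdyefinder)
```

## The problem

When many neurons are labelled simultaneously with a stochastic mixture of
up to seven spectrally distinct fluorescent proteins (XFPs), each neuron
acquires an essentially unique colour *hue* determined by the copy numbers
of the transgenes it happened to receive.  Automated tracing software can
detect bright neurite fragments in such volumes but cannot reliably follow
a neurite through branch points and crossings.  This package takes the
opposite route: it ignores continuity entirely and groups fragments by
colour.  If the hue of a neuron's processes is stable, every fragment of
that neuron falls into one tight cluster in colour space, and clustering
the fragments reconstructs the neuron.

## Colour vectors

An N-channel fluorescence intensity profile is reduced to a **colour
vector**: per-channel background is subtracted, each channel is scaled by
its maximum over the analysed fragment set, and the result is divided by
its Euclidean norm.  The norm before unit-normalization is retained as the
**magnitude** — a brightness measure used for quality control and as the
weight in centroid computations.  Colour similarity is the Euclidean
distance *d* between colour vectors; two hues are treated as
distinguishable when *d* exceeds a threshold distance **Th(d)**.

Two design points deserve note:

* **The norm is L2.**  "Vector-normalized" conventionally means unit
  Euclidean norm, and the working threshold scale (Th(d) around 0.2
  against a maximum separation of sqrt(2) between non-negative unit
  vectors) is consistent with that convention.  An L1 (simplex)
  normalization is available via `vector_normalize(, norm = "l1")` for
  sensitivity analyses, but every default in the package assumes L2.
* **Per-channel maxima are taken over the whole analysed fragment set**,
  not per image.  When several slices or tiles are processed jointly this
  keeps one common colour scale, which per-image maxima would break.
* All-zero profiles are representable (magnitude 0) so that dark
  fragments are dropped by an explicit quality-control rule rather than a
  division-by-zero error.

## The stochastic labelling model

Transgene copy numbers per colour follow a Poisson distribution with mean
λ (copies/colour/cell), truncated at 50.  `simulate_cells()` implements
two generation methods:

* `"shuffle"` (default): the cohort's per-channel copy-number composition
  is fixed to the rounded Poisson probability mass (a quota), and the
  quota is shuffled across cells.  This mirrors expression patterns being
  assigned over a fixed pool and is what the cohort-level uniqueness
  statistics assume.
* `"poisson"`: every cell draws independently.

The two agree closely for large cohorts but differ measurably in
nearest-neighbour statistics at one to two hundred cells, where the fixed
composition suppresses duplicate-rich fluctuations.  Cells that receive
zero copies of every colour are invisible in an experiment; the
independent-draw method redraws them, the quota method drops them.  At
λ = 2 over 7 channels the all-zero probability is e^-14, so this choice
cannot move any headline number; it matters only for λ well below 1.

Three summary statistics quantify labelling performance:

* **Percent discriminable** (`percent_discriminable`): the fraction of
  unordered cell pairs separated by more than Th(d).  Pair distances are
  computed in row blocks, so 10,000 cells (5×10⁷ pairs) run in seconds
  within a few hundred megabytes.
* **Percent unique** (`percent_unique`): the fraction of cells with *no*
  neighbour within Th(d), a birthday-problem quantity that decays with
  cohort size even when pairwise discriminability is high.  Monte-Carlo
  over 200 cohorts by default; mean and SD are reported.
* **Noise-model discriminability** (`discriminability_with_noise`):
  neurite colour fluctuates around the soma colour.  Per-channel Gaussian
  noise (SD `noise_sd`, default interest 0.1) is added to the normalized
  vector, clipped at zero, re-normalized; Th(d) is then *derived* as the
  95th percentile of the noisy-replicate-to-true distances (covering 95%
  of a neuron's own scatter) and pairwise discriminability of true
  vectors is evaluated at that threshold.  The noise is injected on the
  normalized vector — the natural reading of noise expressed in colour
  (not intensity) units; injecting on raw intensities before
  normalization would make the noise brightness-dependent.

## Detector linearity and unmixing

Hybrid photodetectors under-report high intensities.  The correction
`y = a·x + b·e^(c·x) − b` maps measured counts to linearized intensities;
it fixes 0 and is strictly increasing on the valid range.  Counts above a
saturation cutoff (7000 on the calibration hardware, with
a = 0.9838, b = 1.1044, c = 0.001) are unrecoverable and become `NA`
rather than corrected values, and stay `NA` through unmixing.
`fit_linearity()` recovers the coefficients from a laser-power series:
per-pixel straight-line trends over the linear power range predict true
intensities, and the pooled (measured, predicted) pairs are fit by
nonlinear least squares.  One caveat: b and c trade off against each
other in the exponential term, so different (b, c) pairs can describe the
same curve to high accuracy.  The fitted *curve* is stable; the
individual coefficients should not be over-interpreted.

Unmixing is solved per excitation group (e.g. 3 + 2 + 2 channels under
405/488/552 nm lasers), mirroring sequential acquisition;
cross-laser bleed-through is taken as zero, since references are defined
only within groups.  Mixing-matrix columns are per-fluorophore emission
fractions estimated from single-fluorophore reference volumes (top-10%
foreground voxels, median background subtracted, L1-normalized).  Square
systems are solved directly and negative abundances clipped at zero; a
non-negative least-squares option (`method = "nnls"`) exists but the
default stays with the cheap direct solve, as the group systems are
square and well-conditioned when the references are distinct.

## Fragment extraction and quality control

Traces arrive as SWC.  They are split into unbranched fragments at branch
points (crossings are a tracing-software concept with no SWC
representation; mis-joined crossings are caught later by colour-change
splitting).  Soma points are excluded — soma signal exceeds the detectors'
linear range.  Per-fragment intensities are means over the union of
spheres (per-point radius, at least one voxel) swept along the polyline;
background is the global per-channel median of non-trace voxels (a local
alternative was considered and rejected as unnecessary at the densities
the phantom reproduces).

Quality control runs four ordered stages (`run_qc`):

1. **Channel S/N screen** — per channel, the mean fragment intensity in
   the 80–100th percentile window divided by the background median; a
   channel below 2.5 is dropped and colour vectors lose that dimension
   (zero-filling dead channels would distort distances).  The threshold
   default is 2.5; 3.0 appears in stricter descriptions of the same
   procedure, and the parameter is exposed.
2. **Minimum length** — sub-dividing fragments into ever shorter pieces
   makes their colour vectors drift from the parent's; the minimum
   length (default `"auto"`) is the smallest candidate for which the
   *median* piece-to-parent distance stays ≤ 0.1.  The median was chosen
   over the mean for robustness; the aggregate is configurable.  On 63×
   dendrite data this criterion lands near 5 µm.
3. **Minimum brightness** — pieces further than 0.2 from their parent are
   "inaccurate"; the magnitude cut-off (default `"auto"`, typically about
   0.1) is the smallest value at which fewer than 5% of surviving pieces
   are inaccurate.
4. **Colour-change splitting** — fragments whose adjacent minimum-length
   sub-fragments differ by d > 0.3 are cut there: an abrupt hue change
   marks a mis-joined hybrid of crossing neurites.  Pieces falling below
   the length or brightness thresholds after splitting are re-filtered,
   which keeps the pipeline idempotent on its own output.

## dCrawler

The clustering step must work without knowing the number of clusters
(k-means) or a density kernel (mean-shift): neither the number of
labelled neurons nor the fragments-per-neuron density is known.  The only
parameter is Th(d).  Three phases loop until the assignment is stable:

* **Crawl** — points are visited in input order; a point joins the
  nearest existing cluster whose (magnitude-weighted) centroid lies
  within Th(d), updating the centroid immediately, else it seeds a new
  cluster.  Point-driven accretion in input order is the simplest scheme
  consistent with "the first data point is the first cluster"; a
  brightest-first visiting order is available (`order_by =
  "magnitude"`) since bright fragments are more reliable seeds.
* **Adjust** — nearest-centroid reassignment iterated to a fixed point
  (cap 100), removing the crawl's primacy bias.  Ties go to the lowest
  cluster id, making runs deterministic for a fixed input order.
* **Merge** — closest-first fusion of centroid pairs within the merge
  threshold; points left outside Th(d) of their new centroid are
  unassigned and re-enter the next crawl.  Eviction tests against the
  *undecayed* Th(d): the decay below is a termination device and should
  not loosen the cluster-radius invariant.

Convergence is exact equality of consecutive assignment vectors.  To
guarantee termination the merge threshold decays by 0.99 per loop after
loop 20; a hard cap of 1000 loops is an assertion, not a tuning knob.  At
convergence every point lies within Th(d) of its centroid and no two
centroids are within the final merge threshold — both are asserted by the
test suite on random data.

Centroids are magnitude-weighted means and are *not* re-projected onto
the unit sphere; membership distances are measured to the raw mean.
Re-normalizing would move centroids away from the region their members
occupy and break the within-Th(d) invariant.

## Evaluation

With ground-truth neuron labels, each neuron is matched to the cluster
holding the most of its fragments (ties to the lower cluster id), and
fragment-level confusion counts give per-neuron precision, recall and F1.
Counting fragments rather than micrometres follows the fragment-level
definition of the confusion classes; a length-weighted variant would be a
straightforward extension.  `optimal_threshold()` scans Th(d) over a
uniform grid (default 0.05–1.00 in steps of 0.025 — a uniform grid with
an optional explicit list is cleaner than a hand-picked irregular one)
and returns the threshold with the highest median per-neuron F1.
`percent_reconstructed()` rasterizes ground truth at native width and the
prediction dilated by 10 voxels (forgiving sub-10-pixel misalignment) and
reports the covered fraction of ground-truth voxels.

## The phantom generator

`generate_phantom()` renders a synthetic labelled volume with complete
ground truth: neuron colours drawn from the Poisson model, neurite
skeletons as persistent random walks (with optional branching) inside the
volume, Gaussian-profile tubes with per-channel amplitudes proportional
to the neuron's colour, per-segment colour jitter, constant background,
and optional Poisson-like shot noise.  Defaults: 20 neurons, 7 channels,
λ = 2, a 64 × 64 × 32 µm volume at 0.5 × 0.5 × 1 µm voxels, 45-µm fibres,
colour jitter SD 0.05 — the jitter level matching the neurite colour
scatter that motivates the noise model above, and a density at which
fibre crossings are present but not dominant.

What the phantom does *not* emulate: realistic dendritic/axonal
morphology, spatially varying background and autofluorescence, optical
anisotropy beyond a separable Gaussian profile, chromatic aberration, and
tracing errors other than the hybrid-fragment kind.  Passing end-to-end
tests on phantoms therefore demonstrates the internal consistency of the
pipeline — extraction recovers the rendered colours, clustering recovers
the generating labels (median F1 ≥ 0.9 at jitter 0.05 and Th(d) = 0.2) —
not performance on real microscopy, which additionally depends on
acquisition quality and the tracing software.

## Numerical choices and problem sizes

* Pairwise statistics use squared-distance block sweeps with a 1e-12
  slack on the threshold comparison to absorb floating-point noise.
* Voxel membership: world coordinates are micrometres, voxel *i* spans
  `[(i-1)·s, i·s)`; the voxel containing a sample point always belongs to
  the footprint even when a coarse grid puts every voxel centre outside
  the sphere.
* Fragment subdivision keeps a final remainder shorter than half the
  piece length merged into the previous piece.
* The simulation tests and the acceptance script use the cohort sizes the
  statistics are defined with (10,000 cells for pair statistics, 200
  Monte-Carlo cohorts for uniqueness); phantom-based tests use 5–20
  neurons in a 64 × 64 × 32 µm volume, sizes chosen so the full suite
  runs in a few minutes while leaving every geometric regime (branching,
  crossing, short fragments) represented.

## Known limitations

* Crawl results depend on input order in principle; on blob-structured
  data the adjusted Rand index across random orders exceeds 0.95 (tested),
  but heavily overlapping clusters can settle differently.
* Fragments whose true colour legitimately changes along their length
  (e.g. depth-dependent attenuation) are split rather than corrected.
* Unmixing assumes zero cross-laser bleed-through and a single global
  linearity coefficient triple per detector (the calibration hardware
  reports one per microscope); per-pixel corrections are out of scope.
* The tn count in the confusion table includes every QC-passing fragment
  not belonging to the neuron or its best cluster, including fragments of
  unlabelled background structures if such labels are present in the
  ground truth.
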