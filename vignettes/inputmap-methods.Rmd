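---
title: "Methods: whole-brain input mapping on synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-brain input mapping on synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inputmap)
```

# The problem

Monosynaptic rabies tracing labels the neurons one synapse upstream of a
chosen "starter" population — here, dopamine neurons defined by their
projection target (ventral striatum, dorsal striatum, tail of striatum,
globus pallidus, amygdala, orbitofrontal and medial prefrontal cortex,
lateral habenula). After tissue clearing and light-sheet imaging of whole
brains, the analysis question is quantitative: *which brain regions provide
inputs to each dopamine subpopulation, in what proportions, and where exactly
do those inputs sit?*

`inputmap` implements the full analysis chain — cell detection, registration
to a common reference space, region-wise quantification, cross-condition
statistics, and density-based topography — together with a synthetic-data
generator that produces volumes and multi-brain cohorts with known ground
truth, so every stage is tested against what was actually planted.

# Coordinate conventions

All physical coordinates are micrometres. Axes are fixed as
(x = medio-lateral, y = dorso-ventral increasing ventrally,
z = antero-posterior increasing posteriorly). The centre of 0-based voxel
$(i,j,k)$ sits at $\mathrm{origin} + ((i,j,k) + 0.5)\odot\mathrm{spacing}$;
`voxel_to_um()` / `um_to_voxel()` are the only conversion points, which is
what keeps half-voxel errors out of the pipeline. Bregma-style coronal
coordinates are mapped to reference z by a configurable offset
(`bregma_to_z_um()`); the reference origin itself is a free config choice
because no canonical origin is implied by the data model.

# Cell detection

Pixels are featurized slice-by-slice (2D) with six filter families — Gaussian,
Laplacian of Gaussian, Gaussian gradient magnitude, difference of Gaussians,
structure-tensor eigenvalue, Hessian eigenvalue — at radii 0.7, 1.6 and 5
pixels, giving 18 values per pixel. Two conventions had to be pinned:

* *Eigenvalue families contribute one scalar* (the largest-magnitude
  eigenvalue). Any multi-eigenvalue reading would break the 6 x 3 = 18
  feature count, so the single-scalar reading is forced.
* *DoG* is $G(\sigma) - G(1.6\sigma)$; the structure tensor uses gradients at
  $\sigma/2$ smoothed at $\sigma$. These inner scales are conventional
  defaults; they are documented because nothing in the data model forces them.

A 200-tree random forest with 4 candidate features per split (a probability
forest, seeded, single-threaded for determinism) classifies every pixel as
cell/non-cell. Majority vote with ties to non-cell: a false positive pollutes
counts silently, a false negative is visible in the audit table. Each of the
eight coarse "parent regions" gets its own classifier, and only the local
parent's output is retained (`compose_parent_masks()` at voxel level,
`filter_centroids_by_parent()` at centroid level, the post-registration path).

Cell pixels are collapsed into 26-connected 3D components
(8-connected in-plane). Per component we measure:

* **diameter** — equivalent-sphere diameter from the physical volume;
  retained iff in [2.5, 50] um;
* **consecutiveness** — the longest run of adjacent occupied z-planes must be
  at least 2;
* **circularity** — $4\pi A / P^2$ on the component's maximum-area z-slice,
  retained iff > 0.1. The perimeter estimator is the *exposed-edge count*:
  the number of 4-neighbour pixel edges between component and non-component
  pixels, times the pixel size. This estimator is pinned by tests (a 1 x 30
  pixel line has 62 exposed edges and circularity 0.098, below the floor;
  digitized disks score ~0.6). A Crofton-corrected count (x pi/4) was
  considered and rejected because it pushes thin lines above the 0.1 floor,
  defeating the filter's purpose.

Survivor centroids are intensity-unweighted means of voxel centres; every
rejected component is audited with the rule(s) it failed.

# Registration

Brains are aligned by maximizing mutual information (32 equal-width bins per
image over its min-max range, natural log) of block-averaged 20-um volumes.
The affine stage is implemented here: 12 parameters (translation, rotation
about the volume centre, log-scale, shear), Nelder-Mead over a 3-level
pyramid (factors 4, 2, 1) with seeded multi-start at the coarsest level; the
two best coarse optima are refined at the middle level before the final
full-resolution polish. Deformable (B-spline) refinement is *not* fitted —
deformable registration is a discipline of its own — but an externally
produced displacement field is accepted and applied to points by trilinear
interpolation after the affine, with out-of-support points dropped and
audited (or clamped, by config). `average_reference()` provides the
voxelwise-mean template construction used to build a synthetic reference.

# Quantification

`assign_regions()` looks up the atlas label of each point's containing voxel
(the boundary rule: points exactly on a voxel edge belong to the containing
voxel, the only rule that needs no tie-breaking). Regions flagged
`starter_excluded` — by default analogues of VTA, SNc, SNr and RRF, where
labeled cells could be starter neurons rather than inputs — keep their counts
but never enter a percent denominator; the exclusion list is purely
config-driven so carve-outs (such as keeping supramammillary A10rv) are a
config edit, not a code change. Per brain, percents over non-starter regions
sum to 100 (asserted on every table build). Profiles are mean +/- s.e.m.
(sd/sqrt(n)) across 3-5 brains per condition; regions absent in a brain count
as 0%. Display subsampling draws 1500 points per brain from 3 random brains,
without replacement. Chance baselines are voxel-census ratios
(`chance_fraction()`), with "brain" support meaning all labeled non-starter
voxels.

# Cross-condition statistics

Per region, a classical one-way fixed-effects ANOVA on per-brain percent
replicates (raw percentages, as in the source analysis; transforms are
available behind config), screened to the 20 most prominent regions by
maximum condition-mean percent. Multiplicity is controlled by the Holm-Šidák
step-down: the $i$-th smallest p is rejected iff
$p_{(i)} \le 1 - (1-\alpha)^{1/(m-i+1)}$ *and* all smaller-ranked tests were
rejected. `p.adjust()` offers Holm's Bonferroni-style step-down but not the
Šidák-threshold variant, so the procedure is implemented directly and checked
against formula evaluation and against the bracketing property
(Bonferroni-rejections ⊆ Holm-Šidák ⊆ uncorrected). A 10,000-replicate
global-null simulation confirms familywise error ≤ 0.05 + 3 Monte-Carlo s.e.

Similarity between conditions is Pearson correlation of the condition-mean
percent vectors; clustering is UPGMA on $d = 1 - r$ (the transform is the
standard reading of "correlation as distance"; it preserves ordering). Ties
break by lexicographic label order. The reciprocity comparison tests, per
condition, its own brains' percent of inputs from the reciprocal region
against the pooled other-condition brains (two-sided pooled-variance
Student's t; Welch behind an argument since the variant is a genuine open
choice — pooled is the classical default for 3-5 replicates).

# Topography

Centers of mass are computed in 400-um coronal bins (empty bins absent,
s.e.m. undefined below n = 2). Densities: points pooled across all animals
are histogrammed on a 20-um isotropic grid and convolved with a truncated
discrete Gaussian. The "60-um kernel" is read as the FWHM
(sd = 60/2.355 ≈ 25.5 um) because a kernel *size* names a width, not a
standard deviation; sd-mode is one config flag away and the choice is pinned
by the patch-radius test ($r_{1/3} = \sigma\sqrt{2\ln 3}$).

Patches are grown from 26-neighbourhood local density maxima (connected
equal-valued plateaus collapse to one seed; plateaus that continue into a
higher shoulder are not seeds). Growth proceeds in synchronized one-voxel
shells so boundaries between competing patches are equidistant in growth
steps; a voxel joins a patch iff its density is at least 1/3 of *that
patch's own peak* — the per-patch reading keeps small patches nonempty, and
the global-max reading is available as `stop_mode = "global"` because the
stopping rule is genuinely ambiguous. Simultaneous claims resolve by higher
peak, then lower patch id (deterministic). A prominence floor (default 10% of
the global maximum) screens seeds, because raw local maxima of smoothed point
data are noise-dominated; this is an extension beyond the minimal rule and is
off (`prominence_fraction = 0`) in the parameter-recovery tests.

For cohort-level *ventral* patches, `detect_ventral_patches()` restricts the
pooled density to the enclosing region group before segmentation and raises
the prominence floor to 0.3 — above the uniform in-region background density
relative to a genuine hot-spot peak — because a whole-brain density of a
many-region cohort makes every dense region's interior a "patch" otherwise:
the analysis question is where inputs concentrate *within* the ventral
striatum, not whether cortex is dense.

# The synthetic generator: what it emulates, and what it does not

`make_toy_atlas()` carves contiguous regions (budgeted multi-source BFS from
seeded sites) on a 64^3 x 20 um grid — a 1.28-mm cube, so the full pipeline
runs in minutes on a laptop; the full-size 700 x 600 x 350 reference grid is
a parameter choice away. `simulate_brain_volume()` renders cells as blurred
spheres (closed-form ball-Gaussian radial profile) at the acquisition
geometry (1.04 x 1.04 x 5.25 um voxels), default radii 5-7.5 um (10-15 um
somata — cells that span at least two 5.25-um z-steps, as real somata do),
peak contrast 1 over background 0.1, Gaussian noise sd 0.05, minimum centre
separation `2 r_max + 4 blur_sd` (labeling is sparse; touching-cell splitting
is out of scope).

`simulate_centroid_cohort()` draws per-brain region counts multinomially
around Dirichlet-jittered condition proportions (concentration 2000 by
default — percent-scale between-brain s.e.m. of a few tenths to ~1 point,
the order reported for real cohorts; per-brain count dispersion is a free
parameter since no dispersion is published). The default cohort plants the
biological structure of interest: seven "canonical" conditions whose
ventral-striatum fraction is drawn per brain in [0.12, 0.20] (the draw moves
the medial-shell analogue and is compensated in cortex, so it is between-brain
variability, not a between-condition signal), and a TS-like outlier with VS
fixed at 0.05 whose deficit moves to GP/STh/ZI — making the planted
differential regions exactly {VS medial shell, GP, STh, ZI}. Five
truncated-Gaussian hot-spots (3 medial shell, 1 core, 1 lateral shell,
sd 50 um) receive ~21% of canonical VS points and none of the outlier's.

What the generator does **not** emulate — and therefore what green tests do
not certify about real data: realistic optics (stripe artifacts, shadowing,
depth-dependent blur), autofluorescence texture, non-rigid anatomical
variability between brains (deformation fields are consumed, never
generated), region-boundary uncertainty of a drawn atlas, and realistic
neuron morphologies. The detection figures of merit (precision/recall
≥ 0.95) describe blob-like somata on smooth background at the stated noise
level, nothing more.

# Numerical choices and degenerate inputs

* Convolutions use reflective boundaries; derivative kernels are re-centred
  to exact zero sum so constant images give exactly zero gradient features.
* Histograms: min-max equal-width bins; a constant image collapses to one
  bin (entropy 0), and MI errors on geometry mismatch rather than resampling
  silently.
* `register_affine` parameterizes scale as `exp(s/100)` so the optimizer
  cannot cross zero; volumes that do not overlap physically fail fast with
  both extents in the message.
* Empty inputs: empty masks give empty component lists; an empty point set
  rasterizes to a zero density (not an error); an all-zero density yields an
  empty patch set; a brain with zero non-starter points is an error (its
  percent vector is undefined), and in-region fractions for a condition with
  no in-region points are `NA`, never 0.
* Zero within-group variance with unequal means (an infinite F) and zero
  pooled variance with unequal means (undefined t) are explicit errors with
  diagnostics, not silent `Inf`s.
* All stochastic functions take a `seed` and restore the caller's RNG state;
  cohort brains use decorrelated child seeds, so the whole pipeline is
  bit-reproducible from one config and one seed.

# Problem sizes used by the test-suite and acceptance script

Chosen as the package's own desk-scale study conditions: detection on a
256 x 256 x 64 acquisition-geometry volume with 200 planted cells (training
on a separate 128 x 128 x 32 volume, sparse interior/background labels);
outlier recovery on 8 conditions x 4 brains x 5,000 points across 20 cohort
seeds; patch recovery across 100 seeded runs with k = 1..8 peaks at ≥ 4-sd
separation; registration recovery across 50 random misalignments (≤ 200 um,
≤ 10 degrees) of a smoothed region-intensity phantom; statistical calibration
with 10,000 global-null replicates.

# Known limitations

* The affine registration is validated on synthetic self-similar phantoms;
  no claim is made about cross-modality or badly initialized real data
  (initialization beyond ~12 reference voxels of shift relies on the seeded
  multi-start finding the basin).
* The patch stopping rule's per-patch vs global ambiguity changes patch
  extents (not counts) when peaks differ in height; both modes ship.
* Percent-scale ANOVA on compositional data ignores the simplex constraint;
  with 15+ regions and percents well below 50 this is the field's standard
  simplification, and transforms are available behind config.
* HDF5 and NRRD containers are not read natively; NIfTI and TIFF (+ JSON
  sidecar) are the supported raster formats in this implementation.
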