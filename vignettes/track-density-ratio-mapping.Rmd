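---
title: "Track-density ratio mapping by fiber type: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Track-density ratio mapping by fiber type: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The method

Whole-brain tractography produces millions of streamlines ("tracks"), each an
ordered polyline in world millimetres. Most of them are not anatomically
usable: probabilistic tracking terminates freely in white matter and in deep
structures. This package implements a post-processing pipeline that keeps
only tracks whose terminals are anatomically interpretable, sorts them into
the three classical fiber systems, and maps where each system touches the
cortex.

Everything rests on one idea: **a track is characterised entirely by the
tissue compartments of its two terminals, plus its arc length**. Given a
tissue segmentation with labels 0 background, 1 white matter, 2 left cortex,
3 right cortex, 4 subcortical:

* *validation* — a track with a terminal in white matter is a **noise**
  track (the tracking stopped mid-bundle); a track with no terminal in
  cortex is **ineffective** (it never reaches the structure being mapped).
  The white-matter rule takes precedence when both apply. With free-seeded
  probabilistic tracking, the large majority of raw tracks are removed here.
* *classification* of the validated remainder, in decision order:
  1. any subcortical terminal → **projection** fiber (cortex ↔ deep
     structures);
  2. one terminal in each cortex → **commissural** fiber (inter-hemispheric);
  3. both terminals in the same cortex → **association** fiber, split by arc
     length at 6 cm into **short** and **long** association.
  A validated track whose terminal combination fits none of these (e.g. a
  cortical terminal paired with background) belongs to no class in this
  taxonomy and is reclassified as ineffective rather than given an invented
  class.

The **track-density** of a class at a voxel is the number of that class's
terminals whose nearest voxel it is, on a 1 mm isotropic grid (so the unit
is terminals per mm³). At the parcel level the analogous quantity is the
**relative density** `tracks_amount / piece_volume` of each parcellation
piece. Because a projection track has one cortical terminal while
commissural and association tracks have two, equal numbers of projection
and commissural tracks produce cortical densities in a strict 1:2 ratio —
a structural property of the counting rule that the test suite asserts
exactly.

Ratio maps encode the per-class densities as color intensities through the
saturating exponential

$$ I(d) = 1 - e^{-k\,d/d_{\max}} $$

with $I(0) = 0$ and $I(d_{\max}) = 1 - e^{-k}$. The per-voxel count
histogram decays roughly exponentially, so a linear color scale would leave
almost the whole map near black; this transform spends most of the dynamic
range where the data are. The contrast constants are `k = 30` for
voxel-based RGB maps, `k = 8` for parcel-based RGB maps and `k = 2` for
grayscale total maps. Channel assignment is red = commissural, green =
projection, blue = association (short + long summed before the transform);
an alternative two-color mode shows red = short, green = long association.

2D "3D-like" views are produced by slice stacking with a painter's
algorithm: slices are traversed from the far side toward the viewer and a
pixel takes the color of every traversed voxel whose *pre-transform* total
density exceeds the minimum density level (default: any nonzero count), so
empty background never overwrites signal. Medial views mask one hemisphere
by the world-x sign of the voxel centre and stack from the lateral surface
toward the midline.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `length_threshold_mm` | 60 | mm | short/long association split (6 cm) |
| `k_voxel` | 30 | – | voxel RGB contrast |
| `k_parcel` | 8 | – | parcel RGB contrast |
| `k_gray` | 2 | – | grayscale total contrast |
| `dmax_mode` | `global` | – | one $d_{\max}$ across channels preserves cross-class ordering |
| stacking threshold | 0 | counts | exclude only minimum-density voxels |
| `outlier_k_mad` | 3.5 | MAD | advisory subject screen |

The 6 cm boundary itself is half-open: the definition "shorter than 6 cm"
vs "longer than 6 cm" leaves exactly 60 mm unassigned, and we place it with
the long class (`>= 60` → long) so the rule is deterministic. The grid
convention is NIfTI voxel-centre semantics: a world point maps to
`floor(inv(affine) · p + 0.5)`, matching how common neuroimaging tools look
labels up; points outside the volume are background by contract, never an
error, because real tractograms do contain such terminals and the
validation stage is the right place to reject them.

## Group analysis

Subjects must already share a template grid (spatial normalisation is out
of scope; the group module consumes already-transformed tracks). Voxel-wise
group maps average the *densities* first and apply the intensity transform
afterwards — transforming before averaging would make the group map depend
on per-subject maxima. Parcel-level group tables report across-subject mean
and sample SD (n − 1) per label and class, and hemisphere summaries are
unweighted means over that hemisphere's labels (a volume-weighted option
would emphasise large parcels; the unweighted mean treats each parcel as
one observation, matching how per-parcel bar graphs are read).

Hemispheric asymmetry is tested on homotopic parcel pairs (same `name` in
the lookup on both sides). No specific test is canonical for this design;
we adopt a **paired two-sided t-test** across subjects — each subject
contributes one LH−RH difference of the unweighted mean over the requested
label set — with a Wilcoxon signed-rank option. Pooling a multi-label
region into one pair per subject keeps observations independent; testing
label × subject pairs would pseudo-replicate. Raw p-values are reported
(Benjamini–Hochberg is available but off by default, since the per-region
values are meant to be read individually). Degenerate inputs are reported,
not silently tested: all-zero differences give p = 1, constant nonzero
differences are flagged as degenerate with an undefined p. The t statistic
and p are computed directly from mean, SD and the t distribution; the test
suite cross-checks them against the standard reference implementation to
1e-10.

Subjects with an anomalous total validated-track count or commissural
fraction can distort group maps. Because no principled cut-off exists for
"anomalous", the screen is robust and advisory: values outside
median ± 3.5 MAD on either criterion are *flagged* for manual confirmation,
never auto-excluded.

## The phantom

The phantom makes every stage testable with no external data. It emulates
exactly the structure the classifier reads — a spherical brain with two
hemispheric cortical shells (2–3 voxels thick) split at the midplane
x = 0, a central subcortical blob, white matter in between, and a
parcellation tiling each shell into z-bands with homotopic names — and
streamlines whose class is encoded *only* by their terminal compartments
and arc length, never by metadata, so the classifier is tested blind.

Terminals are sampled at voxel centres of the defining compartments;
interior control points are routed through white matter (associations via
inward-pulled arcs, long associations lengthened past 60 mm by inserting
radial detour midpoints — deterministic, no rejection sampling), jittered
with 0.3 mm Gaussian noise, and resampled at 0.2 mm steps, the step size
typical of fixed-step probabilistic tractography, so phantom lengths behave
like real track lengths. The default spec plants 10,000 classifiable
streamlines at the 18.3 / 20.2 / 33.0 / 28.5 % projection / commissural /
short / long mix — echoing the proportions reported for real whole-brain
tractograms, where over 60 % of validated tracks are association fibers —
plus 1,000 noise and 500 ineffective tracks. A fixed seed makes the scene
bit-reproducible down to the TCK bytes.

What the phantom does **not** emulate, and hence what passing tests do not
show about real data: gyral bias (real tracking terminates preferentially
on gyral crowns), susceptibility distortions in inferior regions, realistic
curvature and fanning, partial-volume mixing at tissue boundaries, and the
~90 % rejection rate of free-seeded tracking (the phantom plants rejects
explicitly instead). Points within ~0.5 mm of a cortical terminal
necessarily share its voxel, so "interior points stay in white matter"
holds for the control geometry, not literally for every 0.2 mm sample near
a terminal — irrelevant to classification, which reads terminals only.

## Numerical choices and degenerate inputs

* TCK I/O is bit-exact: float32 little-endian triplets, NaN separators, Inf
  terminator; coordinates survive a round trip to float32 precision
  (~1.2e-7 relative). Malformed headers and truncated streams raise errors
  naming the byte offset.
* `dmax <= 0` (an all-zero map) is an error in the transform itself but a
  warning plus all-zero image in the map composers, so empty inputs render
  instead of crashing a pipeline run.
* Zero validated tracks yield NA fractions, not division errors.
* Empty parcels get NA densities and a warning; terminals in unlabelled
  voxels are tallied to an explicit `unassigned` row rather than dropped.
* Ties at the 60 mm boundary are impossible by construction in the phantom
  (short tracks are built < 58 mm, long ones ≥ 60.05 mm); the classifier
  itself is deterministic at exactly 60 mm.
* The intensity transform saturates at 1 in double precision for
  `k = 30` near $d_{\max}$; tests therefore assert strict monotonicity
  only below the saturation resolution.

## Problem sizes

The shipped tests run the full pipeline on the 10,000-streamline phantom
(recovering every planted label with zero errors), rendering oracles on a
40³ grid, and asymmetry-test calibration with 1,000 replicates of 16
subjects (empirical type-I error at α = 0.05 within [0.03, 0.07]; power
≈ 1 for a planted shift of 5× the noise SD). The same computations are
re-run from scratch by `scripts/acceptance.R`.

## Known limitations

* Classification is purely terminal-based: a track that skirts the cortex
  mid-course is invisible to the taxonomy.
* The voxel maps use nearest-voxel counting with no smoothing or
  along-track interpolation (terminal counting is the definition here;
  super-resolution track-density imaging is a different method).
* The asymmetry test assumes approximately normal LH−RH differences across
  subjects; with 16 subjects the t-test is adequate but the Wilcoxon option
  exists for heavy tails.
* Group averaging requires identical grids; no registration is performed.

## A minimal session

```r
library(tdrm)

ph <- build_phantom(phantom_spec(seed = 1))
fit <- tdrm(ph$tracks, ph$tissue, ph$parcellation, ph$lookup,
            subject_id = "phantom")
print(fit)
plot(fit, view = "superior")

# group level, from per-subject parcel tables
tabs <- lapply(1:4, function(s) {
  p <- build_phantom(phantom_spec(seed = s))
  f <- tdrm(p$tracks, p$tissue, p$parcellation, p$lookup)
  f$parcels
})
group_parcel_stats(tabs)
hemispheric_asymmetry(tabs, class = "long_assoc")
```
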