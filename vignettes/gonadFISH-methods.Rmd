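---
title: "gonadFISH: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gonadFISH: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

gonadFISH does two things: it **simulates** multi-channel smFISH image
stacks of the *C. elegans* distal gonad with complete ground truth, and it
**analyzes** such stacks with an automated quantitation pipeline (gonad
outline, 3-D nuclei, dual-method spot detection, ATS confirmation, Voronoi
cells, positional statistics). No raw imaging data are available at desk scale for this kind of assay, so
the simulator is not a test fixture but the package's measurement standard: every
quantitative claim the test suite makes is a parameter-recovery statement —
the generator states a world, the pipeline must recover it through
rendering, detection and quantitation without bias.

This vignette records the models, the defaults and their rationale, and
every place where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

# The biological model

Germline stem cells fill the distal end of the gonad tube and receive
Notch signaling from a single niche cell (the distal tip cell, DTC).
Transcription of the Notch target gene (*sygl-1* by default) is visualized
with two probe sets: exon probes bind nascent transcripts **and** mature
mRNAs, intron probes bind only unspliced nascent transcripts. An active
transcription site (ATS) is therefore a bright nuclear spot present in both
channels; a single mature mRNA is a dim exon-only cytoplasmic spot. The
assayed quantities are, per gonad: which nuclei have ATS (and how many, up
to the 4 chromosomal loci of a replicated genome), how bright each ATS is
in single-mRNA equivalents, and how mRNAs distribute over germ cells along
the distal-proximal axis.

# The synthetic gonad

## Geometry

Real image stacks are ~15 um deep — shallower than the ~26 um gonad tube —
so the imaged volume is modeled as the **central slab** of the tube: the
in-gonad region is an xy outline (half-width 13 um with a blunt elliptical
distal cap of 4 um) extruded over the full z depth. This matches the
analysis convention of detecting one 2-D boundary from the central planes
and extruding it, and makes that convention exact on synthetic data. The
distal end is at x = 0; `distal_distance` is the straight-axis x
coordinate (synthetic tubes are straight; real gonads bend, which the
simulator does not emulate).

## Nucleus packing

Nuclei are placed on a jittered hexagonal-close-packed lattice, clipped to
the outline with a margin so rendered spheres stay inside the imaged
volume. A lattice is the only sampler that controllably meets the packing
contract — mean nearest-neighbor distance equal to the germ cell diameter
(gcd), 4.55 um, within 5% — while looking like the dense quasi-regular
epithelium-like packing of the distal gonad. Uniform positional jitter
(0.30 um ball) removes crystalline artifacts; because jitter shrinks the
nearest-neighbor minimum, the lattice constant is 4.55 x 1.0557, with the
compensation factor calibrated once by simulation and frozen. Nuclear radii
scale as the cube root of DNA content around a 2.0 um mean with small
lognormal jitter, capped so no pair violates the non-overlap invariant
(center distance at least 0.9 x the radius sum).

## Cell cycle, loci, firing

Cycle stages are i.i.d. G1/S/G2/M = 0.04/0.71/0.22/0.03. DNA content is 2C
in G1, uniform 2C-4C in S, 4C in G2/M. Locus counts follow replication: 2
in G1; 2 + Binomial(2, u) in S with u the uniform S-phase progress (2, 3 or
4 with probability 1/3 each); 4 in G2/M.

Each locus fires independently (Bernoulli) with probability `p(x)`, a
logistic decline along the axis. Two calibrations are baked into the
default profile and deliberately **not** revisited:

* The reported distal positivity in this system is nucleus-level (~70% of
  nuclei carry at least one ATS at the distal-most end; read here as the
  first 5-um bin of the positional profile). Under the locus-count mixture above, nucleus
  positivity is `E_L[1-(1-p)^L]`; solving for the per-locus probability
  that makes the *bin-average* positivity 0.70 gives `p_distal = 0.335`.
  (A per-locus 0.26 with four loci everywhere would give 0.70, but the
  cycle mixture the model also states pushes that down to ~0.61.)
* The decline (midpoint 15 um, scale 3.5 um) brings nucleus positivity
  below 5% before 30 um, reproducing the reported region extent without
  asserting an unmeasured functional form.

Nascent loads per ATS are lognormal with mean 17.2 single-mRNA equivalents
and CV 0.8, truncated to >= 1. The available measurements constrain only the mean
(the 17-fold ATS/mRNA intensity ratio); the lognormal shape and CV are
stand-ins for the broad, position-independent spread of per-ATS
intensities. ATS positions are uniform in the owner sphere — chromatin has
no preferred radial position in this model, and peripheral loci (near the
nuclear envelope) are therefore common, which matters for detection (below).

## The mRNA field

Per-cell mRNA counts are Poisson with mean 15 on the distal plateau
(0-20 um), declining linearly to a basal mean of 1 at 45 um and flat
beyond — a near-uniform field extending past the ATS region, with rare dim
basal signals where the basal level is measured (40-60 um). The plateau
level is a free parameter (no per-cell count is printed); 15/cell matches
the reported global spot budget (~2850 spots per gonad over a somewhat
larger imaged volume) and is low enough that PSF-coincidence losses (two
mRNAs closer than the diffraction limit merging into one spot) stay within
the detection contract. Positions are uniform in the owner cell's
cytoplasmic territory: within 3 um of the nucleus center, nearer to it
than to any other nucleus, outside every nucleus sphere, inside the slab.

## Optics and noise

Pixels are 0.065 um in XY (the physical value is not constrained;
chosen so that a diffraction-limited spot spans ~4 x 4 px, the stated
average size of a detected mRNA) and planes 0.3 um apart in z. Spots render as 3-D Gaussians with
sigma 0.09 um laterally (0.21 lambda/NA for ~600 nm emission at NA 1.4)
and 0.35 um axially, with integrated intensity proportional to load
(9000 photon units per single-mRNA equivalent — high enough that a single
mRNA passes every cascade criterion on >= 2 consecutive planes with ~5
sigma of margin, as it must for the fixed reference thresholds to be meaningful).
Nuclei render as filled DAPI spheres with constant interior density
(volume tracks DNA content, so density is stage-independent), a linear
edge ramp of 0.25 um centered on the true radius standing in for PSF blur,
and a dim (x0.75) nucleolar center. The DIC channel carries the outline
contrast; the GFP channel, when the DTC is enabled, carries a
membrane-GFP arbor: a bright shell wrapping the DTC nucleus (the cell body
envelops its own nucleus), a thin cap hugging the distal tissue tip, and
thin (0.7 um) straight processes running proximally through the tissue.
Noise is signal-dependent Gaussian, `sd = sqrt(I + 3^2)` — a Gaussian
approximation to shot noise plus read noise; it is applied last and can be
disabled for linearity checks.

## Time-course mode

At t = 0 signaling stops: no new firing, each existing ATS gets an
exponential death time with half-life 10 min (the reported constraint is an upper bound of 15 min; 10 min reproduces
the observation that most ATS are lost within 15 min), each mRNA
with half-life 60 min. Later timepoints are nested subsets of earlier
ones, as for a real cohort shifted together.

## The weak-Notch (q224-like) configuration

`q224_spec()` scales **nucleus-level** positivity by 0.5 (inverted through
the locus mixture to a per-locus probability), compresses the firing region
from 30 um to 20 um, and halves the mean load. The reported mutant effect is nucleus-level (an about two-fold lower
percentage of ATS-positive nuclei); halving the per-locus probability instead would yield only a
~1.6-fold nucleus-level drop, so the nucleus-level reading is implemented.

# The analysis pipeline

## Outline and orientation

The boundary comes from the mean of the central 8 DIC planes: light
smoothing, Otsu threshold, largest connected component, hole filling, and
a contrast check (featureless stacks must fail, not yield a noise split).
The 2-D outline is extruded over z. The distal end is the end where the
outline width collapses (the blunt cap); `--distal-end` overrides the
heuristic. Everything downstream assumes distal-left; stacks detected
distal-right are flipped.

## Backgrounds

Per plane and channel, the background is the mean of in-gonad pixels after
iteratively excluding pixels above 1.5 x the running mean (the analog of
"a location without nuclei"). The estimator is a mean over ~2e5 effectively
i.i.d. pixels, so the implementation subsamples to 50k pixels per plane for
speed. Signal outside the outline is replaced by the plane background
before any detection.

## Nuclei

Per DAPI plane, pixels above 1.5 x the Otsu threshold (the reference rule of
150% of the automatic threshold) form components; each component in the 1.3-3.0
um radius range yields one circle. The threshold crossing systematically
erodes the radius, so each circle is refined to the **half-maximum**
crossing of the DAPI edge profile, which is unbiased for a symmetric edge
ramp; the refinement counts only the connected region containing the
circle's center (so neighboring nuclei inside the search box cannot inflate
it) and the interior reference level is the upper-quartile core intensity
(robust to the dim nucleolus). Circles are chained greedily by nearest XY
center between adjacent planes (0.5 um gate); a nucleus requires >= 4
consecutive planes and center spread < 0.5 um, then a least-squares sphere
fit (`r_i^2 + z_i^2` is linear in `z_i`), DAPI integration within the
sphere, and de-duplication of heavily overlapping fits. The lower radius
bound (1.3 um) is chosen so that cross-sections near the poles of two
stacked nuclei — the only place where circles of different nuclei can
merge — are excluded before grouping.

## Spot detection

Both probe channels run the same per-plane dual-method cascade:

1. **Segmentation**: components above 1.5 x plane background. (An
   alternative reading that reuses the per-gene overall ratio, 1.27, as
   the exon segmentation threshold was rejected: at ~2.7 sigma of shot noise it
   admits hundreds of noise pixels per plane and inflates the single-mRNA
   footprint well past the stated ~4 x 4 px.)
2. **Peak detection**: strict local maxima of the lightly smoothed plane
   above the same threshold (computed on padded crops around the
   super-threshold components; a smoothed maximum above threshold cannot
   occur elsewhere).
3. Components holding >= 2 peaks are **split** by nearest peak. This is
   the payoff of running two detectors: an mRNA overlapping the tail of a
   bright ATS, or two mRNAs in one packet, would otherwise fuse into one
   irregular component and be discarded wholesale by the circularity
   criterion.
4. **Intersection**: only candidates found by both methods survive.
5. **The fixed criteria**, per plane candidate: peak/overall-background >
   1.27, peak/local-background > 1.9 (local background from a window
   3 x the spot radius, super-threshold pixels excluded — ~10-17 px for
   ATS-sized spots), pooled-variance Student t-test of footprint versus
   local-background pixels with p < 9e-10, footprint >= 9 px, circularity
   (4 pi area / perimeter^2, edge-count perimeter scaled by pi/4; tiny
   discs can slightly exceed 1) >= 0.7. "Signal" is the candidate's peak
   pixel: with footprint means, the 1.9 x local criterion would reject the
   off-center planes of every single mRNA and nothing could satisfy the
   plane-span rule.

Two interpretation points deserve emphasis. First, the t-test must be the
pooled-variance Student test (the MATLAB `ttest2` default), not Welch: a
Gaussian-profile footprint has internal variance comparable to its
contrast, so the Welch statistic saturates near sqrt(footprint area)
regardless of brightness and p < 9e-10 would reject everything, including
the brightest ATS. Second, the per-gene constants are applied verbatim,
including the sub-unity lst-1 overall ratio (0.8), which passes
sub-background peaks by itself and only filters jointly with the other
criteria.

Surviving candidates chain across adjacent planes (within one spot
radius); a 3-D spot's integrated intensity is the sum of its per-plane
background-normalized footprint sums. Cytoplasmic mRNA candidates must
span >= 2 planes, nuclear ATS candidates >= 3 (the manual-scoring
criterion for ATS in this field), and potential ATS must additionally exceed 10 x background in
integrated intensity.

## Photometry

Footprint sums capture a load-dependent fraction of the PSF flux (~0.75
for a single mRNA versus ~0.95 for a bright ATS, because the threshold
truncates dim spots more), which would bias the ATS/mRNA intensity ratio
upward by ~20%. Reported intensities therefore use fixed-aperture
photometry — background-subtracted sums over a 3 px disc on the centroid
plane +/- 2 planes — which captures the same fraction (~87%) for every
point source and is linear in load. The 3 px radius is a compromise: large
enough that centroid jitter costs little flux, small enough that
neighboring spots in dense distal cytoplasm contribute ~1% rather than
~5% to the single-mRNA reference (contamination there deflates every
ATS-to-mRNA ratio).

## ATS confirmation and mRNA calling

A confirmed ATS needs (1) an intron spot inside a nucleus sphere, (2) a
colocalized (within 0.3 um, one z-step) nuclear exon spot, and (3) both
photometric intensities at least the single-mRNA reference (the same
gonad's mean cytoplasmic spot photometry). The nuclear-membership test for
ATS tolerates 0.2 um beyond the fitted radius: fitted radii carry about
one DAPI-edge-width of uncertainty and peripheral chromatin loci sit at
the envelope, so a strict test would cap ATS recall near 0.93. mRNA
calling, by contrast, removes nuclear exon spots against the **strict**
sphere (a generous sphere would eat the perinuclear cytoplasm, where mRNAs
are densest). Spots below 20% of the gonad's mean mRNA intensity AND below
20% of the mean size are removed (conjunctive reading of the
removal rule); spots >= 2 x brighter AND larger are multi-mRNA packets with
copy count = round(intensity/mean).

## Normalization, cells, statistics

Per gonad, intensities rescale so the mean cytoplasmic spot is exactly
10 a.u.; ATS share the scale (so a 17.2-fold ATS is 172 a.u.). Germ-cell
territories are voxel-level nearest-nucleus labels on a 0.5 um grid,
clipped by the outline and a 3 um cap; unassigned in-mask voxels form the
rachis; a brute-force per-voxel oracle checks the labeling exactly.
Cytoplasmic volume excludes the nucleus sphere. Profiles use half-open
bins `[a, a+w)` from the distal end, per-gonad values averaged across
gonads with across-gonad SEM; the region boundary is the distal edge of
the first bin from which the mean stays below 5%. The test dispatcher
gates on Levene (mean-centered) plus per-group Anderson-Darling normality
(p >= 0.05 each; groups under n = 8 are below the AD approximation's
validity and are recorded but not gated on), choosing t/ANOVA or their
nonparametric analogs (KS / Kruskal-Wallis). Half-lives come from a
nonlinear least-squares fit of `N0 * 2^(-t/h)` started from the log-linear
solution; non-decaying series are flagged.

# What a green test does and does not establish

The simulator emulates: packed spherical nuclei with cycle-dependent DNA
content and locus numbers, independent per-locus firing with a graded
probability, broad position-independent ATS loads, a near-uniform
cytoplasmic mRNA field with a basal tail, diffraction-limited spots on
shot-noise-like backgrounds, a slab-shaped imaged volume, and a
membrane-GFP niche arbor. It does **not** emulate: bent gonad axes,
optical aberrations or depth-dependent PSFs, photobleaching,
autofluorescence texture, nuclear shapes beyond spheres (M-phase figures
are spheres here, as in the original analysis), spatial clustering of
mRNAs beyond the per-cell Poisson model, intercellular mRNA movement, or
live dynamics. A green acceptance suite therefore establishes that the
pipeline recovers the stated world without bias through rendering +
detection + quantitation — not that it would perform identically on raw
confocal data with those unmodeled features.

# Numerical and scale choices

* Acceptance-scale cohorts: `scripts/acceptance.R` runs the stated
  20-gonad desk cohort; the in-suite acceptance tests run 8 gonads (plus 4
  weak-Notch and 2 high-firing gonads) to respect the test-time budget,
  with unchanged tolerances. The time-course gonads are 36 x 30 x 12 um —
  decay kinetics do not depend on the imaged extent.
* The high-firing configuration (p = 0.6 everywhere) exists purely to
  power the pairwise-independence bound (|r| < 0.1 needs >= 500 detected
  ATS pairs, far more multi-ATS nuclei than the wild-type profile yields
  at desk scale).
* Ties and degenerate inputs: greedy matchings (circle-chain, candidate
  intersection, spot-truth matching) resolve ties by smallest distance,
  first index; empty profile bins are missing, not zero; a missing
  annulus (image edge) falls back to whatever in-mask pixels exist and is
  flagged; normalization with zero mRNAs is an error by design (the scale
  is undefined).
* All voxel grids are 0-based physical coordinates with voxel centers at
  `(i - 0.5) x pitch`; bins are half-open `[a, a+w)`; gcd labels round
  half-up, raw microns are kept in every computation.

# Known limitations

Detection recall for cytoplasmic mRNAs sits near its contract (~0.90) at
the default density because ~5% of spots genuinely coincide within the
PSF or abut the stack's z-faces; the per-ATS fold estimate inherits a
small negative bias (a few percent) because coincident mRNA pairs that
survive as single spots inflate the single-mRNA reference — a bias the reference normalization convention
shares (its mean is also taken over all cytoplasmic spots). The DTC fallback heuristic (no GFP
channel) flags the distal-most nucleus within 2 um of the cap and is a
construction of this package, not an established rule.
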