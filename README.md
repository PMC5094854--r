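# gonadFISH

Simulation and automated quantitation of single-molecule FISH (smFISH) in
the *C. elegans* distal gonad.

## The problem

The distal gonad holds a pool of germline stem cells maintained by
GLP-1/Notch signaling from a single niche cell, the distal tip cell (DTC).
smFISH with two probe sets resolves the transcriptional response at
single-locus resolution: **exon** probes light up both nascent transcripts
and mature mRNAs, **intron** probes only unspliced nascent transcripts. A
bright nuclear spot present in both channels is an *active transcription
site* (ATS — a chromosomal locus caught transcribing); a dim exon-only
cytoplasmic spot is a single mRNA. Quantifying thousands of such spots per
gonad by hand is impractical, so this package provides the automated
pipeline — and, because raw image data at this scale are rarely shareable,
a forward simulator that generates realistic multi-channel stacks with
complete ground truth, so that every pipeline claim can be tested as
parameter recovery.

It is aimed at people building or validating smFISH quantitation for
tissue-scale data: the same spot-calling cascade, nucleus reconstruction
and positional statistics apply to any "graded signal along an axis"
design.

## The model in brief

- Germ nuclei pack at a mean nearest-neighbor spacing of one germ cell
  diameter, gcd = 4.55 µm; cell-cycle stages G1/S/G2/M = 4/71/22/3 % set
  DNA content (2C–4C) and locus number L ∈ {2,3,4}.
- Each locus fires independently with probability p(x) declining
  logistically along the distal–proximal axis; nucleus-level positivity is
  E_L[1−(1−p)^L], calibrated to ≈70 % in the distal-most 5 µm bin and
  <5 % beyond 30 µm. Active loci carry lognormal nascent loads
  (mean 17.2 mRNA-equivalents, CV 0.8).
- Per-cell mRNA counts are Poisson along a plateau–decline–basal profile
  extending to ~45 µm; spots render as diffraction-limited 3-D Gaussians
  over shot-noise-like backgrounds.
- Detection: per z-plane, segmentation (components >1.5× background) and
  Gaussian local-peak detection intersect; candidates pass fixed criteria
  (peak/overall bg >1.27, peak/local bg >1.9, pooled-t p <9e-10 vs the
  local annulus, >3×3 px, circularity ≥0.7 for the default *sygl-1*
  probes), chain across planes (mRNA ≥2, ATS ≥3 planes), and ATS are
  confirmed by exon–intron colocalization inside a reconstructed nucleus
  with both signals at least a single-mRNA intensity.
- Intensities normalize per gonad so the mean cytoplasmic spot is 10 a.u.;
  germ cells are capped 3-D Voronoi territories; profiles report per-bin
  percentages/means ± SEM across gonads.

## Worked example

```r
library(gonadFISH)

cfg <- run_config(n_gonads = 2, seed = 1)
run <- run_pipeline(cfg, keep_truth = TRUE)
cat(report_run(run))
```

```
# gonadFISH run report

- gonads analyzed: 2
- nuclei: 305; mRNA spots: 2402; ATS: 73
- mean mRNA intensity: 10.00 a.u. (CV 0.23)
- mean ATS intensity: 170.4 a.u. (17.0-fold over single mRNA)
- max ATS per nucleus: 3
- ATS-positive in distal bin: 69.0%
- ATS region boundary (<5% rule): 25 um
- multi-mRNA spots: 0.08%
- gcd estimate: 4.48 um
```

Reading this: the two simulated gonads held 305 detected nuclei; every
gonad's cytoplasmic spots were rescaled to a mean of exactly 10 a.u., and
the confirmed ATS averaged 170.4 a.u. — i.e. ≈17 nascent transcripts per
active site, recovering the generator's load mean of 17.2 within sampling
noise. 69 % of nuclei in the first 5 µm bin had at least one ATS (the
stated world says ~70 %), the ATS region ended between 25 and 30 µm by
the sustained-below-5 % rule, and the nucleus spacing estimate recovers
the 4.55 µm gcd. Against the ground truth, `evaluate_run(run)` reports
mRNA precision/recall 0.997/0.910 and ATS precision/recall 1.000/0.973.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/gonadfish.R", package = "gonadFISH"))')
Rscript $CLI simulate --seed 1 --n-gonads 3 --out sims/
Rscript $CLI analyze  --in sims/ --out results/ --gene sygl-1 --bin-um 5
Rscript $CLI evaluate --seed 1 --n-gonads 3 --out eval/
Rscript $CLI report   --in results/
```

`--mutant q224` switches the simulator to the weak-Notch configuration
(half the nucleus-level firing, region compressed to 20 µm, half the mean
load); `--distal-end left|right` overrides orientation detection.

## Package layout

- `R/params.R`, `R/synthetic.R`, `R/render.R` — the stated world:
  gonad/optics specs, ground-truth sampling, forward rendering.
- `R/outline.R`, `R/nuclei.R`, `R/spots.R` — reconstruction and the
  detection cascade.
- `R/quant.R`, `R/stats.R` — normalization, Voronoi cells, gradients,
  statistical dispatch, half-life fits.
- `R/pipeline.R`, `R/cli.R` — orchestration, manifests, evaluation, CLI.
- `vignettes/gonadFISH-methods.Rmd` — models, parameter rationale, design
  decisions and limitations.
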