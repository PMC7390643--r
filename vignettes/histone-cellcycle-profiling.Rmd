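---
title: "Methods: single-cell immunofluorescence profiling of histone modifications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell immunofluorescence profiling of histone modifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histomux)
```

## The measurement model

Multicolor immunofluorescence with directly labelled modification-specific
antibodies reports the global level of several histone modifications in each
nucleus simultaneously. The measured quantity per nucleus and channel is the
*total intensity* — average pixel intensity times nuclear area, equivalently
the background-subtracted pixel sum over the nuclear mask — in arbitrary
detector units (ADU). Because total DNA doubles from G1 to G2, the total
Hoechst signal is a proxy for cell-cycle position; an S-phase-deposited
acetylation such as H4K5ac serves as a replication reference channel.
Correlating a modification's per-cell totals with these two references, over
a few hundred asynchronous cells, summarizes its cell-cycle dynamics without
synchronization.

histomux implements this analysis as five composable stages: synthetic
data generation, image quantification, normalization/profiling, perturbation
(demethylase-target) analysis, and plate screening. Each stage reads and
writes plain formats (multi-page TIFF plus a JSON channel sidecar, CSV
tables), so measured data can enter at any point.

## The synthetic population generator

No raw image data accompany the published analyses this pipeline follows, so
the generator is a first-class, tested component: it encodes the statistical
structure the analysis assumes and provides ground truth for every
downstream contract.

**Cell cycle.** Each interphase cell carries a uniform clock $t \in [0,1)$
partitioned into G1/S/G2 by fractions $f_{G1}, f_S, f_{G2}$ (defaults
0.5/0.3/0.2, a typical asynchronous culture). DNA content is $c = 1$ in G1,
$c = 1 + u$ in S (with $u$ the S-phase progress), $c = 2$ in G2. The Hoechst
total is $A_h\,c\,L(\sigma_h)$ where $L(\sigma)$ is unit-mean lognormal
noise (meanlog $-\sigma^2/2$) with $\sigma_h = 0.05$; intensities are
positive and right-skewed, which motivates multiplicative lognormal noise
throughout.

**Mark dynamics.** Five model kinds span the qualitative behaviours of H3/H4
modifications:

| kind | total intensity model | defaults | emulates |
|---|---|---|---|
| `proportional` | $A\,c\,L(\sigma)$ | $\sigma=0.08$ | unmodified residues tracking nucleosome number (H3K4un) |
| `replication_coupled` | $A\,(0.3 + \beta \sin \pi u \cdot 1_S)\,L(\sigma)$ | $\beta=1.7$, $\sigma=0.10$ | deposition-coupled acetylation (H4K5ac, H4K12ac) |
| `replication_synchronous` | $A\,c\,(1 + \beta \sin \pi u \cdot 1_S)\,L(\sigma)$ | $\beta=0.25$, $\sigma=0.10$ | DNA-proportional marks restored during S (H3K4 methylation) |
| `delayed_restoration` | $A\,m(t)\,L(\sigma)\,L(\sigma_{G1} \cdot 1_{G1})$ | $\sigma=0.15$, $\sigma_{G1}=0.25$ | repressive marks diluted at replication, restored next G1 (H3K9me3, H3K27me3) |
| `constant` | $A\,L(\sigma)$ | $\sigma=0.10$ | cycle-independent channels |

$m(t)$ is piecewise linear: 0.85→1.0 across G1, flat 1.0 over the first
half of S, 1.0→0.8 over the second half, 0.8→0.95 across G2. The extra G1
lognormal factor reproduces the broad G1 spread of slowly restored marks.
These functional forms are calibrated constructions, not measurements: the
published evidence for them is qualitative (dot-plot shapes and printed
correlation bands), and the parameters above were fixed once so that the
model populations land inside those bands. Under the defaults the
nucleosome-proportional mark correlates with Hoechst at
$r \approx \mathrm{Var}(c)\,/\sqrt{(\mathrm{Var}(c)+E[c^2](e^{\sigma_m^2}-1))
(\mathrm{Var}(c)+E[c^2](e^{\sigma_h^2}-1))} \approx 0.95$ with
$\mathrm{Var}(c)=0.1775$ and $E[c^2]=2$ — the test suite verifies this
against a brute-force Monte-Carlo oracle rather than trusting the algebra.

Because a single 450-cell draw of the delayed-restoration model has a
correlation sampling sd of about 0.05, its group-3 bound is a property of
*replicate-averaged* correlations (as all published correlation values are:
means over three independent experiments), and the tests check it that way.

**Rendering.** Nuclei are drawn as filled ellipses (radius 12 ± 1.2 px,
aspect 0.9–1.1) with uniform per-pixel density `total/area`, so the pixel
sum equals the true total exactly before optics; fields then receive a
Gaussian PSF (σ = 1 px, replicate boundary), a constant background
(100 ADU) and Gaussian read noise (5 ADU). Interior nuclei never overlap
(minimum center distance 2.2× radius); border-clipped nuclei are placed so
at least ~25% of their area falls outside the field; mitotic figures have
0.4× the mean radius and densities raised so their rendered total is 87% of
an interphase G2 cell's — the single-focal-plane deficit reported for
condensed chromosomes, encoded as a rendering constant. The default scene
(450 interior, 12 edge, 8 mitotic nuclei in 512-px fields of ~48 nuclei)
mirrors the published per-sample cell count.

What the generator does *not* emulate: chromatin texture inside nuclei,
z-structure and focal shifts, photobleaching, antibody chemistry, or
spatial background gradients. Passing tests therefore certify the analysis
logic and its statistical calibration, not robustness to every real-world
artifact.

## Image quantification choices

**Thresholding.** Segmentation thresholds the lightly smoothed (σ = 1 px)
Hoechst channel by Otsu's method computed on `log1p` intensities, mapping
the threshold back through `expm1`. On the linear scale the foreground
spans several-fold (DNA doubling) while the background is tight, and Otsu's
between-class criterion can split dim G1 from bright G2 nuclei instead of
background from foreground; log compression restores the intended
bimodality. The threshold method is pluggable in spirit — it is a stand-in
for the interactive "automatic threshold plus visual fine-tuning" of
microscope vendor software.

**Doublet splitting.** Touching nuclei are split by watershed on the
distance transform: regional maxima of the smoothed distance map become
seeds after greedy suppression of maxima closer than 0.8× the median
object radius (within the same component, keeping the higher peak), and
labels grow by nearest-seed propagation. A single near-circular nucleus has
one surviving seed; a doublet at 1.6× radius separation has two. This is an
objective replacement for interactive doublet separation; it is on by
default and can be disabled.

**Exclusions.** Labels touching any field border are flagged `edge`
(partial nuclei bias totals downward); labels smaller than 0.5× the median
non-edge area are flagged `mitotic` (condensed chromosomes); labels with
solidity below 0.8 are flagged `abnormal_shape` (apoptotic-like), an
objective stand-in for manual deletion. Solidity uses the convex hull of
label pixel centers with a half-perimeter boundary correction, clamped to
1. Excluded nuclei stay in the intensity table with their flags; all
downstream statistics drop them.

**Background and measurement.** Background is a per-channel scalar: the
median over the complement of the 3-px-dilated Hoechst foreground (fields
are small and flat; no illumination surface is fitted). Totals are sums of
`max(pixel − background, 0)` — negative residuals clip to zero. The
summation aperture extends 2 px beyond each label (partitioned between
neighbouring labels by proximity, so apertures stay disjoint): the PSF
pushes a few percent of a dim nucleus's flux just outside the Otsu
boundary, and the ring recaptures it; `ring = 0` gives strict label-pixel
sums. Coordinates are pixel-center, row-major; label IDs are 1-based.

## Normalization and profiling

Hoechst totals are mapped onto ≈[1, 2] by order statistics: the 5th-lowest
nucleus is set to 1 and the 5th-highest to 2 (the extreme nuclei are
sometimes outliers), linearly and without clipping, so the transform is
equivariant under positive scaling. Every modification channel is divided
by its population mean over retained nuclei (relative intensity, mean
exactly 1). Cell-cycle correlations are computed on these linear
normalized values, per replicate, and averaged arithmetically across
replicates; perturbation correlations are computed on `log2(value + 1e-6)`
instead, matching how strongly skewed expression data are displayed and
analysed.

A modification is classified by its mean correlation with the S-phase
reference: group 1 above 0.6 (replication-coupled), group 3 at or below
0.2 (little/anti-correlation, delayed restoration), group 2 between. The
published band for group 2 starts at 0.25 yet a value of exactly 0.20 is
placed in group 3, so the rule here is contiguous with the boundary at
0.2; calls falling in (0.2, 0.25] are labelled with an explicit rule string
flagging the ambiguity. Phase gates (S if reference > 1.3; else G1 below
1.25 normalized Hoechst, G2 above 1.75) are a convenience addition for
confusion-matrix checks — headline outputs never depend on them.

## Perturbation and screening defaults

The demethylase analysis samples 400 cells uniformly without replacement
per replicate, correlates log2 expression with each modification over all
400 cells (the 50-cell top-expresser view is display-only), and calls a
mark a substrate at mean $r \le -0.2$ or a product at mean $r \ge +0.2$.
The thresholds are package defaults — published target calls were made
visually — and both are configurable. The generator's transfection model
(30% transfected, lognormal expression, multiplier $e^{-kE/A_E}$ for
substrates and $2-e^{-kE/A_E}$ for products, $k = 1.5$) makes all three
canonical enzyme presets recoverable.

Screening summarizes each well by the median per-nucleus total (robust to
bright outliers; the mean is available), normalizes to the average of
untreated control wells, and calls a hit at ≥2-fold for any acetylation
channel. Dose–response uses the serial-dilution series 0/1/10/100/1000 nM
with a Hill fold change $1 + E_{max} D^h/(D^h + EC_{50}^h)$
($E_{max}=5$, $h=2$); a TSA-like compound gets one tenth the EC50 of a
SAHA-like one, reproducing the tenfold potency gap as a tenfold lower
minimal effective dose. Simulated wells hold 200 cells by default — medians
are stable to a few percent at that size and whole-plate multi-seed
property tests stay fast. No EC50 fitting is performed: the dilution series
is reported as fold changes plus the minimal effective dose.

## Problem sizes, determinism, degenerate inputs

Every stochastic step takes an explicit seed and restores the caller's RNG
state; identical configurations reproduce byte-identical tables and
images. Multi-seed end-to-end properties (group recovery through rendering
and segmentation; screening false-positive rates) run on a reduced scene —
120 interior, 4 edge, 3 mitotic nuclei in 256-px fields — twenty seeds
each; the full default scene is exercised once per run. Degenerate inputs
fail loudly rather than silently: zero-spread normalization anchors,
zero-variance correlation inputs (e.g. an entirely untransfected
population), plates without dose-0 controls, wells below the 20-nucleus
floor, and fields whose foreground leaves no background region all raise
errors.

## Known limitations

- The mark-dynamics models are calibrated constructions; within-phase
  variances of real modifications are unknown and set by choice.
- Segmentation is 2D single-plane with a Gaussian PSF stand-in; no
  z-stacks, deconvolution, or learned segmentation.
- Background is a scalar per channel; no flat-field correction.
- Mitotic cells are excluded, never quantified.
- Correlation-based target calls inherit the usual caveats of
  correlation: indirect effects of an overexpressed enzyme are
  indistinguishable from direct substrates.
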