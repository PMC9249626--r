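---
title: "Quantifying cell-type-specific RNA-ISH signal: models and methods"
author: "spotquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-type-specific RNA-ISH signal: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Chromogenic RNA in situ hybridization (RNA-CISH) renders single RNA
molecules as brown DAB dots superimposed on a blue hematoxylin nuclear
counterstain in one brightfield channel. Quantifying expression per cell
and per cell type therefore requires separating the two stains,
reconstructing nuclear morphology where strong signal has destroyed the
counterstain, segmenting and classifying nuclei by shape alone (no
marker channels are available), and only then integrating the marker
signal over each cell. spotquant implements this pipeline end to end
for tissue-microarray (TMA) spots or whole-slide tiles, together with
the downstream statistics: area-weighted expression summaries, a
mean-independent expression-variability factor, nested ANOVA for
variance decomposition, and survival grouping with multiplicity
control.

## Stain model and demultiplexing

Brightfield absorbance follows Beer–Lambert: with unit stain vectors
$h$ (hematoxylin) and $d$ (DAB) in optical-density (OD) space, a pixel
transmits $I_c = w_c\,e^{-(C_H h_c + C_D d_c)}$ per channel $c$, where
$C_H, C_D \ge 0$ are stain concentrations and $w$ the white reference.
`rgb_to_od()` applies $\mathrm{OD}_c = -\ln(\max(I_c, 1/512)/w_c)$ (the
floor keeps 8-bit black pixels finite) and `deconvolve_stains()` solves
the linear system per pixel with the stain basis completed by the cross
product. Negative concentrations are clipped. The marker channel is
also reported as a *signal intensity* on $[0,1]$: DAB concentration
divided by a saturation constant (default OD 2.0 maps to 1), so 1 means
chromogen-saturated and typical per-cell averages land in the
$10^{-3}$–$10^{-2}$ range.

Defaults: the standard H-DAB vector pair
$h \approx (0.650, 0.704, 0.286)$, $d \approx (0.269, 0.568, 0.778)$
(normalised), configurable per experiment since scanners and staining
batches differ. The white reference is estimated per image as the
99th percentile of the channel values outside the Otsu tissue mask,
falling back to 1.

Marker background (diffuse nonspecific DAB haze) is removed by
Rényi-entropy thresholding (`renyi_threshold()`): the 256-bin histogram
is split at the edge maximising the sum of background- and
foreground-class Rényi entropies of order $\alpha$ (default 0.5, with
$\alpha \to 1$ reducing to the Shannon/Kapur maximum-entropy rule).
Sub-threshold pixels are zeroed before quantification; the
suprathreshold mask also drives nucleus restoration.

## Nucleus restoration

Where dots saturate the image, the absorbance information under them is
destroyed and the unmixed nuclear channel shows voids or spikes. The
void mask is the marker mask dilated by a 2 px lattice disk.
`inpaint_harmonic()` fills each void with the discrete harmonic
extension of its boundary values (sparse Laplace solve). Harmonic
filling was chosen over patch-based texture synthesis deliberately: it
is deterministic, dependency-free, reproduces constants and linear
ramps exactly, and obeys the maximum principle — and segmentation needs
plausible continuity, not texture fidelity. The interface is pluggable
should a texture backend ever be wanted. The mask-derived region of
interest is an assumption: we define "damaged" as "suprathreshold
marker", since no manual annotation exists per spot.

## Segmentation

`segment_nuclei()` chains four steps, each exported separately:

* robust linear stretch of the 1st–99th percentile to $[0,1]$;
* adaptive Otsu masking: Gaussian pre-blur whose FWHM is the *threshold
  smoothing scale* (default 1.3488 px, the convention of the
  originating segmentation tool), per-tile Otsu thresholds on a 128 px
  grid (each over the tile's observed range, making the mask covariant
  under constant offsets), bilinearly interpolated to a threshold
  surface;
* shape-based declumping: smoothed Euclidean distance transform
  (σ = 2 px), greedy local-maximum seeds with minimum separation of
  half the minimum diameter, nearest-seed assignment within each
  connected component (equivalent to a watershed of the distance map
  for convex nuclei);
* size filtering by equivalent circular diameter
  $2\sqrt{A/\pi}$, inclusive bounds, applied *after* declumping.

Default diameter limits are 25–170 px, appropriate for 40x TMA scans;
they are plain parameters and must be matched to the pixel scale of the
material (the synthetic validation spots use 10–120 px because their
immune nuclei are 8–12 px in equivalent radius). Labelling is
4-connected throughout, which affects counts on touching diagonals.

## Cell-type classification

Four morphology features per nucleus — area, mean counterstain
intensity, eccentricity of the moment-equivalent ellipse, and
perimeter-to-area ratio — feed a quadratic Gaussian classifier
(`fit_qda()`) over six classes: cancer, immune, stromal, and three
artifact classes ("small", "irregular", "large"). Priors are uniform by
default (annotation sets are class-balanced by construction); features
are used unscaled, which is immaterial for QDA with full per-class
covariances. Covariances are regularised by $10^{-6}\,\mathrm{tr}/4$ on
the diagonal when near-singular; truly degenerate training data is an
error. Perimeter uses the 4-neighbour crack length scaled by $\pi/4$,
which is exact in expectation for smooth convex regions — adequate for
elliptical nuclei, biased for ragged shapes.

Posteriors can be smoothed across the tissue (`spatial_smooth()`):
per-class raster maps carry each cell's log posterior on its pixels
(background holds the neutral $\log(1/6)$ so isolated cells drift
toward the uniform distribution, harmless after renormalisation), are
mean-filtered with a uniform 100 px disk, read at the centroid, and
renormalised. This encodes the prior that cells co-localise by type; a
confidently classified cell retains its class because its own pixels
dominate its neighbourhood. *The prior fails* when neighbouring cells
are of diverse types — including our own synthetic spots, which place
cells uniformly at random — so the smoothing switch is off in all
synthetic-cohort configurations and should be off for highly
intermixed tissues. Reading the smoothed value at the centroid rather
than averaging over the cell is a simplification that is exact for
convex nuclei.

Quantification support is the nucleus dilated into unlabelled space by
a class radius — 20 px for cancer, 5 px for immune and stromal,
reflecting cytoplasm size — with contested pixels going to the nearest
original segment in exact Euclidean distance (ties to the lower label
id). The implementation (compiled, boundary-pixel bucketing) is tested
against a dense per-pixel oracle. Artifact classes are never expanded
and never enter expression statistics.

## Quantification and quality control

Nonspecific staining appears as near-saturated regions: seed pixels
with signal within the 5 darkest of 256 display bins of saturation
(signal $\ge 1 - 5/256$), dilated by a 10 px disk, are excluded.
Exclusion reduces both the cell's integrated intensity and its area, so
per-cell means stay unbiased. Per cell $i$, $\mathrm{Intensity}_i$ is
the summed signal over its unmasked expanded segment and
$\mathrm{Area}_i$ the pixel count; fully masked cells are dropped with
a logged count.

RNA quality is controlled through a housekeeping positive control
(PPIB in the motivating assay): spot-level weighted means of the
control, cancer cells only (configurable), are split by Otsu into
reliable/unreliable; failing spots are excluded from patient summaries.
Per-spot means rather than per-cell values feed the split — the
granularity at which QC decisions are made.

## Expression statistics

Spot and patient summaries are area-weighted:
$$m = \sum_i \frac{A_i}{\sum A}\,\frac{X_i}{A_i} = \frac{\sum_i X_i}{\sum_i A_i},
\qquad
v = \sum_i \frac{A_i}{\sum A}\left(\frac{X_i}{A_i} - m\right)^2,$$
with $X_i$ the integrated intensity and $A_i$ the quantified area.
Area weighting favours the large cancer cells whose averages are most
reliable and suppresses residual small artifacts. Patient summaries
pool all QC-passing spots' cancer cells (cells weighted by area across
spots); a per-spot-then-average alternative is available by
configuration.

Variance is mean-linked, so raw $v$ values are not comparable across
samples. The *variability factor* generalises the Fano factor to a
fitted power law: ordinary least squares of $\log_{10} v$ on
$\log_{10} m$ across samples (per gene, base 10), with each sample's
factor defined as its residual. Samples need $m, v > 0$ to enter the
fit; zero-variance samples are assigned the minimum observed factor
with a warning (a conservative convention — the degenerate case carries
no variability evidence). OLS on per-patient summaries was chosen as
the reference specification; robust alternatives would change only the
fit, not the interface.

Nested ANOVA (`nested_anova()`) decomposes cell- or spot-level values
over a hierarchy such as patient ⊃ phase ⊃ spot. Because the factor
subspaces are nested, sequential sums of squares reduce to differences
of within-group means, computed in one streaming pass per level —
linear rather than cubic time in the number of levels. F statistics are
taken against the within-innermost-group residual mean square, which
reproduces a dense sequential least-squares fit exactly (tested to
1e-8 relative). One-factor calls give classical one-way ANOVA, with
the balanced two-group case equal to the squared pooled-variance t
statistic.

## Survival analysis

Kaplan–Meier estimation and the k-group log-rank test are delegated to
the survival package behind thin wrappers; hand-computed
hypergeometric-moment values and permutation nulls serve as test
oracles. Expression grouping offers a median split (ties to the low
group) and an optimised three-way split: candidate cut-fraction pairs
from a 5%-spaced lattice over (20%, 80%), $t_1 < t_2$, truncated to at
most 20 evenly chosen pairs; each candidate's log-rank p is computed
and the whole candidate family is Benjamini–Hochberg adjusted — the
multiplicity cost of optimising the threshold is paid explicitly — with
the split of minimum adjusted p chosen (ties to the smaller first
threshold). The lattice is configurable; uneven splits such as
55/36/9% can be supplied directly as fractions.

## The synthetic-data generator

No public cohort of annotated RNA-CISH TMA images exists at desk scale,
so validation runs on a generator with complete ground truth
(`synth_spot_spec()`, `render_synth_spot()`, `generate_cohort()`). It
emulates exactly the structure the pipeline assumes:

* three morphological classes — cancer nuclei large and pale
  (equivalent radius 20–35 px, counterstain OD 0.35–0.55), immune small,
  round, dark (8–12 px, OD 0.8–1.1), stromal elongated (eccentricity
  0.90–0.95) — placed without overlap by rejection sampling (1000
  retries per cell, a deterministic PRNG stream per cell index, so equal
  seeds give bit-identical images);
* dot-like marker signal: per-cell dot counts are negative binomial
  (mean μ, dispersion k) — the super-Poisson, mean-linked family the
  variability factor presumes — with radially decaying dot profiles
  (default peak OD 0.6, radius 2–3 px) scattered in the nucleus dilated
  by the class expansion radius, so expanded segments capture them by
  construction;
* diffuse nonspecific DAB haze: a smoothed random field plus per-pixel
  granularity (default mean OD 0.10). This term is what the
  entropy-suppression stage exists to remove; without it the background
  class of the marker histogram collapses to a spike and entropy
  thresholding becomes unanchored, splitting the dot distribution
  itself. It can be disabled for closed-form renders;
* Beer–Lambert forward mixing with white level 0.96 (not 1.0, to
  exercise white estimation), quantised to 8 bits like scanner output;
* cohort structure: several spots per patient share the patient's
  log-normal expression level μ_p and dispersion k_p; progression and
  survival times are exponential with hazard
  $h_0 e^{\gamma_m z_m + \gamma_v z_v}$, where $z_m$ and $z_v$ are the
  standardised log mean and log overdispersion — so survival can be
  linked to mean expression, to variability, or to neither, with
  administrative censoring.

What the generator does *not* emulate: histological texture, nucleoli,
chromatin structure, scanner blur and tiling seams, stain batch
variation, or spatial co-localisation of cell types (cells are placed
uniformly at random — hence smoothing is off in synthetic
configurations). Passing the synthetic suite therefore demonstrates
correctness of the algorithms under the stated forward model, not
performance on real tissue; the classifier in particular sees far
cleaner class separation than a pathologist's material provides.

## Study conditions and problem sizes

The validation suite uses: a 512×512, 100-cell spot for the unmixing
round trip (recovered DAB RMSE is ~0.2% of maximum, the residual being
8-bit quantisation); a 768×768, 200-cell spot with ~30% of nuclear area
under saturating dots (peak OD 10) for the restoration study — with
inpainting the cell count error is ≤5% and ≥95% of centroids fall
inside true nuclei, while without it recovery drops below 80%; six
224×224 spots for classification precision; 200 simulated samples
(β = 1.6, σ = 0.3) for variability-factor recovery; and a 90-patient,
2-spots-each cohort with hazard linked only to variability
(γ_v = 1.0 per SD, γ_m = 0, baseline 0.04/month, 48-month censoring)
for the end-to-end biomarker study, in which the variability-factor
median split detects the effect while the mean-expression split does
not. At this effect size and cohort depth (~16 cancer cells per
patient) detection power is moderate, not saturated: the fixed-seed
study passes, but variability estimates from few cells are noisy — by
design, since that is the regime the method targets.

## Numerical choices and degenerate inputs

Histograms are 256-bin throughout; threshold ties resolve to the lowest
candidate. Constant images: rescaling returns zeros with a warning;
thresholding errors ("degenerate histogram") and callers fall back to
empty masks; QC passes all spots with a warning. Empty segmentations
yield empty cell tables with warnings, not failures. Posterior
computations run in log space with log-sum-exp normalisation. The
inpainting solve is exact (sparse Cholesky), not iterative. Declumping
seed selection orders by peak height, then by index, making the
procedure deterministic under ties. All disk structuring elements are
exact lattice disks ($x^2+y^2 \le r^2$), so morphological footprints
have reproducible pixel counts (13 at r = 2, 317 at r = 10).

## Known limitations

Touching TMA spots are not split (no grid-model dearraying). Very high
marker abundance that obliterates whole nuclei limits restoration — the
harmonic fill interpolates, it does not hallucinate nuclei. The
classifier assumes nuclei are mostly convex and similar within a class;
complex morphologies need a different segmentation backend, which the
modular design admits. Absolute molecule counts are out of scope: all
expression values are relative intensity units, comparable within one
staining batch only.
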