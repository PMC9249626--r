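# spotquant

Cell-type-specific quantification of chromogenic RNA in situ
hybridization (RNA-CISH) signal from brightfield tissue images.

Single-molecule RNA-CISH assays (e.g. RNAScope with a DAB chromogen)
render each transcript as a brown dot superimposed on the blue
hematoxylin counterstain in a single colour channel. Quantifying
expression per cell — and per *cell type*, without marker channels —
requires unmixing the stains, repairing the counterstain under strong
signal, segmenting and classifying nuclei from morphology alone, and
integrating the marker over each cell's expanded footprint. spotquant
implements that pipeline for tissue-microarray (TMA) spots and
whole-slide tiles, plus the downstream statistics used for biomarker
work: area-weighted expression summaries, a mean-independent
expression-variability factor, linear-time nested ANOVA, and survival
grouping with multiplicity control. A synthetic image generator with
complete ground truth makes every stage testable without external
data.

## The core quantities

Per segmented, classified and expanded cell $i$, the pipeline records
its quantified area $A_i$ (px²) and integrated marker signal $X_i$
(signal-intensity units, where 1 = chromogen-saturated). Spot and
patient summaries are area-weighted:

$$m = \sum_i \frac{A_i}{\sum A}\cdot\frac{X_i}{A_i} = \frac{\sum_i X_i}{\sum_i A_i},
\qquad
v = \sum_i \frac{A_i}{\sum A}\left(\frac{X_i}{A_i}-m\right)^2 .$$

Because $v$ is strongly mean-linked, samples are compared through the
**variability factor**: the residual of an ordinary least-squares fit
of $\log_{10} v$ on $\log_{10} m$ across samples — a generalised Fano
factor with a fitted power-law exponent instead of the unit slope. It
captures expression heterogeneity independently of expression level,
and is the quantity the survival grouping can act on.

## Worked example

Render a synthetic spot with known ground truth, train the
morphology classifier on two annotation fields, and run the full stage
sequence (demultiplex → restore → segment → classify → expand → mask →
integrate):

```r
library(spotquant)

spec <- synth_spot_spec(seed = 7)          # 512 x 512, 28 cells
spot <- render_synth_spot(spec)

feats <- list(); cls <- list()
for (s in 1:2) {
  fld <- render_nucleus_field(synth_spot_spec(seed = 100 + s))
  f <- extract_features(fld$labels, fld$hema)
  feats[[s]] <- f; cls[[s]] <- fld$cells$class[f$label]
}
model <- fit_qda(do.call(rbind, feats), unlist(cls))

cfg <- spot_config(min_diameter = 12, max_diameter = 120,
                   qda_model = model, smooth = FALSE)
res <- run_spot(spot$image, cfg, spot_id = "demo", patient_id = "P1")
table(res$cells$class)
#>  cancer  immune stromal
#>      12       8       8

cancer <- subset(res$cells, class == "cancer")
m <- weighted_mean_expr(cancer$area, cancer$intensity)
v <- weighted_var_expr(cancer$area, cancer$intensity, m)
sprintf("cancer cells: %d  m = %.5f  v = %.3g", nrow(cancer), m, v)
#> "cancer cells: 12  m = 0.00300  v = 5.96e-06"
```

All 28 ground-truth cells are recovered with their true classes, and
the cancer-cell mean expression (0.003 intensity units) sits in the
typical RNA-CISH band of 0.001–0.01 — far below saturation, since most
of a cell's area carries no dot. Cohort-level work goes through
`generate_cohort()` / `run_cohort()`, which add control-gene spot QC,
per-patient summaries, variability factors, nested ANOVA inputs, and
median-split / optimised three-way survival analysis. The synthetic
pipeline parameters differ from the shipped 40x-scan defaults
(`min_diameter = 25`, 170, smoothing on) because the generator's
nuclei are smaller and placed without spatial class structure; see the
methods vignette (`vignettes/spotquant-methods.Rmd`).

A thin command-line wrapper with `generate`, `crop-spots`, `run-spot`
and `run-cohort` subcommands lives in `inst/scripts/spotquant-cli.R`.

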