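# mitomorph

Quantitative mitochondrial morphometry for transmission electron
micrographs, with a validated end-to-end analysis chain and a synthetic
ground-truth generator.

## What it does and for whom

Mitochondrial size and shape are a measurable, convergent endpoint of
mitochondrial stress: under metabolic insult, mitochondria in neuronal
cell models become smaller and rounder. `mitomorph` is for researchers
who image mitochondria by TEM and need a reproducible route from raw
micrographs to per-condition statistics:

1. **Segmentation** — inversion, rolling-ball background subtraction
   (radius 60 px), FFT bandpass (60/8 px bounds) with vertical scan-line
   suppression (5% tolerance of direction), maximum-entropy (Kapur)
   thresholding, binarization.
2. **Morphometry** — ROI-restricted particle analysis (8-connectivity,
   strict >600 px size filter) yielding eight shape parameters per
   particle: area, area², perimeter, Feret's diameter, circularity
   `4πA/P²`, roundness `4A/(π·major²)`, aspect ratio, and form factor
   `FF = P²/(4πA)`.
3. **Statistics** — per-cell averaging (the cell is the statistical
   unit), Shapiro–Wilk screening, one-way ANOVA, Dunnett's many-to-one
   comparisons against a declared control (Monte Carlo or numerical
   evaluation of the multivariate-t adjustment), and Fisher's LSD.
4. **Expression** — qPCR relative quantification by the 2^−ΔΔCt method
   with triplicate quality control (SD > 0.5 cycles trims the worst
   replicate or excludes the triplicate), normalized to a reference gene.
5. **Synthetic validation** — a TEM-like scene generator with analytic
   per-particle ground truth (elliptical particles, illumination
   gradient, noise, scan-line stripes, membrane band), so segmentation
   and statistics are tested against truth that is computed, not assumed.

See `vignettes/mitomorph-methods.Rmd` for the model, conventions and
design decisions.

## Worked example

Validate the whole chain on a synthetic two-condition experiment with a
planted 30% mean-area reduction (10 cells/condition here; the full-scale
run uses 25):

```r
library(mitomorph)
rep <- validate_pipeline(seed = 42L, n_cells = 10, size_shift = 0.3)
print(rep)
#> Synthetic validation (seed 42, 10 cells/condition, size shift 0.30)
#>   detection rate:          1.000
#>   mean |area error|:       4.469%  (pass: TRUE)
#>   min per-particle Jaccard: 0.905  (pass: TRUE)
#>   per-cell area correlation: 0.9988 (pass: TRUE)
#>   Dunnett area p_adj:      0 (significant: TRUE)

rep$stats$dunnett[, c("parameter", "comparison", "estimate", "t", "p_adj")]
#>   parameter         comparison  estimate         t p_adj
#> 1      area treated vs control -404.1667 -8.326445     0
```

Every planted particle was found (detection 1.0); measured areas carry a
small systematic segmentation dilation (~4%, common to both conditions);
per-particle overlap with the planted ellipses is ≥ 0.9 Jaccard; per-cell
mean areas track truth at r ≈ 0.999; and the planted area reduction is
flagged by ANOVA + Dunnett (the estimate, −404 px², is the treated-minus-
control difference in per-cell mean area; adjusted p below the Monte
Carlo resolution of 10⁻⁵).

Analyzing real data instead: build a manifest (TIFF path, ROI JSON,
condition, cell id per image), then

```r
cfg <- run_config(manifest, pipeline_config(), control = "0mM",
                  out_dir = "results", seed = 1L)
res <- run_full_analysis(cfg)   # particles.csv, cells.csv, anova.csv, dunnett.csv
```

A thin command-line front-end with `simulate` / `segment` / `measure` /
`qpcr` / `stats` / `run-all` / `validate` subcommands is installed at
`inst/cli/mitomorph.R`.

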