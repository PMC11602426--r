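# lateralline

Quantitative analysis of aminoglycoside-induced hair-cell death in the
zebrafish lateral line.

Aminoglycoside antibiotics (neomycin, gentamicin, G418) kill the
mechanosensory hair cells of the zebrafish lateral line by at least two
distinct routes: an **acute** death within ~1 h of exposure, marked by
mitochondrial calcium transients, and a **delayed** death unfolding for up
to 24 h after washout, marked by drug accumulation in Rab7⁺ endolysosomal
vesicles. Telling these apart requires a chain of quantitative steps —
3-D segmentation of neuromasts, hair cells and vesicles from fluorescence
stacks; compartmental drug-accumulation ratios; F/F₀ calcium-transient
classification; and Hill-curve dose–response analysis of per-fish
hair-cell counts. `lateralline` implements that chain as tested,
reusable R functions, for researchers analysing lateral-line ototoxicity
data or benchmarking segmentation pipelines on phantoms with known ground
truth.

## What it computes

**Dose–response.** Per-fish hair-cell counts (summed over 4 neuromasts)
are normalized to untreated controls (100% = control mean) and fitted
with a constrained Hill survival curve

S(d) = 100 / (1 + (d / HC₅₀)^h)

on log-spaced dose, with fish-level bootstrap uncertainty. `HC50` is the
concentration killing half the hair cells; when no dose drops mean
survival below 60%, the fit reports *not determined* rather than
extrapolating.

**Calcium transients.** Per-cell traces (30-s frames, 2.5-min baseline)
are normalized to baseline, F/F₀(t) = F(t) / mean(F over baseline). A
cell *responds* if F/F₀ exceeds baseline mean + 2·SD before its
fragmentation endpoint. Condition tables of responder counts are compared
by Pearson chi-square; per-cell maxima by Kruskal–Wallis with Dunn's
post-hoc z-tests.

**Segmentation.** Neuromast mask: Gaussian blur (σ = 6 px) + triangle
threshold. Hair cells: 5-class multi-Otsu background (replaced with
1e-7), Sauvola local threshold (window 45, k = 0.2), then seeded
watershed on the Euclidean distance transform. Vesicles: fused
multi-scale Laplacian-of-Gaussian spot and Hessian-ridge filament
detectors, slice by slice, with shipped `(scale, cutoff)` presets for
Rab7 and G418 channels; vesicles outside the neuromast are discarded and
cytoplasm = neuromast − vesicles (an exact partition, asserted on every
run). The drug-accumulation statistic is the mean drug intensity in the
vesicle mask over the mean in the cytoplasm mask.

**Synthetic data.** `gen_neuromast_stack()`, `gen_timelapse()`,
`gen_calcium_traces()` and `gen_doseresponse_counts()` generate image
phantoms, drifting time lapses, calcium traces and overdispersed count
tables with exact ground truth, so every stage above is testable without
any microscopy data.

## Worked example

```r
library(lateralline)

# Simulate a 1-h neomycin-like counting experiment (true HC50 = 44 uM,
# 10 fish/dose, counts summed over 4 neuromasts) and estimate HC50.
cp <- count_phantom_params(true_hc50_um = 44,
                           doses_um = c(0, 6.25, 12.5, 25, 50, 100, 200, 400),
                           seed = 1)
counts <- gen_doseresponse_counts(cp)
fit <- fit_hill(normalize_survival(counts), n_boot = 200, seed = 1)
fit
#> <hill_fit> HC50 = 42.09 uM, slope = 2.05 (bootstrap SE 2.4)

# Sixteen dying cells in the acute regime: responder classification and
# maximum F/F0 summary.
g <- gen_calcium_traces(trace_phantom_params(n_dying = 16, n_living = 0,
                                             seed = 1),
                        condition = "neo100_acute")
summarize_condition(g$traces)
#>      condition n_dying n_responders max_ff0_mean max_ff0_sd
#> 1 neo100_acute      16           16       2.2002   0.460038

# Cross-condition contingency statistics on responder counts.
ct <- data.frame(condition = c("neo100_acute", "g418_100_delayed",
                               "g418_400_acute"),
                 n_dying = c(16, 11, 14), n_responders = c(16, 2, 10))
cs <- condition_stats(ct)
sprintf("chi-square = %.2f, df = %d, p = %.2g",
        cs$chisq$statistic, cs$chisq$df, cs$chisq$p_value)
#> "chi-square = 20.25, df = 2, p = 4e-05"
```

The fitted HC50 (42.1 µM) recovers the generating value within the
fish-level sampling noise; the responder summary returns the generating
peak distribution (mean 2.2, SD 0.46) and classifies all 16
suprathreshold cells as responders.

## Package layout

- `R/voxelstack.R`, `R/imaging.R` — stack container and I/O, rigid
  registration, rolling-ball background subtraction, normalization,
  projection
- `R/thresholds.R`, `R/detectors.R`, `R/segmentation.R` — triangle /
  multi-Otsu / Sauvola thresholds, spot and filament detectors, the mask
  pipeline
- `R/quantification.R` — vesicle tables, per-neuromast summaries,
  compartment ratios, two-group tests
- `R/calcium.R` — F/F₀, responder rule, endpoint alignment, condition
  statistics
- `R/dose_response.R` — survival normalization, Hill fits, time-course
  and protection statistics
- `R/synthetic.R` — phantom generators with ground truth
- `vignettes/lateralline-methods.Rmd` — the models, parameter choices and
  limitations in detail
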