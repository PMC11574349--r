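# optoquant

Quantification tools for live-imaging experiments in which nuclear levels of
a morphogen transcription factor are acutely perturbed with light. In early
*Drosophila* embryos the transcription factor Dorsal (DL) patterns the
dorsal-ventral axis: high-threshold targets (*sna*) are expressed ventrally,
low-threshold targets (*sog*) laterally. Optogenetic tags let blue light
either export DL from nuclei reversibly (LEXY-type) or degrade it
irreversibly (BLID-type), and the resulting movies pose a chain of
quantification problems that this package solves end to end:

* **Transcription-site detection** — MS2/MCP foci per frame via a
  two-threshold scheme (low threshold on a median-filtered,
  background-subtracted, blurred image; high threshold on the raw image;
  an object must pass both), with an optional logarithmically increasing
  threshold during nc14, plus instantaneous counts normalized by the
  starting count.
* **Expression-domain geometry** — pooled centroids filtered at 2 median
  absolute deviations per axis, convex-hull areas, and the nc14 − nc13 area
  change; in fixed cross-sections, domain widths as ellipse arc length
  normalized by perimeter.
* **Nuclear quantification** — Laplacian-of-Gaussian segmentation (sigma 4
  population view / 10 high zoom / 20 nuclear rings), watershed splitting,
  embryo-ellipse fitting with a 100 px midline band, mean ± s.d. intensity
  traces, and nearest-neighbour tracking with 10-frame gap closing and
  track-quality filters.
* **Recovery kinetics** — nonlinear least squares of
  `I(t) = I_ss − α·e^(−βt)` for FRAP and for nuclear re-import after
  light-off (β in min⁻¹ is the inverse recovery time), and pooled t-test
  comparison of rates between conditions.
* **Gradient fitting** — Gaussian fit `A·exp(−(x−µ)²/2σ²) + B` of the DV
  nuclear-intensity profile.
* **Statistics** — pooled two-sample t-test, one-way ANOVA with Tukey HSD,
  exact noncentral-t sample size, and cross-embryo averaging via modified
  Akima interpolation.
* **Synthetic embryos** — a generator that renders nuclei movies, MS2 focus
  movies, FRAP movies and fixed cross-sections with exact ground truth, so
  every stage above is testable without microscopy data.

See `vignettes/optoquant-methods.Rmd` for the models, parameter choices and
their rationale.

## Worked example

Compare the published nuclear re-import rates between dark and blue-light
FRAP conditions, then recover kinetics from a simulated FRAP movie:

```r
library(optoquant)

## dark vs light recovery rates (min^-1): pooled two-sample t-test
compareRates(c(0.23, 0.25, 0.17), c(0.84, 0.80, 1.14))
#> $t        -6.457511
#> $df       4
#> $p        0.002961164
#> $meanDiff -0.71

## simulate a light-condition FRAP movie and re-estimate beta
cfg <- frapConfig(nFrames = 150, seed = 5,
                  noise = list(gaussianSd = 50, poisson = FALSE,
                               saltPepperFraction = 0))
sim <- simulateFrapMovie(cfg, bleachRoi = c(96, 96, 40),
                         bleachFrames = 21:40,
                         frapParams = c(Iss = 2781, alpha = 1622, beta = 0.84))
res <- frapAnalyze(sim$stack, c(96, 96, 40), 21:40,
                   segParams(logSigmaPx = 10))
res$fit
#> ExpFitResult: I(t) = 2768 - 1566 * exp(-0.8511 t); rss = 284.1 (converged)
```

The t-test p-value of 0.003 says the light-condition rates (β ≈ 0.8–1.1
min⁻¹) are significantly faster than the dark rates (β ≈ 0.2 min⁻¹): DL
re-enters nuclei several times faster under blue light, i.e. it keeps
cycling in and out even while export is favoured. The movie analysis
recovers the generator's β = 0.84 min⁻¹ within ~1%.

A full simulate → detect → count → area pipeline runs with:

```r
out <- runPipeline(simConfig(imageShape = c(256, 256), nFrames = 20,
                             nucleusRadiusUm = 2.2, nucleusSpacingUm = 5,
                             seed = 1), "run1")
```

A thin command-line wrapper is installed at `inst/scripts/optoquant`
(subcommands `simulate`, `foci`, `area`, `frap`, `stats`, `pipeline`).

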