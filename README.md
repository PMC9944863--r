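# relcol

How much Shannon information does a small palette of *relevant colors*
retain about an image?  When people (or algorithms) reduce a painting's
hundred thousand distinct colors to a dozen representative ones, every
pixel gets mapped to one of $n$ palette colors; `relcol` measures what
that mapping preserves and how close any given method comes to the best
achievable.

The package is aimed at color scientists and visual-psychophysics
researchers who want to score palette-extraction methods — algorithmic or
human — on an information-theoretic scale, with rendering-fidelity metrics
alongside.

## The measure

A pixel drawn at random from an image is a realization of a discrete
variable **A** over RGB triplets; a quantization induces a label variable
**A**<sub>q</sub>.  The information retained is

> *I*(**A**; **A**<sub>q</sub>) = *H*(**A**) + *H*(**A**<sub>q</sub>) −
> *H*(**A**, **A**<sub>q</sub>)   (bits),

estimated from binned histograms with the Grassberger bias-corrected
entropy estimator (digamma per-count corrections; the plug-in estimator is
also available).  A method's **efficiency** on an image at a given *n* is

> η = *I* / *I*<sub>ref</sub>,

where *I*<sub>ref</sub> comes from the reference quantizer that maximizes
mutual information (`mincentropy_quantize()`, hill climbing on the binned
color histogram).  η ≈ 1 means near-optimal information capture.

What's inside:

* **Five clustering quantizers** — k-means++, maximum-entropy clustering,
  Gaussian-mixture EM, MI-maximizing hill climbing, and graph-cut
  alpha-expansion — plus a **colorimetric** quantizer that partitions
  CIELAB into cells and determines *n* automatically.
* **Cluster-count estimators**: Caliński–Harabasz and Davies–Bouldin scans,
  and an adaptive k-means that grows clusters from a spawn threshold.
* **Color rendering metrics**: mean CIECAM02-UCS ΔE (full CIECAM02 forward
  model) and spatially filtered S-CIELAB ΔE.
* **A synthetic painting-image generator** with known mode palettes, mixing
  proportions, spatial layouts and seeded noise — the ground truth that
  makes every stage testable — plus simulated observers who pick relevant
  colors as 5×5 patch means at chosen image locations.
* **A pipeline** (`run_experiment()`) that scores every method at matched
  (image, *n*), pairs fixed-*n* stages (colorimetric, JPEG) at the
  colorimetric *n*, and summarizes with BCa bootstrap limits, regression of
  *I* on log₂ *n*, and Kruskal–Wallis tests.

## A worked example

```r
library(relcol)

corpus <- synthetic_corpus(n_images = 3, n_true_range = c(4, 7),
                           width = 64, height = 64, seed = 3)
cfg <- experiment_config(corpus, methods = c("kmeans", "mincentropy"),
                         n_observers = 2, seed = 5, delta_e = FALSE,
                         max_pixels = 4096)
summary <- run_experiment(cfg)
dplyr::select(summary, image_id, method, n, I, eta)[1:6, ]
#>   image_id method          n     I   eta
#> 1 synth01  kmeans          7  2.68 0.954
#> 2 synth01  mincentropy     7  2.81 1
#> 3 synth01  kmeans          8  2.77 0.923
#> 4 synth01  mincentropy     8  3.00 1
#> 5 synth01  observer        7  2.49 0.887
#> 6 synth01  observer        8  2.50 0.834

summarize_experiment(summary, replicates = 500, seed = 2)
#>   method        rows mean_eta eta_lower eta_upper mean_I
#> 1 colorimetric     3    0.710     0.656     0.740   3.94
#> 2 kmeans           6    0.926     0.894     0.947   2.65
#> 3 mincentropy      9    1         1         1       3.75
#> 4 observer         6    0.854     0.767     0.901   2.42
```

Reading the rows: on the first image the reference maximizer captures
2.81 bits at *n* = 7; k-means captures 2.68 bits of it (η = 0.95), and a
simulated observer's seven picked colors capture 2.49 bits (η = 0.89).
Aggregated over the corpus, k-means sits a few percent below the
reference, observers lower still, and the colorimetric method (scored at
its own automatic *n*) lowest — the qualitative ordering the information
analysis is designed to expose.  Efficiency intervals are 95% BCa
bootstrap limits.  The growth of information with palette size is
summarized by `regression_mi_vs_logn()`:

```r
regression_mi_vs_logn(dplyr::filter(summary, method == "kmeans"),
                      replicates = 500, seed = 7)
#> <relcol_regression> I = -0.6726 + 1.1651 * log2(n); slope 95% CI (0.8213, 1.3848)
```

`autoplot()` methods exist for summaries (boxplots of *I* by method),
regressions, index-scan curves and palettes; `tidy()`/`glance()` methods
cover the fitted objects.  A thin command-line front end lives at
`inst/cli/quantify.R` (`synth`, `run`, `nscan`, `report` subcommands).

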