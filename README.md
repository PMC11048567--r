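# invgrad

Invasion-gradient analysis of vegetation communities on wetland and stream
compensatory mitigation sites.

## The problem

Compensatory mitigation sites (wetlands and streams restored or created to
offset permitted impacts under the Clean Water Act) are held to quantitative
performance standards, and one of the most consequential is the allowed
relative abundance of invasive plants. If the standard is set very low
(e.g. 5%), managers are compelled to apply broad-spectrum herbicides to
communities that may still be functioning well, killing desirable natives in
the process. Setting that standard rationally requires knowing *at what
level of invasion native community properties actually begin to decline*.

`invgrad` implements the plot-based analysis used to answer that question.
Vegetation is sampled in five-plot transects spanning an invasion gradient
from completely invaded (group A, invader relative cover > 20%) to uninvaded
(group E, < 5%), with cover recorded in modified Daubenmire classes
(midpoints 1, 3, 15, 38, 63, 85, 98%) averaged over four 1 m² subplots. The
package is aimed at vegetation ecologists, mitigation practitioners and
agency reviewers who need these analyses reproducible and testable.

## What it computes

- **Floristics** — relative abundance p_i = cover_i / Σ cover; mean native
  species richness; floristic quality index FQI = C̄·√S over the S native
  species with coefficients of conservatism C; 50/20-rule dominants; Rényi
  diversity profiles H_α = log(Σ p_i^α)/(1−α) (richness at α = 0, Shannon at
  α = 1, Simpson at α = 2, dominance at α = ∞); exact and permutation
  species accumulation curves.
- **Composition** — pairwise Sørensen similarity CC = 2a/(2a+b+c) between
  gradient groups, and rank-based ANOSIM,
  R = (r̄_between − r̄_within)/(M/2), with seeded permutation inference and
  per-group dissimilarity-rank summaries.
- **Threshold (the core estimator)** — `invasion_threshold()` sorts plots by
  invader dominance, forms the running average of invader relative abundance
  against native richness (bin = number of transects), fits a polynomial
  trend, and locates the abundance at which richness peaks or its declining
  limb begins. That abundance is the empirical basis for an
  invasive-species performance standard (≈10% on the systems this analysis
  was designed around).
- **Compliance** — `evaluate_standard()` applies the cumulative rule: the
  summed relative abundance of all invaders present must be no greater than
  the standard, per zone.
- **Synthetic studies** — `generate_study()` draws gradient datasets with a
  known hump-shaped richness curve so the whole pipeline can be exercised
  and validated without field data.

## Worked example

```r
library(invgrad)
ds <- generate_study(generator_config(n_transects = 12, seed = 42))
group_summary(ds)
#>   group n_plots mean_native_richness  fqi invader_relabund
#> 1     A      12                  7.7 32.3             51.3
#> 2     B      12                 11.8 35.5             20.7
#> 3     C      12                 12.2 33.0              7.7
#> 4     D      12                 11.2 32.6              1.6
#> 5     E      12                 11.3 32.8              0.0
```

Native richness is *highest at moderate invasion* (group C, ~8% invader
abundance) — the hump the threshold procedure quantifies — while heavy
invasion (group A) depresses it.

```r
anosim_test(dissimilarity_matrix(ds), ds$plots$group,
            n_permutations = 1000, seed = 42)
#> Analysis of similarity (ANOSIM)
#>   R = 0.1201, permutation p = 0.000999 (1000 permutations, one-sided)
```

Composition differs significantly across the gradient (the difference is
driven by the invaded end; the per-group rank summaries in the returned
object show groups B–E aligned with between-group similarity).

```r
fit <- invasion_threshold(ds)
fit
#> Invasion threshold estimate (running-average / polynomial trend)
#>   threshold: 12.34% invader relative abundance (declining limb)
#>   bin = 12 plots, degree-3 fit, R^2 = 0.910, 49 curve points
plot(fit)   # scatter, cubic trend, threshold line

evaluate_standard(ds, standard = 10, zones = "group")
#> Invasive-species performance-standard compliance
#>     zone cumulative_relabund standard pass
#>        A               51.98       10 FAIL
#>        B               20.97       10 FAIL
#>        C                7.80       10 pass
#>        D                1.54       10 pass
#>        E                0.00       10 pass
#>  overall               21.11       10 FAIL
```

The detected threshold for this dataset is 12.3% invader relative abundance:
the fitted native-richness curve rises to a maximum and starts its declining
limb there, close to the 10% level the generator plants. The compliance
table applies a 10% standard zone by zone.

`run_pipeline()` chains every stage (group summary, Sørensen matrix, ANOSIM,
Rényi and accumulation curves, threshold, compliance) and writes a
deterministic CSV/JSON report bundle with a manifest, from either field CSVs
or a generator configuration.

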