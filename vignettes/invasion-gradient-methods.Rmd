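---
title: "Methods: invasion gradients, community metrics and the richness-decline threshold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: invasion gradients, community metrics and the richness-decline threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invgrad)
```

## The sampling model

`invgrad` analyses vegetation sampled along *invasion gradients*: linear
transects laid across a population of a target invasive plant, from its
dense core to adjacent uninvaded vegetation. Each transect carries five
4 m² plots labelled A–E: A "completely invaded" (invader relative cover
above 20%), C near the edge of the invasive population, E "uninvaded"
(below 5%), with B and D in sequence between them. Each plot is sampled as
four nested 1 m² subplots.

Cover is estimated visually on a modified Daubenmire class scale —
0–1, 1–5, 5–25, 25–50, 50–75, 75–95, 95–100 percent — and each class enters
analysis through its midpoint rounded half-up to a whole integer
(1, 3, 15, 38, 63, 85, 98). A plot's cover for a species is the mean of its
four subplot midpoints, absences counting as zero. Two conventions are
deliberate and documented rather than forced by the field protocol:

* **Boundary assignment.** The classes share endpoints, so a value falling
  exactly on a boundary is ambiguous in principle. We treat classes as
  half-open `[lower, upper)` with the last closed at 100, so exactly 1%
  belongs to the 1–5% class. This is deterministic and order-preserving. A
  side effect is that the 0–1% class's *rounded* midpoint (1) sits on its
  own upper boundary and therefore maps to the class above; all other
  midpoints map back to their own classes.
* **Half-up rounding.** Class-bound means round half *up* (37.5 → 38,
  97.5 → 98); banker's rounding would give 62.5 → 62 and break the printed
  midpoint set.

A `study_dataset` bundles the plot × species mean-cover matrix, plot
metadata (transect, gradient group) and a species-attribute table (native
status, coefficient of conservatism 0–10, invader flag). Validation
enforces the design: every transect has exactly one plot per group, every
recorded species has attributes, and the target invader is flagged — note a
taxon may be flagged invasive while botanically native, as regulated
cattails are. Long-form CSV is the canonical interchange format; a wide
layout is accepted read-only, and congeneric taxa can be collapsed onto one
analysis taxon through an alias map (covers summed).

## Community metrics

**Relative abundance** of species *i* over a plot set is
$p_i = \sum \text{cover}_i / \sum_j \sum \text{cover}_j$. Cover sums are
not constrained to 100% (canopies overlap), so proportions are always
renormalised from the recorded covers.

**Native richness** counts native species with cover > 0; the target
invader and all non-natives are excluded. The presence threshold is
"anything above zero after subplot averaging" — a species seen in one
subplot at the lowest class still counts.

**FQI** is $\bar{C}\sqrt{S}$ with $\bar{C}$ the mean coefficient of
conservatism over the $S$ qualifying species pooled across the plot set.
Two decisions were genuinely open. First, pooling: group-level FQI could
also be computed per plot and averaged; we pool across the group's plots
(the alternative is a one-liner on per-plot calls). Second, scope: we
restrict to native species by default, matching the native-centric framing
of mitigation monitoring, with `native_only = FALSE` available. Species
lacking C-values are excluded from both $\bar{C}$ and $S$ and reported.

**50/20 dominants** follow the canonical rule: species sorted by descending
abundance, the minimal leading set reaching a cumulative 50%, plus every
species individually at or above 20%. Ties are broken by abundance then
name, so output is deterministic.

**Rényi profiles** use the closed forms at the special orders —
$H_1 = -\sum p_i \log p_i$, $H_\infty = -\log\max p_i$, $H_0 = \log S$ —
rather than numerical limits; elsewhere
$H_\alpha = \log(\sum p_i^\alpha)/(1-\alpha)$. Profiles are non-increasing
in $\alpha$ and flat exactly for an even community; this ordering property
is what makes one curve lying above another a genuine diversity statement.

**Species accumulation** defaults to the exact analytic estimator: the
expected richness of a random $k$-plot subset is
$\sum_i \left(1 - \binom{n-n_i}{k}/\binom{n}{k}\right)$ for species *i*
occupying $n_i$ of $n$ plots, with the matching hypergeometric subset
variance (computed from pairwise joint-absence probabilities). A seeded
permutation mode (default 1000 orderings) is retained for fidelity to
permutation-based workflows. Binomial coefficients are evaluated through
`lchoose` to avoid overflow.

**Sørensen / ANOSIM.** Group-level composition uses Sørensen similarity on
presence sets pooled across each group's plots (a per-transect variant is
exposed). For significance testing, plots are compared with a
dissimilarity matrix and rank-based ANOSIM:
$R = (\bar{r}_{between} - \bar{r}_{within}) / (M/2)$ over the $M$ pairwise
dissimilarity ranks (average ranks at ties), with one-sided inference from
random relabellings that preserve group sizes and the add-one estimator
$p = (1 + \#\{R^* \ge R\})/(1 + N)$, which is conservative and never zero.
The plot-level metric feeding ANOSIM is not dictated by the group-level
Sørensen analysis; we default to 1 − Sørensen on presence sets (binary),
with a cover-weighted Bray–Curtis option, and document both. Per-group and
"Between" rank distributions are summarised as boxplot statistics (median,
quartiles, whiskers at 1.5 × IQR, outliers beyond) for the standard ANOSIM
diagnostic plot.

## The threshold estimator

The package's central fit, `invasion_threshold()`, operationalises the idea
that native richness is hump-shaped along the invasion gradient — highest
at moderate invasion, depressed at heavy invasion — and that a defensible
performance standard sits where the hump starts to decline:

1. compute each plot's invader relative abundance (summed target-invader
   cover over the plot's total cover) and sort plots in descending order,
   ties broken by transect then plot id;
2. slide a window of width *b* (the *bin*) along the sorted sequence and
   record window means of abundance (x̄) and native richness (ȳ);
3. fit a least-squares polynomial ȳ ≈ P(x̄);
4. report the abundance where P peaks, or where its declining limb begins.

Open choices and their resolutions:

* **Bin width** defaults to the number of transects, the natural block size
  of the design (each gradient group contributes one plot per transect).
* **Window semantics.** A "running average" could mean overlapping or
  disjoint windows. We default to a sliding window with unit step, giving
  $n - b + 1$ points and a smooth scatter; a five-point block-average
  variant is available (`window = "block"`). The same windows are used for
  x and y, so each point is an honest (mean x, mean y) over one plot set,
  and the x̄ sequence inherits monotonicity from the sort.
* **Degree** defaults to 3: a cubic is the lowest degree able to represent
  an asymmetric hump with a declining limb; it is configurable, and the
  test suite uses degree 2 against planted quadratic truth where the vertex
  is analytic.
* **Detection mode.** `declining_limb` (default) scans P′ on a 2001-point
  grid from the low-invasion end of the observed x̄ range and returns the
  first sign change from ≥ 0 to < 0, refined by root-finding on P′;
  `peak` maximises P. For a fitted curve with a single interior maximum the
  two coincide. If the fit is monotone over the observed range there is no
  interior optimum: the estimator returns the range endpoint and flags the
  result (`flagged = TRUE`, with a warning) instead of guessing.
* **Clipping.** Thresholds are always inside the observed windowed
  abundance range; the polynomial is never extrapolated.

The object behaves like a fitted model: `print`, `summary`, `coef`,
`predict`, `fitted`, `residuals` and `plot` methods are provided, and the
running-average curve and sorted plot table ride along for inspection.

**Compliance.** `evaluate_standard()` applies the cumulative rule: the
relative abundances of *all* listed invaders in a zone are summed and
compared with the standard. Compliance is "no greater than" — a zone at
exactly the standard passes; the boundary convention is explicit because
standards are phrased both as thresholds and as tolerances in practice.
Cumulative abundance is additive over disjoint invader sets by
construction.

## What the generator emulates — and what it does not

`generate_study()` exists so every stage above can be exercised and
validated against known truth. It emulates the *statistical structure* the
analysis assumes:

* five plots per transect with group-level target invader relative
  abundances defaulting to (A, B, C, D, E) = (60, 26, 7, 1, 0)% — inside
  the group-mean ranges observed across invaders in comparable field
  datasets (A ≈ 48–66, B ≈ 23–44, C ≈ 3–14, D ≈ 0–2.6, E ≈ 0–0.4) — with a
  truncated-normal within-group spread (SD = 25% of the mean, floor 0.5
  points) and exact zeros when the group mean is zero;
* a unimodal expected native-richness curve: a shifted-lognormal bump
  peaking at 10% invader relative abundance with 12 expected natives per
  plot. The shift (10 points) and log-width (1.2) keep richness at zero
  invasion close to, but below, the peak and depress it towards heavy
  invasion, reproducing the field pattern in which moderately invaded plots
  are the richest, uninvaded plots nearly as rich, and heavily invaded
  plots poorest. A baseline-plus-beta bump was considered and rejected: it
  cannot fall below its own baseline at heavy invasion, which the observed
  group pattern requires. Realized richness is Poisson around the curve,
  truncated at one species;
* a rank-lognormal species-abundance profile over an 80-species native pool
  (plus occasional incidental exotics), giving realistic unevenness for the
  Rényi and accumulation analyses without claiming floristic fidelity to
  any real site;
* the full measurement pathway: raw covers receive multiplicative
  lognormal subplot noise (sdlog 0.35), are discretized to Daubenmire
  classes per subplot, and re-emerge as four-midpoint averages — so
  generated data carry the same quantisation distortion as field data, and
  every emitted cover is an average of four values from the midpoint set.

Noise magnitudes are not reported in the source studies; the defaults here
were chosen once as field-realistic and calibrated only against the
generator's own targets (realized group-mean abundances close to the
configured means and monotone A→E), never against downstream test
outcomes. A single seed drives a splittable per-transect stream, so
transect *k* is identical whatever the total transect count and whole
datasets are bit-reproducible.

The generator does **not** emulate: spatial autocorrelation among plots or
transects, environmental covariates and their interaction with invasion,
mechanistic competition, observer error in species identification, or
between-site heterogeneity. Passing tests therefore demonstrate that the
*procedures* are correct and that the threshold estimator recovers a known
planted truth under realistic sampling noise — not that any particular
field system obeys the planted curve.

## Validation design and problem sizes

The test suite validates each operation against independent oracles:
exhaustive subset enumeration for the exact accumulation curve (≤ 6 plots),
exhaustive relabelling for ANOSIM p-values (6 plots, 2 groups,
$\binom{6}{3} = 20$ relabellings), hand-computed examples for FQI, the
50/20 rule, Sørensen and window means, closed forms for Rényi orders, and
`vegan` as an independent implementation for the ANOSIM statistic, Rényi
profiles and exact accumulation means. Parameter recovery for the
threshold estimator uses batches of seeded default studies (10–12
transects, i.e. 50–60 plots; 8–20 seeds), asking the median detected
threshold to fall within 3 percentage points of the planted 10% peak; the
null behaviour of ANOSIM is checked on 500 exchangeable simulations at 199
permutations each. These sizes were chosen to make every property
statistically decisive at desk scale while keeping the default suite quick
to run.

## Known limitations

* The running-average x-design is irregular (dense where many plots share
  low invader abundance), and a global cubic weights all windows equally;
  with few transects the detected threshold inherits noticeable
  seed-to-seed variance, which is why recovery statements are about the
  median over seeds, not single runs.
* Daubenmire discretization biases realized relative abundances away from
  their continuous targets (most visibly at high cover, where the top
  class caps at 98); the generator reproduces this honestly rather than
  correcting for it.
* FQI depends on regional C-value assignments; the package treats C-values
  as data and does not derive them.
* ANOSIM assumes exchangeability of plots under the null; transect
  structure induces mild dependence the test ignores, as in the standard
  field workflow it mirrors.
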