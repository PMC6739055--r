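---
title: "Methods: fatty-acid trophic analysis and bootstrap-LDA source attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fatty-acid trophic analysis and bootstrap-LDA source attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatrophic)
```

# Scientific problem

Symbiotic corals acquire carbon along a continuum from autotrophy
(translocation of photosynthate from endosymbiotic dinoflagellates) to
heterotrophy (capture of particulate food: zooplankton and phytoplankton).
Fatty acids are useful trophic markers because many are synthesised only by
particular producer groups and are incorporated into consumer tissue with
little modification. This package implements the analysis chain used to
evaluate coral trophic strategies from fatty-acid composition:

1. validation and manipulation of percent-composition fatty-acid profiles;
2. established trophic biomarker indices;
3. distance-based permutation statistics (PERMANOVA, pairwise comparisons,
   PERMDISP) and PCA on the profiles;
4. univariate ANOVA / Tukey comparisons of the indices and host-on-symbiont
   regressions per fatty acid;
5. a bootstrap linear-discriminant procedure that attributes host
   polyunsaturated fatty acids (PUFA) to candidate dietary sources.

# Data model

A profile is a vector of fatty-acid proportions in **percent of total
fatty acids** (0-100 scale, untransformed). Labels use the shorthand
`C:Dn-x` — carbon count, number of double bonds, position of the first
double bond from the methyl end; saturated acids (`D = 0`) carry no `n-x`
part. Class follows the double-bond count: SFA (0), MUFA (1), PUFA (2+).

`fa_profiles()` validates a tibble of samples: metadata columns
(`sample_id`, `species`, `tissue`, `depth_m`, `source_group`, `colony`)
followed by one column per fatty acid. Key validation decisions:

* **Zeros are kept as zeros.** Percent-composition tables routinely report
  below-detection acids as 0; no pseudocount or transformation is applied.
* **Row sums must lie within `100 ± tol`**, with `tol = 1` by default:
  published composition tables are rounded to 0.1, so sums of 99-ish to
  101-ish are legitimate. `renormalize = TRUE` rescales rows to exactly 100.
* **`NA` proportions become 0** (absent from the reported panel), while
  negative values are an error.
* Subsetting to a label set (`subset_fas()`) can renormalize over the
  retained labels, which is how all PUFA-space analyses are constructed.

# Trophic indices

Three conventional biomarker indices, computed per sample by
`index_table()`:

* `ratio_18_1()`: 18:1n-7 / 18:1n-9 — bacterial/herbivory vs general
  animal signal.
* `photo_animal_index()`: (16:1n-7 + 18:1n-7) / (18:1n-9 + 20:1n-9 +
  22:1n-11) — photosynthetic vs animal-derived input.
* `sum_lc_mufa()`: the sum of exactly six long-chain MUFA isomers
  (20:1n-11, 20:1n-9, 20:1n-7, 22:1n-11, 22:1n-9, 22:1n-7) — a calanoid
  copepod marker. Other long-chain MUFA never enter the sum.

A zero denominator makes a ratio **undefined (`NA`)**, not infinite;
downstream ANOVA drops undefined values pairwise with a message reporting
the count.

# Multivariate statistics

`fa_dist()` computes Bray-Curtis (the conventional resemblance for
percent-composition data) or Euclidean distances on the untransformed
percentages.

`permanova()` is the McArdle-Anderson distance-based linear model: with
$G = J(-\tfrac12 D^2)J$ the Gower-centred inner-product matrix and $H_k$
the hat matrix of the design through term $k$, each sequential sum of
squares is $\mathrm{tr}((H_k - H_{k-1})G)$ and the pseudo-F is the usual
mean-square ratio against the residual. P-values use unrestricted
permutation of sample identities with the **add-one estimator**
$p = (1 + \#\{F^\pi \ge F\}) / (1 + n_\text{perm})$, which can never
return 0 and is exact-conservative under exchangeability. When the number
of distinct permutations $n!$ is at most `n_perm`, **all permutations are
enumerated** (with a message) and the p-value is exact. Ties at the
observed statistic are counted as greater-or-equal within `1e-12`.
Degenerate data (zero total sum of squares) yield pseudo-F 0 rather than
NaN.

`pairwise_permanova()` runs the two-level test on each restricted distance
matrix and reports $t = \sqrt{F}$; levels with fewer than 2 samples are
skipped with a warning. No multiplicity correction is applied — permutation
p-values are reported raw, as is conventional for these pairwise tables.

`permdisp()` tests homogeneity of multivariate dispersion: distances to
group centroids come from `vegan::betadisper(type = "centroid")`, the
ANOVA F on those distances is recomputed, and its p-value is obtained by
permuting group labels (seeded, add-one estimator). A significant PERMDISP
warns that a PERMANOVA group effect may partly reflect unequal spread.

`fa_pca()` wraps `stats::prcomp` (correlation matrix by default), reports
percent variance per axis, and variable contributions as $100 \times
\text{loading}^2$ normalised per axis. Axis signs are fixed so the
largest-magnitude loading on each axis is positive, making results
reproducible across platforms. Constant variables are an error under
standardisation.

# Univariate statistics

`fa_anova()` wraps `stats::aov` (one- or two-way fixed effects, optional
interaction, every cell needing at least 2 observations), with a guard: a
response with no variation at all returns F = 0, p = 1 instead of
floating-point noise. `tukey_hsd()` wraps `stats::TukeyHSD`.
`linear_fit()` wraps `stats::lm` and reports slope, intercept, $R^2$,
adjusted $R^2$ and the slope t-test p-value.

`host_symbiont_regressions()` regresses, per fatty acid, host proportion
on symbiont proportion across colonies. Host and symbiont rows are paired
by the `colony` column, or by `sample_id` with a trailing `_host` /
`_symbiont` suffix stripped; unpaired colonies are an error naming the
orphans. A row for the summed LC-MUFA index is appended. Raw p-values are
flagged at alpha = 0.05 with **no multiple-testing correction**, matching
the screening character of the analysis; users requiring family-wise
control should adjust the reported p-values.

# Bootstrap-LDA source attribution

This is the package's central procedure: estimating what fraction of a
coral host's PUFA pool each candidate source (endosymbionts, copepods,
phytoplankton groups) can account for.

**Model space.** All classification happens on a fixed set of PUFA labels;
library and host profiles are restricted to that set and renormalized to
sum 100 over it, so sources reported on different denominators are
comparable (`source_library()`, `prepare_hosts`).

**Classifier.** `fit_lda()` is the pooled-covariance Gaussian rule: class
means $M$, pooled within-class covariance $S$ (divisor $n - k$), linear
scores $x S^{-1} m_g^\top - \tfrac12 m_g S^{-1} m_g^\top + \log \pi_g$.
Because compositional columns sum to 100, $S$ is singular by construction;
a **ridge** of `1e-6 * trace(S)/d` is added to the diagonal by default
(scale-aware, negligible relative to the data variance). `ridge = 0`
forbids regularisation and errors on singularity. **Priors are uniform by
default**: library group sizes reflect literature coverage, not prey
availability, so proportional priors would encode an unjustified diet
assumption (`priors = "proportional"` is available). Ties in the argmax
are broken lexicographically by sorted class name and reported via a
message, making classification deterministic.

**Screening.** `loocv()` gives leave-one-out per-group classification
rates; `prune_sources()` removes groups below a threshold (default
**0.85**) in a **single pass** — iterative re-pruning is available
(`iterate = TRUE`) but off by default, since repeated refitting lets the
retained set depend on removal order. `drop_unshared_pufa()` removes PUFA
absent from every retained source (e.g. 18:5n-3, present in some hosts
but no retained source), since an acid no source carries cannot inform
attribution.

**Bootstrap.** `bootstrap_attribution()` runs, per iteration: resample
each source group **with replacement to its own size** (preserving the
library's group balance, the standard stratified bootstrap), refit the
discriminant model, and hard-classify every host sample of each species.
The iteration's "diet combination" for a species is the fraction of its
hosts assigned to each source — exact multiples of $1/n_\text{hosts}$
summing to 1. Host samples are never resampled and never enter fitting:
the uncertainty quantified is that of the source library. Across
iterations (default **10000**; fewer than 100 warns) the per-source
fractions are summarised by mean, SD and **percentile 95% interval**
(quantiles 0.025 / 0.975) — percentile rather than normal-theory because
the fractions are discrete, bounded and often skewed. A resample in which
any group collapses to a single distinct point is redrawn and counted.
With a fixed `seed` the whole procedure is bit-reproducible. A
`mode = "posterior"` variant averages posterior probabilities instead of
hard counts. `aggregate_contributions()` sums per-iteration fractions over
a source-to-category mapping (typically particulate food vs symbionts),
preserving closure within every iteration.

# Synthetic data generator

Profiles are drawn from a **Dirichlet distribution parameterised by mean
and concentration** (`rdirichlet_mean()`, gamma construction), scaled to
percent. This respects the compositional constraints exactly:
non-negative, closed to 100, zero-mean components remain exactly zero, and
`concentration = Inf` returns the exact mean. Default concentrations
(150-400) give the few-percentage-point within-group scatter typical of
published composition tables.

`simulate_study()` emulates the shape of a reef survey: 3 species with
contrasting strategies (a mixotroph, an autotroph-leaning and a
heterotroph-leaning species, the latter LC-MUFA-enriched) x 2 tissue
fractions x 2 depths, 10 colonies per cell, host and symbiont paired by a
`colony` key. `simulate_host_mixture()` makes hosts whose composition is
a convex combination of source means (zero noise gives the exact
combination); `simulate_host_membership()` makes hosts that each *belong*
to one source, the ground truth for attribution recovery.

What the generator does **not** emulate: chromatographic measurement
error, rounding to 0.1, correlated deviations between acids sharing a
biosynthetic pathway, or true biological covariance between paired host
and symbiont fractions. It is a validation harness, not an ecological
simulator.

# Pipeline orchestration

`run_trophic_pipeline()` runs the stages in order. The depth factor is
tested first by PERMANOVA and **pooled when non-significant** at `alpha`
(default 0.05; `pool_depths = "always"` / `"never"` override). Then:
species x tissue PERMANOVA with pairwise tests (by tissue, and by species
within each tissue), PERMDISP on the interaction grouping, PCA on all
acids and on the PUFA subset, index ANOVA/Tukey per tissue, host-symbiont
regressions, and — when a source library is supplied — LOOCV, pruning,
unshared-PUFA removal, bootstrap attribution and category aggregation.
The default category mapping sends every group whose name contains
"symbiont" to `symbiont` and the rest to `particulate`.

# Numerical choices, in one place

| Choice | Default | Rationale |
|---|---|---|
| Profile sum tolerance | `100 ± 1` | rounding in published tables |
| Ratio with zero denominator | `NA` | undefined, dropped pairwise |
| Permutation p | add-one estimator | never 0, exact-conservative |
| Exhaustive enumeration | when `n! <= n_perm` | exact p on small designs |
| Tie margin on permuted F | `1e-12` | counts numerical ties as >= |
| LDA ridge | `1e-6 * tr(S)/d` | invertibility on compositions |
| LDA priors | uniform | group sizes are not prey availability |
| Classification ties | lexicographic | deterministic, reported |
| LOOCV pruning threshold | 0.85, single pass | order-independent screening |
| Bootstrap resample size | each group to its own size | stratified bootstrap |
| Interval | percentile 95% | discrete, bounded, skewed fractions |
| PCA sign | largest loading positive | platform-stable output |

# Limitations

* Percent compositions are analysed untransformed (no log-ratio
  transformation); this matches field convention for these analyses but
  means distances are not subcompositionally coherent.
* Attribution assumes host PUFA are an unmodified mixture of source
  signatures; biosynthetic modification by the host biases the estimates.
* Hard classification allots each host entirely to one source per
  iteration; species-level fractions are interpretable as diet
  combinations only across hosts, not within one.
* PERMANOVA permutations are unrestricted; designs needing restricted
  permutation (e.g. repeated measures) are out of scope.
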