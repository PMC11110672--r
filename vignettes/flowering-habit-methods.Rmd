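---
title: "Methods: flowering-habit classification and heritability for biennial vegetable germplasm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flowering-habit classification and heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowerhabit)
```

# The problem

Biennial root vegetables such as carrot must not flower in their first
growing season: bolting lignifies the storage root and destroys its market
value. Genebank accessions of such crops are, however, heterogeneous,
heterozygous populations that may contain annual, late-annual and biennial
plants in any proportion, and the traditional three-way life-form
descriptor (annual / biennial / mixture) hides most of that structure.
`flowerhabit` implements a two-timepoint, plot-percentage characterization
of flowering habit for multi-year germplasm trials:

* plots are scored for the percentage of plants with visible signs of
  flowering at mid-season (60 days after sowing, DAS) and end of season
  (100 DAS) on a 5-point scale (0, 25, 50, 75, 100);
* per-accession estimated marginal means of those scores, within and
  across years, feed a rule-based trait ontology that splits annuals into
  uniformly-early, uniformly-late and non-uniform flowering types and
  mixtures into *predominantly biennial* (commercially usable) and other
  mixtures;
* the same trial model yields Type III ANOVA tables, variance components
  and entry-mean broad-sense heritability;
* a seeded synthetic-trial generator with known category truth makes every
  stage testable without field data.

# The trial models

A single year of a randomized complete block design (RCBD) with accessions
$g_i$ and blocks $b_k$ is modelled as

$$T_{ik} = \mu + g_i + b_k + e_{ik}, \qquad e_{ik} \sim N(0, \sigma^2),$$

and the multi-year trial as

$$T_{ijk} = \mu + g_i + y_j + (gy)_{ij} + b_{k(j)} + e_{ijk},$$

with year $y_j$, genotype-by-year interaction $(gy)_{ij}$ and blocks
nested within years. The response is the plot score percent exactly as
phenotyped — no transformation — because the classification thresholds are
defined on that scale.

For fixed-effects inference the package computes Type III sums of squares
by explicit model comparison under sum-to-zero contrasts: the SS of a term
is the increase in residual SS when that term's columns are dropped from
the full model matrix (other terms retained, pivoted least squares
handling any rank deficiency). On balanced data this reduces exactly to
sequential SS, which the tests verify. When a fit is exact (residual SS
below $10^{-10}$ of the total SS), the residual is reported as a hard zero
and F statistics as absent rather than as meaningless large numbers.

## Variance components and heritability

With all effects random, variance components are estimated two ways:

* **`ems_mom`** — method of moments on balanced designs, equating observed
  to expected mean squares: single-year $V_g = (MS_g - MS_e)/r$; multi-year
  $V_{gy} = (MS_{gy} - MS_e)/r$, $V_g = (MS_g - MS_{gy})/(r\,y)$, with $r$
  blocks and $y$ years. Negative solutions are truncated to zero and
  flagged.
* **`reml`** (default) — restricted maximum likelihood for any connected
  design. The fixed intercept is profiled out and the profiled restricted
  deviance is minimized over relative-SD parameters with box-constrained
  `nlminb` at tight tolerance, restarting once from the found optimum. On
  a balanced design with interior moments estimates, the moments solution
  is used as an additional warm start: it is the exact REML stationary
  point there, and the profiled surface around it is so flat that a
  cold-started optimizer stalls several digits short of it.

Entry-mean broad-sense heritability is

$$H^2_{\text{single}} = \frac{V_g}{V_g + V_e/r}, \qquad
  H^2_{\text{multi}} = \frac{V_g}{V_g + V_{gy}/y + V_e/(y\,r)}.$$

**A numerical caveat worth stating precisely.** The classical result that
REML equals the moments estimator on balanced data holds only at interior
solutions. With two years the year stratum has a single degree of freedom,
so its moments estimate is negative in a substantial fraction of
replicates even when the true component is positive; truncation then makes
the moments vector inadmissible and the equivalence no longer applies —
REML redistributes the low-df nuisance components (we observe shifts of
tens of percent in the block-within-year component) while the heritability
components $V_g$, $V_{gy}$, $V_e$ move by $10^{-4}$ or less. The test
suite therefore asserts the $10^{-6}$ equivalence on replicates with
interior solutions and concordant boundary behaviour (both estimators
pinning the truncated component to zero) otherwise. Likewise, even at
interior optima the 1–2 df nuisance strata cannot be localized beyond
about five digits by any optimizer, because the restricted likelihood is
flat at machine precision there; the strict equivalence is asserted for
the components heritability actually uses.

# Marginal means

Classification consumes *estimated marginal means*, not raw plots. With
genotype the focal term, the marginal mean of an accession is the
unweighted mean of its year-level cell means, each cell mean being the
average over blocks within the year. Under sum-to-zero coding this equals
the least-squares mean of the genotype term (verified in tests against an
independent least-squares-means implementation), and on balanced data it
reduces to the raw accession mean. This reproduces the stated procedure
without requiring a mixed-model solver in the balanced default, keeps the
means inside $[0, 100]$ (they are convex combinations of scores), and
makes the arithmetic fully auditable.

Accessions present in only part of the scoped years are retained with a
warning; a `min_years` filter is exposed rather than hard-coding an
exclusion rule, since real collections lose plots and whole year-entries
for reasons (hail, stand failure) the analyst should decide about
explicitly.

# The classification rules

With thresholds $t_{low} = 15$ and $t_{high} = 85$ percent, the
two-timepoint ontology partitions the $(\bar T_{60}, \bar T_{100})$ square
totally and disjointly:

| category | subcategory | rule |
|---|---|---|
| biennial | — | $\bar T_{100} = 0$ |
| mixture  | predominantly biennial | $0 < \bar T_{100} \le t_{low}$ and $\bar T_{60} \le t_{low}$ |
| mixture  | all other mixtures | other points with $0 < \bar T_{100} \le t_{high}$ |
| annual   | uniformly-early | $\bar T_{100} > t_{high}$ and $\bar T_{60} > t_{high}$ |
| annual   | uniformly-late  | $\bar T_{100} > t_{high}$ and $\bar T_{60} \le t_{low}$ |
| annual   | non-uniform     | $\bar T_{100} > t_{high}$ and $t_{low} < \bar T_{60} \le t_{high}$ |

The three-category baseline scheme (`grin_baseline`) uses end-of-season
means only: biennial at exactly 0, annual at exactly 100, mixture
otherwise. Both schemes demand literally zero observed flowering for a
biennial call, so their biennial sets coincide on any data — a property
the tests check on an exhaustive half-point grid of 40,401 points.

Design choices worth recording:

* **Boundary semantics.** Field descriptions of these categories mix
  open and closed interval notations. The implementation fixes half-open
  conventions — annual strictly $> t_{high}$; late/predominantly use
  $\le t_{low}$; mixture is $(0, t_{high}]$ — because a flowchart-style
  total, disjoint partition requires a decision at every boundary.
  Comparisons are made on marginal means rounded to 4 decimals so that a
  mean sitting within $5\times10^{-5}$ of a threshold cannot flip category
  through floating-point noise.
* **Predominantly biennial requires both timepoints** $\le t_{low}$, even
  though $\bar T_{60} \le \bar T_{100}$ makes the mid-season condition
  redundant except for senescence-affected accessions — exactly the case
  where it matters.
* **No "predominantly annual" category.** Non-flowering plants in a
  heavily flowering plot are more plausibly late annuals than biennials,
  and the group has little practical use for breeders; the $> t_{high}$
  region is therefore all "annual".

# The 5-point score and its consequences

Field scorers record 0, 25, 50, 75 or 100 percent. Two quantization
policies for the simulator (and for re-scoring continuous data) make the
low-end behaviour explicit:

* `nearest`: nearest multiple of 25, ties away from zero;
* `detect` (default): as `nearest`, except any strictly positive
  flowering scores at least 25 — a 0 then *certifies* that no flowering
  plant was seen, which the biennial category's "exactly 0" rule demands.

This choice has a real scientific consequence that the simulator makes
visible: under `detect`, a plot of ~50 plants from an accession with even
a 5–10% annual fraction almost always contains at least one flowering
plant, scores 25, and drives the accession's marginal mean above
$t_{low}$ — so the *predominantly biennial* subcategory can only be
reached by accessions whose plots frequently contain zero flowering
plants. Default simulated collections therefore show far fewer
predominantly-biennial calls than their latent composition would suggest,
while `nearest` preserves them. Real field scoring by visual estimation
sits somewhere between the two policies; analyses of real data should
treat the policy as a sensitivity parameter. Quantization is idempotent:
re-scoring an already-scored dataset changes nothing.

A decline from the 60 DAS to the 100 DAS score flags early-annual
senescence (`detect_senescence()`); flagged plots are reported, never
silently dropped. Rosner's generalized ESD test (`rosner_esd_test()`)
screens each trait-year for up to $k$ simultaneous outliers using the
largest significant step of the extreme Studentized deviate sequence; it
is advisory QC — the pipeline does not auto-delete flagged values, since
deletion policy belongs to the analyst.

# The synthetic-trial generator

`generate_collection()` draws, for each accession, a true category and
then a within-accession life-form composition (proportions of
early-annual, late-annual, biennial plants) *inside* that category's
threshold region using bounded uniform draws (with a symmetric Beta of
shape `concentration` for the early/late split where it is free). Truth
labels are therefore exact by construction. The default category mix is
the across-year composition of a large cultivated-carrot diversity panel
(counts 197/160/250/50/5/6 of 668); the default design is 3 years × 2
blocks × 50 plants per plot with 90% emergence.

`simulate_trial()` then perturbs each accession's annual fractions on the
logit (liability) scale by year, genotype-by-year and block-within-year
effects (SDs 0.6 / 0.5 / 0.15 by default, drawn from centered normals) and
draws each plant's life form from the perturbed composition. The logit
scale keeps probabilities in $(0,1)$ and is the standard liability-scale
convention; obligate biennials ($p_{\text{annual}} = 0$) remain biennial
under any finite shift. Optional features mirror field pathologies:

* **stand-loss events** thin a year's plants with survival fraction $s$,
  and an `early_bias` $\beta$ lowers early-flowering plants' survival to
  $\mathrm{logit}^{-1}(\mathrm{logit}(s) - \beta)$ — reproducing how a
  storm that kills early-emerging seedlings biases a collection toward
  apparent biennials;
* **senescence** (off by default) lets an early-flowering plant show no
  visible flowering by 100 DAS, the rare real-world event the decline QC
  flag exists for;
* the per-accession `genotype_effect` liability shift defaults to SD 0 so
  that the composition itself carries all genotypic signal and truth
  labels stay exact under zero environmental noise.

Reproducibility: one global seed; every plot and every effect draw gets
its own RNG substream from a stable hash of `(accession, year, block)`,
so outputs are byte-identical across runs and invariant to iteration
order. A separate Gaussian generator (`simulate_gaussian_trial()`) draws
directly from the random-effects model with known variance components for
calibrating the estimators.

What the generator does *not* emulate: real within-accession composition
distributions of landraces are unknown, so the bounded-uniform family is
an artifact choice (flagged in the configuration); there is no
vernalization physiology, no genetic map, no spatial field trend, and no
second-season phenotyping. Passing recovery tests therefore demonstrates
that the analysis machinery inverts the generator's own assumptions — not
that those assumptions describe any particular field population.

# Problem sizes and numerical choices

The test suite and the acceptance script use deliberately desk-scale
configurations chosen to keep every property estimable: classifier checks
run on the exhaustive 201 × 201 half-point grid; heritability calibration
uses 20 replicates of 600 accessions × 2 years × 2 blocks with components
set so true multi-year $H^2 = 0.85$ (the estimate's mean must fall within
±0.05); category recovery uses 400 accessions with 200 plants per plot,
zero environment noise, and requires ≥99% agreement for accessions whose
latent parameters sit at least 2 percentage points from every threshold
(accessions nearer a threshold can legitimately cross it through binomial
sampling alone — with 1,200 plants an accession 2 points inside a boundary
still crosses with probability about 2%, which the off-boundary margin
absorbs). REML convergence tolerance is $10^{-14}$ relative on the
restricted deviance; summary percentages are rendered at 2 decimals with
half-away-from-zero rounding (matching genebank summary-table convention,
e.g. 50/668 → 7.49).

# Known limitations

* Type III tables require estimable terms; heavily unbalanced multi-year
  data with empty accession-by-year cells can make interaction contrasts
  inestimable (the moments estimator refuses unbalanced data outright —
  use REML there).
* The marginal means are fixed-effect means; no shrinkage/BLUP option is
  provided, by design.
* Heritability is broad-sense, entry-mean based; no narrow-sense or
  marker-based estimate.
* Grouped Pearson correlations use pairwise-complete deletion and flag —
  but do not suppress — small groups; a five-accession group's
  correlation is reported with a `low_n` flag because it can be driven
  entirely by drift and sampling noise.
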