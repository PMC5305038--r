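---
title: "Lick microstructure analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lick microstructure analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lickstat)
```

## The measurement problem

Licking in the rat is driven by a brain-stem central pattern generator and is
remarkably stereotyped: within a bout of drinking, tongue contacts recur every
0.10–0.15 s with only a few percent coefficient of variation. Drinking is
therefore naturally described at two timescales — *clusters* of rhythmic
licking separated by much longer pauses — and subtle oral-motor impairment
shows up in the *microstructure* of the lick train (how much fluid each lick
moves, how clusters are organised) long before gross intake changes. After
experimental stroke (middle cerebral artery occlusion, MCAO, which typically
damages the lateral striatum involved in oral control), the characteristic
signature is a drop in drinking efficiency with compensation: less fluid per
lick, more clusters, unchanged inter-lick interval (ILI).

`lickstat` turns timestamped lick events plus per-session consumption into
seven per-subject measures and runs a two-group statistical battery over them:

1. total water consumption (mL),
2. total number of licks,
3. lick volume = consumption per 1000 licks (mL/1000 licks),
4. mean licks per drinking cluster,
5. total number of clusters,
6. mean within-cluster ILI (s),
7. ILI variability (percent coefficient of variation).

## Segmentation and its two tunable parameters

A **cluster** is a maximal run of licks whose successive ILIs are all below a
*pause criterion*; any interval at or above the criterion starts a new
cluster. Two parameters matter and both are explicit assumptions, not fitted
quantities:

* `pause_criterion` (default **0.5 s**). The lick-microstructure literature
  conventionally separates the intra-cluster rhythm (~0.15 s) from pauses
  (seconds) at 0.5 s; with a bimodal interval distribution any criterion in
  the gap gives identical segmentations, which is why the default is safe but
  still exposed as a flag.
* `artifact_floor` (default **0.05 s**). Contact lickometers occasionally
  register double contacts a few ms apart; intervals below the floor are
  excluded from ILI statistics (they do not delete licks or change
  segmentation — only the ILI mean/CV). 0.05 s is conservative: it is one
  third of a lick cycle and far above switch-bounce timescales.

Both defaults are logged in every report's `assumptions` block so that their
provenance travels with results.

Two further conventions:

* **ILI statistics use within-cluster intervals only.** An interval spanning
  a pause is a pause, not a lick cycle; including it would inflate both the
  mean and the CV with segmentation artefacts. The CV uses the sample SD
  (n − 1): per-cluster interval counts can be small and the unbiased-variance
  estimator is standard.
* **Subject-level aggregation is the unweighted mean over sessions** (four
  daily 15-min sessions in the emulated design), not a re-pooling of all
  licks. Averaging weights each session equally and is robust to one
  low-intake session dominating; the alternative (pooled licks) is easy to
  compute from the per-session summaries if wanted, and the two are compared
  explicitly in the test suite. The choice is recorded in the report.

## The synthetic cohort: a stated world

No raw lickometry data accompany the study design this package emulates, so
validation rests on a generative model with known ground truth
(`simulate_session()`, `simulate_cohort()`):

* number of clusters per session ~ Poisson; licks per cluster ~ 1 + Poisson;
* within-cluster ILIs ~ gamma with mean `ili_mean` and CV `ili_cv`
  (positive support, unimodal, matches the low-variance lick rhythm);
* pauses ~ shifted lognormal with a hard minimum `pause_min` (1 s) strictly
  above the pause criterion, so ground-truth cluster boundaries are exact and
  the segmenter can be tested against them with equality, not tolerance;
* per-lick volumes ~ lognormal around `mean_volume_per_lick`; consumption is
  their sum (only session totals are ever observed, so any positive per-lick
  law with the right mean suffices);
* timestamps are quantised to the recording resolution (0.01 s), with
  collisions resolved by shifting the later lick forward one step, preserving
  strict ordering.

The cohort defaults mirror the emulated design: 30 control and 22 lesioned
subjects, 4 sessions each, 900 s sessions, 0.01 s resolution. Group-level
defaults are **plausible rodent values, not paper-derived estimates** (the
study reports only group summaries in figures): 0.14 s ILI at 5% CV, 5 µL per
lick, ~40-lick clusters, ~60 clusters per session (~12 mL per session, a
realistic water-restricted intake). The default lesioned-group parameters
encode the documented effect *structure*: 20% lower volume per lick, more but
smaller clusters, identical ILI distribution.

What a green simulation test does **not** establish: the generator is a
renewal model. It has no circadian or satiety drift within a session, no
bottle-distance ("tongue travel") effects, no postural artefacts, and its
quantisation is ideal. It validates the *pipeline* (segmentation, summaries,
test battery, power) on data whose truth is known — it does not validate the
biology of any particular parameter value.

One measurable consequence of quantisation worth knowing: rounding 0.14 s
intervals to a 0.01 s grid adds uniform ±5 ms noise, so the *observed* ILI CV
of simulated data sits slightly above the generator's 5% (about 5.8%). The
ILI *mean* is unaffected (rounding is unbiased). This mirrors real equipment
and is why recording resolution belongs in the model.

Seeding: every (subject, session) receives a seed derived deterministically
from `master_seed` by an integer mix, so cohorts are byte-reproducible and
independent of iteration order.

## The statistical battery

Per-measure tests follow the emulated design: pooled-variance Student *t*
(not Welch — the published degrees of freedom, 50 for groups of 30 and 22,
force the pooled form) for consumption, total licks, lick volume, ILI and ILI
CV; Mann–Whitney *U* for the two count-like cluster measures. The *U* test
reports `min(U_A, U_B)` and computes its two-tailed p exactly, by enumeration
over all group assignments of the tie-averaged ranks, whenever the pooled
sample is ≤ 20, falling back to the tie-corrected, continuity-corrected
normal approximation above that.

Family-wise control is Bonferroni with **family size 7** — the seven measures
constitute one battery, and this family size reproduces all published
significance verdicts of the design being emulated. The one-way lesion-subtype
ANOVA (control / striatal-only / striatal+cortical) uses pairwise pooled-*t*
contrasts with Bonferroni over the three pairs as its post-hoc; the source
design names no post-hoc procedure, so this is a documented assumption and
those post-hoc p-values are not used as validation targets.

### JZS Bayes factors

For each parametric contrast the package computes the Jeffreys–Zellner–Siow
default Bayes factor of Rouder et al. (2009): a Cauchy prior with scale
`rscale` on the standardised effect, integrated over the inverse-chi-square
mixing variable by adaptive quadrature (`stats::integrate`, relative
tolerance 1e−8), with effective sample size `n1·n2/(n1+n2)` and
`df = n1 + n2 − 2`. The reported `K` follows the convention of quoting
whichever of BF10/BF01 exceeds 1, together with its direction.

The prior scale behind the published K values was not stated, with `r = 1`
(the original 2009 default) and `r = √2/2` (the modern software default) as
the candidates. Numerical checks settle it: at `rscale = 1` all five
published factors reproduce to two decimals

```{r}
sapply(c(3.179, 4.805, 0.404, 2.143, 2.422),
       function(t) round(jzs_bayes_factor(t, 30, 22, rscale = 1)$K, 2))
```

whereas `rscale = sqrt(2)/2` misses every one. The default is therefore 1,
switchable via the `rscale` argument everywhere it appears.

## Sample-size calculation

`required_n()` answers the planning question for a hypothetical treatment
study: with control performance defined as full recovery and the lesioned
group as no recovery, how many subjects per arm detect a 50% (or 75%)
improvement? The detectable difference is `improvement × |control − lesion|`
group-mean difference; both hypothetical arms take the *lesioned* group's SD
(the more conservative spread); and `n` is solved by iterating the exact
noncentral-*t* power function of the two-sided pooled test (the G*Power-style
computation) rather than the normal approximation, which undershoots by one
to two subjects at the small n typical of such studies. Both routes are
exposed (`method = "t"` / `"normal"`). The published sample sizes themselves
are not validation targets: the group means and SDs they require appear only
graphically in the source design.

## Numerical and degenerate-input choices

* `p_from_t` and the ANOVA p use the central t/F distributions directly;
  tests verify them against independent quadrature of the densities.
* Zero licks in a session leaves consumption and zero counts defined and all
  ratio measures `NA`; aggregation skips missing values rather than
  propagating them. A single retained ILI has a mean but no sample SD, hence
  `NA` CV.
* Zero pooled variance, all-constant correlation input, and a zero detectable
  difference are errors, not silent NaNs.
* Exact-vs-approximate switch in the U test is at pooled n = 20; the exact
  path's symmetric-tail definition `P(|U − n1n2/2| ≥ |u − n1n2/2|)` equals
  the classical doubled one-tail for tie-free data and remains well defined
  under ties.
* The quadrature in the Bayes factor fails loudly (with t and N in the
  message) rather than returning a partial value.

## Known limitations

* The pause criterion and artifact floor of the original apparatus are
  unknown; all published-value validations are criterion-free (they start
  from the published t/U/F statistics), but reanalyses of real data must set
  these two flags deliberately.
* The generator's renewal assumptions make within-session stationarity exact;
  effects that depend on drift (satiety, posture) cannot be studied with it.
* Bayes factors are provided for the pooled-t contrasts only; count-like
  measures analysed by Mann–Whitney carry no default-Bayes analogue here.
* The pipeline models one cluster level (no burst/meal hierarchy) and one
  session structure (no longitudinal body-weight modelling).
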