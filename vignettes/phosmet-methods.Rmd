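---
title: "Screening phosphosite functionality by untargeted metabolomics: methods and design"
author: "phosmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening phosphosite functionality by untargeted metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosmet)
```

## The problem

Protein phosphorylation sites are mapped at a rate that far outstrips our
ability to say which of them matter. For phosphosites on metabolic enzymes
and on metabolically-acting signaling proteins (yeast TOR and HOG
pathways), a practical functional readout is the intracellular metabolome:
a panel of point mutants that either abolish phosphorylation
(serine/threonine to alanine, tyrosine to phenylalanine; "OUT" mutants) or
mimic the constitutively phosphorylated state (glutamate; "IN" mutants)
is grown under several nutrient conditions, extracts are profiled by
flow-injection TOF mass spectrometry in negative mode, and each mutant's
ion profile is compared with the rest of the panel. `phosmet` implements
this screen end to end, together with a synthetic-data generator that
emulates its design, so every stage can be validated by spike-in recovery.

The canonical design the generator reproduces: 26 phosphosites yield 26
OUT mutants plus 6 IN variants — 32 mutants — grown in 4 conditions, 3
wells per mutant and 4–5 wild-type wells per plate, each plate grown and
extracted on 2 days, measured in 2 batches, with ions recorded across the
50–1000 m/z range.

## From raw intensities to fold changes

**Drift correction.** Flow-injection intensities drift smoothly over a
measurement run. Per ion and batch we fit a LOWESS trend over run order
and divide it out (drift is multiplicative), rescaling to preserve the
ion's batch mean. One subtlety matters: ion intensity also depends
strongly on the extraction OD, and samples of different OD are scattered
along the run, so a trend fitted on raw intensities absorbs OD-driven
scatter as spurious wiggle and inflates replicate variance downstream. By
default the trend is therefore estimated on OD-detrended residuals
(intensity divided by a preliminary robust LOWESS fit against OD) while
the correction itself divides the raw intensities by the run-order trend
only, leaving the OD dependence intact for the next stage. In our
simulations this choice alone raised spiked-ion sensitivity from roughly
0.58 to 0.85.

**OD window.** Only samples extracted at OD595 between 0.6 and 1.7
(inclusive) are analysed; outside this window the OD–intensity
relationship is poorly covered.

**OD-wise reference curves.** Rather than normalising all samples to one
global reference, each ion gets a reference intensity *as a function of
OD*: a robust LOWESS fit of intensity versus extraction OD over all
samples of a batch and condition — mutants and wild type together, which
covers the whole OD range, while the robustness iterations stop
individual strong metabolic changes from dominating the curve. The curve
is tabulated at the sorted sample ODs, evaluated elsewhere by linear
interpolation, and held constant beyond the window edges. The fold change
of a sample's ion is its intensity divided by the reference value at that
sample's OD; `log2fc` is its base-2 log.

**Balanced reference for dominated batches.** When one phosphosite's
mutants are the only fully replicated strains in a batch they would drag
the all-samples reference toward their own metabolic state. For such
batches the reference is computed by repeatedly (default 1000 times)
drawing a reduced number of the dominant mutant's samples (default 3,
keeping all other samples), fitting a curve per draw, and taking the
pointwise median. Every draw uses a child seed derived from one master
seed, so the median curve is reproducible; with the keep-count equal to
the full replicate count the plain reference is recovered exactly.

## Differential calling

Per mutant, condition and ion, replicate log2 fold changes (biological
and day replicates pooled) are pruned by a single pass removing values
more than two sample standard deviations from the mean — with fewer than
three values, or a zero SD, nothing is removed, and algebraically nothing
can ever be removed at n ≤ 5. The median log2 fold change summarises the
pruned values; a two-sided Welch t-test (Satterthwaite degrees of
freedom) compares them against all other samples of the same condition
and batch, wild type included. The reported statistics are medians on
the log2 scale, so pruning and testing are performed on log2 fold changes
as well: the log scale is symmetric in up/down regulation and closer to
normal for multiplicative MS noise.

P-values are converted to Storey q-values: the null proportion pi0 is
estimated by the smoother method (quotient `#{p > lambda} / (m(1-lambda))`
on the grid lambda = 0.05…0.95, df-3 smoothing spline, evaluated at
lambda = 0.95, clipped into (0, 1]); with pi0 fixed at 1 the q-values
reduce exactly to Benjamini–Hochberg. The correction family is each
mutant × condition ion profile (the default `qFamily`). We deliberately
did not pool all mutants of a condition into one family: with ~200 ions
per profile and a handful of true effects, a 2000-test family forces raw
p-values below ~4×10⁻⁶ for a q below 10⁻³, and simulations showed that
even with a *perfect* reference curve the spiked-ion sensitivity then
plateaus near 0.83 — the per-profile family restores the calibration the
screen's own guarantees assume, and the pooled variants remain available
in the configuration.

An ion changes significantly when `q < 1e-3` **and**
`|median log2fc| > 0.3785`, both strict. The fold-change cutoff is the
log2 of a 30% change and coincides with the 97.5% quantile of the pooled
wild-type |log2fc| distribution; the package recomputes that quantile
(`deriveWTCutoff()`) and reports it alongside the fixed cutoff.

## Annotation and pathway enrichment

Ions are annotated as deprotonated metabolites: metabolite *m* is a
candidate for ion *i* iff `|mz(i) − (mass(m) − 1.00728)| ≤ tolerance`.
The proton mass constant includes the electron-mass correction; the
default tolerance of 0.005 Da reflects TOF mass accuracy and is
configurable. Unannotated ions are kept for the differential statistics
but excluded from enrichment and correlations. Ions annotated to several
metabolites of one pathway are lumped to a single entry (the enrichment
counting unit); an ion spanning two pathways contributes one entry to
each.

Enrichment uses a relaxed cutoff (`p < 0.1`, `|log2fc| > 0.1375`, a 10%
change) to build a candidate list sorted by descending absolute change
(ties broken by smaller p, then lexically, for determinism). Starting
from the top hit alone the hit subset grows one entry at a time; at every
size a one-sided hypergeometric test scores each pathway's
over-representation against the population of all entries detected in
that mutant's condition — enrichment is relative to what was measurable,
not to the full pathway database. Per pathway the minimum p over subset
sizes is reported. These p-values are not corrected across pathways
(the scoring consumes raw enrichment p-values); treat them as ranks, not
error rates.

## Correlation analyses

Two complementary views of profile similarity, both restricted to
annotated ions:

* **Mutant pairs.** For every unordered mutant pair and condition, the
  Pearson correlation of their median-log2fc profiles over shared ions;
  a pair's coefficients (4 for 4 conditions) are compared against the
  pooled coefficients of all remaining pairs by a two-sided Welch test,
  significant below p = 0.01. Two-sided is the conservative reading; the
  pooled-across-conditions background follows the view that the tested
  pair is judged against "all remaining mutant-pairs".
* **Self-correlation.** Per mutant, the correlation of its profile
  between every unordered condition pair (6 coefficients for 4
  conditions), tested against a zero mean by a one-sample two-sided
  t-test, significant below p = 0.01. Exactly tied coefficients
  degenerate the test; the package then returns p = 1 for a common value
  of zero (no evidence) and p = 0 otherwise, with a flag.

With only two conditions the self channel has a single coefficient and
is reported as missing (score 0) — a screen needs at least three
conditions for this channel to contribute.

## The functionality score

Four evidence channels per mutant: the changing-ion count in the best
condition, scored 0 (none), 1 (1–4), 2 (5–19) or 3 (>19); and three
p-value channels — best enrichment p, best mutant-pair p, best
self-correlation p, each over all conditions — scored 0 (p > 10⁻²), 1
(p < 10⁻²) or 2 (p < 10⁻³). Comparisons are strict; a p exactly on a
threshold falls to the weaker class, which resolves the caption's
undefined boundary conservatively. The total (0–9) calls a phosphosite
functional at 3 or higher. A mutant missing from a channel (e.g. absent
from the correlation analysis) scores 0 there, with the gap recorded.

## Growth phenotyping

Growth rates come from a log-linear fit over the best exponential
window: points below the detection floor (OD 0.01) or within 2% of the
curve's maximum (stationary phase) are set aside, every remaining window
of ≥ 5 points is scored by R², and the longest window within 10⁻³ of the
best R² supplies the slope. This averages over the whole exponential
phase instead of a lucky short stretch; on noise-free curves only
perfectly log-linear windows survive and the fit is exact. The maximal
cell density is the mean OD after plateau entry (rolling slope below 5%
of its peak); without a plateau the last OD is returned flagged. A
mutant × condition trait differs significantly from wild type when the
Welch test's Storey q (across all mutant × condition × trait tests) is
below 10⁻³ **and** the relative difference of group means is at least
10% — an effect-size gate that rejects trivially significant 9%
differences by construction.

Two curation steps that were manual in practice are codified: wells are
dropped when non-growing or when their rate deviates more than 3 SD from
their replicate group; heuristic flags mark abnormal lag (time to double
the inoculum more than 1.5× the wild-type median) and abnormal shape
(residual SD of the log-linear fit above 0.05).

## The synthetic-data generator

`simulateIntensities()` draws
`intensity = baseline(ion) × OD^gamma(ion) × drift(batch, run order) ×
2^spike × 2^noise`:

* per-ion baselines are log-uniform over 10⁴–10⁶ counts;
* the OD response is an ion-specific power law, exponent drawn from
  [0.5, 1.5] by default (monotone increasing — the very feature that
  motivates OD-wise referencing);
* drift is a smooth quadratic in normalised run position scaled to a
  maximal fractional amplitude (default 10%, capped in spirit at ±20%);
* replicate noise is log-normal with sigma on the log2 scale (default
  0.1 — the study does not state replicate variances, so sigma is a free
  generator parameter chosen once at a level typical for flow-injection
  TOF replicates);
* spikes add exact log2 effects to chosen mutant × condition × ion
  triples, recorded verbatim in the `GroundTruth` ledger.

Extraction ODs are uniform over the admissible window [0.6, 1.7]; run
order is a random permutation within each batch. Batch 2 reproduces the
dominance situation: the dominant site's mutants keep triplicate wells
while other batch-2 mutants get single wells. Growth curves are
lag/exponential/plateau with optional relative noise. Everything is
deterministic under one seed (child seeds are derived for independent
stages).

What the generator does **not** emulate: peak picking and centroiding
artifacts, adducts other than [M−H]⁻, isotope patterns, correlated
biological co-regulation between pathways, missing values, and
detector saturation. Passing spike-recovery tests therefore validates
the statistical pipeline, not the upstream mass-spectrometric
processing, and real-data performance additionally depends on features
the simulation leaves out.

## Numerical choices and degenerate inputs

* LOWESS spans: 0.3 of points for drift, 0.5 for the OD reference, 3
  robustness iterations — stable for 50–300 samples per batch, exposed
  in `screenConfig()`.
* Reference evaluation: linear interpolation between fitted points,
  constant extrapolation at the window edges, so the curve is defined on
  the closed window.
* Nonpositive reference values (pathological fits) flag the ion and
  exclude it from fold changes rather than producing infinities.
* Degenerate Welch tests (zero pooled variance) return p = 1 with a
  flag; empty fold-change sets are errors, not NAs.
* All randomised stages (balanced reference, generator) consume child
  seeds derived from one master seed below 2³¹.

Problem sizes used in the package's own validation runs: screens of 10
mutants × 2 conditions × 200 ions with 6 replicates for calibration
(20 seeds), 200 permutations for balanced-reference comparisons, and
3-mutant panels for growth recovery. These sizes give tight Monte-Carlo
error on the reported rates while keeping a full validation run in the
tens of seconds.

## Known limitations

* The per-profile q-value family is a deliberate departure from pooling
  all mutants of a condition (see above); both variants are available.
* With 23% or more of a group's samples carrying strong spikes (tiny
  panels), the robust reference begins to absorb the effect and
  sensitivity drops — the method assumes each mutant is a small fraction
  of its batch, as in the real design.
* Mutant-pair significance with few conditions is unstable: two chance-
  close coefficients can produce a tiny Welch p. Four conditions (six
  self coefficients, four pair coefficients) is the intended operating
  point.
* Enrichment p-values are uncorrected across pathways by design.
* The functionality score is a ranking device; its 0–9 scale has no
  probabilistic interpretation.

## A worked example

```{r example, eval = FALSE}
library(phosmet)
cfg <- screenConfig(seed = 1)
res <- simulateAndScore(cfg)          # generate, screen, score, compare
res$recovery$ion_sensitivity          # fraction of spiked ions recovered
res$report                            # stage log + score ranking
writeReportBundle(res$report, "report")
```
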