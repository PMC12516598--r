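---
title: "Quantifying melodic diversification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying melodic diversification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melodiverge)
library(dplyr)
```

melodiverge studies how orally transmitted melodies diverge from a common
origin. A corpus of folk songs is organised into *song groups* — the field's
analogue of tune families: sets of songs judged to descend from one ancestral
air. The package quantifies the melodic distance between every within-group
pair and asks which circumstances of transmission (crossing between islands,
geographic distance, elapsed time, a change of social context, a change of
data source) are associated with larger divergence.

This vignette explains the model and procedure, the tunable parameters and
their defaults, what the synthetic-data generator emulates, and the numerical
and design choices that were genuinely open.

## Coding melodies as sequences

A melody is reduced to its pitch classes: note durations and octaves are
discarded, the tune is transposed so its tonic is C, and each note becomes
one of twelve letters (`pitch_letters()`). The seven diatonic degrees are
uppercase (`C D E F G A B` for pitch classes 0, 2, 4, 5, 7, 9, 11) and the
five chromatic degrees lowercase (`d e g a b` for 1, 3, 6, 8, 10), so letter
case encodes the *mode* of a degree — a minor third `e` versus a major third
`E`. `recode_ignore_mode()` merges the cases when modal contrast should not
count as a difference. Repeated and responsorial passages are assumed to be
removed editorially before encoding; the codec does not attempt structure
detection. The reserved gap character `-` may never appear in a coded
sequence.

## Alignment, percent identity, melodic distance

Two coded sequences are compared by optimal global alignment with affine gap
penalties: match +1, mismatch −1, and a maximal gap run of length $k$ costs
$\mathrm{GOP} + \mathrm{GEP}\cdot k$ — opening charged once per run,
extension once per gap symbol. Terminal gaps are penalised like any others
(true end-to-end alignment; nothing in the problem suggests semi-global
treatment). The three-state dynamic program (match / gap-in-first /
gap-in-second) is implemented in C++ and is verified in the test suite
against exhaustive enumeration of *all* global alignments for short
sequences, under both penalty regimes and under the alternative
$\mathrm{GOP} + \mathrm{GEP}\cdot(k-1)$ accounting (which the oracle can
score, and which the implementation deliberately does not use).

Two parameter presets are standard for tune-family work and both are carried
through every analysis:

* **set 1**: GOP 12, GEP 6, ignoring mode — gap-averse, suited to separating
  tune families;
* **set 2**: GOP 0.8, GEP 0.2, including mode — gap-friendly, suited to
  comparisons within a family.

Similarity is percent identity,
$$\mathrm{PID} = \frac{100 \cdot 2\,\mathrm{ID}}{L_1 + L_2},$$
with ID the number of identical aligned columns and $L_1, L_2$ the
pre-alignment lengths; the mean-length denominator keeps PID symmetric in
the two inputs and within $[0, 100]$. Melodic distance is
$1 - \mathrm{PID}/100$.

**Tie-breaking.** Many alignments can be co-optimal. The traceback prefers,
deterministically: diagonal moves, then a gap in the shorter input, then a
gap in the longer. The score is unique regardless; ID is reported for the
single returned alignment, and the regression tests confirm the returned
alignment always re-scores to the optimum.

## Comparing same-group and different-group pairs

`pid_group_summary()` reports the median and interquartile range of PID for
same-group and different-group pairs, using R's default type-7
linear-interpolation quantiles so summaries are bit-reproducible. The
distributional comparison uses the Brunner–Munzel rank test
(`brunner_munzel()`), built from scratch: the relative effect
$\hat p = P(X<Y) + \tfrac12 P(X=Y)$ is estimated from midranks, studentised
with separate within-sample rank variances, and referred to a
$t$ distribution with Welch–Satterthwaite degrees of freedom. No equal
variance assumption is made — appropriate here because the two pair classes
have very different sizes and spreads.

When both rank variances vanish (complete separation or all ties) the
studentised statistic is undefined. The implementation still reports
$\hat p$, raises a typed warning, and leaves the asymptotic p-value `NA`
rather than returning a silent 0 or infinity; the permutation method — the
same statistic under relabelings, enumerated exactly when
$\binom{n_1+n_2}{n_1} \le 20{,}000$ and Monte Carlo with 10,000 seeded draws
otherwise — handles these cases correctly (infinite statistics compare as
ties among themselves).

## Treelikeness and split networks

The delta score of a distance matrix measures deviation from additivity:
for every quartet the three pairwise-sum quantities are ordered
$m_1 \le m_2 \le m_3$ and the quartet contributes
$(m_3 - m_2)/(m_3 - m_1)$, taken as 0 when $m_3 = m_1$ (the natural
convention for equidistant quartets). The mean over all
$\binom{n}{4}$ quartets is 0 exactly on additive tree metrics and approaches
1 under maximal conflict. Delta depends only on the distances, so it is
exposed independently of any network estimate; the C++ implementation is
checked against a plain quartet-iterating oracle.

`neighbor_net()` produces a circular split system: the Neighbor-Net
agglomeration yields a circular ordering of the taxa and nonnegative split
weights are estimated by constrained least squares. The agglomeration and
weight estimation are delegated to phangorn's Neighbor-Net implementation,
wrapped into a validated split-system container (every split must be
contiguous in the circular order); the three-taxon case uses the closed-form
decomposition into the three trivial splits with weights
$(d_{ab}+d_{ac}-d_{bc})/2$ and rotations. On additive tree metrics the
system recovers exactly the tree's edges and lengths (tested to $10^{-6}$
over random topologies up to 10 taxa). Splits with weight at or below
`weight_threshold` are dropped; the default 0 keeps every positively
weighted split, since downstream viewers apply their own display thresholds.
`write_splits_nexus()` emits TAXA/DISTANCES/SPLITS blocks in the SplitsTree4
dialect so networks can be rendered there — layout is deliberately out of
scope. Per-region networks are corpus filters plus the same call, not
separate code paths.

## The pairwise-distance linear mixed model

For the within-group pairs, the model is
$$Y_{ij} = \beta_0 + \beta_1 I_{ij} + \beta_2 D_{ij} + \beta_3 T_{ij} +
\beta_4 C_{ij} + \beta_5 S_{ij} + r_{0k} + \varepsilon_{ij},$$
with $Y_{ij}$ the melodic distance of pair $(i,j)$ in song group $k$,
$I$ a different-island indicator, $D$ the great-circle distance in km
between recording sites (haversine on a 6371 km sphere — the effect of $D$
is expected to be small, so centimetre-level geodesy is immaterial), $T$ the
absolute difference in recording years, $C$ a different-social-context
indicator, $S$ a different-source indicator, and $r_{0k}$ a song-group
random intercept absorbing group-level differences in the rate of melodic
change. When either melody's recording site is unknown, $I$ and $D$ are
`NA`: those pairs remain in the table and are dropped only by models that
use $I$ or $D$, so the pair count can exceed the rows usable by the full
model.

Model selection mirrors standard backward elimination for mixed models:
first the random intercept is tested by a likelihood ratio test at level
0.1 (REML likelihoods, $\chi^2_1$ reference — conservative at the
$\tau^2 = 0$ boundary; the halved $\chi^2_0/\chi^2_1$ mixture is available
via `boundary_mixture = TRUE`); then fixed effects are removed one at a
time, largest p first, using Satterthwaite-approximation F tests at level
0.05 until all remaining terms are significant. Selection is run on
standardized variables (every column z-scored over its complete cases,
binary indicators included, matching the generic convention of standardising
all variables; `keep_binary = TRUE` exempts them for sensitivity analyses),
and the selected model is refit on the raw scale for interpretable
coefficients. An optional restriction keeps at most one of $I$ and $D$ in
the start model — these two are substantially correlated by construction,
and `vif_fixed()` reports variance inflation factors (warning threshold 5,
never an automatic removal).

A known limitation, reproduced deliberately: pairs sharing a melody are not
independent, and the model treats pairs as exchangeable within groups. No
dyadic-dependence correction is applied; conclusions about standard errors
inherit this caveat.

`power_simulation()` is a post-hoc power analysis: the response is simulated
from the fitted (or coefficient-overridden) model, the model refit, and the
focal term tested at level $\alpha$; power is the fraction of significant
refits, with a binomial confidence interval, and refits that fail to
converge are counted separately rather than as significant. Setting the
focal coefficient to zero turns the same machinery into a size check, which
the acceptance suite requires to land in $[0.03, 0.07]$ at
$\alpha = 0.05$.

## What the synthetic corpus emulates — and what it does not

The real corpus behind this methodology is not distributable, so
`generate_corpus()` produces corpora with the statistical structure the
analysis assumes, plus ground truth. Defaults are the study conditions, not
dials:

* **38 song groups**, sizes $3 + \mathrm{Poisson}(0.9)$ (at least three
  melodies per group; roughly 148 songs in expectation, matching the corpus
  summary). A deterministic song-list stand-in with exactly the published
  count structure is available separately as `synthetic_song_table()`.
* **Ancestral melodies** of 30–50 notes drawn on one of the four Koizumi
  five-tone scales (ryukyu $\{0,4,5,7,11\}$, ritsu $\{0,2,5,7,9\}$, minyo
  $\{0,3,5,7,10\}$, miyako-bushi $\{0,1,5,7,8\}$), first note the tonic.
  Group scale probabilities 0.4/0.3/0.2/0.1 reflect the relative prevalence
  of the scales in the archipelago.
* **Mutation**: per note and per transmission edge, substitution 0.03
  (replacements stay within the scale — groups retain their mode), insertion
  0.01, deletion 0.01 (suppressed at length 1).
* **Transmission**: a star phylogeny within each group — each descendant
  evolves independently from the ancestor over **3 edges**. A star makes the
  expected divergence of a pair additive in its two lineages' multipliers,
  which gives clean recovery targets; three edges per lineage were fixed at
  design time so that the island effect (the weaker of the two calibrated
  effects) is well identified at the stated rates — at this depth the raw
  island coefficient is about 0.05 on the distance scale, the same order as
  published estimates. A lineage that crosses to another island has its
  rates multiplied by **2**; one that changes social context by **3**
  (probabilities 0.4 and 0.3 per descendant). Effects are therefore positive
  by construction, giving the sign-recovery and retention targets their
  meaning.
* **Metadata**: islands come from a 17-island centroid table (plausible
  coordinates, fixture data); 60% of melodies are published-score (SJF)
  sourced with years 1964–1990, the rest field recordings from 2015–2019;
  3% of melodies have unknown recording sites, exercising the `NA` pathway
  for $I$ and $D$.

Identical seed and configuration give byte-identical corpora; the pipeline
derives one sub-seed per stage from the root seed so stages can be rerun in
isolation.

The generator does *not* emulate: rhythm, lyrics, performance variation,
population structure in transmission, non-star within-group genealogies
(a binary-tree option would change pair exchangeability and is deliberately
not the default), spatially varying island contact rates, or scale-shift
events (a group changing mode wholesale) — substitutions never leave the
ancestral scale. Passing tests on synthetic corpora therefore show the
pipeline recovers known structure of this kind; they do not show that real
melodic evolution has this structure.

## Numerical choices and problem sizes

* Alignment scores are exact floating-point dynamic programming; co-optimal
  ties are resolved by the deterministic preference above with a $10^{-9}$
  comparison tolerance.
* Distance matrices are validated as symmetric to $10^{-8}$ and nonnegative
  before delta or network computation.
* Quantiles are type 7; the Brunner–Munzel exact permutation bound is
  20,000 enumerations, Monte Carlo 10,000 draws beyond it.
* The elimination trace records every decision (term, test, statistic,
  degrees of freedom, p, level) so a selection can be audited after the
  fact.
* Validation problem sizes are chosen to make the checks sharp but quick:
  exhaustive alignment enumeration up to length 6 (500 pairs), quartet
  oracle up to 8 taxa, tree-metric recovery up to 10 taxa, 200 synthetic
  corpora for recovery rates, 200 null corpora for retention rates, 1000
  simulations for the power size check. The acceptance script reports the
  same quantities at 100 corpora per rate.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(simulate = TRUE,
                  sim_config = simulation_config(n_groups = 10),
                  out_dir = "demo_run", seed = 7)
res <- run_pipeline(cfg)

res$results$set2$pid_summary
tidy(res$results$set2$bm)
res$results$set2$delta
tidy(res$results$set2$elimination)
tidy(res$results$set2$selected_raw)
```

The output directory then contains, per parameter set, the distance matrix
(CSV and NEXUS), the PID summary and Brunner–Munzel report, the delta score,
the split network (NEXUS and CSV), the pair table, the full and selected
model tables with the elimination trace, and a manifest with configuration,
seed and counts.
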