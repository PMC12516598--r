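# melodiverge

Tools for studying how orally transmitted melodies diversify. The package is
aimed at cultural-evolution and computational-ethnomusicology researchers who
have (or can simulate) a corpus of melodies organised into *song groups* —
tune families: sets of songs judged to descend from a common ancestral air —
and who want to know which circumstances of transmission are associated with
larger melodic divergence.

## What it computes

Melodies are coded as sequences over a 12-letter pitch-class alphabet
(transposed to a C tonic; durations and octaves ignored; lowercase letters
mark chromatic degrees so letter case carries the mode). From there:

* **Alignment and distance.** Optimal global alignment with affine gap
  penalties (match +1, mismatch −1, a gap run of length *k* costs
  GOP + GEP·*k*), under the two standard presets — set 1 (GOP 12, GEP 6,
  ignoring mode) and set 2 (GOP 0.8, GEP 0.2, including mode). Similarity is
  percent identity, PID = 100·2·ID/(L₁+L₂), and melodic distance is
  1 − PID/100.
* **Group divergence.** Median/IQR of PID for same-group versus
  different-group pairs, compared with a from-scratch Brunner–Munzel rank
  test (asymptotic t with Welch–Satterthwaite df, or exact/Monte-Carlo
  permutation).
* **Networks.** The quartet delta score δ (0 for perfectly tree-like
  distances) and Neighbor-Net circular split systems, exported as
  SplitsTree4-compatible NEXUS.
* **The pairwise mixed model.** For within-group pairs (i, j) in group k,

  Y_ij = β₀ + β₁·I_ij + β₂·D_ij + β₃·T_ij + β₄·C_ij + β₅·S_ij + r_0k + ε_ij

  with Y the melodic distance, I a different-island indicator, D the
  great-circle distance (km) between recording sites, T the recording-year
  difference, C a different-social-context indicator, S a different-source
  indicator, and r_0k a song-group random intercept. Backward elimination
  (random effect by likelihood ratio at 0.1, fixed effects by Satterthwaite
  F at 0.05), standardized and raw fits, variance inflation factors, and a
  simulation-based post-hoc power analysis.
* **Synthetic corpora.** A fully seeded generator produces corpora with
  known ground truth: song groups descend from ancestral melodies on the
  four Koizumi five-tone scales, with island-crossing and context-change
  inflating per-lineage mutation rates, so recovery of the island and
  context effects can be verified end to end.

## Worked example

Simulate a 10-group corpus and run the full analysis with both parameter
sets:

```r
library(melodiverge)

cfg <- run_config(simulate = TRUE,
                  sim_config = simulation_config(n_groups = 10),
                  out_dir = "demo_run", seed = 7)
res <- run_pipeline(cfg)

res$results$set2$pid_summary
#> # A tibble: 2 × 5
#>   class     n_pairs median    q1    q3
#>   <fct>       <int>  <dbl> <dbl> <dbl>
#> 1 same           49   71.8  67.3  78.9
#> 2 different     581   40.5  37.0  46.0
```

Same-group pairs are far more similar (median PID 71.8 vs 40.5), and the
Brunner–Munzel test quantifies the separation — the relative effect 0.995
says a random same-group pair beats a random different-group pair in PID
essentially always:

```r
tidy(res$results$set2$bm)
#> # A tibble: 1 × 5
#>   relative_effect statistic    df  p.value method
#>             <dbl>     <dbl> <dbl>    <dbl> <chr>
#> 1           0.995      129.  50.4 4.10e-65 asymptotic

res$results$set2$delta
#> delta score = 0.2771 over 58,905 quartets
```

A delta score of 0.28 means the distances are far from tree-like — expected,
since the corpus has no single common ancestor. Backward elimination keeps
the island and context effects and drops geographic distance, year and
source; on the raw scale the selected model reads:

```r
tidy(res$results$set2$selected_raw)
#> # A tibble: 3 × 6
#>   term        estimate std.error    df statistic       p.value
#>   <chr>          <dbl>     <dbl> <dbl>     <dbl>         <dbl>
#> 1 (Intercept)   0.202     0.0282  9.21      7.17 0.0000464
#> 2 I             0.0513    0.0150 31.8       3.41 0.00178
#> 3 C             0.123     0.0149 31.9       8.29 0.00000000182
```

Two same-group melodies recorded on different islands are on average 0.051
further apart on the 0–1 distance scale, and two sung in different social
contexts 0.123 further apart — the structure the generator planted. The
output directory holds every artifact per parameter set (distance CSV/NEXUS,
PID summary, Brunner–Munzel report, delta, splits NEXUS/CSV, pair table,
model tables, elimination trace) plus a manifest with seed and counts.

A thin command-line wrapper over the same function ships in
`inst/scripts/run_pipeline.R`:

```sh
Rscript inst/scripts/run_pipeline.R --seed 7 --out demo_run --power-sims 0
```

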