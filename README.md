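# qsarfuse

Combinatorial fusion of QSAR prediction systems, with virtual-screening
triage.

## The problem

Pharmacophore and QSAR modelling routinely produces *several* scoring
systems for the same target — different hypothesis-generation algorithms,
different conformer search settings — each assigning every inhibitor an
estimated activity (IC50, nM). Any single system is imperfect; the question
is which systems to combine, and whether the combination actually predicts
better. `qsarfuse` implements the combinatorial-fusion answer for medicinal
chemists and cheminformaticians evaluating ensembles of activity
predictors:

* **Score functions and evaluation.** Each system *A* is a score function
  *s_A* mapping a compound to an estimated activity. A system's quality is
  the Pearson correlation *r* between experimental and estimated activities
  over a compound set, computed on the log10 activity scale
  (`evaluate_systems()`).
* **Diversity rank/score functions.** For a pair of systems (*A*, *B*) and
  compound *i*, the diversity score is *d_i(A,B) = |s_A(i) − s_B(i)|*.
  Sorting the *t* diversity scores into descending order and re-indexing by
  rank *j* ∈ {1..*t*} gives the diversity rank/score function *f_(A,B)(j)*;
  its plot is the diversity rank/score graph, and its sum (the area under
  the curve) is the pair's aggregate diversity
  (`diversity_profile()`, `all_pair_profiles()`, `recommend_pairs()`).
* **Selection and exhaustive combination.** Fusion helps only when the
  combined systems are (1) individually accurate and (2) mutually diverse.
  `select_systems()` drops systems far below the best performer;
  `fusion_leaderboard()` then evaluates all 2^m − 1 score combinations
  (default: mean of log10 activities, i.e. the geometric mean of IC50s)
  and ranks them by *r*.
* **Screening triage.** `filter_screening()` and `top_hits()` apply the
  post-screening cutoffs — estimated IC50 strictly below a ceiling,
  docking interaction energy strictly above a reference — to nominate
  candidates.
* **Synthetic studies.** `simulate_study()` generates activity tables and
  families of noisy, optionally correlated prediction systems with known
  parameters, so every stage is testable without external data.

The package ships the three tables of a checkpoint kinase 2 (Chk2)
inhibitor study as fixtures (`load_fixture("table1")`, `"table2"`,
`"table3"`): 25 training inhibitors with three systems, 133 testing
inhibitors with six systems, and 21 post-docking screening candidates.

## Worked example

```r
library(qsarfuse)

train <- load_fixture("table1")
evaluate_systems(train)
#> # A tibble: 3 × 4
#>   label            n     r scale
#>   <chr>        <int> <dbl> <chr>
#> 1 Best_train      25 0.955 log10
#> 2 Fast_train      25 0.840 log10
#> 3 Caesar_train    25 0.238 log10
```

`Caesar_train` is far below the other two, so the selection rule drops it
(`select_systems()` keeps `Best_train` and `Fast_train`). The six crossed
test-stage systems derived from the two survivors are then fused
exhaustively:

```r
test <- load_fixture("table2")
lb <- fusion_leaderboard(test)
glance(lb)
#> # A tibble: 1 × 8
#>       m n_combinations rule     scale best_label best_r best_single_r mean_combined_r
#>   <int>          <int> <chr>    <chr> <chr>       <dbl>         <dbl>           <dbl>
#> 1     6             63 mean_log log10 BB+BC+FF    0.819         0.810           0.795
```

The best pairwise combination is `BB+FF` with r = 0.814 — above the best
individual system (BB, r = 0.810) — and `recommend_pairs()` ranks its
aggregate diversity well above the same-parent pairs (`BB+BF`, `BB+BC`)
that fuse poorly. Finally, the screening triage:

```r
screen <- load_fixture("table3")
nrow(filter_screening(screen, min_energy_kcal_mol = 37.786))  # 21
nrow(filter_screening(screen, min_energy_kcal_mol = 50))      # 11
top_hits(screen, 2)
#> # A tibble: 2 × 3
#>   id         est_ic50_nM energy_kcal_mol
#> 1 NSC 136954        1.99            61.2
#> 2 NSC 70804         1.68            59.0
```

`run_pipeline("table1", "table2", screening = "table3",
min_energy_kcal_mol = 37.786)` chains all the stages and can write every
stage's result as CSV; a thin command-line wrapper is installed at
`inst/scripts/qsarfuse-pipeline.R`. `autoplot()` methods draw the diversity
rank/score graphs and the combination leaderboard.

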