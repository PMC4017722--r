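---
title: "Combinatorial fusion of QSAR prediction systems: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial fusion of QSAR prediction systems: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarfuse)
```

## The model

A *scoring system* is any procedure — here, a pharmacophore hypothesis
applied with some conformer-search algorithm — that assigns each inhibitor
an estimated biological activity (IC50, nM). Writing $s_A(i)$ for system
$A$'s estimate on compound $i$, the package treats every system purely as
its score function: no structural information enters any computation, and
an optional SMILES column is carried through file round trips untouched.

System quality is the Pearson correlation $r$ between experimental and
estimated activities over a compound set. Both sides are transformed to
$\log_{10}$ activity first (the `scale = "log10"` default). Activities in
these studies span four or more orders of magnitude, model fitting for
activity estimation operates in log-activity space, and a raw-scale
correlation would be dominated by the handful of weakest binders near
$10^5$ nM. The raw scale remains available (`scale = "raw"`) because the
convention is a choice, not a mathematical necessity; on the packaged
tables the log10 default reproduces the published per-system correlations
to three decimals, which is how the default was fixed.

### Diversity of a pair of systems

Fusion theory says combining systems helps only when (1) each system is
individually accurate and (2) the systems are *diverse* — they err in
different places. For a pair $(A, B)$ and compound $i$ the diversity score
is

$$d_i(A, B) = |s_A(i) - s_B(i)|$$

on the chosen activity scale. One reading ambiguity had to be resolved
here: the quantity is sometimes written with a summation sign even though
it is indexed by a single compound and subsequently *sorted across*
compounds. We take $d_i$ to be the per-compound absolute difference — the
only reading under which sorting the scores into descending order is
meaningful — and expose the sum over compounds separately as the pair's
`aggregate`.

Sorting the $t$ per-compound scores descending and re-indexing by rank
$j \in \{1, \dots, t\}$ gives the *diversity rank/score function*
$f_{(A,B)}(j)$, non-increasing by construction; its plot is the diversity
rank/score graph (`autoplot()` on a `diversity_profile`, or
`plot_divgraphs()` for all pairs). Pairs whose curves lie higher disagree
more across the whole compound spectrum. Because automated pair ranking
needs a scalar where a person would compare curves visually, the package
ranks pairs by the area under the curve — the aggregate diversity
$\sum_j f_{(A,B)}(j)$ — which is invariant under the sort and equals the
sum of the raw scores.

### Selection and exhaustive combination

With $m$ systems there are $2^m - 1$ non-empty subsets, each a candidate
combination; `enumerate_combinations()` lists them all (size-major, then
lexicographic, so output order is reproducible). Before combining,
`select_systems()` applies the accuracy rule: a system is retained when
its correlation is at least `drop_fraction` times the best system's. The
default `drop_fraction = 0.5` is the package's operationalisation of "far
less accurate than the rest": on the packaged training table it separates
the two retained systems (r = 0.955, 0.840) from the dropped one
(r = 0.238) with a wide margin on either side, and it is exposed as a
parameter precisely because the boundary is a judgement call.

The combination itself is a *score combination*: the combined estimate is
the unweighted arithmetic mean of the members' $\log_{10}$ activities,
re-expressed in nM — equivalently the geometric mean of the IC50
estimates (`rule = "mean_log"`). The source convention names score
combination as its method but never writes the averaging formula, so the
rule is a design decision: averaging in log space is the consistent choice
when scores live on a log-activity scale, and the arithmetic-mean
alternative is kept as `rule = "mean_raw"`. Rank combination, voting, and
weighted schemes are deliberately out of scope. Combining a singleton
returns that system's scores unchanged under either rule, which makes the
leaderboard's singleton entries coincide exactly with the per-system
evaluation — a property the tests assert.

`fusion_leaderboard()` evaluates every enumerated combination and sorts by
$r$ descending, breaking ties by smaller subset and then label so repeated
runs agree byte for byte.

## Training/testing split validation

`validate_training_split()` encodes the standard selection rules for
pharmacophore training sets: at least 16 training inhibitors; the training
set contains the most and least active compound of the whole collection;
training activities span at least 4 orders of magnitude; and the two sets
share no identifiers. Overlap is reported as a failed rule rather than an
exception, since a report listing all violations at once is more useful
than stopping at the first. The remaining convention — records must be
clear and complete — is not independently operationalisable and is covered
by the strict ingest validation (positive activities, unique non-empty
identifiers, named schema errors with row indices).

## Screening triage

`filter_screening()` keeps records with estimated IC50 strictly below a
ceiling and/or docking interaction energy strictly above a floor. The
inequalities are strict because that is how the thresholds are worded in
the source convention; on the packaged screening table the choice is inert
(the smallest retained energy, 40.502 kcal/mol, is well clear of the
37.786 reference). The reference energy is an argument, never a constant:
it derives from redocking a known inhibitor, an external computation this
package does not perform. `top_hits()` ranks by energy (descending) or
estimated IC50 (ascending) with identifier tie-breaks.

## The synthetic-data generator

`simulate_study()` draws true $\log_{10}$ activities uniformly over a
`span_orders`-wide interval (log-uniform rather than log-normal: the
relevant design rule constrains the *span* of the activities, and the
uniform draw makes the span exact by construction, with the interval floor
anchored near the most potent packaged inhibitor, ~2.3 nM). System $k$'s
prediction is truth plus a per-system `bias` plus Gaussian noise with
standard deviation `noise_sd`, jointly across systems with correlation
matrix `noise_corr`. This lets both fusion preconditions be dialled
independently: `noise_sd` sets accuracy, `noise_corr` sets diversity
(correlation 1 with equal noise makes two systems' errors identical, so
every diversity score collapses to the bias gap and fusion gains nothing —
a closed form the tests check).

Defaults mirror the packaged study's scale: 25 training and 133 testing
compounds, a 4.6-order activity span, and two systems with 1 log-unit
noise, which places individual test correlations near the 0.7–0.8 range
observed for real pharmacophore models on this kind of data. A single
integer `seed` drives all draws; identical configurations reproduce
identical tables.

What the generator does *not* emulate: heteroscedastic or
activity-dependent prediction error, heavy-tailed outliers (real tables
contain estimates off by 3+ orders of magnitude), censored assay values,
and any structural correlation between related compounds. Tests passing
on synthetic data therefore demonstrate correctness of the fusion
machinery under the stated error model, not robustness of fusion to real
pharmacophore pathologies — the packaged real tables cover that side at
one design point.

## Numerical choices

* Ties everywhere break by identifier or label, lexicographically, so all
  orderings are stable and reproducible.
* Missing predictions are an error by default (`missing = "strict"`); the
  `"drop"` mode exists for exploratory work, reports the reduced $n$, and
  is never used by the pipeline.
* Degenerate inputs fail loudly with classed conditions: non-positive
  activities (log undefined), zero-variance vectors (correlation
  undefined), empty tables, duplicate identifiers, non-PSD noise
  correlation matrices.
* File round trips are exact: writing uses shortest round-trippable float
  representations and reading uses base R's correctly rounded parser, so
  a written table re-reads bit-identically.
* Correlations are reported at full precision and rounded only for
  display; comparisons against published three-decimal values use a
  ±0.005 band, which absorbs the rounding of estimates printed to one
  decimal.

## Problem sizes in the test suite

The suite exercises the brute-force leaderboard oracle at $m \le 4$
systems (agreement to $10^{-12}$), subset and pair counts at $m, q \le
10$, parameter recovery at $n = 10{,}000$, the fusion-gain comparison
against the analytic two-predictor correlation formula at 200 replicates
of $n = 2000$, and the correlation-monotonicity properties at 60–200
replicates of $n$ = 300–400 — sizes chosen to hold Monte-Carlo error
comfortably below the asserted margins while keeping the full suite in
the tens of seconds.

## Known limitations

* Only unweighted score combination is implemented; rank combination and
  weighted schemes are out of scope.
* The pipeline's selection stage links testing systems to their parent
  training systems only through the explicit `system_parent` mapping;
  nothing is inferred from labels.
* The packaged screening table contains only the 21 post-docking
  survivors; upstream database-screening counts are not reproducible from
  shipped data and are not claimed.
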