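---
title: "Methods: forward and all-subsets regression for model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forward and all-subsets regression for model selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(farms)
```

## The selection problem

The package targets wide regression problems from immunogenetics: a
continuous outcome (log10 steady-state HIV viral load) and hundreds of
binary covariates — carriage indicators for HLA class I alleles and
response indicators for overlapping peptides (OLP) tiling the viral
proteome — with carriage frequencies mostly between 1% and 13%.  The goal
is the subset of covariates that best explains the outcome under an
information criterion.  Exhaustive all-subsets regression is the gold
standard but costs $2^p$ model fits; greedy stepwise methods are cheap but
move one variable at a time.  The algorithm implemented here is a middle
path: it repeatedly injects fixed-size groups of unused variables into a
bounded candidate pool and resolves each pool *exactly* by all-subsets
search, so several variables can enter (and current ones leave) in a
single accepted move.

## Model and criteria

Every candidate model is ordinary least squares of the outcome on an
intercept plus a covariate subset $S$, summarised by its residual sum of
squares $RSS$, total sum of squares $TSS$, sample size $n$ and parameter
count $k = 1 + |S|$ (intercept included; for a rank-deficient subset $k$
drops to the design rank and the fit is flagged).  Six criteria are
available, with `RSS` and $R^2$ improving with every added variable
("size-monotone") and the other four penalizing complexity:

| name | value | direction |
|------|-------|-----------|
| RSS | $RSS$ | min |
| R2 | $1 - RSS/TSS$ | max |
| ADJR2 | $1 - \frac{RSS/(n-k)}{TSS/(n-1)}$ | max |
| CP | $RSS/\hat\sigma^2_{full} - n + 2k$ | min |
| AIC | $n\log(2\pi RSS/n) + n + 2(k+1)$ | min |
| BIC | $n\log(2\pi RSS/n) + n + (k+1)\log n$ | min |

Two conventions deserve a note, because different software disagrees on
them and the selected model can only be cross-checked when they are
pinned down:

* **AIC/BIC constants.**  We use the full Gaussian log-likelihood and
  count the residual variance as an estimated parameter (the $k+1$).
  This matches `stats::AIC()`/`BIC()` on `lm` objects exactly (a unit
  test asserts it), so logged values can be compared with mainstream
  output.  For fixed $n$ the additive constant never changes which model
  wins.
* **Mallows' Cp.**  $\hat\sigma^2_{full}$ is the residual-variance
  estimate from the fit on *all* candidate variables, the classical
  definition; when $n \le p + 1$ that fit does not exist and Cp is
  refused with an explanatory error rather than silently substituted.

Model comparisons are *strict*: equal criterion values never count as an
improvement, with exact floating-point comparison and no epsilon band.
Strictness is what guarantees termination of every loop in the package,
and the absence of a tolerance keeps runs bit-reproducible.

## The exhaustive pool search

`search_best_subsets()` evaluates every subset of a pool of at most
`hard_cap` (default 25) free variables, always joined with the forced
set.  It works on the centred cross-product matrix of the pooled columns
and the outcome, applying the symmetric sweep operator to move variables
in and out; centring absorbs the intercept, and after sweeping a subset
the bottom-right element of the matrix is that subset's RSS.  Subsets are
visited along a removal tree (root = all pool variables in; each child
removes one variable), and a subtree is pruned when the RSS at its root —
a lower bound for every descendant, since removing variables can only
increase RSS — is already no better than the incumbent best at every
model size the subtree can still reach.  Pruning only skips provably
suboptimal subsets; the returned models are identical to full
enumeration, which a test suite verifies against an independent naive
oracle (`naive_all_subsets_oracle()`, a `combn()` double loop fitting by
SVD with its own criterion arithmetic).

Within a fixed size, all penalized criteria are monotone transformations
of RSS, so the per-size winners are the per-size RSS minimisers.  Across
sizes the winner is taken by `c1` when `c1` is penalized.  The
size-monotone criteria cannot pick a cross-size winner (they always
prefer the largest subset), yet they are legitimate subset-selection
criteria; our resolution is that under a size-monotone `c1` the per-size
winners are ranked by the model-comparison criterion `c2`, which must
then be penalized.  This makes every listed `c1` usable and reduces to
the familiar "best subset of each size" report.

Tie-breaking is uniform everywhere: prefer fewer free variables, then the
lexicographically smallest index set; a rank-deficient subset is never
preferred over a full-rank subset with equal RSS.  Consequently results
do not depend on the order in which pool variables are supplied.  Exact
RSS ties between different subsets have probability zero for continuous
data; with duplicated binary columns the engine detects the collinearity
at the root of the tree and falls back to direct per-subset fitting,
which applies the same tie rules (feasible for pools up to 20).

The hard cap exists because the search space is $2^{|pool|}$; the error
message tells the user to lower the adding-group size, which is the knob
that controls pool growth inside the main loop.

## The main loop

`run_farms()` iterates, starting from the forced variables plus a
starting set (drawn uniformly without replacement from the non-forced
variables under the run's seed, unless given explicitly):

1. Partition the variables outside the current model into groups of
   `add_size` (reshuffled each iteration under the same seed stream; a
   `reshuffle = FALSE` switch keeps dataset order for debugging).
2. For each group, search the pool formed by the group plus the current
   model's free variables exhaustively under `c1`, with the forced set
   always included.
3. Keep the best pool winner across groups (by `c1` when penalized,
   otherwise by `c2`, with the uniform tie-break).
4. Accept it if it strictly improves the current model under `c2`;
   otherwise stop and declare the current model final.

Because each accepted move strictly improves `c2` and the candidate
models form a finite set, the loop terminates; both the strict
improvement along the recorded trace and the presence of forced variables
in every recorded model are asserted after every run.  Variables dropped
from the model by an inner search are *not* discarded — they return to
the candidate pool at later iterations, in keeping with the all-subsets
spirit.  A wall-clock budget (`max_time_s`, checked at the start of each
iteration) returns the current model with `converged = FALSE` instead of
raising.  A cap on total model size is implemented by limiting the free
variables per search to `max_model_size - |forced|`, i.e. forced
variables count toward the cap.

The per-iteration trace (also appendable to a tab-delimited text file
live during the run, for monitoring) records iteration number, elapsed
wall-clock seconds, AIC, BIC and the 0/1 inclusion vector over all
covariates.  Elapsed time is hardware-bound and excluded from all
reproducibility guarantees; everything else is byte-stable under a fixed
seed.

`robustness_grid()` re-runs the algorithm over a grid of
`(start_size, add_size)` values with fresh random starts (one derived
seed per cell) and summarises each cell's final model, so the stability
of the selection against the two structural parameters can be read off
as the number of distinct final models.  Cell failures are recorded in
the summary rather than aborting the grid.

## Baselines

Forward selection, forward stepwise (additions followed by improving
deletions), backward stepwise (from the full model, which requires
$n > p + 1$) and exhaustive all-subsets regression are provided with the
same criterion machinery, an `intercept_only` or `forced` baseline model,
and deterministic ascending-index candidate scans.  Requesting an
intercept-only baseline together with forced variables is rejected as
contradictory rather than silently merged.  These exist as comparison
points: on strong-signal data, forward stepwise under BIC with a forced
baseline and the main algorithm select the same model, which the
acceptance suite checks.

## Preprocessing and the univariate screen

* `transform_viral_load()` floors values below the assay detection limit
  (50 copies/mL) to 49 copies/mL and applies log10 — the printed summary
  values of the motivating cohorts (e.g. a median of 37800 copies/mL
  mapping to 4.577) are reproduced exactly to 3 decimals.
* `boxcox_lambda()` profiles the one-parameter Box-Cox likelihood over a
  grid (default $[-2, 2]$ in steps of 0.001 — grid bounds and step are
  our choice; the method is standard).  The package reports
  $\hat\lambda$ and leaves the transform decision to the analyst, since
  the canonical workflow is "$\hat\lambda$ near 0, hence log".
* `binarize_alleles()` codes *carriage* (homozygotes are 1, not 2), one
  lexicographically ordered column per observed allele, at most two
  records per locus per subject.  `binarize_olp()` codes a response as
  any strictly positive magnitude by default, with an explicit
  `>= threshold` switch, because the qualitative in-vitro response call
  is made upstream of the data this package sees.
* `univariate_screen()` runs a two-sided pooled-variance Student t-test
  per binary covariate (Welch by switch), with the degenerate
  identical-groups case defined as $t = 0, p = 1$.  Q-values default to
  Benjamini–Hochberg adjusted p-values — deterministic and assumption-
  light — with a Storey-type estimator
  ($\hat\pi_0 = \min(1, 2\,\overline{I(p > .5)})$) as an option; the
  default FDR threshold is 10%.  Covariates with an empty group are
  flagged untestable and excluded from the q-value computation.

## The synthetic-cohort generator

No subject-level data from the motivating cohorts is distributable, so
`generate_cohort()` emulates their statistical shape: independent
Bernoulli 0/1 covariates with frequencies drawn uniformly from
$[0.01, 0.13]$, an outcome linear in a small support plus Gaussian noise,
intercept 4.5 on the log10 scale.  When no noise scale is given it is
solved analytically so the population $R^2$ of the true model equals a
target (default 15%, the scale of variance explained reported for real
viral-load models): $\sigma^2 = Var(X\beta)\,(1 - R^2)/R^2$ with
$Var(X\beta) = \sum_j \beta_j^2 f_j (1 - f_j)$.  Default effect sizes are
$\pm 0.5$ log10 copies/mL, a plausible allele-level effect.

`strong_signal_cohort()` fixes the configuration used by the robustness
and recovery studies: $n = 500$, $p = 80$, six true covariates with
effects of 1.5 residual standard deviations (alternating sign) on a noise
scale of 0.7 log10, and support frequencies restricted to $[0.05, 0.13]$
so each true covariate has a realistic number of carriers (a 1%-frequency
covariate has ~5 carriers at $n = 500$ and is undetectable by any
method; the common range mirrors the most frequent alleles in large
cohorts).  These values were fixed once as the study conditions.

What the generator deliberately does **not** emulate: linkage
disequilibrium between HLA alleles, HLA-restriction structure coupling
peptide responses to alleles, and population stratification.  Covariate
independence makes support recovery *easier* than on real data, so
passing selection tests here does not certify behaviour under strong
collinearity.

`generate_allele_table()` complements this with long-format typing
records — two independent draws per locus per subject (Hardy–Weinberg
style) from a per-locus frequency catalog, with uncatalogued mass treated
as unlisted alleles — to exercise the carriage encoder; its default
catalog is synthetic, with labels and frequency scale mimicking common
class I alleles.

## Study sizes, and what the studies show

The test and acceptance studies use desk-scale problem sizes, chosen so
the full suite runs in minutes: oracle cross-checks at $n = 100$,
$p \le 10$; a $5\times5$ robustness grid with start sizes
$\{2,5,8,11,13\}$ and adding sizes $\{2,4,5,6,8\}$ (pools stay within the
enumeration cap) on one strong-signal cohort; 50 cohorts for support
recovery; 20 all-null cohorts ($n = 300$, 200 covariates) for screen
calibration.  On the strong-signal cohort the grid selects one and the
same model in all 25 cells, and forward stepwise under BIC with the same
forced variable returns that model too.

One study outcome deserves an honest caveat.  Exact-support recovery —
the final model equalling the six true covariates exactly — plateaus far
below 100% at these dimensions, and this is a property of BIC at
$n = 500$ with 74 noise covariates, not of any particular search
strategy: a noise covariate joins a BIC-selected model when its partial
chi-square exceeds $\log(500) \approx 6.2$, which happens with
probability $\approx 0.013$ per covariate, so the chance that *no* noise
covariate qualifies is roughly $0.987^{74} \approx 0.39$.  Observed
recovery rates around 25–45% (seed-dependent), with the true support
almost always *contained* in the selected model, match this expectation;
the acceptance script reports the measured rate.  Recovering the exact
support with high probability at this noise-variable count would require
$n$ on the order of $e^{10}$ or an explicitly stronger penalty than BIC.

## Numerical choices and limitations

* Sweep pivots are aliased below a relative tolerance of $10^{-10}$ of
  the original diagonal; any aliasing at the tree root triggers the
  direct-fit fallback.  `fit_ols()` uses pivoted QR and flags rank
  deficiency.
* The sweep restore on backtracking flips the sign of the restored
  row/column; the flip never touches the diagonal (pivots, RSS) and
  cancels in subsequent updates, so it is harmless — this is why the
  engine can use the sweep as its own inverse.
* Criterion comparisons are exact; ties stop loops and prefer smaller,
  lexicographically earlier subsets.  Under the branch-and-bound pruning
  an exact RSS tie across *different* subsets of the same size may
  resolve differently than in the naive oracle; such ties are
  measure-zero for continuous data and only arise from duplicated
  columns, which route through the fallback path instead.
* Generalized linear models, shrinkage/regularized fits, weighted
  regression and heuristic (genetic, annealing) searches are out of
  scope.  Excel input is not parsed; convert to CSV/TSV first.
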