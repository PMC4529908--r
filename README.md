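# farms

Forward and all-subsets regression for model selection in R.

## The problem

Cohort studies in HIV immunogenetics relate a continuous outcome —
log10 steady-state viral load — to hundreds of binary covariates: carriage
of individual HLA class I alleles and T-cell responses to overlapping
peptides (OLP) spanning the viral proteome, with carriage frequencies
mostly between 1% and 13%. Finding the covariate subset that best explains
the outcome runs into the classic wall: exhaustive all-subsets regression
costs 2^p model fits and is hopeless for p in the hundreds, while greedy
stepwise selection moves one variable at a time and commits early.

This package implements a middle path. Starting from a model containing
any forced-in variables plus a (by default random) starting set, each
iteration

1. partitions the variables outside the current model into groups of
   `add_size`,
2. resolves each group *exactly*: an exhaustive best-subset search over
   the group merged with the current model's free variables, under a
   subset criterion C1 (Mallows' Cp, AIC, BIC, R², adjusted R² or RSS),
3. takes the best pool winner across groups, and
4. accepts it only if it strictly improves the current model under a
   model-comparison criterion C2, stopping otherwise.

Several variables can enter — and incumbent variables leave — in a single
accepted move, yet each inner search is exact. Strict improvement under C2
guarantees termination. The exhaustive inner step runs in compiled code on
the sweep operator with branch-and-bound pruning, and is verified
subset-for-subset against a naive enumeration oracle.

Alongside the main loop the package ships the classical baselines (forward
selection, forward/backward stepwise, all-subsets regression), the
preprocessing used for this kind of data (detection-limit flooring + log10
for viral loads, Box-Cox lambda, carriage/response binarization), a
univariate t-test screen with FDR q-values, a robustness grid over the two
tuning parameters, a synthetic-cohort generator with known truth, and a
command-line interface (`inst/cli/farms.R`).

## Worked example

```r
library(farms)

# a synthetic cohort: 400 subjects, 40 binary covariates, 4 true signals
cohort <- generate_cohort(n = 400, p = 40, n_signal = 4,
                          beta = c(0.6, -0.6, 0.6, -0.6),
                          noise_sd = 0.6, seed = 42)
cohort$data$names[cohort$truth$support]
#> [1] "x08" "x15" "x22" "x36"

# univariate screen: all four true covariates top the q-value ranking
scr <- univariate_screen(cohort$data)
head(scr[order(scr$p_value),
         c("variable", "n1", "t_stat", "p_value", "q_value")], 5)
#>    variable n1    t_stat      p_value      q_value
#> 8       x08 41  5.572240 4.641789e-08 1.856715e-06
#> 36      x36 25 -5.203387 3.140481e-07 6.280962e-06
#> 15      x15 32 -4.914424 1.303635e-06 1.738181e-05
#> 22      x22 41  4.523872 8.026007e-06 8.026007e-05
#> 38      x38 14 -2.585345 1.008288e-02 8.066303e-02

# the selection loop (C1 = C2 = BIC)
res <- run_farms(cohort$data,
                 farms_config(start_size = 6, add_size = 6, seed = 7))
res
#> FARMS result: 4 variable(s) after 4 iteration(s)
#>   selected: x08, x15, x22, x36
#>   AIC = 728.8026, BIC = 752.75139

res$trace
#>   iteration elapsed_s      aic      bic c2_value
#> 1         1     0.004 815.1381 847.0698 847.0698
#> 2         2     0.045 777.6657 797.6231 797.6231
#> 3         3     0.068 751.7313 775.6801 775.6801
#> 4         4     0.091 728.8026 752.7514 752.7514

# forward stepwise under BIC lands on the same model here
sw <- stepwise(cohort$data, "BIC", direction = "both")
identical(sw$subset, res$final_fit$subset)
#> [1] TRUE
```

The trace shows the BIC of the selected model improving strictly at every
accepted iteration, from the random 6-variable start (BIC 847.1) to the
exact true support (BIC 752.8). `run_farms(..., trace_file = "trace.txt")`
appends the same records to a tab-delimited file live during the run, one
line per iteration with the AIC/BIC and a 0/1 inclusion flag per covariate.

The same analysis from a shell:

```sh
Rscript inst/cli/farms.R simulate --n 400 --p 40 --n-signal 4 --seed 42 --out cohort.csv
Rscript inst/cli/farms.R run --data cohort.csv --outcome outcome \
    --start-size 6 --add-size 6 --seed 7 --trace trace.txt --out model.json
```

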