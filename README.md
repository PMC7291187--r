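# sice — hybrid single/multiple imputation for mixed-type tables

Missing cells degrade almost every tabular analysis, and the two standard
remedies each have a cost: single imputation (column mean/median/mode) is
cheap but ignores imputation uncertainty, while multiple imputation by
chained equations (MICE) captures uncertainty at the price of leaving the
analyst *m* completed datasets instead of one. `sice` implements the hybrid
in between, aimed at epidemiologists and data analysts preparing health-
record-style tables (binary, nominal, ordinal, and numeric columns) for
downstream modelling.

The core procedure: run a fully conditional specification engine for *m*
independent chains, so every missing cell *i* accumulates an array of
candidate values x_i^1, …, x_i^m; then collapse each array to a single
value,

- **categorical columns:** the mode of the array (majority vote, with a
  deterministic tie-break toward the level more frequent among the observed
  values),
- **numeric columns:** the arithmetic mean (1/m) Σ_j x_i^j,

producing one completed dataset whose values still reflect the spread of
the m conditional draws. For numeric columns the root-mean-square norm is
convex, so the pooled RMSE never exceeds the average per-chain RMSE.

The engine ships six pluggable univariate kernels — predictive mean
matching (`pmm`), Bayesian linear regression (`blr`), logistic and
multinomial regression (`logreg`, `polyreg`), linear discriminant analysis
(`lda`), and regression trees with leaf sampling (`cart`) — plus the
single-imputation baselines (`mean`, `median`, `mode`, `random`). Around
it: MCAR amputation with held-out ground truth, confusion-matrix and RMSE
scoring, a synthetic mixed-type generator with planted signal, and a CLI.

## Worked example

Mask 10% of a numeric column in a synthetic 2,000-row health-record-like
table, impute it with the chained engine (m = 7 chains of Bayesian linear
regression, mean-pooled), and score against the held-out truth:

```r
library(sice)

tab  <- generate_health_like(n_rows = 2000, seed = 42)
amp  <- ampute_mcar(tab, "Age", rate = 0.1, seed = 43)
amp
#> <sice_amputed> target 'Age': 200 of 2000 cells masked

done <- sice_impute(amp$table,
                    chain_spec(m = 7, method_map = list(Age = "blr"),
                               seed = 44))
score_imputation(done, amp)
#> <sice_rmse> 9.117694 over 200 cells
```

The generator plants Age = 30 + region/diagnosis offsets + N(0, 8.7), so
about half the Age variance is predictable; an RMSE of ≈ 9.1 years means
the engine recovered most of that signal. The single-imputation baseline on
the same mask is markedly worse — close to the column's marginal standard
deviation, as expected when every masked cell gets the same value:

```r
filled <- amp$table
filled$Age[amp$mask] <- mean(filled$Age, na.rm = TRUE)
score_imputation(filled, amp)
#> <sice_rmse> 12.22391 over 200 cells
```

The same pipeline in one call, with per-chain scores included:
`run_experiment(tab, "Age", "blr", rate = 0.1, m = 7, seed = 43)`.

## Command line

A thin wrapper over the same functions is installed as `exec/sice`:

```sh
sice ampute   --schema schema.yaml --target Age --rate 0.1 --seed 3 \
              --mask-out mask.csv data.csv amputed.csv
sice impute   --schema schema.yaml --m 7 --cycles 5 --seed 5 \
              amputed.csv completed            # writes completed.csv
sice evaluate --schema schema.yaml --truth mask.csv \
              --imputed completed.csv --target Age
sice benchmark --n 2000 --method pmm --target Age --m 7 \
              --replicates 20 --seed 9 --out report.csv
```

Schemas are YAML sidecars mapping column name to type (and ordered levels
for categorical columns); missing CSV cells are empty or the token `NA`.

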