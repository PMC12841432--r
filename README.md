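# grainrisk

Risk scoring, prediction and tamper-evident traceability for grain and oil
food-safety monitoring data.

Quality-control laboratories screen wheat and other staples for six routine
hazard indicators — pesticide residues, lead, cadmium, arsenic and the
Fusarium mycotoxins deoxynivalenol (DON) and zearalenone (ZEN). `grainrisk`
turns such per-sample detection tables into a single monitored pipeline for
analysts and regulators:

1. **Composite risk scoring** by Grey Relational Analysis (GRA). Each
   indicator column is range-normalized, `Z_ki = (X_ki − min_i) /
   (max_i − min_i)`, and compared against the maximum-hazard reference
   profile through grey relational coefficients

   γ_ik = (Δmin + ρ·Δmax) / (Δ_ik + ρ·Δmax),  Δ_ik = |1 − Z_ki|,

   with distinguishability factor ρ = 0.5 by default. Indicator weights are
   the normalized relational degrees, ω_i = Σ_k γ_ik / Σ_i Σ_k γ_ik, and the
   composite risk of a sample is R_k = Σ_i ω_i Z_ki ∈ [0, 1] — the
   regression target for the predictive model.
2. **Risk prediction** by an attentive tabular network (`tabnet()`): a
   multi-step architecture in which a sparsemax attentive transformer
   selects a sparse per-sample feature mask at every decision step, masked
   features pass through shared and step-specific gated-linear-unit blocks
   with ghost batch normalization and √0.5-scaled residuals, and ReLU-ed
   decision slices accumulate into a linear regression head. Forward and
   backward passes are written out by hand in base R; training uses Adam
   with a reduce-on-plateau schedule and early stopping. Gaussian-process
   Bayesian optimization (`tune_tabnet()`) searches the hyperparameter box
   N_d, N_a ∈ [8, 128], N_steps ∈ [3, 10], γ ∈ [1, 2], λ ∈ [10⁻⁶, 10⁻²],
   η ∈ [10⁻⁴, 10⁻²] by expected improvement under a Matérn-5/2 surrogate.
3. **Evaluation**: MAE, RMSE, R², absolute-error series and paired t-tests
   on absolute errors between model pairs (`compare_models()`), with thin
   adapters around `randomForest`, `xgboost`, `e1071` (RBF SVR) and `nnet`
   as baselines.
4. **Tiered traceability**: deterministic screening policies classify each
   record against configurable safety limits; exceeding records (with their
   predictions) are signed and anchored in hash-chained blocks carrying
   SHA-256 Merkle roots, while compliant records are encrypted with SM2
   elliptic-curve cryptography into a local store. ID, batch and time-range
   queries run over the chain, and `validate_chain()` pinpoints the first
   tampered block.

A seeded synthetic-data generator (`generate_samples()`) emulates a
multi-year institutional wheat-testing dataset so that the entire pipeline
is reproducible without access to any proprietary data.

## Worked example

```r
library(grainrisk)

# a seeded synthetic detection table: 800 wheat samples, six indicators
tab <- generate_samples(generator_config(n_samples = 800, seed = 42))

# grey relational scoring
sc <- gra_score(tab, rho = 0.5)
print(sc)
#> Grey relational risk scoring (rho = 0.50, reference = ideal)
#>   800 samples, 6 indicators
#>   indicator weights:
#> pesticide_residue              lead           cadmium           arsenic
#>            0.1652            0.1657            0.1712            0.1632
#>               DON               ZEN
#>            0.1714            0.1633
#>   risk: min 0.047  median 0.118  max 0.285
```

The weights say how strongly each indicator column tracks the
maximum-hazard profile; the composite risk is their weighted combination
per sample. Train the network on the risk target and evaluate:

```r
parts <- split_dataset(tab, c(0.7, 0.15, 0.15), seed = 42)
risk  <- function(p) sc$risk[match(p$sample_id, tab$sample_id)]

fit <- tabnet(indicator_matrix(parts$train), risk(parts$train),
              x_valid = indicator_matrix(parts$validation),
              y_valid = risk(parts$validation),
              config = tabnet_config(n_d = 16, n_a = 16, n_steps = 4,
                                     lambda_sparse = 1e-5,
                                     learning_rate = 0.01, batch_size = 128,
                                     virtual_batch_size = 64,
                                     max_epochs = 200, patience = 60,
                                     seed = 42))
print(fit)
#> Attentive tabular network (risk regression)
#>   6 features; n_d=16 n_a=16 steps=4 gamma=1.43
#>   trained 179 epochs; best validation MSE 0.000911077

regression_metrics(risk(parts$test), predict(fit, indicator_matrix(parts$test)))
#>    mae   rmse     r2
#> 0.0191 0.0249 0.7148

round(coef(fit), 3)     # aggregate mask importances, summing to 1
#> pesticide_residue              lead           cadmium           arsenic
#>             0.156             0.101             0.072             0.126
#>               DON               ZEN
#>             0.277             0.267
```

Here MAE/RMSE are on the composite-risk scale (0–1) and `coef()` returns
the attentive-mask feature importances. Finally, screen the test records
and route them through the tiered ledger:

```r
state <- ledger_init()   # default thresholds, fresh SM2 key pair
recs  <- records_from_table(parts$test,
                            predictions = predict(fit, indicator_matrix(parts$test)))
for (r in recs) state <- store_record(state, r)$state
state <- append_block(state)
print(state)
#> Tiered traceability ledger
#>   chain: 1 block(s), 18 on-chain record(s)
#>   staged: 0   encrypted local store: 102
#>   anchoring policy: exceeding_only
validate_chain(state)$valid
#> [1] TRUE
```

The 18 exceeding records (together with their predicted risk values) are
signed and anchored on-chain; the 102 compliant records are SM2-encrypted in
the local store. `ledger_query(state, "batch", value = "B007")` or a
time-range query retrieve anchored records with block provenance.

A thin command-line front end over the same functions ships in
`inst/cli/grainrisk.R` (`simulate`, `score`, `run`, `ledger validate|query`
subcommands).

## Package layout

- `R/synthetic_data.R` — generator, table schema, splits, CSV I/O
- `R/gra.R` — normalization, relational coefficients, weights, risk
- `R/sparsemax.R`, `R/tabnet.R` — simplex projection; network, manual
  backpropagation, training loop, S3 methods
- `R/bayes_opt.R` — GP surrogate, expected improvement, tuning loop
- `R/evaluation.R` — metrics, paired t-tests, comparison harness, baselines
- `R/sm2.R` — SM2 curve arithmetic, keygen/sign/verify/encrypt/decrypt
- `R/ledger.R` — screening policy, Merkle trees, blocks, queries, storage
- `R/pipeline.R` — end-to-end orchestration with a run manifest
- `vignettes/grainrisk-methods.Rmd` — models, assumptions, design choices
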