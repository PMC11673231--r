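# nmtlrank

Discrete-time deep survival modeling for transcriptomic cohorts, with a
pathway-level interpretation arm. The package is aimed at analysts who fit
survival networks to bulk RNA-seq cohorts (hundreds of patients, thousands of
genes), need honest time-dependent evaluation under right-censoring, and want
to turn a trained network into testable biology: per-gene attributions,
per-patient gene-set enrichment, a single-sample activity score, and a
Kaplan–Meier risk stratification that can be transferred to external cohorts.

## The model

Each subject is a triplet *(Xᵢ, tᵢ, dᵢ)*: a gene-expression vector, an
observed time in days, and an event indicator (1 = deceased, 0 =
right-censored). Follow-up is discretized into *m* intervals with cuts
τ₁ < … < τₘ (equidistant or Kaplan–Meier quantiles). A feed-forward network
emits raw outputs ψ(X) ∈ ℝᵐ; the interval logits are their **reverse
cumulative sum** ϕⱼ(X) = Σₖ₌ⱼ..ₘ ψₖ(X), so the estimate at a time is a
function of the estimates at later times (the defining property of neural
multi-task logistic regression, N-MTLR). A softmax over (ϕ₁, …, ϕₘ, 0) gives
the probability mass σₖ per interval plus a residual category "survives past
τₘ", and Ŝ(k|X) = 1 − Σⱼ≤ₖ σⱼ.

The composite training objective is

    loss = α · loss_NMTLR + (1 − α) · loss_rank

where `loss_NMTLR` is the discrete-time negative log-likelihood
(events contribute −log σ_k(t), censored subjects −log Ŝ(k(t)|X)) and
`loss_rank` is a DeepHit-style pairwise penalty: over comparable pairs
(dᵢ = 1, tᵢ < tⱼ),

    exp{ [Ŝ(k(tᵢ)|Xᵢ) − Ŝ(k(tᵢ)|Xⱼ)] / β }

averaged over pairs. α balances calibration against ranking; β is the
penalty temperature. The PMF, DeepHit and Cox partial-likelihood baselines
are included under the same training interface, all with analytic gradients
(verified against finite differences in the test suite).

Evaluation uses the time-dependent (Antolini) concordance index and the
IPCW Integrated Brier Score; model interpretation uses PatternAttribution
signal patterns back-propagated to the input genes, per-patient preranked
GSEA with Benjamini–Hochberg correction, a GSVA-style activity score for a
combined gene set, and quantile-cutoff stratification with the log-rank test.

## Worked example

A synthetic cohort with one planted, hazard-driving expression module stands
in for a real cohort (the generator mirrors an ovarian-cancer-like regime:
372 subjects, ~38% censoring, correlated gene modules on the log2 scale):

```r
library(nmtlrank)

cohort <- simulate_cohort(simulation_config(n = 372, p = 200, seed = 1))
#> <survival_cohort 'synthetic'> 372 subjects x 200 genes, 228 events (38.7% censored)

folds <- stratified_kfold(cohort, k = 5, seed = 1)
train <- cohort[folds[[1]]$train_idx]; test <- cohort[folds[[1]]$test_idx]
fit <- train_survnet(train, hyperparams(seed = 1), "nmtlr_rank")
evaluate_fit(fit, test)
#> <metric_report> C-index(td) = 0.6438, IBS = 0.2098 (window 0..3401)

sets     <- synthetic_gene_sets(cohort, n_decoys = 19, seed = 1)
patterns <- fit_patterns(fit, train$X)
node     <- select_endpoint_nodes(fit$grid, 1919)   # ~5-year endpoint
attr_5y  <- attribute(fit, patterns, cohort, node)
enr      <- enrich_cohort(attr_5y, sets, n_perm = 500, seed = 1)
head(enr$frequency, 3)
#>               set pct_patients
#> 1 PLANTED_MODULE1    33.870968
#> 7        DECOY_06     1.612903
#> 6        DECOY_05     1.075269

combined <- combine_sets(sets, min_frequency = 0.05, freq_table = enr$frequency)
scores   <- gsva_score(cohort$X, combined)
stratify_cohort(cohort, scores,
                fit_cutoff(scores, 0.30, "high_score_high_risk"))
#> <risk_stratification> cutoff -0.3714: 112 low / 260 high; log-rank chi2 = 45.454, p = 1.563e-11
```

Reading the output: the held-out concordance (0.64) sits below the
generating model's oracle (~0.71) but well above chance; the planted module
is the top enriched set in 34% of patients while every decoy stays under 2%;
and the 30/70 split on the combined-set activity score separates survival
decisively. `run_pipeline()` chains the same stages (plus optional tuning,
cross-validation and cutoff transfer) from a single YAML/JSON config, and
`inst/cli/nmtlrank.R` exposes `simulate` and `run` from a shell.

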