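#' Default pipeline configuration
#'
#' @param out_dir artifact directory.
#' @param seed master seed.
#' @param endpoints_days attribution endpoints in days (default 372 and
#'   1919, ~1 and ~5 years).
#' @param low_risk_fraction stratification fraction (default 0.30).
#' @param ... further fields overriding the defaults (see
#'   [run_pipeline]).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "nmtlrank_run", seed = 1L,
                            endpoints_days = c(372, 1919),
                            low_risk_fraction = 0.30, ...) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    simulate = NULL,              # a simulation_config, or NULL to load data
    expression = NULL, survival = NULL, orientation = "samples_rows",
    gmt = NULL,                   # gene-set file; NULL + simulate -> synthetic sets
    auxiliaries = list(),         # list of survival_cohorts or TSV pairs
    loss_name = "nmtlr_rank",
    hyperparams = list(),         # overrides for hyperparams()
    tune_budget = 0L,             # 0 = skip tuning
    cv_k = 0L, cv_repeats = 1L,   # 0 = skip cross-validation
    test_fraction = 0,            # held-out target fraction for metrics
    endpoints_days = endpoints_days,
    enrich_n_perm = 500L, enrich_alpha = 0.05,
    combine_min_frequency = 0.05,
    low_risk_fraction = low_risk_fraction,
    direction = "high_score_low_risk",
    external = NULL)              # optional external cohort for cutoff transfer
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$simulate)) cfg$simulate <- do.call(simulation_config,
                                                      cfg$simulate)
  do.call(pipeline_config, cfg)
}

stage_log <- function(stage, seed, t0) {
  message(sprintf("[%s] stage=%s seed=%s wall=%.2fs",
                  format(Sys.time(), "%H:%M:%S"), stage, seed,
                  as.numeric(Sys.time()) - t0))
}

#' Run the end-to-end survival-interpretation workflow
#'
#' Orchestrates the full pipeline on a cohort: (optional) simulation or
#' loading, normalization, stratified train/test split, (optional)
#' hyperparameter search and cross-validation, refit on all training
#' samples, feature attribution at the configured endpoints, per-patient
#' enrichment, gene-set combination, GSVA activity scoring, quantile-cutoff
#' stratification with Kaplan-Meier curves and the log-rank test, and
#' (optional) cutoff transfer to an external cohort. All tabular artifacts
#' are written as TSV under `config$out_dir` together with a JSON manifest
#' (config snapshot, seeds, input fingerprints, stage outputs); the run is
#' deterministic given the manifest.
#'
#' @param config a [pipeline_config], or a path to a YAML/JSON file with the
#'   same fields.
#' @param cohort optionally, a pre-built [survival_cohort] (overrides the
#'   simulate/load fields).
#' @return list of class `pipeline_result`: `manifest`, `fit`, `metrics`,
#'   `enrichment`, `combined_set`, `scores`, `stratification` (and
#'   `external_stratification` when configured).
#' @export
run_pipeline <- function(config, cohort = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  t0 <- as.numeric(Sys.time())
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config[setdiff(names(config), "simulate")],
                   seed = config$seed, stages = list(),
                   tool_version = as.character(utils::packageVersion("nmtlrank")))
  art <- function(name) file.path(config$out_dir, name)

  # --- data -----------------------------------------------------------------
  gt <- NULL
  if (is.null(cohort)) {
    if (!is.null(config$simulate)) {
      cohort <- simulate_cohort(config$simulate)
      gt <- attr(cohort, "ground_truth")
    } else {
      if (is.null(config$expression) || is.null(config$survival))
        stopf("config needs either `simulate` or expression+survival paths")
      cohort <- read_cohort(config$expression, config$survival,
                            config$orientation)
      manifest$input_fingerprints <- list(
        expression = unname(tools::md5sum(config$expression)),
        survival = unname(tools::md5sum(config$survival)))
    }
  } else gt <- attr(cohort, "ground_truth")
  stage_log("load", config$seed, t0)

  sets <- if (!is.null(config$gmt)) load_gmt(config$gmt)
          else if (!is.null(gt)) synthetic_gene_sets(cohort,
                                                     seed = config$seed)
          else stopf("no gene sets: supply `gmt` or a simulated cohort")

  # --- split ----------------------------------------------------------------
  test <- NULL
  train <- cohort
  if (config$test_fraction > 0) {
    k <- max(2L, round(1 / config$test_fraction))
    folds <- stratified_kfold(cohort, k = k, seed = config$seed)
    train <- cohort[folds[[1L]]$train_idx]
    test <- cohort[folds[[1L]]$test_idx]
  }
  stage_log("split", config$seed, t0)

  # --- hyperparameters ------------------------------------------------------
  hp <- do.call(hyperparams, config$hyperparams)
  hp$seed <- as.integer(child_seed(config$seed, 11L))
  if (config$tune_budget > 0L) {
    tfolds <- stratified_kfold(train, k = 4L, seed = child_seed(config$seed, 13L))
    tuned <- tune_survnet(train[tfolds[[1L]]$train_idx],
                          train[tfolds[[1L]]$test_idx],
                          budget = config$tune_budget,
                          seed = child_seed(config$seed, 17L),
                          loss_name = config$loss_name,
                          overrides = config$hyperparams)
    hp <- tuned$best_hp
    data.table::fwrite(tuned$trials, art("tuning_trials.tsv"), sep = "\t")
    stage_log("tune", config$seed, t0)
  }

  # --- cross-validation -----------------------------------------------------
  metrics <- NULL
  if (config$cv_k >= 2L) {
    metrics <- cross_validate(train, hp, config$loss_name, k = config$cv_k,
                              repeats = config$cv_repeats,
                              seed = child_seed(config$seed, 19L),
                              auxiliaries = config$auxiliaries)
    data.table::fwrite(metrics, art("cv_metrics.tsv"), sep = "\t")
    stage_log("cross_validate", config$seed, t0)
  }

  # --- refit on all training samples ---------------------------------------
  fit <- combined_train(train, config$auxiliaries, hp, config$loss_name)
  save_survnet(fit, art("model"))
  if (!is.null(test)) {
    held_out <- evaluate_fit(fit, test)
    manifest$stages$held_out <- list(c_index = held_out$c_index_td,
                                     ibs = held_out$ibs)
  }
  stage_log("train", hp$seed, t0)

  # --- attribution + enrichment at each endpoint ----------------------------
  patterns <- fit_patterns(fit, train$X)
  nodes <- select_endpoint_nodes(fit$grid, config$endpoints_days)
  enrichment <- list()
  freq_tables <- list()
  for (e in seq_along(nodes)) {
    am <- attribute(fit, patterns, train, nodes[e])
    write_attributions(am, art(sprintf("attributions_%dd.tsv",
                                       round(config$endpoints_days[e]))))
    en <- enrich_cohort(am, sets, alpha = config$enrich_alpha,
                        n_perm = config$enrich_n_perm,
                        seed = child_seed(config$seed, 23L + e))
    enrichment[[e]] <- en
    freq_tables[[e]] <- en$frequency
    stage_log(sprintf("enrich_%dd", round(config$endpoints_days[e])),
              config$seed, t0)
  }
  freq <- Reduce(function(a, b) merge(a, b, by = "set",
                                      suffixes = c("", ".y"), all = TRUE),
                 freq_tables)
  names(freq)[-1L] <- sprintf("pct_%dd", round(config$endpoints_days))
  data.table::fwrite(freq, art("pathway_frequency.tsv"), sep = "\t")

  # --- combined set + activity score + stratification -----------------------
  last <- length(nodes)  # the latest endpoint drives the combined set
  ft <- freq_tables[[last]]
  if (!any(ft$pct_patients > 100 * config$combine_min_frequency)) {
    warnf("no set exceeds the %.0f%% frequency threshold; using the top set",
          100 * config$combine_min_frequency)
    combined <- combine_sets(sets, names = ft$set[which.max(ft$pct_patients)])
  } else {
    combined <- combine_sets(sets, min_frequency = config$combine_min_frequency,
                             freq_table = ft)
  }
  scores <- gsva_score(cohort$X, combined)
  data.table::fwrite(data.frame(subject_id = names(scores),
                                score = as.numeric(scores)),
                     art("activity_scores.tsv"), sep = "\t")
  cut <- fit_cutoff(scores, config$low_risk_fraction,
                    direction = config$direction)
  strat <- stratify_cohort(cohort, scores, cut)
  data.table::fwrite(data.frame(subject_id = cohort$subject_ids,
                                label = as.character(strat$labels)),
                     art("risk_labels.tsv"), sep = "\t")
  jsonlite::write_json(list(cutoff = strat$cutoff,
                            low_risk_fraction = strat$low_risk_fraction,
                            logrank_chi2 = strat$logrank_chi2,
                            logrank_p = strat$logrank_p),
                       art("stratification.json"), auto_unbox = TRUE,
                       digits = NA)
  stage_log("stratify", config$seed, t0)

  # --- optional cutoff transfer to an external cohort -----------------------
  ext_strat <- NULL
  if (!is.null(config$external)) {
    ext <- config$external
    ext_scores <- gsva_score(ext$X, combined)
    ext_strat <- stratify_cohort(ext, ext_scores, cut)
    stage_log("transfer", config$seed, t0)
  }

  manifest$stages$artifacts <- list.files(config$out_dir, recursive = TRUE)
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  structure(list(manifest = manifest, fit = fit, metrics = metrics,
                 enrichment = enrichment, frequency = freq,
                 combined_set = combined, scores = scores,
                 stratification = strat,
                 external_stratification = ext_strat),
            class = "pipeline_result")
}
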