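#' Repeated stratified cross-validation of a survival network
#'
#' Splits the cohort with [stratified_kfold], trains `repeats` models per
#' fold (repeats differ only in the training seed) and evaluates the
#' time-dependent C-index and the IPCW Integrated Brier Score on the
#' untouched test folds. `k = 5, repeats = 10` reproduces the
#' 50-models-per-configuration protocol.
#'
#' @inheritParams train_survnet
#' @param k number of folds.
#' @param repeats training repetitions per fold.
#' @param n_time_bins time-quantile bins for stratification.
#' @param seed seed for the fold split and the per-repeat training seeds.
#' @param eval_points number of evaluation times for the metrics
#'   (equispaced over the test fold's follow-up).
#' @param auxiliaries optional list of auxiliary cohorts passed to
#'   [combined_train]; evaluation stays on the held-out target subjects.
#' @return data.frame with one row per (fold, repeat): `c_index`, `ibs`,
#'   training seed and fold sizes.
#' @export
cross_validate <- function(cohort, hp = hyperparams(), loss_name = "nmtlr_rank",
                           k = 5L, repeats = 10L, n_time_bins = 4L, seed = 1L,
                           eval_points = 100L, auxiliaries = list()) {
  folds <- stratified_kfold(cohort, k, n_time_bins, seed)
  for (f in seq_along(folds)) {
    if (sum(cohort$event[folds[[f]]$test_idx]) == 0L ||
        sum(cohort$event[folds[[f]]$train_idx]) == 0L)
      stopf("fold %d has zero events; use fewer folds or coarser bins", f)
  }
  rows <- list()
  for (f in seq_along(folds)) {
    tr <- cohort[folds[[f]]$train_idx]
    te <- cohort[folds[[f]]$test_idx]
    for (r in seq_len(repeats)) {
      hp_r <- hp
      hp_r$seed <- as.integer(child_seed(seed, f * 1000L + r))
      fit <- combined_train(tr, auxiliaries, hp_r, loss_name)
      met <- evaluate_fit(fit, te, eval_points = eval_points)
      rows[[length(rows) + 1L]] <- data.frame(
        fold = f, rep = r, seed = hp_r$seed,
        c_index = met$c_index_td, ibs = met$ibs,
        n_train = length(folds[[f]]$train_idx),
        n_test = length(folds[[f]]$test_idx))
    }
  }
  do.call(rbind, rows)
}

#' Evaluate a fitted network on a test cohort
#'
#' Computes the time-dependent C-index and IPCW (Integrated) Brier Score
#' from interpolated survival curves on an equispaced evaluation grid over
#' the test follow-up.
#'
#' @param fit a [train_survnet] / [combined_train] result.
#' @param test a [survival_cohort].
#' @param eval_points grid resolution.
#' @return a `metric_report` list: `c_index_td`, `ibs`, `bs_curve`,
#'   `eval_grid`.
#' @export
evaluate_fit <- function(fit, test, eval_points = 100L) {
  grid_times <- seq(0, max(test$time), length.out = eval_points)
  S <- suppressWarnings(
    predict(fit, test, type = "survival", times = grid_times))
  metric_report(S, grid_times, test$time, test$event)
}

#' Random search over the hyperparameter box
#'
#' Seeded random search over the printed search space (widths and learning
#' rates sampled log-uniformly), training each trial on `train_sub` and
#' scoring it on `val_sub` by time-dependent C-index (or IBS). Every trial
#' is logged; the best trial's configuration is returned.
#'
#' @param train_sub training [survival_cohort].
#' @param val_sub validation [survival_cohort].
#' @param budget number of trials (>= 1).
#' @param seed search seed; identical seeds give identical trial sequences.
#' @param loss_name loss to optimize.
#' @param objective `"c_index"` (maximized) or `"ibs"` (minimized).
#' @param overrides named list of hyperparameters to pin instead of sampling
#'   (e.g. `list(epochs = 100, width = 32)`).
#' @return list with `best_hp`, `best_score` and the `trials` log.
#' @export
tune_survnet <- function(train_sub, val_sub, budget, seed = 1L,
                         loss_name = "nmtlr_rank",
                         objective = c("c_index", "ibs"),
                         overrides = list()) {
  objective <- match.arg(objective)
  if (budget < 1L) stopf("budget must be >= 1")
  samples <- with_seed(seed, lapply(seq_len(budget), function(i) {
    hp <- list(
      n_layers = sample(1:8, 1L),
      width = as.integer(round(exp(runif(1, log(8), log(2048))))),
      learning_rate = exp(runif(1, log(1e-5), log(0.1))),
      weight_decay = runif(1, 0, 0.9),
      dropout = runif(1, 0, 0.6),
      activation = sample(c("relu", "selu", "tanh", "sigmoid"), 1L),
      discretization = sample(c("km_quantiles", "equidistant"), 1L),
      interpolation = sample(c("CDI", "CHI"), 1L),
      alpha = runif(1, 0, 1),
      beta = exp(runif(1, log(0.1), log(100))),
      seed = as.integer(child_seed(seed, i)))
    hp[names(overrides)] <- overrides
    hp
  }))
  trials <- list()
  best <- NULL
  for (i in seq_len(budget)) {
    hp <- do.call(hyperparams, samples[[i]])
    res <- tryCatch({
      fit <- train_survnet(train_sub, hp, loss_name)
      met <- evaluate_fit(fit, val_sub)
      list(c_index = met$c_index_td, ibs = met$ibs, error = NA_character_)
    }, error = function(e) list(c_index = NA_real_, ibs = NA_real_,
                                error = conditionMessage(e)))
    score <- if (objective == "c_index") res$c_index else -res$ibs
    trials[[i]] <- data.frame(
      trial = i, c_index = res$c_index, ibs = res$ibs,
      n_layers = hp$n_layers, width = hp$width,
      learning_rate = hp$learning_rate, weight_decay = hp$weight_decay,
      dropout = hp$dropout, activation = hp$activation,
      discretization = hp$discretization, interpolation = hp$interpolation,
      alpha = hp$alpha, beta = hp$beta, seed = hp$seed, error = res$error)
    if (!is.na(score) && (is.null(best) || score > best$score))
      best <- list(score = score, hp = hp, trial = i)
  }
  log <- do.call(rbind, trials)
  if (is.null(best)) {
    print(log)
    stopf("all %d tuning trials failed", budget)
  }
  list(best_hp = best$hp,
       best_score = if (objective == "c_index") best$score else -best$score,
       trials = log)
}

#' Save a fitted network as a model artifact directory
#'
#' Writes the weights (`weights.rds`) plus a JSON sidecar (`model.json`)
#' carrying the hyperparameters, time-grid cuts, gene list and
#' standardization statistics, so the grid and statistics always travel
#' with the weights.
#'
#' @param fit a `survnet_fit`.
#' @param dir output directory (created if needed).
#' @export
save_survnet <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(fit$net$layers, file.path(dir, "weights.rds"))
  sidecar <- list(
    hyperparams = unclass(fit$hp), loss_name = fit$loss_name,
    grid = list(cuts = fit$grid$cuts, scheme = fit$grid$scheme, m = fit$grid$m),
    genes = fit$genes, center = as.list(fit$center), scale = as.list(fit$scale),
    cumsum_head = fit$net$cumsum_head, sizes = fit$net$sizes,
    cohort_label = fit$cohort_label)
  jsonlite::write_json(sidecar, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a model artifact directory written by [save_survnet]
#' @param dir artifact directory.
#' @export
load_survnet <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  layers <- readRDS(file.path(dir, "weights.rds"))
  hp <- do.call(hyperparams, side$hyperparams[names(side$hyperparams) != ""])
  net <- structure(list(layers = layers, activation = hp$activation,
                        sizes = side$sizes, cumsum_head = side$cumsum_head,
                        out_width = side$sizes[length(side$sizes)]),
                   class = "survnet")
  structure(list(net = net, hp = hp, loss_name = side$loss_name,
                 grid = structure(list(cuts = side$grid$cuts,
                                       scheme = side$grid$scheme,
                                       m = side$grid$m), class = "time_grid"),
                 center = unlist(side$center), scale = unlist(side$scale),
                 genes = side$genes, trace = numeric(0),
                 cohort_label = side$cohort_label),
            class = "survnet_fit")
}
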