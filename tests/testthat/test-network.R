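test_that("architecture matches the fully-connected contract", {
  hp <- hyperparams(n_layers = 1, width = 1131, m = 10)
  net <- build_network(p = 100, hp)
  # trunk + linear head; the cumulative-sum head adds no parameters
  expect_equal(nmtlrank:::n_params(net),
               100 * 1131 + 1131 + 1131 * 10 + 10)
  expect_true(net$cumsum_head)
  expect_error(hyperparams(activation = "swish"), "activation")
  expect_error(hyperparams(width = 4000), "width")
})

test_that("forward pass is deterministic without dropout", {
  hp <- hyperparams(width = 8, m = 3, seed = 4)
  net <- build_network(5, hp)
  X <- matrix(rnorm(20 * 5), 20, 5)
  f1 <- nmtlrank:::forward_pass(net, X)$psi
  f2 <- nmtlrank:::forward_pass(net, X)$psi
  expect_identical(f1, f2)
})

test_that("training reduces the loss and is seed-reproducible", {
  co <- tiny_cohort(60, 12, seed = 8)
  hp <- hyperparams(width = 16, epochs = 200, m = 5, seed = 2)
  fit <- train_survnet(co, hp, "nmtlr_rank")
  expect_lt(tail(fit$trace, 1), fit$trace[1])
  fit2 <- train_survnet(co, hp, "nmtlr_rank")
  expect_identical(fit$trace, fit2$trace)
  expect_identical(fit$net$layers, fit2$net$layers)
  # every loss family optimizes on the same smoke fixture
  for (ln in c("nmtlr", "deephit", "pmf", "cox")) {
    f <- train_survnet(co, hyperparams(width = 8, epochs = 80, m = 4, seed = 1),
                       ln)
    expect_lt(tail(f$trace, 1), f$trace[1])
  }
})

test_that("alpha = 1 training trajectory equals pure N-MTLR exactly", {
  co <- tiny_cohort(50, 8, seed = 12)
  hp <- hyperparams(width = 8, epochs = 60, m = 4, alpha = 1, seed = 3)
  fit_a <- train_survnet(co, hp, "nmtlr_rank")
  fit_b <- train_survnet(co, hp, "nmtlr")
  expect_identical(fit_a$trace, fit_b$trace)
  expect_identical(fit_a$net$layers, fit_b$net$layers)
})

test_that("combined training with no auxiliaries is plain training", {
  co <- tiny_cohort(40, 6, seed = 5)
  hp <- hyperparams(width = 8, epochs = 30, m = 3, seed = 9)
  expect_identical(train_survnet(co, hp)$net$layers,
                   combined_train(co, list(), hp)$net$layers)
})

test_that("combined training uses the gene intersection", {
  co1 <- tiny_cohort(30, 8, seed = 1)
  co2 <- tiny_cohort(25, 8, seed = 2)
  colnames(co2$X) <- co2$genes <- c(co1$genes[1:4], paste0("OTHER", 1:4))
  hp <- hyperparams(width = 8, epochs = 20, m = 3, seed = 1)
  fit <- suppressMessages(combined_train(co1, list(co2), hp))
  expect_equal(fit$net$sizes[1], 4L)  # input width = intersection size
  expect_equal(fit$genes, co1$genes[1:4])
  co3 <- co2
  colnames(co3$X) <- co3$genes <- paste0("NONE", 1:8)
  expect_error(combined_train(co1, list(co3), hp), "intersection")
})

test_that("cross-validation emits one row per fold x repeat on test data only", {
  co <- tiny_cohort(80, 10, seed = 21, cens = 0.25)
  hp <- hyperparams(width = 8, epochs = 40, m = 4)
  cv <- suppressWarnings(cross_validate(co, hp, "nmtlr_rank", k = 2,
                                        repeats = 2, seed = 7))
  expect_equal(nrow(cv), 4L)
  expect_true(all(is.finite(cv$c_index)) && all(is.finite(cv$ibs)))
  expect_true(all(cv$n_train + cv$n_test == 80))
  # wiring check: a fold row is reproduced by training on the train slice only
  folds <- stratified_kfold(co, 2, seed = 7)
  hp_r <- hp; hp_r$seed <- as.integer(nmtlrank:::child_seed(7, 1001))
  fit <- train_survnet(co[folds[[1]]$train_idx], hp_r, "nmtlr_rank")
  met <- evaluate_fit(fit, co[folds[[1]]$test_idx])
  expect_equal(cv$c_index[1], met$c_index_td, tolerance = 1e-12)
  expect_equal(cv$ibs[1], met$ibs, tolerance = 1e-12)
  # training statistics come from the train slice, not the full cohort
  expect_equal(fit$center, colMeans(co$X[folds[[1]]$train_idx, ]))
})

test_that("repeats = 10 on 5 folds would give the 50-model protocol", {
  # checked structurally on a reduced grid to keep the suite fast
  co <- tiny_cohort(60, 6, seed = 3, cens = 0.2)
  hp <- hyperparams(width = 8, epochs = 10, m = 3)
  cv <- suppressWarnings(cross_validate(co, hp, "nmtlr", k = 3, repeats = 2,
                                        seed = 1))
  expect_equal(nrow(cv), 3 * 2)
  expect_equal(unique(table(cv$fold)), 2L)
})

test_that("random search logs every trial and returns the best", {
  co <- tiny_cohort(70, 8, seed = 31, cens = 0.25)
  folds <- stratified_kfold(co, 3, seed = 1)
  tr <- co[folds[[1]]$train_idx]; va <- co[folds[[1]]$test_idx]
  ov <- list(epochs = 15L, n_layers = 1L, width = 8L, m = 4L)
  tu <- suppressWarnings(tune_survnet(tr, va, budget = 3, seed = 5,
                                      overrides = ov))
  expect_equal(nrow(tu$trials), 3L)
  expect_true(all(tu$trials$width == 8L))
  expect_gte(tu$best_score, max(tu$trials$c_index, na.rm = TRUE) - 1e-12)
  # identical seed -> identical sampled configurations
  tu2 <- suppressWarnings(tune_survnet(tr, va, budget = 3, seed = 5,
                                       overrides = ov))
  expect_equal(tu$trials$learning_rate, tu2$trials$learning_rate)
  expect_equal(tu$trials$alpha, tu2$trials$alpha)
  # budget = 1 returns the single sampled configuration
  tu1 <- suppressWarnings(tune_survnet(tr, va, budget = 1, seed = 2,
                                       overrides = ov))
  expect_equal(tu1$best_hp$learning_rate, tu1$trials$learning_rate[1])
})

test_that("model artifacts round-trip through save/load", {
  co <- tiny_cohort(40, 6, seed = 77)
  fit <- train_survnet(co, hyperparams(width = 8, epochs = 25, m = 3, seed = 1))
  d <- withr::local_tempdir()
  save_survnet(fit, file.path(d, "model"))
  back <- load_survnet(file.path(d, "model"))
  expect_equal(predict(back, co), predict(fit, co), tolerance = 1e-12)
  expect_equal(back$grid$cuts, fit$grid$cuts)
  expect_equal(back$center, fit$center)
})

test_that("auxiliary cohorts sharing the risk module do not hurt held-out accuracy", {
  # paired comparison over 10 seeds at a small target cohort
  deltas <- vapply(1:10, function(s) {
    suite <- make_benchmark_suite(seed = s)
    tgt <- suite$transfer_target
    aux <- suite$transfer_auxiliary
    folds <- stratified_kfold(tgt, k = 2, seed = s)
    tr <- tgt[folds[[1]]$train_idx]; te <- tgt[folds[[1]]$test_idx]
    hp <- hyperparams(width = 16, epochs = 120, m = 5, seed = s)
    alone <- evaluate_fit(train_survnet(tr, hp), te)$c_index_td
    with_aux <- evaluate_fit(
      suppressMessages(combined_train(tr, list(aux), hp)), te)$c_index_td
    with_aux - alone
  }, 0)
  expect_gte(mean(deltas), -0.02)
})
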