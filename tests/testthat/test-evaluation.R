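test_that("product-limit estimator matches hand computation and survfit", {
  km <- km_estimator(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km_surv(km, c(1, 2, 2.5, 3)), c(2/3, 2/3, 2/3, 0))
  # no events -> S identically 1
  km0 <- km_estimator(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km_surv(km0, c(0.5, 10)), c(1, 1))
  # all events at distinct times -> 1 - ECDF
  tt <- c(2, 5, 9, 11)
  km1 <- km_estimator(tt, rep(1, 4))
  expect_equal(km_surv(km1, tt), 1 - (1:4) / 4)
  # independent cross-check against survival::survfit on censored data
  withr::with_seed(2, {
    tm <- rexp(60, 1 / 10); ev <- rbinom(60, 1, 0.6)
    km2 <- km_estimator(tm, ev)
    sf <- survival::survfit(survival::Surv(tm, ev) ~ 1)
    expect_equal(km_surv(km2, sf$time), sf$surv, tolerance = 1e-12)
  })
})

test_that("left limits give G(t-) for IPCW weights", {
  km <- km_estimator(c(1, 2, 3), c(0, 0, 0), censoring = TRUE)
  expect_lt(km_surv(km, 1), 1)          # right-continuous at the jump
  expect_equal(km_surv(km, 1, left = TRUE), 1)  # left limit before the jump
})

test_that("perfectly ordered predictions give concordance 1", {
  withr::with_seed(9, {
    n <- 30
    tm <- sort(sample(1:500, n))
    ev <- rep(1L, n)
    et <- c(0, sort(tm))  # grid covers the observed event times
    lam <- sort(runif(n, 0.001, 0.1), decreasing = TRUE)  # early event, low S
    S <- exp(-outer(lam, et))
    expect_equal(c_index_td(S, et, tm, ev), 1)
  })
})

test_that("concordance matches exhaustive pair enumeration with ties and censoring", {
  withr::with_seed(13, {
    for (rep in 1:5) {
      n <- 25
      tm <- sample(1:15, n, replace = TRUE)     # forces time ties
      ev <- rbinom(n, 1, 0.6); ev[1] <- 1L
      et <- seq(0, 20, length.out = 12)
      S <- t(apply(matrix(runif(n * 12), n), 1, function(r)
        sort(r, decreasing = TRUE)))
      expect_equal(c_index_td(S, et, tm, ev), c_index_brute(S, et, tm, ev),
                   tolerance = 1e-12)
    }
  })
  expect_error(c_index_td(matrix(0.5, 2, 2), c(1, 2), c(5, 5), c(0, 0)),
               "comparable")
})

test_that("concordance is invariant to monotone transforms and subject order", {
  withr::with_seed(19, {
    n <- 40
    tm <- runif(n, 1, 100); ev <- rbinom(n, 1, 0.7); ev[1] <- 1L
    et <- seq(0, 110, length.out = 25)
    S <- t(apply(matrix(runif(n * 25), n), 1, sort, decreasing = TRUE))
    base <- c_index_td(S, et, tm, ev)
    expect_equal(c_index_td(S^3, et, tm, ev), base)          # monotone transform
    expect_equal(c_index_td(plogis(5 * S), et, tm, ev), base)
    perm <- sample(n)
    expect_equal(c_index_td(S[perm, ], et, tm[perm], ev[perm]), base)
  })
})

test_that("Brier score matches oracle, constant and hand-IPCW cases", {
  # oracle predictions, no censoring -> 0 at every time between events
  tm <- c(10, 20, 30); ev <- c(1, 1, 1)
  et <- seq(0, 35, length.out = 200)
  S_or <- t(vapply(tm, function(ti) as.numeric(et < ti), numeric(200)))
  for (t_eval in c(5, 15, 25, 32))
    expect_lt(brier_score(S_or, et, tm, ev, t_eval), 1e-3)
  # constant S = 0.5, no censoring -> 0.25 everywhere
  S_c <- matrix(0.5, 3, 200)
  for (t_eval in c(5, 15, 25))
    expect_equal(brier_score(S_c, et, tm, ev, t_eval), 0.25)
  # hand-computed IPCW sum on a censored 5-subject toy
  tm5 <- c(2, 4, 6, 8, 10); ev5 <- c(1, 0, 1, 0, 1)
  et5 <- seq(0, 10, length.out = 101)
  S5 <- matrix(rep(c(0.9, 0.8, 0.6, 0.4, 0.2), 101), 5, 101)
  t_eval <- 7
  # censoring KM (deaths leave the risk set first): jumps at 4 (risk 4) and
  # 8 (risk 2) -> G = 3/4 on [4, 8), 3/8 after
  G7 <- 3/4
  Gm <- function(t) if (t <= 4) 1 else if (t <= 8) 3/4 else 3/8  # G(t-)
  hand <- ( (0 - 0.9)^2 / Gm(2)       # died at 2 <= 7
          + (0 - 0.6)^2 / Gm(6)       # died at 6 <= 7
          + 0                          # censored at 4 < 7: weight 0
          + (1 - 0.4)^2 / G7          # alive at 8 > 7
          + (1 - 0.2)^2 / G7 ) / 5    # alive at 10 > 7
  expect_equal(brier_score(S5, et5, tm5, ev5, t_eval), hand, tolerance = 1e-12)
})

test_that("without censoring the Brier score is the plain mean squared error", {
  withr::with_seed(29, {
    n <- 50
    tm <- runif(n, 1, 100); ev <- rep(1L, n)
    et <- seq(0, 110, length.out = 60)
    S <- t(apply(matrix(runif(n * 60), n), 1, sort, decreasing = TRUE))
    for (t_eval in c(20, 50, 80)) {
      St <- vapply(1:n, function(i) approx(et, S[i, ], t_eval)$y, 0)
      mse <- mean(ifelse(tm > t_eval, (1 - St)^2, St^2))
      expect_equal(brier_score(S, et, tm, ev, t_eval), mse, tolerance = 1e-12)
    }
  })
})

test_that("integrated Brier score behaves as a normalized quadrature", {
  # constant BS(t) = c integrates to c
  tm <- c(10, 20, 30); ev <- rep(1L, 3)
  et <- seq(0, 35, length.out = 50)
  expect_equal(integrated_brier_score(matrix(0.5, 3, 50), et, tm, ev,
                                      grid = seq(1, 9, length.out = 20)),
               0.25, tolerance = 1e-12)
  # KM marginal predictor: default 100-point grid vs 10^4-point refinement
  withr::with_seed(37, {
    n <- 300
    T_ev <- rexp(n, 1 / 50); C <- runif(n, 0, 150)
    tm2 <- pmin(T_ev, C); ev2 <- as.integer(T_ev <= C)
    et2 <- seq(0, max(tm2), length.out = 200)
    S <- km_marginal_predictor(tm2, ev2, et2, n)
    coarse <- integrated_brier_score(S, et2, tm2, ev2)
    fine <- integrated_brier_score(S, et2, tm2, ev2,
                                   grid = seq(0, max(tm2), length.out = 1e4))
    expect_lt(abs(coarse - fine), 1e-3)
  })
})

test_that("metric report bundles consistent quantities", {
  withr::with_seed(43, {
    n <- 40
    tm <- runif(n, 1, 100); ev <- rbinom(n, 1, 0.7); ev[1] <- 1L
    et <- seq(0, 110, length.out = 30)
    S <- t(apply(matrix(runif(n * 30), n), 1, sort, decreasing = TRUE))
    mr <- metric_report(S, et, tm, ev)
    expect_equal(mr$c_index_td, c_index_td(S, et, tm, ev))
    # ibs is the trapezoidal integral of its own curve divided by the span
    bs <- mr$bs_curve
    expect_equal(mr$ibs,
                 sum(diff(bs$t) * (head(bs$bs, -1) + tail(bs$bs, -1)) / 2) /
                   diff(range(bs$t)), tolerance = 1e-12)
  })
})
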