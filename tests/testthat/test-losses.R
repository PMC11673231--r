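test_that("reverse cumulative sum matches its definition", {
  expect_equal(drop(reverse_cumsum(matrix(c(1, 2, 3), 1))), c(6, 5, 3))
  expect_equal(reverse_cumsum(matrix(0, 2, 4)), matrix(0, 2, 4))
  expect_equal(reverse_cumsum(matrix(5, 1, 1)), matrix(5, 1, 1))  # m = 1 identity
})

test_that("softmax pmf covers the residual category and saturates correctly", {
  p0 <- pmf_from_phi(matrix(0, 1, 3))
  expect_equal(drop(p0$pmf), rep(0.25, 4))
  expect_equal(drop(p0$S_at_cuts), c(0.75, 0.5, 0.25))
  psat <- pmf_from_phi(matrix(c(50, 0, 0), 1))
  expect_gt(psat$pmf[1, 1], 0.999)
  expect_lt(psat$S_at_cuts[1, 1], 1e-3)
  # direct unstabilized evaluation oracle at phi = (1, -1)
  e <- exp(c(1, -1)); denom <- 1 + sum(e)
  p <- pmf_from_phi(matrix(c(1, -1), 1))
  expect_equal(drop(p$pmf)[1:2], e / denom, tolerance = 1e-12)
  expect_equal(p$pmf[1, 1], 0.6652, tolerance = 1e-4)
  expect_equal(p$pmf[1, 2], 0.0900, tolerance = 1e-3)
})

test_that("pmf rows sum to one and survival is monotone for arbitrary logits", {
  withr::with_seed(3, {
    for (rep in 1:25) {
      phi <- matrix(rnorm(8 * 5, sd = sample(c(1, 10, 40), 1)), 8, 5)
      pr <- pmf_from_phi(phi)
      expect_lt(max(abs(rowSums(pr$pmf) - 1)), 1e-6)
      expect_true(all(pr$pmf >= 0))
      expect_true(all(apply(pr$S_at_cuts, 1, function(s) all(diff(s) <= 1e-12))))
      expect_true(all(pr$S_at_cuts >= 0 & pr$S_at_cuts <= 1))
    }
  })
})

test_that("likelihood loss matches hand-computed toy values", {
  p0 <- pmf_from_phi(matrix(0, 1, 2))   # uniform over 3 categories
  expect_equal(loss_pmf(p0, 1, 1), -log(1 / 3), tolerance = 1e-6)
  expect_equal(loss_pmf(p0, 1, 0), -log(2 / 3), tolerance = 1e-6)
  p1 <- pmf_from_phi(matrix(c(1, -1), 1))
  expect_equal(loss_pmf(p1, 2, 1), 2.408, tolerance = 1e-3)
})

test_that("N-MTLR loss is definitionally the PMF loss on cumulated outputs", {
  withr::with_seed(17, {
    for (rep in 1:100) {
      n <- sample(2:20, 1); m <- sample(2:6, 1)
      psi <- matrix(rnorm(n * m, sd = 3), n, m)
      k <- sample(1:m, n, replace = TRUE)
      d <- rbinom(n, 1, 0.5)
      expect_equal(loss_nmtlr(psi, k, d),
                   loss_pmf(pmf_from_phi(reverse_cumsum(psi)), k, d),
                   tolerance = 1e-12)
    }
  })
})

test_that("ranking loss matches pairwise brute force and its toy values", {
  # identical survival curves, one comparable pair -> exp(0) = 1
  pred <- list(S_at_cuts = matrix(0.5, 2, 2))
  expect_equal(loss_rank(pred, c(1, 1), c(1, 0), c(10, 20), beta = 1), 1)
  # S_i(k) = 0.2, S_j(k) = 0.9, beta = 0.48
  pred2 <- list(S_at_cuts = matrix(c(0.2, 0.9), 2, 1))
  expect_equal(loss_rank(pred2, c(1, 1), c(1, 0), c(5, 9), beta = 0.48),
               exp(-0.7 / 0.48), tolerance = 1e-6)
  expect_equal(exp(-0.7 / 0.48), 0.2326, tolerance = 1e-3)
  # all censored -> empty pair set
  expect_equal(loss_rank(pred2, c(1, 1), c(0, 0), c(5, 9), beta = 1), 0)
  expect_error(loss_rank(pred2, c(1, 1), c(1, 0), c(5, 9), beta = 0), "beta")
  # brute-force pair oracle on a random fixture
  withr::with_seed(23, {
    n <- 12; m <- 4
    pr <- pmf_from_phi(matrix(rnorm(n * m), n, m))
    k <- sample(1:m, n, replace = TRUE)
    d <- rbinom(n, 1, 0.6)
    tm <- sample(1:50, n)
    beta <- 0.7
    acc <- 0; np <- 0
    for (i in 1:n) for (j in 1:n) {
      if (i != j && d[i] == 1 && tm[i] < tm[j]) {
        acc <- acc + exp((pr$S_at_cuts[i, k[i]] - pr$S_at_cuts[j, k[i]]) / beta)
        np <- np + 1
      }
    }
    expect_equal(loss_rank(pr, k, d, tm, beta), acc / np, tolerance = 1e-12)
    expect_equal(loss_rank(pr, k, d, tm, beta, reduction = "sum"), acc,
                 tolerance = 1e-12)
  })
})

test_that("the pairwise ranking term is translation invariant", {
  pred <- list(S_at_cuts = matrix(c(0.3, 0.8), 2, 1))
  shifted <- list(S_at_cuts = pred$S_at_cuts + 0.1)
  args <- list(k_idx = c(1, 1), event = c(1, 0), time = c(1, 2), beta = 0.5)
  expect_equal(do.call(loss_rank, c(list(pred), args)),
               do.call(loss_rank, c(list(shifted), args)))
})

test_that("composite losses reduce to their components", {
  withr::with_seed(31, {
    n <- 10; m <- 4
    psi <- matrix(rnorm(n * m), n, m)
    k <- sample(1:m, n, replace = TRUE)
    d <- rbinom(n, 1, 0.6); d[1] <- 1L
    tm <- runif(n, 1, 100)
    pred <- pmf_from_phi(psi)
    expect_identical(loss_deephit(pred, k, d, tm, alpha = 1, beta = 2),
                     loss_pmf(pred, k, d))
    expect_identical(loss_deephit(pred, k, d, tm, alpha = 0, beta = 2),
                     loss_rank(pred, k, d, tm, 2))
    expect_equal(loss_deephit(pred, k, d, tm, 0.25, 2),
                 0.25 * loss_pmf(pred, k, d) +
                   0.75 * loss_rank(pred, k, d, tm, 2), tolerance = 1e-12)
    expect_identical(loss_nmtlr_rank(psi, k, d, tm, alpha = 1, beta = 0.48),
                     loss_nmtlr(psi, k, d))
    pred_c <- pmf_from_phi(reverse_cumsum(psi))
    expect_identical(loss_nmtlr_rank(psi, k, d, tm, alpha = 0, beta = 0.48),
                     loss_rank(pred_c, k, d, tm, 0.48))
    expect_equal(loss_nmtlr_rank(psi, k, d, tm, 0.25, 0.48),
                 0.25 * loss_nmtlr(psi, k, d) +
                   0.75 * loss_rank(pred_c, k, d, tm, 0.48), tolerance = 1e-12)
    expect_error(loss_deephit(pred, k, d, tm, alpha = 1.2, beta = 1), "alpha")
  })
})

test_that("Cox partial likelihood matches hand-evaluated values", {
  expect_equal(loss_cox(c(0, 0), c(1, 2), c(1, 1)), (log(2) + log(1)) / 2)
  expect_equal(loss_cox(5, 3, 1), 0)  # singleton risk set
  expect_equal(loss_cox(c(1, 0), c(1, 2), c(1, 1)),
               mean(c(-1 + log(exp(1) + 1), 0)), tolerance = 1e-12)
  expect_equal(loss_cox(c(1, 0), c(1, 2), c(1, 1)), 0.1566, tolerance = 1e-3)
  expect_error(loss_cox(c(1, 0), c(1, 2), c(0, 0)), "event")
  # brute-force risk-set oracle with ties (Breslow)
  withr::with_seed(41, {
    n <- 15
    th <- rnorm(n)
    tm <- sample(1:6, n, replace = TRUE)
    d <- rbinom(n, 1, 0.7); d[1] <- 1L
    terms <- vapply(which(d == 1), function(j)
      th[j] - log(sum(exp(th[tm >= tm[j]]))), 0)
    expect_equal(loss_cox(th, tm, d), -mean(terms), tolerance = 1e-12)
  })
})

test_that("all losses are invariant to subject permutation", {
  withr::with_seed(53, {
    n <- 14; m <- 5
    psi <- matrix(rnorm(n * m), n, m)
    k <- sample(1:m, n, replace = TRUE)
    d <- rbinom(n, 1, 0.6); d[2] <- 1L
    tm <- runif(n, 1, 50)
    perm <- sample(n)
    pred <- pmf_from_phi(psi)
    pred_p <- pmf_from_phi(psi[perm, ])
    expect_equal(loss_pmf(pred, k, d), loss_pmf(pred_p, k[perm], d[perm]))
    expect_equal(loss_rank(pred, k, d, tm, 1),
                 loss_rank(pred_p, k[perm], d[perm], tm[perm], 1),
                 tolerance = 1e-12)
    expect_equal(loss_nmtlr_rank(psi, k, d, tm, 0.25, 0.48),
                 loss_nmtlr_rank(psi[perm, ], k[perm], d[perm], tm[perm],
                                 0.25, 0.48), tolerance = 1e-12)
    expect_equal(loss_cox(rnorm(n) -> th, tm, d),
                 loss_cox(th[perm], tm[perm], d[perm]), tolerance = 1e-12)
  })
})

test_that("analytic gradients agree with finite differences", {
  withr::with_seed(61, {
    n <- 8; m <- 3
    psi <- matrix(rnorm(n * m), n, m)
    k <- sample(1:m, n, replace = TRUE)
    d <- rbinom(n, 1, 0.6); d[1] <- 1L
    tm <- runif(n, 1, 20)
    h <- 1e-6
    for (cfg in list(list(a = 1, ch = TRUE), list(a = 0, ch = TRUE),
                     list(a = 0.25, ch = TRUE), list(a = 0.5, ch = FALSE))) {
      g <- nmtlrank:::discrete_loss_grad(psi, k, d, tm, cfg$a, 0.48, cfg$ch)
      num <- matrix(0, n, m)
      for (i in 1:n) for (j in 1:m) {
        up <- psi; up[i, j] <- up[i, j] + h
        dn <- psi; dn[i, j] <- dn[i, j] - h
        num[i, j] <- (nmtlrank:::discrete_loss_grad(up, k, d, tm, cfg$a, 0.48,
                                                    cfg$ch)$loss -
                      nmtlrank:::discrete_loss_grad(dn, k, d, tm, cfg$a, 0.48,
                                                    cfg$ch)$loss) / (2 * h)
      }
      expect_lt(max(abs(g$grad - num)), 1e-6)
    }
    th <- rnorm(n)
    tm2 <- sample(1:4, n, replace = TRUE)  # forces ties
    cg <- nmtlrank:::cox_loss_grad(th, tm2, d)
    num <- vapply(1:n, function(i) {
      up <- th; up[i] <- up[i] + h; dn <- th; dn[i] <- dn[i] - h
      (nmtlrank:::cox_loss_grad(up, tm2, d)$loss -
         nmtlrank:::cox_loss_grad(dn, tm2, d)$loss) / (2 * h)
    }, 0)
    expect_lt(max(abs(drop(cg$grad) - num)), 1e-6)
  })
})
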