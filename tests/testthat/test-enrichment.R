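test_that("enrichment score is extreme for sets at the list ends", {
  scores <- setNames(seq(10, 1), paste0("G", 1:10))
  top <- gsea_preranked(scores, c("G1", "G2"), n_perm = 100, seed = 1)
  expect_gt(top$ES, 0.8)
  bottom <- gsea_preranked(scores, c("G9", "G10"), n_perm = 100, seed = 1)
  expect_lt(bottom$ES, 0)
  # on a symmetric score vector the mirror set has the negated ES
  sym <- setNames(c(5, 4, 3, 2, 1, -1, -2, -3, -4, -5), paste0("G", 1:10))
  es_hi <- gsea_preranked(sym, c("G1", "G2"), n_perm = 10, seed = 1)$ES
  es_lo <- gsea_preranked(sym, c("G9", "G10"), n_perm = 10, seed = 1)$ES
  expect_equal(es_hi, -es_lo, tolerance = 1e-12)
})

test_that("enrichment score equals the literal running-sum walk", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      scores <- setNames(rnorm(12), paste0("G", 1:12))
      set <- sample(names(scores), 3)
      got <- gsea_preranked(scores, set, n_perm = 50, seed = rep)$ES
      expect_equal(got, unname(es_running_sum_oracle(scores, set)),
                   tolerance = 1e-12)
    }
  })
})

test_that("enrichment score agrees with the fgsea statistic", {
  withr::with_seed(11, {
    scores <- setNames(sort(rnorm(40), decreasing = TRUE), paste0("G", 1:40))
    set <- sample(names(scores), 6)
    ours <- gsea_preranked(scores, set, n_perm = 10, seed = 1)$ES
    ref <- fgsea::calcGseaStat(scores, selectedStats = which(names(scores) %in% set),
                               gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-10)
  })
})

test_that("permutation p-values are floored and sets must be strict subsets", {
  scores <- setNames(seq(20, 1), paste0("G", 1:20))
  res <- gsea_preranked(scores, paste0("G", 1:3), n_perm = 99, seed = 2)
  expect_gte(res$p_value, 1 / 100)
  expect_error(gsea_preranked(scores, paste0("G", 1:20)), "covers all")
  expect_error(gsea_preranked(scores, c("ZZZ")), "overlap")
})

test_that("cohort enrichment finds a universally top-ranked set in all patients", {
  withr::with_seed(13, {
    n <- 15; p <- 60
    A <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("P%02d", 1:n), sprintf("G%03d", 1:p)))
    A[, 1:8] <- A[, 1:8] + 20   # set A genes on top for every patient
    sets <- gene_set_collection(list(TOPSET = sprintf("G%03d", 1:8),
                                     DECOY1 = sprintf("G%03d", 21:28),
                                     DECOY2 = sprintf("G%03d", 31:38)))
    en <- enrich_cohort(A, sets, n_perm = 200, seed = 3)
    freq <- setNames(en$frequency$pct_patients, en$frequency$set)
    expect_equal(unname(freq["TOPSET"]), 100)
    expect_true(all(freq[c("DECOY1", "DECOY2")] < freq["TOPSET"]))
    # BH monotonicity within patient
    one <- en$results[en$results$patient == "P01", ]
    expect_true(all(one$p_adjusted >= one$p_value))
    expect_false(is.unsorted(one$p_adjusted[order(one$p_value)]))
  })
})

test_that("pure-noise attributions yield near-zero enrichment frequency", {
  freqs <- vapply(1:2, function(s) {
    withr::with_seed(1000 + s, {
      n <- 10; p <- 80
      A <- matrix(rnorm(n * p), n, p,
                  dimnames = list(NULL, sprintf("G%03d", 1:p)))
      sets <- gene_set_collection(setNames(
        lapply(1:10, function(i) sprintf("G%03d", sample(p, 8))),
        sprintf("SET%02d", 1:10)))
      en <- enrich_cohort(A, sets, n_perm = 100, seed = s)
      mean(en$results$p_adjusted < 0.05)
    })
  }, 0)
  expect_lt(mean(freqs), 0.02)
})

test_that("set combination honors names, unions and frequency thresholds", {
  sets <- gene_set_collection(list(S1 = paste0("A", 1:10),
                                   S2 = paste0("B", 1:10),
                                   S3 = c("A1", "B1", "C1")))
  c12 <- suppressMessages(combine_sets(sets, names = c("S1", "S2")))
  expect_length(c12, 20)
  c13 <- suppressMessages(combine_sets(sets, names = c("S1", "S3")))
  expect_length(c13, 12)  # union with overlap deduplicated
  ft <- data.frame(set = c("S1", "S2", "S3"),
                   pct_patients = c(26, 4, 21))
  sel <- suppressMessages(combine_sets(sets, min_frequency = 0.05,
                                       freq_table = ft))
  expect_equal(sort(attr(sel, "sets")), c("S1", "S3"))
  expect_error(suppressMessages(
    combine_sets(sets, min_frequency = 0.5, freq_table = ft)), "empty")
})

test_that("activity scores respond to coordinated set shifts and respect ranks", {
  withr::with_seed(17, {
    n <- 12; p <- 50
    X <- matrix(rnorm(n * p, 5, 2), n, p,
                dimnames = list(sprintf("S%02d", 1:n), sprintf("G%03d", 1:p)))
    set <- sprintf("G%03d", 1:10)
    # identical samples score identically
    X[2, ] <- X[1, ]
    sc <- gsva_score(X, set)
    expect_equal(unname(sc[1]), unname(sc[2]))
    # shifting all set genes up in one sample strictly raises its score
    X3 <- X
    X3[3, set] <- X3[3, set] + 2
    expect_gt(gsva_score(X3, set)[3], sc[3])
    # per-gene positive rescaling leaves scores unchanged
    X4 <- sweep(X, 2, runif(p, 0.5, 3), "*")
    expect_equal(gsva_score(X4, set), sc, tolerance = 1e-12)
    # sample order and gene order invariance
    perm <- sample(n); gperm <- sample(p)
    expect_equal(gsva_score(X[perm, ], set), sc[perm], tolerance = 1e-12)
    expect_equal(gsva_score(X[, gperm], set), sc, tolerance = 1e-12)
    expect_error(gsva_score(X[1, , drop = FALSE], set), "2 samples")
  })
})
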