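# Small in-code fixtures shared across the suite.

# Quick random cohort with mild signal-free structure.
tiny_cohort <- function(n = 40L, p = 10L, seed = 1L, cens = 0.3) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p, 5, 2), n, p,
                dimnames = list(sprintf("S%03d", 1:n), sprintf("G%03d", 1:p)))
    T_ev <- rexp(n, 1 / 500)
    C <- runif(n, 0, quantile(T_ev, 1 - cens) * 2)
    survival_cohort(X, pmax(pmin(T_ev, C), 0.1), as.integer(T_ev <= C))
  })
}

# Hand-assembled fitted network (for attribution tests where exact weights
# matter). `layers` is a list of list(W, b); activation defaults to linear.
manual_fit <- function(layers, activation = "linear", genes = NULL,
                       cuts = NULL, cumsum_head = TRUE) {
  p <- nrow(layers[[1]]$W)
  out <- ncol(layers[[length(layers)]]$W)
  genes <- genes %||% sprintf("G%03d", seq_len(p))
  cuts <- cuts %||% seq_len(max(out, 2L)) * 100
  sizes <- c(p, vapply(layers, function(l) ncol(l$W), 0L))
  net <- structure(list(layers = layers, activation = activation,
                        sizes = sizes, cumsum_head = cumsum_head,
                        out_width = out), class = "survnet")
  structure(list(net = net,
                 hp = hyperparams(activation = activation, m = length(cuts)),
                 loss_name = "nmtlr_rank",
                 grid = structure(list(cuts = cuts, scheme = "equidistant",
                                       m = length(cuts)), class = "time_grid"),
                 center = setNames(rep(0, p), genes),
                 scale = setNames(rep(1, p), genes),
                 genes = genes, trace = numeric(0),
                 cohort_label = "manual"), class = "survnet_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Literal weighted-KS running sum over the full ranked list: the independent
# enumeration oracle for the enrichment score.
es_running_sum_oracle <- function(scores, gene_set, weight = 1) {
  ord <- order(scores, decreasing = TRUE)
  ranked <- names(scores)[ord]
  hit <- ranked %in% gene_set
  w <- abs(scores[ord])^weight
  NR <- sum(w[hit])
  Nm <- sum(!hit)
  steps <- ifelse(hit, w / NR, -1 / Nm)
  walk <- cumsum(steps)
  walk[which.max(abs(walk))]
}

# Exhaustive comparable-pair enumeration: the brute-force oracle for the
# time-dependent concordance index.
c_index_brute <- function(S_matrix, eval_times, time, event) {
  n <- length(time)
  # same step convention as the implementation, re-derived independently:
  # predicted survival at t is the value at the last grid time <= t
  sval <- function(i, t) {
    j <- which(eval_times <= t)
    S_matrix[i, if (length(j)) max(j) else 1L]
  }
  num <- 0; den <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    comparable <- (event[i] == 1 && time[i] < time[j]) ||
      (event[i] == 1 && time[i] == time[j] && event[j] == 0)
    if (!comparable) next
    si <- sval(i, time[i]); sj <- sval(j, time[i])
    num <- num + (si < sj) + 0.5 * (si == sj)
    den <- den + 1
  }
  num / den
}
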