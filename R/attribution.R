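#' Estimate signal patterns for every linear unit of a fitted network
#'
#' PatternAttribution separates the signal a unit responds to from the
#' distractor the weight vector must cancel. For a linear unit
#' `y = w'x + b` the pattern is
#' `a = (E_r[x y] - E_r[x] E_r[y]) / (w' (E_r[x y] - E_r[x] E_r[y]))`,
#' where `E_r` is the expectation over the unit's active regime: examples
#' with `y > 0` for rectified units, all examples for the linear head and
#' for saturating activations (the linear all-example estimator is used as
#' the documented approximation for selu/tanh/sigmoid trunks). Units with a
#' degenerate denominator (|denom| < 1e-9) or fewer than 2 active examples
#' get a zero pattern and are flagged, keeping matrix shapes stable.
#'
#' @param fit a [train_survnet] fit.
#' @param X training expression matrix (the fit's genes, log scale;
#'   standardized internally with the fit's training statistics, or pass
#'   `standardized = TRUE` if already transformed).
#' @param standardized set `TRUE` when `X` is already the standardized
#'   training matrix.
#' @return list of class `pattern_set`: per layer a pattern matrix `a` of
#'   the layer weight's shape and a logical `flagged` vector per unit.
#' @export
fit_patterns <- function(fit, X, standardized = FALSE) {
  X <- as.matrix(X)
  Xs <- if (standardized) X else apply_standardization(X, fit$center, fit$scale)
  cache <- forward_pass(fit$net, Xs)
  L <- length(fit$net$layers)
  rectified <- fit$net$activation == "relu"
  out <- vector("list", L)
  for (l in seq_len(L)) {
    H_in <- if (l == 1L) Xs else cache$post[[l - 1L]]
    W <- fit$net$layers[[l]]$W
    Y <- if (l < L) cache$pre[[l]] else cache$psi
    A <- matrix(0, nrow(W), ncol(W))
    flagged <- logical(ncol(W))
    for (u in seq_len(ncol(W))) {
      active <- if (l < L && rectified) Y[, u] > 0 else rep(TRUE, nrow(Y))
      n_act <- sum(active)
      if (n_act < 2L) { flagged[u] <- TRUE; next }
      Ha <- H_in[active, , drop = FALSE]
      ya <- Y[active, u]
      covxy <- colMeans(Ha * ya) - colMeans(Ha) * mean(ya)
      denom <- sum(W[, u] * covxy)
      if (abs(denom) < 1e-9) { flagged[u] <- TRUE; next }
      A[, u] <- covxy / denom
    }
    out[[l]] <- list(a = A, flagged = flagged, n_active = NULL)
  }
  structure(list(layers = out, activation = fit$net$activation),
            class = "pattern_set")
}

#' Backpropagate attributions to the input genes
#'
#' Runs a modified backward pass from one selected output node in which each
#' layer's backward weights are replaced by `W * a` (elementwise product of
#' weight and pattern), gated by the layer's activation state at `X`
#' (the active-regime mask for relu, the activation derivative for
#' saturating trunks). The result is a per-subject, per-gene contribution
#' score for that output.
#'
#' @param fit a [train_survnet] fit.
#' @param patterns a [fit_patterns] result.
#' @param X expression matrix (fit's genes, log scale) or
#'   [survival_cohort]; standardized internally.
#' @param output_node interval index in `1..m` selecting the psi output node.
#' @param root `"psi"` (default) roots the attribution at the raw output of
#'   the selected node; `"phi"` roots it at the cumulated logit
#'   `phi_node = sum_{k >= node} psi_k`.
#' @param standardized set `TRUE` when `X` is already standardized.
#' @return matrix of class `attribution_matrix`, n subjects x p genes, with
#'   attributes `output_node`, `endpoint_days` (the matching cut time) and
#'   `root`.
#' @export
attribute <- function(fit, patterns, X, output_node, root = c("psi", "phi"),
                      standardized = FALSE) {
  root <- match.arg(root)
  if (inherits(X, "survival_cohort")) X <- X$X
  X <- as.matrix(X)
  m_out <- fit$net$out_width
  if (output_node < 1L || output_node > m_out)
    stopf("output_node must be in 1..%d", m_out)
  Xs <- if (standardized) X else apply_standardization(X, fit$center, fit$scale)
  cache <- forward_pass(fit$net, Xs)
  act <- activation_fns(fit$net$activation)
  L <- length(fit$net$layers)
  R <- matrix(0, nrow(Xs), m_out)
  if (root == "psi" || !fit$net$cumsum_head) {
    R[, output_node] <- 1
  } else {
    R[, seq(output_node, m_out)] <- 1
  }
  for (l in rev(seq_len(L))) {
    WA <- fit$net$layers[[l]]$W * patterns$layers[[l]]$a
    R <- R %*% t(WA)
    if (l > 1L) {
      pre <- cache$pre[[l - 1L]]
      gate <- if (fit$net$activation == "relu") (pre > 0) * 1
              else act$df(pre, act$f(pre))
      R <- R * gate
    }
  }
  if (!all(is.finite(R))) stopf("non-finite attributions")  # flagged units give 0
  dimnames(R) <- list(rownames(X), fit$genes)
  structure(R, class = c("attribution_matrix", "matrix"),
            output_node = as.integer(output_node),
            endpoint_days = fit$grid$cuts[min(output_node, fit$grid$m)],
            root = root)
}

#' Map endpoint targets in days to output nodes
#'
#' For each target (e.g. 372 days ~ 1 year, 1919 days ~ 5 years) returns the
#' interval index whose cut time is nearest; targets beyond the last cut map
#' to `m` with a warning, and the mapping is reported.
#'
#' @param grid a [make_grid] result.
#' @param targets_days numeric vector of endpoint times in days.
#' @return integer vector of interval indices.
#' @export
select_endpoint_nodes <- function(grid, targets_days) {
  idx <- vapply(targets_days, function(d) which.min(abs(grid$cuts - d)), 0L)
  over <- targets_days > max(grid$cuts)
  if (any(over))
    warnf("%d endpoint(s) beyond tau_m mapped to interval m", sum(over))
  message(paste(sprintf("endpoint %s d -> node %d (cut %s d)",
                        signif(targets_days, 5L), idx,
                        signif(grid$cuts[idx], 5L)), collapse = "; "))
  if (anyDuplicated(idx) && length(targets_days) > 1L)
    warnf("grid too coarse: multiple endpoints map to the same node")
  idx
}

#' Write an attribution matrix as TSV with a JSON metadata sidecar
#' @param attr_matrix an [attribute] result.
#' @param path output TSV path; the sidecar is `<path>.json`.
#' @export
write_attributions <- function(attr_matrix, path) {
  df <- data.frame(subject_id = rownames(attr_matrix) %||%
                     sprintf("S%04d", seq_len(nrow(attr_matrix))),
                   unclass(attr_matrix), check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  jsonlite::write_json(
    list(output_node = attr(attr_matrix, "output_node"),
         endpoint_days = attr(attr_matrix, "endpoint_days"),
         root = attr(attr_matrix, "root")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
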