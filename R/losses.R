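#' Reverse cumulative sum of network outputs
#'
#' The defining transform of (neural) multi-task logistic regression: the
#' logit for interval `j` is the sum of the raw outputs for intervals
#' `j..m`, `phi_j = sum_{k >= j} psi_k`, so the estimate at a time is a
#' function of the estimates at later times.
#'
#' @param psi numeric matrix n x m of raw network outputs.
#' @return matrix n x m with `phi[, j] = rowSums(psi[, j:m])`.
#' @export
reverse_cumsum <- function(psi) {
  psi <- as.matrix(psi)
  if (!all(is.finite(psi))) stopf("psi must be finite")
  psi %*% rev_cumsum_matrix(ncol(psi))
}

#' Discrete survival prediction from interval logits
#'
#' Applies the softmax over the m interval logits plus an implicit zero logit
#' for the residual category "survives past tau_m":
#' `sigma_j = exp(phi_j) / (1 + sum_k exp(phi_k))`, and derives the survival
#' values at the cuts, `S(k) = 1 - sum_{j <= k} sigma_j`. The computation is
#' stabilized by subtracting the row maximum of the (m+1)-logit vector
#' before exponentiation, which makes it exact for arbitrary finite logits.
#'
#' @param phi numeric matrix n x m of interval logits.
#' @return An object of class `discrete_prediction`: list with `pmf`
#'   (n x (m+1), rows sum to 1), `S_at_cuts` (n x m, non-increasing rows) and
#'   the input `phi`.
#' @export
pmf_from_phi <- function(phi) {
  phi <- as.matrix(phi)
  if (!all(is.finite(phi))) stopf("phi must be finite")
  m <- ncol(phi)
  Z <- cbind(phi, 0)
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  pmf <- E / rowSums(E)
  S <- 1 - pmf[, seq_len(m), drop = FALSE] %*% fwd_cumsum_matrix(m)
  S <- pmin(pmax(S, 0), 1)
  structure(list(pmf = pmf, S_at_cuts = S, phi = phi),
            class = "discrete_prediction")
}

LOG_FLOOR <- 1e-12

#' Discrete-time negative log-likelihood (PMF loss)
#'
#' Events contribute the log probability mass of their interval; censored
#' subjects the log estimated survival beyond their interval. Mean-reduced
#' over subjects; log arguments floored at 1e-12.
#'
#' @param pred a [pmf_from_phi] result.
#' @param k_idx interval indices `k(t_i)` in `1..m`.
#' @param event 0/1 indicators.
#' @return scalar loss.
#' @export
loss_pmf <- function(pred, k_idx, event) {
  m <- ncol(pred$S_at_cuts)
  n <- nrow(pred$pmf)
  if (any(k_idx < 1L | k_idx > m)) stopf("k_idx out of 1..m")
  sig_k <- pred$pmf[cbind(seq_len(n), k_idx)]
  S_k <- pred$S_at_cuts[cbind(seq_len(n), k_idx)]
  ll <- ifelse(event == 1, log(pmax(sig_k, LOG_FLOOR)),
               log(pmax(S_k, LOG_FLOOR)))
  -mean(ll)
}

#' N-MTLR negative log-likelihood
#'
#' Exactly the PMF loss evaluated on the reverse cumulative sum of the raw
#' network outputs: `loss_nmtlr(psi) == loss_pmf(pmf_from_phi(reverse_cumsum(psi)))`.
#'
#' @param psi raw network outputs, n x m.
#' @inheritParams loss_pmf
#' @export
loss_nmtlr <- function(psi, k_idx, event) {
  loss_pmf(pmf_from_phi(reverse_cumsum(psi)), k_idx, event)
}

#' DeepHit-style pairwise ranking loss
#'
#' Over all ordered pairs (i, j) with `d_i = 1` and `t_i < t_j` (ties in time
#' excluded), accumulates
#' `exp[(S(k(t_i) | X_i) - S(k(t_i) | X_j)) / beta]`: a subject who fails
#' earlier should carry lower predicted survival at its own interval than a
#' subject still at risk. Reduced as the mean over comparable pairs by
#' default so the loss scale is batch-size invariant (`reduction = "sum"`
#' gives the bare printed sum); 0 when no pair is comparable.
#'
#' @inheritParams loss_pmf
#' @param time observed times (used for pair comparability).
#' @param beta positive temperature of the exponential penalty.
#' @param reduction `"mean"` (default) or `"sum"` over comparable pairs.
#' @export
loss_rank <- function(pred, k_idx, event, time, beta,
                      reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (!is.numeric(beta) || beta <= 0) stopf("beta must be > 0")
  S <- pred$S_at_cuts
  n <- nrow(S)
  comp <- outer(time, time, "<") & (event == 1)  # comp[i, j]: d_i = 1, t_i < t_j
  npairs <- sum(comp)
  if (npairs == 0L) return(0)
  a <- S[cbind(seq_len(n), k_idx)]            # S_i(k_i)
  B <- t(S[, k_idx, drop = FALSE])            # B[i, j] = S_j(k_i)
  E <- exp((a - B) / beta) * comp
  if (reduction == "mean") sum(E) / npairs else sum(E)
}

#' DeepHit composite loss
#'
#' `alpha * loss_pmf + (1 - alpha) * loss_rank` on logits emitted directly by
#' the network (no cumulative-sum head).
#'
#' @inheritParams loss_rank
#' @param alpha likelihood weight in `[0, 1]`.
#' @export
loss_deephit <- function(pred, k_idx, event, time, alpha, beta) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) stopf("alpha must be in [0, 1]")
  lp <- if (alpha > 0) loss_pmf(pred, k_idx, event) else 0
  lr <- if (alpha < 1) loss_rank(pred, k_idx, event, time, beta) else 0
  alpha * lp + (1 - alpha) * lr
}

#' N-MTLR-Rank composite loss
#'
#' The composite objective at the center of this package:
#' `alpha * loss_nmtlr + (1 - alpha) * loss_rank`, both terms computed on the
#' distribution implied by the reverse cumulative sum of `psi`.
#'
#' @inheritParams loss_deephit
#' @param psi raw network outputs, n x m.
#' @export
loss_nmtlr_rank <- function(psi, k_idx, event, time, alpha, beta) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) stopf("alpha must be in [0, 1]")
  pred <- pmf_from_phi(reverse_cumsum(psi))
  lp <- if (alpha > 0) loss_pmf(pred, k_idx, event) else 0
  lr <- if (alpha < 1) loss_rank(pred, k_idx, event, time, beta) else 0
  alpha * lp + (1 - alpha) * lr
}

#' Cox negative partial log-likelihood
#'
#' `-(1/n_events) * sum_{j: d_j = 1} [theta_j - log sum_{i: t_i >= t_j} exp(theta_i)]`
#' with Breslow's handling of tied event times (the full tied risk set enters
#' every tied term's denominator).
#'
#' @param theta real-valued risk scores (length n).
#' @param time observed times.
#' @param event 0/1 indicators.
#' @export
loss_cox <- function(theta, time, event) {
  theta <- as.numeric(theta)
  if (!all(is.finite(theta))) stopf("theta must be finite")
  if (sum(event) == 0L) stopf("Cox partial likelihood needs at least one event")
  # risk-set log-sum-exp per subject: denominators over {i : t_i >= t_j}
  ord <- order(time, decreasing = TRUE)
  th <- theta[ord]
  mx <- max(th)
  cum <- cumsum(exp(th - mx))
  # subjects tied in time share the denominator of the LAST tie-group member
  tt <- time[ord]
  r <- rle(tt)
  last_of_time <- rep(cumsum(r$lengths), r$lengths)
  denom <- mx + log(cum[last_of_time])
  d_ord <- event[ord]
  -mean(th[d_ord == 1] - denom[d_ord == 1])
}
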