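# Analytic gradients of the survival losses with respect to the raw network
# outputs. Verified against finite differences in the test suite.

# Composite discrete-time loss and its gradient wrt psi (n x m).
# cumsum_head = TRUE routes psi through the reverse cumulative sum (N-MTLR
# family); FALSE treats psi as the interval logits directly (PMF / DeepHit).
# alpha = 1 gives the pure likelihood, alpha = 0 the pure ranking loss.
discrete_loss_grad <- function(psi, k_idx, event, time, alpha, beta,
                               cumsum_head = TRUE) {
  m <- ncol(psi)
  n <- nrow(psi)
  phi <- if (cumsum_head) reverse_cumsum(psi) else psi
  pred <- pmf_from_phi(phi)
  sig <- pred$pmf
  S <- pred$S_at_cuts
  G_phi <- matrix(0, n, m)
  loss <- 0

  if (alpha > 0) {
    Gp <- sig[, seq_len(m), drop = FALSE]
    ev <- which(event == 1)
    if (length(ev))
      Gp[cbind(ev, k_idx[ev])] <- Gp[cbind(ev, k_idx[ev])] - 1
    cs <- which(event == 0)
    if (length(cs)) {
      Sk <- pmax(S[cbind(cs, k_idx[cs])], LOG_FLOOR)
      ind <- outer(k_idx[cs], seq_len(m), FUN = "<") * 1  # 1{j > k_i}
      Gp[cs, ] <- sig[cs, seq_len(m), drop = FALSE] * (1 - ind / Sk)
    }
    G_phi <- G_phi + alpha * Gp / n
    loss <- loss + alpha * loss_pmf(pred, k_idx, event)
  }

  if (alpha < 1) {
    comp <- outer(time, time, "<") & (event == 1)
    npairs <- sum(comp)
    if (npairs > 0L) {
      a <- S[cbind(seq_len(n), k_idx)]
      B <- t(S[, k_idx, drop = FALSE])        # B[i, j] = S_j(k_i)
      E <- exp((a - B) / beta) * comp
      lrank <- sum(E) / npairs
      coef <- 1 / (beta * npairs)
      Gs <- matrix(0, n, m)
      rs <- rowSums(E) * coef
      Gs[cbind(seq_len(n), k_idx)] <- Gs[cbind(seq_len(n), k_idx)] + rs
      for (c in unique(k_idx)) {
        rows <- which(k_idx == c)
        Gs[, c] <- Gs[, c] - colSums(E[rows, , drop = FALSE]) * coef
      }
      # S(k) = 1 - sum_{j <= k} sigma_j  =>  dL/dsigma_c = -sum_{k >= c} Gs[, k]
      R <- Gs %*% rev_cumsum_matrix(m)
      g_sig <- cbind(-R, 0)
      dot <- rowSums(g_sig * sig)
      G_rank <- sig[, seq_len(m), drop = FALSE] *
        (g_sig[, seq_len(m), drop = FALSE] - dot)
      G_phi <- G_phi + (1 - alpha) * G_rank
      loss <- loss + (1 - alpha) * lrank
    }
  }

  grad <- if (cumsum_head) G_phi %*% fwd_cumsum_matrix(m) else G_phi
  list(loss = loss, grad = grad)
}

# Cox negative partial log-likelihood (Breslow ties, mean over events) and
# its gradient wrt theta (returned as an n x 1 matrix).
cox_loss_grad <- function(theta, time, event) {
  theta <- as.numeric(theta)
  n <- length(theta)
  nev <- sum(event)
  if (nev == 0L) stopf("Cox partial likelihood needs at least one event")
  ord <- order(time, decreasing = TRUE)
  th <- theta[ord]
  d <- event[ord]
  tt <- time[ord]
  mx <- max(th)
  cum <- cumsum(exp(th - mx))
  r <- rle(tt)
  last_of_time <- rep(cumsum(r$lengths), r$lengths)
  first_of_time <- rep(cumsum(r$lengths) - r$lengths + 1L, r$lengths)
  denom_log <- mx + log(cum[last_of_time])
  loss <- -mean(th[d == 1] - denom_log[d == 1])
  # A_i = sum over event positions j with t_j <= t_i of 1 / D_j
  invD <- d / exp(denom_log)
  A <- rev(cumsum(rev(invD)))[first_of_time]
  grad_ord <- (exp(th) * A - d) / nev
  grad <- numeric(n)
  grad[ord] <- grad_ord
  list(loss = loss, grad = matrix(grad, ncol = 1L))
}

# Dispatch: loss and gradient wrt the raw head output for a named loss.
loss_grad_for <- function(loss_name, out, k_idx, event, time, alpha, beta) {
  switch(loss_name,
    nmtlr_rank = discrete_loss_grad(out, k_idx, event, time, alpha, beta, TRUE),
    nmtlr      = discrete_loss_grad(out, k_idx, event, time, 1, beta, TRUE),
    deephit    = discrete_loss_grad(out, k_idx, event, time, alpha, beta, FALSE),
    pmf        = discrete_loss_grad(out, k_idx, event, time, 1, beta, FALSE),
    cox        = cox_loss_grad(out, time, event),
    stopf("unknown loss '%s'", loss_name))
}
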