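#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx median p.adjust pchisq pnorm predict quantile
#'   rbinom rexp rnorm runif rweibull sd setNames var
#' @importFrom utils head tail write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# m x m matrix R with R[k, j] = 1 iff k >= j, so (psi %*% R)[, j] = sum_{k>=j} psi[, k]
rev_cumsum_matrix <- function(m) {
  R <- matrix(0, m, m)
  R[lower.tri(R, diag = TRUE)] <- 1
  R
}

# m x m matrix U with U[j, k] = 1 iff j <= k, so (g %*% U)[, k] = sum_{j<=k} g[, j]
fwd_cumsum_matrix <- function(m) {
  U <- matrix(0, m, m)
  U[upper.tri(U, diag = TRUE)] <- 1
  U
}

assert_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stopf("`%s` must be a single number in [%s, %s]", name, lo, hi)
  invisible(x)
}

# Run `expr` with a fixed RNG state without touching the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Derive a reproducible child seed below 2^31 from a parent seed and stream id.
child_seed <- function(seed, id) {
  (as.double(seed) * 48271 + id * 9973) %% 2147483629 + 1
}
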