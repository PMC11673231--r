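#' Discretize follow-up time into m intervals
#'
#' Builds the interval cut points `0 = tau_0 < tau_1 < ... < tau_m` used by
#' the discrete-time models. Two schemes:
#' \describe{
#'   \item{equidistant}{cuts at `j * max(time) / m`.}
#'   \item{km_quantiles}{cuts where the Kaplan-Meier survival estimate first
#'     crosses the equally spaced levels `1 - j/m`; the last cut is clamped
#'     to the maximum observed time. Duplicate cut times are collapsed and
#'     `m` reduced with a warning.}
#' }
#' Intervals are left-open / right-closed `(tau_{k-1}, tau_k]`, so an event
#' exactly at a cut belongs to the earlier interval, matching Kaplan-Meier
#' step behavior.
#'
#' @param time positive observed durations.
#' @param event 0/1 indicators (needed for `km_quantiles`).
#' @param m number of intervals (>= 2).
#' @param scheme `"km_quantiles"` (default) or `"equidistant"`.
#' @return An object of class `time_grid` with fields `cuts`, `scheme`, `m`.
#' @export
make_grid <- function(time, event = NULL, m = 10L,
                      scheme = c("km_quantiles", "equidistant")) {
  scheme <- match.arg(scheme)
  if (m < 2L) stopf("m must be >= 2")
  if (any(time <= 0)) stopf("all times must be positive")
  tmax <- max(time)
  if (scheme == "equidistant") {
    cuts <- seq_len(m) * tmax / m
  } else {
    if (is.null(event) || sum(event) == 0L)
      stopf("km_quantiles discretization needs at least one event")
    km <- km_estimator(time, event)
    levels <- 1 - seq_len(m) / m
    cuts <- vapply(levels, function(lv) {
      hit <- which(km$surv <= lv + 1e-12)
      if (length(hit)) km$times[hit[1L]] else tmax
    }, 0)
    cuts[m] <- tmax  # clamp so tau_m covers the observed follow-up
    cuts <- unique(cuts)
    if (length(cuts) < m)
      warnf("duplicate cut times collapsed: m reduced from %d to %d",
            m, length(cuts))
  }
  if (length(cuts) < 1L || any(diff(cuts) <= 0))
    stopf("degenerate time grid")
  structure(list(cuts = as.numeric(cuts), scheme = scheme,
                 m = length(cuts)), class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %s, m = %d, cuts: %s\n", x$scheme, x$m,
              paste(signif(x$cuts, 4L), collapse = ", ")))
  invisible(x)
}

#' Map observed times to interval indices
#'
#' Returns `k` such that `tau_{k-1} < t <= tau_k`. Times beyond the last cut
#' are clamped to interval `m` (with a message) -- needed when a grid fitted
#' on one cohort is transferred to a cohort with longer follow-up.
#'
#' @param t positive durations.
#' @param grid a [make_grid] result.
#' @return integer vector of interval indices in `1..m`.
#' @export
assign_interval <- function(t, grid) {
  if (any(t <= 0)) stopf("times must be positive")
  k <- findInterval(t, c(0, grid$cuts), left.open = TRUE)
  over <- k > grid$m
  if (any(over)) {
    message(sprintf("%d time(s) beyond tau_m = %s clamped to interval %d",
                    sum(over), signif(max(grid$cuts), 4L), grid$m))
    k[over] <- grid$m
  }
  k
}

#' Interpolate a discrete survival curve to continuous time
#'
#' Given per-subject survival values at the grid cuts (with the implicit
#' `S(0) = 1`), evaluates `S(t)` between cuts by
#' \describe{
#'   \item{CDI}{constant density interpolation: linear in `S` between
#'     adjacent cuts.}
#'   \item{CHI}{constant hazard interpolation: piecewise exponential,
#'     `S(t) = S(tau_{j-1}) * (S(tau_j)/S(tau_{j-1}))^{(t - tau_{j-1}) /
#'     (tau_j - tau_{j-1})}`.}
#' }
#' Both schemes are exact at the cut points. Times beyond `tau_m` return
#' `S(tau_m)` with a warning.
#'
#' @param S_at_cuts numeric vector (length m) or matrix (n x m), non-increasing
#'   rows in `[0, 1]`.
#' @param grid a [make_grid] result.
#' @param t evaluation times (vector allowed).
#' @param scheme `"CDI"` (default) or `"CHI"`.
#' @return matrix n x length(t) of survival probabilities (a vector input
#'   gives a 1-row matrix, dropped to a vector).
#' @export
interpolate_survival <- function(S_at_cuts, grid, t, scheme = c("CDI", "CHI")) {
  scheme <- match.arg(scheme)
  vec_in <- is.null(dim(S_at_cuts))
  S <- if (vec_in) matrix(S_at_cuts, nrow = 1L) else as.matrix(S_at_cuts)
  if (ncol(S) != grid$m) stopf("S_at_cuts has %d columns, grid has m = %d",
                               ncol(S), grid$m)
  cuts <- c(0, grid$cuts)
  Sfull <- cbind(1, S)  # S(tau_0) = 1 exactly
  over <- t > grid$cuts[grid$m] + 1e-12
  if (any(over)) warnf("%d time(s) beyond tau_m: returning S(tau_m)", sum(over))
  tt <- pmin(pmax(t, 0), grid$cuts[grid$m])
  j <- findInterval(tt, cuts, left.open = TRUE)  # interval index, 0 for t = 0
  out <- matrix(NA_real_, nrow(S), length(t))
  for (q in seq_along(t)) {
    if (j[q] == 0L) { out[, q] <- 1; next }
    lo <- cuts[j[q]]; hi <- cuts[j[q] + 1L]
    w <- (tt[q] - lo) / (hi - lo)
    S0 <- Sfull[, j[q]]; S1 <- Sfull[, j[q] + 1L]
    out[, q] <- if (scheme == "CDI") {
      (1 - w) * S0 + w * S1
    } else {
      # piecewise-exponential; 0^0 guarded via floor on the ratio
      S0 * (pmax(S1, 1e-300) / pmax(S0, 1e-300))^w
    }
  }
  if (vec_in) drop(out) else out
}
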