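#' Kaplan-Meier product-limit estimator
#'
#' Right-continuous step estimate of the survival function. With
#' `censoring = TRUE` it estimates the censoring distribution G instead
#' (censorings become the "events"), using the standard tie convention that
#' deaths precede censorings at equal times, i.e. tied deaths are removed
#' from the risk set before the censoring events are counted.
#'
#' @param time observed durations.
#' @param event 0/1 indicators (1 = death).
#' @param censoring estimate the censoring distribution G rather than S.
#' @return list of class `km_fit`: `times` (jump times), `surv` (values just
#'   after each jump), plus the inputs' range.
#' @export
km_estimator <- function(time, event, censoring = FALSE) {
  if (!length(time)) stopf("empty sample")
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), 0)
  n_death <- vapply(ut, function(t) sum(time == t & event == 1), 0)
  n_cens <- vapply(ut, function(t) sum(time == t & event == 0), 0)
  if (censoring) {
    d <- n_cens
    r <- n_risk - n_death  # deaths at t leave the risk set first
  } else {
    d <- n_death
    r <- n_risk
  }
  keep <- d > 0
  frac <- ifelse(r > 0, 1 - d / pmax(r, 1), 1)
  surv <- cumprod(frac)
  structure(list(times = ut[keep], surv = surv[keep], tmax = max(time)),
            class = "km_fit")
}

#' Evaluate a Kaplan-Meier step function
#'
#' @param km a [km_estimator] fit.
#' @param t evaluation times.
#' @param left return the left limit `S(t-)` instead of `S(t)`.
#' @export
km_surv <- function(km, t, left = FALSE) {
  if (!length(km$times)) return(rep(1, length(t)))
  idx <- findInterval(t, km$times, left.open = left)
  c(1, km$surv)[idx + 1L]
}

#' Time-dependent concordance index (Antolini)
#'
#' Probability that, among comparable subject pairs, the predicted survival
#' ordering agrees with the observed outcome ordering. A pair (i, j) is
#' comparable when `d_i = 1` and `t_i < t_j`, or `d_i = 1`, `t_i = t_j` and
#' `d_j = 0`. It is concordant when `S_i(t_i) < S_j(t_i)` (ties in predicted
#' survival receive 0.5 credit). 0.5 is equivalent to a random guess, 1 is
#' perfect concordance. Survival at `t_i` is read off the evaluation grid as
#' a right-continuous step function (the last grid point at or before
#' `t_i`), the usual convention for discrete-time predictions -- it makes
#' the index exactly invariant under monotone transforms of the predicted
#' values at each evaluation time.
#'
#' @param S_matrix n x T matrix of predicted survival on `eval_times`.
#' @param eval_times increasing evaluation grid covering the observed event
#'   times.
#' @param time observed durations.
#' @param event 0/1 indicators.
#' @return scalar concordance in `[0, 1]`.
#' @export
c_index_td <- function(S_matrix, eval_times, time, event) {
  S_matrix <- as.matrix(S_matrix)
  n <- length(time)
  if (nrow(S_matrix) != n) stopf("S_matrix rows must match subjects")
  num <- 0; den <- 0
  for (i in which(event == 1)) {
    Si <- step_rows(S_matrix, eval_times, time[i])
    cmp <- (time > time[i]) | (time == time[i] & event == 0)
    cmp[i] <- FALSE
    if (!any(cmp)) next
    diffs <- Si[cmp] - Si[i]
    num <- num + sum(diffs > 0) + 0.5 * sum(diffs == 0)
    den <- den + sum(cmp)
  }
  if (den == 0) stopf("no comparable pairs")
  num / den
}

# Column of survival values at time t as a right-continuous step function
# of the grid (last grid point at or before t; first column before the grid).
step_rows <- function(S_matrix, eval_times, t) {
  j <- max(findInterval(t, eval_times), 1L)
  S_matrix[, j]
}

# Column of per-subject survival values at a single time t, linear between
# grid points, constant beyond the ends.
interp_rows <- function(S_matrix, eval_times, t) {
  T <- length(eval_times)
  if (t <= eval_times[1L]) return(S_matrix[, 1L])
  if (t >= eval_times[T]) return(S_matrix[, T])
  j <- findInterval(t, eval_times)
  w <- (t - eval_times[j]) / (eval_times[j + 1L] - eval_times[j])
  (1 - w) * S_matrix[, j] + w * S_matrix[, j + 1L]
}

#' IPCW Brier score at a time point
#'
#' Mean squared error of the predicted survival probability against the
#' observed status at `t_eval`, reweighted by the inverse of the censoring
#' survival G (Kaplan-Meier of the censoring distribution): subjects with
#' `t_i <= t_eval, d_i = 1` contribute `S_i(t_eval)^2 / G(t_i-)`, subjects
#' with `t_i > t_eval` contribute `(1 - S_i(t_eval))^2 / G(t_eval)`, and
#' subjects censored before `t_eval` contribute 0.
#'
#' @inheritParams c_index_td
#' @param t_eval evaluation time.
#' @param cens_km optional pre-computed censoring [km_estimator].
#' @export
brier_score <- function(S_matrix, eval_times, time, event, t_eval,
                        cens_km = NULL) {
  S_matrix <- as.matrix(S_matrix)
  n <- length(time)
  if (is.null(cens_km)) cens_km <- km_estimator(time, event, censoring = TRUE)
  St <- interp_rows(S_matrix, eval_times, t_eval)
  G_at_eval <- km_surv(cens_km, t_eval)
  contrib <- numeric(n)
  died <- time <= t_eval & event == 1
  alive <- time > t_eval
  if (any(died)) {
    G_im <- km_surv(cens_km, time[died], left = TRUE)
    capped <- G_im <= 0
    if (any(capped)) {
      warnf("censoring survival is 0 at %d needed time(s); weight capped",
            sum(capped))
      G_im[capped] <- 1e-8
    }
    contrib[died] <- (0 - St[died])^2 / G_im
  }
  if (any(alive)) {
    Ge <- G_at_eval
    if (Ge <= 0) {
      warnf("censoring survival is 0 at t_eval; weight capped")
      Ge <- 1e-8
    }
    contrib[alive] <- (1 - St[alive])^2 / Ge
  }
  mean(contrib)
}

#' Integrated Brier score
#'
#' Trapezoidal integral of the IPCW Brier score over an evaluation grid,
#' normalized by the grid span; smaller values indicate better performance.
#'
#' @inheritParams brier_score
#' @param grid integration times; default 100 equispaced points from 0 to
#'   the maximum observed time.
#' @export
integrated_brier_score <- function(S_matrix, eval_times, time, event,
                                   grid = NULL) {
  if (is.null(grid)) grid <- seq(0, max(time), length.out = 100L)
  cens_km <- km_estimator(time, event, censoring = TRUE)
  bs <- vapply(grid, function(t)
    brier_score(S_matrix, eval_times, time, event, t, cens_km = cens_km), 0)
  span <- diff(range(grid))
  sum(diff(grid) * (head(bs, -1L) + tail(bs, -1L)) / 2) / span
}

#' Metric report for a set of survival predictions
#'
#' Bundles the time-dependent C-index, the Integrated Brier Score and the
#' Brier-score curve it integrates, together with the evaluation grid
#' (recorded so the integration window of every run is reproducible).
#'
#' @inheritParams c_index_td
#' @param ibs_grid integration grid; default 100 equispaced points over the
#'   observed follow-up.
#' @return list of class `metric_report`.
#' @export
metric_report <- function(S_matrix, eval_times, time, event, ibs_grid = NULL) {
  if (is.null(ibs_grid)) ibs_grid <- seq(0, max(time), length.out = 100L)
  cens_km <- km_estimator(time, event, censoring = TRUE)
  bs <- vapply(ibs_grid, function(t)
    brier_score(S_matrix, eval_times, time, event, t, cens_km = cens_km), 0)
  ibs <- sum(diff(ibs_grid) * (head(bs, -1L) + tail(bs, -1L)) / 2) /
    diff(range(ibs_grid))
  structure(list(c_index_td = c_index_td(S_matrix, eval_times, time, event),
                 ibs = ibs,
                 bs_curve = data.frame(t = ibs_grid, bs = bs),
                 eval_grid = eval_times),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> C-index(td) = %.4f, IBS = %.4f (window 0..%s)\n",
              x$c_index_td, x$ibs, signif(max(x$bs_curve$t), 4L)))
  invisible(x)
}

#' Kaplan-Meier marginal survival predictor
#'
#' The cohort-level KM curve assigned to every subject: the natural
#' uninformative baseline whose IBS a useful model must beat.
#'
#' @param train_time,train_event training outcomes defining the KM curve.
#' @param eval_times evaluation grid.
#' @param n number of (test) subjects to replicate the curve for.
#' @return n x length(eval_times) matrix.
#' @export
km_marginal_predictor <- function(train_time, train_event, eval_times, n) {
  km <- km_estimator(train_time, train_event)
  matrix(km_surv(km, eval_times), nrow = n, ncol = length(eval_times),
         byrow = TRUE)
}
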