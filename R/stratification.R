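#' Fit a quantile cutoff on activity scores
#'
#' With the default risk direction (`"high_score_low_risk"`, matching
#' immune-activation signatures associated with better survival) the cutoff
#' is the `(1 - low_risk_fraction)` empirical quantile (type-1 order
#' statistic) and subjects with a score strictly above it are labeled
#' low-risk; with `"high_score_high_risk"` the `low_risk_fraction` quantile
#' is used and scores at or below it are low-risk. Ties exactly at the
#' cutoff deterministically fall on the high-risk side of the rule, so the
#' realized fraction can deviate from the request only through tied scores.
#'
#' @param scores named numeric activity scores (>= 2 distinct values).
#' @param low_risk_fraction requested low-risk fraction in (0, 1),
#'   default 0.30.
#' @param direction risk direction flag (see above).
#' @return list of class `risk_cutoff`: `cutoff`, `low_risk_fraction`,
#'   `direction`.
#' @export
fit_cutoff <- function(scores, low_risk_fraction = 0.30,
                       direction = c("high_score_low_risk",
                                     "high_score_high_risk")) {
  direction <- match.arg(direction)
  if (low_risk_fraction <= 0 || low_risk_fraction >= 1)
    stopf("low_risk_fraction must be in (0, 1)")
  if (length(unique(scores)) < 2L) stopf("all scores are equal; no cutoff")
  q <- if (direction == "high_score_low_risk") 1 - low_risk_fraction
       else low_risk_fraction
  cutoff <- as.numeric(quantile(scores, q, type = 1L))
  structure(list(cutoff = cutoff, low_risk_fraction = low_risk_fraction,
                 direction = direction), class = "risk_cutoff")
}

#' Apply a (possibly transferred) cutoff to activity scores
#'
#' Labels subjects low/high risk with a FIXED threshold -- either from
#' [fit_cutoff] on the same cohort or transferred from a reference cohort.
#' Group sizes are reported; an empty group yields the labels plus a warning
#' (downstream log-rank is then skipped).
#'
#' @param scores named numeric activity scores.
#' @param cutoff a [fit_cutoff] result or a bare numeric threshold.
#' @param direction used only when `cutoff` is a bare number.
#' @return factor of labels `low` / `high` (low = lower-risk group).
#' @export
apply_cutoff <- function(scores, cutoff,
                         direction = c("high_score_low_risk",
                                       "high_score_high_risk")) {
  if (inherits(cutoff, "risk_cutoff")) {
    direction <- cutoff$direction
    thr <- cutoff$cutoff
  } else {
    direction <- match.arg(direction)
    thr <- as.numeric(cutoff)
  }
  if (!is.finite(thr)) stopf("cutoff must be finite")
  low <- if (direction == "high_score_low_risk") scores > thr else scores <= thr
  labels <- factor(ifelse(low, "low", "high"), levels = c("low", "high"))
  message(sprintf("%d low-risk versus %d high-risk", sum(low), sum(!low)))
  if (any(table(labels) == 0L))
    warnf("one risk group is empty; log-rank test not meaningful")
  labels
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic (observed-minus-expected event counts over
#' the distinct event times with hypergeometric variance, ties handled
#' jointly), chi-squared with 1 df. Backed by [survival::survdiff].
#'
#' @param time observed durations.
#' @param event 0/1 indicators.
#' @param labels two-level grouping factor.
#' @return list with `chi2` and `p`.
#' @export
log_rank_test <- function(time, event, labels) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2L) stopf("log-rank test needs two non-empty groups")
  if (sum(event) == 0L) stopf("log-rank test needs at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ labels)
  chi2 <- as.numeric(sd$chisq)
  list(chi2 = chi2, p = pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Kaplan-Meier curves per risk group
#'
#' Product-limit curve and median survival per group (single-group input
#' falls back to one curve).
#'
#' @inheritParams log_rank_test
#' @return list of class `km_curves`: per group a data.frame
#'   `(time, surv, n_censored)` plus `medians`.
#' @export
km_curves <- function(time, event, labels) {
  labels <- droplevels(factor(labels))
  groups <- levels(labels)
  curves <- lapply(groups, function(g) {
    sel <- labels == g
    sf <- survival::survfit(survival::Surv(time[sel], event[sel]) ~ 1)
    data.frame(time = sf$time, surv = sf$surv, n_censor = sf$n.censor)
  })
  names(curves) <- groups
  medians <- vapply(groups, function(g) {
    sel <- labels == g
    sf <- survival::survfit(survival::Surv(time[sel], event[sel]) ~ 1)
    unname(summary(sf)$table["median"])
  }, 0)
  structure(list(curves = curves, medians = medians), class = "km_curves")
}

#' @export
plot.km_curves <- function(x, col = c("#2166ac", "#b2182b"), xlab = "days",
                           ylab = "survival probability", ...) {
  graphics::plot(NULL, xlim = c(0, max(unlist(lapply(x$curves, `[[`, "time")))),
                 ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  for (g in seq_along(x$curves)) {
    cv <- x$curves[[g]]
    graphics::lines(stats::stepfun(cv$time, c(1, cv$surv)),
                    col = col[(g - 1L) %% length(col) + 1L], do.points = FALSE)
    cens <- cv$time[cv$n_censor > 0]
    if (length(cens))
      graphics::points(cens, km_surv(structure(
        list(times = cv$time[], surv = cv$surv, tmax = max(cv$time)),
        class = "km_fit"), cens), pch = 3L,
        col = col[(g - 1L) %% length(col) + 1L])
  }
  graphics::legend("topright", legend = names(x$curves), col =
                     col[seq_along(x$curves)], lty = 1L, bty = "n")
  invisible(x)
}

#' Stratify a cohort by activity score
#'
#' Convenience wrapper: labels from a fitted or transferred cutoff, log-rank
#' test (skipped with a warning when a group is empty) and per-group
#' Kaplan-Meier curves.
#'
#' @param cohort a [survival_cohort].
#' @param scores activity scores for the cohort's subjects.
#' @param cutoff a [fit_cutoff] result or bare threshold.
#' @inheritParams apply_cutoff
#' @return list of class `risk_stratification`: `labels`, `cutoff`,
#'   `low_risk_fraction` (realized), `logrank_chi2`, `logrank_p`,
#'   `km` ([km_curves]).
#' @export
stratify_cohort <- function(cohort, scores, cutoff,
                            direction = c("high_score_low_risk",
                                          "high_score_high_risk")) {
  labels <- apply_cutoff(scores, cutoff, direction)
  lr <- if (all(table(labels) > 0L))
    log_rank_test(cohort$time, cohort$event, labels)
  else list(chi2 = NA_real_, p = NA_real_)
  km <- km_curves(cohort$time, cohort$event, labels)
  thr <- if (inherits(cutoff, "risk_cutoff")) cutoff$cutoff else cutoff
  structure(list(labels = labels, cutoff = thr,
                 low_risk_fraction = mean(labels == "low"),
                 logrank_chi2 = lr$chi2, logrank_p = lr$p, km = km),
            class = "risk_stratification")
}

#' @export
print.risk_stratification <- function(x, ...) {
  cat(sprintf("<risk_stratification> cutoff %.4g: %d low / %d high; log-rank chi2 = %.3f, p = %.4g\n",
              x$cutoff, sum(x$labels == "low"), sum(x$labels == "high"),
              x$logrank_chi2, x$logrank_p))
  invisible(x)
}
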