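## Kaplan-Meier estimation and the log-rank test (survival package behind
## the surfaces). Ties follow the standard convention: events precede
## censorings at the same time.

#' Kaplan-Meier product-limit estimate
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return list of class `"KMCurve"`: `event_times` (increasing, event
#'   times only), `survival` (product-limit estimate after each event
#'   time), `at_risk` (risk-set size just before each event time),
#'   `n`, `n_events`.
#' @export
kmEstimate <- function(times, events) {
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0, 1)))
  if (sum(events) == 0) {
    warning("no events: survival curve is constant at 1")
    return(structure(list(event_times = numeric(0), survival = numeric(0),
                          at_risk = integer(0), n = length(times),
                          n_events = 0L), class = "KMCurve"))
  }
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  structure(list(event_times = fit$time[keep], survival = fit$surv[keep],
                 at_risk = fit$n.risk[keep], n = length(times),
                 n_events = sum(events)), class = "KMCurve")
}

#' @export
print.KMCurve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events, S(last) = %.3f\n",
              x$n, x$n_events,
              if (length(x$survival)) tail(x$survival, 1) else 1))
  invisible(x)
}

#' Log-rank test across two or more groups
#'
#' Standard log-rank statistic (hypergeometric expected deaths at each
#' event time) compared to a chi-square with `groups - 1` degrees of
#' freedom.
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @param groups group labels (>= 2 non-empty groups).
#' @return list of class `"LogRankResult"`: `chi2`, `df`, `p`,
#'   `observed` and `expected` per-group event counts.
#' @export
logrankTest <- function(times, events, groups) {
  stopifnot(length(times) == length(events), length(times) == length(groups),
            all(times >= 0), all(events %in% c(0, 1)))
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) == 0L)) stop("every group needs >= 1 subject")
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(fit$n) - 1L
  chi2 <- unname(fit$chisq)
  structure(list(chi2 = chi2, df = df,
                 p = pchisq(chi2, df = df, lower.tail = FALSE),
                 observed = setNames(as.numeric(fit$obs), levels(groups)),
                 expected = setNames(as.numeric(fit$exp), levels(groups))),
            class = "LogRankResult")
}

#' @export
print.LogRankResult <- function(x, ...) {
  cat(sprintf("Log-rank test: chi2 = %.3f on %d df, p = %.3g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' @importFrom utils tail
NULL
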