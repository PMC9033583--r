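#' Kaplan-Meier product-limit estimator
#'
#' Nonparametric survival curve for right-censored data. At each distinct
#' event time t the estimator multiplies by (1 - d/n) where d is the number
#' of deaths and n the number at risk just before t. The median is the
#' earliest time at which the curve reaches 0.5 or below; if the curve never
#' drops that far the median is not reached and reported as `NA`.
#'
#' @param time positive survival/censoring times (days).
#' @param event 1 = death observed, 0 = censored.
#' @return object of class `pme_km`: list with `steps` (data.frame of
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv` at the distinct observed
#'   times) and `median` (NA when not reached).
#' @export
km_estimate <- function(time, event) {
  check_surv(time, event)
  if (length(time) == 0L) stop("empty survival input")
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), 0)
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), 0)
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), 0)
  surv <- cumprod(1 - n_event / n_risk)
  med <- ut[surv <= 0.5 + 1e-12]
  structure(list(steps = data.frame(time = ut, n_risk = n_risk,
                                    n_event = n_event, n_censor = n_censor,
                                    surv = surv),
                 median = if (length(med)) med[1] else NA_real_),
            class = "pme_km")
}

#' @export
print.pme_km <- function(x, ...) {
  n <- x$steps$n_risk[1]
  cat(sprintf("Kaplan-Meier estimate: %d subjects, %d events; median survival %s\n",
              n, sum(x$steps$n_event),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#' @param km a `pme_km` object.
#' @param t times at which to evaluate S(t).
#' @return numeric vector of survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  s <- c(1, km$steps$surv)
  brk <- c(-Inf, km$steps$time)
  s[findInterval(t, brk)]
}

check_surv <- function(time, event) {
  if (length(time) != length(event)) stop("time/event length mismatch")
  if (anyNA(time) || anyNA(event)) stop("missing values in survival data")
  if (any(time <= 0)) stop("survival times must be strictly positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  invisible(TRUE)
}

#' Two-sample log-rank test
#'
#' Standard (unweighted) log-rank test for equality of survival between two
#' groups. At each distinct event time the observed number of deaths in the
#' first group is compared with its expectation under the hypergeometric
#' distribution given the margins, and the variance is accumulated the same
#' way; the statistic (O - E)^2 / V is referred to a chi-square distribution
#' with 1 df. A Monte-Carlo permutation p-value (group labels permuted,
#' statistic recomputed) is available for small samples.
#'
#' @param time,event survival data for all subjects pooled.
#' @param group two-level grouping vector.
#' @param nperm if > 0, also compute a permutation p-value from `nperm`
#'   random relabelings.
#' @param seed RNG seed for the permutation null.
#' @return object of class `pme_logrank`: list with `statistic`, `df`,
#'   `p_value`, `observed`, `expected` (per group) and, when requested,
#'   `perm_p`.
#' @export
logrank_test <- function(time, event, group, nperm = 0, seed = 1) {
  check_surv(time, event)
  g <- as.factor(group)
  g <- droplevels(g)
  if (nlevels(g) != 2) stop("exactly two groups required")
  if (min(table(g)) == 0L) stop("both groups must be non-empty")
  if (sum(event) == 0) stop("no events")

  stat <- logrank_stat(time, event, g)
  out <- list(statistic = stat$chisq, df = 1L,
              p_value = stats::pchisq(stat$chisq, df = 1, lower.tail = FALSE),
              observed = stat$observed, expected = stat$expected)
  if (nperm > 0) {
    obs <- stat$chisq
    perm <- with_seed(seed, {
      vapply(seq_len(nperm), function(i)
        logrank_stat(time, event, sample(g))$chisq, 0)
    })
    out$perm_p <- (1 + sum(perm >= obs - 1e-12)) / (nperm + 1)
  }
  structure(out, class = "pme_logrank")
}

logrank_stat <- function(time, event, g) {
  lev <- levels(g)
  in1 <- g == lev[1]
  et <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & in1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & in1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (V > 0) (O - E)^2 / V else 0
  Otot <- sum(event == 1)
  list(chisq = chisq,
       observed = stats::setNames(c(O, Otot - O), lev),
       expected = stats::setNames(c(E, Otot - E), lev))
}

#' @export
print.pme_logrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (!is.null(x$perm_p))
    cat(sprintf("  permutation p = %.4g\n", x$perm_p))
  invisible(x)
}
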