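# Survival stratification and contingency analyses.

check_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("time", "event", "group") %in% names(records)))
  if (nrow(records) < 1L) stop("no records")
  if (any(records$time < 0)) stop("invalid: negative survival time")
  records
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimate with right censoring; `S(0) = 1`, non-increasing,
#' piecewise constant.
#'
#' @param records `data.frame` with columns `time` (months), `event`
#'   (1 = death, 0 = censored) and `group`.
#' @return A [survival::survfit] object.
#' @export
km_curve <- function(records) {
  records <- check_records(records)
  survival::survfit(survival::Surv(time, event) ~ group, data = records)
}

#' Log-rank test with an observed/expected hazard ratio
#'
#' Chi-square statistic from the log-rank observed-vs-expected event table;
#' the hazard ratio of the second group level relative to the first is
#' `(O2/E2) / (O1/E1)`, with 95% CI
#' `exp(log HR +/- 1.96 * sqrt(1/E1 + 1/E2))`. Swapping the two labels
#' inverts the hazard ratio.
#'
#' @param records `data.frame` as in [km_curve()]; `group` must have exactly
#'   two levels (first level = reference).
#' @return `list(chi2=, p=, hr=, hr_ci=, obs=, exp=)`.
#' @export
logrank <- function(records) {
  records <- check_records(records)
  records$group <- if (is.factor(records$group)) droplevels(records$group)
    else factor(records$group, levels = unique(records$group))
  if (nlevels(records$group) != 2L) stop("need exactly two groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = records)
  O <- sd$obs; E <- sd$exp
  if (any(O == 0)) warning("a group has zero events: hazard ratio unstable")
  hr <- (O[2] / E[2]) / (O[1] / E[1])
  se <- sqrt(1 / E[1] + 1 / E[2])
  ci <- exp(log(hr) + c(-1, 1) * stats::qnorm(0.975) * se)
  list(chi2 = sd$chisq,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       hr = unname(hr), hr_ci = unname(ci),
       obs = unname(O), exp = unname(E))
}

#' Split samples into high/low groups at the median
#'
#' Values strictly above the median go to `"high"`; values at or below the
#' median go to `"low"` (ties at the median are assigned to low).
#'
#' @param values named numeric vector of per-sample expression.
#' @return Named character vector of `"high"`/`"low"` assignments.
#' @export
median_bifurcate <- function(values) {
  if (length(values) < 2L) stop("need at least two samples")
  med <- stats::median(values)
  if (all(values == values[1L])) stop("degenerate split: all values identical")
  stats::setNames(ifelse(values > med, "high", "low"), names(values))
}

#' Pearson chi-square test on an r x c contingency table
#'
#' No continuity correction; `(r-1)(c-1)` degrees of freedom.
#'
#' @param table matrix of non-negative counts with positive margins.
#' @return `list(stat=, p=, df=)`.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("invalid: negative counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("invalid: zero marginal")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(stat = unname(ct$statistic), p = unname(ct$p.value),
       df = unname(ct$parameter))
}
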