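#' Kaplan-Meier disease-free survival estimate
#'
#' Product-limit estimator over the distinct event times, with Greenwood
#' variance and 95% confidence intervals. The default interval uses the
#' complementary log-log transformation so bounds respect [0, 1]; `conf_type
#' = "plain"` gives the linear Greenwood interval. Censored observations
#' leave the risk set without contributing an event; a tie between an event
#' and a censoring at the same time counts the event first (the standard
#' convention). Follow-up is in months (days / 30.4375 when converting from
#' dates).
#'
#' @param time follow-up in months from surgery (> 0).
#' @param event logical/0-1, TRUE = relapse observed.
#' @param conf_type `"log-log"` (default) or `"plain"`.
#' @return An object of class `km_curve`: data.frame `steps` (time, n_risk,
#'   n_event, n_censor, survival, se, ci_low, ci_high) over distinct observed
#'   times, plus `n` and the underlying `survfit` object.
#' @export
km_estimate <- function(time, event, conf_type = c("log-log", "plain")) {
  conf_type <- match.arg(conf_type)
  if (length(time) == 0) stop("no survival records")
  if (any(time <= 0)) stop("follow-up times must be > 0")
  stopifnot(length(time) == length(event))
  fit <- survival::survfit(
    survival::Surv(time, as.integer(event)) ~ 1,
    conf.type = if (conf_type == "log-log") "log-log" else "plain")
  s <- summary(fit, censored = TRUE)
  steps <- data.frame(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
                      n_censor = s$n.censor, survival = s$surv, se = s$std.err,
                      ci_low = ifelse(is.na(s$lower), s$surv, s$lower),
                      ci_high = ifelse(is.na(s$upper), s$surv, s$upper))
  structure(list(steps = steps, n = length(time), conf_type = conf_type,
                 survfit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  ev <- sum(x$steps$n_event)
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, last follow-up %.1f months\n",
              x$n, ev, max(x$steps$time)))
  invisible(x)
}

#' Survival at a time point
#'
#' Step-function value of a Kaplan-Meier curve at `t` months, as a percent
#' with its 95% CI. Querying beyond the last follow-up returns the last step
#' with a warning.
#'
#' @param curve a [km_curve][km_estimate()].
#' @param t months (>= 0).
#' @return list with `survival_pct`, `ci_low_pct`, `ci_high_pct`.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), t >= 0)
  st <- curve$steps
  if (t > max(st$time))
    warning(sprintf("t = %.4g months is beyond the last follow-up (%.4g); returning the last step",
                    t, max(st$time)))
  i <- findInterval(t, st$time)           # 0 => before first step => S = 1
  if (i == 0)
    return(list(survival_pct = 100, ci_low_pct = 100, ci_high_pct = 100))
  list(survival_pct = 100 * st$survival[i],
       ci_low_pct = 100 * st$ci_low[i], ci_high_pct = 100 * st$ci_high[i])
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic comparing the observed event counts with
#' those expected under a common hazard, summed over the pooled event times;
#' 1 degree of freedom.
#'
#' @param time follow-up in months.
#' @param event logical/0-1 relapse indicator.
#' @param group two-level factor (e.g. MTVcsc below vs at/above the cutoff).
#' @return list with `chi2`, `df`, `p`, and per-group `observed`/`expected`.
#' @export
logrank <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2) stop("exactly two groups required")
  if (sum(event) == 0) stop("no events: the log-rank statistic is undefined")
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  list(chi2 = unname(sd$chisq), df = 1,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = unname(sd$obs), expected = unname(sd$exp))
}

#' Export a Kaplan-Meier curve as CSV
#'
#' @param curve a [km_curve][km_estimate()].
#' @param path output CSV path.
#' @export
write_km_csv <- function(curve, path) {
  stopifnot(inherits(curve, "km_curve"))
  utils::write.csv(curve$steps, path, row.names = FALSE)
  invisible(path)
}
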