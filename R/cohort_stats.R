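#' Odds ratio of a 2x2 table with Woolf confidence interval
#'
#' Rows are exposure levels (first row = the index level), columns the
#' outcome (pCR, residual). OR = (a d)/(b c); the 95% CI is
#' `exp(log OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))` (Woolf / log method).
#' With a zero off-diagonal cell the OR is undefined; setting
#' `correction = TRUE` adds the Haldane-Anscombe 0.5 to every cell and flags
#' the result.
#'
#' @param a,b,c,d cell counts: `a` exposed with outcome, `b` exposed without,
#'   `c` unexposed with outcome, `d` unexposed without.
#' @param correction apply the 0.5 continuity correction when a cell is zero.
#' @return list with `or`, `ci` (length 2), `log_se`, `corrected`.
#' @examples
#' odds_ratio(20, 33, 2, 27)$or  # 8.18: lower T stage vs pCR
#' @export
odds_ratio <- function(a, b, c, d, correction = FALSE) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("cell counts must be nonnegative")
  corrected <- FALSE
  if (any(cells == 0)) {
    if (!correction)
      stop("zero cell (", paste(names(cells)[cells == 0], collapse = ", "),
           "); enable `correction` for the Haldane-Anscombe estimate")
    cells <- cells + 0.5
    corrected <- TRUE
  }
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  list(or = unname(or), ci = unname(exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)),
       log_se = se, corrected = corrected)
}

#' Pearson chi-square test on an r x c table
#'
#' Standard Pearson statistic without continuity correction, df =
#' (r-1)(c-1), p from the chi-square upper tail.
#'
#' @param tab matrix of nonnegative counts with positive margins.
#' @return list with `statistic`, `df`, `p`.
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate margins: every row and column must have a positive total")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Fisher's exact test on a 2 x c table by full enumeration
#'
#' Enumerates every table with the observed margins, computes each table's
#' conditional (multivariate hypergeometric) probability, and sums the
#' probabilities not exceeding the observed table's — the exact two-sided
#' conditional test. Enumeration is feasible for the small strata compared
#' here (c <= 5 columns); larger tables should use [pearson_chi2()].
#'
#' @param tab 2 x c matrix of counts.
#' @return Two-sided exact p-value.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2) stop("expected a 2 x c table")
  if (ncol(tab) > 5) stop("table too large for enumeration; use pearson_chi2()")
  cm <- colSums(tab); r1 <- sum(tab[1, ])
  # log-probability of a first row given fixed margins (second row implied)
  logp <- function(row1) sum(lchoose(cm, row1)) - lchoose(sum(cm), r1)
  rows <- .enumerate_rows(cm, r1)
  lp <- vapply(rows, logp, numeric(1))
  lp_obs <- logp(tab[1, ])
  sum(exp(lp[lp <= lp_obs + 1e-7]))
}

# all nonnegative integer first rows summing to r1 with row1[j] <= cm[j]
.enumerate_rows <- function(cm, r1) {
  if (length(cm) == 1) {
    if (r1 <= cm) return(list(r1)) else return(list())
  }
  out <- list()
  for (v in 0:min(cm[1], r1))
    out <- c(out, lapply(.enumerate_rows(cm[-1], r1 - v), function(r) c(v, r)))
  out
}

#' Logistic regression for pCR prediction
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares,
#' convergence when the deviance change is below 1e-8 or after 100
#' iterations) with Wald 95% confidence intervals and two-sided Wald
#' p-values, reported on the odds-ratio scale. Continuous covariates enter
#' per unit, so the MTVcsc coefficient is the OR per 1 cm^3 increase. Rows
#' with missing values are dropped (complete-case analysis, matching
#' per-analysis denominators when grade or Ki-67 are missing). Quasi-complete
#' separation is detected from diverging standard errors and reported via
#' `converged = FALSE` plus a warning, not corrected.
#'
#' @param design data.frame of covariates (numeric or factor).
#' @param outcome logical/0-1 response (TRUE = pCR), length nrow(design).
#' @return An object of class `logistic_fit`: data.frame `table` (term,
#'   estimate, se, or, ci_low, ci_high, p), `converged`, `separation`,
#'   `n_used`, and the underlying `glm` object.
#' @export
logistic_fit <- function(design, outcome) {
  design <- as.data.frame(design)
  if (ncol(design) < 1) stop("need at least one covariate")
  if (length(outcome) != nrow(design)) stop("outcome length must match design rows")
  dat <- cbind(.outcome = as.logical(outcome), design)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < ncol(design) + 1)
    stop("fewer complete cases than parameters")
  if (length(unique(dat$.outcome)) < 2)
    stop("outcome is constant in the complete cases")
  fit <- suppressWarnings(
    stats::glm(.outcome ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  separation <- any(se[-1] > 100) || any(abs(est[-1]) > 15)
  if (separation)
    warning("possible quasi/complete separation: coefficient estimates diverge")
  z <- stats::qnorm(0.975)
  tab <- data.frame(term = names(est), estimate = unname(est), se = unname(se),
                    or = exp(unname(est)),
                    ci_low = exp(unname(est) - z * unname(se)),
                    ci_high = exp(unname(est) + z * unname(se)),
                    p = 2 * stats::pnorm(-abs(unname(est) / unname(se))),
                    row.names = NULL)
  structure(list(table = tab, converged = fit$converged && !separation,
                 separation = separation, n_used = nrow(dat), glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit on %d complete cases (%s)\n", x$n_used,
              if (x$converged) "converged" else "NOT converged"))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], signif, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Univariable odds-ratio table in the published encodings
#'
#' Runs the univariable 2x2 analyses of the pCR predictors with the reference
#' levels that reproduce the published directions: T stage 1-2 vs 3-4,
#' anatomic stage IIA-IIIA vs IIIB-IIIC, grade 3 vs 1-2, Ki-67 high (>= 30%)
#' vs low, ER negative vs positive. Each analysis is complete-case on its own
#' covariate.
#'
#' @param cohort cohort data.frame with columns `t_stage` ("T1-2"/"T3-4"),
#'   `anatomic_stage` ("IIA-IIIA"/"IIIB-IIIC"), `grade` (1-3, NA allowed),
#'   `ki67_pct` (percent, NA allowed), `er_status` ("positive"/"negative"),
#'   and logical/0-1 `pcr`.
#' @return data.frame with one row per predictor: counts, OR, CI, p (Wald,
#'   from the univariable logistic fit — identical to the cross-product OR).
#' @export
univariable_or_table <- function(cohort) {
  pcr <- as.logical(cohort$pcr)
  enc <- list(
    t_stage        = cohort$t_stage == "T1-2",
    anatomic_stage = cohort$anatomic_stage == "IIA-IIIA",
    grade3         = ifelse(is.na(cohort$grade), NA, cohort$grade == 3),
    ki67_high      = ifelse(is.na(cohort$ki67_pct), NA, cohort$ki67_pct >= 30),
    er_negative    = cohort$er_status == "negative")
  out <- lapply(names(enc), function(nm) {
    x <- enc[[nm]]; keep <- !is.na(x)
    a <- sum(x[keep] & pcr[keep]);  b <- sum(x[keep] & !pcr[keep])
    c <- sum(!x[keep] & pcr[keep]); d <- sum(!x[keep] & !pcr[keep])
    res <- tryCatch({
      or <- odds_ratio(a, b, c, d)
      fit <- logistic_fit(data.frame(x = x[keep]), pcr[keep])
      list(or = or$or, ci = or$ci, p = fit$table$p[2])
    }, error = function(e) list(or = NA_real_, ci = c(NA_real_, NA_real_),
                                p = NA_real_))  # degenerate cell: no estimate
    data.frame(predictor = nm, a = a, b = b, c = c, d = d,
               or = res$or, ci_low = res$ci[1], ci_high = res$ci[2], p = res$p)
  })
  do.call(rbind, out)
}
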