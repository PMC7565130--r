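#' Predict pathologic response from MTVcsc
#'
#' A patient is predicted to achieve pathologic complete response (pCR) when
#' the patient-level MTVcsc is strictly below the cutoff (default 1.75 cm^3,
#' the highest MTVcsc observed in the pCR group, rounded up); values at or
#' above the cutoff predict residual tumor. The strict `<` matches the
#' cutoff's derivation: every pCR case sits below it by construction.
#'
#' @param mtv_csc MTVcsc in cm^3 (> 0); vectorised.
#' @param cutoff cutoff in cm^3, default 1.75.
#' @return Logical: `TRUE` = predicted pCR.
#' @examples
#' classify(c(0.9, 2.8, 1.75))  # TRUE FALSE FALSE
#' @export
classify <- function(mtv_csc, cutoff = 1.75) {
  if (any(mtv_csc <= 0)) stop("mtv_csc must be > 0")
  mtv_csc < cutoff
}

#' Derive the response cutoff from the pCR group
#'
#' The cutoff is the highest MTVcsc among patients who achieved pCR,
#' optionally rounded up to the next multiple of `round_up` (default
#' 0.05 cm^3) so the strict-`<` rule keeps the defining maximum itself on the
#' responder side; an observed maximum of 1.7 cm^3 yields 1.75.
#'
#' @param pcr_mtvcsc MTVcsc values (cm^3) of the pCR group.
#' @param round_up rounding step in cm^3; `NULL` or 0 disables rounding.
#' @return Cutoff in cm^3.
#' @examples
#' derive_cutoff(c(0.3, 0.9, 1.7))  # 1.75
#' @export
derive_cutoff <- function(pcr_mtvcsc, round_up = 0.05) {
  if (length(pcr_mtvcsc) == 0) stop("pCR group is empty")
  m <- max(pcr_mtvcsc)
  if (is.null(round_up) || round_up == 0) return(m)
  # next multiple strictly above m (exact multiples still step up once)
  (floor(m / round_up + 1e-9) + 1) * round_up
}

#' Confusion table for cutoff-based response prediction
#'
#' Cross-tabulates the prediction (MTVcsc below vs at/above the cutoff)
#' against the observed response. Cells follow the published layout:
#' `a` = responders below the cutoff, `b` = non-responders below,
#' `c` = responders at/above, `d` = non-responders at/above.
#'
#' @param mtv_csc patient-level MTVcsc values (cm^3).
#' @param pcr logical observed response (TRUE = pCR).
#' @param cutoff cutoff in cm^3, default 1.75.
#' @return An object of class `confusion_table` with counts `a`, `b`, `c`,
#'   `d`, the `cutoff`, and `total`.
#' @export
confusion_table <- function(mtv_csc, pcr, cutoff = 1.75) {
  stopifnot(length(mtv_csc) == length(pcr))
  pred <- classify(mtv_csc, cutoff)
  confusion_counts(a = sum(pred & pcr), b = sum(pred & !pcr),
                   c = sum(!pred & pcr), d = sum(!pred & !pcr),
                   cutoff = cutoff)
}

#' @rdname confusion_table
#' @param a,b,c,d nonnegative patient counts (see above).
#' @export
confusion_counts <- function(a, b, c, d, cutoff = 1.75) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop("counts must be nonnegative")
  structure(as.list(c(counts, cutoff = cutoff, total = sum(counts))),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2,
              dimnames = list(sprintf(c("MTVcsc < %.4g", "MTVcsc >= %.4g"), x$cutoff),
                              c("pCR", "Residual")))
  print(m)
  acc <- accuracy(x)
  cat(sprintf("Prediction accuracy: %d%% (%d/%d)\n",
              round(acc), x$a + x$d, x$total))
  invisible(x)
}

#' Prediction accuracy of a confusion table
#'
#' `100 * (a + d) / total`: correctly predicted responders (below cutoff,
#' achieved pCR) plus correctly predicted non-responders.
#'
#' @param tab a [confusion_table()].
#' @param digits rounding for the returned percent; `NULL` keeps full
#'   precision (summaries print the nearest whole percent).
#' @return Accuracy in percent.
#' @export
accuracy <- function(tab, digits = NULL) {
  stopifnot(inherits(tab, "confusion_table"))
  if (tab$total == 0) stop("empty confusion table")
  acc <- 100 * (tab$a + tab$d) / tab$total
  if (is.null(digits)) acc else round(acc, digits)
}

#' Tabulate prediction accuracy by subgroup
#'
#' Builds one confusion table and accuracy per level of a grouping covariate
#' (molecular subtype, NAC regimen, anti-HER2 exposure, ...), the layout of
#' the published subtype and regimen tables.
#'
#' @param cohort data.frame with columns `mtv_csc` and logical/0-1 `pcr`.
#' @param group name of the grouping column, or a factor/character vector.
#' @param cutoff cutoff in cm^3.
#' @return data.frame with one row per group: counts a-d, n, accuracy_pct
#'   (whole percent) and accuracy_raw.
#' @export
accuracy_by_group <- function(cohort, group, cutoff = 1.75) {
  g <- if (is.character(group) && length(group) == 1) cohort[[group]] else group
  stopifnot(!is.null(g), length(g) == nrow(cohort))
  out <- do.call(rbind, lapply(split(seq_len(nrow(cohort)), g), function(i) {
    tab <- confusion_table(cohort$mtv_csc[i], as.logical(cohort$pcr[i]), cutoff)
    data.frame(group = as.character(g[i[1]]), a = tab$a, b = tab$b,
               c = tab$c, d = tab$d, n = tab$total,
               accuracy_pct = round(accuracy(tab)),
               accuracy_raw = accuracy(tab))
  }))
  rownames(out) <- NULL
  out
}
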