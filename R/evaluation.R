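# Evaluation: confusion matrices, metrics, Fisher's exact test,
# CONTROL/RISK stratification, and the Triple O+ conditional risk table.

as_truth_logical <- function(truth) {
  if (is.logical(truth)) return(truth)
  if (is.character(truth) || is.factor(truth)) {
    truth <- as.character(truth)
    bad <- setdiff(unique(truth), c("HIGH", "LOW", "NONE"))
    if (length(bad) > 0L) {
      stop(sprintf("unknown truth status: %s", paste(bad, collapse = ", ")))
    }
    return(truth != "NONE")
  }
  stop("truth must be logical or HIGH/LOW/NONE statuses")
}

#' Predicted-vs-true outlier confusion matrix
#'
#' The evaluation is unsigned: a brain-outlier call counts as a true
#' positive when the subject is an outcome outlier in either direction
#' (`HIGH` or `LOW`).
#'
#' @param predicted logical brain-outlier calls.
#' @param truth logical outcome-outlier indicators, or `HIGH`/`LOW`/`NONE`
#'   statuses.
#' @param subject_ids optional aligned ids (checked for agreement if both
#'   inputs carry names).
#' @return object of class `tripleo_confusion`: list with `tp`, `fp`,
#'   `fn`, `tn`, `n_total`.
#' @export
confusion_matrix <- function(predicted, truth, subject_ids = NULL) {
  truth <- as_truth_logical(truth)
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have the same length")
  }
  if (any(is.na(predicted)) || any(is.na(truth))) {
    stop("predicted and truth must not contain NA")
  }
  structure(
    list(
      tp = sum(predicted & truth),
      fp = sum(predicted & !truth),
      fn = sum(!predicted & truth),
      tn = sum(!predicted & !truth),
      n_total = length(predicted)
    ),
    class = "tripleo_confusion"
  )
}

#' Build a confusion object directly from counts
#'
#' @param tp,fp,fn,tn nonnegative cell counts.
#' @return object of class `tripleo_confusion`.
#' @export
confusion_from_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be nonnegative integers")
  }
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn, n_total = tp + fp + fn + tn),
    class = "tripleo_confusion"
  )
}

#' @export
print.tripleo_confusion <- function(x, ...) {
  cat(sprintf("confusion (n = %d): tp = %d, fp = %d, fn = %d, tn = %d\n",
              x$n_total, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Sensitivity, specificity and accuracy from a confusion matrix
#'
#' Percentages: sensitivity = 100 tp / (tp + fn), specificity =
#' 100 tn / (tn + fp), accuracy = 100 (tp + tn) / n. A zero denominator
#' yields `NA` (absent), never 0. Raw values are retained alongside
#' half-up-rounded report values.
#'
#' @param confusion a `tripleo_confusion` (from [confusion_matrix()] or
#'   [confusion_from_counts()]).
#' @param round_to decimals for the rounded report values, default 1.
#' @return object of class `tripleo_metrics`: list with `sensitivity`,
#'   `specificity`, `accuracy` (raw percentages), their `_rounded`
#'   counterparts, and the `confusion`.
#' @export
#' @examples
#' prediction_metrics(confusion_from_counts(tp = 8, fp = 6, fn = 11, tn = 150))
prediction_metrics <- function(confusion, round_to = 1L) {
  c_ <- confusion
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  sens <- ratio(c_$tp, c_$tp + c_$fn)
  spec <- ratio(c_$tn, c_$tn + c_$fp)
  acc <- ratio(c_$tp + c_$tn, c_$n_total)
  structure(
    list(
      sensitivity = sens, specificity = spec, accuracy = acc,
      sensitivity_rounded = round_half_up(sens, round_to),
      specificity_rounded = round_half_up(spec, round_to),
      accuracy_rounded = round_half_up(acc, round_to),
      confusion = c_
    ),
    class = "tripleo_metrics"
  )
}

#' @export
print.tripleo_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "--" else sprintf("%.1f%%", v)
  cat(sprintf("sensitivity %s, specificity %s, accuracy %s\n",
              fmt(x$sensitivity_rounded), fmt(x$specificity_rounded),
              fmt(x$accuracy_rounded)))
  print(x$confusion)
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 confusion table
#'
#' Exact p-value by hypergeometric enumeration with the point-probability
#' rule: the sum of the probabilities of all tables with the observed
#' margins whose point probability does not exceed that of the observed
#' table (within relative tolerance `rel_tol` for floating-point ties). A
#' table with any zero margin carries no association information; its p is
#' 1 by convention, with a warning.
#'
#' @param confusion a `tripleo_confusion`.
#' @param rel_tol relative tie tolerance, default 1e-7.
#' @return the two-sided p-value in (0, 1].
#' @export
fisher_exact_test <- function(confusion, rel_tol = 1e-7) {
  a <- confusion$tp; b <- confusion$fp
  c_ <- confusion$fn; d <- confusion$tn
  n <- a + b + c_ + d
  r1 <- a + b  # predicted positive
  c1 <- a + c_ # true positive
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) {
    warning("a margin of the 2x2 table is zero; p = 1 by convention")
    return(1)
  }
  k <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(k, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + rel_tol)])
  min(p, 1)
}

#' Classify subjects into CONTROL and RISK groups
#'
#' `CONTROL` = singleton, full-term, no maternal-disorder diagnosis; `RISK`
#' = at least one of twin birth, preterm birth, maternal disorder. Any
#' `UNKNOWN` component that leaves the classification ambiguous makes the
#' subject unclassifiable (`NA`, with a warning); a single known risk
#' factor is sufficient for `RISK` regardless of the other components.
#'
#' @param term_status `"FULL_TERM"` / `"PRETERM"` / `"UNKNOWN"`.
#' @param twin_status `"SINGLETON"` / `"TWIN"` / `"UNKNOWN"`.
#' @param maternal_disorder `"NO"` / `"YES"` / `"UNKNOWN"`.
#' @return character vector of `"CONTROL"` / `"RISK"` / `NA`.
#' @export
classify_group <- function(term_status, twin_status, maternal_disorder) {
  risky <- (term_status == "PRETERM") | (twin_status == "TWIN") |
    (maternal_disorder == "YES")
  all_known <- term_status != "UNKNOWN" & twin_status != "UNKNOWN" &
    maternal_disorder != "UNKNOWN"
  out <- ifelse(risky, "RISK", ifelse(all_known, "CONTROL", NA_character_))
  if (any(is.na(out))) {
    warning(sprintf(
      "%d subject(s) unclassifiable (UNKNOWN group component); excluded from stratified outputs",
      sum(is.na(out))
    ))
  }
  out
}

#' Per-group prediction metrics (CONTROL / RISK stratification)
#'
#' Computes the confusion matrix and metrics within each group
#' independently, plus the pooled (whole-cohort) metrics. Subjects with
#' `NA` group are excluded from the stratified tables only, never from the
#' pooled one.
#'
#' @param predicted logical brain-outlier calls.
#' @param truth outcome truth (see [confusion_matrix()]).
#' @param groups group labels (`"CONTROL"` / `"RISK"` / `NA`).
#' @return named list of `tripleo_metrics`, one per group level present,
#'   plus `pooled`.
#' @export
stratified_metrics <- function(predicted, truth, groups) {
  if (length(predicted) != length(groups)) {
    stop("groups must align with predictions")
  }
  truth <- as_truth_logical(truth)
  out <- list(pooled = prediction_metrics(confusion_matrix(predicted, truth)))
  for (g in unique(groups[!is.na(groups)])) {
    sel <- !is.na(groups) & groups == g
    out[[g]] <- prediction_metrics(confusion_matrix(predicted[sel],
                                                    truth[sel]))
  }
  out
}

#' Conditional risk table for signed (Triple O+) predictions
#'
#' For each group and each predicted call cell (`HIGH_OUTLIER`,
#' `LOW_OUTLIER`, `NONE`), plus the unconditional `ALL` base-rate row, the
#' empirical probability (in percent) that a subject in that cell truly is
#' a high or low outcome outlier. Empty cells report counts of 0 and `NA`
#' probabilities.
#'
#' @param calls signed calls from [signed_prediction()] (`call` column or
#'   character vector).
#' @param truth truth statuses (`HIGH`/`LOW`/`NONE`).
#' @param groups group labels (`"CONTROL"`/`"RISK"`/`NA`).
#' @param round_to decimals for the rounded percentages, default 2.
#' @return data.frame with columns `group`, `cell`, `n`, `n_high`,
#'   `n_low`, `p_high`, `p_low`, `p_high_rounded`, `p_low_rounded`.
#' @export
conditional_risk_table <- function(calls, truth, groups, round_to = 2L) {
  if (is.data.frame(calls)) calls <- calls$call
  calls <- as.character(calls)
  truth <- as.character(truth)
  if (length(calls) != length(truth) || length(calls) != length(groups)) {
    stop("calls, truth and groups must be aligned")
  }
  cells <- c("ALL", "HIGH_OUTLIER", "LOW_OUTLIER", "NONE")
  rows <- list()
  for (g in unique(groups[!is.na(groups)])) {
    in_g <- !is.na(groups) & groups == g
    for (cell in cells) {
      sel <- if (cell == "ALL") in_g else in_g & calls == cell
      n <- sum(sel)
      n_high <- sum(truth[sel] == "HIGH")
      n_low <- sum(truth[sel] == "LOW")
      p_high <- if (n > 0) 100 * n_high / n else NA_real_
      p_low <- if (n > 0) 100 * n_low / n else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, cell = cell, n = n, n_high = n_high, n_low = n_low,
        p_high = p_high, p_low = p_low,
        p_high_rounded = round_half_up(p_high, round_to),
        p_low_rounded = round_half_up(p_low, round_to),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
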