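# IQ outlier definition.

#' Classify cohort IQ scores as high/low outliers
#'
#' Normalizes IQ scores to Z-scores and labels subjects `HIGH` when
#' `z > threshold`, `LOW` when `z < -threshold` (strict inequalities),
#' otherwise `NONE`. Normalization uses the cohort's own sample mean and SD
#' by default, or an external mean/SD when supplied.
#'
#' @param iq numeric IQ scores (all finite).
#' @param subject_ids optional subject ids.
#' @param mean,sd external normalization constants; both `NULL` (default)
#'   normalizes against the cohort itself (sample SD, n-1).
#' @param threshold outlier Z cut, default 1.645 (one-tailed p = .05).
#' @return data.frame with `subject_id`, `iq`, `z_iq`, `status` (one of
#'   `"HIGH"`, `"LOW"`, `"NONE"`).
#' @export
#' @examples
#' iq_outlier_status(c(130, 107, 83), mean = 106.9, sd = 11.8)
iq_outlier_status <- function(iq, subject_ids = NULL,
                              mean = NULL, sd = NULL, threshold = 1.645) {
  if (any(!is.finite(iq))) stop("all IQ values must be finite")
  if (threshold <= 0) stop("threshold must be positive")
  if (is.null(mean) != is.null(sd)) {
    stop("supply both mean and sd for external normalization, or neither")
  }
  if (is.null(mean)) {
    if (length(iq) < 2L) stop("cohort normalization needs at least 2 IQ values")
    mean <- base::mean(iq)
    sd <- stats::sd(iq)
  }
  if (sd <= 0) stop("IQ normalization SD must be positive")
  z <- (iq - mean) / sd
  status <- ifelse(z > threshold, "HIGH", ifelse(z < -threshold, "LOW", "NONE"))
  data.frame(
    subject_id = subject_ids %||% sprintf("S%03d", seq_along(iq)),
    iq = iq, z_iq = z, status = status,
    stringsAsFactors = FALSE
  )
}
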