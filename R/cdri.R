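# Cumulative Demographic Risk Index and Triple O+ signing.

CDRI_COMPONENTS <- c("ga_birth_days", "birthweight_g", "maternal_edu_years")

# Z-score the named demographic columns of `subjects` against the reference
# cohort's non-missing mean/SD (sample SD). Returns subjects x components.
demographic_z_matrix <- function(subjects, reference,
                                 components = CDRI_COMPONENTS) {
  missing_cols <- setdiff(components, intersect(names(subjects),
                                                names(reference)))
  if (length(missing_cols) > 0L) {
    stop(sprintf("demographic column(s) missing: %s",
                 paste(missing_cols, collapse = ", ")))
  }
  Z <- matrix(NA_real_, nrow(subjects), length(components),
              dimnames = list(subjects$subject_id, components))
  for (j in seq_along(components)) {
    ref_vals <- reference[[components[j]]]
    ref_vals <- ref_vals[!is.na(ref_vals)]
    if (length(ref_vals) < 2L) {
      stop(sprintf("reference has fewer than 2 values for %s", components[j]))
    }
    s <- stats::sd(ref_vals)
    if (s <= 0) {
      stop(sprintf("reference SD for %s is zero", components[j]))
    }
    Z[, j] <- (subjects[[components[j]]] - mean(ref_vals)) / s
  }
  Z
}

#' Compute the Cumulative Demographic Risk Index (CDRI)
#'
#' Each demographic component — by default gestational age at birth,
#' birthweight, and maternal education in years — is Z-scored against the
#' reference cohort's mean and sample SD; the CDRI is the mean of the
#' component Z-scores and its sign (`POSITIVE` for cdri > 0, `NEGATIVE`
#' for cdri < 0, an exact 0 resolves to `POSITIVE` with a warning) later
#' polarizes brain-outlier calls into predicted high vs low performers.
#'
#' @param subjects data.frame of subject records (needs `subject_id` and the
#'   component columns).
#' @param reference data.frame of reference subject records supplying the
#'   normalization constants (typically the same cohort).
#' @param components demographic columns to use.
#' @param missing_policy `"require_all"` (default: any missing component is
#'   an error) or `"use_available"` (cdri = mean of the non-missing
#'   component Z-scores; at least one required).
#' @return data.frame with `subject_id`, one `z_<component>` column per
#'   component, `cdri`, `n_components_used`, `sign`.
#' @export
compute_cdri <- function(subjects, reference,
                         components = CDRI_COMPONENTS,
                         missing_policy = c("require_all", "use_available")) {
  missing_policy <- match.arg(missing_policy)
  Z <- demographic_z_matrix(subjects, reference, components)
  n_used <- rowSums(!is.na(Z))
  if (missing_policy == "require_all" && any(n_used < length(components))) {
    bad <- subjects$subject_id[n_used < length(components)]
    stop(sprintf(
      "missing demographic component(s) for subject(s): %s (missing_policy = 'require_all')",
      paste(utils::head(bad, 5L), collapse = ", ")
    ))
  }
  if (any(n_used == 0L)) {
    stop(sprintf("no demographic components available for subject(s): %s",
                 paste(subjects$subject_id[n_used == 0L], collapse = ", ")))
  }
  cdri <- rowMeans(Z, na.rm = TRUE)
  if (any(cdri == 0)) {
    warning(sprintf(
      "%d subject(s) with CDRI exactly 0 assigned POSITIVE by the tie rule",
      sum(cdri == 0)
    ))
  }
  out <- data.frame(subject_id = subjects$subject_id,
                    stringsAsFactors = FALSE)
  for (j in seq_along(components)) out[[paste0("z_", components[j])]] <- Z[, j]
  out$cdri <- unname(cdri)
  out$n_components_used <- as.integer(n_used)
  out$sign <- ifelse(cdri >= 0, "POSITIVE", "NEGATIVE")
  out
}

#' Sign brain-outlier calls with the CDRI (Triple O+)
#'
#' Polarity only refines, never creates: non-outliers stay `NONE`; brain
#' outliers become `HIGH_OUTLIER` under a positive CDRI and `LOW_OUTLIER`
#' under a negative one.
#'
#' @param measures measure table from [predict.tripleo()] (needs
#'   `subject_id` and `is_brain_outlier`).
#' @param cdri CDRI table from [compute_cdri()] for the same subjects.
#' @return data.frame with `subject_id`, `is_brain_outlier`, `cdri`,
#'   `sign`, `call` (`"HIGH_OUTLIER"`, `"LOW_OUTLIER"` or `"NONE"`).
#' @export
signed_prediction <- function(measures, cdri) {
  if (!identical(as.character(measures$subject_id),
                 as.character(cdri$subject_id))) {
    stop("measures and cdri tables must cover the same subjects in the same order")
  }
  call <- ifelse(!measures$is_brain_outlier, "NONE",
                 ifelse(cdri$sign == "POSITIVE", "HIGH_OUTLIER",
                        "LOW_OUTLIER"))
  data.frame(
    subject_id = measures$subject_id,
    is_brain_outlier = measures$is_brain_outlier,
    cdri = cdri$cdri,
    sign = cdri$sign,
    call = call,
    stringsAsFactors = FALSE
  )
}

#' Demographic-only outlier detection
#'
#' Runs the three demographic component Z-scores through the same outlier
#' logic as the three brain measures: indicator = Z above `threshold`
#' (upper tail), subject flagged when at least `min_votes` indicators are
#' true. Provided as the comparison arm showing that demographics alone do
#' not predict outcome outliers above chance — not as a recommended
#' predictor.
#'
#' @inheritParams compute_cdri
#' @param threshold indicator Z cut, default 1.645.
#' @param min_votes indicators required, default 2.
#' @return logical vector, one flag per subject.
#' @export
demographic_only_outliers <- function(subjects, reference,
                                      components = CDRI_COMPONENTS,
                                      threshold = 1.645, min_votes = 2L) {
  Z <- demographic_z_matrix(subjects, reference, components)
  if (any(is.na(Z))) {
    stop("demographic outlier detection needs all components for all subjects")
  }
  unname(rowSums(Z > threshold) >= min_votes)
}
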