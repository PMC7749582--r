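# Single-subject operation surface over the measure engine.

#' Count a subject's outlying connections against the reference
#'
#' Number of connections whose reference Z-score exceeds the model's
#' connection threshold — two-sided (`|Z|`) by default, upper tail only if
#' the model was fitted with `connection_sidedness = "upper"`.
#'
#' @param vec connection vector (length must match the model).
#' @param model a fitted [tripleo()] model.
#' @return nonnegative integer count.
#' @export
count_outlying_connections <- function(vec, model) {
  raw_measures(matrix(vec, nrow = 1L), model)[, "m1"]
}

#' Mean Euclidean distance of a subject to the reference cohort
#'
#' Average of the Euclidean norms between `vec` and every reference
#' subject's connection vector. If `self_index` is given and the model was
#' fitted with `self_exclusion = TRUE`, the subject's own (zero) term is
#' omitted from the average.
#'
#' @param vec connection vector.
#' @param model a fitted [tripleo()] model.
#' @param self_index optional row index of `vec` within the reference.
#' @return nonnegative real.
#' @export
mean_euclidean_distance <- function(vec, model, self_index = NULL) {
  raw_measures(matrix(vec, nrow = 1L), model,
               self_index = self_index)[, "m2"]
}

#' Within-subject standard deviation across connections
#'
#' Sample SD (denominator n-1) of a subject's connection values.
#'
#' @param vec connection vector of length at least 2.
#' @return nonnegative real.
#' @export
within_subject_sd <- function(vec) {
  if (length(vec) < 2L) stop("connection vector needs at least 2 entries")
  if (any(!is.finite(vec))) stop("connection vector must be finite")
  stats::sd(vec)
}

#' Compute a single subject's Triple O measures and vote
#'
#' Convenience wrapper equivalent to a one-row [predict.tripleo()] call,
#' optionally with a `min_votes` override.
#'
#' @param vec connection vector.
#' @param model a fitted [tripleo()] model.
#' @param self_index optional reference row index of this subject.
#' @param min_votes vote threshold; defaults to the model's.
#' @param subject_id id for the output row.
#' @return one-row measure data.frame (see [predict.tripleo()]).
#' @export
compute_triple_o <- function(vec, model, self_index = NULL,
                             min_votes = NULL, subject_id = "subject") {
  m <- model
  if (!is.null(min_votes)) {
    min_votes <- as.integer(min_votes)
    if (!min_votes %in% 1:3) stop("min_votes must be 1, 2 or 3")
    m$min_votes <- min_votes
  }
  X <- matrix(vec, nrow = 1L, dimnames = list(subject_id, NULL))
  raw <- raw_measures(X, m, self_index = self_index)
  score_measures(raw, subject_id, m)
}
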