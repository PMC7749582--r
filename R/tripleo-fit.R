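# The Triple O reference (normative) model: fitting and S3 methods.

#' Fit a Triple O reference model to a normative cohort
#'
#' Estimates, from a reference cohort of vectorized connectivity matrices,
#' everything needed to score new subjects as "brain outliers":
#'
#' 1. per-connection mean and sample SD across reference subjects, used to
#'    Z-score individual connections;
#' 2. the three outlier measures of every reference subject — m1, the count
#'    of outlying connections (connection |Z| above `connection_z`); m2, the
#'    mean Euclidean distance of the subject's connection vector to every
#'    reference subject's vector; m3, the within-subject SD across all
#'    connections;
#' 3. the mean and sample SD of each measure over the reference cohort, used
#'    to Z-normalize the measures of any scored subject.
#'
#' A subject is a brain outlier when at least `min_votes` of its three
#' measure Z-scores strictly exceed `measure_z` (upper tail only: being
#' unusually typical is not an outlier).
#'
#' Connection-level outliers are counted two-sided by default
#' (`|Z| > connection_z`, each tail at one-tailed p < .05 for the default
#' 1.645): the measures are deliberately sign-insensitive so that deviations
#' in either direction — and subgroups with opposite brain-behavior coupling
#' — count equally. `connection_sidedness = "upper"` restricts to the upper
#' tail.
#'
#' When the scored cohort is the reference itself (the self-reference
#' design), each subject is included in the per-connection statistics but by
#' default excluded from its own m2 average (`self_exclusion = TRUE`): a
#' guaranteed zero distance term would bias m2 downward for in-reference
#' subjects relative to externally scored ones. Reference subjects' own
#' measures are computed under the same policy, so reference and test
#' measures are exchangeable under the null.
#'
#' @param x reference cohort: a subjects-by-connections numeric matrix (one
#'   row per subject, columns in [vectorize_connectivity()] order), a list
#'   of connection vectors, or a `tripleo_cohort`.
#' @param subject_ids optional subject ids (defaults to rownames / names).
#' @param connection_z Z threshold for connection-level outliers (default
#'   1.645, one-tailed p < .05 per tail).
#' @param measure_z Z threshold for measure-level indicators (default 1.645).
#' @param min_votes measure indicators required for a brain-outlier call
#'   (default 2 of 3).
#' @param connection_sidedness `"two_sided"` (default) or `"upper"`.
#' @param self_exclusion exclude a subject's own zero term from its m2 when
#'   it is part of the reference (default `TRUE`).
#' @param zero_variance policy for zero-variance connections in the
#'   reference: `"error"` (default) or `"zero"` (connection Z set to 0,
#'   with a warning).
#' @param measure_variance policy when an outlier measure has zero variance
#'   over the reference (possible for tiny or near-degenerate references,
#'   e.g. every reference subject with an outlying-connection count of 0):
#'   `"error"` (default) or `"tolerate"` (that measure's Z-scores become
#'   `NA`, its indicator never fires, and a warning is raised).
#' @return an object of class `tripleo`; see Details. Use [predict.tripleo()]
#'   to score subjects, [fitted.tripleo()] for the reference cohort's own
#'   measures.
#' @seealso [compute_triple_o()], [evaluate_with_reference()]
#' @export
#' @examples
#' set.seed(1)
#' ref <- matrix(rnorm(50 * 45), 50, 45)   # 50 subjects, 10 regions
#' fit <- tripleo(ref)
#' fit
#' head(fitted(fit))
tripleo <- function(x, subject_ids = NULL,
                    connection_z = 1.645, measure_z = 1.645,
                    min_votes = 2L,
                    connection_sidedness = c("two_sided", "upper"),
                    self_exclusion = TRUE,
                    zero_variance = c("error", "zero"),
                    measure_variance = c("error", "tolerate")) {
  connection_sidedness <- match.arg(connection_sidedness)
  zero_variance <- match.arg(zero_variance)
  measure_variance <- match.arg(measure_variance)
  if (!is.numeric(connection_z) || connection_z <= 0 ||
      !is.numeric(measure_z) || measure_z <= 0) {
    stop("thresholds connection_z and measure_z must be positive")
  }
  min_votes <- as.integer(min_votes)
  if (!min_votes %in% 1:3) stop("min_votes must be 1, 2 or 3")

  X <- as_vector_matrix(x, subject_ids)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2L) stop("reference cohort needs at least 2 subjects")
  if (p < 2L) stop("connection vectors need at least 2 entries")

  conn_mean <- colMeans(X)
  conn_sd <- col_sds(X)
  zero_sd <- conn_sd <= 0
  if (any(zero_sd)) {
    if (zero_variance == "error") {
      stop(sprintf(
        "%d reference connection(s) have zero variance (first at index %d); set zero_variance = 'zero' to tolerate",
        sum(zero_sd), which(zero_sd)[1L]
      ))
    }
    warning(sprintf(
      "%d zero-variance connection(s); their connection Z-scores are set to 0",
      sum(zero_sd)
    ))
  }

  model <- structure(
    list(
      n_regions = tryCatch(n_regions_from_length(p),
                           error = function(e) NA_integer_),
      n_connections = p,
      n_reference = n,
      conn_mean = conn_mean,
      conn_sd = conn_sd,
      zero_sd = zero_sd,
      reference = X,
      measure_variance = measure_variance,
      connection_z = connection_z,
      measure_z = measure_z,
      min_votes = min_votes,
      connection_sidedness = connection_sidedness,
      self_exclusion = self_exclusion,
      call = match.call()
    ),
    class = "tripleo"
  )

  # reference subjects' own measures, under the same self policy
  raw <- raw_measures(X, model, self = TRUE)
  measure_mean <- colMeans(raw)
  measure_sd <- apply(raw, 2L, stats::sd)
  if (any(measure_sd <= 0)) {
    if (measure_variance == "error") {
      stop(sprintf(
        "reference outlier measure %d has zero variance; reference cohort is degenerate",
        which(measure_sd <= 0)[1L]
      ))
    }
    warning(sprintf(
      "outlier measure(s) %s have zero reference variance; their indicators are disabled",
      paste(which(measure_sd <= 0), collapse = ", ")
    ))
    measure_sd[measure_sd <= 0] <- NA_real_
  }
  model$measure_mean <- measure_mean
  model$measure_sd <- measure_sd
  model$reference_measures <- score_measures(raw, rownames(X), model)
  model
}

# Coerce cohort-ish input to a subjects x connections matrix with rownames.
as_vector_matrix <- function(x, subject_ids = NULL) {
  if (inherits(x, "tripleo_cohort")) {
    X <- x$vectors
  } else if (is.list(x) && !is.data.frame(x)) {
    lens <- vapply(x, length, integer(1))
    if (length(unique(lens)) != 1L) {
      stop("all connection vectors must have the same length")
    }
    X <- do.call(rbind, x)
    if (!is.null(names(x))) rownames(X) <- names(x)
  } else if (is.matrix(x)) {
    X <- x
  } else if (is.numeric(x)) {
    X <- matrix(x, nrow = 1L)
  } else {
    stop("cannot interpret input as a cohort of connection vectors")
  }
  if (!is.numeric(X) || any(!is.finite(X))) {
    stop("connection vectors must be finite numeric")
  }
  if (!is.null(subject_ids)) {
    if (length(subject_ids) != nrow(X)) {
      stop("subject_ids length does not match number of subjects")
    }
    rownames(X) <- as.character(subject_ids)
  } else if (is.null(rownames(X))) {
    rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
  }
  X
}

# The measure engine: m1, m2, m3 for the rows of X against `model`.
# self = TRUE means X *is* the model's reference matrix (row i of X is
# reference subject i); self_index gives the reference row matching a single
# externally supplied subject. m2 drops the matching self term when
# model$self_exclusion is TRUE.
raw_measures <- function(X, model, self = FALSE, self_index = NULL) {
  p <- ncol(X)
  if (p != model$n_connections) {
    stop(sprintf("connection vector length %d does not match model (%d)",
                 p, model$n_connections))
  }
  sd_safe <- ifelse(model$zero_sd, 1, model$conn_sd)
  Z <- sweep(sweep(X, 2L, model$conn_mean), 2L, sd_safe, "/")
  if (any(model$zero_sd)) Z[, model$zero_sd] <- 0
  m1 <- if (model$connection_sidedness == "two_sided") {
    rowSums(abs(Z) > model$connection_z)
  } else {
    rowSums(Z > model$connection_z)
  }

  R <- model$reference
  nref <- nrow(R)
  # squared cross-distances via the Gram identity; exact enough at these
  # scales and BLAS-fast for 222-region cohorts
  G <- tcrossprod(X, R)
  d2 <- pmax(rowSums(X^2) - 2 * G + rep(rowSums(R^2), each = nrow(X)), 0)
  D <- sqrt(d2)
  if (self) {
    if (!isTRUE(all.equal(dim(X), dim(R))) && nrow(X) != nref) {
      stop("self = TRUE requires X to be the reference matrix")
    }
    if (model$self_exclusion) {
      if (nref < 2L) stop("self exclusion impossible with a single reference subject")
      m2 <- (rowSums(D) - diag(D)) / (nref - 1)
    } else {
      m2 <- rowSums(D) / nref
    }
  } else if (!is.null(self_index)) {
    if (nrow(X) != 1L) stop("self_index applies to a single subject")
    if (self_index < 1L || self_index > nref) {
      stop(sprintf("self_index %d out of range 1..%d", self_index, nref))
    }
    if (model$self_exclusion) {
      if (nref < 2L) stop("self exclusion impossible with a single reference subject")
      m2 <- (sum(D) - D[1L, self_index]) / (nref - 1)
    } else {
      m2 <- sum(D) / nref
    }
  } else {
    m2 <- rowMeans(D)
  }

  m3 <- row_sds(X)
  cbind(m1 = m1, m2 = m2, m3 = m3)
}

# Z-normalize raw measures against the model and apply the vote rule.
score_measures <- function(raw, ids, model) {
  z <- sweep(sweep(raw, 2L, model$measure_mean), 2L, model$measure_sd, "/")
  ind <- !is.na(z) & z > model$measure_z   # strict, upper tail only
  votes <- rowSums(ind)
  data.frame(
    subject_id = ids,
    m1 = as.numeric(raw[, "m1"]), m2 = raw[, "m2"], m3 = raw[, "m3"],
    z1 = z[, "m1"], z2 = z[, "m2"], z3 = z[, "m3"],
    o1 = ind[, "m1"], o2 = ind[, "m2"], o3 = ind[, "m3"],
    votes = as.integer(votes),
    is_brain_outlier = votes >= model$min_votes,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Score subjects against a fitted Triple O reference model
#'
#' Computes the three raw outlier measures, their Z-scores against the
#' reference distribution, the three indicator flags and the brain-outlier
#' vote for each subject in `newdata`. With `newdata` missing, returns the
#' reference cohort's own (fitted) measures.
#'
#' @param object a fitted [tripleo()] model.
#' @param newdata subjects to score: matrix, list of connection vectors, or
#'   `tripleo_cohort`.
#' @param subject_ids optional ids for `newdata`.
#' @param self_indices optional integer vector mapping each row of `newdata`
#'   to its own row in the reference matrix (for scoring the reference
#'   cohort through the external path); `NA` for external subjects.
#' @param ... unused.
#' @return a data.frame with one row per subject: `subject_id`, raw
#'   measures `m1`/`m2`/`m3`, Z-scores `z1`/`z2`/`z3`, indicators
#'   `o1`/`o2`/`o3`, `votes`, `is_brain_outlier`.
#' @export
predict.tripleo <- function(object, newdata = NULL, subject_ids = NULL,
                            self_indices = NULL, ...) {
  if (is.null(newdata)) return(object$reference_measures)
  X <- as_vector_matrix(newdata, subject_ids)
  if (is.null(self_indices)) {
    raw <- raw_measures(X, object)
  } else {
    if (length(self_indices) != nrow(X)) {
      stop("self_indices length must match the number of subjects")
    }
    rows <- lapply(seq_len(nrow(X)), function(i) {
      raw_measures(X[i, , drop = FALSE], object,
                   self_index = if (is.na(self_indices[i])) NULL
                                else self_indices[i])
    })
    raw <- do.call(rbind, rows)
  }
  score_measures(raw, rownames(X), object)
}

#' Reference cohort measures of a fitted Triple O model
#' @param object a fitted [tripleo()] model.
#' @param ... unused.
#' @return the reference cohort's measure table (see [predict.tripleo()]).
#' @export
fitted.tripleo <- function(object, ...) object$reference_measures

#' Measure Z-scores of the reference cohort
#'
#' The normalized deviations of each reference subject's three outlier
#' measures from the reference measure means — the model's analogue of
#' residuals.
#'
#' @param object a fitted [tripleo()] model.
#' @param ... unused.
#' @return numeric matrix (subjects x 3) of measure Z-scores.
#' @export
residuals.tripleo <- function(object, ...) {
  rm <- object$reference_measures
  out <- as.matrix(rm[, c("z1", "z2", "z3")])
  rownames(out) <- rm$subject_id
  out
}

#' Measure-level coefficients of a Triple O model
#'
#' @param object a fitted [tripleo()] model.
#' @param ... unused.
#' @return data.frame with the reference mean and SD of each outlier
#'   measure and the thresholds in force.
#' @export
coef.tripleo <- function(object, ...) {
  data.frame(
    measure = c("outlying_connection_count", "mean_euclidean_distance",
                "within_subject_sd"),
    mean = unname(object$measure_mean),
    sd = unname(object$measure_sd),
    z_threshold = object$measure_z,
    row.names = NULL
  )
}

#' @export
print.tripleo <- function(x, ...) {
  cat("Triple O reference model\n")
  cat(sprintf("  reference subjects: %d; regions: %d; connections: %d\n",
              x$n_reference, x$n_regions, x$n_connections))
  cat(sprintf("  connection Z > %.3f (%s), measure Z > %.3f, votes >= %d\n",
              x$connection_z, x$connection_sidedness, x$measure_z,
              x$min_votes))
  cat(sprintf("  reference brain outliers: %d of %d\n",
              sum(x$reference_measures$is_brain_outlier), x$n_reference))
  invisible(x)
}

#' Summarize a Triple O reference model
#' @param object a fitted [tripleo()] model.
#' @param ... unused.
#' @return an object of class `summary.tripleo`.
#' @export
summary.tripleo <- function(object, ...) {
  rm <- object$reference_measures
  structure(
    list(
      model = object,
      measure_table = coef(object),
      reference_outliers = sum(rm$is_brain_outlier),
      vote_table = table(factor(rm$votes, levels = 0:3)),
      conn_sd_range = range(object$conn_sd)
    ),
    class = "summary.tripleo"
  )
}

#' @export
print.summary.tripleo <- function(x, ...) {
  print(x$model)
  cat("\nReference measure distribution:\n")
  print(x$measure_table, digits = 4)
  cat("\nVotes over reference subjects:\n")
  print(x$vote_table)
  cat(sprintf("\nPer-connection SD range: [%.4g, %.4g]\n",
              x$conn_sd_range[1L], x$conn_sd_range[2L]))
  invisible(x)
}

#' Simulate connection vectors from the fitted per-connection model
#'
#' Draws subjects whose connections are independent Gaussians with the
#' reference per-connection means and SDs — a parametric null cohort with no
#' measure-level structure, useful for calibration checks.
#'
#' @param object a fitted [tripleo()] model.
#' @param nsim number of subjects to draw.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param ... unused.
#' @return subjects x connections numeric matrix.
#' @export
simulate.tripleo <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() {
    p <- object$n_connections
    X <- matrix(stats::rnorm(nsim * p), nsim, p)
    X <- sweep(sweep(X, 2L, object$conn_sd, "*"), 2L, object$conn_mean, "+")
    rownames(X) <- sprintf("sim%03d", seq_len(nsim))
    X
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Plot the reference distributions of the three outlier measures
#'
#' One panel per measure: histogram of the reference cohort's measure
#' Z-scores with the measure threshold marked.
#'
#' @param x a fitted [tripleo()] model.
#' @param ... passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.tripleo <- function(x, ...) {
  rm <- x$reference_measures
  titles <- c("outlying connections (z1)", "mean distance (z2)",
              "within-subject SD (z3)")
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old))
  for (k in 1:3) {
    z <- rm[[paste0("z", k)]]
    graphics::hist(z, main = titles[k], xlab = "reference Z", col = "grey85",
                   border = "white", ...)
    graphics::abline(v = x$measure_z, col = "red3", lwd = 2)
  }
  invisible(x)
}
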