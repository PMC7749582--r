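# External-reference validation and the reference-sample-size sweep.

#' Score and evaluate a test cohort against a reference cohort
#'
#' Fits the Triple O reference model on `reference` only, scores every
#' `test` subject against it, defines outcome outliers from the test
#' cohort's IQ scores, and evaluates the calls (confusion matrix, metrics,
#' Fisher's exact test; CONTROL/RISK stratification when group components
#' are known). Passing the test cohort itself as `reference` reproduces
#' the self-reference design, with subjects matched to their own reference
#' rows by `subject_id` so the m2 self-exclusion policy applies.
#'
#' @param test a `tripleo_cohort` with IQ scores.
#' @param reference a `tripleo_cohort` sharing the test cohort's region
#'   count; overlapping subject ids other than full identity are an error.
#' @param signed also compute CDRI-signed (Triple O+) calls and the
#'   conditional risk table (default `TRUE` when the demographic columns
#'   are complete).
#' @param iq_threshold,measure_z,connection_z,min_votes,connection_sidedness,self_exclusion,zero_variance
#'   thresholds and policies passed to [tripleo()] / [iq_outlier_status()].
#' @return list with `model`, `measures`, `iq` (outcome table),
#'   `confusion`, `metrics`, `fisher_p`, `stratified` (when groups are
#'   known), and — when `signed` — `cdri`, `calls`, `risk_table`.
#' @export
evaluate_with_reference <- function(test, reference, signed = TRUE,
                                    iq_threshold = 1.645,
                                    measure_z = 1.645,
                                    connection_z = 1.645,
                                    min_votes = 2L,
                                    connection_sidedness = "two_sided",
                                    self_exclusion = TRUE,
                                    zero_variance = "error") {
  stopifnot(inherits(test, "tripleo_cohort"),
            inherits(reference, "tripleo_cohort"))
  if (test$n_regions != reference$n_regions) {
    stop(sprintf("region count mismatch: test %d, reference %d",
                 test$n_regions, reference$n_regions))
  }
  test_ids <- test$subjects$subject_id
  ref_ids <- reference$subjects$subject_id
  self_mode <- identical(sort(test_ids), sort(ref_ids))
  overlap <- intersect(test_ids, ref_ids)
  if (!self_mode && length(overlap) > 0L) {
    stop(sprintf(
      "test and reference cohorts share subject id(s) (%s) without being identical",
      paste(utils::head(overlap, 3L), collapse = ", ")
    ))
  }
  if (any(is.na(test$subjects$iq))) {
    stop("every test subject needs an IQ score for evaluation")
  }

  model <- tripleo(
    reference,
    connection_z = connection_z, measure_z = measure_z,
    min_votes = min_votes, connection_sidedness = connection_sidedness,
    self_exclusion = self_exclusion, zero_variance = zero_variance
  )
  if (self_mode) {
    self_indices <- match(test_ids, rownames(model$reference))
    measures <- predict(model, test$vectors, self_indices = self_indices)
  } else {
    measures <- predict(model, test$vectors)
  }

  iq <- iq_outlier_status(test$subjects$iq, subject_ids = test_ids,
                          threshold = iq_threshold)
  confusion <- confusion_matrix(measures$is_brain_outlier, iq$status)
  metrics <- prediction_metrics(confusion)
  fisher_p <- fisher_exact_test(confusion)

  out <- list(model = model, measures = measures, iq = iq,
              confusion = confusion, metrics = metrics,
              fisher_p = fisher_p)

  known_groups <- with(test$subjects,
                       term_status != "UNKNOWN" & twin_status != "UNKNOWN" &
                         maternal_disorder != "UNKNOWN")
  if (any(known_groups)) {
    groups <- classify_group(test$subjects$term_status,
                             test$subjects$twin_status,
                             test$subjects$maternal_disorder)
    out$groups <- groups
    out$stratified <- stratified_metrics(measures$is_brain_outlier,
                                         iq$status, groups)
  }

  demo_complete <- !any(is.na(test$subjects$ga_birth_days)) &&
    !any(is.na(test$subjects$birthweight_g)) &&
    !any(is.na(test$subjects$maternal_edu_years))
  if (signed && demo_complete) {
    out$cdri <- compute_cdri(test$subjects, test$subjects)
    out$calls <- signed_prediction(measures, out$cdri)
    if (!is.null(out$groups)) {
      out$risk_table <- conditional_risk_table(out$calls$call, iq$status,
                                               out$groups)
    }
  }
  out
}

#' Reference-sample-size resampling sweep
#'
#' For each reference size, draws `n_replicates` subsamples without
#' replacement from the `pool` cohort, scores the `test` cohort against
#' each subsampled reference, and records prediction metrics plus the
#' mean/SD of each raw outlier measure over the replicate's reference
#' subjects. Each (size, replicate) cell runs on a seed substream derived
#' with [mix_seed()], so results are deterministic and adding sizes never
#' perturbs existing replicates.
#'
#' @param test a `tripleo_cohort` with IQ.
#' @param pool reference pool cohort.
#' @param sizes integer vector of reference sizes (each at least 2 and at
#'   most the pool size).
#' @param n_replicates replicates per size, default 100.
#' @param seed base seed.
#' @param ... thresholds/policies forwarded to
#'   [evaluate_with_reference()].
#' @return object of class `tripleo_sweep`: list with `replicates` (long
#'   data.frame: size, replicate, sensitivity, specificity, accuracy,
#'   mean/SD of m1, m2, m3 over the replicate's reference) and `summary`
#'   (per-size means and SDs across replicates), plus `sizes`,
#'   `n_replicates`, `seed`.
#' @export
sweep_reference_size <- function(test, pool, sizes, n_replicates = 100L,
                                 seed = 1L, ...) {
  stopifnot(inherits(test, "tripleo_cohort"),
            inherits(pool, "tripleo_cohort"))
  sizes <- as.integer(sizes)
  n_replicates <- as.integer(n_replicates)
  pool_n <- nrow(pool$subjects)
  if (n_replicates < 1L) stop("n_replicates must be at least 1")
  if (any(sizes < 2L)) stop("every reference size must be at least 2")
  if (max(sizes) > pool_n) {
    stop(sprintf("size %d exceeds pool size %d", max(sizes), pool_n))
  }

  rows <- vector("list", length(sizes) * n_replicates)
  k <- 0L
  for (size in sizes) {
    for (rep_i in seq_len(n_replicates)) {
      idx <- with_seed(mix_seed(seed, size, rep_i),
                       sort(sample.int(pool_n, size)))
      ref <- new_cohort(
        subjects = pool$subjects[idx, , drop = FALSE],
        vectors = pool$vectors[idx, , drop = FALSE],
        n_regions = pool$n_regions,
        label = sprintf("%s_sub%d_rep%d", pool$label, size, rep_i)
      )
      ev <- evaluate_with_reference(test, ref, signed = FALSE, ...)
      ref_meas <- ev$model$reference_measures
      k <- k + 1L
      rows[[k]] <- data.frame(
        size = size, replicate = rep_i,
        sensitivity = ev$metrics$sensitivity,
        specificity = ev$metrics$specificity,
        accuracy = ev$metrics$accuracy,
        m1_mean = mean(ref_meas$m1), m1_sd = stats::sd(ref_meas$m1),
        m2_mean = mean(ref_meas$m2), m2_sd = stats::sd(ref_meas$m2),
        m3_mean = mean(ref_meas$m3), m3_sd = stats::sd(ref_meas$m3)
      )
    }
  }
  replicates <- do.call(rbind, rows)

  agg <- function(col) {
    means <- tapply(replicates[[col]], replicates$size, mean, na.rm = TRUE)
    sds <- tapply(replicates[[col]], replicates$size, stats::sd,
                  na.rm = TRUE)
    list(mean = as.numeric(means), sd = as.numeric(sds))
  }
  size_levels <- sort(unique(replicates$size))
  summary_df <- data.frame(size = size_levels)
  for (col in c("sensitivity", "specificity", "accuracy",
                "m1_mean", "m2_mean", "m3_mean")) {
    a <- agg(col)
    summary_df[[paste0(col, "_mean")]] <- a$mean
    summary_df[[paste0(col, "_sd")]] <- a$sd
  }

  structure(
    list(replicates = replicates, summary = summary_df,
         sizes = sizes, n_replicates = n_replicates, seed = seed),
    class = "tripleo_sweep"
  )
}

#' @export
print.tripleo_sweep <- function(x, ...) {
  cat(sprintf(
    "reference-size sweep: sizes %s, %d replicates each (seed %d)\n",
    paste(sort(unique(x$sizes)), collapse = ", "), x$n_replicates, x$seed
  ))
  print(x$summary[, c("size", "sensitivity_mean", "specificity_mean",
                      "accuracy_mean")], digits = 3, row.names = FALSE)
  invisible(x)
}

#' Plot reference-size sweep curves with mean +/- SD ribbons
#'
#' Top row: sensitivity, specificity, accuracy against reference size.
#' Bottom row: reference mean of each raw outlier measure. Ribbons span
#' one SD across replicates.
#'
#' @param x a `tripleo_sweep`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.tripleo_sweep <- function(x, ...) {
  s <- x$summary
  panels <- list(
    list(col = "sensitivity", lab = "sensitivity (%)"),
    list(col = "specificity", lab = "specificity (%)"),
    list(col = "accuracy", lab = "accuracy (%)"),
    list(col = "m1_mean", lab = "reference mean m1"),
    list(col = "m2_mean", lab = "reference mean m2"),
    list(col = "m3_mean", lab = "reference mean m3")
  )
  old <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (p in panels) {
    mu <- s[[paste0(p$col, "_mean")]]
    sd_ <- s[[paste0(p$col, "_sd")]]
    ylim <- range(mu - sd_, mu + sd_, na.rm = TRUE)
    graphics::plot(s$size, mu, type = "n", ylim = ylim,
                   xlab = "reference size", ylab = p$lab)
    graphics::polygon(c(s$size, rev(s$size)),
                      c(mu - sd_, rev(mu + sd_)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(s$size, mu, col = "steelblue4", lwd = 2)
  }
  invisible(x)
}
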