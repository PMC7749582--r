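# The three outlier measures, Z-normalization and the 2-of-3 vote.

test_that("vectorization is upper-triangle row-major of the right length", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 10
  m[1, 3] <- m[3, 1] <- 20
  m[2, 3] <- m[3, 2] <- 30
  expect_equal(vectorize_connectivity(m), c(10, 20, 30))

  m2 <- matrix(c(0, 5, 5, 0), 2, 2)
  expect_equal(vectorize_connectivity(m2), 5)

  expect_length(vectorize_connectivity(matrix(0, 222, 222)), 24531)
  # round trip through the matrix form
  v <- rnorm(10)
  expect_equal(vectorize_connectivity(connectivity_from_vector(v, 5)), v)
})

test_that("reference fitting estimates per-connection stats and guards degeneracy", {
  # identical reference vectors -> zero variance
  X <- matrix(0.4, 10, 6)
  expect_error(tripleo(X), "zero variance")

  # tolerant policy zeroes the connection Z with a warning
  set.seed(11)
  X2 <- matrix(rnorm(60), 10, 6)
  X2[, 3] <- 1
  expect_warning(fit2 <- tripleo(X2, zero_variance = "zero"),
                 "zero-variance")
  expect_equal(fit2$conn_mean[3], 1)
  # the degenerate connection never contributes outlying counts
  probe <- colMeans(X2); probe[3] <- 99
  expect_equal(unname(count_outlying_connections(probe, fit2)), 0)

  # standard-normal reference recovers mean 0 / sd 1 within 4 SE
  set.seed(12)
  n <- 50; p <- 45
  X3 <- matrix(rnorm(n * p), n, p)
  fit3 <- tripleo(X3)
  expect_equal(fit3$n_reference, n)
  se_mean <- 1 / sqrt(n)
  se_sd <- 1 / sqrt(2 * (n - 1))
  expect_lt(max(abs(fit3$conn_mean)), 4 * se_mean + 3 * se_mean)  # max over p
  expect_lt(mean(fit3$conn_mean), 4 * se_mean)
  expect_equal(mean(fit3$conn_sd), 1, tolerance = 4 * se_sd)

  expect_error(tripleo(X3[1, , drop = FALSE]), "at least 2 subjects")
})

test_that("outlying-connection counts match definition and oracle", {
  set.seed(21)
  ref <- random_reference(20, 8, seed = 21)
  fit <- tripleo(ref)

  # at the mean: zero deviation
  expect_equal(unname(count_outlying_connections(fit$conn_mean, fit)), 0)

  # exactly 7 connections pushed to +2 SD
  v <- fit$conn_mean
  idx <- c(1, 3, 5, 10, 15, 20, 25)
  v[idx] <- v[idx] + 2 * fit$conn_sd[idx]
  expect_equal(unname(count_outlying_connections(v, fit)), 7)

  # random probes agree exactly with the brute-force loop, both sidedness modes
  fit_up <- tripleo(ref, connection_sidedness = "upper")
  for (i in 1:20) {
    probe <- rnorm(ncol(ref), 0.25, 0.5)
    expect_identical(
      as.integer(count_outlying_connections(probe, fit)),
      oracle_m1(probe, fit$conn_mean, fit$conn_sd, fit$connection_z)
    )
    expect_identical(
      as.integer(count_outlying_connections(probe, fit_up)),
      oracle_m1(probe, fit_up$conn_mean, fit_up$conn_sd,
                fit_up$connection_z, two_sided = FALSE)
    )
  }
})

test_that("mean Euclidean distance handles self-exclusion and known geometry", {
  # reference {(0,0,0), (3,4,0), (0,0,6)}: distances from the origin are
  # 0, 5 (the 3-4-5 norm) and 6
  ref <- rbind(c(0, 0, 0), c(3, 4, 0), c(0, 0, 6))
  fit <- suppressWarnings(tripleo(ref, self_exclusion = FALSE,
                                  measure_variance = "tolerate"))
  expect_equal(unname(mean_euclidean_distance(c(0, 0, 0), fit)),
               (0 + 5 + 6) / 3)
  # with self-exclusion, the subject's own zero term is dropped
  fit_ex <- suppressWarnings(tripleo(ref, self_exclusion = TRUE,
                                     measure_variance = "tolerate"))
  expect_equal(unname(mean_euclidean_distance(c(0, 0, 0), fit_ex,
                                              self_index = 1)), 5.5)
  expect_error(mean_euclidean_distance(c(0, 0, 0), fit_ex, self_index = 9),
               "out of range")

  # random instances against the pairwise loop
  set.seed(22)
  ref2 <- random_reference(15, 6, seed = 22)
  fit2 <- tripleo(ref2)
  for (i in 1:10) {
    probe <- rnorm(ncol(ref2), 0.25, 0.3)
    expect_equal(unname(mean_euclidean_distance(probe, fit2)),
                 oracle_m2(probe, ref2), tolerance = 1e-12)
  }
})

test_that("within-subject SD is the n-1 sample SD", {
  expect_equal(within_subject_sd(rep(0.7, 10)), 0)
  expect_equal(within_subject_sd(c(0, 2)), sqrt(2))
  set.seed(23)
  for (i in 1:10) {
    v <- rnorm(50, 0, 2)
    expect_equal(within_subject_sd(v), oracle_m3(v), tolerance = 1e-14)
  }
  expect_error(within_subject_sd(1), "at least 2")
})

test_that("all three measures match brute-force oracles on random small cohorts", {
  set.seed(31)
  for (case in 1:100) {
    n_regions <- sample(4:12, 1)
    n_ref <- sample(5:15, 1)
    p <- n_regions * (n_regions - 1) / 2
    ref <- matrix(rnorm(n_ref * p, 0.2, 0.3), n_ref, p)
    fit <- suppressWarnings(tripleo(ref, self_exclusion = FALSE,
                                    measure_variance = "tolerate"))
    probe <- rnorm(p, 0.2, 0.5)
    got <- predict(fit, matrix(probe, 1))
    expect_identical(as.integer(got$m1),
                     oracle_m1(probe, fit$conn_mean, fit$conn_sd, 1.645))
    expect_lt(abs(got$m2 - oracle_m2(probe, ref)), 1e-10)
    expect_lt(abs(got$m3 - oracle_m3(probe)), 1e-10)
  }
})

test_that("indicators are strict upper-tail and votes obey the 2-of-3 rule", {
  set.seed(41)
  ref <- random_reference(40, 10, seed = 41)
  fit <- tripleo(ref)
  probes <- matrix(rnorm(30 * ncol(ref), 0.25, 0.4), 30)
  got <- predict(fit, probes)

  expect_identical(got$o1, got$z1 > fit$measure_z)
  expect_identical(got$o2, got$z2 > fit$measure_z)
  expect_identical(got$o3, got$z3 > fit$measure_z)
  expect_identical(got$votes, as.integer(got$o1 + got$o2 + got$o3))
  expect_identical(got$is_brain_outlier, got$votes >= 2L)

  # vote threshold monotonicity: 1 can only add, 3 can only remove
  fit1 <- tripleo(ref, min_votes = 1L)
  fit3 <- tripleo(ref, min_votes = 3L)
  got1 <- predict(fit1, probes)
  got3 <- predict(fit3, probes)
  expect_true(all(got1$is_brain_outlier >= got$is_brain_outlier))
  expect_true(all(got3$is_brain_outlier <= got$is_brain_outlier))

  # compute_triple_o agrees with the batch path
  one <- compute_triple_o(probes[1, ], fit, subject_id = "x")
  expect_equal(one$m1, got$m1[1])
  expect_equal(one$m2, got$m2[1])
  expect_equal(one$z3, got$z3[1])

  # a subject at the reference mean has the minimum possible m1
  at_mean <- predict(fit, matrix(fit$conn_mean, 1))
  expect_equal(at_mean$m1, 0)
  expect_false(at_mean$is_brain_outlier)
})

test_that("outlier calls are invariant to affine maps and permutations", {
  set.seed(51)
  ref <- random_reference(30, 8, seed = 51)
  probes <- matrix(rnorm(10 * ncol(ref), 0.25, 0.4), 10)
  fit <- tripleo(ref)
  base <- predict(fit, probes)

  # affine v -> a v + b applied to everyone
  a <- 2.7; b <- -1.3
  fit_t <- tripleo(a * ref + b)
  got_t <- predict(fit_t, a * probes + b)
  expect_equal(got_t$m1, base$m1)
  expect_equal(got_t$m2, a * base$m2, tolerance = 1e-10)
  expect_equal(got_t$z1, base$z1, tolerance = 1e-8)
  expect_equal(got_t$z2, base$z2, tolerance = 1e-8)
  expect_equal(got_t$z3, base$z3, tolerance = 1e-8)
  expect_identical(got_t$is_brain_outlier, base$is_brain_outlier)

  # reference subject order permutation
  perm <- sample(nrow(ref))
  fit_p <- tripleo(ref[perm, ])
  got_p <- predict(fit_p, probes)
  expect_equal(got_p$m2, base$m2, tolerance = 1e-12)
  expect_equal(got_p$z1, base$z1, tolerance = 1e-10)
  expect_identical(got_p$is_brain_outlier, base$is_brain_outlier)

  # consistent region permutation across all subjects
  n_regions <- 8
  rperm <- sample(n_regions)
  permute_regions <- function(X) {
    t(apply(X, 1, function(v) {
      m <- connectivity_from_vector(v, n_regions)
      vectorize_connectivity(m[rperm, rperm])
    }))
  }
  fit_r <- tripleo(permute_regions(ref))
  got_r <- predict(fit_r, permute_regions(probes))
  expect_equal(got_r$m1, base$m1)
  expect_equal(got_r$m2, base$m2, tolerance = 1e-10)
  expect_equal(got_r$m3, base$m3, tolerance = 1e-10)
  expect_identical(got_r$is_brain_outlier, base$is_brain_outlier)
})

test_that("pushing one connection past the threshold never decreases the count", {
  set.seed(61)
  ref <- random_reference(25, 7, seed = 61)
  fit <- tripleo(ref)
  for (i in 1:10) {
    probe <- rnorm(ncol(ref), 0.25, 0.3)
    before <- count_outlying_connections(probe, fit)
    k <- sample(ncol(ref), 1)
    probe2 <- probe
    probe2[k] <- fit$conn_mean[k] + 3 * fit$conn_sd[k]
    expect_gte(count_outlying_connections(probe2, fit), before - (
      abs((probe[k] - fit$conn_mean[k]) / fit$conn_sd[k]) > 1.645))
    expect_gte(count_outlying_connections(probe2, fit),
               count_outlying_connections(probe, fit) -
                 (abs((probe[k] - fit$conn_mean[k]) / fit$conn_sd[k]) > 1.645))
    # and strictly: starting from a sub-threshold connection, never decreases
    probe3 <- probe
    probe3[k] <- fit$conn_mean[k]
    base <- count_outlying_connections(probe3, fit)
    probe3[k] <- fit$conn_mean[k] + 3 * fit$conn_sd[k]
    expect_equal(unname(count_outlying_connections(probe3, fit)),
                 unname(base) + 1)
  }
})

test_that("IQ outliers follow the one-tailed 1.645 rule", {
  # against external norms: (130 - 106.9) / 11.8 = 1.958 -> HIGH
  one <- iq_outlier_status(130, mean = 106.9, sd = 11.8)
  expect_equal(one$z_iq, 1.95762711864407, tolerance = 1e-10)
  expect_equal(one$status, "HIGH")

  got <- iq_outlier_status(c(106.9, 106.9 - 2 * 11.8, 130),
                           mean = 106.9, sd = 11.8)
  expect_equal(got$status, c("NONE", "LOW", "HIGH"))
  expect_equal(got$z_iq[1], 0)

  # cohort self-normalization uses the sample SD
  iq <- c(90, 100, 110, 140)
  got2 <- iq_outlier_status(iq)
  expect_equal(got2$z_iq, (iq - mean(iq)) / sd(iq))

  expect_error(iq_outlier_status(c(100, NA)), "finite")
  expect_error(iq_outlier_status(c(100, 100)), "SD must be positive")
  expect_error(iq_outlier_status(100, mean = 100), "both mean and sd")
})
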