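# Independent brute-force oracles and small fixture builders.

# measure 1: per-connection loop, no vectorization shared with the package
oracle_m1 <- function(vec, conn_mean, conn_sd, thr, two_sided = TRUE) {
  count <- 0L
  for (k in seq_along(vec)) {
    z <- (vec[k] - conn_mean[k]) / conn_sd[k]
    hit <- if (two_sided) abs(z) > thr else z > thr
    if (hit) count <- count + 1L
  }
  count
}

# measure 2: direct pairwise-norm loop
oracle_m2 <- function(vec, ref_matrix, exclude = NULL) {
  ds <- numeric(0)
  for (i in seq_len(nrow(ref_matrix))) {
    if (!is.null(exclude) && i == exclude) next
    ds <- c(ds, sqrt(sum((vec - ref_matrix[i, ])^2)))
  }
  mean(ds)
}

# measure 3: explicit two-pass sample SD
oracle_m3 <- function(vec) {
  mu <- sum(vec) / length(vec)
  sqrt(sum((vec - mu)^2) / (length(vec) - 1))
}

# random reference matrix of n subjects over a small region count
random_reference <- function(n_subjects, n_regions, seed) {
  p <- n_regions * (n_regions - 1) / 2
  set.seed(seed)
  matrix(rnorm(n_subjects * p, mean = 0.25, sd = 0.2), n_subjects, p)
}

# write a numeric matrix as a plain text file and return the path
write_matrix_file <- function(m, sep = " ") {
  path <- tempfile(fileext = ".txt")
  write_connectivity_matrix(m, path, sep = sep)
  path
}

# a tiny valid manifest + matrix files in a temp dir; returns manifest path
write_tiny_cohort_files <- function(n_subjects = 3, n_regions = 4,
                                    seed = 1, iq = NULL) {
  dir <- tempfile()
  dir.create(file.path(dir, "matrices"), recursive = TRUE)
  set.seed(seed)
  ids <- sprintf("T%02d", seq_len(n_subjects))
  for (i in seq_len(n_subjects)) {
    v <- rnorm(n_regions * (n_regions - 1) / 2, 0.3, 0.2)
    m <- connectivity_from_vector(v, n_regions)
    write_connectivity_matrix(m, file.path(dir, "matrices",
                                           paste0(ids[i], ".txt")))
  }
  df <- data.frame(
    subject_id = ids,
    matrix_path = file.path("matrices", paste0(ids, ".txt")),
    sex = "F", term_status = "FULL_TERM", twin_status = "SINGLETON",
    maternal_disorder = "NO",
    ga_birth_days = 260 + seq_len(n_subjects),
    birthweight_g = 2800 + 10 * seq_len(n_subjects),
    maternal_edu_years = 14 + seq_len(n_subjects),
    stringsAsFactors = FALSE
  )
  if (!is.null(iq)) df$iq <- iq
  path <- file.path(dir, "manifest.csv")
  write.csv(df, path, row.names = FALSE)
  path
}

# training-based comparison predictor: score each subject by the pooled
# connection-IQ correlation profile, flag |z| of the score beyond the cut
naive_corr_predictor <- function(X, iq, threshold = 1.645) {
  r <- as.numeric(cor(X, iq))
  score <- as.numeric(X %*% r)
  z <- (score - mean(score)) / sd(score)
  abs(z) > threshold
}

# out-of-sample variant: correlation profile learned on a training cohort,
# applied to a disjoint test cohort from the same population
naive_corr_predictor_trained <- function(train, test, threshold = 1.645) {
  r <- as.numeric(cor(train$vectors, train$subjects$iq))
  score <- as.numeric(test$vectors %*% r)
  z <- (score - mean(score)) / sd(score)
  abs(z) > threshold
}

# per-subject signed dataset reproducing a published-style stratified
# confusion structure; used by the conditional risk table tests
build_strata_dataset <- function() {
  control <- data.frame(
    group = "CONTROL",
    call = c(rep("HIGH_OUTLIER", 2), rep("NONE", 54)),
    truth = c(rep("HIGH", 2), rep("HIGH", 5), rep("NONE", 49)),
    stringsAsFactors = FALSE
  )
  risk <- data.frame(
    group = "RISK",
    call = c(rep("HIGH_OUTLIER", 6), rep("LOW_OUTLIER", 6),
             rep("NONE", 107)),
    truth = c(rep("HIGH", 3), rep("NONE", 3),   # positive calls
              rep("LOW", 3), rep("NONE", 3),    # negative calls
              rep("HIGH", 3), rep("LOW", 3), rep("NONE", 101)),
    stringsAsFactors = FALSE
  )
  rbind(control, risk)
}
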