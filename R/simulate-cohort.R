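# Synthetic cohort generator: latent-trait connection coupling, IQ,
# correlated demographics, CONTROL/RISK structure.

#' Parameters for the synthetic cohort generator
#'
#' Defaults emulate the study conditions the method targets: 222-region
#' connectivity matrices (24,531 unique connections), IQ with mean 106.9
#' and SD 11.8, demographic-IQ correlations in the .17-.40 range,
#' connection-behavior couplings of mixed sign, a CONTROL fraction of 0.32
#' and a RISK-group IQ deficit of 0.4 SD. Demographic units follow
#' realistic neonatal cohorts: gestational age 261 +/- 18.27 days,
#' birthweight 2805.6 +/- 685.4 g, maternal education 15.3 +/- 3.33 years.
#'
#' @param n_subjects cohort size.
#' @param n_regions regions per matrix (connections = n(n-1)/2).
#' @param n_coupled number K of connections coupled to the latent cognitive
#'   score.
#' @param effect_size coupling magnitude beta, in units of the
#'   across-subject connection noise SD.
#' @param frac_negative fraction of coupled connections with negative
#'   coupling sign.
#' @param subgroup_flip_fraction fraction of subjects whose coupled-
#'   connection signs are flipped (heterogeneous brain-behavior mapping;
#'   the flip applies to the brain side only, IQ marginals are unchanged).
#' @param connection_noise_sd across-subject SD of each connection.
#' @param baseline_mean,baseline_sd mean and spread of the per-connection
#'   baseline (population) connectivity values.
#' @param iq_mean,iq_sd outcome IQ mean and SD.
#' @param latent_weight share of IQ variance carried by the latent score g
#'   (in `[0, 1]`).
#' @param demographic_iq_r length-3 vector of target demographic-IQ
#'   correlations (gestational age, birthweight, maternal education).
#' @param control_fraction probability of CONTROL group membership.
#' @param risk_iq_shift IQ shift of RISK subjects in `iq_sd` units
#'   (default -0.4).
#' @param seed integer seed; fixes the population (baseline means, coupled
#'   connections, coupling signs) and, together with `cohort_id` at
#'   generation time, the subjects.
#' @return validated `sim_params` list.
#' @export
sim_params <- function(n_subjects = 175L, n_regions = 222L,
                       n_coupled = 200L, effect_size = 1,
                       frac_negative = 0.5, subgroup_flip_fraction = 0,
                       connection_noise_sd = 0.15,
                       baseline_mean = 0.25, baseline_sd = 0.25,
                       iq_mean = 106.9, iq_sd = 11.8,
                       latent_weight = 0.5,
                       demographic_iq_r = c(ga_birth_days = 0.24,
                                            birthweight_g = 0.28,
                                            maternal_edu_years = 0.35),
                       control_fraction = 0.32, risk_iq_shift = -0.4,
                       seed = 1L) {
  p <- list(
    n_subjects = as.integer(n_subjects), n_regions = as.integer(n_regions),
    n_coupled = as.integer(n_coupled), effect_size = effect_size,
    frac_negative = frac_negative,
    subgroup_flip_fraction = subgroup_flip_fraction,
    connection_noise_sd = connection_noise_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    iq_mean = iq_mean, iq_sd = iq_sd, latent_weight = latent_weight,
    demographic_iq_r = demographic_iq_r,
    control_fraction = control_fraction, risk_iq_shift = risk_iq_shift,
    seed = as.integer(seed)
  )
  n_conn <- p$n_regions * (p$n_regions - 1) / 2
  stopifnot(
    p$n_subjects >= 2L, p$n_regions >= 2L,
    p$n_coupled >= 0L, p$n_coupled <= n_conn,
    p$effect_size >= 0,
    p$frac_negative >= 0, p$frac_negative <= 1,
    p$subgroup_flip_fraction >= 0, p$subgroup_flip_fraction <= 1,
    p$connection_noise_sd > 0, p$baseline_sd > 0, p$iq_sd > 0,
    p$latent_weight >= 0, p$latent_weight <= 1,
    length(p$demographic_iq_r) == 3L,
    all(abs(p$demographic_iq_r) < 1),
    p$control_fraction >= 0, p$control_fraction <= 1
  )
  p$n_connections <- as.integer(n_conn)
  class(p) <- "sim_params"
  p
}

# Population-level structure shared by all cohorts drawn from one seed:
# per-connection baseline means, coupled connection indices, coupling signs.
sim_population <- function(params) {
  with_seed(mix_seed(params$seed, 9001), {
    mu <- stats::rnorm(params$n_connections, params$baseline_mean,
                       params$baseline_sd)
    coupled <- sort(sample.int(params$n_connections, params$n_coupled))
    csign <- ifelse(stats::runif(params$n_coupled) < params$frac_negative,
                    -1, 1)
    list(mu = mu, coupled = coupled, coupling_sign = csign)
  })
}

#' Generate a synthetic cohort
#'
#' Per subject i: a latent cognitive score `g_i ~ N(0, 1)`; a subgroup sign
#' `s_i` flipped to -1 with probability `subgroup_flip_fraction`; coupled
#' connection k takes
#' `mu_k + beta * noise_sd * c_k * g_i * s_i + noise`, uncoupled
#' connections `mu_k + noise`. IQ couples to `g_i` directly (subgroup flips
#' change the brain-behavior mapping, not the outcome marginals):
#' `IQ_i = iq_mean + shift_i + iq_sd * (sqrt(w) g_i + sqrt(1-w) eta_i)`
#' with `shift_i = risk_iq_shift * iq_sd` for RISK subjects. Continuous
#' demographics are drawn Gaussian, correlated with the realized IQ
#' Z-score at the target correlations. Group membership (CONTROL vs RISK)
#' is drawn by `control_fraction`; RISK subjects receive at least one of
#' twin birth, preterm birth, or maternal-disorder diagnosis.
#'
#' Cohorts generated with the same `seed` but different `cohort_id` share
#' one population (baseline connectivity, coupled connections, coupling
#' signs) with independent subjects — i.e., disjoint samples from the same
#' population, as needed for external-reference designs.
#'
#' @param params a [sim_params()] object.
#' @param cohort_id integer distinguishing cohorts from one population.
#' @param label cohort label.
#' @return a `tripleo_cohort` whose `truth` field records the latent
#'   scores, subgroup signs, coupled connections and coupling signs (kept
#'   out of the manifest so pipeline code cannot read it by accident).
#' @export
generate_cohort <- function(params, cohort_id = 1L, label = NULL) {
  stopifnot(inherits(params, "sim_params"))
  pop <- sim_population(params)
  n <- params$n_subjects
  p <- params$n_connections

  with_seed(mix_seed(params$seed, 101, cohort_id), {
    g <- stats::rnorm(n)
    s <- ifelse(stats::runif(n) < params$subgroup_flip_fraction, -1, 1)
    group <- ifelse(stats::runif(n) < params$control_fraction,
                    "CONTROL", "RISK")

    # connectivity
    X <- matrix(stats::rnorm(n * p, 0, params$connection_noise_sd), n, p)
    X <- sweep(X, 2L, pop$mu, "+")
    if (params$n_coupled > 0L && params$effect_size > 0) {
      X[, pop$coupled] <- X[, pop$coupled] +
        params$effect_size * params$connection_noise_sd *
        outer(g * s, pop$coupling_sign)
    }

    # outcome IQ
    w <- params$latent_weight
    eta <- stats::rnorm(n)
    shift <- ifelse(group == "RISK", params$risk_iq_shift * params$iq_sd, 0)
    iq <- params$iq_mean + shift +
      params$iq_sd * (sqrt(w) * g + sqrt(1 - w) * eta)

    # continuous demographics, correlated with realized IQ
    z_iq <- (iq - mean(iq)) / stats::sd(iq)
    demo_units <- list(
      ga_birth_days = c(mean = 261, sd = 18.27),
      birthweight_g = c(mean = 2805.61, sd = 685.42),
      maternal_edu_years = c(mean = 15.3, sd = 3.33)
    )
    demo <- matrix(NA_real_, n, 3L,
                   dimnames = list(NULL, names(demo_units)))
    for (j in 1:3) {
      r <- params$demographic_iq_r[j]
      d_std <- r * z_iq + sqrt(1 - r^2) * stats::rnorm(n)
      u <- demo_units[[j]]
      demo[, j] <- u["mean"] + u["sd"] * d_std
    }

    # categorical risk factors: CONTROL subjects carry none; RISK subjects
    # at least one (twin births dominate, as in mixed neonatal cohorts)
    twin <- preterm <- disorder <- rep(FALSE, n)
    risk_idx <- which(group == "RISK")
    for (i in risk_idx) {
      repeat {
        f <- stats::runif(3) < c(0.65, 0.45, 0.15)
        if (any(f)) break
      }
      twin[i] <- f[1L]; preterm[i] <- f[2L]; disorder[i] <- f[3L]
    }
    sex <- ifelse(stats::runif(n) < 0.5, "M", "F")

    subjects <- data.frame(
      subject_id = sprintf("C%d_S%03d", cohort_id, seq_len(n)),
      matrix_path = sprintf("matrices/C%d_S%03d.txt", cohort_id, seq_len(n)),
      sex = sex,
      term_status = ifelse(preterm, "PRETERM", "FULL_TERM"),
      twin_status = ifelse(twin, "TWIN", "SINGLETON"),
      maternal_disorder = ifelse(disorder, "YES", "NO"),
      ga_birth_days = demo[, "ga_birth_days"],
      birthweight_g = demo[, "birthweight_g"],
      maternal_edu_years = demo[, "maternal_edu_years"],
      iq = iq,
      stringsAsFactors = FALSE
    )
    rownames(X) <- subjects$subject_id

    truth <- list(
      g = g, subgroup_sign = s, group = group,
      coupled = pop$coupled, coupling_sign = pop$coupling_sign,
      baseline_mu = pop$mu,
      iq_map = paste(
        "iq = iq_mean + risk_shift + iq_sd * (sqrt(latent_weight) * g",
        "+ sqrt(1 - latent_weight) * eta); connections couple to g * s"
      )
    )
    new_cohort(subjects = subjects, vectors = X,
               n_regions = params$n_regions,
               label = label %||% sprintf("synthetic_%d_%d",
                                          params$seed, cohort_id),
               truth = truth, params = params)
  })
}

#' Write a cohort to the on-disk layout the pipeline consumes
#'
#' Writes one dense text matrix per subject under `matrices/`, the cohort
#' manifest as `manifest.csv`, and — for synthetic cohorts — the hidden
#' truth record under `truth/` (a separate directory never referenced by
#' the manifest, so analysis code cannot read it by accident).
#'
#' @param cohort a `tripleo_cohort`.
#' @param out_dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "tripleo_cohort"))
  dir.create(file.path(out_dir, "matrices"), recursive = TRUE,
             showWarnings = FALSE)
  for (i in seq_len(nrow(cohort$subjects))) {
    m <- connectivity_from_vector(cohort$vectors[i, ], cohort$n_regions)
    write_connectivity_matrix(
      m, file.path(out_dir, cohort$subjects$matrix_path[i])
    )
  }
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(cohort$subjects, manifest_path, row.names = FALSE)
  if (!is.null(cohort$truth)) {
    truth_dir <- file.path(out_dir, "truth")
    dir.create(truth_dir, showWarnings = FALSE)
    utils::write.csv(
      data.frame(subject_id = cohort$subjects$subject_id,
                 g = cohort$truth$g,
                 subgroup_sign = cohort$truth$subgroup_sign,
                 group = cohort$truth$group),
      file.path(truth_dir, "subjects.csv"), row.names = FALSE
    )
    utils::write.csv(
      data.frame(coupled_index = cohort$truth$coupled,
                 coupling_sign = cohort$truth$coupling_sign),
      file.path(truth_dir, "couplings.csv"), row.names = FALSE
    )
  }
  invisible(manifest_path)
}
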