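# Run configuration: defaults, validation, YAML loading.

#' Build a validated run configuration
#'
#' Collects every threshold and policy the pipeline honours, with the
#' framework's standard values as defaults. Unknown keys fail fast, named.
#'
#' @param connection_z,measure_z,iq_z Z thresholds (all default 1.645).
#' @param min_votes measure indicators needed for a brain-outlier call
#'   (1-3, default 2).
#' @param connection_sidedness `"two_sided"` (default) or `"upper"`.
#' @param self_exclusion drop a subject's own m2 term when it is in the
#'   reference (default `TRUE`).
#' @param zero_variance `"error"` (default) or `"zero"`.
#' @param missing_policy CDRI missing-component policy: `"require_all"`
#'   (default) or `"use_available"`.
#' @param rounding report decimals, default 1.
#' @param seed integer seed for any stochastic step, default 1.
#' @param sizes,n_replicates sweep settings (defaults 10, 25, 50, 100, 150
#'   and 100 replicates).
#' @return a validated `tripleo_config` list.
#' @export
tripleo_config <- function(connection_z = 1.645, measure_z = 1.645,
                           iq_z = 1.645, min_votes = 2L,
                           connection_sidedness = "two_sided",
                           self_exclusion = TRUE,
                           zero_variance = "error",
                           missing_policy = "require_all",
                           rounding = 1L, seed = 1L,
                           sizes = c(10L, 25L, 50L, 100L, 150L),
                           n_replicates = 100L) {
  cfg <- list(
    connection_z = connection_z, measure_z = measure_z, iq_z = iq_z,
    min_votes = as.integer(min_votes),
    connection_sidedness = connection_sidedness,
    self_exclusion = isTRUE(self_exclusion),
    zero_variance = zero_variance, missing_policy = missing_policy,
    rounding = as.integer(rounding), seed = as.integer(seed),
    sizes = as.integer(sizes), n_replicates = as.integer(n_replicates)
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  for (key in c("connection_z", "measure_z", "iq_z")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("config key '%s' must be a single positive number", key))
    }
  }
  if (!cfg$min_votes %in% 1:3) stop("config key 'min_votes' must be 1, 2 or 3")
  if (!cfg$connection_sidedness %in% c("two_sided", "upper")) {
    stop("config key 'connection_sidedness' must be 'two_sided' or 'upper'")
  }
  if (!cfg$zero_variance %in% c("error", "zero")) {
    stop("config key 'zero_variance' must be 'error' or 'zero'")
  }
  if (!cfg$missing_policy %in% c("require_all", "use_available")) {
    stop("config key 'missing_policy' must be 'require_all' or 'use_available'")
  }
  if (any(cfg$sizes < 2L)) stop("config key 'sizes' entries must be >= 2")
  if (cfg$n_replicates < 1L) stop("config key 'n_replicates' must be >= 1")
  class(cfg) <- "tripleo_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Keys in the file override the built-in defaults; `overrides` (e.g. from
#' command-line flags) override both. Unknown keys are rejected by name.
#'
#' @param path YAML config file, or `NULL` for pure defaults.
#' @param overrides named list of final overrides.
#' @return a validated `tripleo_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- unclass(tripleo_config())
  from_file <- if (is.null(path)) list() else yaml::read_yaml(path)
  for (src in list(from_file, overrides)) {
    if (length(src) == 0L) next
    unknown <- setdiff(names(src), names(cfg))
    if (length(unknown) > 0L) {
      stop(sprintf("unknown config key(s): %s",
                   paste(unknown, collapse = ", ")))
    }
    for (key in names(src)) {
      cfg[[key]] <- if (key %in% c("min_votes", "rounding", "seed",
                                   "sizes", "n_replicates")) {
        as.integer(src[[key]])
      } else if (key == "self_exclusion") {
        isTRUE(src[[key]])
      } else {
        src[[key]]
      }
    }
  }
  validate_config(cfg)
}
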