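# Internal helpers: seed substreams, RNG scoping, rounding, column SDs.

#' Derive a deterministic seed substream from integer components
#'
#' Mixes an arbitrary number of integer-valued components into a single seed
#' below 2^31, so that e.g. the (size, replicate) cells of a resampling sweep
#' each get an independent, reproducible stream and adding new sizes never
#' perturbs existing replicates.
#'
#' @param ... integer-valued numeric components (base seed first by
#'   convention).
#' @return a single integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' mix_seed(42, 50, 3)
mix_seed <- function(...) {
  parts <- as.numeric(c(...))
  if (length(parts) == 0L || any(!is.finite(parts))) {
    stop("mix_seed() needs at least one finite component")
  }
  # multiplicative congruential mix; 69069 * modulus < 2^53 so doubles are exact
  h <- 104729
  for (x in parts) {
    h <- (h * 69069 + (abs(x) %% 2147483629) + 1) %% 2147483629
  }
  as.integer(h)
}

# Evaluate `expr` under `set.seed(seed)` and restore the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Half-up decimal rounding (report tables print e.g. 96.15 -> 96.2).
round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Sample SDs (n-1) of the columns of a matrix, two-pass for stability.
col_sds <- function(X) {
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 rows to compute column SDs")
  mu <- colMeans(X)
  sqrt(colSums(sweep(X, 2L, mu)^2) / (n - 1))
}

# Sample SDs (n-1) of the rows of a matrix.
row_sds <- function(X) {
  p <- ncol(X)
  if (p < 2L) stop("need at least 2 columns to compute row SDs")
  mu <- rowMeans(X)
  sqrt(rowSums((X - mu)^2) / (p - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
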