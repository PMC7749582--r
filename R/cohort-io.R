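# Connectivity-matrix and cohort-manifest I/O, validation, Fisher-Z transform.

SEX_LEVELS <- c("M", "F", "UNKNOWN")
TERM_LEVELS <- c("FULL_TERM", "PRETERM", "UNKNOWN")
TWIN_LEVELS <- c("SINGLETON", "TWIN", "UNKNOWN")
YESNO_LEVELS <- c("YES", "NO", "UNKNOWN")

MANIFEST_REQUIRED <- c("subject_id", "matrix_path")
MANIFEST_OPTIONAL <- c(
  "sex", "term_status", "twin_status", "maternal_disorder",
  "ga_birth_days", "birthweight_g", "maternal_edu_years", "iq"
)

#' Construct and validate a connectivity matrix
#'
#' A `connectivity_matrix` holds one subject's square symmetric region-by-
#' region connectivity values, either raw Pearson correlations (`"raw_r"`)
#' or Fisher-Z transformed values (`"fisher_z"`). The diagonal
#' (self-connections) is carried but never used by any downstream analysis.
#'
#' @param values square numeric matrix.
#' @param subject_id subject identifier string.
#' @param scale `"raw_r"` or `"fisher_z"`.
#' @param tol absolute symmetry tolerance; asymmetry within `tol` is
#'   symmetrized by averaging with the transpose, beyond it is an error.
#' @return an object of class `connectivity_matrix` with fields `values`,
#'   `subject_id`, `n_regions`, `scale`.
#' @export
connectivity_matrix <- function(values, subject_id = "subject",
                                scale = c("fisher_z", "raw_r"),
                                tol = 1e-8) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("connectivity values must be numeric")
  if (nrow(values) != ncol(values)) {
    stop(sprintf("connectivity matrix must be square, got %d x %d",
                 nrow(values), ncol(values)))
  }
  n <- nrow(values)
  if (n < 2L) stop("connectivity matrix needs at least 2 regions")
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-finite connectivity value at row %d, column %d",
                 bad[1L, 1L], bad[1L, 2L]))
  }
  asym <- abs(values - t(values))
  if (max(asym) > tol) {
    w <- which(asym == max(asym), arr.ind = TRUE)
    stop(sprintf(
      "asymmetry %.3g beyond tolerance %g at row %d, column %d",
      max(asym), tol, w[1L, 1L], w[1L, 2L]
    ))
  }
  values <- (values + t(values)) / 2
  if (scale == "raw_r") {
    off <- abs(values) > 1 & row(values) != col(values)
    if (any(off)) {
      w <- which(off, arr.ind = TRUE)
      stop(sprintf(
        "raw correlation outside [-1, 1] at row %d, column %d (value %.4g)",
        w[1L, 1L], w[1L, 2L], values[w[1L, , drop = FALSE]]
      ))
    }
  }
  dimnames(values) <- NULL
  structure(
    list(subject_id = as.character(subject_id), values = values,
         n_regions = n, scale = scale),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix: subject '%s', %d x %d regions, scale %s\n",
              x$subject_id, x$n_regions, x$n_regions, x$scale))
  invisible(x)
}

#' Read a connectivity matrix from a dense numeric text file
#'
#' The file dialect is plain dense numeric text, one matrix per file,
#' whitespace- or comma-delimited, no header.
#'
#' @param path path to the matrix file.
#' @param scale scale of the stored values, `"fisher_z"` (default) or
#'   `"raw_r"`.
#' @param subject_id subject identifier; defaults to the file name without
#'   extension.
#' @param tol symmetry tolerance, see [connectivity_matrix()].
#' @return a validated [connectivity_matrix()].
#' @export
read_connectivity_matrix <- function(path, scale = c("fisher_z", "raw_r"),
                                     subject_id = NULL, tol = 1e-8) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop(sprintf("matrix file not found: %s", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          strip.white = TRUE, colClasses = "numeric")
  m <- as.matrix(df)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  connectivity_matrix(m, subject_id = subject_id, scale = scale, tol = tol)
}

#' Write a connectivity matrix to a dense numeric text file
#'
#' Values are written with 17 significant digits so a read/write/read round
#' trip reproduces them to better than 1e-12.
#'
#' @param matrix a [connectivity_matrix()] or plain square numeric matrix.
#' @param path output path.
#' @param sep field separator, `" "` (default) or `","`.
#' @return `path`, invisibly.
#' @export
write_connectivity_matrix <- function(matrix, path, sep = " ") {
  m <- if (inherits(matrix, "connectivity_matrix")) matrix$values else matrix
  lines <- apply(m, 1L, function(r) {
    paste(formatC(r, digits = 17, format = "g"), collapse = sep)
  })
  writeLines(lines, path)
  invisible(path)
}

#' Fisher-Z transform a raw-correlation connectivity matrix
#'
#' Applies `atanh` to every off-diagonal entry after clipping to
#' `[-(1 - clamp), 1 - clamp]`, which keeps degenerate correlations of
#' exactly +/-1 finite. The diagonal is set to 0. Applying the transform to
#' an already Fisher-Z matrix is an error (double-transform guard).
#'
#' @param matrix a [connectivity_matrix()] with scale `"raw_r"`.
#' @param clamp clipping margin in (0, 1); default `1e-7`.
#' @return a [connectivity_matrix()] with scale `"fisher_z"`.
#' @export
#' @examples
#' m <- connectivity_matrix(diag(3) * 0 + 0.5 * (1 - diag(3)) + diag(3),
#'                          scale = "raw_r")
#' fisher_z_transform(m)$values[1, 2]  # atanh(0.5) = 0.5493
fisher_z_transform <- function(matrix, clamp = 1e-7) {
  if (!inherits(matrix, "connectivity_matrix")) {
    stop("fisher_z_transform() expects a connectivity_matrix")
  }
  if (matrix$scale != "raw_r") {
    stop("matrix is already Fisher-Z transformed (scale is not 'raw_r')")
  }
  if (!is.numeric(clamp) || clamp <= 0 || clamp >= 1) {
    stop("clamp must be in (0, 1)")
  }
  v <- pmin(pmax(matrix$values, -(1 - clamp)), 1 - clamp)
  z <- atanh(v)
  diag(z) <- 0
  connectivity_matrix(z, subject_id = matrix$subject_id, scale = "fisher_z")
}

#' Vectorize a connectivity matrix to its unique connections
#'
#' Extracts the upper triangle (i < j) in row-major order, excluding the
#' diagonal, giving a vector of length `n_regions * (n_regions - 1) / 2`
#' (24,531 for a 222-region matrix).
#'
#' @param matrix a [connectivity_matrix()] or plain square symmetric matrix.
#' @return numeric connection vector.
#' @export
vectorize_connectivity <- function(matrix) {
  m <- if (inherits(matrix, "connectivity_matrix")) matrix$values else matrix
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  # for a symmetric matrix the column-major lower triangle equals the
  # row-major upper triangle: (1,2), (1,3), ..., (1,n), (2,3), ...
  m[lower.tri(m)]
}

#' Rebuild a symmetric matrix from a connection vector
#'
#' Inverse of [vectorize_connectivity()]; the diagonal is filled with
#' `diag_value` (connectivity self-values are ignored downstream).
#'
#' @param vec connection vector of length `n * (n - 1) / 2`.
#' @param n_regions number of regions `n`.
#' @param diag_value diagonal fill, default 0.
#' @return an `n_regions` x `n_regions` symmetric numeric matrix.
#' @export
connectivity_from_vector <- function(vec, n_regions, diag_value = 0) {
  expected <- n_regions * (n_regions - 1) / 2
  if (length(vec) != expected) {
    stop(sprintf("connection vector length %d does not match %d regions (%d)",
                 length(vec), n_regions, expected))
  }
  m <- matrix(0, n_regions, n_regions)
  m[lower.tri(m)] <- vec
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

# number of regions implied by a connection-vector length
n_regions_from_length <- function(p) {
  n <- (1 + sqrt(1 + 8 * p)) / 2
  if (abs(n - round(n)) > 1e-9) {
    stop(sprintf("length %d is not a triangular number n*(n-1)/2", p))
  }
  as.integer(round(n))
}

#' Read a cohort manifest
#'
#' The manifest is a delimited table (CSV, or TSV for `.tsv` files) with a
#' header and one row per subject. Columns `subject_id` and `matrix_path`
#' are required; the optional columns are `sex`, `term_status`,
#' `twin_status`, `maternal_disorder`, `ga_birth_days`, `birthweight_g`,
#' `maternal_edu_years` and `iq`. Missing optional values stay missing
#' (`NA` / `"UNKNOWN"`); they are never imputed, and operations that need
#' them refuse the affected subjects later.
#'
#' @param path manifest file path.
#' @param eager if `TRUE`, verify at load time that every `matrix_path`
#'   exists (resolved relative to the manifest's directory when relative).
#' @return a `data.frame` of subject records, in file row order, with
#'   attribute `manifest_dir`.
#' @export
read_cohort_manifest <- function(path, eager = FALSE) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  # read as character first: sex columns of all "F" must not become logical
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", strip.white = TRUE)
  missing_req <- setdiff(MANIFEST_REQUIRED, names(df))
  if (length(missing_req) > 0L) {
    stop(sprintf("manifest missing required column(s): %s",
                 paste(missing_req, collapse = ", ")))
  }
  df$subject_id <- as.character(df$subject_id)
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate subject_id in manifest: %s",
                 paste(unique(dup), collapse = ", ")))
  }
  for (col in c("sex", "term_status", "twin_status", "maternal_disorder")) {
    levels <- switch(col,
      sex = SEX_LEVELS, term_status = TERM_LEVELS,
      twin_status = TWIN_LEVELS, maternal_disorder = YESNO_LEVELS
    )
    if (!col %in% names(df)) {
      df[[col]] <- "UNKNOWN"
    } else {
      df[[col]] <- toupper(as.character(df[[col]]))
      df[[col]][is.na(df[[col]]) | df[[col]] %in% c("", "NA")] <- "UNKNOWN"
      bad <- setdiff(unique(df[[col]]), levels)
      if (length(bad) > 0L) {
        stop(sprintf("invalid %s value(s): %s (allowed: %s)",
                     col, paste(bad, collapse = ", "),
                     paste(levels, collapse = ", ")))
      }
    }
  }
  for (col in c("ga_birth_days", "birthweight_g", "maternal_edu_years", "iq")) {
    if (!col %in% names(df)) {
      df[[col]] <- NA_real_
    } else {
      vals <- df[[col]]
      vals[vals %in% c("", "NA")] <- NA_character_
      num <- suppressWarnings(as.numeric(vals))
      bad <- !is.na(vals) & (is.na(num) | !is.finite(num))
      if (any(bad)) {
        stop(sprintf("non-numeric or non-finite value in column %s: '%s'",
                     col, vals[bad][1L]))
      }
      df[[col]] <- num
    }
  }
  attr(df, "manifest_dir") <- dirname(normalizePath(path))
  if (eager) {
    paths <- resolve_matrix_paths(df)
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0L) {
      stop(sprintf("matrix file(s) not found: %s",
                   paste(utils::head(missing, 3L), collapse = ", ")))
    }
  }
  df
}

resolve_matrix_paths <- function(manifest) {
  base <- attr(manifest, "manifest_dir") %||% "."
  ifelse(grepl("^(/|[A-Za-z]:)", manifest$matrix_path),
         manifest$matrix_path,
         file.path(base, manifest$matrix_path))
}

#' Read a full cohort: manifest plus all connectivity matrices
#'
#' Loads the manifest, reads every subject's matrix, checks that all share
#' one region count, and returns the cohort with matrices already
#' vectorized (upper triangle), the form every analysis consumes.
#'
#' @param path a manifest file, or a directory containing `manifest.csv`.
#' @param scale stored scale of the matrices (see
#'   [read_connectivity_matrix()]).
#' @param label cohort label.
#' @return a `tripleo_cohort`: list with `subjects` (the manifest
#'   data.frame), `vectors` (subjects x connections matrix, rownames =
#'   subject ids), `n_regions` and `label`.
#' @export
read_cohort <- function(path, scale = c("fisher_z", "raw_r"), label = NULL) {
  scale <- match.arg(scale)
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  manifest <- read_cohort_manifest(path, eager = TRUE)
  paths <- resolve_matrix_paths(manifest)
  vecs <- vector("list", nrow(manifest))
  n_regions <- NULL
  for (i in seq_len(nrow(manifest))) {
    cm <- read_connectivity_matrix(paths[i], scale = scale,
                                   subject_id = manifest$subject_id[i])
    if (is.null(n_regions)) {
      n_regions <- cm$n_regions
    } else if (cm$n_regions != n_regions) {
      stop(sprintf(
        "subject '%s' has %d regions but cohort has %d",
        manifest$subject_id[i], cm$n_regions, n_regions
      ))
    }
    vecs[[i]] <- vectorize_connectivity(cm)
  }
  X <- do.call(rbind, vecs)
  rownames(X) <- manifest$subject_id
  new_cohort(subjects = manifest, vectors = X, n_regions = n_regions,
             label = label %||% basename(dirname(path)))
}

new_cohort <- function(subjects, vectors, n_regions, label = "cohort",
                       truth = NULL, params = NULL) {
  structure(
    list(subjects = subjects, vectors = vectors, n_regions = n_regions,
         label = label, truth = truth, params = params),
    class = "tripleo_cohort"
  )
}

#' @export
print.tripleo_cohort <- function(x, ...) {
  cat(sprintf(
    "tripleo_cohort '%s': %d subjects, %d regions (%d connections)\n",
    x$label, nrow(x$subjects), x$n_regions, ncol(x$vectors)
  ))
  cat(sprintf("  IQ available: %d; synthetic truth: %s\n",
              sum(!is.na(x$subjects$iq)), !is.null(x$truth)))
  invisible(x)
}
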