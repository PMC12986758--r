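# Data model and readers for parcellated BOLD time series, functional
# connectivity, the shared spatial adjacency and sliding-window segmentation.

#' Construct a parcellated ROI time series
#'
#' An `roi_timeseries` holds one subject's T x N matrix of region-averaged
#' BOLD signal (rows are timepoints, columns are atlas regions), the ordered
#' region labels and the repetition time.
#'
#' @param values Numeric T x N matrix, timepoints in rows.
#' @param region_labels Character vector of N region labels, in column order.
#' @param subject_id Subject identifier.
#' @param tr_seconds Repetition time in seconds (default 2, the acquisition
#'   this package targets).
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, region_labels, subject_id = "subject",
                           tr_seconds = 2) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L) {
    abort("A time series needs at least 2 timepoints.",
          class = "stgcnet_error_shape")
  }
  if (length(region_labels) != ncol(values)) {
    abort(sprintf("%d region labels supplied for %d columns.",
                  length(region_labels), ncol(values)),
          class = "stgcnet_error_shape")
  }
  if (anyDuplicated(region_labels)) {
    abort("Region labels must be unique.", class = "stgcnet_error_labels")
  }
  if (!all(is.finite(values))) {
    abort("Time series contains non-finite values.",
          class = "stgcnet_error_nonfinite")
  }
  sds <- apply(values, 2L, sd)
  if (any(sds == 0)) {
    bad <- region_labels[sds == 0]
    abort(paste0("Zero-variance region column(s): ",
                 paste(bad, collapse = ", ")),
          class = "stgcnet_error_zero_variance")
  }
  stopifnot_scalar_number(tr_seconds, "tr_seconds", positive = TRUE)
  dimnames(values) <- list(NULL, region_labels)
  structure(
    list(subject_id = as.character(subject_id), values = values,
         region_labels = as.character(region_labels),
         tr_seconds = tr_seconds),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> subject %s: %d timepoints x %d regions (TR = %gs)\n",
              x$subject_id, nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}

#' @export
dim.roi_timeseries <- function(x) dim(x$values)

#' Read a parcellated time series from delimited text
#'
#' Rows are timepoints and columns are regions; comma or tab delimiters are
#' auto-detected and a header line is optional. If both a header and `labels`
#' are given they must agree in order.
#'
#' @param path Path to a CSV/TSV file.
#' @param labels Optional character vector of expected region labels.
#' @param subject_id Subject identifier (defaults to the file name).
#' @param tr_seconds Repetition time in seconds.
#' @return An [roi_timeseries()].
#' @export
read_roi_timeseries <- function(path, labels = NULL, subject_id = NULL,
                                tr_seconds = 2) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "stgcnet_error_io")
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  fields <- strsplit(first, sep, fixed = TRUE)[[1L]]
  has_header <- suppressWarnings(any(is.na(as.numeric(fields))))
  dat <- utils::read.table(path, sep = sep, header = has_header,
                           check.names = FALSE, colClasses = "character")
  mat <- suppressWarnings(apply(as.matrix(dat), c(1, 2), as.numeric))
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    abort(sprintf("Non-numeric cell at row %d, column %d of %s.",
                  bad[1L], bad[2L], path),
          class = "stgcnet_error_nonnumeric")
  }
  file_labels <- if (has_header) colnames(dat) else NULL
  if (!is.null(labels)) {
    if (length(labels) != ncol(mat)) {
      abort(sprintf("File %s has %d columns but %d labels were supplied.",
                    path, ncol(mat), length(labels)),
            class = "stgcnet_error_shape")
    }
    if (!is.null(file_labels) && !identical(as.character(file_labels),
                                            as.character(labels))) {
      abort("File header does not match the supplied labels (order matters).",
            class = "stgcnet_error_labels")
    }
  }
  use_labels <- labels %||% file_labels %||% sprintf("R%03d", seq_len(ncol(mat)))
  roi_timeseries(mat, use_labels,
                 subject_id = subject_id %||% sub("\\.[^.]*$", "", basename(path)),
                 tr_seconds = tr_seconds)
}

#' Write a parcellated time series as CSV
#'
#' @param ts An [roi_timeseries()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_timeseries <- function(ts, path) {
  utils::write.table(ts$values, path, sep = ",", row.names = FALSE,
                     col.names = ts$region_labels, quote = FALSE)
  invisible(path)
}

#' Validate (and coerce) a cohort manifest
#'
#' The manifest is a tibble with one row per subject: `subject_id`, `group`
#' (`"patient"` or `"control"`), `age_years`, `sex` (`"male"`/`"female"`),
#' `education_years`, optionally `symptom_score` (patients only) and
#' `series_path`.
#'
#' @param manifest A data frame.
#' @return The validated manifest as a tibble.
#' @export
validate_manifest <- function(manifest) {
  manifest <- tibble::as_tibble(manifest)
  needed <- c("subject_id", "group", "age_years", "sex", "education_years")
  missing <- setdiff(needed, names(manifest))
  if (length(missing)) {
    abort(paste0("Manifest is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "stgcnet_error_manifest")
  }
  if (anyDuplicated(manifest$subject_id)) {
    abort("Manifest subject_ids must be unique.",
          class = "stgcnet_error_manifest")
  }
  if (!all(manifest$group %in% c("patient", "control"))) {
    abort("Manifest group must be 'patient' or 'control'.",
          class = "stgcnet_error_manifest")
  }
  if (length(unique(manifest$group)) < 2L) {
    abort("Manifest must contain both groups.",
          class = "stgcnet_error_manifest")
  }
  manifest
}

#' Read / write a cohort manifest CSV
#'
#' @param path CSV path.
#' @return [read_manifest()] returns a validated tibble.
#' @export
read_manifest <- function(path) {
  validate_manifest(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_manifest
#' @param manifest A manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(validate_manifest(manifest), path, row.names = FALSE)
  invisible(path)
}

#' AAL 90-region labels
#'
#' The standard 90-region Automated Anatomical Labeling cortical/subcortical
#' parcellation, in conventional atlas order (left/right interleaved),
#' shipped as a plain-text fixture.
#'
#' @return Character vector of 90 labels.
#' @export
aal90_labels <- function() {
  path <- system.file("extdata", "aal90_labels.txt", package = "stgcnet")
  readLines(path)
}

#' Load a cohort's series into memory
#'
#' Reads every subject's series (from `series_path`, relative to `base_dir`)
#' and attaches it as a list-column `series`.
#'
#' @param manifest A manifest with a `series_path` column.
#' @param base_dir Directory that `series_path` is relative to.
#' @param labels Optional expected region labels.
#' @return The manifest tibble with a `series` list-column.
#' @export
load_cohort <- function(manifest, base_dir = ".", labels = NULL) {
  manifest <- validate_manifest(manifest)
  if (!"series_path" %in% names(manifest)) {
    abort("Manifest has no series_path column.",
          class = "stgcnet_error_manifest")
  }
  manifest$series <- purrr::map2(
    manifest$series_path, manifest$subject_id,
    function(p, id) read_roi_timeseries(file.path(base_dir, p),
                                        labels = labels, subject_id = id)
  )
  check_cohort_labels(manifest)
  manifest
}

check_cohort_labels <- function(cohort) {
  labs <- purrr::map(cohort$series, "region_labels")
  ref <- labs[[1L]]
  ok <- purrr::map_lgl(labs, identical, y = ref)
  if (!all(ok)) {
    abort(sprintf("Region labels differ across subjects (first mismatch: %s).",
                  cohort$subject_id[which(!ok)[1L]]),
          class = "stgcnet_error_labels")
  }
  invisible(ref)
}

#' Pearson functional connectivity
#'
#' Correlates every pair of region time courses, giving the subject's static
#' N x N functional-connectivity matrix.
#'
#' @param ts An [roi_timeseries()].
#' @return An `fc_matrix` with `transform = "pearson"`.
#' @export
pearson_fc <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  r <- cor(ts$values)
  r <- (r + t(r)) / 2
  structure(
    list(values = r, transform = "pearson", region_labels = ts$region_labels,
         subject_id = ts$subject_id),
    class = "fc_matrix"
  )
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %s, %d regions (%s)\n", x$transform,
              ncol(x$values), x$subject_id %||% "?"))
  invisible(x)
}

#' Fisher z transform of a correlation matrix
#'
#' Applies `z = atanh(r)` off-diagonal to variance-stabilise correlations;
#' the diagonal is stored as 0 because `atanh(1)` is undefined. Off-diagonal
#' correlations at exactly +/-1 are clipped to `1 - 1e-7` with a warning.
#'
#' @param fc An `fc_matrix` with `transform = "pearson"`.
#' @return An `fc_matrix` with `transform = "fisher_z"`.
#' @export
fisher_z <- function(fc) {
  stopifnot(inherits(fc, "fc_matrix"))
  if (!identical(fc$transform, "pearson")) {
    abort("fisher_z() expects a pearson fc_matrix.",
          class = "stgcnet_error_transform")
  }
  eps <- 1e-7
  r <- fc$values
  diag(r) <- 0
  clip <- abs(r) >= 1
  if (any(clip)) {
    warn(sprintf("%d off-diagonal correlation(s) at |r| >= 1 clipped to 1 - 1e-7.",
                 sum(clip)))
    r[clip] <- sign(r[clip]) * (1 - eps)
  }
  z <- atanh(r)
  diag(z) <- 0
  fc$values <- z
  fc$transform <- "fisher_z"
  fc
}

#' Read / write a connectivity or adjacency matrix
#'
#' Labelled CSV for interchange (`write_fc_matrix()` / `read_fc_matrix()`);
#' for speed-critical round trips an RDS checkpoint of the full object is
#' the binary container (`saveRDS`/`readRDS` of the `fc_matrix`).
#'
#' @param fc An `fc_matrix` or `shared_adjacency`.
#' @param path CSV path.
#' @export
write_fc_matrix <- function(fc, path) {
  vals <- if (inherits(fc, "shared_adjacency")) fc$W else fc$values
  labels <- if (inherits(fc, "shared_adjacency")) fc$region_labels else
    fc$region_labels
  dimnames(vals) <- list(labels, labels)
  utils::write.csv(vals, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_fc_matrix
#' @param transform Transform tag for the reconstructed `fc_matrix`.
#' @export
read_fc_matrix <- function(path, transform = "fisher_z") {
  dat <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  vals <- as.matrix(dat)
  if (!identical(rownames(vals), colnames(vals))) {
    abort("Row and column labels disagree.", class = "stgcnet_error_labels")
  }
  structure(
    list(values = vals, transform = transform,
         region_labels = colnames(vals), subject_id = NULL),
    class = "fc_matrix"
  )
}

#' Group-level shared spatial adjacency
#'
#' Builds the single spatial edge-weight matrix used by every subject:
#' subjects' series are concatenated along time (in canonical `subject_id`
#' order, so the result does not depend on manifest row order), Pearson
#' correlation and the Fisher z transform are applied to the long series,
#' and the absolute value is taken with the diagonal zeroed. A
#' `max(z, 0)`-style positive-part alternative is available via
#' `negative = "clip"`.
#'
#' @param cohort A cohort tibble with a `series` list-column (see
#'   [load_cohort()] or [simulate_cohort()]).
#' @param negative How negative Fisher z weights enter the adjacency:
#'   `"absolute"` (default) or `"clip"` (negative weights set to 0).
#' @return A `shared_adjacency` object with fields `W`, `region_labels` and
#'   `provenance` (the subject ids used).
#' @export
build_shared_adjacency <- function(cohort, negative = c("absolute", "clip")) {
  negative <- match.arg(negative)
  if (nrow(cohort) < 2L) {
    abort("Need at least 2 subjects to build the shared adjacency.",
          class = "stgcnet_error_shape")
  }
  labels <- check_cohort_labels(cohort)
  ord <- order(cohort$subject_id)
  long <- do.call(rbind, purrr::map(cohort$series[ord], "values"))
  long_ts <- roi_timeseries(long, labels, subject_id = "pooled")
  z <- fisher_z(pearson_fc(long_ts))$values
  W <- if (negative == "absolute") abs(z) else pmax(z, 0)
  diag(W) <- 0
  W <- (W + t(W)) / 2
  structure(
    list(W = W, region_labels = labels,
         provenance = sort(cohort$subject_id), negative = negative),
    class = "shared_adjacency"
  )
}

#' @export
print.shared_adjacency <- function(x, ...) {
  cat(sprintf("<shared_adjacency> %d regions from %d subjects (%s weights)\n",
              ncol(x$W), length(x$provenance), x$negative))
  invisible(x)
}

#' Sliding-window specification
#'
#' The dynamic (sliding-window) dialect used throughout: stride fixed at 1 TR;
#' window starts are either every possible start (`"all"`) or
#' `n_segments_per_subject` starts drawn uniformly without replacement
#' (`"random"`, seeded).
#'
#' @param window_size Window length in TRs.
#' @param n_segments_per_subject Number of windows for the random policy.
#' @param start_policy `"random"` or `"all"`.
#' @param seed Integer seed for the random policy.
#' @return A `window_spec` object.
#' @export
window_spec <- function(window_size, n_segments_per_subject = 8L,
                        start_policy = c("random", "all"), seed = 1L) {
  start_policy <- match.arg(start_policy)
  stopifnot_scalar_number(window_size, "window_size", positive = TRUE)
  stopifnot_scalar_number(n_segments_per_subject, "n_segments_per_subject",
                          positive = TRUE)
  structure(
    list(window_size = as.integer(window_size), step = 1L,
         start_policy = start_policy,
         n_segments_per_subject = as.integer(n_segments_per_subject),
         seed = as.integer(seed)),
    class = "window_spec"
  )
}

window_starts <- function(T_len, spec, seed_offset = 0L) {
  n_starts <- T_len - spec$window_size + 1L
  if (n_starts < 1L) {
    abort(sprintf("window_size %d exceeds series length %d.",
                  spec$window_size, T_len),
          class = "stgcnet_error_window")
  }
  if (spec$start_policy == "all") {
    seq_len(n_starts)
  } else {
    n <- min(spec$n_segments_per_subject, n_starts)
    with_seed(child_seed(spec$seed, seed_offset),
              sort(sample.int(n_starts, n)))
  }
}

#' Segment a subject's series into sliding windows
#'
#' Returns a `segment_batch`: a rank-4 feature array with axes
#' (batch, channel, window-time, region) and channel dimension 1, the shape
#' the classifier consumes.
#'
#' @param ts An [roi_timeseries()].
#' @param spec A [window_spec()].
#' @param label Optional 0/1 class label attached to every segment.
#' @return A `segment_batch` with fields `features` (B x 1 x W x N),
#'   `subject_ids`, `labels` and `starts`.
#' @export
extract_windows <- function(ts, spec, label = NA_integer_) {
  stopifnot(inherits(ts, "roi_timeseries"), inherits(spec, "window_spec"))
  T_len <- nrow(ts$values)
  starts <- window_starts(T_len, spec,
                          seed_offset = string_seed_offset(ts$subject_id))
  W <- spec$window_size
  B <- length(starts)
  N <- ncol(ts$values)
  feats <- array(0, dim = c(B, 1L, W, N))
  for (b in seq_len(B)) {
    feats[b, 1L, , ] <- ts$values[starts[b]:(starts[b] + W - 1L), ]
  }
  structure(
    list(features = feats,
         subject_ids = rep(ts$subject_id, B),
         labels = rep(as.integer(label), B),
         starts = starts,
         region_labels = ts$region_labels),
    class = "segment_batch"
  )
}

# Stable per-subject offset so each subject draws distinct window starts
# under one spec seed.
string_seed_offset <- function(id) {
  sum(utf8ToInt(as.character(id)) * seq_along(utf8ToInt(as.character(id)))) %% 65011L
}

#' @export
print.segment_batch <- function(x, ...) {
  d <- dim(x$features)
  cat(sprintf("<segment_batch> %d segments x %d channel x %d TRs x %d regions\n",
              d[1L], d[2L], d[3L], d[4L]))
  invisible(x)
}

# Bind several segment_batches into one.
bind_segment_batches <- function(batches) {
  feats <- do.call(abind4, purrr::map(batches, "features"))
  structure(
    list(features = feats,
         subject_ids = unlist(purrr::map(batches, "subject_ids")),
         labels = unlist(purrr::map(batches, "labels")),
         starts = unlist(purrr::map(batches, "starts")),
         region_labels = batches[[1L]]$region_labels),
    class = "segment_batch"
  )
}

# rbind along the batch (first) axis of rank-4 arrays.
abind4 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1L]])
  Bs <- vapply(parts, function(p) dim(p)[1L], integer(1))
  out <- array(0, dim = c(sum(Bs), d[2L], d[3L], d[4L]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1L]), , , ] <- p
    at <- at + dim(p)[1L]
  }
  out
}

# Per-segment, per-region z-scoring; constant regions are centred and left
# at zero rather than divided by a zero sd (occlusion can zero a region).
standardize_segments <- function(feats) {
  d <- dim(feats)
  for (b in seq_len(d[1L])) {
    for (n in seq_len(d[4L])) {
      v <- feats[b, 1L, , n]
      s <- sd(v)
      feats[b, 1L, , n] <- if (s < 1e-8) v - mean(v) else (v - mean(v)) / s
    }
  }
  feats
}

#' Dynamic functional connectivity
#'
#' One Fisher-z FC matrix per sliding window (stride 1; every start is
#' enumerated regardless of the `spec` argument's start policy).
#'
#' @param ts An [roi_timeseries()].
#' @param spec A [window_spec()]; only its `window_size` is used.
#' @return A list of `fc_matrix` objects, one per window.
#' @export
dynamic_fc <- function(ts, spec) {
  stopifnot(inherits(ts, "roi_timeseries"), inherits(spec, "window_spec"))
  T_len <- nrow(ts$values)
  W <- spec$window_size
  if (W > T_len) {
    abort(sprintf("window_size %d exceeds series length %d.", W, T_len),
          class = "stgcnet_error_window")
  }
  starts <- seq_len(T_len - W + 1L)
  purrr::map(starts, function(s) {
    win <- roi_timeseries(ts$values[s:(s + W - 1L), , drop = FALSE],
                          ts$region_labels, subject_id = ts$subject_id,
                          tr_seconds = ts$tr_seconds)
    fisher_z(pearson_fc(win))
  })
}
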