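#' Canonical marker set for quiet-standing recordings
#'
#' The pipeline tracks 11 signal sources: the whole-body center of mass (COM)
#' and 10 reflective markers placed symmetrically on the shoulders, hips,
#' knees, ankles and toes (left/right each). Every source carries X/Y/Z
#' displacement, giving 33 kinematic variables. Axis convention: X is
#' medial-lateral (ML), Y anterior-posterior, Z vertical.
#'
#' @return A data frame with one row per kinematic variable (33 rows) and
#'   columns `variable` (canonical column name, `<part>_<side>_<axis>`, with
#'   an empty side field for the COM, e.g. `com__X`), `part`, `side` (`"L"`,
#'   `"R"` or `""`) and `axis` (`"X"`, `"Y"`, `"Z"`).
#' @examples
#' head(marker_set())
#' @export
marker_set <- function() {
  parts <- c("com", "shoulder", "hip", "knee", "ankle", "toe")
  rows <- list()
  for (part in parts) {
    sides <- if (part == "com") "" else c("L", "R")
    for (side in sides) {
      for (axis in c("X", "Y", "Z")) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = paste(part, side, axis, sep = "_"),
          part = part, side = side, axis = axis,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Canonical variable names
#'
#' @return Character vector of the 33 kinematic variable names in canonical
#'   order (COM first, then shoulder/hip/knee/ankle/toe, left before right,
#'   X/Y/Z within each source).
#' @export
marker_variables <- function() marker_set()$variable

#' Column indices of one marker's X/Y/Z triple
#' @noRd
marker_cols <- function(part, side = "") {
  ms <- marker_set()
  which(ms$part == part & ms$side == side)
}

#' Construct a sway recording
#'
#' A recording is one quiet-standing trial: a samples-by-variables matrix of
#' marker displacements (default unit: mm) plus subject metadata. The data
#' matrix must have exactly 33 columns in canonical [marker_set()] order and
#' `rate * duration` rows (1800 for the standard 30 s at 60 Hz).
#'
#' @param data Numeric matrix, rows = time samples, 33 columns.
#' @param subject_id Subject identifier string.
#' @param disease One of `"CH"` (cerebral hemorrhage), `"CI"` (cerebral
#'   infarction), `"other"`, `"unknown"`.
#' @param age Age in years.
#' @param days_after_onset Days elapsed since the stroke event.
#' @param hemiplegia Paretic side: `"left"`, `"right"`, `"either"`, `"unknown"`.
#' @param rate Sampling rate in samples/s (default 60).
#' @return An object of class `sway_recording`.
#' @export
sway_recording <- function(data, subject_id, disease = "unknown", age = NA_real_,
                           days_after_onset = NA_integer_,
                           hemiplegia = "unknown", rate = 60) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  vars <- marker_variables()
  if (ncol(data) != length(vars)) {
    stop("recording data must have exactly ", length(vars), " columns, got ",
         ncol(data))
  }
  if (is.null(colnames(data))) colnames(data) <- vars
  if (!identical(colnames(data), vars)) {
    missing <- setdiff(vars, colnames(data))
    if (length(missing)) stop("column ", missing[1L], " absent")
    data <- data[, vars, drop = FALSE]
  }
  if (nrow(data) == 0L) stop("recording has 0 samples")
  if (anyNA(data)) stop("recording contains missing values")
  disease <- match.arg(disease, c("CH", "CI", "other", "unknown"))
  hemiplegia <- match.arg(hemiplegia, c("left", "right", "either", "unknown"))
  structure(
    list(data = data, subject_id = as.character(subject_id), disease = disease,
         age = as.numeric(age), days_after_onset = as.integer(days_after_onset),
         hemiplegia = hemiplegia, rate = as.numeric(rate)),
    class = "sway_recording"
  )
}

#' @export
print.sway_recording <- function(x, ...) {
  cat(sprintf(
    "<sway_recording> subject %s (%s), %d samples x %d variables @ %g Hz (%.1f s)\n",
    x$subject_id, x$disease, nrow(x$data), ncol(x$data), x$rate,
    nrow(x$data) / x$rate))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A `sway_recording`.
#' @export
recording_duration <- function(rec) nrow(rec$data) / rec$rate

#' Read a marker-trajectory recording from CSV
#'
#' Expects delimited text with a header whose first column is `time_s`
#' followed by the 33 kinematic variable columns named `<part>_<side>_<axis>`
#' (e.g. `shoulder_L_X`, `com__Y`) in any order; columns are reordered into
#' canonical [marker_set()] order on load. One row per sample.
#'
#' @param path CSV file path.
#' @param metadata Named list of subject fields (`subject_id`, `disease`,
#'   `age`, `days_after_onset`, `hemiplegia`, `rate`; `rate` defaults to 60).
#' @param duration Expected duration in seconds. If given, the row count must
#'   equal `rate * duration` exactly.
#' @param interpolate_gaps If `TRUE`, linearly interpolate runs of missing
#'   samples of length at most `max_gap`; by default missing values are
#'   rejected.
#' @param max_gap Longest interpolatable gap, in samples.
#' @return A [sway_recording()].
#' @export
read_recording <- function(path, metadata, duration = NULL,
                           interpolate_gaps = FALSE, max_gap = 5L) {
  stopifnot(is.list(metadata), !is.null(metadata$subject_id))
  rate <- if (is.null(metadata$rate)) 60 else metadata$rate
  tab <- utils::read.csv(path, check.names = FALSE)
  vars <- marker_variables()
  missing <- setdiff(vars, names(tab))
  if (length(missing)) stop("column ", missing[1L], " absent")
  mat <- as.matrix(tab[, vars, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(tab[, vars, drop = FALSE], is.numeric, logical(1)))
    col <- vars[bad[1L]]
    row <- which(is.na(suppressWarnings(as.numeric(tab[[col]]))) &
                   !is.na(tab[[col]]))[1L]
    stop("non-numeric cell in column ", col, ", row ", row)
  }
  if (!is.null(duration) && nrow(mat) != round(rate * duration)) {
    stop("expected ", round(rate * duration), " rows for ", duration,
         " s at ", rate, " Hz, found ", nrow(mat))
  }
  if (anyNA(mat)) {
    if (!interpolate_gaps) stop("recording contains missing values")
    mat <- apply(mat, 2L, fill_short_gaps, max_gap = max_gap)
    if (anyNA(mat)) stop("missing-value gap longer than ", max_gap, " samples")
  }
  sway_recording(
    mat, subject_id = metadata$subject_id,
    disease = if (is.null(metadata$disease)) "unknown" else metadata$disease,
    age = if (is.null(metadata$age)) NA_real_ else metadata$age,
    days_after_onset = if (is.null(metadata$days_after_onset)) NA_integer_
      else metadata$days_after_onset,
    hemiplegia = if (is.null(metadata$hemiplegia)) "unknown"
      else metadata$hemiplegia,
    rate = rate
  )
}

# Linear interpolation of interior NA runs no longer than max_gap.
fill_short_gaps <- function(x, max_gap) {
  if (!anyNA(x)) return(x)
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] > max_gap) next
    i0 <- starts[k] - 1L
    i1 <- ends[k] + 1L
    if (i0 < 1L || i1 > length(x)) next  # edge gaps stay NA (rejected upstream)
    x[starts[k]:ends[k]] <- x[i0] +
      (x[i1] - x[i0]) * (seq_len(r$lengths[k])) / (i1 - i0)
  }
  x
}

#' Write a recording to CSV
#'
#' Writes the canonical format consumed by [read_recording()]: header
#' `time_s` followed by the 33 canonical variable names, one row per sample,
#' full double precision. Metadata is not embedded in the CSV; cohorts carry a
#' JSON sidecar (see [write_cohort()]).
#'
#' @param rec A [sway_recording()].
#' @param path Output file path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "sway_recording"))
  if (nrow(rec$data) == 0L) stop("cannot write an empty recording")
  tab <- data.frame(time_s = (seq_len(nrow(rec$data)) - 1) / rec$rate,
                    check.names = FALSE)
  tab <- cbind(tab, as.data.frame(rec$data, check.names = FALSE))
  utils::write.csv(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Write a cohort of recordings plus a metadata sidecar
#'
#' One CSV per recording (named `<subject_id>.csv`, or `<subject_id>_s<k>.csv`
#' for repeated sessions) plus `cohort.json` listing per-recording subject
#' fields, mirroring the usual subject-information table of a clinical study
#' (id, disease type, age, days after onset, hemiplegia side).
#'
#' @param recs List of [sway_recording()] objects.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(recs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- vapply(recs, function(r) r$subject_id, character(1))
  files <- paste0(make.unique(ids, sep = "_s"), ".csv")
  meta <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    list(file = files[i], subject_id = r$subject_id, disease = r$disease,
         age = r$age, days_after_onset = r$days_after_onset,
         hemiplegia = r$hemiplegia, rate = r$rate)
  })
  jsonlite::write_json(meta, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (i in seq_along(recs)) write_recording(recs[[i]], file.path(dir, files[i]))
  invisible(NULL)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `cohort.json` and the per-recording CSVs.
#' @return List of [sway_recording()] objects.
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"))
  lapply(meta, function(m) {
    read_recording(file.path(dir, m$file), metadata = m)
  })
}
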