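#' Offset a recording to the ankle midpoint
#'
#' Anchors the coordinate frame at the stance: the time-averaged midpoint of
#' the left and right ankle markers is subtracted, per axis, from every
#' variable. The subtracted quantity is a single constant vector per
#' recording, so within-trial sway (including ankle sway) is preserved; after
#' the operation the mean of `(ankle_L + ankle_R) / 2` is the zero vector.
#'
#' @param rec A [sway_recording()].
#' @return The offset recording.
#' @export
offset_by_ankle_midpoint <- function(rec) {
  stopifnot(inherits(rec, "sway_recording"))
  ms <- marker_set()
  out <- rec$data
  for (axis in c("X", "Y", "Z")) {
    li <- which(ms$part == "ankle" & ms$side == "L" & ms$axis == axis)
    ri <- which(ms$part == "ankle" & ms$side == "R" & ms$axis == axis)
    mid <- mean((rec$data[, li] + rec$data[, ri]) / 2)
    cols <- which(ms$axis == axis)
    out[, cols] <- out[, cols] - mid
  }
  rec$data <- out
  rec
}

#' Body-segment lengths for anthropometric scaling
#'
#' Computes the three segment lengths used to remove between-subject size
#' differences: `l1` shoulder-hip, `l2` hip-knee, `l3` knee-ankle. Each is the
#' mean over all time samples and over the left and right sides of the 3D
#' Euclidean distance between the paired markers. Distances are
#' translation-invariant, so it is immaterial whether the recording has been
#' offset first.
#'
#' @param rec A [sway_recording()].
#' @return List with elements `l1`, `l2`, `l3` (same units as the data).
#' @export
compute_segment_lengths <- function(rec) {
  stopifnot(inherits(rec, "sway_recording"))
  pair_mean <- function(upper, lower) {
    per_side <- vapply(c("L", "R"), function(side) {
      u <- rec$data[, marker_cols(upper, side), drop = FALSE]
      l <- rec$data[, marker_cols(lower, side), drop = FALSE]
      mean(sqrt(rowSums((u - l)^2)))
    }, numeric(1))
    mean(per_side)
  }
  seg <- list(l1 = pair_mean("shoulder", "hip"),
              l2 = pair_mean("hip", "knee"),
              l3 = pair_mean("knee", "ankle"))
  if (any(unlist(seg) <= 0)) stop("degenerate geometry: zero-length body segment")
  seg
}

#' Scale a recording by total segment length
#'
#' Divides every value by `l1 + l2 + l3`, making the data dimensionless and
#' removing anthropometric size differences between subjects: two
#' geometrically similar recordings differing only by a global scale factor
#' map to identical output. Apply once, after offsetting.
#'
#' @param rec A [sway_recording()].
#' @param seg Segment lengths from [compute_segment_lengths()].
#' @return The scaled recording.
#' @export
scale_by_height <- function(rec, seg) {
  stopifnot(inherits(rec, "sway_recording"))
  total <- seg$l1 + seg$l2 + seg$l3
  if (!is.finite(total) || total <= 0) stop("non-positive segment-length sum")
  rec$data <- rec$data / total
  rec
}

#' Zero-phase Butterworth low-pass filter
#'
#' Double-pass (forward-backward) Butterworth low-pass filter applied
#' independently to each of the 33 columns. The double pass cancels phase
#' distortion (zero lag) and squares the single-pass magnitude response.
#' Edges are handled by odd (point-reflected) extension of the signal before
#' filtering, so slot boundaries carry no start-up transient.
#'
#' @param rec A [sway_recording()].
#' @param cutoff Cutoff frequency in Hz (default 12).
#' @param order Filter order of each pass (default 2).
#' @return The filtered recording.
#' @export
lowpass_filter <- function(rec, cutoff = 12, order = 2) {
  stopifnot(inherits(rec, "sway_recording"))
  if (cutoff >= rec$rate / 2) {
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency (",
         rec$rate / 2, " Hz)")
  }
  bf <- signal::butter(order, cutoff / (rec$rate / 2), type = "low")
  rec$data <- apply(rec$data, 2L, filtfilt_odd, b = bf$b, a = bf$a)
  rec
}

# Forward-backward IIR filtering with odd-extension padding at both ends.
# The reflected pad absorbs the filter start-up transient of each pass.
filtfilt_odd <- function(x, b, a) {
  n <- length(x)
  pad <- min(n - 1L, max(3L * (max(length(a), length(b)) - 1L), 60L))
  ext <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- signal::filter(b, a, ext)
  y <- rev(signal::filter(b, a, rev(y)))
  as.numeric(y[(pad + 1L):(pad + n)])
}

#' Cut a recording into fixed-length data slots
#'
#' Divides a preprocessed recording into consecutive, non-overlapping,
#' left-aligned windows of `t` seconds; any trailing remainder shorter than
#' one window is discarded. Each slot is the unit later clustered: a
#' `(rate * t)`-sample by 33-variable matrix (300 x 33 for 5-s slots at
#' 60 Hz) carrying its source recording's subject metadata.
#'
#' @param rec A [sway_recording()].
#' @param t Slot length in seconds; `rate * t` must be a whole number of
#'   samples.
#' @return List of `sway_slot` objects (`floor(duration / t)` of them).
#' @export
slice_slots <- function(rec, t) {
  stopifnot(inherits(rec, "sway_recording"), t > 0)
  rows <- rec$rate * t
  if (abs(rows - round(rows)) > 1e-9) stop("rate * t must be an integer sample count")
  rows <- as.integer(round(rows))
  n <- nrow(rec$data)
  if (rows > n) stop("slot length ", t, " s exceeds recording duration ",
                     n / rec$rate, " s")
  n_slots <- n %/% rows
  # Repeated sessions of one subject are distinguished by days after onset.
  session <- if (is.na(rec$days_after_onset)) rec$subject_id else
    paste0(rec$subject_id, "@", rec$days_after_onset)
  lapply(seq_len(n_slots), function(k) {
    idx <- ((k - 1L) * rows + 1L):(k * rows)
    structure(
      list(
        source_id = paste0(session, "#", k),
        slot_index = k,
        subject_id = rec$subject_id, disease = rec$disease, age = rec$age,
        days_after_onset = rec$days_after_onset, hemiplegia = rec$hemiplegia,
        rate = rec$rate,
        data = rec$data[idx, , drop = FALSE]
      ),
      class = "sway_slot"
    )
  })
}

#' @export
print.sway_slot <- function(x, ...) {
  cat(sprintf("<sway_slot> %s: %d samples x %d variables @ %g Hz\n",
              x$source_id, nrow(x$data), ncol(x$data), x$rate))
  invisible(x)
}

#' Preprocess a cohort of recordings into data slots
#'
#' Runs the full standardization chain on every recording, in order: offset
#' to ankle midpoint, segment-length computation, scaling to dimensionless
#' units, zero-phase low-pass filtering, slot slicing. Recordings are
#' processed independently, so the result is equivariant under reordering of
#' the cohort.
#'
#' @param recs List of [sway_recording()] objects.
#' @param t Slot length in seconds.
#' @param cutoff,order Low-pass filter settings (see [lowpass_filter()]).
#' @return List of `sway_slot` objects, recordings in input order, slots in
#'   time order within each recording.
#' @export
preprocess_cohort <- function(recs, t = 5, cutoff = 12, order = 2) {
  out <- lapply(recs, function(rec) {
    rec <- offset_by_ankle_midpoint(rec)
    seg <- compute_segment_lengths(rec)
    rec <- scale_by_height(rec, seg)
    rec <- lowpass_filter(rec, cutoff = cutoff, order = order)
    slice_slots(rec, t)
  })
  do.call(c, out)
}
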