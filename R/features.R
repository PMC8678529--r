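#' Sway amplitude of one variable in one slot
#'
#' The gap between the maximum and minimum values of a kinematic variable
#' over one data slot.
#'
#' @param x Numeric series (one variable of one slot).
#' @return Non-negative scalar; 0 for a constant series.
#' @export
sway_amplitude <- function(x) {
  if (length(x) == 0L) stop("empty series")
  max(x) - min(x)
}

#' Sway standard deviation of one variable in one slot
#'
#' Sample standard deviation (denominator `n - 1`) of a kinematic variable
#' over one data slot.
#'
#' @param x Numeric series of length at least 2.
#' @export
sway_sd <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples")
  stats::sd(x)
}

#' Dominant sway frequency of one variable in one slot
#'
#' The frequency of the most prominent spectral peak: the series is demeaned
#' and the frequency of the maximum-magnitude FFT bin strictly between 0 and
#' the Nyquist frequency is returned. The frequency resolution is
#' `rate / length(x)` (0.2 Hz for 5-s slots at 60 Hz), so a bin-aligned
#' sinusoid is recovered exactly. No taper window is applied; the upstream
#' low-pass filter and offset have already conditioned the signal.
#'
#' @param x Numeric series of length at least 16.
#' @param rate Sampling rate in Hz.
#' @return Frequency in Hz, or `NA_real_` for a constant series.
#' @export
sway_frequency <- function(x, rate) {
  n <- length(x)
  if (n < 16L) stop("series too short for a frequency estimate")
  x <- x - mean(x)
  if (all(x == 0)) return(NA_real_)
  mag <- Mod(stats::fft(x))
  bins <- 2:((n + 1L) %/% 2)  # exclude DC and the Nyquist bin
  peak <- bins[which.max(mag[bins])]
  (peak - 1L) * rate / n
}

#' Sway features for every variable of every slot
#'
#' Applies the three sway parameters (amplitude, SD, dominant frequency) to
#' each of the 33 kinematic variables of each slot and attaches the slot's
#' cluster label, producing the long table that feeds the between-cluster
#' post-hoc analysis and box plots.
#'
#' @param slots List of `sway_slot` objects (from [preprocess_cohort()]).
#' @param solution Optional [cluster_solution()] aligned with `slots`; when
#'   omitted the `cluster` column is `NA`.
#' @return Data frame with one row per (slot, variable): `slot_id`,
#'   `subject_id`, `disease`, `days_after_onset`, `cluster`, `variable`
#'   (index 1-33), `part`, `side`, `axis`, `amplitude`, `sd`, `frequency`.
#' @export
featurize <- function(slots, solution = NULL) {
  if (!is.null(solution) && length(solution$assignment) != length(slots)) {
    stop("solution does not match the slot list")
  }
  ms <- marker_set()
  p <- nrow(ms)
  rows <- lapply(seq_along(slots), function(i) {
    s <- slots[[i]]
    data.frame(
      slot_id = s$source_id, subject_id = s$subject_id, disease = s$disease,
      days_after_onset = s$days_after_onset,
      cluster = if (is.null(solution)) NA_integer_ else solution$assignment[i],
      variable = seq_len(p), part = ms$part, side = ms$side, axis = ms$axis,
      amplitude = apply(s$data, 2L, sway_amplitude),
      sd = apply(s$data, 2L, sway_sd),
      frequency = apply(s$data, 2L, sway_frequency, rate = s$rate),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  do.call(rbind, rows)
}
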