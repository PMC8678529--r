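#' Specification of a synthetic quiet-standing cohort
#'
#' Defines a motion-capture-like cohort with planted cluster structure so
#' every pipeline stage can be exercised and validated without patient data.
#' The defaults emulate the shape of the clinical study the pipeline targets:
#' 31 recordings of 30 s at 60 Hz, a four-cluster sway structure with
#' dominant frequencies inside the 0.5-1.5 Hz postural-sway band, larger
#' sway amplitude for the upper body (shoulder, hip, COM) than the lower
#' (knee, ankle, toe), and per-recording subject metadata (disease type, age,
#' days after onset, hemiplegia side).
#'
#' Each recording is a static standing pose (built from the subject's
#' segment lengths with anatomically ordered marker heights) plus per-marker
#' sway: a sinusoid at the planted cluster's frequency with random phase,
#' scaled by the marker's baseline amplitude times the cluster's amplitude
#' multiplier, plus low-pass-filtered Gaussian noise. The COM is a fixed
#' anthropometric weighted mean of the marker positions. Cluster frequencies
#' default to multiples of 0.2 Hz so that 5-s slots resolve them on exact
#' FFT bins.
#'
#' @param n_subjects Number of subjects (one 30-s recording each unless an
#'   onset-drift schedule adds sessions).
#' @param duration Recording length in seconds.
#' @param rate Sampling rate in Hz.
#' @param K_true Number of planted clusters.
#' @param cluster_freq Dominant sway frequency (Hz) per cluster.
#' @param cluster_amp Sway-amplitude multiplier per cluster.
#' @param marker_amp Named baseline sway amplitudes (mm, ML direction) per
#'   body part; must decrease from the upper group (shoulder/hip) to the
#'   lower (knee/ankle/toe).
#' @param axis_ratio Sway amplitude of the Y (anterior-posterior) and Z
#'   (vertical) axes relative to X (ML).
#' @param noise_sd Standard deviation (mm) of the additive measurement
#'   noise before low-pass filtering.
#' @param noise_cutoff Low-pass cutoff (Hz) applied to the noise.
#' @param ch_fraction Fraction of subjects with cerebral hemorrhage (CH);
#'   the rest are cerebral infarction (CI).
#' @param hemiplegia_ratio Left/right sway amplitude ratio modeling paretic
#'   asymmetry (default 1: symmetric).
#' @param segment_lengths Baseline `l1` (shoulder-hip), `l2` (hip-knee), `l3`
#'   (knee-ankle) in mm; each subject's lengths are jittered around these.
#' @param seed RNG seed; the generated cohort is a deterministic function of
#'   this specification object.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 31L, duration = 30, rate = 60,
                        K_true = 4L,
                        cluster_freq = c(0.6, 0.8, 1.2, 1.4),
                        cluster_amp = c(1, 2, 3.5, 5),
                        marker_amp = c(shoulder = 20, hip = 15, knee = 8,
                                       ankle = 4, toe = 2),
                        axis_ratio = c(Y = 0.6, Z = 0.2),
                        noise_sd = 1.5, noise_cutoff = 10,
                        ch_fraction = 0.5, hemiplegia_ratio = 1,
                        segment_lengths = c(l1 = 480, l2 = 400, l3 = 420),
                        seed = 1L) {
  stopifnot(length(cluster_freq) == K_true, length(cluster_amp) == K_true,
            all(cluster_freq > 0), all(cluster_freq < rate / 2),
            all(cluster_amp > 0), noise_sd >= 0,
            all(segment_lengths > 0), n_subjects >= 1L)
  upper <- min(marker_amp[c("shoulder", "hip")])
  lower <- max(marker_amp[c("knee", "ankle", "toe")])
  if (!(upper > lower)) {
    stop("upper-body baseline amplitudes must exceed lower-body ones")
  }
  if (!(marker_amp["knee"] >= marker_amp["ankle"] &&
        marker_amp["ankle"] >= marker_amp["toe"])) {
    stop("lower-body amplitudes must decrease from knee to toe")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), duration = duration,
         rate = rate, K_true = as.integer(K_true),
         cluster_freq = cluster_freq, cluster_amp = cluster_amp,
         marker_amp = marker_amp, axis_ratio = axis_ratio,
         noise_sd = noise_sd, noise_cutoff = noise_cutoff,
         ch_fraction = ch_fraction, hemiplegia_ratio = hemiplegia_ratio,
         segment_lengths = segment_lengths, seed = as.integer(seed),
         onset_drift = NULL),
    class = "cohort_spec"
  )
}

#' Plant an onset-day cluster drift into a cohort spec
#'
#' Adds repeated measurement sessions per subject and makes the true cluster
#' of CH-flagged subjects a step function of days after onset (emulating
#' gradual recovery through sway patterns), while CI-flagged subjects keep an
#' onset-independent cluster across their sessions.
#'
#' @param spec A [cohort_spec()].
#' @param schedule Cluster index per session for CH subjects (e.g.
#'   `c(4, 3, 2, 1)`).
#' @param session_days Days after onset of each session; same length as
#'   `schedule`.
#' @return The modified spec.
#' @export
planted_onset_drift <- function(spec, schedule = c(4L, 3L, 2L, 1L),
                                session_days = c(50L, 300L, 600L, 1100L)) {
  stopifnot(inherits(spec, "cohort_spec"),
            length(schedule) == length(session_days),
            all(schedule >= 1L), all(schedule <= spec$K_true),
            !is.unsorted(session_days, strictly = TRUE))
  spec$onset_drift <- list(schedule = as.integer(schedule),
                           session_days = as.integer(session_days))
  spec
}

# Static standing pose: one row of 33 canonical coordinates (mm).
# X medial-lateral, Y anterior-posterior, Z vertical; ankle height 80 mm.
# `size` scales every transverse dimension so that subjects are geometrically
# similar up to their segment proportions (anthropometric scaling then
# removes most of the between-subject pose differences, as intended).
standing_pose <- function(seg, size = 1) {
  z_ankle <- 80 * size
  z_knee <- z_ankle + seg["l3"]
  z_hip <- z_knee + seg["l2"]
  z_shoulder <- z_hip + seg["l1"]
  half <- list(shoulder = c(180 * size, 0, z_shoulder),
               hip = c(120 * size, 0, z_hip),
               knee = c(105 * size, 0, z_knee),
               ankle = c(100 * size, 0, z_ankle),
               toe = c(110 * size, 150 * size, 30 * size))
  ms <- marker_set()
  pose <- numeric(nrow(ms))
  for (part in names(half)) {
    for (side in c("L", "R")) {
      sgn <- if (side == "L") -1 else 1
      p <- half[[part]] * c(sgn, 1, 1)
      pose[marker_cols(part, side)] <- p
    }
  }
  pose[marker_cols("com")] <- com_from_markers(pose)
  names(pose) <- ms$variable
  pose
}

# Anthropometric COM weights per marker (trunk-heavy); sum to 1 over the
# 10 markers.
com_weights <- function() {
  c(shoulder = 0.15, hip = 0.20, knee = 0.08, ankle = 0.05, toe = 0.02)
}

# Weighted mean of the 10 markers' X/Y/Z; works on a pose vector or a
# samples-by-33 matrix (returns the 3 COM columns).
com_from_markers <- function(x) {
  w <- com_weights()
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  com <- matrix(0, nrow(x), 3L)
  for (part in names(w)) {
    for (side in c("L", "R")) {
      com <- com + w[[part]] * x[, marker_cols(part, side), drop = FALSE]
    }
  }
  com
}

#' Generate a synthetic cohort with planted cluster structure
#'
#' See [cohort_spec()] for the generative model. Without an onset-drift
#' schedule each subject contributes one recording and true clusters are
#' allocated in balanced round-robin order over subjects; with
#' [planted_onset_drift()] each subject contributes one recording per
#' session day, CH subjects following the planted cluster schedule and CI
#' subjects keeping their base cluster.
#'
#' @param spec A [cohort_spec()].
#' @return List with `recordings` (list of [sway_recording()]) and `truth`
#'   (data frame: `subject_id`, `disease`, `days_after_onset`, `cluster`),
#'   one truth row per recording in the same order. Slots sliced from a
#'   recording inherit its true cluster.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  n_ch <- round(spec$ch_fraction * n)
  disease <- sample(c(rep("CH", n_ch), rep("CI", n - n_ch)))
  base_cluster <- rep_len(seq_len(spec$K_true), n)[sample.int(n)]
  ages <- round(stats::runif(n, 40, 80))
  hemi <- sample(c("left", "right"), n, replace = TRUE)
  prefix <- ifelse(disease == "CH", "CH", "CI")
  ids <- paste0(prefix, stats::ave(seq_len(n), prefix, FUN = seq_along))

  recordings <- list()
  truth <- list()
  for (i in seq_len(n)) {
    # one global body-size factor plus small segment-proportion jitter
    size <- stats::runif(1, 0.9, 1.1)
    seg <- spec$segment_lengths * size * stats::runif(3, 0.98, 1.02)
    names(seg) <- c("l1", "l2", "l3")
    if (is.null(spec$onset_drift)) {
      sessions <- data.frame(days = sample(30:1100, 1L),
                             cluster = base_cluster[i])
    } else {
      days <- spec$onset_drift$session_days
      cl <- if (disease[i] == "CH") spec$onset_drift$schedule
            else rep(base_cluster[i], length(days))
      sessions <- data.frame(days = days, cluster = cl)
    }
    for (s in seq_len(nrow(sessions))) {
      rec <- synth_recording(spec, seg, size = size,
                             cluster = sessions$cluster[s],
                             subject_id = ids[i], disease = disease[i],
                             age = ages[i], days = sessions$days[s],
                             hemiplegia = hemi[i])
      recordings[[length(recordings) + 1L]] <- rec
      truth[[length(truth) + 1L]] <- data.frame(
        subject_id = ids[i], disease = disease[i],
        days_after_onset = sessions$days[s], cluster = sessions$cluster[s],
        stringsAsFactors = FALSE
      )
    }
  }
  list(recordings = recordings, truth = do.call(rbind, truth))
}

# One synthetic recording; consumes RNG state (caller seeds).
synth_recording <- function(spec, seg, size, cluster, subject_id, disease,
                            age, days, hemiplegia) {
  n_samp <- as.integer(round(spec$rate * spec$duration))
  tt <- (seq_len(n_samp) - 1) / spec$rate
  pose <- standing_pose(seg, size)
  data <- matrix(rep(pose, each = n_samp), n_samp, length(pose))
  colnames(data) <- names(pose)
  freq <- spec$cluster_freq[cluster]
  mult <- spec$cluster_amp[cluster]
  axis_amp <- c(X = 1, Y = unname(spec$axis_ratio["Y"]),
                Z = unname(spec$axis_ratio["Z"]))
  phase0 <- stats::runif(3, 0, 2 * pi)  # common body phase per axis
  bf <- signal::butter(2, spec$noise_cutoff / (spec$rate / 2), type = "low")
  for (part in names(spec$marker_amp)) {
    for (side in c("L", "R")) {
      side_gain <- if (side == "L") spec$hemiplegia_ratio else 1
      cols <- marker_cols(part, side)
      jitter <- stats::runif(3, -0.2, 0.2)  # small per-marker phase offset
      for (ax in 1:3) {
        amp <- spec$marker_amp[[part]] * mult * axis_amp[ax] * side_gain
        sway <- amp * sin(2 * pi * freq * tt + phase0[ax] + jitter[ax])
        if (spec$noise_sd > 0) {
          noise <- filtfilt_odd(stats::rnorm(n_samp, 0, spec$noise_sd),
                                bf$b, bf$a)
          sway <- sway + noise
        }
        data[, cols[ax]] <- data[, cols[ax]] + sway
      }
    }
  }
  data[, marker_cols("com")] <- com_from_markers(data)
  sway_recording(data, subject_id = subject_id, disease = disease, age = age,
                 days_after_onset = days, hemiplegia = hemiplegia,
                 rate = spec$rate)
}
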