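# Helper: recording with a prescribed constant pose plus optional sway.
pose_recording <- function(n = 120, pose = NULL, jitter = 0, seed = 1) {
  set.seed(seed)
  ms <- marker_set()
  if (is.null(pose)) {
    pose <- numeric(33)
    heights <- c(com = 900, shoulder = 1400, hip = 900, knee = 500,
                 ankle = 80, toe = 30)
    for (p in names(heights)) {
      sides <- if (p == "com") "" else c("L", "R")
      for (s in sides) {
        cols <- which(ms$part == p & ms$side == s)
        sgn <- if (s == "L") -1 else 1
        pose[cols] <- c(sgn * 120, 0, heights[[p]])
      }
    }
  }
  data <- matrix(rep(pose, each = n), n, 33) +
    matrix(rnorm(n * 33, sd = jitter), n, 33)
  colnames(data) <- ms$variable
  sway_recording(data, subject_id = "t")
}

test_that("ankle-midpoint offset subtracts the time-mean midpoint per axis", {
  rec <- pose_recording(jitter = 2, seed = 4)
  ms <- marker_set()
  out <- offset_by_ankle_midpoint(rec)
  for (axis in c("X", "Y", "Z")) {
    li <- which(ms$part == "ankle" & ms$side == "L" & ms$axis == axis)
    ri <- which(ms$part == "ankle" & ms$side == "R" & ms$axis == axis)
    mid <- mean((rec$data[, li] + rec$data[, ri]) / 2)
    cols <- which(ms$axis == axis)
    expect_equal(out$data[, cols], rec$data[, cols] - mid)
    expect_equal(mean((out$data[, li] + out$data[, ri]) / 2), 0,
                 tolerance = 1e-12)
  }
  # a single constant vector is subtracted, so sway (deviation from the
  # column mean) is untouched - including the ankle markers' own sway
  expect_equal(sweep(out$data, 2, colMeans(out$data)),
               sweep(rec$data, 2, colMeans(rec$data)), tolerance = 1e-12)
  # idempotent on already-centered data
  again <- offset_by_ankle_midpoint(out)
  expect_equal(again$data, out$data, tolerance = 1e-12)
})

test_that("segment lengths average the per-sample pair distances over both sides", {
  # constant asymmetric pose: left shoulder-hip distance 400, right 600
  ms <- marker_set()
  pose <- numeric(33)
  set_marker <- function(part, side, xyz) {
    pose[which(ms$part == part & ms$side == side)] <<- xyz
  }
  set_marker("shoulder", "L", c(-100, 0, 1300))
  set_marker("shoulder", "R", c(100, 0, 1500))
  set_marker("hip", "L", c(-100, 0, 900)); set_marker("hip", "R", c(100, 0, 900))
  set_marker("knee", "L", c(-100, 0, 480)); set_marker("knee", "R", c(100, 0, 480))
  set_marker("ankle", "L", c(-100, 0, 80)); set_marker("ankle", "R", c(100, 0, 80))
  rec <- pose_recording(pose = pose)
  seg <- compute_segment_lengths(rec)
  expect_equal(seg$l1, 500)  # mean of 400 and 600
  expect_equal(seg$l2, 420)
  expect_equal(seg$l3, 400)

  # jittered pose: oracle is the direct per-sample distance mean
  rec <- pose_recording(jitter = 5, seed = 11)
  seg <- compute_segment_lengths(rec)
  direct <- function(upper, lower) {
    mean(sapply(c("L", "R"), function(side) {
      u <- rec$data[, which(ms$part == upper & ms$side == side)]
      l <- rec$data[, which(ms$part == lower & ms$side == side)]
      mean(sqrt(rowSums((u - l)^2)))
    }))
  }
  expect_equal(seg$l1, direct("shoulder", "hip"))
  expect_equal(seg$l2, direct("hip", "knee"))
  expect_equal(seg$l3, direct("knee", "ankle"))
})

test_that("height scaling divides by l1+l2+l3 and removes global size", {
  rec <- pose_recording(jitter = 3, seed = 5)
  seg <- list(l1 = 1, l2 = 1, l3 = 1)
  scaled <- scale_by_height(rec, seg)
  expect_equal(scaled$data, rec$data / 3)

  # two geometrically similar recordings (global x2) give identical output
  big <- rec
  big$data <- rec$data * 2
  s1 <- scale_by_height(rec, compute_segment_lengths(rec))
  s2 <- scale_by_height(big, compute_segment_lengths(big))
  expect_equal(s1$data, s2$data, tolerance = 1e-12)

  expect_error(scale_by_height(rec, list(l1 = 0, l2 = 0, l3 = 0)),
               "non-positive")
})

test_that("low-pass filter passes the sway band, kills high frequencies, zero phase", {
  n <- 1800
  tt <- (0:(n - 1)) / 60
  base <- pose_recording(n = n)
  rec1 <- base; rec1$data <- base$data + sin(2 * pi * 1 * tt)
  out1 <- lowpass_filter(rec1)
  rms <- function(x) sqrt(mean((x - mean(x))^2))
  # 1 Hz sinusoid: amplitude preserved within 1%
  expect_equal(rms(out1$data[, 1]), rms(rec1$data[, 1]), tolerance = 0.01)

  rec25 <- base; rec25$data <- base$data + sin(2 * pi * 25 * tt)
  out25 <- lowpass_filter(rec25)
  # double-pass 2nd-order Butterworth at 25/12 ratio: > 90% attenuation
  expect_lt(rms(out25$data[, 1]) / rms(rec25$data[, 1]), 0.10)

  # constant signal unchanged (DC gain 1)
  outc <- lowpass_filter(base)
  expect_equal(outc$data, base$data, tolerance = 1e-8)

  # zero phase: cross-correlation peak lag of a band-limited signal is 0
  x <- rec1$data[, 1] - mean(rec1$data[, 1])
  y <- out1$data[, 1] - mean(out1$data[, 1])
  cc <- stats::ccf(x, y, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(lowpass_filter(base, cutoff = 30), "Nyquist")
})

test_that("slot slicing produces exact non-overlapping windows, remainder dropped", {
  rec <- pose_recording(n = 1800, jitter = 1, seed = 6)
  expect_length(slice_slots(rec, 5), 6L)
  expect_length(slice_slots(rec, 10), 3L)
  expect_length(slice_slots(rec, 6), 5L)
  expect_length(slice_slots(rec, 7), 4L)  # 30 %/% 7, remainder dropped
  slots <- slice_slots(rec, 5)
  expect_true(all(vapply(slots, function(s) nrow(s$data) == 300L, logical(1))))
  expect_true(all(vapply(slots, function(s) ncol(s$data) == 33L, logical(1))))
  # concatenated slots reproduce the signal prefix exactly
  expect_equal(do.call(rbind, lapply(slots, `[[`, "data")), rec$data)
  expect_error(slice_slots(rec, 31), "exceeds")
})

test_that("cohort preprocessing is deterministic and permutation-equivariant", {
  coh <- small_cohort(n_subjects = 3, duration = 10, seed = 12)
  slots <- preprocess_cohort(coh$recordings, t = 5)
  expect_length(slots, 6L)
  perm <- c(3, 1, 2)
  slots_p <- preprocess_cohort(coh$recordings[perm], t = 5)
  ids <- vapply(slots, `[[`, character(1), "source_id")
  ids_p <- vapply(slots_p, `[[`, character(1), "source_id")
  expect_setequal(ids, ids_p)
  for (i in seq_along(slots)) {
    j <- match(ids[i], ids_p)
    expect_equal(slots[[i]]$data, slots_p[[j]]$data, tolerance = 1e-12)
  }
  # dimensionless slots: values are order-1 fractions of body height
  expect_lt(max(abs(slots[[1]]$data)), 2)
})

test_that("preprocessing is invariant to global geometric rescaling", {
  coh <- small_cohort(n_subjects = 2, duration = 10, seed = 13)
  doubled <- lapply(coh$recordings, function(r) { r$data <- r$data * 2; r })
  s1 <- preprocess_cohort(coh$recordings, t = 5)
  s2 <- preprocess_cohort(doubled, t = 5)
  for (i in seq_along(s1)) expect_equal(s1[[i]]$data, s2[[i]]$data,
                                        tolerance = 1e-12)
})
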