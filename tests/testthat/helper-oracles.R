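# Independent oracles used to validate the implementation. These deliberately
# avoid the package's own algorithms: DTW by explicit enumeration of every
# monotone warp path, k-medoids by exhaustive subset search, validity indices
# by direct double-loop reimplementation.

# All monotone warp paths from (1,1) to (n,m) with steps {(1,0),(0,1),(1,1)}.
# Cached since path counts grow quickly (6x6 already has 1683 paths).
.path_cache <- new.env(parent = emptyenv())
enumerate_warp_paths <- function(n, m) {
  key <- paste(n, m)
  if (!is.null(.path_cache[[key]])) return(.path_cache[[key]])
  grow <- function(path) {
    i <- path[nrow(path), 1L]
    j <- path[nrow(path), 2L]
    if (i == n && j == m) return(list(path))
    out <- list()
    if (i < n) out <- c(out, grow(rbind(path, c(i + 1L, j))))
    if (j < m) out <- c(out, grow(rbind(path, c(i, j + 1L))))
    if (i < n && j < m) out <- c(out, grow(rbind(path, c(i + 1L, j + 1L))))
    out
  }
  paths <- grow(matrix(c(1L, 1L), 1L))
  .path_cache[[key]] <- paths
  paths
}

# Minimum over all warp paths of the summed local cost; `a`, `b` matrices
# (rows = time). Dependent mode: Euclidean local cost across columns.
dtw_brute_dependent <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  paths <- enumerate_warp_paths(nrow(a), nrow(b))
  min(vapply(paths, function(p) {
    sum(sqrt(rowSums((a[p[, 1L], , drop = FALSE] -
                        b[p[, 2L], , drop = FALSE])^2)))
  }, numeric(1)))
}

# Independent mode: per-variable univariate enumeration, summed.
dtw_brute_independent <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  sum(vapply(seq_len(ncol(a)), function(v) {
    dtw_brute_dependent(a[, v, drop = FALSE], b[, v, drop = FALSE])
  }, numeric(1)))
}

# Exhaustive k-medoids: best total assignment cost over all C(n, K) medoid
# subsets of a distance matrix.
kmedoids_exhaustive <- function(dm, K) {
  n <- nrow(dm)
  best <- Inf
  subsets <- utils::combn(n, K)
  for (s in seq_len(ncol(subsets))) {
    meds <- subsets[, s]
    cost <- sum(apply(dm[, meds, drop = FALSE], 1L, min))
    if (cost < best) best <- cost
  }
  best
}

# Direct reimplementations of the validity indices from their definitions.
db_brute <- function(dm, assignment, medoids) {
  K <- length(medoids)
  delta <- vapply(seq_len(K), function(k) {
    mean(dm[assignment == k, medoids[k]])
  }, numeric(1))
  mean(vapply(seq_len(K), function(i) {
    max(vapply(setdiff(seq_len(K), i), function(j) {
      (delta[i] + delta[j]) / dm[medoids[i], medoids[j]]
    }, numeric(1)))
  }, numeric(1)))
}

ch_brute <- function(dm, assignment, medoids) {
  n <- length(assignment)
  K <- length(medoids)
  sums <- rowSums(dm)
  g <- which.min(sums)  # overall medoid, lowest index on ties
  wgss <- sum(vapply(seq_len(n), function(i) {
    dm[i, medoids[assignment[i]]]^2
  }, numeric(1)))
  bgss <- sum(vapply(seq_len(K), function(k) {
    sum(assignment == k) * dm[medoids[k], g]^2
  }, numeric(1)))
  ((n - K) / (K - 1)) * bgss / wgss
}

dunn_brute <- function(dm, assignment) {
  n <- length(assignment)
  d_min <- Inf
  d_max <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (assignment[i] == assignment[j]) {
        d_max <- max(d_max, dm[i, j])
      } else {
        d_min <- min(d_min, dm[i, j])
      }
    }
  }
  d_min / d_max
}

# Random symmetric distance matrix with zero diagonal.
random_dm <- function(n) {
  m <- matrix(stats::runif(n * n, 0.1, 10), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# 1-D toy partition used for the hand-computed index values:
# clusters {0, 2} (medoid 0) and {10, 12} (medoid 10), absolute distance.
toy_partition <- function() {
  pts <- c(0, 2, 10, 12)
  dm <- abs(outer(pts, pts, "-"))
  sol <- cluster_solution(c(1L, 1L, 2L, 2L), medoids = c(1L, 3L),
                          method = "pam")
  list(dm = dm, sol = sol)
}

# Small synthetic cohort for pipeline-level tests.
small_cohort <- function(n_subjects = 8, duration = 15, seed = 1, ...) {
  generate_cohort(cohort_spec(n_subjects = n_subjects, duration = duration,
                              seed = seed, ...))
}

# True cluster per slot, matched through subject id + onset day.
slot_truth <- function(slots, truth) {
  key <- paste(vapply(slots, function(s) s$subject_id, character(1)),
               vapply(slots, function(s) s$days_after_onset, integer(1)))
  truth$cluster[match(key, paste(truth$subject_id, truth$days_after_onset))]
}
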