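#' Dynamic time warping distance between two multivariate sequences
#'
#' Computes the DTW distance with the symmetric step pattern (unit weights on
#' the diagonal, vertical and horizontal steps), no warping window and no
#' path-length normalization — the slots compared in this pipeline all share
#' the same length, so normalization would only rescale every distance by the
#' same factor.
#'
#' Two multivariate modes are supported. In `"independent"` mode (the
#' default) each of the variables is aligned on its own univariate DTW and
#' the per-variable distances are summed; this matches comparing each
#' kinematic variable of one data slot against the corresponding variable of
#' another. In `"dependent"` mode a single alignment is computed over time
#' with local cost equal to the Euclidean norm across all variables. The two
#' modes coincide for single-variable sequences.
#'
#' DTW is symmetric and zero on identical sequences but does not satisfy the
#' triangle inequality; it is a dissimilarity, not a metric.
#'
#' @param a,b Numeric matrices (rows = time, columns = variables; vectors are
#'   treated as single-variable sequences). Must have the same number of
#'   columns; lengths may differ.
#' @param mode `"independent"` or `"dependent"`.
#' @param return_path If `TRUE`, also return the optimal warp path (only for
#'   dependent mode or single-variable input; ties in the dynamic program are
#'   broken preferring the diagonal step, which affects the path but never
#'   the distance).
#' @return The distance (non-negative scalar), or if `return_path = TRUE` a
#'   list with elements `distance` and `path` (two-column matrix of 1-based
#'   index pairs from `(1, 1)` to `(nrow(a), nrow(b))`).
#' @examples
#' dtw_distance(c(1, 2, 3), c(1, 2, 2, 3))  # time-warped copy: 0
#' @export
dtw_distance <- function(a, b, mode = c("independent", "dependent"),
                         return_path = FALSE) {
  mode <- match.arg(mode)
  a <- as_sequence(a)
  b <- as_sequence(b)
  d <- cpp_dtw_distance(a, b, dependent = (mode == "dependent"))
  if (!return_path) return(d)
  path <- cpp_dtw_path(a, b, dependent = (mode == "dependent"))
  colnames(path) <- c("i", "j")
  list(distance = d, path = path)
}

as_sequence <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  storage.mode(x) <- "double"
  x
}

#' Pairwise DTW distance matrix over data slots
#'
#' @param slots List of `sway_slot` objects, or list of numeric matrices of
#'   identical column count.
#' @param mode Multivariate DTW mode, see [dtw_distance()].
#' @return A symmetric non-negative matrix with zero diagonal; row/column
#'   names are the slot `source_id`s when available.
#' @export
dtw_distance_matrix <- function(slots, mode = c("independent", "dependent")) {
  mode <- match.arg(mode)
  if (length(slots) < 2L) stop("need at least 2 slots")
  mats <- lapply(slots, function(s) {
    as_sequence(if (inherits(s, "sway_slot")) s$data else s)
  })
  p <- vapply(mats, ncol, integer(1))
  if (length(unique(p)) != 1L) stop("slots have differing variable counts")
  D <- cpp_dtw_matrix(mats, dependent = (mode == "dependent"))
  ids <- vapply(seq_along(slots), function(i) {
    if (inherits(slots[[i]], "sway_slot")) slots[[i]]$source_id else as.character(i)
  }, character(1))
  dimnames(D) <- list(ids, ids)
  D
}

#' DTW barycenter average (DBA) of a set of sequences
#'
#' Iteratively refines an average sequence under DTW alignment: each member
#' sequence is aligned to the current average, every average sample is
#' replaced by the mean of all member samples warped onto it, and the loop
#' stops when the summed DTW cost of the members to the average decreases by
#' less than `tol`, or after `max_iter` iterations. The summed cost is
#' non-increasing across iterations. The returned sequence has the length of
#' the initial sequence.
#'
#' For multivariate sequences the averaging follows the configured DTW mode:
#' independent mode averages each variable on its own univariate alignment;
#' dependent mode uses a single joint alignment.
#'
#' By default the average is initialized at the medoid of the members (the
#' member with the smallest summed DTW distance to the rest), which makes the
#' result deterministic.
#'
#' @param sequences Non-empty list of numeric matrices/vectors with a common
#'   variable count.
#' @param init Optional initial average sequence; defaults to the medoid
#'   member.
#' @param max_iter Maximum refinement iterations.
#' @param tol Absolute tolerance on the decrease of the summed DTW cost.
#' @param mode Multivariate DTW mode, see [dtw_distance()].
#' @return List with the averaged `sequence`, the per-iteration summed-cost
#'   trace `cost_trace`, and `iterations`.
#' @export
dba_average <- function(sequences, init = NULL, max_iter = 15L, tol = 1e-8,
                        mode = c("independent", "dependent")) {
  mode <- match.arg(mode)
  if (length(sequences) == 0L) stop("empty sequence list")
  mats <- lapply(sequences, as_sequence)
  if (length(mats) == 1L && is.null(init)) {
    return(list(sequence = mats[[1L]],
                cost_trace = 0, iterations = 0L))
  }
  if (is.null(init)) {
    D <- dtw_distance_matrix(mats, mode = mode)
    init <- mats[[which.min(rowSums(D))]]
  } else {
    init <- as_sequence(init)
  }
  avg <- init
  dep <- (mode == "dependent")
  p <- ncol(avg)
  total_cost <- function(a) {
    sum(vapply(mats, function(m) cpp_dtw_distance(a, m, dep), numeric(1)))
  }
  trace <- total_cost(avg)
  for (iter in seq_len(max_iter)) {
    sums <- matrix(0, nrow(avg), p)
    counts <- matrix(0, nrow(avg), p)
    for (m in mats) {
      if (dep || p == 1L) {
        path <- cpp_dtw_path(avg, m, dependent = TRUE)
        for (v in seq_len(p)) {
          contrib <- tapply(m[path[, 2L], v], path[, 1L], sum)
          idx <- as.integer(names(contrib))
          sums[idx, v] <- sums[idx, v] + contrib
          cnt <- tapply(rep(1, nrow(path)), path[, 1L], sum)
          counts[idx, v] <- counts[idx, v] + cnt
        }
      } else {
        for (v in seq_len(p)) {
          path <- cpp_dtw_path(avg[, v, drop = FALSE], m[, v, drop = FALSE],
                               dependent = TRUE)
          contrib <- tapply(m[path[, 2L], v], path[, 1L], sum)
          idx <- as.integer(names(contrib))
          sums[idx, v] <- sums[idx, v] + contrib
          cnt <- tapply(rep(1, nrow(path)), path[, 1L], sum)
          counts[idx, v] <- counts[idx, v] + cnt
        }
      }
    }
    new_avg <- sums / pmax(counts, 1)
    new_cost <- total_cost(new_avg)
    if (new_cost <= trace[length(trace)]) {
      avg <- new_avg
      trace <- c(trace, new_cost)
      if (trace[length(trace) - 1L] - new_cost < tol) break
    } else {
      break  # keep the previous average; cost trace stays monotone
    }
  }
  list(sequence = avg, cost_trace = trace, iterations = length(trace) - 1L)
}
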