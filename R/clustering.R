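#' Construct a cluster solution object
#'
#' Container for the result of [pam_cluster()] or [dba_cluster()]. Mostly for
#' internal use and for building small hand-specified partitions in
#' validation code.
#'
#' @param assignment Integer vector, one cluster index in `1..K` per slot.
#' @param medoids For method `"pam"`: integer vector of K slot indices,
#'   sorted ascending. For `"dba"`: list of K centroid sequences.
#' @param method `"pam"` or `"dba"`.
#' @param total_cost Sum over slots of the DTW distance to their own
#'   centroid.
#' @param restarts,seed Clustering configuration echo.
#' @param slot_ids Optional slot identifiers.
#' @param cost_trace Optional per-iteration cost trace of the winning run.
#' @return An object of class `sway_clustering`.
#' @export
cluster_solution <- function(assignment, medoids, method = c("pam", "dba"),
                             total_cost = NA_real_, restarts = NA_integer_,
                             seed = NA_integer_, slot_ids = NULL,
                             cost_trace = NULL) {
  method <- match.arg(method)
  assignment <- as.integer(assignment)
  K <- if (method == "pam") length(medoids) else length(medoids)
  if (!all(assignment >= 1L & assignment <= K)) stop("assignment outside 1..K")
  if (length(unique(assignment)) != K) stop("empty cluster in assignment")
  structure(
    list(K = as.integer(K), assignment = assignment, medoids = medoids,
         method = method, total_cost = total_cost,
         restarts = as.integer(restarts), seed = seed, slot_ids = slot_ids,
         cost_trace = cost_trace),
    class = "sway_clustering"
  )
}

#' @export
print.sway_clustering <- function(x, ...) {
  cat(sprintf("<sway_clustering> %s, K = %d, n = %d, total cost %.6g\n",
              toupper(x$method), x$K, length(x$assignment), x$total_cost))
  cat("cluster sizes:", paste(tabulate(x$assignment, x$K), collapse = " "), "\n")
  invisible(x)
}

# Nearest-medoid assignment (ties -> lowest cluster index) and its cost.
assign_to_medoids <- function(dm, medoids) {
  sub <- dm[, medoids, drop = FALSE]
  assignment <- max.col(-sub, ties.method = "first")
  cost <- sum(sub[cbind(seq_len(nrow(dm)), assignment)])
  list(assignment = assignment, cost = cost)
}

#' Partition around medoids (PAM) over a precomputed distance matrix
#'
#' Classic k-medoids with random initialization and a steepest-descent swap
#' phase: starting from K medoids drawn uniformly at random, the single
#' (medoid, non-medoid) exchange giving the largest reduction of the total
#' assignment cost is applied until no exchange reduces the cost. Random
#' centroid starts can land in different local optima, so the whole procedure
#' is repeated `restarts` times and the solution with the minimum total cost
#' is kept. Deterministic given `seed`.
#'
#' @param dm Symmetric distance matrix (e.g. from [dtw_distance_matrix()]).
#' @param K Number of clusters, `2 <= K < n`.
#' @param restarts Number of random initializations (default 10).
#' @param seed RNG seed.
#' @return A [cluster_solution()] (method `"pam"`); medoids are sorted
#'   ascending and clusters are numbered in that order. The final solution is
#'   swap-optimal: no single medoid/non-medoid exchange lowers the cost.
#' @export
pam_cluster <- function(dm, K, restarts = 10L, seed = 1L) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (K < 2L) stop("K must be at least 2")
  if (K >= n) stop("K must be smaller than the number of slots")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    medoids <- sort(sample.int(n, K))
    cur <- assign_to_medoids(dm, medoids)
    repeat {
      best_swap <- NULL
      best_cost <- cur$cost
      for (mi in seq_len(K)) {
        for (h in setdiff(seq_len(n), medoids)) {
          cand <- medoids
          cand[mi] <- h
          cost <- assign_to_medoids(dm, cand)$cost
          if (cost < best_cost - 1e-12) {
            best_cost <- cost
            best_swap <- cand
          }
        }
      }
      if (is.null(best_swap)) break
      medoids <- sort(best_swap)
      cur <- assign_to_medoids(dm, medoids)
    }
    if (is.null(best) || cur$cost < best$cost) {
      best <- list(medoids = medoids, cost = cur$cost,
                   assignment = assign_to_medoids(dm, medoids)$assignment)
    }
  }
  cluster_solution(best$assignment, best$medoids, method = "pam",
                   total_cost = best$cost, restarts = restarts, seed = seed,
                   slot_ids = rownames(dm))
}

#' Check swap-optimality of a PAM solution
#'
#' `TRUE` when no single (medoid, non-medoid) exchange lowers the total
#' assignment cost by more than a numerical tolerance.
#'
#' @param dm Distance matrix.
#' @param solution A PAM [cluster_solution()].
#' @param tol Cost-improvement tolerance.
#' @export
pam_swap_optimal <- function(dm, solution, tol = 1e-9) {
  dm <- as.matrix(dm)
  medoids <- solution$medoids
  base <- assign_to_medoids(dm, medoids)$cost
  for (mi in seq_along(medoids)) {
    for (h in setdiff(seq_len(nrow(dm)), medoids)) {
      cand <- medoids
      cand[mi] <- h
      if (assign_to_medoids(dm, cand)$cost < base - tol) return(FALSE)
    }
  }
  TRUE
}

#' Medoid of a subset of slots
#'
#' The member of `members` minimizing the summed distance to the other
#' members; ties are broken by the lowest slot index.
#'
#' @param dm Distance matrix.
#' @param members Integer indices of the subset (non-empty).
#' @return One index from `members`.
#' @export
medoid_of <- function(dm, members) {
  if (length(members) == 0L) stop("empty member set")
  dm <- as.matrix(dm)
  sums <- rowSums(dm[members, members, drop = FALSE])
  members[which.min(sums)]
}

#' DBA-centroid clustering of data slots
#'
#' k-means-style clustering in DTW space: each slot is assigned to the
#' nearest centroid by DTW distance, then every centroid is recomputed as the
#' DTW barycenter average ([dba_average()]) of its members, iterating until
#' the assignment stops changing or `max_iter` is reached. If a cluster
#' empties during iteration its centroid is re-seeded with the slot farthest
#' from its current centroid. The total cost is non-increasing across
#' iterations within a run; `restarts` random initializations are run and the
#' lowest-cost solution kept. Deterministic given `seed`.
#'
#' @param slots List of `sway_slot` objects or numeric matrices.
#' @param K Number of clusters.
#' @param restarts Random initializations (default 10).
#' @param seed RNG seed.
#' @param max_iter Maximum assign/update iterations per restart.
#' @param dba_iter Refinement iterations inside each [dba_average()] call.
#' @param mode Multivariate DTW mode.
#' @return A [cluster_solution()] (method `"dba"`); `medoids` holds the K
#'   centroid sequences and `cost_trace` the winning run's per-iteration
#'   total cost.
#' @export
dba_cluster <- function(slots, K, restarts = 10L, seed = 1L, max_iter = 10L,
                        dba_iter = 5L, mode = c("independent", "dependent")) {
  mode <- match.arg(mode)
  mats <- lapply(slots, function(s) {
    as_sequence(if (inherits(s, "sway_slot")) s$data else s)
  })
  n <- length(mats)
  if (K < 1L) stop("K must be positive")
  if (K > n) stop("K must not exceed the number of slots")
  dep <- (mode == "dependent")
  dist_to <- function(centroid, m) cpp_dtw_distance(centroid, m, dep)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    centroids <- mats[sample.int(n, K)]
    assignment <- rep(0L, n)
    trace <- numeric(0)
    for (iter in seq_len(max_iter)) {
      d <- vapply(centroids, function(ct) {
        vapply(mats, dist_to, numeric(1), centroid = ct)
      }, numeric(n))
      d <- matrix(d, nrow = n)
      new_assignment <- max.col(-d, ties.method = "first")
      for (k in seq_len(K)) {
        if (!any(new_assignment == k)) {
          far <- which.max(d[cbind(seq_len(n), new_assignment)])
          new_assignment[far] <- k
          centroids[[k]] <- mats[[far]]
        }
      }
      cost <- sum(vapply(seq_len(n), function(i) {
        dist_to(centroids[[new_assignment[i]]], mats[[i]])
      }, numeric(1)))
      trace <- c(trace, cost)
      if (identical(new_assignment, assignment)) break
      assignment <- new_assignment
      for (k in seq_len(K)) {
        members <- mats[assignment == k]
        centroids[[k]] <- dba_average(members, init = centroids[[k]],
                                      max_iter = dba_iter, mode = mode)$sequence
      }
    }
    final_cost <- sum(vapply(seq_len(n), function(i) {
      dist_to(centroids[[assignment[i]]], mats[[i]])
    }, numeric(1)))
    trace <- c(trace, final_cost)
    if (is.null(best) || final_cost < best$cost) {
      best <- list(assignment = assignment, centroids = centroids,
                   cost = final_cost, trace = trace)
    }
  }
  ids <- vapply(seq_along(slots), function(i) {
    if (inherits(slots[[i]], "sway_slot")) slots[[i]]$source_id else as.character(i)
  }, character(1))
  cluster_solution(best$assignment, best$centroids, method = "dba",
                   total_cost = best$cost, restarts = restarts, seed = seed,
                   slot_ids = ids, cost_trace = best$trace)
}
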