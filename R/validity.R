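#' @title Cluster validity indices in DTW space
#'
#' @description
#' Davies-Bouldin (lower is better), Calinski-Harabasz (higher is better) and
#' Dunn (higher is better) indices for a partition of data slots. Because the
#' clustered objects are sequences, all three indices are evaluated in DTW
#' distance space rather than a Euclidean feature space: member-to-centroid
#' and centroid-to-centroid gaps are DTW distances to the solution's medoids
#' (PAM) or DBA averages (DBA), and squared DTW distances stand in for the
#' squared Euclidean deviations of the classical Calinski-Harabasz sums of
#' squares. The global center used by Calinski-Harabasz is the overall medoid
#' of all slots (PAM) or the DBA average of all slots (DBA).
#'
#' All three indices are invariant under relabeling of the clusters.
#'
#' @param solution A [cluster_solution()].
#' @param dm Distance matrix over the slots (required for PAM solutions and
#'   for [dunn_index()]).
#' @param slots The clustered slots (required for DBA solutions, whose
#'   centroids are sequences not present in `dm`).
#' @param mode Multivariate DTW mode used for centroid distances of DBA
#'   solutions.
#' @name validity_indices
NULL

# Distance geometry of a solution: n x K member-to-centroid distances,
# K x K centroid-to-centroid distances, K-vector centroid-to-global-center
# distances.
centroid_geometry <- function(solution, dm = NULL, slots = NULL,
                              mode = "independent") {
  K <- solution$K
  if (solution$method == "pam") {
    if (is.null(dm)) stop("PAM validity indices need the distance matrix")
    dm <- as.matrix(dm)
    memb <- dm[, solution$medoids, drop = FALSE]
    cent <- dm[solution$medoids, solution$medoids, drop = FALSE]
    g <- medoid_of(dm, seq_len(nrow(dm)))
    cent_glob <- dm[solution$medoids, g]
  } else {
    if (is.null(slots)) stop("DBA validity indices need the slots")
    mats <- lapply(slots, function(s) {
      as_sequence(if (inherits(s, "sway_slot")) s$data else s)
    })
    dep <- (mode == "dependent")
    cents <- solution$medoids
    memb <- vapply(cents, function(ct) {
      vapply(mats, function(m) cpp_dtw_distance(ct, m, dep), numeric(1))
    }, numeric(length(mats)))
    memb <- matrix(memb, nrow = length(mats))
    cent <- matrix(0, K, K)
    for (i in seq_len(K)) for (j in seq_len(K)) {
      if (i < j) cent[i, j] <- cent[j, i] <-
          cpp_dtw_distance(cents[[i]], cents[[j]], dep)
    }
    glob <- dba_average(mats, mode = mode)$sequence
    cent_glob <- vapply(cents, function(ct) cpp_dtw_distance(ct, glob, dep),
                        numeric(1))
  }
  list(memb = memb, cent = cent, cent_glob = cent_glob)
}

#' @rdname validity_indices
#' @details
#' `davies_bouldin()`: with `delta_i` the mean distance of cluster `i`'s
#' members to its centroid and `d(c_i, c_j)` the centroid gap,
#' `DB = (1/K) * sum_i max_{j != i} (delta_i + delta_j) / d(c_i, c_j)`.
#' Coincident centroids (a zero gap) make the ratio undefined and raise an
#' error flagging the degenerate solution.
#' @export
davies_bouldin <- function(solution, dm = NULL, slots = NULL,
                           mode = "independent") {
  K <- solution$K
  if (K < 2L) stop("Davies-Bouldin needs at least 2 clusters")
  geo <- centroid_geometry(solution, dm, slots, mode)
  delta <- vapply(seq_len(K), function(k) {
    mean(geo$memb[solution$assignment == k, k])
  }, numeric(1))
  off <- geo$cent[upper.tri(geo$cent)]
  if (any(off <= 0)) stop("degenerate solution: coincident cluster centroids")
  r <- vapply(seq_len(K), function(i) {
    max(vapply(setdiff(seq_len(K), i), function(j) {
      (delta[i] + delta[j]) / geo$cent[i, j]
    }, numeric(1)))
  }, numeric(1))
  mean(r)
}

#' @rdname validity_indices
#' @details
#' `calinski_harabasz()`: `C-H = ((N - K) / (K - 1)) * BGSS / WGSS`, where
#' `WGSS` is the sum of squared distances of members to their own centroid
#' and `BGSS = sum_i n_i * d(c_i, c_global)^2`. A zero `WGSS` (every member
#' coincides with its centroid) yields `+Inf` with a warning.
#' @export
calinski_harabasz <- function(solution, dm = NULL, slots = NULL,
                              mode = "independent") {
  K <- solution$K
  N <- length(solution$assignment)
  if (K < 2L) stop("Calinski-Harabasz needs at least 2 clusters")
  if (N <= K) stop("Calinski-Harabasz needs more slots than clusters")
  geo <- centroid_geometry(solution, dm, slots, mode)
  wgss <- sum(geo$memb[cbind(seq_len(N), solution$assignment)]^2)
  sizes <- tabulate(solution$assignment, K)
  bgss <- sum(sizes * geo$cent_glob^2)
  if (wgss == 0) {
    warning("zero within-cluster sum of squares; Calinski-Harabasz is +Inf")
    return(Inf)
  }
  ((N - K) / (K - 1)) * bgss / wgss
}

#' @rdname validity_indices
#' @details
#' `dunn_index()`: the minimum between-cluster slot-pair distance divided by
#' the maximum within-cluster slot-pair distance (the largest cluster
#' diameter). A zero diameter yields `+Inf` with a warning.
#' @export
dunn_index <- function(dm, solution) {
  K <- solution$K
  if (K < 2L) stop("Dunn index needs at least 2 clusters")
  dm <- as.matrix(dm)
  a <- solution$assignment
  n <- length(a)
  same <- outer(a, a, "==")
  diag_mask <- diag(TRUE, n)
  intra <- dm[same & !diag_mask]
  inter <- dm[!same]
  d_max <- if (length(intra)) max(intra) else 0
  d_min <- min(inter)
  if (d_max == 0) {
    warning("zero cluster diameter; Dunn index is +Inf")
    return(Inf)
  }
  d_min / d_max
}

#' Grid search over slot length and cluster count
#'
#' Reproduces the model-selection experiment of the pipeline: for every slot
#' length `t`, the cohort is preprocessed and its DTW distance matrix
#' computed once; for every cluster count `K` and method, the slots are
#' clustered (with `restarts` random initializations, keeping the lowest-cost
#' run) and the three validity indices of the winning solution are evaluated.
#'
#' The pipeline reports the full grid so an analyst can weigh the three
#' indices; a single cell is additionally flagged `chosen` by a majority
#' vote: each index votes for its best cell (minimum Davies-Bouldin, maximum
#' Calinski-Harabasz, maximum Dunn) and the cell with the most votes wins,
#' ties broken by the Calinski-Harabasz value.
#'
#' @param cohort List of [sway_recording()] objects.
#' @param ts Slot lengths (seconds) to try, e.g. `c(3, 5, 6, 10)`.
#' @param Ks Cluster counts to try, e.g. `3:5`.
#' @param methods Subset of `c("pam", "dba")`.
#' @param restarts,seed Clustering configuration.
#' @param mode Multivariate DTW mode.
#' @param cutoff,order Filter settings passed to [preprocess_cohort()].
#' @return Data frame with one row per `(t, K, method)`: `total_cost`, `ch`,
#'   `db`, `dunn` and logical `chosen`.
#' @export
grid_search <- function(cohort, ts = c(3, 5, 6, 10), Ks = 3:5,
                        methods = "pam", restarts = 10L, seed = 1L,
                        mode = c("independent", "dependent"),
                        cutoff = 12, order = 2) {
  mode <- match.arg(mode)
  stopifnot(length(ts) > 0, length(Ks) > 0, length(methods) > 0)
  rows <- list()
  for (t in ts) {
    slots <- preprocess_cohort(cohort, t = t, cutoff = cutoff, order = order)
    dm <- dtw_distance_matrix(slots, mode = mode)
    for (method in methods) {
      for (K in Ks) {
        sol <- if (method == "pam") {
          pam_cluster(dm, K, restarts = restarts, seed = seed)
        } else {
          dba_cluster(slots, K, restarts = restarts, seed = seed, mode = mode)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          t = t, K = K, method = method, total_cost = sol$total_cost,
          ch = calinski_harabasz(sol, dm = dm, slots = slots, mode = mode),
          db = davies_bouldin(sol, dm = dm, slots = slots, mode = mode),
          dunn = dunn_index(dm, sol),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  report <- do.call(rbind, rows)
  report$chosen <- seq_len(nrow(report)) == select_grid_cell(report)
  report
}

# Majority vote of the three indices; ties broken by Calinski-Harabasz.
select_grid_cell <- function(report) {
  votes <- c(which.max(report$ch), which.min(report$db), which.max(report$dunn))
  counts <- table(votes)
  winners <- as.integer(names(counts)[counts == max(counts)])
  if (length(winners) == 1L) return(winners)
  winners[which.max(report$ch[winners])]
}
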