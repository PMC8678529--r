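test_that("validity indices match hand-computed values on the 1-D toy partition", {
  toy <- toy_partition()
  # clusters {0,2} medoid 0 and {10,12} medoid 10, absolute distance:
  # delta1 = delta2 = 1, centroid gap 10 -> DB = 0.2
  expect_equal(davies_bouldin(toy$sol, dm = toy$dm), 0.2)
  # d_min = |10-2| = 8, d_max = 2 -> Dunn = 4
  expect_equal(dunn_index(toy$dm, toy$sol), 4)
  # global medoid of {0,2,10,12} is point 2 (sums 24,20,20,24; lowest index);
  # WGSS = 0+4+0+4 = 8, BGSS = 2*d(0,2)^2 + 2*d(10,2)^2 = 8+128 = 136
  # C-H = ((4-2)/(2-1)) * 136/8 = 34
  expect_equal(calinski_harabasz(toy$sol, dm = toy$dm), 34)
})

test_that("degenerate partitions hit the documented sentinels and errors", {
  # two singleton clusters: deltas are 0 -> DB = 0
  pts <- c(0, 7)
  dm <- abs(outer(pts, pts, "-"))
  sol <- cluster_solution(c(1L, 2L), medoids = c(1L, 2L), method = "pam")
  expect_equal(davies_bouldin(sol, dm = dm), 0)
  # coincident centroids are an error for DB
  dm0 <- matrix(0, 4, 4)
  sol2 <- cluster_solution(c(1L, 1L, 2L, 2L), medoids = c(1L, 3L),
                           method = "pam")
  expect_error(davies_bouldin(sol2, dm = dm0), "coincident")
  # duplicated points within each cluster: WGSS = 0 -> C-H sentinel +Inf
  pts <- c(0, 0, 9, 9)
  dmd <- abs(outer(pts, pts, "-"))
  expect_warning(ch <- calinski_harabasz(sol2, dm = dmd), "Inf")
  expect_identical(ch, Inf)
  expect_warning(dn <- dunn_index(dmd, sol2), "Inf")
  expect_identical(dn, Inf)
  expect_error(davies_bouldin(cluster_solution(rep(1L, 3), medoids = 1L,
                                               method = "pam"), dm = dm0),
               "at least 2")
})

test_that("indices equal brute-force reimplementations on random partitions", {
  set.seed(41)
  for (rep in 1:40) {
    n <- sample(8:30, 1)
    K <- sample(2:4, 1)
    dm <- random_dm(n)
    assignment <- sample(rep(seq_len(K), length.out = n))
    medoids <- vapply(seq_len(K), function(k) {
      medoid_of(dm, which(assignment == k))
    }, integer(1))
    sol <- cluster_solution(assignment, medoids = medoids, method = "pam")
    expect_equal(davies_bouldin(sol, dm = dm),
                 db_brute(dm, assignment, medoids))
    expect_equal(calinski_harabasz(sol, dm = dm),
                 ch_brute(dm, assignment, medoids))
    expect_equal(dunn_index(dm, sol), dunn_brute(dm, assignment))
  }
})

test_that("indices are invariant under cluster relabeling", {
  set.seed(42)
  dm <- random_dm(15)
  assignment <- sample(rep(1:3, 5))
  medoids <- vapply(1:3, function(k) medoid_of(dm, which(assignment == k)),
                    integer(1))
  sol <- cluster_solution(assignment, medoids, method = "pam")
  perm <- c(3L, 1L, 2L)
  sol_p <- cluster_solution(perm[assignment], medoids[order(perm)],
                            method = "pam")
  expect_equal(davies_bouldin(sol_p, dm = dm), davies_bouldin(sol, dm = dm))
  expect_equal(calinski_harabasz(sol_p, dm = dm),
               calinski_harabasz(sol, dm = dm))
  expect_equal(dunn_index(dm, sol_p), dunn_index(dm, sol))
})

test_that("indices improve monotonically as planted separation grows", {
  # three 1-D groups at separation s: DB falls, Dunn and C-H rise
  make <- function(s) {
    set.seed(43)
    pts <- c(rnorm(5, 0, 0.3), rnorm(5, s, 0.3), rnorm(5, 2 * s, 0.3))
    dm <- abs(outer(pts, pts, "-"))
    assignment <- rep(1:3, each = 5)
    medoids <- vapply(1:3, function(k) medoid_of(dm, which(assignment == k)),
                      integer(1))
    sol <- cluster_solution(assignment, medoids, method = "pam")
    c(db = davies_bouldin(sol, dm = dm),
      ch = calinski_harabasz(sol, dm = dm),
      dunn = dunn_index(dm, sol))
  }
  res <- sapply(c(5, 25, 125), make)
  expect_true(all(diff(res["db", ]) < 0))
  expect_true(all(diff(res["ch", ]) > 0))
  expect_true(all(diff(res["dunn", ]) > 0))
})

test_that("DBA solutions get indices from centroid-sequence distances", {
  set.seed(44)
  a <- matrix(sin(seq(0, 4 * pi, length.out = 25)), ncol = 1)
  b <- matrix(8 + sin(seq(0, 4 * pi, length.out = 25)), ncol = 1)
  slots <- c(lapply(1:3, function(i) a + rnorm(25, sd = 0.05)),
             lapply(1:3, function(i) b + rnorm(25, sd = 0.05)))
  sol <- dba_cluster(slots, K = 2, restarts = 2, seed = 1)
  dm <- dtw_distance_matrix(slots)
  expect_lt(davies_bouldin(sol, slots = slots), 0.5)
  expect_gt(calinski_harabasz(sol, slots = slots), 100)
  expect_gt(dunn_index(dm, sol), 1)
})

test_that("grid search reports all cells and flags one chosen configuration", {
  coh <- small_cohort(n_subjects = 6, duration = 10, seed = 45,
                      K_true = 3, cluster_freq = c(0.6, 1.0, 1.4),
                      cluster_amp = c(1, 3, 6))
  report <- grid_search(coh$recordings, ts = 5, Ks = 3:4, methods = "pam",
                        restarts = 5, seed = 1)
  expect_equal(nrow(report), 2L)
  expect_true(all(is.finite(report$ch)))
  expect_true(all(is.finite(report$db)))
  expect_true(all(is.finite(report$dunn)))
  expect_equal(sum(report$chosen), 1L)
})
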