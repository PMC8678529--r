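test_that("gate routes normal/homogeneous data to Tukey, otherwise Wilcoxon", {
  set.seed(61)
  tukey_picks <- sum(replicate(10, {
    groups <- lapply(1:3, function(i) rnorm(50))
    gate_test_choice(groups) == "tukey"
  }))
  expect_gte(tukey_picks, 6)  # each gate test falsely rejects ~5% of the time

  wilcox_picks <- sum(replicate(10, {
    groups <- list(rlnorm(50, sdlog = 1.5), rnorm(50), rnorm(50))
    gate_test_choice(groups) == "wilcoxon"
  }))
  expect_gte(wilcox_picks, 9)

  # heterogeneous variances fail Bartlett even when every group is normal
  set.seed(62)
  groups <- list(rnorm(80, sd = 1), rnorm(80, sd = 6), rnorm(80, sd = 1))
  expect_equal(gate_test_choice(groups), "wilcoxon")

  # constant groups: Shapiro-Wilk undefined -> Wilcoxon fallback
  expect_equal(gate_test_choice(list(rep(1, 10), rep(1, 10))), "wilcoxon")

  expect_warning(gate_test_choice(list(rnorm(30), rnorm(30), c(1, 2))),
                 "excluded")
  expect_error(suppressWarnings(gate_test_choice(list(c(1, 2), c(3, 4)))),
               "usable")
})

test_that("Benjamini-Hochberg adjustment reproduces the hand-worked step-up", {
  # raw p {0.01, 0.02, 0.04, 0.30}, m = 4:
  # step-up: 0.30*4/4 = .30; 0.04*4/3 = .05333; 0.02*4/2 = .04; 0.01*4/1 = .04
  # with monotonicity: {0.04, 0.04, 0.05333..., 0.30}
  raw <- c(0.01, 0.02, 0.04, 0.30)
  expect_equal(stats::p.adjust(raw, "BH"),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.30))
  # the same correction drives the pairwise table: 4 groups -> 6 pairs
  set.seed(63)
  groups <- list(rnorm(30), rnorm(30, 10), rnorm(30, 20), rnorm(30, 30))
  res <- pairwise_wilcoxon_bh(groups)
  expect_equal(nrow(res), 6L)
  expect_equal(res$p_adj, stats::p.adjust(res$p_raw, "BH"))
  expect_true(all(res$p_adj >= res$p_raw))
  expect_true(all(diff(res$p_adj[order(res$p_raw)]) >= -1e-15))
  expect_true(all(res$significant))
})

test_that("pairwise Wilcoxon flags overwhelming shifts and nothing under identity", {
  set.seed(64)
  base <- rnorm(30)
  res <- pairwise_wilcoxon_bh(list(base, base + 10 * sd(base)))
  expect_true(res$significant)
  res0 <- pairwise_wilcoxon_bh(list(base, base))
  expect_false(res0$significant)
  # zero-variance identical groups get p = 1 by convention
  resc <- pairwise_wilcoxon_bh(list(rep(1, 10), rep(1, 10)))
  expect_equal(resc$p_raw, 1)
  expect_error(pairwise_wilcoxon_bh(list(rnorm(5))), "at least 2")
})

test_that("Tukey-Kramer branch separates shifted normal groups", {
  set.seed(65)
  groups <- list(a = rnorm(40), b = rnorm(40, 5), c = rnorm(40, 0.05))
  res <- pairwise_tukey(groups)
  expect_equal(nrow(res), 3L)
  ab <- res$significant[(res$group1 == "a" & res$group2 == "b") |
                          (res$group1 == "b" & res$group2 == "a")]
  ac <- res$significant[(res$group1 == "a" & res$group2 == "c") |
                          (res$group1 == "c" & res$group2 == "a")]
  expect_true(ab)
  expect_false(ac)
})

test_that("under a shuffled-label null the family positive rate stays near alpha", {
  set.seed(66)
  hits <- replicate(100, {
    groups <- split(rnorm(80), rep(1:4, 20))
    any(pairwise_wilcoxon_bh(groups, alpha = 0.05)$significant)
  })
  expect_lte(mean(hits), 3 * 0.05)
})

test_that("significance table attributes amplitude-only differences correctly", {
  # two planted clusters share the sway frequency and differ in amplitude
  coh <- small_cohort(n_subjects = 8, duration = 15, seed = 67, K_true = 2,
                      cluster_freq = c(1.0, 1.0), cluster_amp = c(1, 6))
  slots <- preprocess_cohort(coh$recordings, t = 5)
  truth <- slot_truth(slots, coh$truth)
  meds <- c(which(truth == 1)[1], which(truth == 2)[1])
  sol <- cluster_solution(truth, medoids = as.integer(meds), method = "pam")
  feats <- featurize(slots, sol)
  tab <- build_significance_table(feats)
  expect_equal(nrow(tab), 33L * 3L)
  amp_hits <- sum(tab$n_significant[tab$parameter == "amplitude"] > 0)
  sd_hits <- sum(tab$n_significant[tab$parameter == "sd"] > 0)
  freq_hits <- sum(tab$n_significant[tab$parameter == "frequency"] > 0)
  expect_gt(amp_hits, 25)
  expect_gt(sd_hits, 25)
  expect_lt(freq_hits, amp_hits / 2)
  expect_true(all(tab$pairs[tab$n_significant == 0] == "None"))
  # K = 1 is rejected
  sol1 <- cluster_solution(rep(1L, length(slots)), medoids = 1L,
                           method = "pam")
  expect_error(build_significance_table(featurize(slots, sol1)),
               "at least 2")
})

test_that("transition table reports per-session labels, majority and ties", {
  # hand-built slots: one subject, 6 slots labeled 4 4 4 4 2 2
  mk_slot <- function(subject, days, k, disease = "CH") {
    structure(list(source_id = paste0(subject, "@", days, "#", k),
                   slot_index = k, subject_id = subject, disease = disease,
                   age = 60, days_after_onset = as.integer(days),
                   hemiplegia = "left", rate = 60,
                   data = matrix(0, 4, 33)), class = "sway_slot")
  }
  slots <- c(lapply(1:6, function(k) mk_slot("CH3", 58, k)),
             lapply(1:6, function(k) mk_slot("CH9", 300, k)))
  sol <- cluster_solution(c(4L, 4L, 4L, 4L, 2L, 2L, 1L, 1L, 1L, 3L, 3L, 3L),
                          medoids = c(1L, 5L, 10L, 2L), method = "pam")
  tab <- build_transition_table(slots, sol)
  expect_equal(nrow(tab), 2L)
  ch3 <- tab[tab$subject_id == "CH3", ]
  expect_equal(ch3$slot_labels, "4 4 4 4 2 2")
  expect_equal(ch3$majority, 4L)
  expect_false(ch3$tie)
  ch9 <- tab[tab$subject_id == "CH9", ]
  expect_equal(ch9$majority, 1L)  # 3-3 tie resolves to the lower index
  expect_true(ch9$tie)
})
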