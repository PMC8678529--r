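#' Choose the post-hoc test branch for one feature family
#'
#' Before comparing a sway parameter between clusters, the distributional
#' assumptions of the parametric branch are checked: every cluster's values
#' must look normal (Shapiro-Wilk, `p >= alpha_gate` in each group) and the
#' group variances homogeneous (Bartlett, `p >= alpha_gate`). Only if both
#' hold is the Tukey-Kramer branch used; any failure — including groups on
#' which the tests are undefined (constant values) — routes to the pairwise
#' Wilcoxon branch.
#'
#' @param groups List of numeric vectors, one per cluster. Groups with fewer
#'   than 3 values are excluded with a warning; fewer than 2 usable groups is
#'   an error.
#' @param alpha_gate Gate significance level (default 0.05).
#' @return `"tukey"` or `"wilcoxon"`.
#' @export
gate_test_choice <- function(groups, alpha_gate = 0.05) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  usable <- lengths(groups) >= 3L
  if (any(!usable)) {
    warning(sum(!usable), " group(s) with fewer than 3 values excluded")
  }
  groups <- groups[usable]
  if (length(groups) < 2L) stop("fewer than 2 usable groups")
  shapiro_ok <- vapply(groups, function(g) {
    p <- tryCatch(stats::shapiro.test(g)$p.value, error = function(e) NA_real_)
    !is.na(p) && p >= alpha_gate
  }, logical(1))
  if (!all(shapiro_ok)) return("wilcoxon")
  bart_p <- tryCatch(stats::bartlett.test(groups)$p.value,
                     error = function(e) NA_real_)
  if (is.na(bart_p) || bart_p < alpha_gate) return("wilcoxon")
  "tukey"
}

#' Pairwise Wilcoxon rank-sum tests with Benjamini-Hochberg adjustment
#'
#' Rank-sum (Mann-Whitney) test for every unordered pair of clusters — the
#' cluster groups are disjoint slot sets, so the unpaired test applies. All
#' `choose(K, 2)` p-values of one (variable, parameter) family are adjusted
#' jointly by the Benjamini-Hochberg step-up procedure. Adjusted p-values are
#' monotone in, and no smaller than, the raw p-values. A pair of identical
#' zero-variance groups gets `p = 1` by convention.
#'
#' @param groups Named or unnamed list of numeric vectors, one per cluster
#'   (names default to `1..K`).
#' @param alpha Significance level applied to adjusted p-values.
#' @return Data frame with one row per pair: `group1`, `group2`, `p_raw`,
#'   `p_adj`, `significant`.
#' @export
pairwise_wilcoxon_bh <- function(groups, alpha = 0.05) {
  K <- length(groups)
  if (K < 2L) stop("need at least 2 groups")
  if (is.null(names(groups))) names(groups) <- seq_len(K)
  pairs <- utils::combn(K, 2L)
  p_raw <- apply(pairs, 2L, function(ij) {
    x <- groups[[ij[1L]]]
    y <- groups[[ij[2L]]]
    if (length(unique(c(x, y))) == 1L) return(1)
    stats::wilcox.test(x, y, exact = FALSE)$p.value
  })
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  data.frame(
    group1 = names(groups)[pairs[1L, ]], group2 = names(groups)[pairs[2L, ]],
    p_raw = p_raw, p_adj = p_adj, significant = p_adj < alpha,
    stringsAsFactors = FALSE
  )
}

#' Tukey-Kramer pairwise comparisons
#'
#' Studentized-range pairwise comparisons via one-way ANOVA and
#' [stats::TukeyHSD()]; the Kramer extension handles unequal group sizes.
#' Same return schema as [pairwise_wilcoxon_bh()] (the `p_adj` column holds
#' the family-wise adjusted Tukey p-value and `p_raw` repeats it, since the
#' procedure has no separate unadjusted stage).
#'
#' @inheritParams pairwise_wilcoxon_bh
#' @export
pairwise_tukey <- function(groups, alpha = 0.05) {
  K <- length(groups)
  if (K < 2L) stop("need at least 2 groups")
  if (is.null(names(groups))) names(groups) <- seq_len(K)
  value <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  tk <- stats::TukeyHSD(stats::aov(value ~ g))$g
  lab <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(
    group1 = vapply(lab, `[`, character(1), 2L),
    group2 = vapply(lab, `[`, character(1), 1L),
    p_raw = tk[, "p adj"], p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Between-cluster significance table over all variables and parameters
#'
#' For each of the 33 kinematic variables and each sway parameter
#' (amplitude, SD, frequency), the slots' values are grouped by cluster, the
#' test branch is gated per family ([gate_test_choice()]), the pairwise
#' comparisons are run, and the set of cluster pairs with adjusted `p <
#' alpha` is reported. Multiplicity is corrected within each
#' (variable, parameter) family — the `choose(K, 2)` pairs of one row — not
#' across rows, matching the per-row reporting of the significance table.
#'
#' Slots from one recording are not statistically independent; the procedure
#' treats them as exchangeable observations by design, faithfully mirroring
#' the slot-level analysis it implements.
#'
#' @param features Feature table from [featurize()] with cluster labels.
#' @param alpha Significance level on adjusted p-values.
#' @param alpha_gate Gate level for the branch choice.
#' @return Data frame with one row per (variable, parameter): `variable`,
#'   `part`, `side`, `axis`, `parameter`, `branch`, `pairs` (e.g.
#'   `"1&2, 3&4"`, or `"None"`), `n_significant`.
#' @export
build_significance_table <- function(features, alpha = 0.05,
                                     alpha_gate = 0.05) {
  if (anyNA(features$cluster)) stop("features carry no cluster labels")
  clusters <- sort(unique(features$cluster))
  if (length(clusters) < 2L) stop("need at least 2 clusters")
  rows <- list()
  for (v in sort(unique(features$variable))) {
    fv <- features[features$variable == v, , drop = FALSE]
    for (param in c("amplitude", "sd", "frequency")) {
      vals <- fv[[param]]
      groups <- lapply(clusters, function(k) {
        x <- vals[fv$cluster == k]
        x[!is.na(x)]
      })
      names(groups) <- clusters
      branch <- suppressWarnings(gate_test_choice(groups, alpha_gate))
      res <- if (branch == "tukey") {
        pairwise_tukey(groups, alpha)
      } else {
        pairwise_wilcoxon_bh(groups, alpha)
      }
      sig <- res[res$significant, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, part = fv$part[1L], side = fv$side[1L],
        axis = fv$axis[1L], parameter = param, branch = branch,
        pairs = if (nrow(sig) == 0L) "None" else
          paste(paste0(sig$group1, "&", sig$group2), collapse = ", "),
        n_significant = nrow(sig),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Cluster membership by days after stroke onset
#'
#' Tabulates, per recording session, the cluster labels of its slots in time
#' order together with the majority label ("main cluster"), sorted by subject
#' and then by days after onset — the layout used to inspect whether
#' patients transit between sway clusters as recovery progresses. A majority
#' tie is resolved to the lowest cluster index and flagged.
#'
#' @param slots List of `sway_slot` objects (with subject metadata).
#' @param solution A [cluster_solution()] aligned with `slots`.
#' @return Data frame with one row per (subject, session): `subject_id`,
#'   `disease`, `days_after_onset`, `slot_labels` (space-separated, time
#'   order), `majority`, `tie`.
#' @export
build_transition_table <- function(slots, solution) {
  if (length(solution$assignment) != length(slots)) {
    stop("solution does not match the slot list")
  }
  meta <- data.frame(
    subject_id = vapply(slots, function(s) s$subject_id, character(1)),
    disease = vapply(slots, function(s) s$disease, character(1)),
    days_after_onset = vapply(slots, function(s) {
      as.integer(s$days_after_onset)
    }, integer(1)),
    slot_index = vapply(slots, function(s) s$slot_index, integer(1)),
    label = solution$assignment,
    stringsAsFactors = FALSE
  )
  if (anyNA(meta$days_after_onset)) {
    warning("sessions with missing days-after-onset are flagged and sorted last")
  }
  key <- paste(meta$subject_id, meta$days_after_onset, sep = "\r")
  rows <- lapply(split(meta, key), function(m) {
    m <- m[order(m$slot_index), , drop = FALSE]
    counts <- tabulate(m$label, max(solution$K, max(m$label)))
    top <- which(counts == max(counts))
    data.frame(
      subject_id = m$subject_id[1L], disease = m$disease[1L],
      days_after_onset = m$days_after_onset[1L],
      slot_labels = paste(m$label, collapse = " "),
      majority = top[1L], tie = length(top) > 1L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id, out$days_after_onset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Demographic characteristics per cluster
#'
#' Summarizes, for each cluster of a solution, the slots' subject metadata:
#' slot count, median days after onset, median age and the disease-type mix —
#' the companion table to a chosen clustering solution.
#'
#' @param slots List of `sway_slot` objects.
#' @param solution A [cluster_solution()] aligned with `slots`.
#' @return Data frame with one row per cluster: `cluster`, `n_slots`,
#'   `median_days_after_onset`, `median_age`, `pct_CH`, `pct_CI`.
#' @export
cluster_characteristics <- function(slots, solution) {
  if (length(solution$assignment) != length(slots)) {
    stop("solution does not match the slot list")
  }
  days <- vapply(slots, function(s) as.numeric(s$days_after_onset), numeric(1))
  age <- vapply(slots, function(s) as.numeric(s$age), numeric(1))
  disease <- vapply(slots, function(s) s$disease, character(1))
  do.call(rbind, lapply(seq_len(solution$K), function(k) {
    in_k <- solution$assignment == k
    data.frame(
      cluster = k, n_slots = sum(in_k),
      median_days_after_onset = stats::median(days[in_k], na.rm = TRUE),
      median_age = stats::median(age[in_k], na.rm = TRUE),
      pct_CH = 100 * mean(disease[in_k] == "CH"),
      pct_CI = 100 * mean(disease[in_k] == "CI"),
      stringsAsFactors = FALSE
    )
  }))
}
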