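# Target-gene rate stage: per-species molecular rates on terminal branches,
# with/without-regulator group means per TF-TG interaction, and a paired test
# of the deceleration hypothesis (d = without - with; a planted deceleration
# makes d negative).

#' Terminal-branch molecular rates of a target-gene tree
#'
#' rate(i) = terminal branch length of species i (subs/site) divided by the
#' terminal branch duration of i in the species tree (My). The tree must be
#' single-copy per species for the attribution to be unambiguous.
#'
#' @param tg_gt `genetree` with species-id leaves (or `<species>_1` labels)
#' @param tt `timetree`
#' @return named numeric vector, subs/site/My; species absent from the tree
#'   are omitted
#' @export
terminal_rates <- function(tg_gt, tt) {
  phy <- tg_gt$phy
  sp <- tg_gt$species
  if (anyDuplicated(sp)) stop("target-gene tree is not single-copy per species")
  known <- sp %in% names(tt$tip_id)
  dur <- branch_durations(tt)
  tip_edge <- match(seq_along(sp), phy$edge[, 2])
  len <- phy$edge.length[tip_edge]
  rates <- len[known] / dur[sp[known]]
  stats::setNames(as.numeric(rates), sp[known])
}

#' Group-mean terminal rates for one TF-TG pair
#'
#' @param rates named per-species rates (from [terminal_rates()])
#' @param tf_presence named 0/1 vector: presence of the regulator per species
#' @param min_group minimum species per group (default 3); smaller groups
#'   exclude the pair
#' @return one-row data.frame (x = mean with TF, y = mean without TF, n_x,
#'   n_y) or NULL when excluded
#' @export
pair_means <- function(rates, tf_presence, min_group = 3) {
  common <- intersect(names(rates), names(tf_presence))
  r <- rates[common]; p <- tf_presence[common]
  with_tf <- r[p == 1]; without_tf <- r[p == 0]
  if (length(with_tf) < min_group || length(without_tf) < min_group) return(NULL)
  data.frame(x = mean(with_tf), y = mean(without_tf),
             n_x = length(with_tf), n_y = length(without_tf))
}

#' Paired test of rate deceleration over TF-TG pairs
#'
#' One-sample two-sided t test of d = y - x (without minus with) against 0,
#' with a Wilcoxon signed-rank companion. d < 0 means target genes evolve
#' more slowly in species that lost the regulator.
#'
#' @param pairs data.frame with columns x, y (one row per pair)
#' @return list: t, p, mean_diff, wilcoxon_p, n
#' @export
paired_test <- function(pairs) {
  d <- pairs$y - pairs$x
  d <- d[is.finite(d)]
  if (length(d) < 2) stop("need at least 2 pairs with finite differences")
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, mean_diff = 0, wilcoxon_p = 1,
                                 n = length(d)))
    return(list(t = sign(mean(d)) * Inf, p = 0, mean_diff = mean(d),
                wilcoxon_p = NA_real_, n = length(d)))
  }
  tt_ <- stats::t.test(d)
  w <- suppressWarnings(stats::wilcox.test(d))
  list(t = unname(tt_$statistic), p = tt_$p.value, mean_diff = mean(d),
       wilcoxon_p = w$p.value, n = length(d))
}

#' Deceleration analysis over a TF-TG interaction list
#'
#' For every interaction, terminal rates of the target-gene tree are split by
#' regulator presence; group means give one (x, y) scatter point (x: species
#' still possessing the regulator, y: species that lost it). Points below the
#' diagonal support the deceleration reading. Each TF-TG interaction
#' contributes one pair (pseudo-replication across shared targets is
#' documented, mode `by = "tg"` aggregates regulators per target instead).
#'
#' @param tg_trees named list of target-gene `genetree`s (names = tg_id)
#' @param interactions data.frame with columns tf_og_id, tg_id
#' @param presence binary species x TF matrix (single-copy presence)
#' @param tt `timetree`
#' @param min_group minimum group size per side
#' @param by `"interaction"` (default) or `"tg"` (mean x/y over a target's
#'   regulators)
#' @return list: `pairs` (scatter table tf_og_id, tg_id, x, y, n_x, n_y),
#'   `test` ([paired_test()] output), `excluded` (data.frame with reasons)
#' @export
deceleration_analysis <- function(tg_trees, interactions, presence, tt,
                                  min_group = 3, by = c("interaction", "tg")) {
  by <- match.arg(by)
  pairs <- list(); excluded <- list()
  for (i in seq_len(nrow(interactions))) {
    tf <- interactions$tf_og_id[i]; tg <- interactions$tg_id[i]
    if (is.null(tg_trees[[tg]])) {
      excluded[[length(excluded) + 1L]] <- data.frame(tf_og_id = tf, tg_id = tg,
                                                      reason = "no target tree")
      next
    }
    if (!tf %in% colnames(presence)) {
      excluded[[length(excluded) + 1L]] <- data.frame(tf_og_id = tf, tg_id = tg,
                                                      reason = "TF not in presence matrix")
      next
    }
    rates <- terminal_rates(tg_trees[[tg]], tt)
    pm <- pair_means(rates, presence[, tf], min_group)
    if (is.null(pm)) {
      excluded[[length(excluded) + 1L]] <- data.frame(tf_og_id = tf, tg_id = tg,
                                                      reason = "group below min_group")
      next
    }
    pairs[[length(pairs) + 1L]] <- cbind(tf_og_id = tf, tg_id = tg, pm)
  }
  pairs <- do.call(rbind, c(pairs, list(make.row.names = FALSE)))
  excluded <- do.call(rbind, c(excluded, list(make.row.names = FALSE)))
  if (is.null(excluded)) excluded <- data.frame(tf_og_id = character(0),
                                                tg_id = character(0),
                                                reason = character(0))
  if (is.null(pairs) || nrow(pairs) == 0) stop("no valid TF-TG pairs")
  if (by == "tg") {
    agg <- stats::aggregate(cbind(x, y) ~ tg_id, data = pairs, FUN = mean)
    test <- paired_test(agg)
  } else {
    test <- paired_test(pairs)
  }
  list(pairs = pairs, test = test, excluded = excluded)
}

#' Monte-Carlo calibration of the paired deceleration test
#'
#' Simulates `n_reps` studies of `n_pairs` TF-TG pairs under the generator's
#' rate model (per-species lognormal noise, deceleration `delta` for the
#' without-TF group) and reports the rejection rate of the two-sided paired t
#' test at level `alpha`. `delta = 0` measures type-I error; `delta > 0`
#' measures power.
#'
#' @param n_pairs pairs per study
#' @param n_reps number of simulated studies
#' @param delta deceleration factor in [0, 1)
#' @param sigma_g lognormal noise sd
#' @param n_with,n_without species per group (defaults 8 and 4: species that
#'   lost a regulator are typically the minority)
#' @param alpha test level
#' @param seed optional RNG seed
#' @return list: rejection_rate, mean_diff (average over studies), n_reps
#' @export
calibrate_paired_test <- function(n_pairs = 500, n_reps = 1000, delta = 0,
                                  sigma_g = 0.2, n_with = 8, n_without = 4,
                                  alpha = 0.05, seed = NULL) {
  if (delta < 0 || delta >= 1) stop("delta must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  base <- 0.002
  rej <- logical(n_reps); md <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    xw <- matrix(base * stats::rlnorm(n_pairs * n_with, 0, sigma_g),
                 n_pairs, n_with)
    xo <- matrix(base * (1 - delta) * stats::rlnorm(n_pairs * n_without, 0, sigma_g),
                 n_pairs, n_without)
    d <- rowMeans(xo) - rowMeans(xw)
    tt_ <- stats::t.test(d)
    rej[r] <- tt_$p.value < alpha
    md[r] <- mean(d)
  }
  list(rejection_rate = mean(rej), mean_diff = mean(md), n_reps = n_reps)
}
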