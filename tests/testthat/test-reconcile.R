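test_that("LCA mapping matches hand computation and satisfies its invariants", {
  s <- abc_timetree()
  g <- gt_parse("((A_1,B_1),(A_2,C_1));")
  m <- lca_map(g, s)
  # tips map to their species; ((a1,b1)) -> AB ancestor; (a2,c1) and root -> root
  ab <- setdiff(seq_along(s$labels), c(s$tip_id, s$root))
  expect_equal(unname(m$M[1:4]), unname(s$tip_id[c("A", "B", "A", "C")]))
  expect_equal(m$M[5], s$root)          # gene root
  expect_equal(m$M[6], ab)              # (a1,b1)
  expect_equal(m$M[7], s$root)          # (a2,c1)
  # ancestor-or-equal along every gene edge
  for (i in seq_len(nrow(g$phy$edge))) {
    v <- g$phy$edge[i, 1]; c0 <- g$phy$edge[i, 2]
    a <- m$M[c0]
    repeat {
      if (a == m$M[v]) break
      expect_false(a == s$root)
      a <- s$parent[a]
    }
  }
  expect_error(lca_map(gt_parse("(X_1,(B_1,C_1));"), s), "X")
})

test_that("worked discordance examples match the exhaustive oracle", {
  s <- abc_timetree()
  cases <- list(
    # congruent single copy: no events
    list(g = "((A_1,B_1),C_1);", D = 0, L = 0),
    # classic discordance: one duplication, three losses
    list(g = "(A_1,(B_1,C_1));", D = 1, L = 3),
    # root duplication with one lost copy on each of B and C
    list(g = "((A_1,B_1),(A_2,C_1));", D = 1, L = 2)
  )
  for (cs in cases) {
    g <- gt_parse(cs$g)
    rec <- classify_events(g, s, assume_root_origin = FALSE)
    expect_equal(rec$D, cs$D, info = cs$g)
    expect_equal(rec$L, cs$L, info = cs$g)
    expect_equal(rec$cost, oracle_min_dl(g, s), info = cs$g)
    expect_equal(rec$D, oracle_min_dl(g, s, 1, 0), info = cs$g)
    expect_equal(rec$L, oracle_min_dl(g, s, 0, 1), info = cs$g)
  }
  # stem-origin convention: family restricted to A and B loses the C copy
  rec <- classify_events(gt_parse("((A_1,B_1),(A_2,B_2));"), s,
                         assume_root_origin = TRUE)
  expect_equal(rec$D, 1)
  expect_equal(rec$L, 1)
  expect_equal(rec$events$branch_id[rec$events$type == "loss"], "C")
})

test_that("LCA reconciliation attains the exhaustive minimum on random instances", {
  set.seed(42)
  for (i in seq_len(80)) {
    k <- sample(3:5, 1)
    tt <- random_species_timetree(k)
    gt <- random_gene_tree(LETTERS[seq_len(k)], sample(4:7, 1), 2)
    rec <- classify_events(gt, tt, assume_root_origin = FALSE)
    expect_equal(rec$cost, oracle_min_dl(gt, tt), info = write_newick(gt))
    expect_equal(rec$D, oracle_min_dl(gt, tt, 1, 0), info = write_newick(gt))
    expect_equal(rec$L, oracle_min_dl(gt, tt, 0, 1), info = write_newick(gt))
  }
})

test_that("event counts are invariant to leaf order and copy relabeling", {
  s <- abc_timetree()
  g1 <- gt_parse("((A_1,B_1),(A_2,C_1));")
  g2 <- gt_parse("((A_9,C_1),(B_4,A_3));")  # rotated + relabeled copies
  r1 <- classify_events(g1, s)
  r2 <- classify_events(g2, s)
  expect_equal(c(r1$D, r1$L), c(r2$D, r2$L))
  expect_equal(sort(r1$events$branch_id), sort(r2$events$branch_id))
})

test_that("DL rooting minimizes cost over all edges (brute-force check)", {
  s <- abc_timetree()
  g <- genetree(ape::unroot(gt_parse("((A_1:1,B_1:1):1,C_1:2);")$phy))
  rooted <- root_gene_tree(g, s)
  expect_equal(attr(rooted, "root_cost"), 0)
  expect_equal(classify_events(rooted, s)$cost, 0)

  set.seed(7)
  for (i in seq_len(15)) {
    k <- sample(3:5, 1)
    tt <- random_species_timetree(k)
    gt <- random_gene_tree(LETTERS[seq_len(k)], sample(5:8, 1), 2)
    un <- genetree(ape::unroot(gt$phy))
    best <- root_gene_tree(un, tt)
    expect_equal(attr(best, "root_cost"),
                 min(all_rooting_costs(un, tt)), info = write_newick(gt))
  }
})

test_that("mu is the mean root-to-tip path over the root age, per generation", {
  g <- gt_parse("((A_1:0.3,B_1:0.38):0.04,C_1:0.34);")
  # mean path = (0.34 + 0.42 + 0.34)/3; A = 1.7e8 y, g = 10 y
  mp <- mean(c(0.34, 0.42, 0.34))
  expect_equal(compute_mu(g, 1.7e8, 10), 10 * mp / 1.7e8)
  expect_error(compute_mu(g, 0), "positive")
  g0 <- gt_parse("((A_1:0,B_1:0):0,C_1:0);")
  expect_warning(mu0 <- compute_mu(g0, 1.7e8), "zero-length")
  expect_equal(mu0, 0)

  # clock identity on simulated trees: mu ~ generation_years * rate / 1e6
  tt <- study_tree()
  fam <- simulate_gene_family(tt, 0, 0, seed = 5)
  gt <- assign_branch_lengths(fam$gt, 0.002, 0)
  expect_equal(compute_mu(gt, 170e6, 10), 10 * 0.002 / 1e6, tolerance = 1e-9)
})

test_that("weak edges are internal edges strictly under the threshold", {
  g <- gt_parse("(((A_1:1,B_1:1):0.01,C_1:1):0.05,D_1:1);")
  expect_length(weak_edges(g, 0), 0)
  expect_equal(sort(weak_edges(g, 10)), sort(g$phy$edge[g$phy$edge[, 2] > 4, 2]))
  w <- weak_edges(g, 0.02)
  expect_length(w, 1)  # only the 0.01 edge; terminal edges never weak
  expect_equal(threshold_value(threshold_spec(1e6, 10),
                               gt_parse("((A_1:0.17,B_1:0.17):0.17,C_1:0.34);"),
                               abc_timetree_170()), 0.02)
})

test_that("weak-edge rearrangement absorbs an ILS-style NNI and never increases cost", {
  tt <- study_tree()
  set.seed(19)
  for (i in seq_len(8)) {
    # congruent family; ILS perturbation plants pure topological noise
    fam <- simulate_gene_family(tt, 0, 0)
    gt <- assign_branch_lengths(fam$gt, 0.002, 0)
    pert <- perturb_ils(gt, 0.01, 1)
    rec0 <- classify_events(pert, tt)
    rec <- rearrange_weak(pert, tt, 0.011)
    expect_lte(rec$cost, rec0$cost)
    # the noise-free history (no events at all) is recovered
    expect_equal(c(rec$D, rec$L), c(0, 0))
  }
  # event-bearing families: rearrangement can only reduce the cost
  for (i in seq_len(8)) {
    fam <- simulate_gene_family(tt, 0.002, 0.003)
    if (is.null(fam$gt) || sum(fam$members) < 4) next
    gt <- perturb_ils(assign_branch_lengths(fam$gt, 0.002, 0.2), 0.01, 1)
    rec0 <- classify_events(gt, tt)
    rec <- rearrange_weak(gt, tt, 0.011)
    expect_lte(rec$cost, rec0$cost)
  }
  # no weak edges: identical to plain classification
  g <- gt_parse("((A_1:1,B_1:1):1,C_1:2);")
  r <- rearrange_weak(g, abc_timetree(), 1e-6)
  expect_equal(c(r$D, r$L), c(0, 0))
})

test_that("rearrangement cost is monotone in the threshold", {
  tt <- study_tree()
  set.seed(23)
  for (i in seq_len(6)) {
    fam <- simulate_gene_family(tt, 0.002, 0.003)
    if (is.null(fam$gt) || sum(fam$members) < 4) next
    gt <- perturb_ils(assign_branch_lengths(fam$gt, 0.002, 0.3), 0.01, 0.3)
    costs <- vapply(c(0.002, 0.01, 0.03), function(Tv) {
      rearrange_weak(gt, tt, Tv)$cost
    }, numeric(1))
    expect_true(all(diff(costs) <= 1e-9))
  }
})

test_that("reconcile_og recovers observable truth exactly in the noise-free regime", {
  tt <- study_tree()
  set.seed(33)
  n_checked <- 0
  for (i in seq_len(25)) {
    fam <- simulate_gene_family(tt, 0.002, 0.004, og_id = sprintf("og%d", i))
    if (is.null(fam$gt)) next
    gt <- assign_branch_lengths(fam$gt, 0.002, 0.2)
    rec <- reconcile_og(ortholog_group(fam$og_id, gt), tt, ne = NULL)
    inferred <- table(rec$events$type, rec$events$branch_id)
    truth <- table(fam$observable$type, fam$observable$branch_id)
    expect_equal(sum(rec$events$type == "gain"), sum(fam$observable$type == "gain"))
    expect_equal(sum(rec$events$type == "loss"), sum(fam$observable$type == "loss"))
    # branch-level agreement
    all_b <- union(colnames(inferred), colnames(truth))
    for (ty in c("gain", "loss")) {
      iv <- sapply(all_b, function(b) if (ty %in% rownames(inferred) && b %in% colnames(inferred)) inferred[ty, b] else 0)
      tv <- sapply(all_b, function(b) if (ty %in% rownames(truth) && b %in% colnames(truth)) truth[ty, b] else 0)
      expect_equal(iv, tv, info = paste(fam$og_id, ty))
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 10)
})

test_that("ortholog-group filter keeps families with more than three members", {
  s <- abc_timetree()
  g4 <- ortholog_group("a", gt_parse("((A_1,B_1),(A_2,C_1));"))
  g3 <- ortholog_group("b", gt_parse("((A_1,B_1),C_1);"))
  kept <- filter_ogs(list(g4, g3))
  expect_length(kept, 1)
  expect_equal(kept[[1]]$og_id, "a")
})
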