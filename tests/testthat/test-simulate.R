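test_that("species-tree simulation is deterministic and hits the root age exactly", {
  tt <- simulate_species_timetree(3, 170, seed = 3)
  expect_equal(tt$n_tip, 3)
  expect_equal(tt$phy$Nnode, 2)
  expect_equal(tt$ages[tt$root], 170)
  expect_identical(write_newick(simulate_species_timetree(16, 170, seed = 9)),
                   write_newick(simulate_species_timetree(16, 170, seed = 9)))
  expect_error(simulate_species_timetree(2, 170), "at least 3")
})

test_that("divergence ages follow the conditioned pure-birth expectation", {
  # closed form for the truncated-exponential age density:
  # E[age] = 1/birth - A / (exp(birth * A) - 1)
  A <- 100; birth <- 0.01
  expected <- 1 / birth - A / (exp(birth * A) - 1)
  set.seed(21)
  ages <- unlist(lapply(seq_len(400), function(i) {
    tt <- simulate_species_timetree(8, A, birth)
    a <- tt$ages[(tt$n_tip + 1):length(tt$ages)]
    a[a < A]  # non-root divergences
  }))
  se <- stats::sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - expected), 4 * se + 1e-9)
})

test_that("zero-rate gene families are congruent with the species tree", {
  tt <- study_tree()
  fam <- simulate_gene_family(tt, 0, 0, seed = 1)
  expect_equal(nrow(fam$events), 0)
  expect_equal(unname(fam$members), rep(1L, 16))
  expect_equal(sort(fam$gt$species), sort(names(tt$tip_id)))
  rec <- classify_events(fam$gt, tt)
  expect_equal(c(rec$D, rec$L), c(0, 0))
})

test_that("every simulated event lies within its branch's age interval", {
  tt <- study_tree()
  bt <- branch_table(tt)
  set.seed(4)
  batch <- simulate_og_batch(tt, 30, 0.003, 0.005)
  ev <- merge(batch$events, bt, by = "branch_id")
  expect_true(all(ev$time <= ev$parent_age + 1e-9 & ev$time >= ev$child_age - 1e-9))
  # per-branch totals match event-list tallies (conservation)
  tot <- table(batch$events$type)
  expect_equal(sum(batch$events$type == "gain") + sum(batch$events$type == "loss"),
               nrow(batch$events))
  expect_identical(
    simulate_og_batch(tt, 5, 0.003, 0.005, seed = 77)$events,
    simulate_og_batch(tt, 5, 0.003, 0.005, seed = 77)$events
  )
})

test_that("a high loss rate on one terminal branch removes that species", {
  tt <- study_tree()
  dur <- branch_durations(tt)
  mu <- 2 / dur[["s01"]]  # survival probability e^-2 ~ 0.135
  set.seed(8)
  pres <- vapply(seq_len(300), function(i) {
    fam <- simulate_gene_family(tt, 0, c(s01 = mu))
    fam$members[["s01"]] > 0
  }, logical(1))
  p <- mean(pres)
  expect_lt(p, 0.25)
  expect_gt(p, 0.06)
})

test_that("branch lengths follow the lognormal relaxed clock", {
  tt <- study_tree()
  fam <- simulate_gene_family(tt, 0, 0, seed = 2)
  gt0 <- assign_branch_lengths(fam$gt, 0.002, 0)
  # strict clock: all root-to-tip paths equal rate * root age
  d <- ape::node.depth.edgelength(gt0$phy)[seq_len(16)]
  expect_equal(d, rep(0.002 * 170, 16), tolerance = 1e-9)
  expect_error(assign_branch_lengths(fam$gt, -1), "non-negative")

  sigma <- 0.5
  span <- fam$gt$node_age[fam$gt$phy$edge[, 1]] - fam$gt$node_age[fam$gt$phy$edge[, 2]]
  set.seed(31)
  ratios <- unlist(lapply(seq_len(350), function(i) {
    g <- assign_branch_lengths(fam$gt, 0.002, sigma)
    g$phy$edge.length / (0.002 * span)
  }))
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - exp(sigma^2 / 2)), 4 * se)
})

test_that("ILS perturbation rearranges only short edges, 50/50 over the two NNIs", {
  g <- gt_parse("((A_1:1,B_1:1):0.001,(C_1:1,D_1:1):1);")
  expect_identical(write_newick(perturb_ils(g, 0.01, 0)), write_newick(g))
  expect_identical(write_newick(perturb_ils(g, 0, 1)), write_newick(g))
  outside <- vapply(seq_len(200), function(s) {
    p <- perturb_ils(g, 0.01, 1, seed = s)
    # after NNI at the short edge, one of A/B becomes the root-child leaf
    root_kids <- p$phy$edge[p$phy$edge[, 1] == 5, 2]
    leaf <- root_kids[root_kids <= 4]
    expect_length(leaf, 1)
    p$phy$tip.label[leaf]
  }, character(1))
  expect_true(all(outside %in% c("A_1", "B_1")))
  f <- mean(outside == "A_1")
  expect_gt(f, 0.35); expect_lt(f, 0.65)
})

test_that("trait simulation follows the logistic model", {
  set.seed(12)
  pm <- simulate_presence_matrix(5000, 3, c(0.3, 0.7))
  y0 <- simulate_traits(pm, colnames(pm)[1], 0, beta0 = -1, seed = 1)
  expect_lt(abs(mean(y0) - stats::plogis(-1)), 0.03)

  y2 <- simulate_traits(pm, colnames(pm)[1:2], c(2, -2), beta0 = 0.5, seed = 2)
  eta <- 0.5 + 2 * pm[, 1] - 2 * pm[, 2]
  expect_equal(unname(attr(y2, "prob")), unname(stats::plogis(eta)))

  ysat <- simulate_traits(pm, colnames(pm)[1], 20, beta0 = -10, seed = 3)
  expect_equal(as.integer(ysat), unname(pm[, 1]))

  pm2 <- cbind(pm, const = 1)
  expect_warning(simulate_traits(pm2, "const", 1, seed = 4), "constant")
})

test_that("target-gene rates are decelerated by exactly 1-delta without noise", {
  tt <- study_tree()
  absent <- names(tt$tip_id)[1:5]
  sim <- simulate_tg_rates(tt, absent, base_rate = 0.002, delta = 0.3, sigma_g = 0)
  expect_equal(unname(sim$rates[absent]), rep(0.002 * 0.7, 5))
  expect_equal(unname(sim$rates[setdiff(names(sim$rates), absent)]),
               rep(0.002, 11))
  expect_error(simulate_tg_rates(tt, absent, delta = 1), "delta")

  # lognormal noise cancels in the group-mean ratio
  set.seed(55)
  sums <- c(with = 0, without = 0)
  for (i in seq_len(400)) {
    s <- simulate_tg_rates(tt, absent, 0.002, 0.3, sigma_g = 0.2)
    sums["with"] <- sums["with"] + mean(s$rates[setdiff(names(s$rates), absent)])
    sums["without"] <- sums["without"] + mean(s$rates[absent])
  }
  expect_lt(abs(sums[["without"]] / sums[["with"]] - 0.7), 0.02)
})
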