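test_that("aggregation sums events per branch and conserves totals", {
  tt <- abc_timetree()
  empty <- aggregate_events(list(), tt)
  expect_true(all(empty$gains == 0) && all(empty$losses == 0))

  ev <- data.frame(type = c("loss", "loss", "gain"),
                   branch_id = c("A", "A", "C"))
  atlas <- aggregate_events(ev, tt)
  expect_equal(atlas$losses[atlas$branch_id == "A"], 2)
  expect_equal(atlas$gains[atlas$branch_id == "C"], 1)
  expect_equal(sum(atlas$gains), sum(ev$type == "gain"))
  expect_equal(sum(atlas$losses), sum(ev$type == "loss"))
  expect_error(aggregate_events(data.frame(type = "loss", branch_id = "Z"), tt),
               "unknown branch")
})

test_that("aggregated atlas equals observable truth totals in the noise-free regime", {
  tt <- study_tree()
  set.seed(14)
  batch <- simulate_og_batch(tt, 40, 0.0015, 0.003)
  ogs <- lapply(batch$ogs, function(f) {
    ortholog_group(f$og_id, assign_branch_lengths(f$gt, 0.002, 0.2))
  })
  recs <- reconcile_batch(ogs, tt, ne = NULL)
  atlas <- aggregate_events(recs$recs, tt)
  truth <- batch$observable[batch$observable$og_id %in% names(ogs), ]
  expect_equal(sum(atlas$losses) + nrow(attr(atlas, "root_events")[
    attr(atlas, "root_events")$type == "loss", , drop = FALSE]),
    sum(truth$type == "loss"))
  tl <- table(factor(truth$branch_id[truth$type == "loss"],
                     levels = atlas$branch_id))
  expect_equal(atlas$losses, as.integer(tl))
})

test_that("branch rates divide counts by durations", {
  expect_equal(branch_rate(10, 5), 2)
  expect_equal(branch_rate(0, 5), 0)
  expect_error(branch_rate(1, 0), "positive")
})

test_that("windowed rates smear events uniformly and conserve totals", {
  # one branch spanning [20, 10] Mya with 6 losses
  tt <- parse_newick("((A:10,B:10):10,C:20);", "species")
  ab <- setdiff(seq_along(tt$labels), c(tt$tip_id, tt$root))
  ev <- data.frame(type = rep("loss", 6), branch_id = tt$labels[ab])
  atlas <- aggregate_events(ev, tt)
  w1 <- window_rates(atlas, c(20, 10))
  expect_equal(w1$losses, 6)
  expect_equal(w1$loss_rate, 0.6)
  w2 <- window_rates(atlas, c(20, 15))
  expect_equal(w2$losses, 3)  # half the branch
  expect_error(window_rates(atlas, c(20, 20, 10)), "zero-width")

  # full-span windowing conserves totals on a simulated atlas
  tt2 <- study_tree()
  set.seed(3)
  batch <- simulate_og_batch(tt2, 20, 0.002, 0.004)
  atlas2 <- aggregate_events(batch$events[, c("type", "branch_id")], tt2)
  wins <- window_rates(atlas2, seq(170, 0, by = -8.5))
  expect_equal(sum(wins$losses), sum(atlas2$losses), tolerance = 1e-9)
  expect_equal(sum(wins$gains), sum(atlas2$gains), tolerance = 1e-9)
})

test_that("epoch means average the rates of branches alive in the epoch", {
  tt <- parse_newick("((A:10,B:10):10,C:20);", "species")
  ab <- tt$labels[setdiff(seq_along(tt$labels), c(tt$tip_id, tt$root))]
  ev <- data.frame(type = c(rep("loss", 20), rep("loss", 20)),
                   branch_id = c(rep(ab, 20), rep("C", 20)))
  atlas <- aggregate_events(ev, tt)
  # internal branch rate 2.0/My, C rate 1.0/My; epoch [20,10]: both alive
  expect_equal(lineage_mean_rate(atlas, c(20, 10)), 1.5)
  # epoch [10, 0]: A, B (rate 0) and C alive
  expect_equal(lineage_mean_rate(atlas, c(10, 0)), 1 / 3)
  expect_warning(r <- lineage_mean_rate(atlas, c(40, 30)), "no branch alive")
  expect_true(is.na(r))
})

test_that("planted loss-rate spikes surface as the top-rate branches", {
  tt <- study_tree()
  bt <- branch_table(tt)
  # two deep, long internal branches get a planted loss load (no background)
  anc <- plant_spike_branches(tt, 2, 10)
  loss <- spike_rates(tt, anc, base_loss = 0)
  set.seed(99)
  batch <- simulate_og_batch(tt, 100, 0.0005, loss)
  atlas <- aggregate_events(batch$observable[, c("type", "branch_id")], tt)
  top2 <- atlas$branch_id[order(atlas$loss_rate, decreasing = TRUE)][1:2]
  expect_setequal(top2, anc)
})
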