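# Self-contained recovery experiments over the synthetic generator. Each
# returns the quantities its acceptance check asserts, so the test suite and
# the reproduction script share one experiment definition.

#' ILS-threshold experiment
#'
#' Simulates families under the study conditions, perturbs short gene-tree
#' edges (the ILS mimic), and reconciles (i) with no threshold and (ii) with
#' the matched Nmu threshold (Ne = 1e6 under the generator's clock), plus a
#' full Ne sweep. False events are the excess of inferred over
#' truth-observable event counts.
#'
#' @param n_taxa,root_age,n_og,dup_rate,loss_rate,rate,sigma_r,p_ils,eps_len
#'   study conditions (defaults as in [default_config()])
#' @param ne_grid effective population sizes, ascending
#' @param seed RNG seed
#' @return list: `false_t0`, `false_matched`, `sweep_totals` (named by Ne),
#'   `true_total`
#' @export
ils_threshold_experiment <- function(n_taxa = 16, root_age = 170, n_og = 80,
                                     dup_rate = 0.0015, loss_rate = 0.003,
                                     rate = 0.002, sigma_r = 0.3, p_ils = 0.2,
                                     eps_len = 0.01,
                                     ne_grid = c(1e4, 1e5, 1e6, 1e7),
                                     seed = 1) {
  tt <- simulate_species_timetree(n_taxa, root_age, seed = seed)
  set.seed(seed)
  batch <- simulate_og_batch(tt, n_og, dup_rate, loss_rate)
  ogs <- list()
  for (id in names(batch$ogs)) {
    gt <- assign_branch_lengths(batch$ogs[[id]]$gt, rate, sigma_r)
    ogs[[id]] <- ortholog_group(id, perturb_ils(gt, eps_len, p_ils))
  }
  ogs <- filter_ogs(ogs)
  true_total <- sum(batch$observable$og_id %in% names(ogs))
  t0 <- reconcile_batch(ogs, tt, ne = NULL)
  matched <- reconcile_batch(ogs, tt, ne = 1e6)
  sweep <- reconcile_sweep(ogs, tt, ne_grid = ne_grid)
  list(
    false_t0 = nrow(t0$events) - true_total,
    false_matched = nrow(matched$events) - true_total,
    sweep_totals = vapply(sweep, function(b) nrow(b$events), numeric(1)),
    true_total = true_total
  )
}

#' Loss rates with planted spikes on chosen branches
#'
#' Spikes are planted as an expected per-lineage event *load*: the spiked
#' branch's rate is `spike_load / duration`, so each family crossing it
#' suffers ~`spike_load` expected losses regardless of branch length. A rate
#' spike fixed in events/My would either be lethal on a 100-My branch
#' (erasing the families that carry the signal) or invisible on a short one.
#'
#' @param tt `timetree`
#' @param spikes branch ids to spike
#' @param base_loss background loss rate (events/lineage/My)
#' @param spike_load expected losses per lineage crossing a spiked branch
#' @return named per-branch loss-rate vector
#' @export
spike_rates <- function(tt, spikes, base_loss = 0.001, spike_load = 0.8) {
  bt <- branch_table(tt)
  loss <- stats::setNames(rep(base_loss, nrow(bt)), bt$branch_id)
  loss[spikes] <- spike_load / bt$duration[match(spikes, bt$branch_id)]
  loss
}

#' Planted loss-spike recovery experiment
#'
#' Plants elevated loss on the two oldest long internal branches (an
#' expected 0.8 losses per family lineage crossing them) over a loss-free
#' background and asks whether the reconciliation atlas localizes and ranks
#' them on top. The background is noise-free by design: per-branch *rates*
#' divide by durations spanning two orders of magnitude, so even a tiny
#' background loss rate lets a single chance event on a sub-My branch
#' out-rank a genuine spike — that regime is exercised separately by the
#' ILS-threshold experiment and the truth-recovery tests, while this
#' experiment isolates localization.
#'
#' @param n_taxa,root_age,n_og,dup_rate,base_loss,spike_load,rate,sigma_r
#'   study conditions
#' @param seed RNG seed
#' @return list: `spikes` (planted branch ids), `top2` (top loss-rate
#'   branches), `rho` (Spearman, inferred vs true per-branch loss counts),
#'   `conserved` (aggregation conservation, logical), `atlas`
#' @export
spike_recovery <- function(n_taxa = 16, root_age = 170, n_og = 200,
                           dup_rate = 5e-4, base_loss = 0,
                           spike_load = 0.8, rate = 0.002, sigma_r = 0.2,
                           seed = 1) {
  tt <- simulate_species_timetree(n_taxa, root_age, seed = seed)
  spikes <- plant_spike_branches(tt, 2, 10)
  loss <- spike_rates(tt, spikes, base_loss, spike_load)
  set.seed(seed)
  batch <- simulate_og_batch(tt, n_og, dup_rate, loss)
  ogs <- lapply(batch$ogs, function(f) {
    ortholog_group(f$og_id, assign_branch_lengths(f$gt, rate, sigma_r))
  })
  recs <- reconcile_batch(ogs, tt, ne = NULL)
  atlas <- aggregate_events(recs$recs, tt)
  truth_losses <- table(factor(
    batch$events$branch_id[batch$events$type == "loss"], levels = atlas$branch_id))
  n_loss <- sum(vapply(recs$recs, function(r) sum(r$events$type == "loss"), numeric(1)))
  n_root <- sum(attr(atlas, "root_events")$type == "loss")
  list(
    spikes = spikes,
    top2 = atlas$branch_id[order(atlas$loss_rate, decreasing = TRUE)][1:2],
    rho = stats::cor(atlas$losses, as.integer(truth_losses), method = "spearman"),
    conserved = identical(sum(atlas$losses) + n_root, as.integer(n_loss)),
    atlas = atlas
  )
}
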