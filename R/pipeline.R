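# Config-driven orchestration of the full chain on synthetic data:
# simulate -> reconcile -> atlas -> associate -> tgrates, with every stage
# output written as TSV/newick under an output directory and a manifest
# recording the configuration, seed and file checksums. One master seed
# drives a single RNG stream, so a fixed config yields byte-identical
# artifacts.

#' Default pipeline configuration (the study conditions)
#'
#' Desk-scale stand-in for the mammalian setting: 16 taxa under a 170-My
#' root; families originate as single copies at the root and duplicate/die
#' at per-lineage rates chosen to yield a handful of events per family;
#' branch lengths follow a relaxed clock around 0.002 subs/site/My; a fifth
#' of short internal edges are NNI-perturbed below 0.01 subs/site (the ILS
#' mimic); the Nmu threshold uses Ne = 1e6 and 10-year generations.
#'
#' @param seed master seed
#' @return nested config list
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    species = list(n_taxa = 16, root_age = 170, birth = 0.025),
    families = list(n_og = 60, dup_rate = 0.0015, loss_rate = 0.003,
                    min_members = 4),
    lengths = list(rate = 0.002, sigma_r = 0.3),
    ils = list(p_ils = 0.2, eps_len = 0.01),
    reconcile = list(ne = 1e6, generation_years = 10,
                     costs = c(dup = 1, loss = 1), k_max = 6, hard_cap = 12,
                     assume_root_origin = TRUE),
    atlas = list(window_width = 10),
    association = list(alpha = 0.05, nfolds = 5, n_causal = 3, beta_abs = 2),
    tgrates = list(base_rate = 0.002, delta = 0.3, sigma_g = 0.2,
                   min_group = 3, n_tf = 8)
  )
}

#' Run the full synthetic-analysis pipeline
#'
#' @param config list as from [default_config()]
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list with the in-memory stage results
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  paths <- character(0)
  emit <- function(name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    paths <<- c(paths, p)
    p
  }

  # -- simulate ---------------------------------------------------------------
  sp <- config$species
  tt <- simulate_species_timetree(sp$n_taxa, sp$root_age, sp$birth)
  emit("species_tree.nwk", function(p) write_newick(tt, p))
  fam <- config$families
  batch <- simulate_og_batch(tt, fam$n_og, fam$dup_rate, fam$loss_rate)
  ogs <- list()
  for (id in names(batch$ogs)) {
    gt <- batch$ogs[[id]]$gt
    gt <- assign_branch_lengths(gt, config$lengths$rate, config$lengths$sigma_r)
    gt <- perturb_ils(gt, config$ils$eps_len, config$ils$p_ils)
    ogs[[id]] <- ortholog_group(id, gt)
  }
  ogs <- filter_ogs(ogs, fam$min_members)
  emit("gene_trees.nwk", function(p) {
    writeLines(vapply(ogs, function(og) write_newick(og$gt), character(1)), p)
  })
  emit("truth_events.tsv", function(p) write_tsv(batch$events, p))
  emit("truth_observable.tsv", function(p) write_tsv(batch$observable, p))
  pm <- build_single_copy_matrix(batch$counts)
  emit("presence.tsv", function(p) write_tsv(as.data.frame(pm), p, "species"))

  # -- reconcile --------------------------------------------------------------
  rc <- config$reconcile
  recs <- reconcile_batch(ogs, tt, ne = rc$ne,
                          generation_years = rc$generation_years,
                          assume_root_origin = rc$assume_root_origin,
                          costs = rc$costs, k_max = rc$k_max,
                          hard_cap = rc$hard_cap)
  emit("events.tsv", function(p) write_tsv(recs$events, p))
  if (nrow(recs$skipped)) emit("skipped.tsv", function(p) write_tsv(recs$skipped, p))

  # -- atlas ------------------------------------------------------------------
  atlas <- aggregate_events(recs$recs, tt)
  emit("atlas.tsv", function(p) write_tsv(as.data.frame(atlas), p))
  w <- config$atlas$window_width
  wins <- window_rates(atlas, seq(tt$ages[tt$root], 0, by = -w))
  emit("windows.tsv", function(p) write_tsv(wins, p))

  # -- associate --------------------------------------------------------------
  as_cfg <- config$association
  assoc <- NULL; trait <- NULL
  if (ncol(pm) >= as_cfg$n_causal) {
    causal <- colnames(pm)[seq_len(as_cfg$n_causal)]
    beta <- as_cfg$beta_abs * rep_len(c(-1, 1), as_cfg$n_causal)
    beta0 <- -sum(beta * colMeans(pm[, causal, drop = FALSE]))
    trait <- simulate_traits(pm, causal, beta, beta0)
    emit("traits.tsv", function(p) {
      write_tsv(data.frame(species = names(trait), trait = as.integer(trait)), p)
    })
    assoc <- suppressWarnings(
      associate_trait(pm, trait, alpha = as_cfg$alpha, nfolds = as_cfg$nfolds)
    )
    emit("association.tsv", function(p) write_tsv(assoc$table, p))
  }

  # -- tgrates ----------------------------------------------------------------
  tg_cfg <- config$tgrates
  usable <- colnames(pm)[colSums(pm == 0) >= tg_cfg$min_group &
                         colSums(pm == 1) >= tg_cfg$min_group]
  tg <- NULL
  if (length(usable)) {
    tfs <- utils::head(usable, tg_cfg$n_tf)
    tg_trees <- list(); inter <- list()
    for (i in seq_along(tfs)) {
      tg_id <- sprintf("tg%03d", i)
      absent <- rownames(pm)[pm[, tfs[i]] == 0]
      sim <- simulate_tg_rates(tt, absent, tg_cfg$base_rate, tg_cfg$delta,
                               tg_cfg$sigma_g)
      tg_trees[[tg_id]] <- sim$gt
      inter[[i]] <- data.frame(tf_og_id = tfs[i], tg_id = tg_id)
    }
    interactions <- do.call(rbind, inter)
    emit("interactions.tsv", function(p) write_tsv(interactions, p))
    tg <- deceleration_analysis(tg_trees, interactions, pm, tt,
                                min_group = tg_cfg$min_group)
    emit("tg_pairs.tsv", function(p) write_tsv(tg$pairs, p))
    emit("tg_test.tsv", function(p) {
      write_tsv(data.frame(t = tg$test$t, p = tg$test$p,
                           mean_diff = tg$test$mean_diff,
                           wilcoxon_p = tg$test$wilcoxon_p, n = tg$test$n), p)
    })
  }

  # -- manifest ---------------------------------------------------------------
  manifest <- list(
    package = "tfatlas",
    version = as.character(utils::packageVersion("tfatlas")),
    seed = config$seed,
    config = config,
    outputs = as.list(tools::md5sum(sort(paths)))
  )
  names(manifest$outputs) <- basename(sort(paths))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(tt = tt, ogs = ogs, batch = batch, presence = pm,
                 recs = recs, atlas = atlas, trait = trait, assoc = assoc,
                 tg = tg))
}
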