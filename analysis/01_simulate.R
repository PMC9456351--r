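#!/usr/bin/env Rscript
# Stage 1 — synthetic study conditions.
#
# Simulates a 16-taxon, 170-My species time tree and 60 gene families that
# originate as single copies at the root, duplicate/die along the branches,
# get relaxed-clock substitution lengths, and have a fifth of their short
# internal edges NNI-perturbed (the incomplete-lineage-sorting mimic).
# Writes the dataset plus the ground-truth event tables.

suppressMessages(library(tfatlas))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- default_config(seed = 20260921)
set.seed(cfg$seed)

tt <- simulate_species_timetree(cfg$species$n_taxa, cfg$species$root_age,
                                cfg$species$birth)
write_newick(tt, file.path(out, "species_tree.nwk"))

batch <- simulate_og_batch(tt, cfg$families$n_og, cfg$families$dup_rate,
                           cfg$families$loss_rate)
rows <- list()
for (id in names(batch$ogs)) {
  gt <- assign_branch_lengths(batch$ogs[[id]]$gt, cfg$lengths$rate,
                              cfg$lengths$sigma_r)
  gt <- perturb_ils(gt, cfg$ils$eps_len, cfg$ils$p_ils)
  rows[[id]] <- data.frame(og_id = id, newick = write_newick(gt))
}
write_tsv(do.call(rbind, rows), file.path(out, "gene_trees.tsv"))
write_tsv(batch$events, file.path(out, "truth_events.tsv"))
write_tsv(batch$observable, file.path(out, "truth_observable.tsv"))
pm <- build_single_copy_matrix(batch$counts)
write_tsv(as.data.frame(pm), file.path(out, "presence.tsv"), "species")

cat("species tree: ", cfg$species$n_taxa, " taxa, root ",
    cfg$species$root_age, " Mya\n", sep = "")
cat("families simulated: ", cfg$families$n_og,
    " (fully extinct: ", length(batch$empty),
    "; with >= 2 surviving copies: ", length(batch$ogs), ")\n", sep = "")
cat("true events: ", sum(batch$events$type == "gain"), " gains, ",
    sum(batch$events$type == "loss"), " losses (",
    nrow(batch$observable), " observable)\n", sep = "")
cat("single-copy presence matrix: ", nrow(pm), " species x ", ncol(pm),
    " families\n", sep = "")
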