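#!/usr/bin/env Rscript
# Stage 3 — the gain/loss atlas.
#
# Aggregates the Ne = 1e6 reconciliation events onto species-tree branches,
# derives per-My gain/loss rates, 10-My windowed rates and a 5-My epoch
# series of mean rates, and reports the peak loss windows.

suppressMessages(library(tfatlas))

out <- "results/atlas"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
tt <- parse_newick("results/data/species_tree.nwk", "species")
events <- utils::read.delim("results/reconcile/events_ne1000000.tsv",
                            stringsAsFactors = FALSE)

atlas <- aggregate_events(events[, c("type", "branch_id")], tt)
write_tsv(as.data.frame(atlas), file.path(out, "atlas.tsv"))

root_age <- tt$ages[tt$root]
wins <- window_rates(atlas, seq(root_age, 0, by = -10))
write_tsv(wins, file.path(out, "windows.tsv"))
eps <- epoch_series(atlas, width = 5, what = "loss")
write_tsv(eps, file.path(out, "epoch_loss_rates.tsv"))

cat("atlas totals: ", sum(atlas$gains), " gains, ", sum(atlas$losses),
    " losses over ", nrow(atlas), " branches\n", sep = "")
peak <- wins[which.max(wins$loss_rate), ]
cat(sprintf("peak loss window: [%g, %g] Mya at %.3f losses/My\n",
            peak$window_start, peak$window_end, peak$loss_rate))
top <- atlas[order(atlas$loss_rate, decreasing = TRUE)[1:3],
             c("branch_id", "duration", "losses", "loss_rate")]
cat("top loss-rate branches:\n")
print(top, row.names = FALSE)
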