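# Shared fixtures, built in code.

# three-species ultrametric tree: ((A:1,B:1):1,C:2);
abc_timetree <- function() parse_newick("((A:1,B:1):1,C:2);", "species")

# gene tree text shortcuts over species A, B, C (unit lengths)
gt_parse <- function(text) parse_newick(text, "gene")

# mammal-scale three-species tree (root 170 Mya)
abc_timetree_170 <- function() parse_newick("((A:100,B:100):70,C:170);", "species")

# the printed sociality/TF table (solitary = 1), bundled as extdata
table1_path <- function() {
  system.file("extdata", "table1_sociality.tsv", package = "tfatlas")
}

table1_fixture <- function() {
  df <- utils::read.delim(table1_path(), stringsAsFactors = FALSE)
  rownames(df) <- df$species
  df
}

# a 16-taxon study-condition fixture shared by threshold/atlas tests
study_tree <- function(seed = 101) simulate_species_timetree(16, 170, 0.025, seed = seed)
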