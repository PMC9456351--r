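# Tree and table containers shared by every stage of the pipeline.
#
# Species trees are stored node-age based (Mya): rate computations need branch
# durations in My, not raw newick lengths. Gene trees keep their branch
# lengths in substitutions/site and map each leaf to a species via the
# reserved "_" separator in the leaf label.

TIME_TOL <- 1e-6

#' Parse a newick string into a species time tree or a gene tree
#'
#' Species trees must be rooted, binary and ultrametric (leaf ages 0); their
#' branch lengths are read as durations in My and converted to node ages.
#' Gene trees carry branch lengths in substitutions/site and leaves labeled
#' `<species_id>_<copy_index>` (a label without `_` is taken as a bare
#' species id, the single-copy convention used for target-gene trees).
#'
#' @param text Newick string (or a file path containing one tree).
#' @param kind `"species"` or `"gene"`.
#' @return A `timetree` or `genetree` object.
#' @export
parse_newick <- function(text, kind = c("species", "gene")) {
  kind <- match.arg(kind)
  phy <- tryCatch(
    suppressWarnings(
      if (file.exists(text)) ape::read.tree(text) else ape::read.tree(text = text)
    ),
    error = function(e) stop("newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(phy)) stop("newick parse error: no tree found", call. = FALSE)
  if (kind == "species") timetree(phy) else genetree(phy)
}

#' Construct a time-calibrated species tree
#'
#' @param phy An `ape::phylo` object, rooted and binary, with branch lengths
#'   in My (ultrametric) so that node ages can be recovered with leaves at 0.
#' @param ages Optional explicit node ages (Mya), one per node in `phylo`
#'   node numbering (tips first). Overrides lengths when given.
#' @return Object of class `timetree`: the phylo tree plus node ages, parent
#'   pointers, topological depths and branch ids (each branch named by its
#'   child node label).
#' @export
timetree <- function(phy, ages = NULL) {
  if (!inherits(phy, "phylo")) stop("phy must be an ape phylo object")
  if (!ape::is.rooted(phy)) stop("species tree must be rooted")
  n_tip <- length(phy$tip.label)
  n_node <- phy$Nnode
  tab <- tabulate(phy$edge[, 1], nbins = n_tip + n_node)
  bad <- which(tab > 2 | (tab == 1 & seq_along(tab) > n_tip))
  if (length(bad)) {
    lab <- node_labels_raw(phy)
    stop("species tree is not binary at node '", lab[bad[1]], "'")
  }
  if (is.null(ages)) {
    if (is.null(phy$edge.length)) stop("species tree needs branch lengths or explicit ages")
    depth <- ape::node.depth.edgelength(phy)
    root_age <- max(depth[seq_len(n_tip)])
    if (any(abs(depth[seq_len(n_tip)] - root_age) > TIME_TOL * max(root_age, 1))) {
      stop("species tree is not ultrametric: leaf ages are assumed 0 but root-to-tip path lengths differ")
    }
    ages <- root_age - depth
    ages[seq_len(n_tip)] <- 0
  }
  if (anyDuplicated(phy$tip.label)) stop("duplicated species labels in tree")
  # deterministic internal labels when absent
  if (is.null(phy$node.label) || any(is.na(phy$node.label)) || any(phy$node.label == "")) {
    phy$node.label <- paste0("N", seq_len(n_node))
  }
  labels <- c(phy$tip.label, phy$node.label)
  if (anyDuplicated(labels)) stop("node labels must be unique across tips and internal nodes")
  parent <- integer(n_tip + n_node)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- n_tip + 1L
  depth_top <- integer(n_tip + n_node)
  ord <- preorder_nodes(phy)
  for (v in ord[-1]) depth_top[v] <- depth_top[parent[v]] + 1L
  for (v in seq_len(n_tip + n_node)) {
    if (v != root && ages[parent[v]] <= ages[v] - TIME_TOL) {
      stop("node '", labels[v], "' is older than its parent")
    }
  }
  children <- vector("list", n_tip + n_node)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    children[[p]] <- c(children[[p]], phy$edge[i, 2])
  }
  structure(list(
    phy = phy, ages = as.numeric(ages), labels = labels,
    n_tip = n_tip, root = root, parent = parent, depth = depth_top,
    children = children,
    tip_id = stats::setNames(seq_len(n_tip), phy$tip.label)
  ), class = "timetree")
}

node_labels_raw <- function(phy) {
  nl <- phy$node.label
  if (is.null(nl)) nl <- paste0("node", seq_len(phy$Nnode))
  c(phy$tip.label, nl)
}

preorder_nodes <- function(phy) {
  e <- ape::reorder.phylo(phy, "cladewise")$edge
  c(length(phy$tip.label) + 1L, e[, 2])
}

postorder_edges <- function(phy) {
  ape::reorder.phylo(phy, "postorder")$edge
}

#' Construct a gene tree
#'
#' @param phy An `ape::phylo`; branch lengths in substitutions/site when
#'   present. May be unrooted (flagged; reconciliation roots it first).
#' @param node_age Optional node ages in Mya (simulation output), used to
#'   convert time spans into substitutions when assigning branch lengths.
#' @return Object of class `genetree` with the per-leaf species id recovered
#'   from the `<species>_<copy>` naming convention.
#' @export
genetree <- function(phy, node_age = NULL) {
  if (!inherits(phy, "phylo")) stop("phy must be an ape phylo object")
  if (!is.null(phy$edge.length) && any(phy$edge.length < -1e-12)) {
    stop("gene tree has negative branch lengths")
  }
  structure(list(
    phy = phy,
    species = leaf_species(phy$tip.label),
    rooted = ape::is.rooted(phy),
    node_age = node_age
  ), class = "genetree")
}

#' Species ids of gene-tree leaves
#'
#' Strips the final `_<copy_index>` component; a label without `_` is
#' returned unchanged (single-copy convention).
#' @param labels Character vector of leaf labels.
#' @return Character vector of species ids.
#' @export
leaf_species <- function(labels) {
  ifelse(grepl("_", labels), sub("_[^_]*$", "", labels), labels)
}

#' Check that every gene-tree leaf maps to a species in the time tree
#' @param gt genetree
#' @param tt timetree
#' @return Invisibly TRUE; error naming the first unknown species otherwise.
#' @export
check_leaf_consistency <- function(gt, tt) {
  missing <- setdiff(unique(gt$species), names(tt$tip_id))
  if (length(missing)) {
    stop("gene-tree species not present in species tree: ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Branch durations of a time tree
#'
#' @param tt timetree
#' @return Named numeric vector, one entry per non-root node (branch named by
#'   its child label), `duration = age(parent) - age(child)` in My.
#' @export
branch_durations <- function(tt) {
  v <- setdiff(seq_along(tt$labels), tt$root)
  d <- tt$ages[tt$parent[v]] - tt$ages[v]
  names(d) <- tt$labels[v]
  bad <- which(d <= 0)
  if (length(bad)) stop("non-positive duration on branch '", names(d)[bad[1]], "'")
  d
}

#' Branch table of a time tree
#'
#' @param tt timetree
#' @return data.frame with branch_id, parent_age, child_age, duration,
#'   child_node (internal node index), is_tip.
#' @export
branch_table <- function(tt) {
  v <- setdiff(seq_along(tt$labels), tt$root)
  data.frame(
    branch_id = tt$labels[v],
    parent_age = tt$ages[tt$parent[v]],
    child_age = tt$ages[v],
    duration = tt$ages[tt$parent[v]] - tt$ages[v],
    child_node = v,
    is_tip = v <= tt$n_tip,
    stringsAsFactors = FALSE
  )
}

#' Lowest common ancestor of a set of species-tree nodes
#' @param tt timetree
#' @param ids integer node ids
#' @return integer node id
#' @export
lca_nodes <- function(tt, ids) {
  a <- ids[1]
  for (b in ids[-1]) {
    while (tt$depth[a] > tt$depth[b]) a <- tt$parent[a]
    while (tt$depth[b] > tt$depth[a]) b <- tt$parent[b]
    while (a != b) { a <- tt$parent[a]; b <- tt$parent[b] }
  }
  a
}

#' Write a tree to newick
#' @param x timetree, genetree or phylo
#' @param file Optional path; when NULL the newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return Newick string (invisibly when writing to file).
#' @export
write_newick <- function(x, file = NULL, digits = 12) {
  phy <- if (inherits(x, "phylo")) x else x$phy
  s <- ape::write.tree(phy, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Read a species/feature table (TSV)
#'
#' @param path TSV file with a header; first column holds species ids for the
#'   binary schemas.
#' @param schema `"presence"` (binary species x OG), `"trait"` (binary with
#'   missing values allowed) or `"interaction"` (columns tf_og_id, tg_id).
#' @param species Optional character vector of known species; rows for other
#'   species are dropped with a warning (count reported).
#' @return data.frame (binary schemas: species ids as row names).
#' @export
read_table <- function(path, schema = c("presence", "trait", "interaction"),
                       species = NULL) {
  schema <- match.arg(schema)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (schema == "interaction") {
    need <- c("tf_og_id", "tg_id")
    if (!all(need %in% names(df))) {
      stop("interaction table must have columns: ", paste(need, collapse = ", "))
    }
    return(df[, need, drop = FALSE])
  }
  if (ncol(df) < 2) stop(schema, " table needs a species column plus data columns")
  sp <- as.character(df[[1]])
  m <- df[, -1, drop = FALSE]
  for (j in seq_along(m)) {
    vals <- m[[j]]
    ok <- is.na(vals) | vals %in% c(0, 1)
    if (schema == "presence") ok <- !is.na(vals) & vals %in% c(0, 1)
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop("non-binary cell in ", schema, " table at row ", i,
           " (species '", sp[i], "'), column '", names(m)[j], "': ", vals[i])
    }
  }
  rownames(m) <- sp
  if (!is.null(species)) {
    unknown <- setdiff(sp, species)
    if (length(unknown)) {
      warning("dropping ", length(unknown), " species absent from the species tree")
      m <- m[sp %in% species, , drop = FALSE]
    }
  }
  m
}

#' Write a data frame as TSV
#' @param df data.frame
#' @param path output path
#' @param row_names_as Optional column name under which to emit row names
#'   first (species ids).
#' @export
write_tsv <- function(df, path, row_names_as = NULL) {
  if (!is.null(row_names_as)) {
    df <- cbind(stats::setNames(data.frame(rownames(df), stringsAsFactors = FALSE),
                                row_names_as), df)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
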