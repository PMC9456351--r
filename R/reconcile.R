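# Duplication-loss parsimony reconciliation of gene trees against a
# time-calibrated species tree.
#
# The chain per ortholog group: root (if needed, by exhaustive minimum-cost
# rooting) -> LCA mapping -> Nmu weak-branch contraction -> minimum-cost
# polytomy re-resolution -> event classification. Events are localized on
# species-tree branches so that they can be aggregated into a gain/loss atlas.
#
# Conventions (configurable where noted):
#  - unit costs c_dup = c_loss = 1;
#  - a duplication mapping to species node s sits on the branch ending at s;
#  - a loss sits on the branch of the lost lineage (the off-path child of each
#    skipped species node);
#  - stem-origin: every family is assumed present as a single copy at the
#    species root, so species hanging off the path from the root to the
#    mapping of the gene root count as losses.

# ---- generic DL core over a lightweight tree structure -----------------------
# children: list of integer child vectors (empty = leaf); tip_map: species
# node id for leaves (NA internal). Leaves may map to *internal* species
# nodes, which is what makes local polytomy resolution exact.

dl_postorder <- function(children, root) {
  n <- length(children)
  order <- integer(n)
  stack <- integer(n)
  seen <- integer(n)
  top <- 1L; stack[1] <- root; k <- 0L
  while (top > 0L) {
    v <- stack[top]
    kids <- children[[v]]
    if (seen[v] < length(kids)) {
      seen[v] <- seen[v] + 1L
      top <- top + 1L
      stack[top] <- kids[seen[v]]
    } else {
      k <- k + 1L
      order[k] <- v
      top <- top - 1L
    }
  }
  order[seq_len(k)]
}

dl_core <- function(children, root, tip_map, tt, assume_root_origin = TRUE,
                    costs = c(dup = 1, loss = 1), collect = TRUE) {
  ord <- dl_postorder(children, root)
  n <- length(children)
  M <- tip_map
  dup <- logical(n)
  for (v in ord) {
    kids <- children[[v]]
    if (length(kids)) {
      M[v] <- lca_nodes(tt, M[kids])
      dup[v] <- any(M[kids] == M[v])
    }
  }
  depth <- tt$depth
  D <- 0L; L <- 0L
  ev_type <- character(0); ev_node <- integer(0)
  for (v in ord) {
    kids <- children[[v]]
    if (!length(kids)) next
    if (dup[v]) {
      D <- D + 1L
      if (collect) { ev_type <- c(ev_type, "gain"); ev_node <- c(ev_node, M[v]) }
    }
    for (c0 in kids) {
      span <- depth[M[c0]] - depth[M[v]] - (if (dup[v]) 0L else 1L)
      if (span > 0L) {
        L <- L + span
        if (collect) {
          a <- M[c0]
          reps <- span
          while (reps > 0L) {
            p <- tt$parent[a]
            sib <- setdiff(tt$children[[p]], a)
            ev_type <- c(ev_type, "loss"); ev_node <- c(ev_node, sib)
            a <- p
            reps <- reps - 1L
          }
        }
      }
    }
  }
  if (assume_root_origin) {
    stem <- depth[M[root]]
    if (stem > 0L) {
      L <- L + stem
      if (collect) {
        a <- M[root]
        while (a != tt$root) {
          p <- tt$parent[a]
          sib <- setdiff(tt$children[[p]], a)
          ev_type <- c(ev_type, "loss"); ev_node <- c(ev_node, sib)
          a <- p
        }
      }
    }
  }
  cost <- costs[[1]] * D + costs[[2]] * L
  events <- NULL
  if (collect) {
    events <- data.frame(
      type = ev_type,
      branch_id = tt$labels[ev_node],
      species_node = ev_node,
      stringsAsFactors = FALSE
    )
  }
  list(M = M, dup = dup, D = D, L = L, cost = cost, events = events)
}

gstruct_from_phylo <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  children <- vector("list", n)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    children[[p]] <- c(children[[p]], phy$edge[i, 2])
  }
  list(children = children, root = length(phy$tip.label) + 1L, n = n)
}

gene_tip_map <- function(gt, tt) {
  check_leaf_consistency(gt, tt)
  n <- length(gt$phy$tip.label) + gt$phy$Nnode
  tip_map <- rep(NA_integer_, n)
  tip_map[seq_along(gt$species)] <- tt$tip_id[gt$species]
  tip_map
}

# ---- LCA mapping and event classification -----------------------------------

#' LCA mapping of a rooted gene tree into the species tree
#'
#' Each gene leaf maps to its species; each internal gene node maps to the
#' lowest common ancestor of its children's images. This mapping attains the
#' parsimony-minimal duplication count and minimal duplication+loss cost.
#'
#' @param gt rooted `genetree`
#' @param tt `timetree`
#' @return Object of class `lca_mapping`: integer vector `M` over gene nodes
#'   (species node ids), duplication flags, and the input trees.
#' @export
lca_map <- function(gt, tt) {
  if (!gt$rooted) stop("lca_map needs a rooted gene tree; see root_gene_tree()")
  gs <- gstruct_from_phylo(gt$phy)
  res <- dl_core(gs$children, gs$root, gene_tip_map(gt, tt), tt, collect = FALSE)
  structure(list(M = res$M, dup = res$dup, gt = gt, tt = tt), class = "lca_mapping")
}

#' Classify duplication and loss events of a reconciliation
#'
#' A gene node is a duplication iff one of its children maps to the same
#' species node. Losses are read off the skipped species nodes along each
#' gene edge (off-path child branches); with `assume_root_origin`, species
#' hanging off the path from the species root down to the mapping of the gene
#' root are counted as stem losses.
#'
#' @param x `genetree` (rooted) or `lca_mapping`
#' @param tt `timetree` (ignored when `x` is an `lca_mapping`)
#' @param assume_root_origin Count stem losses above the gene root's mapping
#'   (single-copy origin at the species root).
#' @param costs length-2 numeric, cost of a duplication and of a loss.
#' @return Object of class `reconciliation`: counts `D`, `L`, `cost` and the
#'   event table (type gain/loss, branch_id).
#' @export
classify_events <- function(x, tt = NULL, assume_root_origin = TRUE,
                            costs = c(dup = 1, loss = 1)) {
  if (inherits(x, "lca_mapping")) { gt <- x$gt; tt <- x$tt } else { gt <- x }
  if (is.null(tt)) stop("species tree required")
  gs <- gstruct_from_phylo(gt$phy)
  res <- dl_core(gs$children, gs$root, gene_tip_map(gt, tt), tt,
                 assume_root_origin = assume_root_origin, costs = costs,
                 collect = TRUE)
  new_reconciliation(res, gt, info = list(n_weak = 0L, approx = FALSE))
}

new_reconciliation <- function(res, gt, info = list()) {
  structure(list(
    D = res$D, L = res$L, cost = res$cost,
    events = res$events, M = res$M, gt = gt, info = info
  ), class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("DL reconciliation: D =", x$D, " L =", x$L, " cost =", x$cost, "\n")
  invisible(x)
}

# ---- rooting ----------------------------------------------------------------

canonical_newick <- function(children, root, labels) {
  rec <- function(v) {
    kids <- children[[v]]
    if (!length(kids)) return(labels[v])
    parts <- sort(vapply(kids, rec, character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(root), ";")
}

#' Root an unrooted gene tree by minimum duplication-loss cost
#'
#' Tries every edge as the root position and keeps the rooting whose
#' reconciliation cost is minimal. Ties are broken by preferring the rooting
#' whose root maps closest to the species root, then by the lexicographically
#' smallest canonical newick, so results are reproducible.
#'
#' @param gt `genetree` (unrooted; a rooted input is returned unchanged)
#' @param tt `timetree`
#' @param assume_root_origin,costs passed to the cost evaluation.
#' @return rooted `genetree` with attribute `"root_cost"`.
#' @export
root_gene_tree <- function(gt, tt, assume_root_origin = TRUE,
                           costs = c(dup = 1, loss = 1)) {
  if (gt$rooted) return(gt)
  phy <- gt$phy
  n_tip <- length(phy$tip.label)
  if (n_tip < 3) stop("need at least 3 leaves to root")
  n <- n_tip + phy$Nnode
  # undirected adjacency with edge lengths
  adj <- vector("list", n)
  len <- if (is.null(phy$edge.length)) rep(0, nrow(phy$edge)) else phy$edge.length
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1]; b <- phy$edge[i, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, len[i]))
    adj[[b]] <- rbind(adj[[b]], c(a, len[i]))
  }
  tip_map0 <- rep(NA_integer_, n + 1L)
  tip_map0[seq_len(n_tip)] <- tt$tip_id[gt$species]
  best <- NULL
  for (i in seq_len(nrow(phy$edge))) {
    u <- phy$edge[i, 1]; v <- phy$edge[i, 2]; l_uv <- len[i]
    root_id <- n + 1L
    children <- vector("list", n + 1L)
    elen <- numeric(n + 1L)
    children[[root_id]] <- c(u, v)
    elen[u] <- l_uv / 2; elen[v] <- l_uv / 2
    # orient away from the new root
    stack <- c(u, v); parent <- integer(n + 1L)
    parent[u] <- root_id; parent[v] <- root_id
    # forbid traversing the split edge
    blocked <- c(u, v)
    while (length(stack)) {
      w <- stack[length(stack)]; stack <- stack[-length(stack)]
      nb <- adj[[w]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        x <- nb[r, 1]
        if (x == parent[w]) next
        if ((w %in% blocked) && (x %in% blocked)) next
        children[[w]] <- c(children[[w]], x)
        parent[x] <- w
        elen[x] <- nb[r, 2]
        stack <- c(stack, x)
      }
    }
    res <- dl_core(children, root_id, tip_map0, tt,
                   assume_root_origin = assume_root_origin, costs = costs,
                   collect = FALSE)
    cand <- list(cost = res$cost, root_depth = tt$depth[res$M[root_id]],
                 children = children, elen = elen, root = root_id)
    if (is.null(best) || cand$cost < best$cost ||
        (cand$cost == best$cost && cand$root_depth < best$root_depth) ||
        (cand$cost == best$cost && cand$root_depth == best$root_depth &&
         canonical_newick(cand$children, cand$root, c(phy$tip.label, rep("", n + 1 - n_tip))) <
         canonical_newick(best$children, best$root, c(phy$tip.label, rep("", n + 1 - n_tip))))) {
      best <- cand
    }
  }
  rooted <- phylo_from_struct(best$children, best$root, phy$tip.label, best$elen)
  out <- genetree(rooted)
  attr(out, "root_cost") <- best$cost
  out
}

# rebuild an ape phylo from a children-list structure (labels for leaves,
# elen[v] = length of the edge above v)
phylo_from_struct <- function(children, root, tip_labels, elen = NULL) {
  rec <- function(v) {
    kids <- children[[v]]
    l <- if (is.null(elen)) NULL else elen[v]
    if (!length(kids)) {
      s <- tip_labels[v]
    } else {
      s <- paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")")
    }
    if (!is.null(l) && v != root) paste0(s, ":", format(l, digits = 15)) else s
  }
  ape::read.tree(text = paste0(rec(root), ";"))
}

# ---- Nmu threshold ----------------------------------------------------------

#' Per-generation substitution rate of an ortholog group
#'
#' mu_gen = generation_years * (mean root-to-leaf path length, subs/site) /
#' (root age in years).
#'
#' @param gt rooted `genetree` with branch lengths
#' @param root_age_years age of the species root in years (e.g. 170e6)
#' @param generation_years mean generation length, years (default 10)
#' @return mu in substitutions/site/generation
#' @export
compute_mu <- function(gt, root_age_years, generation_years = 10) {
  if (root_age_years <= 0) stop("root age must be positive")
  if (is.null(gt$phy$edge.length)) stop("gene tree has no branch lengths")
  d <- ape::node.depth.edgelength(gt$phy)[seq_along(gt$phy$tip.label)]
  mp <- mean(d)
  if (mp == 0) {
    warning("zero-length gene tree: mu set to 0")
    return(0)
  }
  generation_years * mp / root_age_years
}

#' Weak-branch threshold specification (N*mu)
#'
#' @param ne effective population size (the default grid in the analysis is
#'   1e4, 1e5, 1e6, 1e7)
#' @param generation_years generation length in years
#' @return object of class `threshold_spec`
#' @export
threshold_spec <- function(ne = 1e6, generation_years = 10) {
  if (ne < 0 || generation_years <= 0) stop("invalid threshold specification")
  structure(list(ne = ne, generation_years = generation_years),
            class = "threshold_spec")
}

threshold_value <- function(tspec, gt, tt) {
  if (is.numeric(tspec)) return(tspec)
  mu <- compute_mu(gt, root_age_years = tt$ages[tt$root] * 1e6,
                   generation_years = tspec$generation_years)
  tspec$ne * mu
}

#' Weak internal edges of a gene tree
#'
#' Internal edges with length strictly below the threshold. Terminal edges
#' are never weak: a leaf's species identity is data, not topology.
#'
#' @param gt `genetree`
#' @param threshold numeric threshold in substitutions/site
#' @return integer vector of child node ids of the weak edges
#' @export
weak_edges <- function(gt, threshold) {
  phy <- gt$phy
  if (threshold <= 0 || is.null(phy$edge.length)) return(integer(0))
  n_tip <- length(phy$tip.label)
  internal <- phy$edge[, 2] > n_tip
  phy$edge[internal & phy$edge.length < threshold, 2]
}

# all rooted binary topologies over k labeled items, as nested pair lists
enumerate_topologies <- function(k) {
  trees <- list(1L)
  for (i in seq_len(k - 1L) + 1L) {
    out <- list()
    for (tr in trees) out <- c(out, insert_leaf(tr, i))
    trees <- out
  }
  trees
}

insert_leaf <- function(tree, i) {
  res <- list(list(tree, i))
  if (is.list(tree)) {
    for (v in insert_leaf(tree[[1]], i)) res <- c(res, list(list(v, tree[[2]])))
    for (v in insert_leaf(tree[[2]], i)) res <- c(res, list(list(tree[[1]], v)))
  }
  res
}

# mini-tree DL cost of a nested topology over super-leaves with given species
# mappings (stem of the component excluded; exact local objective)
mini_cost <- function(nested, leaf_maps, tt, costs) {
  n_leaf <- length(leaf_maps)
  children <- vector("list", 2L * n_leaf)
  tip_map <- rep(NA_integer_, 2L * n_leaf)
  tip_map[seq_len(n_leaf)] <- leaf_maps
  nxt <- n_leaf
  build <- function(x) {
    if (!is.list(x)) return(x)
    nxt <<- nxt + 1L
    me <- nxt
    kids <- c(build(x[[1]]), build(x[[2]]))
    children[[me]] <<- kids
    me
  }
  root <- build(nested)
  dl_core(children[seq_len(nxt)], root, tip_map[seq_len(nxt)], tt,
          assume_root_origin = FALSE, costs = costs, collect = FALSE)$cost
}

greedy_resolution <- function(leaf_maps, tt, costs) {
  items <- as.list(seq_along(leaf_maps))
  maps <- leaf_maps
  while (length(items) > 1L) {
    best <- NULL
    for (i in seq_len(length(items) - 1L)) {
      for (j in seq(i + 1L, length(items))) {
        anc <- lca_nodes(tt, c(maps[i], maps[j]))
        inc <- (tt$depth[maps[i]] - tt$depth[anc]) +
               (tt$depth[maps[j]] - tt$depth[anc]) +
               (maps[i] == anc || maps[j] == anc)
        if (is.null(best) || inc < best$inc) best <- list(i = i, j = j, inc = inc, anc = anc)
      }
    }
    merged <- list(items[[best$i]], items[[best$j]])
    keep <- setdiff(seq_along(items), c(best$i, best$j))
    items <- c(items[keep], list(merged))
    maps <- c(maps[keep], best$anc)
  }
  items[[1]]
}

#' Contract weak edges and re-resolve polytomies at minimum DL cost
#'
#' All internal edges below the threshold are contracted into polytomies.
#' Because the mapping of a polytomy's node and the duplication status of its
#' parent are invariant under re-resolution, each polytomy can be resolved
#' independently by an exact local search: exhaustive enumeration of the
#' (2k-3)!! rooted binary resolutions for k <= `k_max` children, greedy
#' pairwise agglomeration above (flagged approximate). The original topology
#' is always among the candidates, so the returned cost never exceeds the
#' cost of the input tree.
#'
#' @param gt rooted `genetree` with branch lengths
#' @param tt `timetree`
#' @param threshold numeric (subs/site) or a `threshold_spec`
#' @param assume_root_origin,costs see [classify_events()]
#' @param k_max exhaustive-resolution cap (default 6)
#' @param hard_cap polytomies larger than this abort the ortholog group
#'   (condition class `tfatlas_polytomy_overflow`)
#' @return `reconciliation` whose `gt` element is the resolved tree (new
#'   internal edges get length 0)
#' @export
rearrange_weak <- function(gt, tt, threshold, assume_root_origin = TRUE,
                           costs = c(dup = 1, loss = 1), k_max = 6,
                           hard_cap = 12) {
  Tv <- threshold_value(threshold, gt, tt)
  weak <- weak_edges(gt, Tv)
  if (!length(weak)) {
    rec <- classify_events(gt, tt, assume_root_origin, costs)
    rec$info$threshold <- Tv
    return(rec)
  }
  phy <- gt$phy
  n_tip <- length(phy$tip.label)
  n <- n_tip + phy$Nnode
  gs <- gstruct_from_phylo(phy)
  children <- gs$children
  elen <- numeric(n)
  parent <- integer(n)
  for (i in seq_len(nrow(phy$edge))) {
    elen[phy$edge[i, 2]] <- if (is.null(phy$edge.length)) 0 else phy$edge.length[i]
    parent[phy$edge[i, 2]] <- phy$edge[i, 1]
  }
  orig_children <- children
  # contract weak edges child-first so cascades merge into one polytomy
  post <- dl_postorder(children, gs$root)
  merged_into <- seq_len(n)
  active <- rep(TRUE, n)
  for (v in intersect(post, weak)) {
    p <- merged_into[parent[v]]
    children[[p]] <- c(setdiff(children[[p]], v), children[[v]])
    merged_into[v] <- p
    merged_into[merged_into == v] <- p
    active[v] <- FALSE
  }
  # LCA mapping on the contracted (possibly non-binary) tree
  tip_map <- rep(NA_integer_, n)
  tip_map[seq_len(n_tip)] <- tt$tip_id[gt$species]
  mres <- dl_core(children, gs$root, tip_map, tt, collect = FALSE)
  M <- mres$M
  info <- list(threshold = Tv, n_weak = length(weak),
               polytomy_sizes = integer(0), approx = FALSE)
  # resolve polytomies (exact local decomposition)
  poly <- which(active & vapply(children, length, 1L) > 2L)
  extra <- list()  # new internal nodes appended after n
  for (p in poly) {
    kids <- children[[p]]
    k <- length(kids)
    info$polytomy_sizes <- c(info$polytomy_sizes, k)
    if (k > hard_cap) {
      cond <- structure(class = c("tfatlas_polytomy_overflow", "error", "condition"),
                        list(message = sprintf("polytomy with %d children exceeds hard cap %d", k, hard_cap),
                             call = NULL))
      stop(cond)
    }
    maps <- M[kids]
    orig_nested <- component_structure(p, p, orig_children, merged_into, kids)
    if (k <= k_max) {
      cands <- enumerate_topologies(k)
    } else {
      info$approx <- TRUE
      cands <- list(greedy_resolution(maps, tt, costs), orig_nested)
    }
    best <- NULL
    for (cand in cands) {
      cst <- mini_cost(cand, maps, tt, costs)
      if (is.null(best) || cst < best$cost) best <- list(cost = cst, nested = cand)
    }
    # graft resolved structure back: nested indices refer to kids[]
    graft <- function(x) {
      if (!is.list(x)) return(kids[x])
      id <- n + length(extra) + 1L
      extra[[length(extra) + 1L]] <<- integer(0)  # placeholder
      kk <- c(graft(x[[1]]), graft(x[[2]]))
      extra[[id - n]] <<- kk
      id
    }
    children[[p]] <- c(graft(best$nested[[1]]), graft(best$nested[[2]]))
  }
  if (length(extra)) {
    children <- c(children, extra)
    elen <- c(elen, numeric(length(extra)))
  }
  labels <- phy$tip.label
  res_phy <- phylo_from_struct(children, gs$root, labels, elen)
  res_gt <- genetree(res_phy)
  rec <- classify_events(res_gt, tt, assume_root_origin, costs)
  rec$info <- utils::modifyList(rec$info, info)
  rec
}

# original (pre-contraction) topology of a polytomy component, as a nested
# structure over its current children (indices into kids)
component_structure <- function(v, p, orig_children, merged_into, kids) {
  rec <- function(u) {
    if (merged_into[u] == p && length(orig_children[[u]]) && u != p) {
      # contracted internal node: expand
      parts <- lapply(orig_children[[u]], rec)
    } else if (u == p) {
      parts <- lapply(orig_children[[u]], rec)
    } else {
      return(match(u, kids))
    }
    while (length(parts) > 2L) {
      parts <- c(list(list(parts[[1]], parts[[2]])), parts[-(1:2)])
    }
    if (length(parts) == 1L) parts[[1]] else list(parts[[1]], parts[[2]])
  }
  rec(v)
}

# ---- per-OG driver ----------------------------------------------------------

#' Bundle a gene tree as an ortholog group
#' @param og_id character id
#' @param gt `genetree`
#' @return `ortholog_group` with per-species member counts
#' @export
ortholog_group <- function(og_id, gt) {
  structure(list(og_id = og_id, gt = gt,
                 members = table(gt$species)), class = "ortholog_group")
}

#' Ortholog-group size filter
#'
#' Keeps groups with more than `min_members - 1` genes (the analysis default
#' keeps groups with more than three members, i.e. at least four).
#' @param ogs list of `ortholog_group`
#' @param min_members minimum total member count (default 4)
#' @return filtered list
#' @export
filter_ogs <- function(ogs, min_members = 4) {
  keep <- vapply(ogs, function(og) sum(og$members) >= min_members, logical(1))
  ogs[keep]
}

#' Reconcile one ortholog group against the species tree
#'
#' Full chain: root (if the tree is unrooted) -> Nmu threshold -> weak-edge
#' rearrangement -> event classification.
#'
#' @param og `ortholog_group` (or a rooted `genetree`)
#' @param tt `timetree`
#' @param ne effective population size for the Nmu threshold; `NULL` or 0
#'   disables rearrangement (threshold T = 0)
#' @param generation_years generation length (years) entering mu
#' @param assume_root_origin,costs,k_max,hard_cap see [rearrange_weak()]
#' @return `reconciliation` with `og_id` and an `events` table carrying the id
#' @export
reconcile_og <- function(og, tt, ne = NULL, generation_years = 10,
                         assume_root_origin = TRUE, costs = c(dup = 1, loss = 1),
                         k_max = 6, hard_cap = 12) {
  gt <- if (inherits(og, "ortholog_group")) og$gt else og
  og_id <- if (inherits(og, "ortholog_group")) og$og_id else "og"
  if (!gt$rooted) gt <- root_gene_tree(gt, tt, assume_root_origin, costs)
  Tv <- if (is.null(ne) || ne <= 0) 0 else threshold_value(threshold_spec(ne, generation_years), gt, tt)
  rec <- if (Tv > 0) {
    rearrange_weak(gt, tt, Tv, assume_root_origin, costs, k_max, hard_cap)
  } else {
    classify_events(gt, tt, assume_root_origin, costs)
  }
  rec$og_id <- og_id
  rec$events <- data.frame(og_id = rep(og_id, nrow(rec$events)), rec$events,
                           stringsAsFactors = FALSE)
  rec
}

#' Reconcile a batch of ortholog groups
#'
#' @inheritParams reconcile_og
#' @param ogs list of `ortholog_group`
#' @return list with `recs` (reconciliations), `events` (combined table),
#'   `skipped` (data.frame og_id/reason for polytomy overflows)
#' @export
reconcile_batch <- function(ogs, tt, ne = NULL, generation_years = 10,
                            assume_root_origin = TRUE, costs = c(dup = 1, loss = 1),
                            k_max = 6, hard_cap = 12) {
  recs <- list(); skipped <- data.frame(og_id = character(0), reason = character(0))
  for (og in ogs) {
    r <- tryCatch(
      reconcile_og(og, tt, ne, generation_years, assume_root_origin, costs,
                   k_max, hard_cap),
      tfatlas_polytomy_overflow = function(e) e
    )
    if (inherits(r, "condition")) {
      skipped <- rbind(skipped, data.frame(og_id = og$og_id, reason = conditionMessage(r)))
    } else {
      recs[[r$og_id]] <- r
    }
  }
  events <- do.call(rbind, c(lapply(recs, `[[`, "events"),
                             list(make.row.names = FALSE)))
  if (is.null(events)) {
    events <- data.frame(og_id = character(0), type = character(0),
                         branch_id = character(0), species_node = integer(0))
  }
  list(recs = recs, events = events, skipped = skipped)
}

#' Reconcile a batch across an effective-population-size sweep
#'
#' Runs the threshold grid in ascending Ne order. For every group the
#' resolved tree found at the previous (smaller) threshold is kept as a
#' warm-start candidate, so the minimum found can only improve as the
#' rearrangement freedom grows and total event counts are non-increasing in
#' Ne.
#'
#' @inheritParams reconcile_batch
#' @param ne_grid numeric vector of Ne values (default `c(1e4,1e5,1e6,1e7)`)
#' @return named list (one entry per Ne) of [reconcile_batch()] results
#' @export
reconcile_sweep <- function(ogs, tt, ne_grid = c(1e4, 1e5, 1e6, 1e7),
                            generation_years = 10, assume_root_origin = TRUE,
                            costs = c(dup = 1, loss = 1), k_max = 6,
                            hard_cap = 12) {
  ne_grid <- sort(ne_grid)
  out <- list()
  prev <- list()  # og_id -> best reconciliation so far
  for (ne in ne_grid) {
    batch <- reconcile_batch(ogs, tt, ne, generation_years, assume_root_origin,
                             costs, k_max, hard_cap)
    for (id in names(batch$recs)) {
      if (!is.null(prev[[id]]) && prev[[id]]$cost < batch$recs[[id]]$cost) {
        batch$recs[[id]] <- prev[[id]]
      }
      prev[[id]] <- batch$recs[[id]]
    }
    # groups skipped at this level keep nothing; larger thresholds only skip more
    batch$events <- do.call(rbind, c(lapply(batch$recs, `[[`, "events"),
                                     list(make.row.names = FALSE)))
    if (is.null(batch$events)) {
      batch$events <- data.frame(og_id = character(0), type = character(0),
                                 branch_id = character(0), species_node = integer(0))
    }
    out[[format(ne, scientific = FALSE)]] <- batch
  }
  out
}
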