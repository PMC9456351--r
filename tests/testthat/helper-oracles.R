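# Independent oracles used to validate the reconciliation engine.
#
# oracle_min_dl(): dynamic program over *all* valid gene-node -> species-node
# mappings (each internal gene node may map to any ancestor-or-equal node of
# its children's images; a node is a speciation only when its children map
# into distinct child subtrees of its image). Shares no code with the LCA
# shortcut in R/.

oracle_min_dl <- function(gt, tt, c_dup = 1, c_loss = 1,
                          assume_root_origin = FALSE) {
  phy <- gt$phy
  n_tip <- length(phy$tip.label)
  n <- n_tip + phy$Nnode
  ns <- length(tt$labels)
  # ancestor-or-equal matrix over species nodes
  anc <- matrix(FALSE, ns, ns)
  for (j in seq_len(ns)) {
    a <- j
    repeat {
      anc[a, j] <- TRUE
      if (a == tt$root) break
      a <- tt$parent[a]
    }
  }
  # child of s on the path towards x (NA if x == s or not below s)
  path_child <- matrix(NA_integer_, ns, ns)
  for (s in seq_len(ns)) {
    for (x in seq_len(ns)) {
      if (x == s || !anc[s, x]) next
      a <- x
      while (tt$parent[a] != s) a <- tt$parent[a]
      path_child[s, x] <- a
    }
  }
  kids <- vector("list", n)
  for (i in seq_len(nrow(phy$edge))) {
    kids[[phy$edge[i, 1]]] <- c(kids[[phy$edge[i, 1]]], phy$edge[i, 2])
  }
  post <- rev(unlist(lapply(seq_len(nrow(phy$edge)), function(i) NULL)))
  # explicit postorder
  post <- integer(0); stack <- n_tip + 1L; seen <- integer(n)
  while (length(stack)) {
    v <- stack[length(stack)]
    if (seen[v] < length(kids[[v]])) {
      seen[v] <- seen[v] + 1L
      stack <- c(stack, kids[[v]][seen[v]])
    } else {
      post <- c(post, v)
      stack <- stack[-length(stack)]
    }
  }
  sp_id <- tt$tip_id[gt$species]
  g <- matrix(Inf, n, ns)
  for (v in post) {
    if (!length(kids[[v]])) {
      g[v, sp_id[v]] <- 0
      next
    }
    c1 <- kids[[v]][1]; c2 <- kids[[v]][2]
    for (s in seq_len(ns)) {
      best <- Inf
      for (s1 in which(anc[s, ])) {
        if (!is.finite(g[c1, s1])) next
        for (s2 in which(anc[s, ])) {
          if (!is.finite(g[c2, s2])) next
          d1 <- tt$depth[s1] - tt$depth[s]
          d2 <- tt$depth[s2] - tt$depth[s]
          spec <- s1 != s && s2 != s && path_child[s, s1] != path_child[s, s2]
          cost <- if (spec) {
            c_loss * ((d1 - 1) + (d2 - 1))
          } else {
            c_dup + c_loss * (d1 + d2)
          }
          tot <- g[c1, s1] + g[c2, s2] + cost
          if (tot < best) best <- tot
        }
      }
      g[v, s] <- best
    }
  }
  root <- n_tip + 1L
  tot <- g[root, ]
  if (assume_root_origin) tot <- tot + c_loss * tt$depth
  min(tot)
}

# random rooted binary gene tree over a species set, <= max_copies per species
random_gene_tree <- function(species, n_leaf, max_copies = 3) {
  pool <- rep(species, max_copies)
  n_leaf <- min(n_leaf, length(pool))
  labs <- sample(pool, n_leaf)
  counts <- stats::ave(seq_along(labs), labs, FUN = seq_along)
  tips <- paste0(labs, "_", counts)
  phy <- ape::rtree(n_leaf, rooted = TRUE, tip.label = tips)
  genetree(phy)
}

random_species_timetree <- function(n_taxa, labels = LETTERS[seq_len(n_taxa)]) {
  phy <- ape::rcoal(n_taxa, tip.label = labels)
  timetree(phy)
}

# exhaustive check over every rooting of an unrooted gene tree, using
# phytools::reroot as the independent rooting mechanism
all_rooting_costs <- function(gt, tt, assume_root_origin = TRUE) {
  phy <- ape::unroot(gt$phy)
  costs <- numeric(0)
  for (i in seq_len(nrow(phy$edge))) {
    len <- if (is.null(phy$edge.length)) 1 else phy$edge.length[i]
    r <- phytools::reroot(phy, phy$edge[i, 2], position = len / 2)
    rec <- classify_events(genetree(r), tt, assume_root_origin = assume_root_origin)
    costs <- c(costs, rec$cost)
  }
  costs
}

# Pearson chi-square statistic on a 2x2 table, written from the definition
pearson_chi2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}
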