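# Seeded generators for the study conditions the analysis assumes: a
# time-calibrated species tree, birth-death gene families evolving along it
# (with ground truth for every event), clock-with-noise branch lengths,
# short-edge topological perturbation mimicking incomplete lineage sorting,
# logistic binary traits driven by a causal subset of presence columns, and
# decelerated terminal rates for target genes of lost regulators.

# build an ape phylo directly from a children-list structure (exact edge
# lengths, no newick round trip); `tips` are the node ids that are leaves, in
# the order that defines tip numbering/labels
phylo_build <- function(children, root, tips, tip_labels, elen) {
  n_tip <- length(tips)
  id <- integer(length(children))
  id[tips] <- seq_len(n_tip)
  # preorder assignment of internal numbers, root first
  nxt <- n_tip
  stack <- root
  order_int <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (length(children[[v]])) {
      nxt <- nxt + 1L
      id[v] <- nxt
      stack <- c(stack, rev(children[[v]]))
    }
  }
  edge <- matrix(0L, nxt - 1L, 2)
  len <- numeric(nxt - 1L)
  k <- 0L
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (c0 in children[[v]]) {
      k <- k + 1L
      edge[k, ] <- c(id[v], id[c0])
      len[k] <- elen[c0]
      stack <- c(stack, c0)
    }
  }
  phy <- structure(list(edge = edge, edge.length = len,
                        tip.label = tip_labels, Nnode = nxt - n_tip),
                   class = "phylo", order = "cladewise")
  list(phy = phy, id = id)
}

#' Simulate a time-calibrated species tree
#'
#' Conditioned pure-birth construction: the root age is fixed at `root_age`;
#' the remaining `n_taxa - 2` divergence ages are i.i.d. truncated-exponential
#' (rate `birth`, support (0, root_age), ages measured from the present) and
#' topology grows by splitting a uniformly chosen extant lineage at each age,
#' as in a Yule process. The mean divergence age has the closed form
#' `1/birth - root_age / (exp(birth * root_age) - 1)`.
#'
#' @param n_taxa number of species (>= 3)
#' @param root_age root age A in Mya (default 170, a mammal-scale root)
#' @param birth speciation rate per lineage per My (default 0.025)
#' @param seed optional RNG seed
#' @return `timetree` with tips labeled `s01`, `s02`, ...
#' @export
simulate_species_timetree <- function(n_taxa, root_age = 170, birth = 0.025,
                                      seed = NULL) {
  if (n_taxa < 3) stop("n_taxa must be at least 3")
  if (root_age <= 0 || birth <= 0) stop("root_age and birth must be positive")
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n_taxa - 2L)
  inner <- -log(1 - u * (1 - exp(-birth * root_age))) / birth
  ages <- sort(inner, decreasing = TRUE)
  n_nodes <- 2L * n_taxa - 1L
  children <- vector("list", n_nodes)
  age_of <- numeric(n_nodes)
  # node 1 = root; open lineages are (parent node) slots
  age_of[1] <- root_age
  open <- c(1L, 1L)
  nxt <- 1L
  for (a in ages) {
    i <- sample.int(length(open), 1L)
    nxt <- nxt + 1L
    age_of[nxt] <- a
    children[[open[i]]] <- c(children[[open[i]]], nxt)
    open <- c(open[-i], nxt, nxt)
  }
  tips <- integer(0)
  for (p in open) {
    nxt <- nxt + 1L
    children[[p]] <- c(children[[p]], nxt)
    tips <- c(tips, nxt)
  }
  elen <- numeric(n_nodes)
  for (v in seq_len(n_nodes)) for (c0 in children[[v]]) {
    elen[c0] <- age_of[v] - age_of[c0]
  }
  labels <- sprintf("s%02d", seq_len(n_taxa))
  pb <- phylo_build(children, 1L, tips, labels, elen)
  timetree(pb$phy)
}

rate_lookup <- function(rate, tt) {
  out <- numeric(length(tt$labels))
  if (length(rate) == 1L && is.null(names(rate))) {
    out[] <- rate
  } else {
    if (is.null(names(rate))) stop("per-branch rates must be named by branch id")
    idx <- match(names(rate), tt$labels)
    if (anyNA(idx)) stop("unknown branch id in rate vector: ",
                         names(rate)[which(is.na(idx))[1]])
    out[idx] <- rate
  }
  if (any(out < 0)) stop("rates must be non-negative")
  out
}

#' Simulate one gene family along the species tree
#'
#' A single gene copy is present at the species root. Descending each branch,
#' every gene lineage duplicates with rate `dup_rate` and dies with rate
#' `loss_rate` (events per lineage per My); at speciation nodes lineages
#' enter both child branches. The returned truth records every event with its
#' branch and time, plus the *observable* events: duplications with surviving
#' descendants on both sides, and one loss per maximal extinct clade hanging
#' off a surviving lineage, placed on the branch where that clade started
#' (what a perfect reconciliation of the pruned tree can recover).
#'
#' @param tt `timetree`
#' @param dup_rate,loss_rate scalar or per-branch named vectors
#'   (events/lineage/My)
#' @param og_id id recorded in the truth tables
#' @param seed optional RNG seed
#' @return list: `gt` (`genetree` with edge lengths in My and node ages, or
#'   NULL when fewer than two copies survive), `members` (per-species copy
#'   counts, named integer), `events` and `observable` truth tables.
#' @export
simulate_gene_family <- function(tt, dup_rate, loss_rate, og_id = "og",
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lam <- rate_lookup(dup_rate, tt)
  mu <- rate_lookup(loss_rate, tt)
  ev <- new.env(parent = emptyenv())
  ev$type <- character(0); ev$branch <- character(0); ev$time <- numeric(0)
  ev$otype <- character(0); ev$obranch <- character(0); ev$otime <- numeric(0)
  ev$copies <- integer(length(tt$tip_id))
  rec_event <- function(type, node, time) {
    ev$type <- c(ev$type, type)
    ev$branch <- c(ev$branch, tt$labels[node])
    ev$time <- c(ev$time, time)
  }
  rec_obs <- function(type, node, time) {
    ev$otype <- c(ev$otype, type)
    ev$obranch <- c(ev$obranch, tt$labels[node])
    ev$otime <- c(ev$otime, time)
  }
  drop_obs_loss <- function(node, time) {
    i <- which(ev$otype == "loss" & ev$obranch == tt$labels[node] &
               ev$otime == time)[1]
    ev$otype <- ev$otype[-i]; ev$obranch <- ev$obranch[-i]
    ev$otime <- ev$otime[-i]
  }
  descend <- function(s, t_from) {
    # one gene lineage on the branch ending at species node s, age t_from
    rate <- lam[s] + mu[s]
    t_end <- tt$ages[s]
    t_ev <- if (rate > 0) t_from - stats::rexp(1, rate) else -Inf
    if (t_ev > t_end) {
      if (stats::runif(1) < lam[s] / rate) {
        rec_event("gain", s, t_ev)
        a <- descend(s, t_ev)
        b <- descend(s, t_ev)
        if (!is.null(a) && !is.null(b)) {
          # the recoverable duplication sits at the LCA of the surviving
          # species; pass-through losses double-counted by the two daughter
          # lineages between s and that LCA are collapsed to one
          l <- lca_nodes(tt, c(a$map, b$map))
          if (a$map == l || b$map == l) {
            rec_obs("gain", l, t_ev)
          } else {
            # daughters survive in different child subtrees of l: the
            # duplication is indistinguishable from a speciation at l, and
            # the two cross-losses the daughters recorded at l are not
            # recoverable either
            child_toward <- function(x) {
              w <- x
              while (tt$parent[w] != l) w <- tt$parent[w]
              w
            }
            drop_obs_loss(child_toward(b$map), tt$ages[l])
            drop_obs_loss(child_toward(a$map), tt$ages[l])
          }
          w <- l
          while (w != s) {
            p <- tt$parent[w]
            drop_obs_loss(setdiff(tt$children[[p]], w), tt$ages[p])
            w <- p
          }
          return(list(age = t_ev, children = list(a, b), map = l))
        }
        if (!is.null(a)) return(a)
        return(b)
      }
      rec_event("loss", s, t_ev)
      return(NULL)
    }
    if (s <= tt$n_tip) {
      ev$copies[s] <- ev$copies[s] + 1L
      return(list(age = 0, species = s, copy = ev$copies[s], map = s))
    }
    kids <- tt$children[[s]]
    a <- descend(kids[1], t_end)
    b <- descend(kids[2], t_end)
    if (!is.null(a) && !is.null(b)) {
      return(list(age = t_end, children = list(a, b), map = s))
    }
    if (!is.null(a)) { rec_obs("loss", kids[2], t_end); return(a) }
    if (!is.null(b)) { rec_obs("loss", kids[1], t_end); return(b) }
    NULL
  }
  kids <- tt$children[[tt$root]]
  t0 <- tt$ages[tt$root]
  a <- descend(kids[1], t0)
  b <- descend(kids[2], t0)
  tree <- if (!is.null(a) && !is.null(b)) {
    list(age = t0, children = list(a, b))
  } else if (!is.null(a)) { rec_obs("loss", kids[2], t0); a
  } else if (!is.null(b)) { rec_obs("loss", kids[1], t0); b
  } else NULL
  members <- stats::setNames(ev$copies, names(tt$tip_id))
  events <- data.frame(og_id = rep(og_id, length(ev$type)), type = ev$type,
                       branch_id = ev$branch, time = ev$time,
                       stringsAsFactors = FALSE)
  observable <- data.frame(og_id = rep(og_id, length(ev$otype)), type = ev$otype,
                           branch_id = ev$obranch, time = ev$otime,
                           stringsAsFactors = FALSE)
  gt <- NULL
  if (!is.null(tree) && sum(members) >= 2L) {
    gt <- gene_tree_from_sim(tree, tt)
  }
  list(og_id = og_id, gt = gt, members = members,
       events = events, observable = observable)
}

gene_tree_from_sim <- function(tree, tt) {
  nodes <- list(); ages <- numeric(0)
  children <- list(); tips <- integer(0); labels <- character(0)
  add <- function(x) {
    id <- length(children) + 1L
    children[[id]] <<- integer(0)
    ages[id] <<- x$age
    if (!is.null(x$species)) {
      tips <<- c(tips, id)
      labels <<- c(labels, paste0(names(tt$tip_id)[x$species], "_", x$copy))
    } else {
      kid_ids <- vapply(x$children, add, integer(1))
      children[[id]] <<- kid_ids
    }
    id
  }
  root <- add(tree)
  elen <- numeric(length(children))
  for (v in seq_along(children)) for (c0 in children[[v]]) {
    elen[c0] <- ages[v] - ages[c0]
  }
  pb <- phylo_build(children, root, tips, labels, elen)
  node_age <- numeric(length(pb$id))
  node_age[pb$id] <- ages
  genetree(pb$phy, node_age = node_age)
}

#' Simulate a batch of gene families
#'
#' @inheritParams simulate_gene_family
#' @param n_og number of families
#' @param seed RNG seed for the whole batch
#' @return list: `ogs` (families with >= 2 surviving copies, each as returned
#'   by [simulate_gene_family()]), `counts` (species x OG copy-count matrix
#'   over all non-empty families), `events`/`observable` (combined truth),
#'   `empty` (ids of fully extinct families).
#' @export
simulate_og_batch <- function(tt, n_og, dup_rate, loss_rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ogs <- list(); empty <- character(0)
  events <- list(); observable <- list(); counts <- list()
  for (i in seq_len(n_og)) {
    id <- sprintf("og%04d", i)
    fam <- simulate_gene_family(tt, dup_rate, loss_rate, og_id = id)
    events[[id]] <- fam$events
    observable[[id]] <- fam$observable
    if (sum(fam$members) == 0L) {
      empty <- c(empty, id)
    } else {
      counts[[id]] <- fam$members
      if (!is.null(fam$gt)) ogs[[id]] <- fam
    }
  }
  cnt <- if (length(counts)) do.call(cbind, counts) else
    matrix(0L, length(tt$tip_id), 0)
  list(ogs = ogs, counts = cnt,
       events = do.call(rbind, c(events, list(make.row.names = FALSE))),
       observable = do.call(rbind, c(observable, list(make.row.names = FALSE))),
       empty = empty)
}

#' Assign substitution branch lengths to a simulated gene tree
#'
#' `length = rate * timespan * eps` with `eps ~ lognormal(0, sigma_r^2)`
#' (strict clock when `sigma_r = 0`).
#'
#' @param gt `genetree` with node ages (simulation output)
#' @param rate substitution rate, subs/site/My
#' @param sigma_r lognormal sd of the per-branch rate multiplier
#' @param seed optional RNG seed
#' @return `genetree` with edge lengths in substitutions/site
#' @export
assign_branch_lengths <- function(gt, rate, sigma_r = 0, seed = NULL) {
  if (rate < 0) stop("rate must be non-negative")
  if (is.null(gt$node_age)) stop("gene tree carries no node ages (not a simulation output?)")
  if (!is.null(seed)) set.seed(seed)
  phy <- gt$phy
  span <- gt$node_age[phy$edge[, 1]] - gt$node_age[phy$edge[, 2]]
  eps <- if (sigma_r > 0) stats::rlnorm(nrow(phy$edge), 0, sigma_r) else 1
  phy$edge.length <- rate * span * eps
  genetree(phy, node_age = gt$node_age)
}

#' Perturb short gene-tree edges by random NNI (ILS mimic)
#'
#' Each internal edge with length below `eps_len` is, with probability
#' `p_ils`, subjected to one of its two nearest-neighbor-interchange
#' alternatives (chosen with equal probability) and its length is resampled
#' uniformly in `[0, eps_len]`. This reproduces, phenomenologically, the
#' short-branch discordance that incomplete lineage sorting concentrates on
#' weak edges.
#'
#' @param gt rooted binary `genetree` with branch lengths
#' @param eps_len short-edge scale (subs/site)
#' @param p_ils per-edge perturbation probability
#' @param seed optional RNG seed
#' @return perturbed `genetree` (node ages dropped: times are no longer
#'   meaningful at rearranged edges)
#' @export
perturb_ils <- function(gt, eps_len, p_ils, seed = NULL) {
  if (p_ils < 0 || p_ils > 1) stop("p_ils must be in [0, 1]")
  if (p_ils == 0 || eps_len <= 0) return(gt)
  if (!is.null(seed)) set.seed(seed)
  phy <- gt$phy
  n_tip <- length(phy$tip.label)
  short <- phy$edge[phy$edge[, 2] > n_tip & phy$edge.length < eps_len, 2]
  changed <- FALSE
  for (v in sort(short)) {
    if (stats::runif(1) >= p_ils) next
    row_v <- which(phy$edge[, 2] == v)
    u <- phy$edge[row_v, 1]
    kids_v <- which(phy$edge[, 1] == v)
    row_w <- setdiff(which(phy$edge[, 1] == u), row_v)
    if (!length(row_w) || length(kids_v) != 2) next
    row_c <- kids_v[sample.int(2, 1)]
    # swap the chosen child of v with v's sibling
    phy$edge[row_c, 1] <- u
    phy$edge[row_w[1], 1] <- v
    phy$edge.length[row_v] <- stats::runif(1, 0, eps_len)
    changed <- TRUE
  }
  if (!changed) return(gt)
  phy <- ape::reorder.phylo(phy, "cladewise")
  genetree(phy, node_age = NULL)
}

#' Choose ancestral branches for a planted rate-spike experiment
#'
#' Recovery experiments plant elevated loss rates on ancestral branches and
#' ask whether the atlas ranks them on top. Rates on very short branches are
#' dominated by Poisson noise, so the experiment targets deep branches of
#' substantial duration: the `k` oldest internal branches at least
#' `min_duration` My long.
#'
#' @param tt `timetree`
#' @param k number of branches
#' @param min_duration minimum branch duration (My)
#' @return character branch ids
#' @export
plant_spike_branches <- function(tt, k = 2, min_duration = 10) {
  bt <- branch_table(tt)
  cand <- bt[!bt$is_tip & bt$duration >= min_duration, ]
  if (nrow(cand) < k) stop("species tree has too few long internal branches")
  cand$branch_id[order(cand$parent_age, decreasing = TRUE)][seq_len(k)]
}

#' Simulate a presence/absence matrix
#'
#' Independent Bernoulli columns with per-column presence probability drawn
#' uniformly from `prevalence` (losses are the minority state, as for real
#' single-copy ortholog matrices).
#'
#' @param n_species,n_og matrix dimensions
#' @param prevalence length-2 range of presence probabilities
#' @param seed optional RNG seed
#' @return binary matrix, species in rows
#' @export
simulate_presence_matrix <- function(n_species, n_og,
                                     prevalence = c(0.5, 0.95), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- stats::runif(n_og, prevalence[1], prevalence[2])
  m <- matrix(stats::rbinom(n_species * n_og, 1, rep(p, each = n_species)),
              n_species, n_og)
  dimnames(m) <- list(sprintf("s%02d", seq_len(n_species)),
                      sprintf("og%04d", seq_len(n_og)))
  m
}

#' Simulate a binary trait from presence columns (logistic model)
#'
#' `P(trait = 1) = plogis(beta0 + X[, causal] %*% beta)`, i.i.d. across
#' species given the matrix (no phylogenetic autocorrelation, matching the
#' non-phylogenetic regression downstream).
#'
#' @param pm binary presence matrix (species x OG)
#' @param causal column names or indices of the causal regulators
#' @param beta coefficients, one per causal column
#' @param beta0 intercept
#' @param seed optional RNG seed
#' @return named 0/1 vector with attributes `prob`, `causal`, `beta`
#' @export
simulate_traits <- function(pm, causal, beta, beta0 = 0, seed = NULL) {
  if (length(causal) != length(beta)) stop("causal and beta lengths differ")
  X <- pm[, causal, drop = FALSE]
  const <- apply(X, 2, function(x) length(unique(x)) == 1L)
  if (any(const)) warning("causal column(s) constant across species (unidentifiable): ",
                          paste(colnames(X)[const], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  eta <- beta0 + as.numeric(X %*% beta)
  pr <- stats::plogis(eta)
  y <- stats::rbinom(nrow(pm), 1, pr)
  names(y) <- rownames(pm)
  attr(y, "prob") <- pr
  attr(y, "causal") <- causal
  attr(y, "beta") <- beta
  y
}

#' Simulate target-gene terminal rates under regulator loss
#'
#' Terminal rate of species i is `base_rate * (1 - delta)` when i lacks the
#' regulator, `base_rate` otherwise, times lognormal(0, sigma_g^2) noise. The
#' emitted target-gene tree has terminal branch lengths `rate_i * terminal
#' duration` (internal branches follow the base clock), so terminal-rate
#' estimation can round-trip the generator.
#'
#' @param tt `timetree`
#' @param tf_absent character vector of species lacking the regulator
#' @param base_rate subs/site/My
#' @param delta deceleration factor in [0, 1)
#' @param sigma_g lognormal noise sd
#' @param seed optional RNG seed
#' @return list: `rates` (named per-species), `gt` (target-gene `genetree`
#'   with species-id leaves)
#' @export
simulate_tg_rates <- function(tt, tf_absent, base_rate = 0.002, delta = 0.3,
                              sigma_g = 0.2, seed = NULL) {
  if (delta < 0 || delta >= 1) stop("delta must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  sp <- names(tt$tip_id)
  eta <- if (sigma_g > 0) stats::rlnorm(length(sp), 0, sigma_g) else rep(1, length(sp))
  rates <- base_rate * (1 - delta * (sp %in% tf_absent)) * eta
  names(rates) <- sp
  phy <- tt$phy
  dur <- tt$ages[phy$edge[, 1]] - tt$ages[phy$edge[, 2]]
  len <- base_rate * dur
  tip_edge <- phy$edge[, 2] <= tt$n_tip
  len[tip_edge] <- rates[phy$tip.label[phy$edge[tip_edge, 2]]] * dur[tip_edge]
  phy$edge.length <- len
  list(rates = rates, gt = genetree(phy))
}
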