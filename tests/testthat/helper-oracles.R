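# Independent oracles and small generators used across the suite.

rand_species_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$tip.label <- paste0("s", seq_len(n))
  tr
}

# Random gene tree over `nleaf` leaves with species drawn from `species`.
rand_gene_tree <- function(nleaf, species) {
  tr <- ape::rtree(nleaf)
  sp <- sample(species, nleaf, replace = TRUE)
  tr$tip.label <- paste0("g", seq_len(nleaf), "_", sp)
  tr
}

# Brute-force minimum-duplication reconciliation: enumerate every valid
# mapping of gene internal nodes to species-tree nodes (a node must map to
# an ancestor-or-self of its children's images) and count duplications
# (image equal to a child's image).
brute_min_dup <- function(gene_tree, species_tree) {
  sp <- sub("^.*_", "", gene_tree$tip.label)
  ntip_s <- length(species_tree$tip.label)
  nn_s <- ntip_s + species_tree$Nnode
  # ancestor-or-self matrix of the species tree
  anc <- matrix(FALSE, nn_s, nn_s)
  parent <- rep(NA_integer_, nn_s)
  parent[species_tree$edge[, 2]] <- species_tree$edge[, 1]
  for (v in seq_len(nn_s)) {
    a <- v
    while (!is.na(a)) { anc[a, v] <- TRUE; a <- parent[a] }
  }
  ntip_g <- length(gene_tree$tip.label)
  nn_g <- ntip_g + gene_tree$Nnode
  leaf_img <- match(sp, species_tree$tip.label)
  internal <- (ntip_g + 1L):nn_g
  m <- length(internal)
  kids <- lapply(seq_len(nn_g), function(v)
    gene_tree$edge[gene_tree$edge[, 1] == v, 2])
  # which child subtree of x contains y: 1/2, or 0 when y == x (or neither)
  childslot <- matrix(0L, nn_s, nn_s)
  for (x in seq_len(nn_s)) {
    ch_x <- species_tree$edge[species_tree$edge[, 1] == x, 2]
    for (k in seq_along(ch_x))
      childslot[x, anc[ch_x[k], ]] <- k
  }
  grid <- as.matrix(expand.grid(rep(list(seq_len(nn_s)), m)))
  R <- nrow(grid)
  ok <- rep(TRUE, R)
  dup <- matrix(FALSE, R, m)
  for (j in seq_len(m)) {
    v <- internal[j]
    gv <- grid[, j]
    slots <- vector("list", length(kids[[v]]))
    for (ki in seq_along(kids[[v]])) {
      ch <- kids[[v]][ki]
      gch <- if (ch <= ntip_g) rep(leaf_img[ch], R)
             else grid[, match(ch, internal)]
      ok <- ok & anc[cbind(gv, gch)]
      slots[[ki]] <- childslot[cbind(gv, gch)]
    }
    # a speciation needs its two children in distinct child subtrees of the
    # image; anything else is a duplication
    dup[, j] <- slots[[1]] == 0L | slots[[2]] == 0L |
      slots[[1]] == slots[[2]]
  }
  min(rowSums(dup)[ok])
}

# Naive all-pairs orthology: MRCA event lookup, independent of the
# node-sweep implementation.
naive_orthologs <- function(labeled) {
  tr <- labeled$tree
  tips <- tr$tip.label
  ev <- stats::setNames(labeled$labels$event, labeled$labels$node)
  out <- list()
  for (i in seq_along(tips)) for (j in seq_along(tips)) {
    if (i >= j) next
    m <- ape::getMRCA(tr, c(tips[i], tips[j]))
    a <- sort(c(tips[i], tips[j]))
    out[[length(out) + 1L]] <- data.frame(
      id_a = a[1], id_b = a[2],
      orthology = if (ev[[as.character(m)]] == "speciation") "ortholog"
                  else "paralog",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Brute-force site likelihood: sum over all internal-state assignments.
# Uniform rates (alpha = Inf, p_inv = 0) only.
brute_site_lik <- function(aln, tree, model) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  internal <- (ntip + 1L):nn
  m <- length(internal)
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    prob_matrix(model, tree$edge.length[e]))
  states <- match(toupper(aln[tree$tip.label, , drop = FALSE]),
                  phylomer:::AA)
  states <- matrix(states, ntip, ncol(aln))
  grid <- as.matrix(expand.grid(rep(list(1:20), m)))
  R <- nrow(grid)
  root_col <- match(ntip + 1L, internal)
  vapply(seq_len(ncol(aln)), function(s) {
    pr <- model$freq[grid[, root_col]]
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      gp <- grid[, match(p, internal)]
      if (ch <= ntip) {
        if (is.na(states[ch, s])) next   # missing tip: row sums to 1
        pr <- pr * P[[e]][cbind(gp, states[ch, s])]
      } else {
        pr <- pr * P[[e]][cbind(gp, grid[, match(ch, internal)])]
      }
    }
    sum(pr)
  }, numeric(1))
}

# Independent straightforward re-simulation of the expected number of
# observable duplications per family under a pure gene-birth process
# (loss 0, full sampling): one lineage enters the root; on each species-tree
# edge every entering lineage spawns duplications as a Yule process.
oracle_dup_count <- function(species_tree, dup_rate) {
  ntip <- length(species_tree$tip.label)
  root <- ntip + 1L
  count <- 0L
  n_enter <- stats::setNames(integer(ntip + species_tree$Nnode), NULL)
  n_enter[root] <- 1L
  # process nodes in preorder
  for (e in rev(ape::postorder(species_tree))) {
    p <- species_tree$edge[e, 1]; ch <- species_tree$edge[e, 2]
    t_len <- species_tree$edge.length[e]
    exits <- 0L
    for (l in seq_len(n_enter[p])) {
      k <- 1L
      t <- 0
      repeat {
        dt <- stats::rexp(1, k * dup_rate)
        if (dup_rate == 0 || t + dt > t_len) break
        t <- t + dt; k <- k + 1L; count <- count + 1L
      }
      exits <- exits + k
    }
    n_enter[ch] <- exits
  }
  count
}
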