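# Bitmask machinery shared by LCA reconciliation, duplication dating and the
# supertree criteria. Species sets are encoded as integer bitmasks over a
# fixed taxon ordering (at most 30 species).

.check_taxa <- function(taxa) {
  if (length(taxa) > 30)
    stop("bitmask machinery supports at most 30 species (got ",
         length(taxa), ")")
  taxa
}

.taxon_bits <- function(taxa) {
  stats::setNames(bitwShiftL(1L, seq_along(taxa) - 1L), taxa)
}

.pc_env <- new.env(parent = emptyenv())

.popcount32 <- function(x) {
  tab <- .pc_env$tab
  if (is.null(tab)) {           # 16-bit lookup table, built once per session
    v <- 0:65535
    tab <- integer(65536L)
    for (b in 1:16) {
      tab <- tab + bitwAnd(v, 1L)
      v <- bitwShiftR(v, 1L)
    }
    .pc_env$tab <- tab
  }
  tab[bitwAnd(x, 65535L) + 1L] + tab[bitwShiftR(x, 16L) + 1L]
}

# Per-node species bitmask of a rooted tree whose tips map to `taxa`
# via the `tipsp` character vector (species per tip, in tip order).
.node_masks <- function(tree, tipsp, taxa) {
  bits <- .taxon_bits(taxa)
  ntip <- length(tree$tip.label)
  mask <- integer(ntip + tree$Nnode)
  mask[seq_len(ntip)] <- bits[tipsp]
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    mask[p] <- bitwOr(mask[p], mask[ch])
  }
  mask
}

# LCA lookup in a rooted species tree for a vector of query masks:
# the node with the fewest species whose clade mask contains the query.
.lca_of_masks <- function(species_tree, taxa, query_masks) {
  smask <- .node_masks(species_tree, species_tree$tip.label, taxa)
  pc <- .popcount32(smask)
  nn <- length(smask)
  q <- length(query_masks)
  # superset test: bitwAnd(smask_i, query_j) == query_j
  M <- matrix(bitwAnd(rep(smask, times = q), rep(query_masks, each = nn)),
              nn, q)
  cost <- matrix(rep(pc, times = q), nn, q)
  cost[M != rep(query_masks, each = nn)] <- length(smask) + 1L
  max.col(-t(cost), ties.method = "first")
}

# Precompute, once per gene-tree collection, everything the duplication-
# parsimony criterion needs: the global unique-mask table and per-internal-
# node (self, left, right) mask indices.
.gtp_precompute <- function(gene_trees, taxa, rule = "suffix") {
  taxa <- .check_taxa(taxa)
  self <- integer(0); left <- integer(0); right <- integer(0)
  masks <- list()
  for (tr in gene_trees) {
    sp <- leaf_species(tr$tip.label, rule)
    unknown <- setdiff(unique(sp), taxa)
    if (length(unknown))
      stop("gene-tree species absent from species tree: ",
           paste(unknown, collapse = ", "))
    if (!ape::is.binary(tr)) tr <- resolve_polytomies(tr)
    m <- .node_masks(tr, unname(sp), taxa)
    ntip <- length(tr$tip.label)
    for (nd in (ntip + 1L):(ntip + tr$Nnode)) {
      kids <- tr$edge[tr$edge[, 1] == nd, 2]
      self <- c(self, m[nd]); left <- c(left, m[kids[1]])
      right <- c(right, m[kids[2]])
    }
  }
  u <- unique(c(self, left, right))
  list(taxa = taxa, masks = u,
       self = match(self, u), left = match(left, u), right = match(right, u))
}

# Total duplication count of the collection against a rooted candidate.
.gtp_cost <- function(precomp, candidate) {
  lca <- .lca_of_masks(candidate, precomp$taxa, precomp$masks)
  s <- lca[precomp$self]
  sum(s == lca[precomp$left] | s == lca[precomp$right])
}
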