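#' Label gene-tree nodes as duplication or speciation by species overlap
#'
#' For every internal node the species sets of its two child subtrees are
#' compared; the node is a duplication iff the Jaccard overlap
#' `|intersection| / |union|` exceeds `threshold` (default 0: any shared
#' species implies a duplication), otherwise a speciation.
#'
#' @param tree Rooted `phylo` gene tree. Polytomies are resolved
#'   deterministically first (left-to-right) and this is recorded.
#' @param threshold Species-overlap score threshold in `[0, 1)`.
#' @param rule Leaf-naming rule for [leaf_species()].
#' @return Object of class `labeled_gene_tree`: list with `tree` (binary),
#'   `species` (named by leaf), `labels` (data frame: node, event,
#'   overlap_score), `resolved` (whether polytomies were resolved).
#' @export
label_events <- function(tree, threshold = 0, rule = "suffix") {
  if (!ape::is.rooted(tree))
    stop("gene tree is unrooted; call root_tree() first")
  resolved <- !ape::is.binary(tree)
  if (resolved) tree <- resolve_polytomies(tree)
  sp <- leaf_species(tree$tip.label, rule)
  ntip <- length(tree$tip.label)
  desc <- .node_descendants(tree)
  spsets <- lapply(desc, function(ix) unique(sp[tree$tip.label[ix]]))
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  score <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    kids <- tree$edge[tree$edge[, 1] == nodes[i], 2]
    a <- spsets[[kids[1]]]; b <- spsets[[kids[2]]]
    score[i] <- length(intersect(a, b)) / length(union(a, b))
  }
  labels <- data.frame(node = nodes,
                       event = ifelse(score > threshold, "duplication",
                                      "speciation"),
                       overlap_score = score, stringsAsFactors = FALSE)
  structure(list(tree = tree, species = sp, labels = labels,
                 threshold = threshold, resolved = resolved),
            class = "labeled_gene_tree")
}

#' @export
print.labeled_gene_tree <- function(x, ...) {
  cat(sprintf("labeled gene tree: %d leaves, %d duplication / %d speciation nodes\n",
              length(x$tree$tip.label),
              sum(x$labels$event == "duplication"),
              sum(x$labels$event == "speciation")))
  invisible(x)
}

#' Ortholog/paralog catalogue from a labeled gene tree
#'
#' Two leaves are orthologs iff their most recent common ancestor is a
#' speciation node, paralogs otherwise. The relation type counts, at the
#' mediating node, how many leaves each side contributes of the two species
#' involved: 1 vs 1 is one-to-one, 1 vs >1 one-to-many, >1 vs >1
#' many-to-many.
#'
#' @param labeled A `labeled_gene_tree` from [label_events()].
#' @param seed_only Restrict to pairs involving the seed leaf (the tree's
#'   `"seed_leaf"` attribute).
#' @return Data frame: id_a, id_b, orthology (`"ortholog"`/`"paralog"`),
#'   relation, node. Each unordered pair appears once (id_a < id_b).
#' @export
infer_orthologs <- function(labeled, seed_only = FALSE) {
  if (!inherits(labeled, "labeled_gene_tree"))
    stop("input must be labeled by label_events()")
  tree <- labeled$tree
  sp <- labeled$species
  ntip <- length(tree$tip.label)
  desc <- .node_descendants(tree)
  seed <- attr(tree, "seed_leaf")
  if (seed_only && is.null(seed)) stop("tree carries no seed leaf")
  out <- vector("list", tree$Nnode)
  for (i in seq_len(tree$Nnode)) {
    nd <- ntip + i
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    left <- tree$tip.label[desc[[kids[1]]]]
    right <- tree$tip.label[desc[[kids[2]]]]
    ev <- labeled$labels$event[labeled$labels$node == nd]
    pairs <- expand.grid(a = left, b = right, stringsAsFactors = FALSE)
    if (seed_only) pairs <- pairs[pairs$a == seed | pairs$b == seed, ]
    if (!nrow(pairs)) next
    # per-species leaf counts on each side of the mediating node
    ltab <- table(sp[left]); rtab <- table(sp[right])
    na <- as.integer(ltab[sp[pairs$a]])
    nb <- as.integer(rtab[sp[pairs$b]])
    relation <- ifelse(na == 1 & nb == 1, "one-to-one",
                       ifelse(na > 1 & nb > 1, "many-to-many", "one-to-many"))
    swap <- pairs$a > pairs$b
    ida <- ifelse(swap, pairs$b, pairs$a)
    idb <- ifelse(swap, pairs$a, pairs$b)
    out[[i]] <- data.frame(id_a = ida, id_b = idb,
                           orthology = if (ev == "speciation") "ortholog"
                                       else "paralog",
                           relation = relation, node = nd,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(id_a = character(0), id_b = character(0),
                      orthology = character(0), relation = character(0),
                      node = integer(0))
  rownames(res) <- NULL
  res
}

# Internal: recursive decomposition into speciation-only subtrees.
# Returns a list of newick fragments (no trailing ';'), one per subtree,
# each a character vector of the leaf labels it contains (attribute).
.decompose_node <- function(node, tree, events, desc) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) {
    frag <- tree$tip.label[node]
    attr(frag, "leaves") <- frag
    return(list(frag))
  }
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  l <- .decompose_node(kids[1], tree, events, desc)
  r <- .decompose_node(kids[2], tree, events, desc)
  if (events[as.character(node)] == "duplication")
    return(c(l, r))
  # speciation: all pairwise combinations of left and right alternatives
  out <- vector("list", length(l) * length(r))
  k <- 0L
  for (a in l) for (b in r) {
    k <- k + 1L
    frag <- sprintf("(%s,%s)", a, b)
    attr(frag, "leaves") <- c(attr(a, "leaves"), attr(b, "leaves"))
    out[[k]] <- frag
  }
  out
}

#' Decompose a labeled gene tree into speciation-only subtrees
#'
#' Splits the tree at every duplication node into the implied alternative
#' speciation histories: at a duplication the two child subtrees are taken
#' separately; at a speciation every combination of the alternatives of the
#' two children is formed. Each output is relabeled by species codes and is
#' single-labeled (every species at most once) under the default overlap
#' threshold of 0.
#'
#' @param labeled A `labeled_gene_tree`.
#' @param seed_containing_only Keep only subtrees containing the seed leaf.
#' @param dedup Drop duplicate species topologies (default keeps repeats, so
#'   downstream support counting can weight by occurrence).
#' @return List of `phylo` objects with species codes as tip labels
#'   (subtrees reduced to a single leaf are dropped: they carry no topology).
#' @export
decompose_speciation_subtrees <- function(labeled, seed_containing_only = FALSE,
                                          dedup = FALSE) {
  if (!inherits(labeled, "labeled_gene_tree"))
    stop("input must be labeled by label_events()")
  tree <- labeled$tree
  ntip <- length(tree$tip.label)
  events <- stats::setNames(labeled$labels$event, labeled$labels$node)
  desc <- .node_descendants(tree)
  frags <- .decompose_node(ntip + 1L, tree, events, desc)
  seed <- attr(tree, "seed_leaf")
  if (seed_containing_only) {
    if (is.null(seed)) stop("tree carries no seed leaf")
    frags <- Filter(function(f) seed %in% attr(f, "leaves"), frags)
  }
  frags <- Filter(function(f) length(attr(f, "leaves")) >= 2, frags)
  out <- lapply(frags, function(f) {
    tr <- ape::read.tree(text = paste0(f, ";"))
    tr$tip.label <- unname(labeled$species[tr$tip.label])
    tr
  })
  for (tr in out) {
    if (anyDuplicated(tr$tip.label))
      stop("decomposition produced a species-repeating subtree; ",
           "this can only happen with overlap threshold > 0")
  }
  if (dedup && length(out)) {
    keys <- vapply(out, function(t) .topology_key(t), character(1))
    out <- out[!duplicated(keys)]
  }
  out
}

# Canonical key for an unrooted leaf-labeled topology.
.topology_key <- function(tree) {
  paste(sort(tree_bipartitions(tree)), collapse = "&")
}

#' Label every tree of a phylome
#'
#' @param phylome A `phylome` (or plain named list of gene trees).
#' @param threshold Species-overlap threshold.
#' @return Named list of `labeled_gene_tree` objects.
#' @export
label_phylome <- function(phylome, threshold = 0) {
  trees <- if (inherits(phylome, "phylome")) phylome$trees else phylome
  lapply(trees, label_events, threshold = threshold)
}

#' Ortholog catalogue over a phylome
#'
#' @param labeled_trees Named list from [label_phylome()].
#' @param seed_only Restrict to seed-involving pairs per tree.
#' @return Data frame with a `tree_id` column prepended to the per-tree
#'   catalogue of [infer_orthologs()].
#' @export
phylome_catalogue <- function(labeled_trees, seed_only = FALSE) {
  rows <- lapply(names(labeled_trees), function(nm) {
    df <- infer_orthologs(labeled_trees[[nm]], seed_only = seed_only)
    if (nrow(df)) cbind(tree_id = nm, df) else NULL
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(tree_id = character(0), id_a = character(0),
                      id_b = character(0), orthology = character(0),
                      relation = character(0), node = integer(0))
  rownames(res) <- NULL
  res
}
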