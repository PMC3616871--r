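#' LCA reconciliation of a gene tree with a species tree
#'
#' Maps every gene-tree node to the lowest common ancestor (in the species
#' tree) of its descendant species. A gene node is a duplication iff it maps
#' to the same species-tree node as at least one of its children; the total
#' duplication count is the reconciliation cost used by gene-tree parsimony.
#'
#' @param gene_tree Rooted `phylo` whose leaves encode species (see
#'   [leaf_species()]).
#' @param species_tree Rooted `phylo` over species codes.
#' @param rule Leaf-naming rule.
#' @return List: `mapping` (integer vector, gene node -> species-tree node
#'   id, tips included), `duplications` (logical per gene internal node,
#'   named by node id), `cost` (duplication count).
#' @export
reconcile_lca <- function(gene_tree, species_tree, rule = "suffix") {
  if (!ape::is.rooted(gene_tree)) stop("gene tree must be rooted")
  if (!ape::is.rooted(species_tree)) stop("species tree must be rooted")
  taxa <- .check_taxa(species_tree$tip.label)
  sp <- leaf_species(gene_tree$tip.label, rule)
  unknown <- setdiff(unique(sp), taxa)
  if (length(unknown))
    stop("species not in species tree: ", paste(unknown, collapse = ", "))
  if (!ape::is.binary(gene_tree)) gene_tree <- resolve_polytomies(gene_tree)
  m <- .node_masks(gene_tree, unname(sp), taxa)
  lca_all <- .lca_of_masks(species_tree, taxa, unique(m))
  mapping <- lca_all[match(m, unique(m))]
  ntip <- length(gene_tree$tip.label)
  nodes <- (ntip + 1L):(ntip + gene_tree$Nnode)
  dup <- logical(length(nodes))
  for (i in seq_along(nodes)) {
    kids <- gene_tree$edge[gene_tree$edge[, 1] == nodes[i], 2]
    dup[i] <- any(mapping[nodes[i]] == mapping[kids])
  }
  list(mapping = mapping, duplications = stats::setNames(dup, nodes),
       cost = sum(dup))
}

#' Date species-overlap duplications onto species-tree lineages
#'
#' Every duplication node (by species-overlap labeling) is dated to the
#' species-tree branch ending at the LCA of the species below it;
#' speciations are not dated.
#'
#' @param labeled_trees Named list of `labeled_gene_tree` objects
#'   (see [label_phylome()]).
#' @param species_tree Rooted `phylo` over species codes.
#' @return Data frame of events: tree_id, node, lineage (species-tree node
#'   id the dated branch leads to), lineage_label, side1, side2 (descendant
#'   sequence-id sets, `;`-joined, sorted).
#' @export
date_duplications <- function(labeled_trees, species_tree) {
  taxa <- .check_taxa(species_tree$tip.label)
  lab_of <- c(stats::setNames(taxa, seq_along(taxa)),
              stats::setNames(paste0("node", (length(taxa) + 1L):
                                       (length(taxa) + species_tree$Nnode)),
                              (length(taxa) + 1L):(length(taxa) + species_tree$Nnode)))
  rows <- list()
  for (nm in names(labeled_trees)) {
    lt <- labeled_trees[[nm]]
    dups <- lt$labels$node[lt$labels$event == "duplication"]
    if (!length(dups)) next
    tr <- lt$tree
    unknown <- setdiff(unique(lt$species), taxa)
    if (length(unknown))
      stop("species not in species tree: ", paste(unknown, collapse = ", "))
    m <- .node_masks(tr, unname(lt$species), taxa)
    desc <- .node_descendants(tr)
    lca <- .lca_of_masks(species_tree, taxa, m[dups])
    for (i in seq_along(dups)) {
      kids <- tr$edge[tr$edge[, 1] == dups[i], 2]
      rows[[length(rows) + 1L]] <- data.frame(
        tree_id = nm, node = dups[i], lineage = lca[i],
        lineage_label = unname(lab_of[as.character(lca[i])]),
        side1 = paste(sort(tr$tip.label[desc[[kids[1]]]]), collapse = ";"),
        side2 = paste(sort(tr$tip.label[desc[[kids[2]]]]), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(tree_id = character(0), node = integer(0),
                      lineage = integer(0), lineage_label = character(0),
                      side1 = character(0), side2 = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Merge redundant duplication events across overlapping trees
#'
#' A phylome reports the same evolutionary event once per seed whose tree
#' covers it. Two events from different trees are merged iff their unordered
#' pairs of descendant leaf-id sets are identical after restricting each set
#' to the intersection of the two trees' leaf universes, with both restricted
#' sides non-empty (`rule = "restricted-exact"`, the default), or iff the raw
#' sets are identical (`rule = "exact"`). Groups are connected components of
#' this relation; the first event of each group (input order) is its
#' representative.
#'
#' @param events Data frame from [date_duplications()].
#' @param universes Named list: tree_id -> character vector of the tree's
#'   leaf ids.
#' @param rule `"restricted-exact"` or `"exact"`.
#' @return `events` with columns `group` (integer id) and `representative`
#'   (logical) appended.
#' @export
merge_redundant_events <- function(events, universes,
                                   rule = c("restricted-exact", "exact")) {
  rule <- match.arg(rule)
  n <- nrow(events)
  if (!n) return(cbind(events, group = integer(0), representative = logical(0)))
  side1 <- strsplit(events$side1, ";", fixed = TRUE)
  side2 <- strsplit(events$side2, ";", fixed = TRUE)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  # candidate pairs share at least one leaf id
  leaf_index <- new.env(hash = TRUE)
  for (i in seq_len(n)) for (lf in c(side1[[i]], side2[[i]])) {
    leaf_index[[lf]] <- c(leaf_index[[lf]], i)
  }
  pairs <- unique(do.call(rbind, lapply(ls(leaf_index), function(lf) {
    ix <- unique(leaf_index[[lf]])
    if (length(ix) < 2) return(NULL)
    t(utils::combn(sort(ix), 2))
  })))
  if (!is.null(pairs)) for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (events$tree_id[i] == events$tree_id[j]) next
    a1 <- side1[[i]]; b1 <- side2[[i]]; a2 <- side1[[j]]; b2 <- side2[[j]]
    if (rule == "restricted-exact") {
      I <- intersect(universes[[events$tree_id[i]]],
                     universes[[events$tree_id[j]]])
      a1 <- intersect(a1, I); b1 <- intersect(b1, I)
      a2 <- intersect(a2, I); b2 <- intersect(b2, I)
      if (!length(a1) || !length(b1) || !length(a2) || !length(b2)) next
    }
    same <- (setequal(a1, a2) && setequal(b1, b2)) ||
            (setequal(a1, b2) && setequal(b1, a2))
    if (same) unite(i, j)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  group <- match(roots, unique(roots))
  representative <- !duplicated(group)
  cbind(events, group = group, representative = representative)
}

#' Per-lineage duplication counts and rates
#'
#' For each species-tree branch `b` (identified by the node it leads to):
#' `rate(b) = merged duplications dated to b / informative trees for b`.
#' A tree is informative for an internal branch iff it contains at least one
#' species below the branch and at least one outside; for a terminal branch
#' iff it contains that species; for the root iff it spans at least two of
#' the root's child subtrees. Branches with no informative tree get rate
#' `NA` (undefined, not 0).
#'
#' @param merged_events Output of [merge_redundant_events()].
#' @param labeled_trees Named list of `labeled_gene_tree` (the phylome).
#' @param species_tree Rooted `phylo` over species codes.
#' @param denominator `"observable"` (informative trees, default) or
#'   `"all"` (every tree).
#' @return Object of class `lineage_rates`: data frame (branch, label,
#'   count, informative, rate) with attributes `frac_trees_with_dup` (share
#'   of trees reporting >= 1 duplication) and `frac_trees_with_merged_dup`
#'   (share of trees owning >= 1 representative event).
#' @export
lineage_duplication_rates <- function(merged_events, labeled_trees,
                                      species_tree,
                                      denominator = c("observable", "all")) {
  denominator <- match.arg(denominator)
  taxa <- .check_taxa(species_tree$tip.label)
  ntip <- length(taxa)
  nn <- ntip + species_tree$Nnode
  smask <- .node_masks(species_tree, taxa, taxa)
  full <- smask[ntip + 1L]
  root_kids <- species_tree$edge[species_tree$edge[, 1] == ntip + 1L, 2]
  bits <- .taxon_bits(taxa)
  tree_mask <- vapply(labeled_trees, function(lt)
    Reduce(bitwOr, bits[unique(lt$species)], 0L), integer(1))
  informative <- integer(nn)
  for (v in seq_len(nn)) {
    if (denominator == "all") { informative[v] <- length(labeled_trees); next }
    if (v == ntip + 1L) {
      hits <- vapply(root_kids, function(k)
        as.integer(bitwAnd(tree_mask, smask[k]) != 0L), integer(length(tree_mask)))
      informative[v] <- sum(rowSums(matrix(hits, ncol = length(root_kids))) >= 2)
    } else if (v <= ntip) {
      informative[v] <- sum(bitwAnd(tree_mask, smask[v]) != 0L)
    } else {
      below <- bitwAnd(tree_mask, smask[v]) != 0L
      outside <- bitwAnd(tree_mask, bitwAnd(full, bitwNot(smask[v]))) != 0L
      informative[v] <- sum(below & outside)
    }
  }
  reps <- merged_events[merged_events$representative, , drop = FALSE]
  count <- integer(nn)
  if (nrow(reps)) {
    tb <- table(reps$lineage)
    count[as.integer(names(tb))] <- as.integer(tb)
  }
  lab_of <- c(taxa, paste0("node", (ntip + 1L):nn))
  rate <- ifelse(informative > 0, count / informative, NA_real_)
  out <- data.frame(branch = seq_len(nn), label = lab_of, count = count,
                    informative = informative, rate = rate,
                    stringsAsFactors = FALSE)
  has_dup <- vapply(labeled_trees, function(lt)
    any(lt$labels$event == "duplication"), logical(1))
  attr(out, "frac_trees_with_dup") <- mean(has_dup)
  attr(out, "frac_trees_with_merged_dup") <-
    if (length(labeled_trees))
      length(unique(reps$tree_id)) / length(labeled_trees) else NA_real_
  class(out) <- c("lineage_rates", class(out))
  out
}

#' Species tree annotated with duplication rates
#'
#' Writes per-lineage rates as internal node / tip suffix labels, one value
#' per branch, for plotting or inspection.
#'
#' @param rates A `lineage_rates` data frame.
#' @param species_tree The species tree the rates refer to.
#' @param digits Rounding for the labels.
#' @return Newick string.
#' @export
annotate_rates_newick <- function(rates, species_tree, digits = 3) {
  ntip <- length(species_tree$tip.label)
  fmt <- function(r) ifelse(is.na(r), "NA", format(round(r, digits)))
  tr <- species_tree
  tr$node.label <- fmt(rates$rate[(ntip + 1L):nrow(rates)])
  tr$tip.label <- paste0(tr$tip.label, "|", fmt(rates$rate[seq_len(ntip)]))
  ape::write.tree(tr)
}
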