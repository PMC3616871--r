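#' Parse a Newick string into a validated tree
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned object is a
#' standard `phylo`; gene-tree leaf labels are expected to encode both a
#' sequence id and a species code (see [leaf_species()]).
#'
#' @param text A single Newick string (terminating `;` optional).
#' @param file Alternatively, path to a file containing one tree.
#' @return A `phylo` object.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick string")
  if (!endsWith(text, ";")) text <- paste0(text, ";")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop(sprintf("malformed Newick: %d '(' vs %d ')' near character %d",
                 n_open, n_close, nchar(text)))
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tr)) stop("malformed Newick: parser returned no tree")
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup))
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "))
  if (!is.null(tr$edge.length)) {
    if (any(!is.finite(tr$edge.length)))
      stop("non-finite branch lengths")
    if (any(tr$edge.length < 0))
      stop("negative branch lengths")
  }
  tr
}

#' Write a tree as a Newick string
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @return A Newick string.
#' @export
write_newick <- function(tree, digits = 12) {
  ape::write.tree(tree, digits = digits)
}

#' Extract species codes from gene-tree leaf labels
#'
#' The default naming convention is `SEQID_SPECIES`: the species code is the
#' token after the last underscore. An explicit mapping (named character
#' vector or two-column data frame `sequence_id`, `species_code`) overrides
#' the convention.
#'
#' @param labels Character vector of leaf labels.
#' @param rule `"suffix"` (default) or a named character vector / data frame
#'   mapping sequence id to species code.
#' @return Named character vector: species code per label.
#' @export
leaf_species <- function(labels, rule = "suffix") {
  if (is.data.frame(rule)) {
    map <- stats::setNames(as.character(rule[[2]]), as.character(rule[[1]]))
    rule <- map
  }
  if (is.character(rule) && length(rule) == 1 && identical(unname(rule), "suffix")) {
    bad <- labels[!grepl("_", labels)]
    if (length(bad))
      stop("leaf labels not matching SEQID_SPECIES convention: ",
           paste(utils::head(bad, 5), collapse = ", "))
    sp <- sub("^.*_", "", labels)
    return(stats::setNames(sp, labels))
  }
  missing <- setdiff(labels, names(rule))
  if (length(missing))
    stop("labels absent from species map: ", paste(utils::head(missing, 5), collapse = ", "))
  stats::setNames(unname(rule[labels]), labels)
}

#' Read a two-column species map file
#'
#' @param path TSV file with columns sequence_id, species_code (no header).
#' @return Named character vector usable as the `rule` of [leaf_species()].
#' @export
read_species_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sequence_id", "species_code"),
                          stringsAsFactors = FALSE)
  stats::setNames(df$species_code, df$sequence_id)
}

#' Root a tree by outgroup or at the midpoint
#'
#' Outgroup rooting places the root on the edge above the smallest clade
#' containing all present outgroup leaves; midpoint rooting uses the midpoint
#' of the longest leaf-to-leaf path (ties broken towards the lexicographically
#' smallest leaf pair).
#'
#' @param tree A `phylo` object.
#' @param outgroup Character vector of species codes (or leaf labels, see
#'   `by`); required for `method = "outgroup"`.
#' @param method `"outgroup"` or `"midpoint"`.
#' @param by Whether `outgroup` names `"species"` (matched through
#'   [leaf_species()]) or literal `"label"`s.
#' @param rule Leaf-naming rule forwarded to [leaf_species()].
#' @return A rooted `phylo`.
#' @export
root_tree <- function(tree, outgroup = NULL,
                      method = if (is.null(outgroup)) "midpoint" else "outgroup",
                      by = c("species", "label"), rule = "suffix") {
  method <- match.arg(method, c("outgroup", "midpoint"))
  if (method == "outgroup") {
    by <- match.arg(by)
    tips <- if (by == "species") {
      sp <- leaf_species(tree$tip.label, rule)
      tree$tip.label[sp %in% outgroup]
    } else intersect(outgroup, tree$tip.label)
    if (!length(tips))
      stop("no outgroup leaves present in the tree")
    if (length(tips) == length(tree$tip.label))
      stop("outgroup covers every leaf; cannot root")
    out <- ape::root(tree, outgroup = tips, resolve.root = TRUE)
    return(out)
  }
  if (is.null(tree$edge.length) || all(tree$edge.length == 0))
    stop("midpoint rooting needs positive branch lengths; use outgroup rooting")
  phangorn::midpoint(tree)
}

#' Non-trivial bipartitions of a tree
#'
#' One bipartition per internal edge of the unrooted topology, optionally
#' after pruning to a leaf subset. Each bipartition is canonicalized: both
#' sides sorted, the lexicographically smaller side first, encoded as
#' `"a,b|c,d"`.
#'
#' @param tree A `phylo`.
#' @param restrict_to Optional character vector of leaf labels to prune to
#'   first.
#' @return Character vector of canonical split keys (possibly empty).
#' @export
tree_bipartitions <- function(tree, restrict_to = NULL) {
  if (!is.null(restrict_to)) {
    restrict_to <- intersect(tree$tip.label, restrict_to)
    if (length(restrict_to) < 4) return(character(0))
    tree <- prune_to_taxa(tree, restrict_to)
  }
  if (length(tree$tip.label) < 4) return(character(0))
  ut <- ape::unroot(tree)
  ntip <- length(ut$tip.label)
  labs <- ut$tip.label
  # clade sets per internal non-root node
  clades <- .node_descendants(ut)
  root <- ntip + 1L
  keys <- character(0)
  for (nd in setdiff((ntip + 1L):(ntip + ut$Nnode), root)) {
    side1 <- sort(labs[clades[[nd]]])
    side2 <- sort(setdiff(labs, side1))
    if (length(side1) < 2 || length(side2) < 2) next
    keys <- c(keys, .split_key(side1, side2))
  }
  unique(keys)
}

.split_key <- function(side1, side2) {
  a <- paste(side1, collapse = ",")
  b <- paste(side2, collapse = ",")
  if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
}

# Internal: list over all nodes of tip indices below each node.
.node_descendants <- function(tree) {
  ntip <- length(tree$tip.label)
  res <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) res[[i]] <- i
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    res[[p]] <- c(res[[p]], res[[ch]])
  }
  res
}

#' Prune a tree to a subset of leaves
#'
#' Removes all leaves outside `keep`, suppressing unary internal nodes
#' (branch lengths are summed along suppressed paths).
#'
#' @param tree A `phylo`.
#' @param keep Character vector of leaf labels, a non-empty subset of the
#'   tree's leaves.
#' @return The induced `phylo` on `keep`.
#' @export
prune_to_taxa <- function(tree, keep) {
  if (!length(keep)) stop("`keep` is empty")
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("unknown leaf labels: ", paste(unknown, collapse = ", "))
  if (length(keep) == length(tree$tip.label)) return(tree)
  if (length(keep) == 1) {
    # degenerate single-leaf tree
    return(structure(list(edge = matrix(c(2L, 1L), 1, 2),
                          tip.label = keep, Nnode = 1L,
                          edge.length = if (!is.null(tree$edge.length)) sum_path_to_tip(tree, keep)),
                     class = "phylo"))
  }
  ape::keep.tip(tree, keep)
}

sum_path_to_tip <- function(tree, tip) {
  # total length from root to a tip (used for the 1-leaf pruning degenerate)
  i <- match(tip, tree$tip.label)
  len <- 0
  repeat {
    e <- which(tree$edge[, 2] == i)
    if (!length(e)) break
    len <- len + tree$edge.length[e]
    i <- tree$edge[e, 1]
  }
  len
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of non-trivial bipartitions of the unrooted
#' topologies. Zero iff the unrooted topologies are identical.
#'
#' @param t1,t2 `phylo` objects over the same leaf set.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  d <- c(setdiff(t1$tip.label, t2$tip.label), setdiff(t2$tip.label, t1$tip.label))
  if (length(d))
    stop("leaf sets differ; symmetric difference: ", paste(d, collapse = ", "))
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Resolve polytomies deterministically
#'
#' Multifurcations are resolved left-to-right (in the node's child order)
#' with zero-length branches, so repeated calls give identical results.
#'
#' @param tree A `phylo`.
#' @return A binary `phylo`.
#' @export
resolve_polytomies <- function(tree) {
  if (ape::is.binary(tree)) return(tree)
  ape::multi2di(tree, random = FALSE)
}
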