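# Split utilities on integer bitmasks (taxa universe fixed, <= 30 species).

# Canonical non-trivial split masks of an (unrooted view of a) tree whose
# tips are species codes drawn from `taxa`. A split restricted to `present`
# (a mask) is canonicalized as the side NOT containing the lowest set bit of
# `present`.
.canon_splits <- function(clade_masks, present) {
  if (!length(clade_masks)) return(integer(0))
  low <- bitwAnd(present, -present)            # lowest set bit
  s <- bitwAnd(clade_masks, present)
  flip <- bitwAnd(s, low) != 0L
  s[flip] <- bitwAnd(present, bitwNot(s[flip]))
  pc <- .popcount32(s)                         # sides partition `present`
  unique(s[pc >= 2L & (.popcount32(present) - pc) >= 2L])
}

# Clade masks of internal non-root nodes (the split-defining clades).
.internal_clade_masks <- function(tree, taxa, tips_are_species = TRUE,
                                  rule = "suffix") {
  tipsp <- if (tips_are_species) tree$tip.label else
    unname(leaf_species(tree$tip.label, rule))
  m <- .node_masks(tree, tipsp, taxa)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nodes <- setdiff(unique(tree$edge[, 1]), root)
  nodes <- nodes[nodes > ntip]
  # for a rooted binary tree also count the root's child clades (unrooted view)
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  c(m[nodes], m[kids[kids > ntip]])
}

# Present-taxa mask of a species-labeled tree.
.present_mask <- function(tree, taxa) {
  bits <- .taxon_bits(taxa)
  Reduce(bitwOr, bits[unique(tree$tip.label)], 0L)
}

#' Split-fit (SFIT) score of a candidate species tree
#'
#' For every single-labeled source topology sharing at least 4 species with
#' the candidate, the candidate is pruned to the source's species and the
#' fit is `shared splits / max(source splits, pruned-candidate splits)`
#' (switchable to `shared / source splits`). The score is the mean fit over
#' eligible sources.
#'
#' @param candidate `phylo` over species codes.
#' @param gene_topologies List of single-labeled species topologies (e.g.
#'   from [decompose_speciation_subtrees()]).
#' @param denominator `"max"` (default) or `"source"`.
#' @return Mean fit in `[0, 1]`, with attribute `"skipped"` (sources sharing
#'   fewer than 4 species).
#' @export
sfit_score <- function(candidate, gene_topologies,
                       denominator = c("max", "source")) {
  denominator <- match.arg(denominator)
  taxa <- .check_taxa(sort(unique(c(candidate$tip.label,
                                    unlist(lapply(gene_topologies,
                                                  `[[`, "tip.label"))))))
  pre <- .sfit_precompute(gene_topologies, taxa, denominator)
  .sfit_score_fast(pre, candidate)
}

# Source masks and raw clade masks computed once per collection. Sources are
# grouped by identical taxon mask so a candidate is restricted once per
# unique mask, not once per source.
.sfit_precompute <- function(gene_topologies, taxa, denominator = "max") {
  masks <- vapply(gene_topologies, .present_mask, integer(1), taxa = taxa)
  clades <- lapply(gene_topologies, .internal_clade_masks, taxa = taxa)
  src_splits <- lapply(seq_along(clades), function(j)
    .canon_splits(clades[[j]], masks[j]))
  # collapse sources with identical (taxon set, split set): they score
  # identically against every candidate, so a weighted mean is exact
  key <- vapply(seq_along(masks), function(j)
    paste(masks[j], paste(sort(src_splits[[j]]), collapse = ","), sep = "#"),
    character(1))
  uix <- which(!duplicated(key))
  w <- as.numeric(table(match(key, key[uix]))[as.character(seq_along(uix))])
  masks_u <- masks[uix]
  umask <- unique(masks_u)
  list(taxa = taxa, masks = masks_u, weight = w,
       umask = umask, group = match(masks_u, umask),
       eligible_mask = .popcount32(umask) >= 4L,
       clades = clades[uix], src_splits = src_splits[uix],
       denominator = denominator)
}

.sfit_score_fast <- function(pre, candidate) {
  cand_clades <- .internal_clade_masks(candidate, pre$taxa)
  cand_mask <- .present_mask(candidate, pre$taxa)
  # restricted candidate split sets, one per unique source mask
  cnd_by_mask <- vector("list", length(pre$umask))
  eligible <- pre$eligible_mask &
    .popcount32(bitwAnd(pre$umask, cand_mask)) >= 4L
  for (u in which(eligible))
    cnd_by_mask[[u]] <- .canon_splits(cand_clades,
                                      bitwAnd(pre$umask[u], cand_mask))
  fits <- numeric(length(pre$masks))
  use <- logical(length(pre$masks))
  skipped <- 0L
  for (j in seq_along(pre$masks)) {
    u <- pre$group[j]
    if (!eligible[u]) { skipped <- skipped + pre$weight[j]; next }
    shared_mask <- bitwAnd(pre$umask[u], cand_mask)
    src <- if (shared_mask == pre$umask[u]) pre$src_splits[[j]]
           else .canon_splits(pre$clades[[j]], shared_mask)
    cnd <- cnd_by_mask[[u]]
    shared <- length(intersect(src, cnd))
    denom <- if (pre$denominator == "max") max(length(src), length(cnd))
             else length(src)
    fits[j] <- if (denom == 0) 1 else shared / denom
    use[j] <- TRUE
  }
  if (!any(use)) stop("no eligible source topologies (need >= 4 shared species)")
  structure(sum(fits[use] * pre$weight[use]) / sum(pre$weight[use]),
            skipped = skipped)
}

#' Gene-tree duplication-parsimony cost of a candidate species tree
#'
#' Sum over gene trees of the LCA-reconciliation duplication count against
#' the candidate (see [reconcile_lca()]); the criterion minimized by
#' gene-tree parsimony.
#'
#' @param candidate Rooted `phylo` over species codes.
#' @param gene_trees List of rooted gene trees (multi-labeled; leaves encode
#'   species).
#' @param rule Leaf-naming rule.
#' @return Non-negative integer.
#' @export
gtp_duplication_cost <- function(candidate, gene_trees, rule = "suffix") {
  taxa <- .check_taxa(sort(candidate$tip.label))
  pre <- .gtp_precompute(gene_trees, taxa, rule)
  .gtp_cost_restricted(pre, candidate)
}

# Cost of a candidate that may span only a subset of the precompute taxa:
# masks are restricted to the candidate's species (equivalent to pruning
# every gene tree to those species first).
.gtp_cost_restricted <- function(pre, candidate) {
  cmask <- .present_mask(candidate, pre$taxa)
  l <- bitwAnd(pre$masks[pre$left], cmask)
  r <- bitwAnd(pre$masks[pre$right], cmask)
  keep <- l != 0L & r != 0L
  if (!any(keep)) return(0L)
  s <- bitwOr(l[keep], r[keep])
  u <- unique(c(s, l[keep], r[keep]))
  lca <- .lca_of_masks(candidate, pre$taxa, u)
  si <- lca[match(s, u)]
  sum(si == lca[match(l[keep], u)] | si == lca[match(r[keep], u)])
}

# ---- search ---------------------------------------------------------------

# Deterministic rooted-NNI neighborhood: for each internal non-root node v
# (in increasing node order) with parent u and sibling w, the two trees
# obtained by swapping w with each child of v.
.nni_neighbors <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  out <- list()
  cand <- sort(setdiff(unique(tree$edge[, 1]), root))
  cand <- cand[cand > ntip]
  for (v in cand) {
    u <- tree$edge[tree$edge[, 2] == v, 1]
    sibs <- setdiff(tree$edge[tree$edge[, 1] == u, 2], v)
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    for (w in sibs) for (c1 in kids) {
      tr <- tree
      ew <- which(tr$edge[, 2] == w)
      ec <- which(tr$edge[, 2] == c1)
      tr$edge[ew, 1] <- v
      tr$edge[ec, 1] <- u
      out[[length(out) + 1L]] <- ape::read.tree(text = ape::write.tree(tr))
    }
  }
  out
}

# Newick-fragment machinery for prune/regraft moves. `v = 0` means no
# pruning (used by greedy taxon addition). Returns base fragment plus all
# variants with `sub` inserted below every node of the remaining tree.
.graft_variants <- function(nd, v, tree, kids, sub) {
  if (nd == v) return(NULL)
  ntip <- length(tree$tip.label)
  if (nd <= ntip) {
    b <- tree$tip.label[nd]
    return(list(base = b, vars = paste0("(", b, ",", sub, ")")))
  }
  parts <- lapply(kids[[nd]], .graft_variants, v = v, tree = tree,
                  kids = kids, sub = sub)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) return(NULL)
  if (length(parts) == 1) return(parts[[1]])   # unary node suppressed
  bases <- vapply(parts, `[[`, character(1), "base")
  base <- paste0("(", paste(bases, collapse = ","), ")")
  vars <- character(0)
  for (i in seq_along(parts)) {
    others <- bases[-i]
    vars <- c(vars, vapply(parts[[i]]$vars, function(vr)
      paste0("(", paste(c(vr, others), collapse = ","), ")"), character(1)))
  }
  vars <- c(vars, paste0("(", base, ",", sub, ")"))
  list(base = base, vars = vars)
}

.node_kids <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  lapply(seq_len(nn), function(v) tree$edge[tree$edge[, 1] == v, 2])
}

.node_frags <- function(tree, kids) {
  ntip <- length(tree$tip.label)
  frag <- character(ntip + tree$Nnode)
  frag[seq_len(ntip)] <- tree$tip.label
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]
    if (!nzchar(frag[p]))
      frag[p] <- paste0("(",
                        paste(frag[kids[[p]]], collapse = ","), ")")
  }
  frag
}

# canonical key for dedup: sorted-clade newick
.canon_newick <- function(txt) {
  tr <- ape::read.tree(text = txt)
  ape::write.tree(ape::rotateConstr(tr, sort(tr$tip.label)))
}

# Full rooted SPR neighborhood: every subtree pruned and regrafted below
# every remaining node (including as a new sister to the whole rest).
.spr_neighbors <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 4) return(list())
  root <- ntip + 1L
  kids <- .node_kids(tree)
  frag <- .node_frags(tree, kids)
  texts <- character(0)
  for (v in setdiff(seq_len(ntip + tree$Nnode), root)) {
    res <- .graft_variants(root, v, tree, kids, frag[v])
    if (is.null(res)) next
    vars <- res$vars
    # res already includes sub as sister to the remaining root
    texts <- c(texts, paste0(vars, ";"))
  }
  texts <- unique(texts)
  self <- .canon_newick(ape::write.tree(tree))
  out <- list()
  seen <- character(0)
  for (tx in texts) {
    key <- .canon_newick(tx)
    if (key == self || key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- ape::read.tree(text = tx)
  }
  out
}

.random_rooted_topology <- function(taxa) {
  tr <- ape::rtree(length(taxa), tip.label = sample(taxa))
  tr$edge.length <- NULL
  tr
}

#' Supertree search under split-fit or duplication parsimony
#'
#' Hill-climbing over rooted species topologies with NNI moves
#' (first-improvement, deterministic neighbor order) plus one SPR round
#' whenever NNI stalls; restarts from `n_starts` random topologies plus one
#' greedy taxon-addition topology. Deterministic given `seed`.
#'
#' @param gene_trees For `criterion = "duplication_parsimony"`: rooted
#'   multi-labeled gene trees (leaves encode species). For
#'   `criterion = "sfit"`: single-labeled species topologies.
#' @param criterion `"sfit"` or `"duplication_parsimony"`.
#' @param n_starts Number of random starting topologies.
#' @param seed Integer seed.
#' @param rule Leaf-naming rule for multi-labeled input.
#' @param denominator Forwarded to [sfit_score()].
#' @return Object of class `supertree_result`: list with `tree`, `criterion`,
#'   `score` (mean split fit, or total duplication count), `trace`
#'   (data frame: step, move, score).
#' @export
search_supertree <- function(gene_trees,
                             criterion = c("sfit", "duplication_parsimony"),
                             n_starts = 2L, seed = 1L, rule = "suffix",
                             denominator = "max") {
  criterion <- match.arg(criterion)
  tips_are_species <- criterion == "sfit"
  taxa <- sort(unique(unlist(lapply(gene_trees, function(t)
    if (tips_are_species) t$tip.label else leaf_species(t$tip.label, rule)))))
  .check_taxa(taxa)
  if (length(taxa) < 4) stop("need at least 4 species across the gene trees")
  if (criterion == "duplication_parsimony") {
    pre <- .gtp_precompute(gene_trees, taxa, rule)
    score_fn <- function(cand) -.gtp_cost_restricted(pre, cand)
  } else {
    pre <- .sfit_precompute(gene_trees, taxa, denominator)
    score_fn <- function(cand) {
      as.numeric(tryCatch(.sfit_score_fast(pre, cand),
                          error = function(e) -Inf))
    }
  }
  set.seed(seed)
  starts <- c(list(.greedy_addition(taxa, score_fn)),
              replicate(n_starts, .random_rooted_topology(taxa),
                        simplify = FALSE))
  best <- NULL; best_score <- -Inf
  trace <- data.frame(step = integer(0), move = character(0),
                      score = numeric(0))
  step <- 0L
  for (stree in starts) {
    cur <- stree; cur_score <- score_fn(cur)
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, move = "start",
                                     score = if (criterion == "sfit")
                                       cur_score else -cur_score))
    repeat {
      improved <- FALSE
      for (nb in .nni_neighbors(cur)) {
        s <- score_fn(nb)
        if (s > cur_score) {
          cur <- nb; cur_score <- s; improved <- TRUE
          step <- step + 1L
          trace <- rbind(trace, data.frame(step = step, move = "nni",
                                           score = if (criterion == "sfit") s else -s))
          break
        }
      }
      if (improved) next
      # NNI stalled: one SPR round
      spr_best <- NULL; spr_score <- cur_score
      for (nb in .spr_neighbors(cur)) {
        s <- score_fn(nb)
        if (s > spr_score ||
            (s == spr_score && !is.null(spr_best) &&
             ape::write.tree(nb) < ape::write.tree(spr_best))) {
          spr_best <- nb; spr_score <- s
        }
      }
      if (!is.null(spr_best) && spr_score > cur_score) {
        cur <- spr_best; cur_score <- spr_score
        step <- step + 1L
        trace <- rbind(trace, data.frame(step = step, move = "spr",
                                         score = if (criterion == "sfit") spr_score else -spr_score))
        next
      }
      break
    }
    if (cur_score > best_score ||
        (cur_score == best_score &&
         ape::write.tree(cur) < ape::write.tree(best))) {
      best <- cur; best_score <- cur_score
    }
  }
  score <- if (criterion == "duplication_parsimony") -best_score else best_score
  structure(list(tree = best, criterion = criterion, score = score,
                 trace = trace), class = "supertree_result")
}

#' @export
print.supertree_result <- function(x, ...) {
  cat(sprintf("supertree (%s): score %s, %d search steps\n%s\n",
              x$criterion, format(x$score), nrow(x$trace),
              ape::write.tree(x$tree)))
  invisible(x)
}

# Greedy stepwise taxon addition: grow the candidate species by species,
# each time inserting at the position that scores best (criterion restricted
# to the species added so far).
.greedy_addition <- function(taxa, score_fn) {
  cur <- ape::read.tree(text = sprintf("((%s,%s),%s);",
                                       taxa[1], taxa[2], taxa[3]))
  for (sp in taxa[-(1:3)]) {
    kids <- .node_kids(cur)
    res <- .graft_variants(length(cur$tip.label) + 1L, 0L, cur, kids, sp)
    best <- NULL; best_s <- -Inf
    for (tx in paste0(res$vars, ";")) {
      tr <- ape::read.tree(text = tx)
      s <- score_fn(tr)
      if (s > best_s) { best <- tr; best_s <- s }
    }
    cur <- best
  }
  cur
}

#' Exhaustive supertree optimum over all rooted topologies
#'
#' Enumerates every rooted binary topology (feasible up to ~7 species) and
#' returns the optimum; used as an oracle for [search_supertree()].
#'
#' @inheritParams search_supertree
#' @return `supertree_result` (trace has one row per topology scored).
#' @export
enumerate_supertree <- function(gene_trees,
                                criterion = c("sfit", "duplication_parsimony"),
                                rule = "suffix", denominator = "max") {
  criterion <- match.arg(criterion)
  tips_are_species <- criterion == "sfit"
  taxa <- sort(unique(unlist(lapply(gene_trees, function(t)
    if (tips_are_species) t$tip.label else leaf_species(t$tip.label, rule)))))
  if (length(taxa) > 7) stop("exhaustive enumeration limited to 7 species")
  if (criterion == "duplication_parsimony") {
    pre <- .gtp_precompute(gene_trees, taxa, rule)
    score_fn <- function(cand) -.gtp_cost_restricted(pre, cand)
  } else {
    pre <- .sfit_precompute(gene_trees, taxa, denominator)
    score_fn <- function(cand) as.numeric(.sfit_score_fast(pre, cand))
  }
  all <- phangorn::allTrees(length(taxa), rooted = TRUE, tip.label = taxa)
  best <- NULL; best_score <- -Inf
  for (i in seq_along(all)) {
    tr <- all[[i]]    # [[ reattaches multiPhylo compressed tip labels
    s <- score_fn(tr)
    if (s > best_score ||
        (s == best_score && ape::write.tree(tr) < ape::write.tree(best))) {
      best <- tr; best_score <- s
    }
  }
  score <- if (criterion == "duplication_parsimony") -best_score else best_score
  structure(list(tree = best, criterion = criterion, score = score,
                 trace = data.frame(step = seq_along(all), move = "enum",
                                    score = NA_real_)),
            class = "supertree_result")
}

#' Per-bipartition gene-tree support of a species tree
#'
#' A gene topology is eligible for a bipartition iff, after restricting the
#' bipartition to the topology's species, both sides retain at least two
#' species (`eligibility = "restricted"`; `"strict"` requires every species
#' present); it supports the bipartition iff the restricted split is among
#' its own non-trivial splits.
#'
#' @param species_tree `phylo` over species codes.
#' @param gene_topologies Single-labeled species topologies.
#' @param eligibility `"restricted"` or `"strict"`.
#' @return Data frame: split (canonical `a,b|c,d` key), supporting,
#'   eligible, support_pct (percent, `NA` where no tree is eligible).
#' @export
bipartition_support <- function(species_tree, gene_topologies,
                                eligibility = c("restricted", "strict")) {
  eligibility <- match.arg(eligibility)
  taxa <- .check_taxa(sort(species_tree$tip.label))
  full <- Reduce(bitwOr, .taxon_bits(taxa), 0L)
  cand_splits <- .canon_splits(.internal_clade_masks(species_tree, taxa), full)
  tree_masks <- vapply(gene_topologies, .present_mask, integer(1), taxa = taxa)
  tree_splits <- lapply(gene_topologies, function(t) {
    tm <- .present_mask(t, taxa)
    .canon_splits(.internal_clade_masks(t, taxa), tm)
  })
  sup <- el <- integer(length(cand_splits))
  for (i in seq_along(cand_splits)) {
    b <- cand_splits[i]
    for (j in seq_along(gene_topologies)) {
      tm <- tree_masks[j]
      if (eligibility == "strict" && tm != full) next
      s1 <- bitwAnd(b, tm)
      s2 <- bitwAnd(bitwAnd(full, bitwNot(b)), tm)
      if (.popcount32(s1) < 2L || .popcount32(s2) < 2L) next
      el[i] <- el[i] + 1L
      restricted <- .canon_splits(b, tm)
      if (length(restricted) && restricted %in% tree_splits[[j]])
        sup[i] <- sup[i] + 1L
    }
  }
  bits <- .taxon_bits(taxa)
  key <- vapply(cand_splits, function(b) {
    s1 <- taxa[bitwAnd(bits, b) != 0L]
    .split_key(sort(s1), sort(setdiff(taxa, s1)))
  }, character(1))
  data.frame(split = key, supporting = sup, eligible = el,
             support_pct = ifelse(el > 0, 100 * sup / el, NA_real_),
             stringsAsFactors = FALSE)
}
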