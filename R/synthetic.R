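#' Simulation configuration for synthetic phylomes
#'
#' Bundles every knob of the generator: a birth-death species tree, gene
#' families evolving along it with duplication and loss, transcriptome-style
#' incomplete sampling of gene copies, optional one-move NNI topology error,
#' and protein alignments evolved under an empirical model with discrete
#' gamma + invariant-sites rate heterogeneity.
#'
#' @param n_species Number of extant species (>= 2).
#' @param birth,death Species-tree birth and death rates (events per lineage
#'   per unit time).
#' @param n_families Number of gene families.
#' @param dup_rate,loss_rate Gene duplication and loss rates per gene lineage
#'   per unit species-tree branch length.
#' @param sampling_prob Probability that a surviving gene copy is observed
#'   (models transcriptome incompleteness).
#' @param topology_error_p Probability a simulated gene tree receives one
#'   random NNI perturbation.
#' @param aln_length Alignment columns.
#' @param model Substitution model name (see [subst_model()]).
#' @param alpha Gamma shape for among-site rates (`Inf` = uniform).
#' @param k Discrete gamma categories.
#' @param p_inv Invariant-site fraction.
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#' @param seed_species Species code carrying the seed sequence of each tree;
#'   default: first tip of the species tree.
#' @param subs_per_time Scaling from species-tree time units to expected
#'   substitutions per site on gene-tree branches.
#' @param max_retries Resimulation cap per family.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_species = 8, birth = 1, death = 0.5,
                       n_families = 100, dup_rate = 0.3, loss_rate = 0.1,
                       sampling_prob = 1, topology_error_p = 0,
                       aln_length = 300, model = "WAG", alpha = 1, k = 4L,
                       p_inv = 0.1, seed = 1L, seed_species = NULL,
                       subs_per_time = 0.5, max_retries = 100L) {
  cfg <- list(n_species = n_species, birth = birth, death = death,
              n_families = n_families, dup_rate = dup_rate,
              loss_rate = loss_rate, sampling_prob = sampling_prob,
              topology_error_p = topology_error_p, aln_length = aln_length,
              model = model, alpha = alpha, k = as.integer(k), p_inv = p_inv,
              seed = as.integer(seed), seed_species = seed_species,
              subs_per_time = subs_per_time, max_retries = as.integer(max_retries))
  stopifnot(cfg$n_species >= 2, cfg$birth > 0, cfg$death >= 0,
            cfg$dup_rate >= 0, cfg$loss_rate >= 0,
            cfg$sampling_prob >= 0, cfg$sampling_prob <= 1,
            cfg$topology_error_p >= 0, cfg$topology_error_p <= 1,
            cfg$p_inv >= 0, cfg$p_inv < 1, cfg$alpha > 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a species tree
#'
#' Rooted ultrametric birth-death tree conditioned on `n_species` extant
#' tips (via [ape::rphylo()]); tips are labelled `s1..sn`, branch lengths are
#' in time units.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed override.
#' @return A `phylo` with `n_species` tips.
#' @export
simulate_species_tree <- function(config, seed = config$seed) {
  if (config$death >= config$birth)
    stop("death rate >= birth rate: the conditioned process is degenerate; lower `death`")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(config$n_species, config$birth, config$death)
  tr$tip.label <- paste0("s", seq_len(config$n_species))
  tr
}

# Internal: one gene lineage entering the species-tree edge that ends at
# `node`, with `t_left` time remaining on it. Returns NULL (lost/unsampled)
# or list(kind, node(=species edge end), children, stem, species/tip label).
.evolve_edge <- function(stree, node, t_left, cfg, counter) {
  rate <- cfg$dup_rate + cfg$loss_rate
  t_ev <- if (rate > 0) stats::rexp(1, rate) else Inf
  if (t_ev < t_left) {
    if (stats::runif(1) < cfg$dup_rate / rate) {   # duplication
      l <- .evolve_edge(stree, node, t_left - t_ev, cfg, counter)
      r <- .evolve_edge(stree, node, t_left - t_ev, cfg, counter)
      if (is.null(l) && is.null(r)) return(NULL)
      if (is.null(l)) { r$stem <- r$stem + t_ev; return(r) }
      if (is.null(r)) { l$stem <- l$stem + t_ev; return(l) }
      return(list(kind = "dup", sp_node = node, children = list(l, r),
                  stem = t_ev))
    }
    return(NULL)                                   # loss
  }
  ntip <- length(stree$tip.label)
  if (node <= ntip) {                              # species tip: sample copy
    if (stats::runif(1) >= cfg$sampling_prob) return(NULL)
    counter$n <- counter$n + 1L
    return(list(kind = "leaf", sp_node = node, stem = t_left,
                species = stree$tip.label[node], copy = counter$n))
  }
  kids <- stree$edge[stree$edge[, 1] == node, 2]
  lens <- stree$edge.length[stree$edge[, 1] == node]
  parts <- vector("list", length(kids))
  for (i in seq_along(kids))
    parts[[i]] <- .evolve_edge(stree, kids[i], lens[i], cfg, counter)
  alive <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(alive)) return(NULL)
  if (length(alive) == 1) {
    a <- alive[[1]]; a$stem <- a$stem + t_left
    return(a)
  }
  list(kind = "spec", sp_node = node, children = alive, stem = t_left)
}

# Internal: gene-node structure -> newick with truth labels.
.struct_newick <- function(x, fam) {
  if (x$kind == "leaf")
    return(sprintf("F%sg%d_%s:%.10f", fam, x$copy, x$species, x$stem))
  inner <- paste(vapply(x$children, .struct_newick, character(1), fam = fam),
                 collapse = ",")
  lab <- if (x$kind == "dup") paste0("D", x$sp_node) else paste0("S", x$sp_node)
  sprintf("(%s)%s:%.10f", inner, lab, x$stem)
}

# Internal: one rooted NNI move, uniform over eligible internal nodes.
.random_nni <- function(tree) {
  ntip <- length(tree$tip.label)
  # eligible: internal non-root nodes v whose parent has another child
  root <- ntip + 1L
  cand <- setdiff(unique(tree$edge[, 1]), root)
  cand <- cand[cand > ntip]
  if (!length(cand)) return(tree)
  v <- if (length(cand) == 1) cand else sample(cand, 1)
  u <- tree$edge[tree$edge[, 2] == v, 1]
  sibs <- setdiff(tree$edge[tree$edge[, 1] == u, 2], v)
  w <- if (length(sibs) == 1) sibs else sample(sibs, 1)
  kids <- tree$edge[tree$edge[, 1] == v, 2]
  c1 <- if (length(kids) == 1) kids else sample(kids, 1)
  # swap subtree w (sibling of v) with subtree c1 (child of v)
  ew <- which(tree$edge[, 2] == w)
  ec <- which(tree$edge[, 2] == c1)
  tree$edge[ew, 1] <- v
  tree$edge[ec, 1] <- u
  ape::read.tree(text = ape::write.tree(tree))  # renumber canonically
}

#' Simulate one gene family along a species tree
#'
#' Gene lineages evolve down the species tree: duplications arise as a
#' Poisson process at `dup_rate` per lineage per unit branch length (each
#' bifurcates the lineage in place), losses at `loss_rate` kill a lineage,
#' and each copy surviving to a tip is retained with `sampling_prob`.
#' Families with fewer than 3 retained leaves, or without a retained copy in
#' the seed species, are resimulated (the count is returned). With
#' probability `topology_error_p` one random NNI is applied after
#' construction (recorded in `nni_applied`); planted events always describe
#' the pre-perturbation tree.
#'
#' @param species_tree `phylo` from [simulate_species_tree()].
#' @param config A [sim_config()].
#' @param family_id Label used in sequence ids (`F<id>g<k>_<species>`).
#' @return List: `tree` (rooted `phylo`, time-unit branch lengths, attribute
#'   `"seed_leaf"`), `events` (data frame: node, lineage, side1, side2 --
#'   lineage is the species-tree node id ending the branch the duplication
#'   occurred on), `nni_applied`, `n_resim`.
#' @export
simulate_gene_family <- function(species_tree, config, family_id = 1) {
  seed_sp <- config$seed_species
  if (is.null(seed_sp)) seed_sp <- species_tree$tip.label[1]
  ntip <- length(species_tree$tip.label)
  root <- ntip + 1L
  for (try in seq_len(config$max_retries)) {
    counter <- new.env(); counter$n <- 0L
    st <- .evolve_edge(species_tree, root, 0, config, counter)
    if (is.null(st)) next
    if (st$kind == "leaf") next
    txt <- paste0(.struct_newick(st, family_id), ";")
    tr <- ape::read.tree(text = txt)
    if (length(tr$tip.label) < 3) next
    sp <- leaf_species(tr$tip.label)
    if (!any(sp == seed_sp)) next
    # planted events from truth labels, sides as leaf-id sets
    desc <- .node_descendants(tr)
    ev <- data.frame(node = integer(0), lineage = integer(0),
                     side1 = character(0), side2 = character(0),
                     stringsAsFactors = FALSE)
    for (nd in (length(tr$tip.label) + 1L):(length(tr$tip.label) + tr$Nnode)) {
      lab <- tr$node.label[nd - length(tr$tip.label)]
      if (!startsWith(lab, "D")) next
      kids <- tr$edge[tr$edge[, 1] == nd, 2]
      s1 <- sort(tr$tip.label[desc[[kids[1]]]])
      s2 <- sort(tr$tip.label[desc[[kids[2]]]])
      ev <- rbind(ev, data.frame(node = nd, lineage = as.integer(sub("D", "", lab)),
                                 side1 = paste(s1, collapse = ";"),
                                 side2 = paste(s2, collapse = ";"),
                                 stringsAsFactors = FALSE))
    }
    nni <- FALSE
    if (config$topology_error_p > 0 && stats::runif(1) < config$topology_error_p &&
        length(tr$tip.label) >= 4) {
      tr <- .random_nni(tr)
      nni <- TRUE
    }
    seed_candidates <- tr$tip.label[leaf_species(tr$tip.label) == seed_sp]
    seed_leaf <- if (length(seed_candidates) == 1) seed_candidates else
      sample(seed_candidates, 1)
    attr(tr, "seed_leaf") <- seed_leaf
    return(list(tree = tr, events = ev, nni_applied = nni, n_resim = try - 1L))
  }
  stop("family simulation failed after ", config$max_retries,
       " retries; lower `loss_rate` or raise `sampling_prob`")
}

#' Simulate a phylome with planted ground truth
#'
#' @param config A [sim_config()].
#' @param species_tree Optional fixed species tree; simulated if `NULL`.
#' @return Object of class `phylome`: list with `species_tree`, `trees`
#'   (named list of gene trees; names are seed sequence ids), `events`
#'   (data frame: family, node, lineage, side1, side2), `lineage_counts`
#'   (planted duplications per species-tree branch, named by the node id the
#'   branch leads to), `nni_flags`, `n_resim`.
#' @export
simulate_phylome <- function(config, species_tree = NULL) {
  set.seed(config$seed)
  if (is.null(species_tree)) {
    species_tree <- simulate_species_tree(config, seed = NULL)
  }
  trees <- list()
  evs <- list()
  nni <- logical(config$n_families)
  n_resim <- 0L
  for (f in seq_len(config$n_families)) {
    fam <- simulate_gene_family(species_tree, config, family_id = f)
    trees[[attr(fam$tree, "seed_leaf")]] <- fam$tree
    if (nrow(fam$events))
      evs[[length(evs) + 1L]] <- cbind(family = f, fam$events)
    nni[f] <- fam$nni_applied
    n_resim <- n_resim + fam$n_resim
  }
  events <- if (length(evs)) do.call(rbind, evs) else
    data.frame(family = integer(0), node = integer(0), lineage = integer(0),
               side1 = character(0), side2 = character(0))
  nbr <- length(species_tree$tip.label) + species_tree$Nnode
  counts <- stats::setNames(integer(nbr), seq_len(nbr))
  if (nrow(events)) {
    tb <- table(events$lineage)
    counts[names(tb)] <- as.integer(tb)
  }
  structure(list(species_tree = species_tree, trees = trees, events = events,
                 lineage_counts = counts, nni_flags = nni, n_resim = n_resim,
                 config = config),
            class = "phylome")
}

#' @export
print.phylome <- function(x, ...) {
  cat(sprintf("phylome: %d gene trees over %d species; %d planted duplications (%d resimulations)\n",
              length(x$trees), length(x$species_tree$tip.label),
              nrow(x$events), x$n_resim))
  invisible(x)
}

#' Simulate a protein alignment on a tree
#'
#' The root sequence is drawn from the model's stationary frequencies and
#' evolved along branches with transition probabilities `exp(Qt)`. Site
#' rates follow the model's discrete gamma (+ invariant) mixture, matching
#' the inference machinery.
#'
#' @param tree `phylo` with branch lengths (expected substitutions/site).
#' @param length Number of columns.
#' @param model A [subst_model()].
#' @param seed Optional seed.
#' @return Character matrix, rows = tips (named).
#' @export
simulate_alignment <- function(tree, length, model, seed = NULL) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!is.null(seed)) set.seed(seed)
  L <- length
  rates <- discrete_gamma_rates(model$alpha, model$k)
  rate_id <- sample.int(model$k, L, replace = TRUE)
  site_rate <- rates[rate_id]
  if (model$p_inv > 0)
    site_rate[stats::runif(L) < model$p_inv] <- 0
  ntip <- base::length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  seqs <- matrix(NA_integer_, nnode, L)
  root <- ntip + 1L
  seqs[root, ] <- sample.int(20, L, replace = TRUE, prob = model$freq)
  for (e in rev(ape::postorder(tree))) {     # root-to-tip order
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    t <- tree$edge.length[e]
    child <- seqs[p, ]
    if (t > 0) {
      for (r in unique(site_rate)) {
        if (r == 0) next
        P <- prob_matrix(model, t * r)
        idx <- which(site_rate == r)
        for (s in 1:20) {
          ii <- idx[seqs[p, idx] == s]
          if (base::length(ii))
            child[ii] <- sample.int(20, base::length(ii), replace = TRUE,
                                    prob = P[s, ])
        }
      }
    }
    seqs[ch, ] <- child
  }
  out <- matrix(AA[seqs[seq_len(ntip), , drop = FALSE]], ntip, L,
                dimnames = list(tree$tip.label, NULL))
  out
}

#' Write an alignment as FASTA
#' @param aln Character matrix, rows = sequences (named).
#' @param path Output file.
#' @export
write_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln)))
    cat(">", rownames(aln)[i], "\n", paste(aln[i, ], collapse = ""), "\n",
        sep = "", file = con)
}

#' Read a FASTA alignment into a character matrix
#' @param path FASTA file.
#' @return Character matrix, rows = sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i)
    paste(lines[(hdr[i] + 1L):ends[i]], collapse = ""), character(1))
  names(seqs) <- sub("^>\\s*", "", lines[hdr])
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1]]))
}

#' Write phylome files to a directory
#'
#' Species tree and gene trees as Newick, planted-event truth as TSV.
#'
#' @param phylome A `phylome` from [simulate_phylome()].
#' @param dir Output directory (created if needed).
#' @export
write_phylome <- function(phylome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(phylome$species_tree, file.path(dir, "species_tree.nwk"))
  con <- file(file.path(dir, "gene_trees.nwk"), "w")
  for (nm in names(phylome$trees))
    cat(ape::write.tree(phylome$trees[[nm]]), "\n", sep = "", file = con)
  close(con)
  utils::write.table(phylome$events, file.path(dir, "planted_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
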