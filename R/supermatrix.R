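#' Select strict one-to-one orthologous families
#'
#' A family qualifies iff its tree contains exactly one sequence from every
#' required species and every cross-species pair in it is a one-to-one
#' ortholog. Such families are the raw material for supermatrix
#' concatenation.
#'
#' @param labeled_trees Named list of `labeled_gene_tree` (one per family).
#' @param required_species Character vector of species codes.
#' @return Character vector of qualifying tree ids (selection is a set:
#'   input order does not matter).
#' @export
select_one_to_one_families <- function(labeled_trees, required_species) {
  if (!length(required_species)) stop("`required_species` is empty")
  ok <- vapply(names(labeled_trees), function(nm) {
    lt <- labeled_trees[[nm]]
    cnt <- table(lt$species)
    if (!all(required_species %in% names(cnt))) return(FALSE)
    if (!all(cnt[required_species] == 1)) return(FALSE)
    if (length(lt$species) != length(required_species)) return(FALSE)
    cat_ <- infer_orthologs(lt)
    cross <- cat_[lt$species[cat_$id_a] != lt$species[cat_$id_b], , drop = FALSE]
    all(cross$orthology == "ortholog" & cross$relation == "one-to-one")
  }, logical(1))
  names(labeled_trees)[ok]
}

#' Trim alignment columns by gap score and entropy
#'
#' A column is kept iff its fraction of non-gap residues is at least
#' `gap_score_cutoff` and (when `entropy_cutoff` is set) its Shannon entropy
#' over non-gap residues, in bits, is at most `entropy_cutoff`. The second
#' filter removes the most compositionally heterogeneous columns.
#'
#' @param aln Character matrix over the 20 amino acids plus gap characters.
#' @param gap_score_cutoff Minimum non-gap fraction (default 0.1).
#' @param entropy_cutoff Maximum column entropy in bits, or `NULL` to skip.
#' @return List: `alignment` (trimmed), `kept` (original 1-based column
#'   indices). Trimming is idempotent at fixed cutoffs.
#' @export
trim_alignment <- function(aln, gap_score_cutoff = 0.1, entropy_cutoff = NULL) {
  if (!is.matrix(aln)) stop("alignment must be a character matrix")
  gap <- matrix(toupper(aln) %in% .AMBIG, nrow(aln), ncol(aln))
  nongap_frac <- 1 - colMeans(gap)
  keep <- nongap_frac >= gap_score_cutoff
  if (!is.null(entropy_cutoff)) {
    ent <- vapply(seq_len(ncol(aln)), function(j) {
      r <- toupper(aln[!gap[, j], j])
      if (!length(r)) return(0)
      p <- table(r) / length(r)
      -sum(p * log2(p))
    }, numeric(1))
    keep <- keep & ent <= entropy_cutoff
  }
  if (!any(keep))
    stop("all columns removed; relax gap_score_cutoff/entropy_cutoff")
  list(alignment = aln[, keep, drop = FALSE], kept = which(keep))
}

#' Concatenate family alignments into a partitioned supermatrix
#'
#' Families are grouped into blocks by their assigned model (blocks ordered
#' by model name, families in stable input order within a block) and
#' concatenated; each species contributes exactly one row.
#'
#' @param alignments Named list of character matrices, one per family, each
#'   with exactly one row per species (rownames are species codes).
#' @param models Character vector (same length/order) of model names.
#' @param species_order Row order of the supermatrix.
#' @return List: `matrix` (supermatrix), `partitions` (data frame: name,
#'   model, start, end, families; 1-based inclusive intervals tiling the
#'   matrix).
#' @export
concatenate_supermatrix <- function(alignments, models, species_order) {
  stopifnot(length(alignments) == length(models))
  if (is.null(names(alignments)))
    names(alignments) <- paste0("fam", seq_along(alignments))
  for (nm in names(alignments)) {
    missing <- setdiff(species_order, rownames(alignments[[nm]]))
    if (length(missing))
      stop("family ", nm, " is missing species: ",
           paste(missing, collapse = ", "))
  }
  ord <- order(factor(models, levels = sort(unique(models))))
  blocks <- split(seq_along(alignments)[ord], models[ord])
  blocks <- blocks[sort(names(blocks))]
  pieces <- list()
  parts <- list()
  pos <- 0L
  for (mdl in names(blocks)) {
    ix <- blocks[[mdl]]
    ix <- ix[order(match(ix, seq_along(alignments)))]  # stable input order
    blk <- do.call(cbind, lapply(alignments[ix], function(a)
      a[species_order, , drop = FALSE]))
    pieces[[mdl]] <- blk
    parts[[mdl]] <- data.frame(name = mdl, model = mdl,
                               start = pos + 1L, end = pos + ncol(blk),
                               families = paste(names(alignments)[ix],
                                                collapse = ";"),
                               stringsAsFactors = FALSE)
    pos <- pos + ncol(blk)
  }
  mat <- do.call(cbind, pieces)
  rownames(mat) <- species_order
  partitions <- do.call(rbind, parts)
  rownames(partitions) <- NULL
  list(matrix = mat, partitions = partitions)
}

#' Write a partition file
#'
#' One line per block, `MODEL, name = start-end` with 1-based inclusive
#' intervals — the common partition-file convention of ML tools.
#'
#' @param partitions Partition data frame from [concatenate_supermatrix()].
#' @param path Output file.
#' @export
write_partitions <- function(partitions, path) {
  writeLines(sprintf("%s, %s = %d-%d", partitions$model, partitions$name,
                     partitions$start, partitions$end), path)
}

#' Write a relaxed PHYLIP alignment
#'
#' @param aln Character matrix, rows = taxa.
#' @param path Output file.
#' @export
write_phylip <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(nrow(aln), ncol(aln), "\n", file = con)
  for (i in seq_len(nrow(aln)))
    cat(rownames(aln)[i], "  ", paste(aln[i, ], collapse = ""), "\n",
        sep = "", file = con)
}

#' Amino-acid composition PCA across species
#'
#' Computes per-species amino-acid frequency vectors over non-gap sites,
#' centers them, and eigendecomposes their covariance; departures from
#' compositional homogeneity (a known source of phylogenetic artifacts)
#' show up as spread along the leading components. A per-species chi-square
#' statistic against the pooled composition is also reported.
#'
#' @param matrix Character supermatrix, rows = species.
#' @return Object of class `composition_pca`: list with `frequencies`
#'   (species x 20), `coordinates` (species x components), `explained`
#'   (eigenvalues; sums to the total variance of the centered vectors),
#'   `chisq` (data frame: species, statistic, df, p).
#' @export
composition_pca <- function(matrix) {
  if (nrow(matrix) < 3) stop("need at least 3 species")
  st <- .aln_states(matrix)
  counts <- t(apply(st, 1, function(s) tabulate(s[!is.na(s)], nbins = 20)))
  if (any(rowSums(counts) == 0))
    stop("species with all-gap rows: ",
         paste(rownames(matrix)[rowSums(counts) == 0], collapse = ", "))
  freq <- counts / rowSums(counts)
  colnames(freq) <- AA
  pc <- stats::prcomp(freq, center = TRUE, scale. = FALSE)
  pooled <- colSums(counts) / sum(counts)
  chi <- t(vapply(seq_len(nrow(counts)), function(i) {
    exp_ <- sum(counts[i, ]) * pooled
    ok <- exp_ > 0
    stat <- sum((counts[i, ok] - exp_[ok])^2 / exp_[ok])
    c(stat, sum(ok) - 1)
  }, numeric(2)))
  chisq <- data.frame(species = rownames(matrix), statistic = chi[, 1],
                      df = chi[, 2],
                      p = stats::pchisq(chi[, 1], chi[, 2], lower.tail = FALSE),
                      stringsAsFactors = FALSE)
  structure(list(frequencies = freq, coordinates = pc$x,
                 explained = pc$sdev^2, chisq = chisq),
            class = "composition_pca")
}

#' @export
print.composition_pca <- function(x, ...) {
  ev <- x$explained / sum(x$explained)
  cat(sprintf("composition PCA over %d species; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$frequencies), 100 * ev[1], 100 * ev[2]))
  invisible(x)
}
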