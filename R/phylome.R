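#' Filter homology-search hits
#'
#' Keeps hits with e-value at most `evalue_max` whose single continuous
#' aligned region covers more than `min_query_coverage` of the query, then
#' retains per query the `max_hits` best hits by ascending e-value (ties by
#' subject id). The defaults are the thresholds used for transcriptome
#' phylomes (1e-5, 30%, 200); a laxer 15% coverage preset is common for a
#' well-annotated reference proteome.
#'
#' @param hits Data frame with columns query, subject, evalue, qstart,
#'   qend, qlen (1-based inclusive interval).
#' @param evalue_max Maximum e-value.
#' @param min_query_coverage Minimum aligned fraction of the query
#'   (exclusive bound: the region must be longer than this fraction).
#' @param max_hits Hits retained per query.
#' @return Filtered data frame (original row order within each query's
#'   retained set follows ascending e-value).
#' @export
filter_homolog_hits <- function(hits, evalue_max = 1e-5,
                                min_query_coverage = 0.30, max_hits = 200L) {
  need <- c("query", "subject", "evalue", "qstart", "qend", "qlen")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("hit table lacks columns: ", paste(miss, collapse = ", "))
  bad <- hits$qstart < 1 | hits$qend > hits$qlen | hits$qstart > hits$qend
  if (any(bad))
    stop("malformed aligned intervals in rows: ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  cov <- (hits$qend - hits$qstart + 1) / hits$qlen
  keep <- hits$evalue <= evalue_max & cov > min_query_coverage
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$query, out$evalue, out$subject), , drop = FALSE]
  sel <- unlist(lapply(split(seq_len(nrow(out)), out$query), function(ix)
    ix[seq_len(min(length(ix), max_hits))]), use.names = FALSE)
  out <- out[sort(sel), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a 6-column tabular hit file
#'
#' The common projection of tabular homology-search output: query, subject,
#' e-value, query start, query end, query length.
#'
#' @param path TSV file without header.
#' @return Data frame with the six named columns.
#' @export
read_hit_table <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("query", "subject", "evalue",
                                  "qstart", "qend", "qlen"),
                    stringsAsFactors = FALSE)
}

# Leaf universe of a phylome: every sequence id appearing in any tree.
.phylome_leaves <- function(trees) {
  unique(unlist(lapply(trees, `[[`, "tip.label"), use.names = FALSE))
}

#' Combine a primary phylome with fallback phylomes
#'
#' The primary phylome is the main source of trees; a fallback contributes
#' its seed tree only for target transcripts not represented (as any leaf)
#' in the primary. Fallbacks are consulted in order.
#'
#' @param primary Named list of gene trees (names = seed ids), or a
#'   `phylome`.
#' @param fallbacks List of phylomes (each a named list of trees), in
#'   priority order; names of this list label the provenance.
#' @param targets Character vector of target transcript ids (or a list of
#'   such vectors, one per species, which is flattened).
#' @param represented `"leaf"` (default: a transcript is represented if it
#'   appears as any leaf of any primary tree) or `"seed"` (only as a seed).
#' @return Object of class `combined_phylome`: list with `assignment`
#'   (data frame: target, provenance, tree), `trees` (named list: the
#'   combined tree set), `uncovered` (targets in no phylome), `coverage`
#'   (fraction of targets covered).
#' @export
combine_phylomes <- function(primary, fallbacks = list(), targets,
                             represented = c("leaf", "seed")) {
  represented <- match.arg(represented)
  if (inherits(primary, "phylome")) primary <- primary$trees
  fallbacks <- lapply(fallbacks, function(f)
    if (inherits(f, "phylome")) f$trees else f)
  if (is.null(names(fallbacks)) && length(fallbacks))
    names(fallbacks) <- paste0("fallback", seq_along(fallbacks))
  targets <- unique(unlist(targets, use.names = FALSE))
  prim_universe <- if (represented == "leaf") .phylome_leaves(primary)
                   else names(primary)
  rows <- list()
  trees <- list()
  uncovered <- character(0)
  for (tg in targets) {
    if (tg %in% prim_universe) {
      tree_id <- if (tg %in% names(primary)) tg else {
        hit <- which(vapply(primary, function(t) tg %in% t$tip.label,
                            logical(1)))[1]
        names(primary)[hit]
      }
      rows[[length(rows) + 1L]] <- data.frame(target = tg,
                                              provenance = "primary",
                                              tree = tree_id,
                                              stringsAsFactors = FALSE)
      trees[[tree_id]] <- primary[[tree_id]]
      next
    }
    placed <- FALSE
    for (fb in names(fallbacks)) {
      if (tg %in% names(fallbacks[[fb]])) {
        rows[[length(rows) + 1L]] <- data.frame(target = tg,
                                                provenance = paste0("fallback:", fb),
                                                tree = tg,
                                                stringsAsFactors = FALSE)
        if (is.null(trees[[tg]])) trees[[tg]] <- fallbacks[[fb]][[tg]]
        placed <- TRUE
        break
      }
    }
    if (!placed) uncovered <- c(uncovered, tg)
  }
  assignment <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target = character(0), provenance = character(0),
               tree = character(0))
  structure(list(assignment = assignment, trees = trees,
                 uncovered = uncovered,
                 coverage = if (length(targets))
                   1 - length(uncovered) / length(targets) else NA_real_),
            class = "combined_phylome")
}

#' @export
print.combined_phylome <- function(x, ...) {
  cat(sprintf("combined phylome: %d trees; coverage %.1f%% (%d uncovered)\n",
              length(x$trees), 100 * x$coverage, length(x$uncovered)))
  invisible(x)
}

#' Phylome coverage report
#'
#' Per-species coverage of target transcripts, mean homologs per tree, and
#' (when relative ortholog lengths are supplied) the Pearson correlation of
#' homolog count per tree against transcript length relative to its
#' reference ortholog — truncated transcripts retrieve fewer homologs, so a
#' positive correlation diagnoses assembly incompleteness.
#'
#' @param phylome Named list of gene trees, `phylome`, or
#'   `combined_phylome`.
#' @param targets Named list: species code -> character vector of target
#'   transcript ids.
#' @param ortholog_lengths Optional data frame with columns transcript,
#'   length, ortholog_length; rows are matched to covered targets.
#' @param rule Leaf-naming rule.
#' @return Object of class `coverage_report`: list with `per_species`
#'   (data frame: species, targets, covered, coverage_pct),
#'   `mean_homologs_per_tree`, and optionally `correlation` (list: r, p, n;
#'   `NULL` with fewer than 3 points).
#' @export
coverage_report <- function(phylome, targets, ortholog_lengths = NULL,
                            rule = "suffix") {
  trees <- if (inherits(phylome, "phylome")) phylome$trees
           else if (inherits(phylome, "combined_phylome")) phylome$trees
           else phylome
  if (!length(targets)) stop("`targets` is empty")
  leaves <- .phylome_leaves(trees)
  per <- do.call(rbind, lapply(names(targets), function(sp) {
    tg <- targets[[sp]]
    cov <- sum(tg %in% leaves)
    data.frame(species = sp, targets = length(tg), covered = cov,
               coverage_pct = 100 * cov / length(tg),
               stringsAsFactors = FALSE)
  }))
  mean_hom <- mean(vapply(trees, function(t) length(t$tip.label) - 1L,
                          integer(1)))
  correlation <- NULL
  if (!is.null(ortholog_lengths)) {
    seed_of <- names(trees)
    n_hom <- vapply(trees, function(t) length(t$tip.label) - 1L, integer(1))
    m <- match(seed_of, ortholog_lengths$transcript)
    ok <- !is.na(m)
    if (sum(ok) >= 3) {
      rel <- ortholog_lengths$length[m[ok]] /
        ortholog_lengths$ortholog_length[m[ok]]
      ct <- stats::cor.test(n_hom[ok], rel, method = "pearson")
      correlation <- list(r = unname(ct$estimate), p = ct$p.value,
                          n = sum(ok))
    }
  }
  structure(list(per_species = per, mean_homologs_per_tree = mean_hom,
                 correlation = correlation),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  print(x$per_species, row.names = FALSE)
  cat(sprintf("mean homologs per tree: %.1f\n", x$mean_homologs_per_tree))
  if (!is.null(x$correlation))
    cat(sprintf("homolog count vs relative length: r = %.3f, p = %.3g (n = %d)\n",
                x$correlation$r, x$correlation$p, x$correlation$n))
  invisible(x)
}
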