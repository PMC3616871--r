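#' Constrained topologies resolving a single focal placement
#'
#' Builds multifurcating constraint trees in which every node is unresolved
#' except the one placing a focal taxon as sister to a named group — the
#' standard construction for likelihood-based tests of one contested
#' placement.
#'
#' @param species Character vector of all taxa.
#' @param assignments List of lists, each with elements `focal` (one taxon)
#'   and `sister` (character vector): the focal taxon is attached as sister
#'   to the (unresolved) sister group; all remaining taxa form a root
#'   polytomy.
#' @return List of multifurcating `phylo` constraint trees.
#' @export
build_constrained_topologies <- function(species, assignments) {
  lapply(assignments, function(a) {
    if (!a$focal %in% species) stop("focal taxon absent: ", a$focal)
    miss <- setdiff(a$sister, species)
    if (length(miss)) stop("sister-group taxa absent: ",
                           paste(miss, collapse = ", "))
    if (a$focal %in% a$sister) stop("focal taxon cannot sit in its sister group")
    rest <- setdiff(species, c(a$focal, a$sister))
    if (!length(rest))
      stop("assignment places ", a$focal,
           " with all remaining taxa: the constraint is an uninformative star")
    sister <- if (length(a$sister) > 1)
      sprintf("(%s)", paste(a$sister, collapse = ",")) else a$sister
    txt <- sprintf("(%s,(%s,%s));", paste(rest, collapse = ","),
                   a$focal, sister)
    ape::read.tree(text = txt)
  })
}

#' RELL bootstrap of per-site log-likelihoods
#'
#' Resampling estimated log-likelihoods: each replicate draws `size` site
#' indices with replacement and sums the selected per-site values per
#' topology — no re-optimization.
#'
#' @param sitelnl Numeric matrix, rows = topologies, columns = sites.
#' @param n_rep Number of replicates.
#' @param seed Integer seed (ignored when `indices` is supplied).
#' @param size Sites per replicate (default: the site count).
#' @param indices Optional integer matrix (`size` x `n_rep`) of site
#'   indices, as a deterministic test hook.
#' @return Matrix `n_rep` x `ntopologies` of replicate total lnL.
#' @export
rell_bootstrap <- function(sitelnl, n_rep, seed = 1L, size = ncol(sitelnl),
                           indices = NULL) {
  if (!is.matrix(sitelnl) || !ncol(sitelnl)) stop("empty site-lnL matrix")
  if (n_rep < 1) stop("n_rep must be >= 1")
  S <- ncol(sitelnl)
  ntop <- nrow(sitelnl)
  if (is.null(indices)) {
    set.seed(seed)
  } else {
    stopifnot(nrow(indices) == size, ncol(indices) == n_rep)
  }
  out <- matrix(0, n_rep, ntop)
  chunk <- max(1L, floor(2e6 / size))
  done <- 0L
  while (done < n_rep) {
    b <- min(chunk, n_rep - done)
    idx <- if (is.null(indices))
      matrix(sample.int(S, size * b, replace = TRUE), size, b)
    else indices[, (done + 1L):(done + b), drop = FALSE]
    for (t in seq_len(ntop))
      out[(done + 1L):(done + b), t] <- colSums(matrix(sitelnl[t, idx],
                                                       size, b))
    done <- done + b
  }
  colnames(out) <- rownames(sitelnl)
  out
}

# Weighted least-squares fit of BP(r) = 1 - pnorm(d*sqrt(r) + c/sqrt(r)).
# Returns c(d, c) or NULL when fewer than 2 scales are usable.
.au_fit <- function(bp, scales, n_rep, iterations = 3) {
  usable <- bp > 0 & bp < 1
  if (sum(usable) < 2) return(NULL)
  r <- scales[usable]
  z <- stats::qnorm(1 - bp[usable])
  X <- cbind(sqrt(r), 1 / sqrt(r))
  beta <- stats::coef(stats::lm.fit(X, z))
  for (it in seq_len(iterations)) {
    zf <- X %*% beta
    bpf <- 1 - stats::pnorm(zf)
    w <- n_rep * stats::dnorm(zf)^2 / pmax(bpf * (1 - bpf), 1e-10)
    beta <- stats::coef(stats::lm.wfit(X, z, as.numeric(w)))
  }
  as.numeric(beta)
}

#' KH, SH and AU topology tests from per-site log-likelihoods
#'
#' All three tests resample the per-site log-likelihood matrix (RELL).
#' KH compares each topology with the maximum-likelihood one using
#' centered bootstrap replicates of the lnL difference: the p-value is the
#' proportion of replicates whose centered difference is at least the
#' observed one (so an exact tie gives p = 1). SH centers each topology's
#' replicates at its own mean and compares the observed difference against
#' the replicate-wise maximum over topologies, which makes it conservative
#' (SH >= KH). The AU test resamples at multiple scales `r`, records the
#' bootstrap proportion BP(r) of replicates in which each topology is best,
#' fits `1 - BP(r) = pnorm(d*sqrt(r) + c/sqrt(r))` by iterated weighted
#' least squares (binomial variance weights), and reports
#' `p_AU = 1 - pnorm(d - c)`; degenerate BP (all 0 or all 1) yields p = 0
#' or 1 with a flag.
#'
#' @param sitelnl Numeric matrix, rows = topologies (>= 2), cols = sites.
#' @param n_rep Replicates per scale (default 10000).
#' @param au_scales Resampling scale factors (default ten scales
#'   0.5..1.4). Each scale uses its own seed stream derived from `seed`, so
#'   adding scales does not perturb the others.
#' @param seed Integer seed.
#' @return Object of class `topo_test`: data frame with topology, lnL,
#'   dlnL, KH, SH, AU, au_flag (`"ok"`, `"degenerate0"`, `"degenerate1"`,
#'   `"unavailable"`), d, c; attribute `"bp"` holds the BP(r) matrix.
#' @export
topology_tests <- function(sitelnl, n_rep = 10000L,
                           au_scales = seq(0.5, 1.4, by = 0.1), seed = 1L) {
  if (!is.matrix(sitelnl) || nrow(sitelnl) < 2)
    stop("need a site-lnL matrix with >= 2 topologies")
  ntop <- nrow(sitelnl)
  S <- ncol(sitelnl)
  if (is.null(rownames(sitelnl)))
    rownames(sitelnl) <- paste0("topology", seq_len(ntop))
  lnl <- rowSums(sitelnl)
  best <- which.max(lnl)
  dlnl <- max(lnl) - lnl
  # unit-scale replicates for KH and SH
  rep1 <- rell_bootstrap(sitelnl, n_rep, seed = seed + 7777L)
  centered <- sweep(rep1, 2, colMeans(rep1))
  kh <- sh <- numeric(ntop)
  for (t in seq_len(ntop)) {
    kh[t] <- mean(centered[, best] - centered[, t] >= dlnl[t])
    sh[t] <- mean(apply(centered, 1, max) - centered[, t] >= dlnl[t])
  }
  # multiscale BP for AU
  bp <- matrix(NA_real_, ntop, length(au_scales))
  dimnames(bp) <- list(rownames(sitelnl),
                       if (length(au_scales)) paste0("r", au_scales))
  for (i in seq_along(au_scales)) {
    sz <- max(2L, round(au_scales[i] * S))
    ri <- rell_bootstrap(sitelnl, n_rep, seed = seed + round(1000 * au_scales[i]),
                         size = sz)
    win <- max.col(ri, ties.method = "first")
    bp[, i] <- tabulate(win, nbins = ntop) / n_rep
  }
  au <- d <- cc <- rep(NA_real_, ntop)
  flag <- character(ntop)
  for (t in seq_len(ntop)) {
    if (!length(au_scales)) { flag[t] <- "unavailable"; next }
    if (all(bp[t, ] == 0)) { au[t] <- 0; flag[t] <- "degenerate0"; next }
    if (all(bp[t, ] == 1)) { au[t] <- 1; flag[t] <- "degenerate1"; next }
    beta <- .au_fit(bp[t, ], au_scales, n_rep)
    if (is.null(beta)) { flag[t] <- "unavailable"; next }
    d[t] <- beta[1]; cc[t] <- beta[2]
    au[t] <- 1 - stats::pnorm(beta[1] - beta[2])
    flag[t] <- "ok"
  }
  out <- data.frame(topology = rownames(sitelnl), lnL = lnl, dlnL = dlnl,
                    KH = kh, SH = sh, AU = au, au_flag = flag,
                    d = d, c = cc, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "bp") <- bp
  class(out) <- c("topo_test", class(out))
  out
}
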