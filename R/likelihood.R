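#' @useDynLib phylomer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

AA <- c("A","R","N","D","C","Q","E","G","H","I",
        "L","K","M","F","P","S","T","W","Y","V")

.MODEL_ALIASES <- c(JTT = "JTT", WAG = "WAG", MtREV = "mtREV24", LG = "LG",
                    Blosum62 = "Blosum62", DCMut = "Dayhoff_DCMut")

#' Amino-acid substitution model
#'
#' Builds a reversible 20-state rate matrix from empirical exchangeabilities
#' and stationary frequencies, normalized to one expected substitution per
#' site at stationarity, together with discrete-gamma + invariant-sites rate
#' heterogeneity. Empirical matrices (JTT, WAG, MtREV, LG, Blosum62, DCMut)
#' are taken from phangorn's model data; `Poisson` has uniform
#' exchangeabilities and frequencies and admits closed-form checks.
#'
#' @param name One of `"JTT"`, `"WAG"`, `"MtREV"`, `"LG"`, `"Blosum62"`,
#'   `"DCMut"`, `"Poisson"`.
#' @param alpha Gamma shape (> 0); `Inf` means uniform rates across sites.
#' @param k Number of discrete gamma categories (default 4).
#' @param p_inv Fraction of invariant sites, in `[0, 1)`.
#' @param frequencies Optional length-20 stationary frequency override
#'   (summing to 1), e.g. for compositional simulations.
#' @return An object of class `subst_model`.
#' @export
subst_model <- function(name, alpha = Inf, k = 4L, p_inv = 0,
                        frequencies = NULL) {
  stopifnot(alpha > 0, k >= 1, p_inv >= 0, p_inv < 1)
  name <- match.arg(name, c(names(.MODEL_ALIASES), "Poisson"))
  if (name == "Poisson") {
    ex <- matrix(1, 20, 20); diag(ex) <- 0
    bf <- rep(1 / 20, 20)
  } else {
    Q <- NULL; bf <- NULL
    phangorn:::getModelAA(.MODEL_ALIASES[[name]], bf = TRUE, Q = TRUE)
    ex <- matrix(0, 20, 20)
    ex[lower.tri(ex)] <- Q
    ex <- ex + t(ex)
  }
  if (!is.null(frequencies)) {
    stopifnot(length(frequencies) == 20, all(frequencies > 0))
    bf <- frequencies / sum(frequencies)
  }
  Qm <- ex * rep(bf, each = 20)       # Q_ij = s_ij * pi_j
  diag(Qm) <- 0
  diag(Qm) <- -rowSums(Qm)
  mu <- -sum(bf * diag(Qm))           # expected rate at stationarity
  Qm <- Qm / mu
  # symmetrized eigendecomposition: B = D^1/2 Q D^-1/2
  s <- sqrt(bf)
  B <- Qm * (s %o% (1 / s))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  structure(list(name = name, exchangeabilities = ex, freq = bf, Q = Qm,
                 eigvec = eig$vectors, eigval = eig$values,
                 left = t(eig$vectors) * rep(s, each = 20),      # U' D^1/2
                 right = (1 / s) * eig$vectors,                  # D^-1/2 U
                 alpha = alpha, k = as.integer(k), p_inv = p_inv),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("subst_model %s: alpha=%s, k=%d, p_inv=%.3f\n",
              x$name, format(x$alpha), x$k, x$p_inv))
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model A [subst_model()].
#' @param t Branch length (expected substitutions per site) times rate.
#' @return 20 x 20 row-stochastic matrix, rows = source state.
#' @export
prob_matrix <- function(model, t) {
  stopifnot(t >= 0)
  P <- model$right %*% (exp(model$eigval * t) * model$left)
  P[P < 0] <- 0
  P
}

#' Discrete gamma category rates (mean-of-bin scheme)
#'
#' Splits the mean-1 gamma into `k` equal-probability bins and uses each
#' bin's conditional mean as its category rate; rates average exactly 1.
#'
#' @param alpha Gamma shape; `Inf` returns `k` unit rates.
#' @param k Number of categories.
#' @return Numeric vector of length `k`.
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  if (!is.finite(alpha)) return(rep(1, k))
  stopifnot(alpha > 0, k >= 1)
  if (k == 1) return(1)
  qb <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  # E[X | bin] * k using the Gamma(alpha+1, alpha) incomplete-moment identity
  p <- stats::pgamma(qb, shape = alpha + 1, rate = alpha)
  k * diff(p)
}

.AMBIG <- c("-", "?", "X", "B", "Z", "*", ".")

# Internal: alignment (character matrix, rows = taxa) -> integer state matrix,
# NA for gap/ambiguity.
.aln_states <- function(aln) {
  if (is.null(rownames(aln))) stop("alignment rows must be named by taxon")
  st <- match(toupper(aln), AA)    # gaps/ambiguity codes fall through to NA
  matrix(st, nrow(aln), ncol(aln), dimnames = dimnames(aln))
}

# Internal: per-site per-category log-likelihoods via the compiled pruning
# kernel. Returns an S x k matrix.
.prune_percat <- function(tree, states, model) {
  states[is.na(states)] <- 0L
  storage.mode(states) <- "integer"
  po <- ape::postorder(tree)
  cpp_prune_loglik(tree$edge[po, , drop = FALSE], tree$edge.length[po],
                   states, model$right, model$left, model$eigval, model$freq,
                   discrete_gamma_rates(model$alpha, model$k), tree$Nnode)
}

#' Per-site log-likelihoods under a model (gamma + invariant sites)
#'
#' Felsenstein pruning per column. The per-column likelihood is
#' `p_inv * I(column constant) * pi[residue] + (1 - p_inv) * mean over k
#' gamma categories` of the pruned likelihood with branch lengths scaled by
#' the category rate. Gaps and ambiguity codes are treated as missing.
#'
#' @param aln Character matrix (rows = taxa, named) of amino acids.
#' @param tree Rooted or unrooted `phylo` with branch lengths, leaves
#'   matching `rownames(aln)`.
#' @param model A [subst_model()].
#' @return Numeric vector of natural-log per-site likelihoods
#'   (class `site_lnl`); `sum()` is the total log-likelihood.
#' @export
site_log_likelihoods <- function(aln, tree, model) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  d <- setdiff(tree$tip.label, rownames(aln))
  if (length(d)) stop("alignment rows missing for leaves: ", paste(d, collapse = ", "))
  aln <- aln[tree$tip.label, , drop = FALSE]
  states <- .aln_states(aln)
  percat <- .prune_percat(tree, states, model)
  mx <- apply(percat, 1, max)
  lik_var <- rowMeans(exp(percat - mx))           # mean over categories
  ll <- mx + log(lik_var)
  if (model$p_inv > 0) {
    # invariant component: all non-missing residues identical
    const_state <- apply(states, 2, function(s) {
      u <- unique(s[!is.na(s)])
      if (length(u) == 1) u else if (length(u) == 0) 0L else NA_integer_
    })
    inv_lik <- ifelse(is.na(const_state), 0,
                      ifelse(const_state == 0L, 1, model$freq[pmax(const_state, 1)]))
    ll <- log(model$p_inv * inv_lik + (1 - model$p_inv) * exp(ll))
  }
  structure(as.numeric(ll), class = "site_lnl")
}

#' Total log-likelihood of an alignment on a tree
#' @inheritParams site_log_likelihoods
#' @return Scalar log-likelihood.
#' @export
tree_log_likelihood <- function(aln, tree, model) {
  sum(site_log_likelihoods(aln, tree, model))
}

#' Optimize branch lengths by cyclic univariate search
#'
#' Cycles over branches, optimizing each with Brent's method while holding
#' the others fixed, until the total log-likelihood improves by less than
#' `tol`. The log-likelihood is non-decreasing across cycles.
#'
#' @param tree `phylo` with starting branch lengths.
#' @param aln Character alignment matrix (rows = taxa).
#' @param model A [subst_model()].
#' @param tol Convergence tolerance on the total log-likelihood.
#' @param max_cycles Cycle cap; non-convergence raises a warning, not an
#'   error.
#' @param upper Upper bound per branch (expected substitutions/site).
#' @param brent_tol Absolute branch-length tolerance of the inner
#'   univariate search.
#' @return The tree with optimized `edge.length` and attribute `"lnl"`.
#' @export
optimize_branch_lengths <- function(tree, aln, model, tol = 1e-6,
                                    max_cycles = 100L, upper = 10,
                                    brent_tol = tol / 10) {
  states_ok <- intersect(tree$tip.label, rownames(aln))
  if (length(states_ok) != length(tree$tip.label))
    stop("alignment rows missing for some leaves")
  cur <- sum(site_log_likelihoods(aln, tree, model))
  for (cycle in seq_len(max_cycles)) {
    prev <- cur
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(x) {
        tree$edge.length[e] <- x
        sum(site_log_likelihoods(aln, tree, model))
      }
      op <- stats::optimize(f, c(0, upper), maximum = TRUE, tol = brent_tol)
      if (op$objective > cur) {
        tree$edge.length[e] <- op$maximum
        cur <- op$objective
      }
    }
    if (cur - prev < tol) {
      attr(tree, "lnl") <- cur
      return(tree)
    }
  }
  warning("branch-length optimization did not converge within ", max_cycles,
          " cycles (last improvement ", format(cur - prev), ")")
  attr(tree, "lnl") <- cur
  tree
}

#' Pairwise protein distances
#'
#' Observed proportion distance or its Poisson-model correction
#' `d = -(19/20) log(1 - (20/19) p)`; pairs are compared over their shared
#' non-missing sites.
#'
#' @param aln Character alignment matrix (rows = taxa).
#' @param correction `"observed"` or `"poisson"`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
protein_distance <- function(aln, correction = c("poisson", "observed")) {
  correction <- match.arg(correction)
  st <- .aln_states(aln)
  n <- nrow(st)
  D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(st[i, ]) & !is.na(st[j, ])
    if (!any(ok)) stop("no shared sites between ", rownames(aln)[i], " and ",
                       rownames(aln)[j])
    p <- mean(st[i, ok] != st[j, ok])
    d <- if (correction == "observed") p else {
      pm <- min(p, 0.94)  # clamp below the Poisson saturation point 19/20
      -(19 / 20) * log(1 - (20 / 19) * pm)
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration via [ape::nj()]; negative branch lengths are
#' clamped to zero and the total clamped amount is recorded in the
#' `"clamped"` attribute.
#'
#' @param distances Symmetric matrix, zero diagonal, >= 3 taxa.
#' @return Unrooted `phylo`.
#' @export
nj_tree <- function(distances) {
  distances <- as.matrix(distances)
  if (nrow(distances) < 3) stop("need at least 3 taxa")
  if (max(abs(distances - t(distances))) > 1e-9)
    stop("distance matrix is not symmetric")
  tr <- ape::nj(as.dist(distances))
  clamped <- 0
  if (any(tr$edge.length < 0)) {
    clamped <- -sum(tr$edge.length[tr$edge.length < 0])
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  attr(tr, "clamped") <- clamped
  tr
}

#' Model selection by AIC on a fixed topology
#'
#' For each candidate model, branch lengths, the gamma shape and the
#' invariant fraction are optimized by alternating univariate searches
#' (shape in log-space on `[0.02, 100]`, invariant fraction on `[0, 0.99]`),
#' then `AIC = 2 * params - 2 * lnL` with `params = branch count + 2`.
#' Ties are broken by candidate order.
#'
#' @param aln Character alignment matrix.
#' @param topology `phylo` with starting branch lengths (e.g. from
#'   [nj_tree()] on [protein_distance()]).
#' @param models Character vector of candidate model names.
#' @param k Gamma categories.
#' @param rounds Alternation rounds of (branch lengths, alpha, p_inv).
#' @param bl_cycles Branch-length optimization cycles per round; model
#'   ranking is driven by large lnL differences, so a couple of coarse
#'   cycles suffice.
#' @param tol Branch-length optimization tolerance.
#' @return List with `best` (name), `model` (fitted [subst_model()]),
#'   `tree` (branch lengths under the best model) and `table`
#'   (data frame: model, lnL, alpha, p_inv, params, AIC, dAIC).
#' @export
select_model_aic <- function(aln, topology,
                             models = c("JTT", "WAG", "MtREV", "LG",
                                        "Blosum62", "DCMut"),
                             k = 4L, rounds = 2L, bl_cycles = 2L, tol = 1e-3) {
  if (!length(models)) stop("empty candidate model list")
  if (is.null(topology$edge.length))
    topology$edge.length <- rep(0.1, nrow(topology$edge))
  fit_one <- function(name) {
    alpha <- 1; p_inv <- 0.05
    tr <- topology
    lnl <- -Inf
    for (r in seq_len(rounds)) {
      m <- subst_model(name, alpha = alpha, k = k, p_inv = p_inv)
      up <- min(10, max(1, 4 * max(tr$edge.length)))
      tr <- suppressWarnings(
        optimize_branch_lengths(tr, aln, m, tol = tol,
                                max_cycles = if (r == 1) bl_cycles else 1L,
                                upper = up, brent_tol = 0.01))
      oa <- stats::optimize(function(la) {
        sum(site_log_likelihoods(aln, tr, subst_model(name, alpha = exp(la),
                                                      k = k, p_inv = p_inv)))
      }, log(c(0.02, 100)), maximum = TRUE, tol = 0.01)
      alpha <- exp(oa$maximum)
      oi <- stats::optimize(function(pi_) {
        sum(site_log_likelihoods(aln, tr, subst_model(name, alpha = alpha,
                                                      k = k, p_inv = pi_)))
      }, c(0, 0.99), maximum = TRUE, tol = 0.005)
      p_inv <- oi$maximum
      lnl <- oi$objective
    }
    list(lnl = lnl, alpha = alpha, p_inv = p_inv, tree = tr)
  }
  fits <- lapply(models, fit_one)
  params <- nrow(topology$edge) + 2
  tab <- data.frame(model = models,
                    lnL = vapply(fits, `[[`, numeric(1), "lnl"),
                    alpha = vapply(fits, `[[`, numeric(1), "alpha"),
                    p_inv = vapply(fits, `[[`, numeric(1), "p_inv"),
                    params = params)
  tab$AIC <- 2 * tab$params - 2 * tab$lnL
  tab$dAIC <- tab$AIC - min(tab$AIC)
  best <- which.min(tab$AIC)           # first minimum = candidate-order ties
  bestfit <- fits[[best]]
  list(best = models[best],
       model = subst_model(models[best], alpha = bestfit$alpha, k = k,
                           p_inv = bestfit$p_inv),
       tree = bestfit$tree, table = tab)
}

#' Write a per-site log-likelihood matrix
#'
#' Plain whitespace-delimited format: header line `ntopologies nsites`,
#' then one row of per-site values per topology.
#'
#' @param mat Numeric matrix, rows = topologies.
#' @param path Output file.
#' @export
write_sitelnl <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(nrow(mat), ncol(mat), "\n", file = con)
  utils::write.table(format(mat, digits = 17), con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a per-site log-likelihood matrix
#'
#' Accepts the plain matrix format of [write_sitelnl()] and the RAxML
#' per-site output dialect (`-f g`): a header `ntrees nsites` followed by
#' rows optionally prefixed by `tr<k>` labels.
#'
#' @param path Input file.
#' @return Numeric matrix, rows = topologies.
#' @export
read_sitelnl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- scan(text = lines[1], what = numeric(), quiet = TRUE)
  if (length(hdr) != 2) stop("bad header: expected 'ntopologies nsites'")
  body <- lines[-1]
  rows <- lapply(body, function(l) {
    toks <- strsplit(trimws(l), "[ \t]+")[[1]]
    suppressWarnings(v <- as.numeric(toks))
    v[!is.na(v)]                      # drops RAxML 'tr1'-style row labels
  })
  rows <- rows[lengths(rows) > 0]
  # rows may be wrapped; concatenate then reshape
  all <- unlist(rows)
  if (length(all) != hdr[1] * hdr[2])
    stop(sprintf("expected %d x %d = %d values, found %d",
                 hdr[1], hdr[2], hdr[1] * hdr[2], length(all)))
  matrix(all, nrow = hdr[1], byrow = TRUE)
}
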