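test_that("rate matrices are valid generators and P(t) is stochastic", {
  for (name in c("JTT", "WAG", "MtREV", "LG", "Blosum62", "DCMut")) {
    m <- subst_model(name)
    expect_lt(max(abs(rowSums(m$Q))), 1e-12)
    expect_equal(-sum(m$freq * diag(m$Q)), 1, tolerance = 1e-12)
    set.seed(1)
    for (t in stats::runif(3, 0, 5)) {
      P <- prob_matrix(m, t)
      expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
      expect_true(all(P >= 0))
    }
  }
})

test_that("discrete gamma categories average to one", {
  for (a in c(0.2, 0.7, 1, 3, 50)) {
    r <- discrete_gamma_rates(a, 4)
    expect_equal(mean(r), 1, tolerance = 1e-10)
    expect_true(all(diff(r) > 0))
  }
  expect_equal(discrete_gamma_rates(Inf, 4), rep(1, 4))
})

test_that("two-sequence Poisson likelihood matches the closed form", {
  m <- subst_model("Poisson")
  tr <- parse_newick("(A:0.6,B:0.4);")
  pii <- 1 / 20 + (19 / 20) * exp(-(20 / 19) * 1.0)
  pij <- (1 - pii) / 19
  same <- matrix(c("A", "A"), 2, 1, dimnames = list(c("A", "B"), NULL))
  diff_ <- matrix(c("A", "R"), 2, 1, dimnames = list(c("A", "B"), NULL))
  expect_equal(sum(site_log_likelihoods(same, tr, m)), log(pii / 20),
               tolerance = 1e-10)
  expect_equal(sum(site_log_likelihoods(diff_, tr, m)), log(pij / 20),
               tolerance = 1e-10)
})

test_that("alpha = Inf equals the single-category computation", {
  set.seed(5)
  tr <- ape::rtree(5)
  a <- simulate_alignment(tr, 60, subst_model("JTT"), seed = 2)
  m4 <- subst_model("JTT", alpha = Inf, k = 4)
  m1 <- subst_model("JTT", alpha = Inf, k = 1)
  expect_equal(as.numeric(site_log_likelihoods(a, tr, m4)),
               as.numeric(site_log_likelihoods(a, tr, m1)), tolerance = 1e-12)
})

test_that("summed log-likelihood is invariant to column permutation", {
  set.seed(6)
  tr <- ape::rtree(4)
  a <- simulate_alignment(tr, 50, subst_model("WAG", alpha = 0.8), seed = 3)
  m <- subst_model("WAG", alpha = 0.8, p_inv = 0.2)
  perm <- sample(ncol(a))
  expect_equal(sum(site_log_likelihoods(a, tr, m)),
               sum(site_log_likelihoods(a[, perm], tr, m)),
               tolerance = 1e-10)
})

test_that("pruning equals brute-force state summation on small trees", {
  set.seed(8)
  for (i in 1:6) {
    n <- sample(4:5, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.8)
    model <- subst_model(sample(c("Poisson", "JTT"), 1))
    a <- simulate_alignment(tr, 6, model, seed = i)
    if (i == 1) a[2, 3] <- "-"   # missing data handled as sum-to-one
    mine <- site_log_likelihoods(a, tr, model)
    brute <- log(brute_site_lik(a, tr, model))
    expect_equal(as.numeric(mine), as.numeric(brute), tolerance = 1e-8)
  }
})

test_that("likelihood is invariant under re-rooting (pulley principle)", {
  set.seed(9)
  tr <- ape::rtree(6)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.5)
  m <- subst_model("WAG", alpha = 1.2, p_inv = 0.1)
  a <- simulate_alignment(tr, 40, m, seed = 4)
  l0 <- sum(site_log_likelihoods(a, tr, m))
  for (og in tr$tip.label[1:3]) {
    rerooted <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE)
    expect_equal(sum(site_log_likelihoods(a, rerooted, m)), l0,
                 tolerance = 1e-8)
  }
})

test_that("NJ recovers additive topologies and validates input", {
  set.seed(10)
  tr <- ape::rtree(5)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  D <- ape::cophenetic.phylo(tr)
  nj <- nj_tree(D)
  expect_equal(rf_distance(nj, tr), 0)
  expect_lt(attr(nj, "clamped"), 1e-12)

  # three taxa: closed three-point formulas
  D3 <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(D3)
  len <- stats::setNames(t3$edge.length[match(1:3, t3$edge[, 2])],
                         t3$tip.label)
  expect_equal(unname(len["a"]), (0.3 + 0.5 - 0.6) / 2, tolerance = 1e-9)
  expect_equal(unname(len["b"]), (0.3 + 0.6 - 0.5) / 2, tolerance = 1e-9)
  expect_equal(unname(len["c"]), (0.5 + 0.6 - 0.3) / 2, tolerance = 1e-9)

  bad <- D3; bad[1, 2] <- 0.9
  expect_error(nj_tree(bad), "symmetric")
})

test_that("branch-length optimization attains the analytic pairwise MLE", {
  m <- subst_model("Poisson")
  tr <- parse_newick("(A:0.3,B:0.3);")
  a <- simulate_alignment(parse_newick("(A:0.5,B:0.5);"), 4000, m, seed = 12)
  p <- mean(a[1, ] != a[2, ])
  analytic <- -(19 / 20) * log(1 - (20 / 19) * p)
  opt <- optimize_branch_lengths(tr, a, m, tol = 1e-9)
  expect_equal(sum(opt$edge.length), analytic, tolerance = 1e-6)
  # fixed point: restarting at the optimum does not decrease the lnL
  again <- optimize_branch_lengths(opt, a, m, tol = 1e-9)
  expect_gte(attr(again, "lnl"), attr(opt, "lnl") - 1e-9)
})

test_that("AIC selection handles degenerate input and respects the lnL bound", {
  set.seed(13)
  tr <- ape::rtree(4)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 0.4)
  a <- simulate_alignment(tr, 150, subst_model("JTT", alpha = 1), seed = 5)
  res <- select_model_aic(a, tr, models = "JTT", rounds = 1)
  expect_equal(res$best, "JTT")
  expect_equal(nrow(res$table), 1L)
  # saturated bound: sum over columns of log(max residue frequency)
  bound <- sum(apply(a, 2, function(col) {
    tb <- table(col) / length(col)
    log(max(tb))
  }))
  expect_lte(res$table$lnL, bound)
  expect_error(select_model_aic(a, tr, models = character(0)), "empty")
})

test_that("site-lnL matrices round-trip in both dialects", {
  set.seed(14)
  mat <- matrix(rnorm(10, -8), 2, 5)
  d <- withr::local_tempdir()
  f <- file.path(d, "sitelnl.txt")
  write_sitelnl(mat, f)
  back <- read_sitelnl(f)
  expect_equal(back, mat, tolerance = 1e-12)

  raxml <- file.path(d, "raxml.txt")
  writeLines(c("2 3", "tr1\t-1.5 -2.5 -3.5", "tr2\t-1 -2 -3"), raxml)
  rx <- read_sitelnl(raxml)
  expect_equal(rx, rbind(c(-1.5, -2.5, -3.5), c(-1, -2, -3)))
  bad <- file.path(d, "bad.txt")
  writeLines(c("2 3", "-1 -2"), bad)
  expect_error(read_sitelnl(bad), "expected")
})
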