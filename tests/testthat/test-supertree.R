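test_that("SFIT scoring matches its definition", {
  cand <- parse_newick("((A,B),(C,D));")
  expect_equal(as.numeric(sfit_score(cand, list(cand, cand))), 1)
  expect_equal(as.numeric(sfit_score(cand,
                                     list(parse_newick("((A,C),(B,D));")))), 0)
  # appending a perfectly congruent source never lowers the mean fit
  srcs <- list(parse_newick("((A,C),(B,D));"),
               parse_newick("((A,B),(C,D));"))
  s1 <- as.numeric(sfit_score(cand, srcs[1]))
  s2 <- as.numeric(sfit_score(cand, srcs))
  expect_gte(s2, s1)
  # sources sharing < 4 species are skipped and counted
  sk <- sfit_score(cand, list(cand, parse_newick("((A,B),C);")))
  expect_equal(attr(sk, "skipped"), 1)
  expect_error(sfit_score(cand, list(parse_newick("((A,B),C);"))), "eligible")
})

test_that("duplication-parsimony cost is additive and zero on congruence", {
  cand <- parse_newick("((s1,s2),(s3,s4));")
  cong <- list(parse_newick("((A_s1,B_s2),(C_s3,D_s4));"),
               parse_newick("((A_s1,B_s2),C_s3);"))
  expect_equal(gtp_duplication_cost(cand, cong), 0L)
  dup1 <- list(parse_newick("((X_s1,Y_s1),B_s2);"))
  expect_equal(gtp_duplication_cost(cand, dup1), 1L)
  expect_equal(gtp_duplication_cost(cand, c(cong, dup1)),
               gtp_duplication_cost(cand, cong) +
                 gtp_duplication_cost(cand, dup1))
})

test_that("search returns the input topology for a single clean gene tree", {
  g <- parse_newick("((A_s1,B_s2),(C_s3,D_s4));")
  res <- search_supertree(list(g), "duplication_parsimony", n_starts = 1,
                          seed = 2)
  expect_equal(res$score, 0)
  sp <- g; sp$tip.label <- unname(leaf_species(sp$tip.label))
  expect_equal(rf_distance(res$tree, sp), 0)

  top <- parse_newick("((s1,s2),(s3,s4));")
  resf <- search_supertree(list(top, top), "sfit", n_starts = 1, seed = 2)
  expect_equal(resf$score, 1)
  expect_equal(rf_distance(resf$tree, top), 0)
})

test_that("search is deterministic under a seed and traces monotonically", {
  cfg <- sim_config(n_species = 7, dup_rate = 0.3, loss_rate = 0.1,
                    sampling_prob = 0.9, n_families = 30, seed = 6)
  ph <- simulate_phylome(cfg)
  a <- search_supertree(unname(ph$trees), "duplication_parsimony",
                        n_starts = 2, seed = 4)
  b <- search_supertree(unname(ph$trees), "duplication_parsimony",
                        n_starts = 2, seed = 4)
  expect_identical(write_newick(a$tree), write_newick(b$tree))
  expect_identical(a$trace, b$trace)
  # within each start, parsimony trace is non-increasing
  runs <- split(a$trace, cumsum(a$trace$move == "start"))
  for (r in runs) expect_true(all(diff(r$score) <= 0))

  lts <- label_phylome(ph)
  tops <- unlist(lapply(lts, decompose_speciation_subtrees),
                 recursive = FALSE)
  f <- search_supertree(unname(tops), "sfit", n_starts = 2, seed = 4)
  runsf <- split(f$trace, cumsum(f$trace$move == "start"))
  for (r in runsf) expect_true(all(diff(r$score) >= 0))
  expect_gte(f$score, 0); expect_lte(f$score, 1)
  expect_equal(f$score, round(f$score, 10))  # numeric sanity
})

test_that("bipartition support saturates on identical topologies and applies eligibility", {
  set.seed(12)
  st <- rand_species_tree(6)
  ident <- replicate(10, st, simplify = FALSE)
  bs <- bipartition_support(st, ident)
  expect_true(all(bs$support_pct == 100))
  expect_true(all(bs$supporting == bs$eligible))

  # a tree missing one full side of a split is not eligible for it
  st2 <- parse_newick("((s1,s2),(s3,s4));")
  partial <- parse_newick("((s1,s2),s3);")
  bs2 <- bipartition_support(st2, list(partial))
  expect_equal(bs2$eligible, 0L)
  expect_true(is.na(bs2$support_pct))

  # 3 eligible, 2 supporting -> 66.7
  st3 <- parse_newick("(((s1,s2),s3),(s4,s5));")
  yes <- parse_newick("(((s1,s2),s3),(s4,s5));")
  no <- parse_newick("(((s1,s4),s3),(s2,s5));")
  bs3 <- bipartition_support(st3, list(yes, yes, no))
  row <- bs3[bs3$split == "s1,s2|s3,s4,s5", ]
  expect_equal(row$eligible, 3L)
  expect_equal(row$supporting, 2L)
  expect_equal(round(row$support_pct, 1), 66.7)

  # strict eligibility requires every species
  bs4 <- bipartition_support(st2, list(partial), eligibility = "strict")
  expect_true(all(bs4$eligible == 0L))
})

test_that("hill climbing matches exhaustive enumeration at 6 species", {
  cfg <- sim_config(n_species = 6, dup_rate = 0.3, loss_rate = 0.1,
                    sampling_prob = 0.9, n_families = 25, seed = 44)
  ph <- simulate_phylome(cfg)
  e <- enumerate_supertree(unname(ph$trees), "duplication_parsimony")
  s <- search_supertree(unname(ph$trees), "duplication_parsimony",
                        n_starts = 2, seed = 9)
  expect_equal(s$score, e$score)

  lts <- label_phylome(ph)
  tops <- unlist(lapply(lts, decompose_speciation_subtrees),
                 recursive = FALSE)
  ef <- enumerate_supertree(unname(tops), "sfit")
  sf <- search_supertree(unname(tops), "sfit", n_starts = 2, seed = 9)
  expect_equal(sf$score, ef$score, tolerance = 1e-12)
})
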