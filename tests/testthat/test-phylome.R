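make_hits <- function(...) {
  df <- data.frame(...)
  df$subject <- as.character(df$subject)
  df$query <- as.character(df$query)
  df
}

test_that("hit filtering enforces e-value, coverage and per-query caps", {
  hits <- make_hits(
    query = "q1", subject = c("h1", "h2", "h3", "h4"),
    evalue = c(1e-4, 1e-10, 1e-10, 1e-5),
    qstart = c(1, 1, 1, 1), qend = c(80, 31, 29, 30), qlen = 100)
  out <- filter_homolog_hits(hits)
  # 1e-4 fails e-value; 31% passes, 29% fails; 30% is not > 30% -> fails
  expect_equal(out$subject, "h2")

  # boundary: e-value exactly at the threshold is kept
  b <- make_hits(query = "q", subject = "s", evalue = 1e-5,
                 qstart = 1, qend = 50, qlen = 100)
  expect_equal(nrow(filter_homolog_hits(b)), 1L)

  # 250 passing hits -> the 200 smallest e-values survive
  many <- make_hits(query = "q", subject = sprintf("s%03d", 1:250),
                    evalue = (1:250) * 1e-9, qstart = 1, qend = 90,
                    qlen = 100)
  kept <- filter_homolog_hits(many)
  expect_equal(nrow(kept), 200L)
  expect_setequal(kept$subject, sprintf("s%03d", 1:200))

  # idempotent and order-independent within queries
  again <- filter_homolog_hits(kept)
  expect_equal(again, kept)
  shuffled <- many[sample(nrow(many)), ]
  expect_setequal(filter_homolog_hits(shuffled)$subject, kept$subject)

  bad <- make_hits(query = "q", subject = "s", evalue = 1e-9,
                   qstart = 5, qend = 3, qlen = 10)
  expect_error(filter_homolog_hits(bad), "malformed")
})

test_that("hit tables read from the 6-column TSV projection", {
  d <- withr::local_tempdir()
  f <- file.path(d, "hits.tsv")
  writeLines(c("q1\th1\t1e-06\t1\t50\t100", "q1\th2\t0.01\t1\t90\t100"), f)
  h <- read_hit_table(f)
  expect_equal(nrow(h), 2L)
  expect_equal(filter_homolog_hits(h)$subject, "h1")
})

test_that("phylome combination prefers the primary and reports coverage", {
  t1 <- parse_newick("((t1_s1,x1_s2),x2_s3);")
  t2 <- parse_newick("((t2_s1,y1_s2),y2_s3);")
  f3 <- parse_newick("((t3_s1,z1_s2),z2_s3);")
  primary <- list(t1_s1 = t1, t2_s1 = t2)
  fallback <- list(t2_s1 = t2, t3_s1 = f3)
  cp <- combine_phylomes(primary, list(fb = fallback),
                         targets = c("t1_s1", "t2_s1", "t3_s1"))
  expect_equal(cp$coverage, 1)
  expect_equal(sort(unique(cp$assignment$provenance)),
               c("fallback:fb", "primary"))
  expect_equal(cp$assignment$provenance[cp$assignment$target == "t2_s1"],
               "primary")
  # leaf-level representation: a non-seed leaf counts as covered
  cp2 <- combine_phylomes(primary, list(), targets = c("x1_s2", "nope"))
  expect_equal(cp2$uncovered, "nope")
  expect_equal(cp2$coverage, 0.5)
  # seed-level flag is stricter
  cp3 <- combine_phylomes(primary, list(), targets = c("x1_s2"),
                          represented = "seed")
  expect_equal(cp3$coverage, 0)
})

test_that("combined coverage is never below primary coverage", {
  set.seed(31)
  for (i in 1:10) {
    cfgA <- sim_config(n_species = 5, n_families = 10, dup_rate = 0.2,
                       sampling_prob = 0.8, seed = 100 + i)
    cfgB <- sim_config(n_species = 5, n_families = 10, dup_rate = 0.2,
                       sampling_prob = 0.8, seed = 200 + i)
    phA <- simulate_phylome(cfgA)
    phB <- simulate_phylome(cfgB)
    targets <- unique(c(sample(unlist(lapply(phA$trees, `[[`, "tip.label")), 8),
                        sample(unlist(lapply(phB$trees, `[[`, "tip.label")), 8),
                        paste0("ghost", 1:3)))
    alone <- combine_phylomes(phA$trees, list(), targets)
    both <- combine_phylomes(phA$trees, list(fb = phB$trees), targets)
    expect_gte(both$coverage, alone$coverage)
  }
})

test_that("coverage report computes fractions and the length correlation", {
  trees <- list(a_s1 = parse_newick("((a_s1,b_s2),c_s3);"),
                d_s1 = parse_newick("((d_s1,e_s2),(f_s3,g_s4));"))
  rep1 <- coverage_report(trees, targets = list(
    s1 = c("a_s1", "d_s1", "q1", "q2", "q3", "q4", "q5", "q6", "q7", "q8")))
  expect_equal(rep1$per_species$coverage_pct, 20)
  expect_equal(rep1$mean_homologs_per_tree, mean(c(2, 3)))

  # homolog counts exactly proportional to relative length -> r = 1
  tr <- lapply(1:6, function(i) {
    labs <- c(paste0("seed", i, "_s1"),
              paste0("h", seq_len(i + 1), "_", "s", 2))
    ape::rtree(length(labs), tip.label = labs)
  })
  names(tr) <- paste0("seed", 1:6, "_s1")
  ol <- data.frame(transcript = names(tr),
                   length = (2:7) * 100, ortholog_length = 100)
  rep2 <- coverage_report(tr, targets = list(s1 = names(tr)),
                          ortholog_lengths = ol)
  expect_equal(rep2$correlation$r, 1, tolerance = 1e-12)
  expect_lt(rep2$correlation$p, 0.01)

  # fewer than 3 matched points: correlation omitted
  rep3 <- coverage_report(tr, targets = list(s1 = names(tr)),
                          ortholog_lengths = ol[1:2, ])
  expect_null(rep3$correlation)
  expect_error(coverage_report(tr, targets = list()), "empty")
})

test_that("truncation-driven dropout yields a positive length correlation", {
  # families whose seed transcript is shorter retain fewer homolog leaves:
  # emulate by pruning leaves with probability tied to a planted length
  set.seed(41)
  cfg <- sim_config(n_species = 8, dup_rate = 0.3, loss_rate = 0,
                    sampling_prob = 1, n_families = 200, seed = 51)
  ph <- simulate_phylome(cfg)
  rel_len <- stats::runif(length(ph$trees), 0.3, 1)
  trees <- ph$trees
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    seed_leaf <- attr(tr, "seed_leaf")
    others <- setdiff(tr$tip.label, seed_leaf)
    keep <- others[stats::runif(length(others)) < rel_len[i]]
    if (length(keep) < 2) keep <- others[1:2]
    trees[[i]] <- prune_to_taxa(tr, c(seed_leaf, keep))
    attr(trees[[i]], "seed_leaf") <- seed_leaf
  }
  ol <- data.frame(transcript = names(trees), length = rel_len * 1000,
                   ortholog_length = 1000)
  rep <- coverage_report(trees, targets = list(s1 = names(trees)),
                         ortholog_lengths = ol)
  expect_gt(rep$correlation$r, 0)
  expect_lt(rep$correlation$p, 0.05)
})
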