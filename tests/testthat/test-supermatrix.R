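test_that("one-to-one family selection matches the planted single-copy set", {
  cfg <- sim_config(n_species = 6, dup_rate = 0.4, loss_rate = 0,
                    sampling_prob = 1, n_families = 60, seed = 23)
  ph <- simulate_phylome(cfg)
  lts <- label_phylome(ph)
  sel <- select_one_to_one_families(lts, ph$species_tree$tip.label)
  truth <- names(ph$trees)[!(seq_along(ph$trees) %in% ph$events$family)]
  expect_setequal(sel, truth)
  # order independence
  sel2 <- select_one_to_one_families(lts[rev(names(lts))],
                                     ph$species_tree$tip.label)
  expect_setequal(sel2, sel)
  expect_error(select_one_to_one_families(lts, character(0)), "empty")
  # a family missing one species is rejected
  miss <- lts[[sel[1]]]
  keep <- miss$tree$tip.label[-1]
  sub <- label_events(prune_to_taxa(miss$tree, keep))
  expect_length(select_one_to_one_families(list(f = sub),
                                           ph$species_tree$tip.label), 0L)
})

test_that("gap-score and entropy trimming follow the stated rule", {
  aln <- rbind(a = c("A", "-", "A", "W"),
               b = c("A", "-", "C", "R"),
               c = c("A", "-", "C", "N"),
               d = c("A", "A", "C", "D"))
  # column 2: 1/4 non-gap = 0.25 >= 0.1 -> kept; at 0.3 -> removed
  t1 <- trim_alignment(aln, gap_score_cutoff = 0.1)
  expect_equal(t1$kept, 1:4)
  t2 <- trim_alignment(aln, gap_score_cutoff = 0.3)
  expect_equal(t2$kept, c(1L, 3L, 4L))
  # 19/20 gapped at cutoff 0.1 -> removed
  big <- matrix("-", 20, 1, dimnames = list(paste0("t", 1:20), NULL))
  big[1, 1] <- "A"
  big2 <- cbind(big, matrix("A", 20, 1))
  t3 <- trim_alignment(big2, gap_score_cutoff = 0.1)
  expect_equal(t3$kept, 2L)
  # conserved gap-free column survives any entropy cutoff >= 0
  t4 <- trim_alignment(aln[, c(1, 4), drop = FALSE], entropy_cutoff = 0)
  expect_equal(t4$kept, 1L)
  # no gaps + filter off -> identity; idempotence
  clean <- aln[, c(1, 3, 4), drop = FALSE]
  t5 <- trim_alignment(clean, gap_score_cutoff = 0.1)
  expect_identical(t5$alignment, clean)
  tt <- trim_alignment(t1$alignment, gap_score_cutoff = 0.1)
  expect_identical(tt$alignment, t1$alignment)
  expect_error(trim_alignment(big, gap_score_cutoff = 0.5), "relax")
})

test_that("concatenation partitions tile the matrix by model blocks", {
  sp <- c("s1", "s2", "s3")
  mk <- function(L) matrix(sample(phylomer:::AA, 3 * L, replace = TRUE), 3,
                           dimnames = list(sp, NULL))
  set.seed(2)
  alns <- list(f1 = mk(100), f2 = mk(150), f3 = mk(50))
  cc <- concatenate_supermatrix(alns, c("JTT", "JTT", "WAG"), sp)
  expect_equal(cc$partitions$start, c(1L, 251L))
  expect_equal(cc$partitions$end, c(250L, 300L))
  expect_equal(cc$partitions$model, c("JTT", "WAG"))
  expect_equal(ncol(cc$matrix), 300L)
  expect_true(all(rownames(cc$matrix) == sp))

  one <- concatenate_supermatrix(alns[1], "LG", sp)
  expect_equal(one$partitions$start, 1L)
  expect_equal(one$partitions$end, 100L)

  # random family sets: intervals always tile [1, total]
  for (i in 1:10) {
    n <- sample(2:6, 1)
    a <- lapply(seq_len(n), function(j) mk(sample(10:80, 1)))
    names(a) <- paste0("g", seq_len(n))
    mods <- sample(c("JTT", "WAG", "LG", "DCMut"), n, replace = TRUE)
    p <- concatenate_supermatrix(a, mods, sp)$partitions
    expect_equal(p$start[1], 1L)
    if (nrow(p) > 1) expect_equal(p$start[-1], utils::head(p$end, -1) + 1L)
    expect_equal(p$end[nrow(p)], sum(vapply(a, ncol, integer(1))))
  }
  bad <- alns; rownames(bad$f2) <- c("s1", "s2", "s9")
  expect_error(concatenate_supermatrix(bad, c("JTT", "JTT", "WAG"), sp), "f2")
})

test_that("partition and PHYLIP writers emit the expected formats", {
  sp <- c("s1", "s2")
  a <- list(f1 = matrix("A", 2, 10, dimnames = list(sp, NULL)),
            f2 = matrix("C", 2, 5, dimnames = list(sp, NULL)))
  cc <- concatenate_supermatrix(a, c("WAG", "JTT"), sp)
  d <- withr::local_tempdir()
  write_partitions(cc$partitions, file.path(d, "parts.txt"))
  lines <- readLines(file.path(d, "parts.txt"))
  expect_equal(lines[1], "JTT, JTT = 1-5")
  expect_equal(lines[2], "WAG, WAG = 6-15")
  write_phylip(cc$matrix, file.path(d, "supermatrix.phy"))
  phy <- readLines(file.path(d, "supermatrix.phy"))
  expect_match(phy[1], "^2 15")
})

test_that("composition PCA conserves variance and separates planted groups", {
  sp <- paste0("s", 1:4)
  same <- matrix(rep(c("A", "C", "D", "E"), each = 4), 4,
                 dimnames = list(sp, NULL))
  pc0 <- composition_pca(same)
  expect_lt(sum(pc0$explained), 1e-20)
  expect_true(all(abs(pc0$coordinates) < 1e-10))
  expect_equal(rowSums(pc0$frequencies), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)

  # two compositional clusters drawn from different stationary frequencies
  set.seed(33)
  fA <- rep(1 / 20, 20)
  fB <- c(rep(2, 10), rep(0.5, 10)); fB <- fB / sum(fB)
  draw <- function(f) sample(phylomer:::AA, 400, replace = TRUE, prob = f)
  mat <- rbind(g1a = draw(fA), g1b = draw(fA), g2a = draw(fB), g2b = draw(fB))
  pc <- composition_pca(mat)
  tot <- sum(diag(stats::cov(pc$frequencies)))
  expect_equal(sum(pc$explained), tot, tolerance = 1e-12)
  pc1 <- pc$coordinates[, 1]
  expect_true(all(sign(pc1[1:2]) == sign(pc1[1])))
  expect_true(all(sign(pc1[3:4]) == -sign(pc1[1])))
  expect_true(all(pc$chisq$p[3:4] < 0.05) || all(pc$chisq$p[1:2] < 0.05))
  expect_error(composition_pca(same[1:2, ]), "3 species")
})
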