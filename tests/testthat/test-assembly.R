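test_that("Bray-Curtis matches the hand formula", {
  m <- otu(c(1L, 0L), c(0L, 1L))
  expect_equal(unname(bray_curtis(m)[1, 2]), 1)
  m2 <- otu(c(2L, 2L), c(2L, 2L))
  expect_equal(unname(bray_curtis(m2)[1, 2]), 0)
  m3 <- otu(c(6L, 2L), c(2L, 2L))
  expect_equal(unname(bray_curtis(m3)[1, 2]), 4 / 12)
  expect_error(bray_curtis(otu(c(0L, 0L), c(1L, 2L))), "all-zero")
})

test_that("betaMNTD evaluates hand cases", {
  tree <- abc_tree()
  same <- otu(c(2L, 1L, 3L), c(2L, 1L, 3L), taxa = c("A", "B", "C"))
  expect_equal(unname(beta_mntd(same, tree)[1, 2]), 0)

  ab <- otu(c(1L, 0L, 0L), c(0L, 1L, 0L), taxa = c("A", "B", "C"))
  expect_equal(unname(beta_mntd(ab, tree)[1, 2]), 2)

  bad <- otu(c(1L, 1L), c(1L, 1L), taxa = c("A", "Z"))
  expect_error(beta_mntd(bad, tree), "Z")
})

test_that("betaMNTD equals the brute-force double-loop oracle", {
  for (seed in 1:50) {
    inst <- random_instance(seed)
    expect_equal(beta_mntd(inst$table, inst$tree),
                 bmntd_oracle(inst$table, inst$tree), tolerance = 1e-12)
  }
})

test_that("betaMNTD agrees with an independent reference implementation", {
  skip_if_not_installed("picante")
  inst <- random_instance(99)
  ours <- beta_mntd(inst$table, inst$tree)
  ref <- as.matrix(picante::comdistnt(inst$table,
                                      ape::cophenetic.phylo(inst$tree),
                                      abundance.weighted = TRUE))
  expect_equal(ours, ref[rownames(ours), colnames(ours)], tolerance = 1e-10)
})

test_that("betaNTI is deterministic under seed and flags degenerate nulls", {
  inst <- random_instance(7)
  b1 <- suppressWarnings(beta_nti(inst$table, inst$tree, reps = 49, seed = 42))
  b2 <- suppressWarnings(beta_nti(inst$table, inst$tree, reps = 49, seed = 42))
  expect_identical(b1, b2)
  expect_error(beta_nti(inst$table, inst$tree, reps = 1), ">= 2")

  # star tree with equal branch lengths: all distances equal, null sd = 0
  star <- tree_from_text("(A:1,B:1,C:1,D:1);")
  m <- otu(c(3L, 1L, 0L, 2L), c(0L, 2L, 4L, 1L),
           taxa = c("A", "B", "C", "D"))
  expect_warning(b <- beta_nti(m, star, reps = 19, seed = 1), "degenerate")
  expect_true(is.na(b[1, 2]))
  expect_true(attr(b, "degenerate")[1, 2])
})

test_that("Raup-Crick stays in [-1, 1] and detects extremes", {
  inst <- random_instance(15)
  rc <- raup_crick(inst$table, reps = 99, seed = 5)
  expect_true(all(rc >= -1 & rc <= 1))
  expect_equal(rc, t(rc))
  expect_identical(rc, raup_crick(inst$table, reps = 99, seed = 5))

  # identical, abundant, low-richness pair inside a diverse metacommunity:
  # observed dissimilarity 0 sits below essentially every null draw
  meta <- otu(c(50L, 50L, 0L, 0L, 0L, 0L),
              c(50L, 50L, 0L, 0L, 0L, 0L),
              c(5L, 3L, 9L, 8L, 2L, 7L),
              c(1L, 9L, 4L, 2L, 8L, 6L),
              c(3L, 2L, 7L, 9L, 1L, 4L))
  rc2 <- raup_crick(meta, reps = 199, seed = 2)
  expect_lt(rc2[1, 2], -0.95)

  empty <- otu(c(0L, 0L), c(1L, 2L))
  expect_error(raup_crick(empty, reps = 99), "richness")
})

test_that("pair classification follows the two-stage decision rule", {
  mk <- function(b, r) {
    ids <- c("a", "b")
    bm <- matrix(c(0, b, b, 0), 2, 2, dimnames = list(ids, ids))
    rm <- matrix(c(0, r, r, 0), 2, 2, dimnames = list(ids, ids))
    classify_pairs(bm, rm)$process
  }
  expect_equal(mk(2.5, 0), "heterogeneous_selection")
  expect_equal(mk(-2.5, 0), "homogeneous_selection")
  expect_equal(mk(0.5, 0.2), "drift")
  expect_equal(mk(1.0, 0.97), "dispersal_limitation")
  expect_equal(mk(1.0, -0.97), "homogenizing_dispersal")
  # boundary semantics: exactly 2 is not selection, exactly 0.95 is drift
  expect_equal(mk(2, 0), "drift")
  expect_equal(mk(-2, 0), "drift")
  expect_equal(mk(0, 0.95), "drift")
  expect_equal(mk(0, -0.95), "drift")
  # degenerate pairs become 'undefined' with a warning
  bm <- matrix(c(0, NA, NA, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  rm <- matrix(0, 2, 2, dimnames = dimnames(bm))
  expect_warning(lab <- classify_pairs(bm, rm), "undefined")
  expect_equal(lab$process, "undefined")
})

test_that("process summaries count within-group pairs", {
  labels <- data.frame(
    sample_a = c("s1", "s1", "s1", "s2", "s2", "s3"),
    sample_b = c("s2", "s3", "s4", "s3", "s4", "s4"),
    bnti = 0, rc = 0,
    process = c("heterogeneous_selection", "heterogeneous_selection",
                "homogeneous_selection", "drift", "drift", "drift"),
    stringsAsFactors = FALSE)
  g1 <- setNames(rep("g", 4), paste0("s", 1:4))
  s1 <- summarize_processes(labels, g1)
  expect_equal(s1$heterogeneous_selection, 2 / 6)
  expect_equal(s1$n_pairs, 6)
  expect_equal(rowSums(s1[, 2:6]), c(g = 1))

  # 2 het + 1 hom + 1 drift -> 0.50 / 0.25 / 0.25
  sub <- labels[c(1, 2, 3, 4), ]
  sub$process[4] <- "drift"
  s2 <- summarize_processes(sub, g1)
  expect_equal(s2$heterogeneous_selection, 0.5)
  expect_equal(s2$homogeneous_selection, 0.25)
  expect_equal(s2$drift, 0.25)

  # two groups are summarized independently (cross-group pairs dropped)
  g2 <- setNames(c("x", "x", "y", "y"), paste0("s", 1:4))
  s3 <- summarize_processes(labels, g2)
  expect_equal(nrow(s3), 2)
  expect_equal(s3["x", "n_pairs"], 1)
  expect_equal(s3["x", "heterogeneous_selection"], 1)
  expect_equal(s3["y", "drift"], 1)

  expect_error(summarize_processes(labels,
    setNames(c("x", "y", "y", "y"), paste0("s", 1:4))), "fewer than 2")
})
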