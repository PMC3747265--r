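test_that("pairwise distances: p, jc, pairwise deletion, saturation", {
  lib <- seq_library(c(a = "ACGT", b = "ACGT", c = "ACGA", d = "AC-A"))
  d <- pairwise_seq_distance(lib, "p")
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 0.25)
  expect_equal(d["a", "d"], 1 / 3)  # gap column skipped

  dj <- pairwise_seq_distance(lib, "jc")
  expect_equal(dj["a", "c"], -0.75 * log(1 - 4 * 0.25 / 3), tolerance = 1e-12)
  expect_equal(dj["a", "c"], 0.3041, tolerance = 1e-4)

  sat <- seq_library(c(a = "ACGTACGTACGT", b = "CGTACGTACGTA"))
  expect_error(pairwise_seq_distance(sat, "jc"), "saturation")
  expect_silent(pairwise_seq_distance(sat, "jc", on_saturation = "cap"))
})

test_that("neighbor joining: three-point formulas, additive recovery, determinism", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(dm)
  pm <- patristic_matrix(tr)
  expect_equal(pm["A", "B"], 2)
  expect_equal(pm["A", "C"], 4)
  leaf_edges <- tr$edge.length[match(1:3, tr$edge[, 2])]
  expect_equal(sort(leaf_edges), c(1, 1, 3))

  # additive matrices from random trees are recovered exactly
  for (seed in 1:10) {
    true <- random_tree(7, seed)
    dm <- patristic_matrix(true)
    nj <- neighbor_joining(dm)
    expect_identical(rf_distance(nj, true), 0L)
    expect_equal(patristic_matrix(nj)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-9)
  }

  # equal distances: fully tied Q; output deterministic across calls
  n <- 6
  dm <- matrix(1, n, n, dimnames = list(letters[1:n], letters[1:n]))
  diag(dm) <- 0
  expect_identical(ape::write.tree(neighbor_joining(dm)),
                   ape::write.tree(neighbor_joining(dm)))
  # and invariant to row order
  o <- c(4, 2, 6, 1, 3, 5)
  dm2 <- dm[o, o]
  expect_identical(rf_distance(neighbor_joining(dm), neighbor_joining(dm2)), 0L)

  bad <- dm; bad[1, 2] <- 2
  expect_error(neighbor_joining(bad), "asymmetric")
})

test_that("patristic_matrix equals graph-search oracle; diagonal zero", {
  skip_if_not_installed("igraph")
  cherry <- ape::read.tree(text = "(A:1,B:2);")
  expect_equal(patristic_matrix(cherry)["A", "B"], 3)
  for (seed in 1:15) {
    tr <- random_tree(sample(4:20, 1), seed)
    pm <- patristic_matrix(tr)
    expect_true(all(diag(pm) == 0))
    expect_equal(pm, oracle_patristic(tr), tolerance = 1e-9)
  }
})

test_that("bootstrap supports: determinism, clean-signal support, star degeneracy", {
  # strong signal for the AB|CD split: many supporting columns
  seqs <- c(A = strrep("A", 40), B = strrep("A", 40),
            C = strrep("C", 40), D = strrep("C", 40))
  # add a little noise so distances are not ultra-degenerate
  substr(seqs["B"], 1, 2) <- "GG"
  substr(seqs["D"], 1, 2) <- "TT"
  lib <- seq_library(seqs)
  tr <- bootstrap_supports(lib, n_replicates = 200L, seed = 4L, model = "p")
  sp <- tree_splits(tr)
  expect_identical(nrow(sp), 1L)
  expect_gte(sp$support, 0.99)

  tr2 <- bootstrap_supports(lib, n_replicates = 200L, seed = 4L, model = "p")
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))

  same <- seq_library(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"))
  star <- bootstrap_supports(same, n_replicates = 10L, seed = 1L, model = "p")
  expect_identical(star$Nnode, 1L)  # single multifurcation
  expect_error(bootstrap_supports(lib, n_replicates = 0L), "value error")
})

test_that("rf distance matches brute-force enumeration and is a metric", {
  skip_if_not_installed("igraph")
  t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  expect_identical(rf_distance(t1, t1), 0L)
  expect_identical(rf_distance(t1, t2), 2L)

  res10 <- random_tree(10, 1)
  star10 <- star_tree(res10$tip.label)
  expect_identical(rf_distance(res10, star10), 7L)  # n-3 internal edges

  # symmetry + triangle inequality on random triples
  for (seed in 1:25) {
    n <- sample(5:9, 1)
    ta <- random_tree(n, seed); tb <- random_tree(n, seed + 100); tc <- random_tree(n, seed + 200)
    ab <- rf_distance(ta, tb)
    expect_identical(ab, rf_distance(tb, ta))
    expect_identical(ab, oracle_rf(ta, tb))
    expect_lte(ab, rf_distance(ta, tc) + rf_distance(tc, tb))
  }
  expect_error(rf_distance(random_tree(5, 1), random_tree(6, 1)), "leaf sets")
})

test_that("wrf1/wrf2: quoted examples, bounds, reduction to rf", {
  t1 <- ape::read.tree(text = "((A:1,B:1)0.6:1,(C:1,D:1):1);")
  t2 <- ape::read.tree(text = "((A:1,C:1)0.8:1,(B:1,D:1):1);")
  expect_equal(wrf1(t1, t1), 0)
  expect_equal(wrf1(t1, t2), 1.4)          # 0.6 + 0.8, both splits unique

  shared1 <- ape::read.tree(text = "((A:1,B:1)0.9:1,(C:1,D:1):1);")
  shared2 <- ape::read.tree(text = "((A:1,B:1)0.7:1,(C:1,D:1):1);")
  expect_equal(wrf1(shared1, shared2), 0)
  expect_equal(wrf2(shared1, shared2), 0.2)  # |0.9 - 0.7|

  for (seed in 1:40) {
    n <- sample(5:10, 1)
    ta <- random_support_tree(n, seed)
    tb <- random_support_tree(n, seed + 500)
    r <- rf_distance(ta, tb)
    w1 <- wrf1(ta, tb); w2 <- wrf2(ta, tb)
    expect_gte(w1, 0); expect_lte(w1, r + 1e-12)
    expect_gte(w2, w1 - 1e-12)
    # all supports 1 -> wrf1 == rf
    ta1 <- ta; ta1$node.label <- NULL
    tb1 <- tb; tb1$node.label <- NULL
    expect_equal(wrf1(ta1, tb1), r)
  }
})
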