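test_that("normalize_max1 and pair_distances behave", {
  dm <- random_dist(5, 1, scale = 4)
  nd <- normalize_max1(dm)
  expect_equal(max(nd), 1)
  expect_equal(normalize_max1(nd), nd)  # idempotent
  expect_error(normalize_max1(matrix(0, 2, 2,
                                     dimnames = list(c("a", "b"), c("a", "b")))),
               "all-zero")

  pd <- pair_distances(dm, dm)
  expect_identical(nrow(pd), 10L)      # C(5,2)
  expect_equal(pd$x, pd$y)

  dm2 <- random_dist(4, 2)
  rownames(dm2) <- colnames(dm2) <- paste0("z", 1:4)
  expect_error(pair_distances(dm, dm2), "shared ids")
})

test_that("pearson matches two-pass oracle; degenerate cases", {
  pd <- data.frame(x = c(0, 1), y = c(1, 0))
  expect_equal(pearson(pd), -1)
  expect_equal(pearson(data.frame(x = 1:5, y = 1:5)), 1)
  set.seed(42)
  x <- runif(1000); y <- x + rnorm(1000, 0, 0.2)
  expect_equal(pearson(data.frame(x = x, y = y)), oracle_pearson(x, y),
               tolerance = 1e-12)
  expect_true(is.na(suppressMessages(pearson(data.frame(x = c(1, 1), y = c(1, 2))))))

  # r is invariant under separate rescaling (so max-1 normalization never
  # changes it)
  expect_equal(pearson(data.frame(x = 3 * x, y = 0.2 * y)),
               pearson(data.frame(x = x, y = y)), tolerance = 1e-12)
})

test_that("slope through origin", {
  expect_equal(slope_through_origin(data.frame(x = c(1, 2, 3), y = c(2, 4, 6))), 2)
  expect_equal(slope_through_origin(data.frame(x = c(1, 2), y = c(1, 1))), 0.6)
  pd <- data.frame(x = runif(50), y = runif(50))
  expect_equal(slope_through_origin(data.frame(x = pd$x, y = pd$x)), 1)
  expect_error(slope_through_origin(data.frame(x = c(0, 0), y = c(1, 2))), "all x are zero")
})

test_that("binned_profile: bin stats, conservation, flags", {
  pd <- data.frame(x = c(0.005, 0.007), y = c(0.1, 0.3))
  bp <- binned_profile(pd)
  expect_identical(nrow(bp), 1L)
  expect_equal(bp$mean, 0.2)
  expect_equal(bp$sd, sd(c(0.1, 0.3)))
  expect_equal(bp$sd, 0.1414, tolerance = 1e-3)

  set.seed(8)
  pd <- data.frame(x = runif(500), y = runif(500))
  bp <- binned_profile(pd, width = 0.01)
  expect_equal(sum(bp$mean * bp$count) / sum(bp$count), mean(pd$y), tolerance = 1e-9)
  expect_true(all(bp$flagged == (bp$bin_start >= 0.8)))

  ident <- binned_profile(data.frame(x = pd$x, y = pd$x))
  expect_true(all(is.na(ident$sd) | ident$sd < 0.01 / sqrt(2) + 1e-12))

  expect_error(binned_profile(pd, width = 0), "width")
})

test_that("mds_embed reproduces Euclidean-realizable distances and is deterministic", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("p", "q", "r"), c("p", "q", "r")))
  X <- mds_embed(d, dims = 2)
  expect_equal(as.matrix(dist(X)), unname(d), ignore_attr = TRUE, tolerance = 1e-9)

  two <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  X1 <- mds_embed(two, dims = 1)
  expect_equal(sort(as.vector(X1)), c(-0.5, 0.5), tolerance = 1e-12)

  dm <- random_dist(8, 3)
  expect_identical(mds_embed(dm, 3), mds_embed(dm, 3))
  expect_error(mds_embed(dm, 8), "dims")

  # agrees with stats::cmdscale up to per-axis sign
  X <- mds_embed(dm, 3)
  Y <- stats::cmdscale(dm, k = 3)
  for (k in 1:3) {
    expect_equal(abs(X[, k]), abs(Y[, k]), ignore_attr = TRUE, tolerance = 1e-9)
  }
})

test_that("wrmsd superposition: invariances and hand example", {
  X <- cbind(c(0, 1, 0, -1), c(1, 0, -1, 0))
  rownames(X) <- letters[1:4]
  expect_equal(wrmsd_superimpose(X, X), 0)
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(wrmsd_superimpose(X, X %*% R + 5), 0, tolerance = 1e-12)
  # reflection is allowed
  expect_equal(wrmsd_superimpose(X, X %*% diag(c(-1, 1))), 0, tolerance = 1e-12)

  A <- matrix(c(0, 1), ncol = 1); B <- matrix(c(0, 2), ncol = 1)
  expect_equal(wrmsd_superimpose(A, B), 0.5)

  set.seed(9)
  P <- matrix(rnorm(20), 10, 2); Q <- matrix(rnorm(20), 10, 2)
  expect_equal(wrmsd_superimpose(P, Q), wrmsd_superimpose(Q, P), tolerance = 1e-9)
  expect_error(wrmsd_superimpose(P, Q[1:5, ]), "mismatched")
  expect_error(wrmsd_superimpose(P, Q, weights = rep(0, 10)), "weights")
})

test_that("wrmsd agrees with vegan procrustes on uniform weights", {
  skip_if_not_installed("vegan")
  set.seed(10)
  for (rep in 1:5) {
    P <- matrix(rnorm(30), 10, 3); Q <- matrix(rnorm(30), 10, 3)
    pr <- vegan::procrustes(P, Q, scale = FALSE, symmetric = FALSE)
    expect_equal(wrmsd_superimpose(P, Q),
                 sqrt(sum(stats::residuals(pr)^2) / 10),
                 tolerance = 1e-8)
  }
})

test_that("compare_trees: self-comparison fixed point and composition", {
  for (seed in 1:5) {
    tr <- random_tree(10, seed)
    cmp <- compare_trees(tr, tr)
    expect_equal(cmp$pearson_r, 1, tolerance = 1e-12)
    expect_equal(cmp$slope, 1, tolerance = 1e-12)
    expect_lte(cmp$wrmsd, 1e-8)
    expect_identical(cmp$rf, 0L)
    expect_equal(cmp$wrf1 + cmp$wrf2, 0)
  }
  t1 <- random_tree(12, 31); t2 <- random_tree(12, 32)
  cmp <- compare_trees(t1, t2)
  pd <- pair_distances(normalize_max1(patristic_matrix(t1)),
                       normalize_max1(patristic_matrix(t2)))
  expect_equal(cmp$pearson_r, pearson(pd), tolerance = 1e-12)
  # rf parity: symmetric difference between binary trees is even
  expect_identical(cmp$rf %% 2L, 0L)
})

test_that("sliding window placement: additive fixed point and displacement", {
  set.seed(21)
  base <- ape::rtree(8, rooted = FALSE)
  base$edge.length <- sample(1:4, nrow(base$edge), replace = TRUE)
  add <- make_additive_library(base, cols_per_unit = 12L)
  tr <- neighbor_joining(pairwise_seq_distance(add$library, "p"))
  swp <- sliding_window_placement(add$library, tr,
                                  window = alignment_length(add$library))
  expect_identical(ncol(swp$per_taxon), 1L)
  expect_equal(unname(swp$profile$mean_node_dist), 0)
  expect_true(all(swp$per_taxon >= 0))

  # make one taxon's window region identical to a distant taxon's
  lib <- add$library
  pm <- patristic_matrix(tr)
  far <- names(which.max(pm[rownames(pm)[1], ]))
  near <- rownames(pm)[1]
  L <- alignment_length(lib)
  win <- 1:floor(L / 2)
  s <- lib$seqs[[near]]
  substr(s, 1, floor(L / 2)) <- substr(lib$seqs[[far]], 1, floor(L / 2))
  lib$seqs[[near]] <- s
  swp2 <- sliding_window_placement(lib, tr, window = floor(L / 2), step = L)
  expect_gt(swp2$per_taxon[near, 1], 0)

  expect_error(sliding_window_placement(subset_library(add$library,
                                                       names(add$library$seqs)[1:3]),
                                        tr, window = 10),
               "value error")
})
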