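test_that("training: smoothing formulas and determinism", {
  lib <- seq_library(c(a = "ACGTACGTACGT", b = "TTTTGGGGCCCC"),
                     parse_lineages(c("a", "b"),
                                    c("Bacteria;P1;C1;O1;F1;GA",
                                      "Bacteria;P2;C2;O2;F2;GB")))
  model <- train(lib, k = 4L)
  expect_identical(sort(model$genera), c("GA", "GB"))
  expect_identical(model$N, 2L)
  # word present in exactly one sequence: prior = (1 + 0.5) / (2 + 1)
  w <- primereval:::.seq_words("ACGT", 4L)
  i <- match(w, model$vocab)
  expect_equal(model$prior[i], 1.5 / 3)
  # conditional of a GA-only word under GB = smoothed floor prior / (M + 1)
  expect_equal(unname((model$m["GB", i] + model$prior[i]) / (model$M[["GB"]] + 1)),
               model$prior[i] / 2)

  model2 <- train(lib, k = 4L)
  expect_identical(model, model2)

  bad <- seq_library(c(a = "ACGTACGT"), parse_lineages("a", "Bacteria;P1"))
  expect_error(train(bad), "genus")
})

test_that("classification: recovery, vocabulary miss, ambiguity below cutoff", {
  lib <- simulate_genus_library(n_genera = 6L, n_per_genus = 4L,
                                seq_length = 400L, seed = 3L)
  model <- train(lib, k = 8L)
  # training sequences classify back to their own genus with full confidence
  res <- classify(model, lib$seqs[[1]], seed = 1L)
  expect_identical(res$label[res$rank == "genus"],
                   lib$taxonomy$genus[1])
  expect_gte(res$confidence[res$rank == "genus"], 95)
  # lineage consistency: labels nest, confidence non-increasing with depth
  expect_true(all(diff(res$confidence) <= 1e-9))

  # out-of-vocabulary query
  res2 <- classify(model, strrep("AG", 100), seed = 1L)
  expect_true(all(res2$label == "unclassified"))
  expect_true(all(res2$confidence == 0))

  # a query equally similar to two genera in different phyla stays
  # unclassified at every rank
  half <- paste0(substr(lib$seqs[[1]], 1, 200),
                 substr(lib$seqs[[5]], 201, 400))  # g01 (phy01) + g02 (phy02)
  for (seed in 1:3) {
    res3 <- classify(model, half, seed = seed)
    gconf <- res3$confidence[res3$rank == "genus"]
    expect_lte(gconf, 80)
    expect_identical(res3$label[res3$rank == "genus"], "unclassified")
  }

  # same seed -> identical result
  expect_identical(classify(model, lib$seqs[[10]], seed = 7L),
                   classify(model, lib$seqs[[10]], seed = 7L))
})

test_that("confidence declines as genera become similar", {
  confs <- vapply(c(0.40, 0.20, 0.10, 0.05, 0.01), function(div) {
    # two genera whose ancestors differ at a fraction `div` of sites
    set.seed(99)
    base <- sample(c("A", "C", "G", "T"), 600, replace = TRUE)
    alt <- base
    idx <- seq_len(round(div * 600))
    alt[idx] <- chartr("ACGT", "CGTA", alt[idx])
    seqs <- c(x1 = paste(base, collapse = ""), x2 = paste(base, collapse = ""),
              y1 = paste(alt, collapse = ""), y2 = paste(alt, collapse = ""))
    lib <- seq_library(seqs, parse_lineages(names(seqs), c(
      "Bacteria;P1;C1;O1;F1;GX", "Bacteria;P1;C1;O1;F1;GX",
      "Bacteria;P2;C2;O2;F2;GY", "Bacteria;P2;C2;O2;F2;GY")))
    model <- train(lib, k = 8L)
    res <- classify(model, seqs[["x1"]], seed = 11L)
    res$confidence[res$rank == "genus"]
  }, 0)
  expect_true(all(diff(confs) <= 0))
  expect_gte(confs[1], 95)
})

test_that("assignment scoring implements the correct/FP/FN definitions", {
  mk <- function(labels) {
    data.frame(id = sprintf("r%02d", seq_along(labels)), rank = "genus",
               label = labels, stringsAsFactors = FALSE)
  }
  ten <- sprintf("G%d", 1:10)
  sc <- score_assignments(mk(ten), mk(ten), "genus")
  expect_equal(sc$correct_incl, 100)
  expect_equal(sc$false_positive, 0)
  expect_equal(sc$false_negative, 0)

  # one read classified in SR but unclassified in NFL
  nfl <- ten; nfl[1] <- "unclassified"
  sc <- score_assignments(mk(ten), mk(nfl), "genus")
  expect_equal(sc$false_positive, 10)
  expect_equal(sc$unclassified_ref, 10)
  expect_equal(sc$correct_excl, 100)

  # two reads classified in NFL but unclassified in SR
  sr <- ten; sr[1:2] <- "unclassified"
  sc <- score_assignments(mk(sr), mk(ten), "genus")
  expect_equal(sc$false_negative, 20)
  expect_gte(sc$unclassified_total, 20)

  # both-unclassified counts as agreement under the inclusive convention
  both <- ten; both[3] <- "unclassified"
  sc_in <- score_assignments(mk(both), mk(both), "genus")
  expect_equal(sc_in$correct_incl, 100)
  sc_ex <- score_assignments(mk(both), mk(both), "genus",
                             both_unclassified_agree = FALSE)
  expect_equal(sc_ex$correct_incl, 90)

  # permutation invariance in read order
  o <- sample(10)
  a <- mk(ten)[o, ]; b <- mk(nfl)
  expect_equal(score_assignments(a, b, "genus"),
               score_assignments(mk(ten), mk(nfl), "genus"))

  expect_error(score_assignments(mk(ten)[1:5, ], mk(ten), "genus"), "id mismatch")
})
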