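test_that("iupac_match basics: exact hits, degeneracy, mismatch budget", {
  h <- iupac_match("ACGT", "TTACGTTT")
  expect_true(any(h$start == 2L & h$strand == "+"))

  # 799f with M->C, K->T realized
  h <- iupac_match(builtin_primers()[["799f"]], "AACCGGATTAGATACCCTG")
  expect_identical(h$start[h$strand == "+"], 0L)

  expect_identical(nrow(iupac_match("ACGT", "ACGA", 0L, strands = "+")), 0L)
  h <- iupac_match("ACGT", "ACGA", 1L, strands = "+")
  expect_identical(h$start, 0L)

  # target N consumes mismatch budget
  expect_identical(nrow(iupac_match("ACGT", "ACNT", 0L, strands = "+")), 0L)
  expect_identical(nrow(iupac_match("ACGT", "ACNT", 1L, strands = "+")), 1L)

  expect_error(iupac_match("ACXT", "ACGT"), "non-IUPAC")
  expect_error(iupac_match("ACGT", "ACGT", 4L), "max_mismatches")
  expect_error(iupac_match("ACGT", "AC-GT"), "ungapped")
})

test_that("iupac_match equals the expansion oracle on degenerate primers", {
  set.seed(101)
  primers <- c("RY", "ACGT", "NNS", "AMKG", "CWGTC", "BDHV", "ACGRYT")
  for (p in primers) {
    for (rep in 1:25) {
      target <- paste(sample(c("A", "C", "G", "T", "N"), 12, replace = TRUE,
                             prob = c(rep(0.24, 4), 0.04)), collapse = "")
      for (mm in 0:1) {
        got <- iupac_match(p, target, mm)
        want <- oracle_iupac_match(p, target, mm)
        expect_equal(got$start, want$start, label = paste(p, target, mm))
        expect_equal(got$strand, want$strand)
        expect_equal(got$mismatches, want$mismatches)
      }
    }
  }
})

test_that("strand symmetry: match(P, S) == match(revcomp(P), revcomp(S)) swapped", {
  set.seed(77)
  for (rep in 1:20) {
    p <- paste(sample(names(primereval:::.IUPAC_MASK), 6, replace = TRUE), collapse = "")
    s <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
    h1 <- iupac_match(p, s, 1L)
    h2 <- iupac_match(revcomp_iupac(p), revcomp_iupac(s), 1L)
    # positions mirror; strand labels are preserved because hit positions are
    # always reported as the leftmost reference coordinate
    L <- nchar(s); m <- nchar(p)
    flip <- data.frame(start = L - h2$start - m,
                       strand = h2$strand,
                       mismatches = h2$mismatches)
    flip <- flip[order(flip$start, flip$strand), ]
    expect_equal(h1$start, flip$start)
    expect_equal(h1$strand, flip$strand)
    expect_equal(h1$mismatches, flip$mismatches)
  }
})

test_that("coverage arithmetic and grouping", {
  lib <- toy_library()
  p <- primer_spec("toy", "AACCGGAT", "forward")
  cov <- coverage(p, lib, group_rank = "all")
  expect_equal(cov$coverage[cov$group == "all"], 50)   # b and c carry the site; a has a gap-split site
  expect_equal(cov$coverage + cov$noncoverage, rep(100, nrow(cov)), tolerance = 1e-9)

  # matching happens on degapped sequence: a's site is AAC-GGAT -> AACGGAT (no hit)
  covg <- coverage(p, lib, group_rank = "phylum")
  expect_setequal(covg$group, c("all", "P1", "P2"))
  expect_equal(covg$coverage[covg$group == "P1"], 50)
  expect_equal(covg$coverage[covg$group == "P2"], 50)
  expect_equal(covg$covered[covg$group == "all"], 2L)

  expect_error(coverage(p, lib, group_rank = "kingdom"), "config error")
})

test_that("amplicon windows follow the 280-upstream/downstream convention", {
  # one gapless sequence, forward primer of length 19 at ungapped position 100
  site <- paste(expand_iupac(builtin_primers()[["799f"]]$iupac_seq)[1], collapse = "")
  s <- paste0(strrep("A", 100), site, strrep("G", 400))
  lib <- seq_library(c(x = s, y = s))
  sr <- extract_amplicons(lib, builtin_primers()[["799f"]], read_length = 280L)
  info <- attr(sr, "read_info")
  expect_equal(info$start, c(119L, 119L))
  expect_equal(info$end, c(380L, 380L))
  expect_equal(nchar(degap(sr$seqs[["x"]])), 280L - 19L)

  # reverse primer of length 18 whose site occupies ungapped 482..499
  rsite <- revcomp_iupac("CTCACRRCACGAGCTGAC")
  rsite <- gsub("Y", "C", rsite)                      # concrete site
  s2 <- paste0(strrep("A", 482), rsite, strrep("G", 300))
  lib2 <- seq_library(c(x = s2))
  sr2 <- extract_amplicons(lib2, builtin_primers()[["1062r"]], read_length = 280L)
  info2 <- attr(sr2, "read_info")
  expect_equal(info2$start, 220L)
  expect_equal(info2$end, 482L)
  expect_equal(nchar(degap(sr2$seqs[["x"]])), 280L - 18L)

  expect_error(extract_amplicons(lib, builtin_primers()[["799f"]], read_length = 19L),
               "value error")
})

test_that("short-read library stays column-consistent; missing anchors handled", {
  sim <- simulate_library(sim_config(n_taxa = 20L, seed = 9L))
  p <- builtin_primers()[["518f"]]
  sr <- extract_amplicons(sim$library, p)
  # one shared column space
  expect_length(unique(nchar(sr$seqs)), 1L)
  info <- attr(sr, "read_info")
  expect_true(all(nchar(degap(sr$seqs)) <=
                    280L - nchar(p$iupac_seq)))
  full <- info$anchored & !info$truncated
  expect_true(all(nchar(degap(sr$seqs[info$id[full]])) == 280L - nchar(p$iupac_seq)))

  # majority-column keeps sequences that lack an anchor
  broken <- sim$library
  s <- broken$seqs[[1]]
  substr(s, 527, 542) <- strrep("T", 16)  # destroy the 518 site of one sequence
  broken$seqs[[1]] <- s
  sr_ex <- extract_amplicons(broken, p, on_missing = "exclude")
  sr_mc <- extract_amplicons(broken, p, on_missing = "majority-column")
  expect_false(names(broken$seqs)[1] %in% names(sr_ex$seqs))
  expect_true(names(broken$seqs)[1] %in% names(sr_mc$seqs))
})
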