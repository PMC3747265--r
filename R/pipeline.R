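#' Build a run configuration for the full evaluation
#'
#' Defaults mirror the evaluation's canonical settings: 280-bp unidirectional
#' reads, five replicate trees per short-read library and three for the
#' full-length library, 500 bootstrap replicates, 0.01 binning, OTU cutoffs
#' 0.01/0.02/0.03, and a word-size-8 classifier with 100 bootstrap rounds
#' and an 80% confidence cutoff. A single master seed fixes the whole run.
#'
#' @param mode "simulate" or "load"
#' @param fasta,taxonomy input paths (load mode)
#' @param primers list of [primer_spec()] or a primer-table TSV path
#' @param n_taxa taxa to simulate (simulate mode)
#' @param read_length read window in bases
#' @param n_sr_trees,n_nfl_trees replicate trees per library
#' @param bootstrap_replicates support bootstrap replicates per tree
#' @param bin_width profile bin width
#' @param otu_cutoffs clustering cutoffs
#' @param classifier_k,classifier_bootstrap,classifier_cutoff classifier settings
#' @param group_rank taxon rank for coverage grouping
#' @param dims MDS dimensionality
#' @param window_step column step of the sliding-window analysis (NULL = auto)
#' @param seed master seed
#' @return a `run_config` list
#' @export
run_config <- function(mode = c("simulate", "load"), fasta = NULL, taxonomy = NULL,
                       primers = builtin_primers(), n_taxa = 50L,
                       read_length = 280L, n_sr_trees = 5L, n_nfl_trees = 3L,
                       bootstrap_replicates = 500L, bin_width = 0.01,
                       otu_cutoffs = c(0.01, 0.02, 0.03), classifier_k = 8L,
                       classifier_bootstrap = 100L, classifier_cutoff = 80,
                       group_rank = "phylum", dims = 3L, window_step = NULL,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (is.character(primers)) primers <- read_primer_table(primers)
  if (mode == "load" && is.null(fasta)) stop("config error: load mode needs a fasta path")
  structure(list(mode = mode, fasta = fasta, taxonomy = taxonomy,
                 primers = primers, n_taxa = as.integer(n_taxa),
                 read_length = as.integer(read_length),
                 n_sr_trees = as.integer(n_sr_trees),
                 n_nfl_trees = as.integer(n_nfl_trees),
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 bin_width = bin_width, otu_cutoffs = otu_cutoffs,
                 classifier_k = as.integer(classifier_k),
                 classifier_bootstrap = as.integer(classifier_bootstrap),
                 classifier_cutoff = classifier_cutoff,
                 group_rank = group_rank, dims = as.integer(dims),
                 window_step = window_step, seed = as.integer(seed)),
            class = "run_config")
}

#' Replicate distance trees from one library
#'
#' Each replicate resamples the alignment columns with replacement under its
#' own derived seed and builds a support-decorated NJ tree from the
#' resampled alignment — a desk-scale stand-in for repeated heuristic tree
#' searches, reproducing search-to-search variability.
#'
#' @param library aligned [seq_library()]
#' @param n number of replicate trees
#' @param seed integer seed
#' @param bootstrap_replicates support bootstrap replicates per tree
#' @param model distance model
#' @return list of `ape::phylo`
#' @export
replicate_trees <- function(library, n, seed = 1L, bootstrap_replicates = 100L,
                            model = "jc") {
  L <- alignment_length(library)
  lapply(seq_len(n), function(k) {
    sk <- derive_seed(seed, paste0("replicate-", k))
    cols <- with_seed(sk, sample.int(L, L, replace = TRUE))
    m <- seq_matrix(library)[, cols, drop = FALSE]
    sub <- seq_library(apply(m, 1L, paste, collapse = ""))
    bootstrap_supports(sub, n_replicates = bootstrap_replicates, seed = sk,
                       model = model)
  })
}

.write_stage <- function(state, name, df) {
  path <- file.path(state$outdir, name)
  write_report_tsv(df, path)
  state$written <- c(state$written, path)
  state
}

#' Run the full primer evaluation
#'
#' Orchestrates: input library (simulated or loaded) -> primer coverage table
#' -> per-primer short-read libraries -> replicate trees -> within-library
#' and versus-full-length tree comparisons -> OTU richness ratios ->
#' taxonomic assignment scoring -> sliding-window profile -> binned distance
#' profiles. All outputs are TSV files in `outdir`; `manifest.json` records
#' the configuration and seed. Any stage failure renames completed outputs
#' with a `.partial` suffix and aborts with a stage-labelled error.
#'
#' @param config a [run_config()]
#' @param outdir output directory (created if needed)
#' @return `outdir`, invisibly
#' @export
run_evaluation <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  state$outdir <- outdir
  state$written <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      for (p in state$written) file.rename(p, paste0(p, ".partial"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  seed <- config$seed

  nfl <- stage("input", {
    if (config$mode == "simulate") {
      sim <- simulate_library(sim_config(n_taxa = config$n_taxa, seed = seed))
      sim$library
    } else {
      read_fasta(config$fasta, config$taxonomy)
    }
  })

  stage("coverage", {
    rank <- if (!is.null(nfl$taxonomy)) config$group_rank else "all"
    cov <- coverage(config$primers, nfl, group_rank = rank)
    state <- .write_stage(state, "coverage.tsv", cov)
  })

  sr_libs <- stage("extract", {
    libs <- lapply(config$primers, function(p) {
      extract_amplicons(nfl, p, read_length = config$read_length)
    })
    names(libs) <- vapply(config$primers, `[[`, "", "name")
    libs
  })

  all_trees <- stage("trees", {
    trees <- list(NFL = replicate_trees(nfl, config$n_nfl_trees,
                                        seed = derive_seed(seed, "trees-NFL"),
                                        bootstrap_replicates = config$bootstrap_replicates))
    for (nm in names(sr_libs)) {
      trees[[nm]] <- replicate_trees(sr_libs[[nm]], config$n_sr_trees,
                                     seed = derive_seed(seed, paste0("trees-", nm)),
                                     bootstrap_replicates = config$bootstrap_replicates)
    }
    trees
  })

  stage("within-library comparison", {
    rows <- list()
    for (nm in names(all_trees)) {
      trs <- all_trees[[nm]]
      prs <- utils::combn(length(trs), 2)
      per <- lapply(seq_len(ncol(prs)), function(c2) {
        i <- prs[1, c2]; j <- prs[2, c2]
        cmp <- compare_trees(trs[[i]], trs[[j]], dims = config$dims)
        data.frame(library = nm, tree_a = i, tree_b = j,
                   pearson_r = cmp$pearson_r, slope = cmp$slope,
                   wrmsd = cmp$wrmsd, rf = cmp$rf, wrf1 = cmp$wrf1,
                   wrf2 = cmp$wrf2, stringsAsFactors = FALSE)
      })
      per <- do.call(rbind, per)
      avg <- data.frame(library = nm, tree_a = NA_integer_, tree_b = NA_integer_,
                        pearson_r = mean(per$pearson_r), slope = mean(per$slope),
                        wrmsd = mean(per$wrmsd), rf = mean(per$rf),
                        wrf1 = mean(per$wrf1), wrf2 = mean(per$wrf2))
      rows[[nm]] <- rbind(per, avg)
    }
    state <- .write_stage(state, "tree_comparison_within.tsv", do.call(rbind, rows))
  })

  stage("versus-NFL comparison", {
    nfl_norm_pw <- normalize_max1(pairwise_seq_distance(nfl, model = "p"))
    rows <- lapply(names(sr_libs), function(nm) {
      cmps <- list()
      for (i in seq_along(all_trees[[nm]])) {
        for (j in seq_along(all_trees$NFL)) {
          cmps[[length(cmps) + 1L]] <-
            compare_trees(all_trees$NFL[[j]], all_trees[[nm]][[i]], dims = config$dims)
        }
      }
      slope11 <- cmps[[1]]$slope
      sr_norm_pw <- normalize_max1(pairwise_seq_distance(sr_libs[[nm]], model = "p"))
      pdw <- pair_distances(nfl_norm_pw, sr_norm_pw)
      data.frame(primer = nm,
                 pc_patristic = mean(vapply(cmps, `[[`, 0, "pearson_r")),
                 pc_pairwise = pearson(pdw),
                 wrmsd = mean(vapply(cmps, `[[`, 0, "wrmsd")),
                 slope_patristic = slope11,
                 slope_pairwise = slope_through_origin(pdw),
                 rf = mean(vapply(cmps, `[[`, 0, "rf")),
                 wrf1 = mean(vapply(cmps, `[[`, 0, "wrf1")),
                 wrf2 = mean(vapply(cmps, `[[`, 0, "wrf2")),
                 stringsAsFactors = FALSE)
    })
    state <- .write_stage(state, "tree_comparison_vs_nfl.tsv", do.call(rbind, rows))
  })

  stage("otu richness", {
    rows <- lapply(names(sr_libs), function(nm) {
      rr <- richness_ratio(sr_libs[[nm]], nfl, cutoffs = config$otu_cutoffs)
      cbind(data.frame(primer = nm, stringsAsFactors = FALSE), rr)
    })
    state <- .write_stage(state, "otu_richness.tsv", do.call(rbind, rows))
  })

  stage("taxonomy", {
    if (is.null(nfl$taxonomy) || !"genus" %in% names(nfl$taxonomy)) {
      pe_log("warn", "no genus taxonomy; skipping assignment scoring")
      state <- .write_stage(state, "taxonomy_performance.tsv",
                            data.frame(primer = character(), rank = character()))
    } else {
      model <- train(nfl, k = config$classifier_k)
      nfl_res <- classify_library(model, nfl, seed = derive_seed(seed, "classify-NFL"),
                                  n_bootstrap = config$classifier_bootstrap,
                                  cutoff = config$classifier_cutoff)
      rows <- list()
      for (nm in names(sr_libs)) {
        ## reads are emitted in reference (sense) orientation by
        ## extract_amplicons, so no re-orientation is needed here
        sr_res <- classify_library(model, sr_libs[[nm]],
                                   seed = derive_seed(seed, paste0("classify-", nm)),
                                   n_bootstrap = config$classifier_bootstrap,
                                   cutoff = config$classifier_cutoff)
        shared <- intersect(unique(sr_res$id), unique(nfl_res$id))
        for (rk in c("phylum", "genus")) {
          sc <- score_assignments(sr_res[sr_res$id %in% shared, ],
                                  nfl_res[nfl_res$id %in% shared, ], rk)
          rows[[length(rows) + 1L]] <-
            cbind(data.frame(primer = nm, stringsAsFactors = FALSE), sc)
        }
      }
      state <- .write_stage(state, "taxonomy_performance.tsv", do.call(rbind, rows))
    }
  })

  stage("sliding window", {
    swp <- sliding_window_placement(nfl, all_trees$NFL[[1]],
                                    window = config$read_length,
                                    step = config$window_step)
    state <- .write_stage(state, "window_profile.tsv", swp$profile)
  })

  stage("binned profiles", {
    nfl_pat <- normalize_max1(patristic_matrix(all_trees$NFL[[1]]))
    nfl_pw <- normalize_max1(pairwise_seq_distance(nfl, model = "p"))
    rows <- list()
    for (nm in names(sr_libs)) {
      sr_pat <- normalize_max1(patristic_matrix(all_trees[[nm]][[1]]))
      sr_pw <- normalize_max1(pairwise_seq_distance(sr_libs[[nm]], model = "p"))
      for (kind in c("patristic", "pairwise")) {
        pd <- if (kind == "patristic") pair_distances(nfl_pat, sr_pat)
              else pair_distances(nfl_pw, sr_pw)
        bp <- binned_profile(pd, width = config$bin_width)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(primer = nm, kind = kind, stringsAsFactors = FALSE), bp)
      }
    }
    state <- .write_stage(state, "binned_profiles.tsv", do.call(rbind, rows))
  })

  stage("manifest", {
    cfg <- config
    cfg$primers <- lapply(cfg$primers, function(p) {
      list(name = p$name, sequence = p$iupac_seq, direction = p$direction)
    })
    manifest <- list(config = unclass(cfg), seed = seed,
                     package_version = as.character(utils::packageVersion("primereval")),
                     r_version = R.version.string)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  })

  invisible(outdir)
}
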