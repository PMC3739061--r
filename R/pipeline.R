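#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates the cohort described by `spec`, builds per-subject
#' connectivity and per-group networks, detects group modules on the
#' non-thresholded positive group networks, maps the module
#' reorganization from the first group to the second, reports homotopic
#' splits, computes the biomarker table (index A, index B, module GMC,
#' GMC-residualized index A), group statistics and the combined
#' classifier, and writes everything to `out_dir` with a manifest.
#' Deterministic: the same spec/config produce byte-identical outputs.
#'
#' @param spec a `cohort_spec`.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param config an `analysis_config`.
#' @return list with all intermediate products (invisible when writing).
#' @export
run_pipeline <- function(spec = cohort_spec(), out_dir = NULL,
                         config = analysis_config(seed = spec$seed)) {
  cohort <- simulate_cohort(spec)
  mats <- lapply(cohort$subjects, subject_connectivity)
  by_group <- split(mats, vapply(mats, `[[`, "", "group"))
  by_group <- by_group[unique(spec$groups)]  # stable group order

  networks <- lapply(names(by_group), function(g) {
    group_network(by_group[[g]], sd_type = config$sd_type,
                  positive_mask = config$positive_mask)
  })
  names(networks) <- names(by_group)
  partitions <- lapply(names(networks), function(g) {
    detect_modules(as_weighted_graph(networks[[g]], id = g),
                   refine = config$refine)
  })
  names(partitions) <- names(networks)

  reorg <- NULL
  if (length(partitions) >= 2) {
    reorg <- compare_partitions(partitions[[1]], partitions[[2]])
  }
  splits <- lapply(partitions, homotopic_splits, atlas = spec$atlas)

  bt <- biomarker_table(mats, spec$atlas, gmc_table = cohort$gmc,
                        pairs = spec$affected_pairs,
                        index_b_mode = config$index_b_mode)
  bt <- control_gmc(bt)
  stats_a <- group_stats(bt, "index_A")
  stats_gmc <- group_stats(bt, "gmc_module_mean")
  stats_resid <- group_stats(bt, "residual_index_A")
  cls <- classify(bt, features = config$classify_features,
                  groups = unique(spec$groups)[1:2], seed = config$seed)

  out <- list(cohort = cohort, connectivity = mats, networks = networks,
              partitions = partitions, reorganization = reorg,
              homotopic = splits, biomarkers = bt,
              stats = list(index_A = stats_a, gmc = stats_gmc,
                           residual_index_A = stats_resid),
              classification = cls)
  if (!is.null(out_dir)) {
    objs <- list()
    for (g in names(networks)) {
      objs[[paste0("group_network_", g)]] <- networks[[g]]
      objs[[paste0("partition_", g)]] <- partitions[[g]]
      objs[[paste0("homotopic_splits_", g)]] <-
        list(n_pairs = splits[[g]]$n_pairs, n_split = splits[[g]]$n_split,
             subset_counts = splits[[g]]$subset_counts,
             pairs = splits[[g]]$pairs)
    }
    objs$biomarkers <- bt
    if (!is.null(reorg)) {
      objs$reorganization <- list(crosstab = reorg$crosstab,
                                  flows = reorg$flows, match = reorg$match)
    }
    objs$statistics <- out$stats
    objs$classification <- list(features = cls$features,
                                groups = cls$groups, auc = cls$auc,
                                weights = as.list(cls$weights),
                                orientation = cls$orientation,
                                roc = cls$roc)
    write_results(objs, out_dir, config = config)
    return(invisible(out))
  }
  out
}

# ---------------------------------------------------------------------------
# Command-line interface

.cli_usage <- function() {
  cat("usage: brainmod <command> [--config FILE] [--seed S] [--out DIR] ...\n",
      "commands:\n",
      "  simulate       --out DIR [--config FILE] [--seed S]\n",
      "  connectivity   --in DIR --out DIR\n",
      "  group-network  --in DIR --groups FILE --out DIR\n",
      "  modules        --network FILE.tsv --out FILE.tsv\n",
      "  q-curve        --in DIR --groups FILE --grid a:b:step",
      " [--nulls K] [--seed S] --out FILE.json\n",
      "  reorganize     --source P1.tsv --target P2.tsv --out FILE.json\n",
      "  indices        --in DIR --groups FILE [--gmc FILE]",
      " [--pairs NAME] --out FILE.tsv\n",
      "  classify       --table FILE.tsv --features f1,f2 --groups A,B",
      " --out FILE.json\n",
      "  run-all        --out DIR [--config FILE] [--seed S]\n", sep = "")
}

.cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      stop("option --", key, " needs a value")
    }
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  opts
}

.cli_config <- function(opts) {
  cfg <- if (!is.null(opts$config)) read_config(opts$config)
         else analysis_config()
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  cfg
}

.cli_read_cohort_mats <- function(in_dir, groups_file, atlas) {
  groups <- utils::read.delim(groups_file)
  mats <- lapply(seq_len(nrow(groups)), function(i) {
    sid <- groups$subject_id[i]
    ts <- read_timeseries(file.path(in_dir, paste0("ts_", sid, ".tsv")),
                          atlas, subject_id = sid, group = groups$group[i])
    subject_connectivity(ts)
  })
  names(mats) <- groups$subject_id
  mats
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands (`simulate`, `connectivity`,
#' `group-network`, `modules`, `q-curve`, `reorganize`, `indices`,
#' `classify`, `run-all`). Run via the `inst/cli/brainmod` Rscript wrapper
#' or directly as `Rscript -e 'brainmod::brainmod_cli()' <cmd> ...`.
#'
#' @param args character vector of command-line arguments; defaults to the
#'   trailing arguments of the calling Rscript process.
#' @return exit status 0 invisibly (errors raise conditions).
#' @export
brainmod_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help", "help")) {
    .cli_usage()
    return(invisible(0L))
  }
  cmd <- args[1]
  opts <- .cli_opts(args[-1])
  cfg <- .cli_config(opts)
  atlas <- aal116_atlas()
  need <- function(key) {
    if (is.null(opts[[key]])) stop("command ", cmd, " needs --", key)
    opts[[key]]
  }
  switch(cmd,
    "simulate" = {
      spec <- cohort_spec(seed = cfg$seed)
      write_cohort(simulate_cohort(spec), need("out"))
    },
    "connectivity" = {
      in_dir <- need("in"); out_dir <- need("out")
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      for (f in list.files(in_dir, pattern = "^ts_.*\\.tsv$")) {
        ts <- read_timeseries(file.path(in_dir, f), atlas)
        cm <- subject_connectivity(ts)
        write_matrix_tsv(cm$cc, file.path(out_dir, sub("^ts_", "cc_", f)))
      }
    },
    "group-network" = {
      mats <- .cli_read_cohort_mats(need("in"), need("groups"), atlas)
      out_dir <- need("out")
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      gl <- vapply(mats, `[[`, "", "group")
      for (g in unique(gl)) {
        gn <- group_network(mats[gl == g], sd_type = cfg$sd_type,
                            positive_mask = cfg$positive_mask)
        write_matrix_tsv(gn$a, file.path(out_dir,
                                         paste0("group_", g, ".tsv")))
      }
    },
    "modules" = {
      w <- read_matrix_tsv(need("network"))
      p <- detect_modules(weighted_graph(w, id = basename(need("network"))),
                          refine = cfg$refine)
      write_partition(p, need("out"))
    },
    "q-curve" = {
      mats <- .cli_read_cohort_mats(need("in"), need("groups"), atlas)
      gl <- vapply(mats, `[[`, "", "group")
      grid <- if (!is.null(opts$grid)) .parse_grid(opts$grid)
              else cfg$ne_grid
      n_null <- if (!is.null(opts$nulls)) as.integer(opts$nulls)
                else cfg$n_null
      qc <- q_curve(split(mats, gl), grid, n_null = n_null,
                    seed = cfg$seed, refine = cfg$refine)
      jsonlite::write_json(list(per_subject = qc$per_subject,
                                comparison = qc$comparison,
                                n_null = n_null, seed = cfg$seed),
                           need("out"), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    },
    "reorganize" = {
      ps <- read_partition(need("source"))
      pt <- read_partition(need("target"))
      rm_ <- compare_partitions(ps, pt)
      spl <- homotopic_splits(pt, atlas)
      jsonlite::write_json(list(crosstab = rm_$crosstab, flows = rm_$flows,
                                match = rm_$match,
                                homotopic = list(n_pairs = spl$n_pairs,
                                                 n_split = spl$n_split)),
                           need("out"), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    },
    "indices" = {
      mats <- .cli_read_cohort_mats(need("in"), need("groups"), atlas)
      gmc <- if (!is.null(opts$gmc)) utils::read.delim(opts$gmc) else NULL
      pairs <- if (!is.null(opts$pairs)) opts$pairs
               else "insula_module_pairs"
      bt <- biomarker_table(mats, atlas, gmc_table = gmc, pairs = pairs,
                            index_b_mode = cfg$index_b_mode)
      if (!is.null(gmc)) bt <- control_gmc(bt)
      utils::write.table(bt, need("out"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    },
    "classify" = {
      bt <- utils::read.delim(need("table"))
      features <- trimws(strsplit(need("features"), ",")[[1]])
      groups <- trimws(strsplit(need("groups"), ",")[[1]])
      cls <- classify(bt, features = features, groups = groups,
                      seed = cfg$seed)
      jsonlite::write_json(list(features = cls$features, auc = cls$auc,
                                groups = cls$groups,
                                weights = as.list(cls$weights),
                                orientation = cls$orientation,
                                roc = cls$roc, seed = cfg$seed),
                           need("out"), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    },
    "run-all" = {
      spec <- cohort_spec(seed = cfg$seed)
      run_pipeline(spec, out_dir = need("out"), config = cfg)
    },
    stop("unknown command: ", cmd)
  )
  invisible(0L)
}
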