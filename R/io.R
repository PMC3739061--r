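#' @keywords internal
#' Format numbers losslessly for text serialization (round-trips doubles).
.fmt <- function(x) sprintf("%.17g", x)

#' Write a square region matrix as TSV with a region-id header
#'
#' @param m numeric matrix with region-id dimnames (or plain, in which case
#'   1..N ids are used).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  m <- as.matrix(m)
  ids <- colnames(m)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ids, collapse = "\t"), con)
  body <- apply(m, 1, function(r) paste(.fmt(r), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path TSV file path.
#' @return numeric matrix with column names from the header.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- NULL
  m
}

#' Analysis configuration
#'
#' Bundles the tunables shared across pipeline stages. Any subset of the
#' fields can be overridden; the rest keep their defaults.
#'
#' @param ne_grid integer vector: edge counts for Q-vs-edges curves.
#' @param n_null number of random-network null realizations.
#' @param seed master random seed (recorded in every manifest).
#' @param positive_mask `"group"` (mask the group matrix, default) or
#'   `"subject"` (zero negative per-subject correlations before pooling).
#' @param refine logical: Kernighan-Lin style refinement after each
#'   spectral bisection.
#' @param alpha significance level for group comparisons.
#' @param sd_type `"population"` (1/n, default) or `"sample"` (1/(n-1))
#'   standard deviation in the group-network ratio.
#' @param index_b_mode `"mean_pairs"` (default) or `"literal"`.
#' @param classify_features features for the combined classifier.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(ne_grid = seq(200L, 2000L, by = 200L),
                            n_null = 100L,
                            seed = 20130809L,
                            positive_mask = c("group", "subject"),
                            refine = TRUE,
                            alpha = 0.05,
                            sd_type = c("population", "sample"),
                            index_b_mode = c("mean_pairs", "literal"),
                            classify_features = c("index_A",
                                                  "gmc_module_mean")) {
  positive_mask <- match.arg(positive_mask)
  sd_type <- match.arg(sd_type)
  index_b_mode <- match.arg(index_b_mode)
  stopifnot(all(ne_grid >= 1), n_null >= 1, alpha > 0, alpha < 1)
  structure(list(ne_grid = as.integer(ne_grid), n_null = as.integer(n_null),
                 seed = as.integer(seed), positive_mask = positive_mask,
                 refine = isTRUE(refine), alpha = alpha, sd_type = sd_type,
                 index_b_mode = index_b_mode,
                 classify_features = classify_features),
            class = "analysis_config")
}

#' Read a flat key=value config file
#'
#' Keys mirror the arguments of [analysis_config()]; unknown keys are an
#' error. `ne_grid` accepts `from:to:step` or comma-separated values;
#' `classify_features` is comma-separated.
#'
#' @param path config file path.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  known <- names(formals(analysis_config))
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    args[[k]] <- switch(k,
      ne_grid = .parse_grid(v),
      n_null = as.integer(v),
      seed = as.integer(v),
      refine = as.logical(v),
      alpha = as.numeric(v),
      classify_features = trimws(strsplit(v, ",")[[1]]),
      v)
  }
  do.call(analysis_config, args)
}

.parse_grid <- function(v) {
  if (grepl(":", v, fixed = TRUE)) {
    p <- as.integer(strsplit(v, ":", fixed = TRUE)[[1]])
    if (length(p) == 2) p <- c(p, 1L)
    if (length(p) != 3 || anyNA(p)) stop("bad grid spec: ", v)
    seq(p[1], p[2], by = p[3])
  } else {
    as.integer(trimws(strsplit(v, ",")[[1]]))
  }
}

#' Write pipeline products to a directory with a manifest
#'
#' Accepts a named list of pipeline objects and serializes each by type:
#' matrices as TSV (region-id header), module partitions as two-column TSV,
#' data.frames as TSV, everything else as JSON. A `manifest.json` records
#' the config, seed, package version, and the file list. Output is
#' byte-stable: identical inputs produce identical files.
#'
#' @param objects named list of results.
#' @param out_dir output directory (created if absent).
#' @param config an `analysis_config` recorded in the manifest.
#' @return the manifest (invisibly), after writing it.
#' @export
write_results <- function(objects, out_dir, config = analysis_config()) {
  stopifnot(is.list(objects), !is.null(names(objects)),
            all(nzchar(names(objects))))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  files <- character(0)
  for (nm in names(objects)) {
    obj <- objects[[nm]]
    if (inherits(obj, "module_partition")) {
      fn <- paste0(nm, ".tsv")
      write_partition(obj, file.path(out_dir, fn))
    } else if (inherits(obj, "connectivity_matrix")) {
      fn <- paste0(nm, ".tsv")
      write_matrix_tsv(obj$cc, file.path(out_dir, fn))
    } else if (inherits(obj, "group_network")) {
      fn <- paste0(nm, ".tsv")
      write_matrix_tsv(obj$a, file.path(out_dir, fn))
    } else if (is.matrix(obj)) {
      fn <- paste0(nm, ".tsv")
      write_matrix_tsv(obj, file.path(out_dir, fn))
    } else if (is.data.frame(obj)) {
      fn <- paste0(nm, ".tsv")
      utils::write.table(obj, file.path(out_dir, fn), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    } else {
      fn <- paste0(nm, ".json")
      jsonlite::write_json(obj, file.path(out_dir, fn), auto_unbox = TRUE,
                           digits = NA, null = "null", pretty = TRUE)
    }
    files <- c(files, fn)
  }
  manifest <- list(
    package = "brainmod",
    version = as.character(utils::packageVersion("brainmod")),
    seed = config$seed,
    config = unclass(config),
    files = sort(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a module partition as two-column TSV (region_id, module)
#'
#' @param p a `module_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(p, path) {
  stopifnot(inherits(p, "module_partition"))
  df <- data.frame(region_id = seq_along(p$assignment),
                   module = p$assignment)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a module partition written by [write_partition()]
#'
#' @param path TSV path with columns region_id, module.
#' @param graph_id source graph identifier (optional).
#' @return a `module_partition` (with `Q = NA`; recompute against a graph
#'   with [modularity_q()] if needed).
#' @export
read_partition <- function(path, graph_id = basename(path)) {
  df <- utils::read.delim(path)
  stopifnot(all(c("region_id", "module") %in% names(df)))
  df <- df[order(df$region_id), ]
  module_partition(df$module, Q = NA_real_, source = graph_id)
}
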