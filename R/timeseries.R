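#' Subject time-series objects
#'
#' A `subject_timeseries` holds one subject's region-averaged signal: a
#' T x N matrix (time points x regions) with columns in atlas order.
#'
#' @param subject_id subject identifier (text).
#' @param data numeric T x N matrix, columns named by region id.
#' @param atlas a `region_atlas`; column count must match.
#' @param group group label (text), e.g. "CN" or "AD".
#' @param sampling_interval seconds between samples (informational).
#' @return a `subject_timeseries` object.
#' @export
subject_timeseries <- function(subject_id, data, atlas, group = NA_character_,
                               sampling_interval = NA_real_) {
  stopifnot(inherits(atlas, "region_atlas"))
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("time-series data must be numeric")
  if (anyNA(data)) stop("time-series contains missing values")
  if (nrow(data) < 3) {
    stop("need at least 3 time points, got ", nrow(data))
  }
  if (ncol(data) != atlas$n_regions) {
    stop("time-series has ", ncol(data), " columns but atlas has ",
         atlas$n_regions, " regions")
  }
  colnames(data) <- as.character(atlas$region_id)
  structure(
    list(subject_id = as.character(subject_id), group = as.character(group),
         data = data, sampling_interval = sampling_interval),
    class = "subject_timeseries"
  )
}

#' @export
print.subject_timeseries <- function(x, ...) {
  cat("<subject_timeseries> ", x$subject_id,
      if (!is.na(x$group)) paste0(" (", x$group, ")"),
      ": ", nrow(x$data), " x ", ncol(x$data), "\n", sep = "")
  invisible(x)
}

#' Read a subject time-series table
#'
#' Accepts TSV or CSV with a header row of region ids or region names.
#' Columns are reordered to atlas order; all atlas regions must be present.
#'
#' @param path file path (.tsv or .csv, sniffed from extension).
#' @param atlas a `region_atlas`.
#' @param subject_id subject id; default the file name without extension.
#' @param group optional group label.
#' @return a `subject_timeseries`.
#' @export
read_timeseries <- function(path, atlas, subject_id = NULL, group = NA) {
  stopifnot(inherits(atlas, "region_atlas"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  hdr <- names(df)
  # header may carry region ids or region names
  pos <- match(as.character(atlas$region_id), hdr)
  if (anyNA(pos)) pos <- match(atlas$name, hdr)
  if (anyNA(pos)) {
    missing_ids <- atlas$region_id[is.na(match(as.character(atlas$region_id),
                                               hdr))]
    stop("time-series file ", path, " is missing region columns (by id): ",
         paste(utils::head(missing_ids, 5), collapse = ", "),
         if (length(missing_ids) > 5) " ...")
  }
  m <- as.matrix(df[, pos, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- names(df)[pos][!vapply(df[pos], is.numeric, logical(1))]
    stop("non-numeric values in column(s): ", paste(bad, collapse = ", "))
  }
  subject_timeseries(subject_id, m, atlas, group = group)
}

#' Write a subject time-series table as TSV
#'
#' @param ts a `subject_timeseries`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "subject_timeseries"))
  write_matrix_tsv(ts$data, path)
  invisible(path)
}
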