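#' Module reorganization map between two partitions
#'
#' Cross-tabulates region membership between a source partition (e.g. the
#' control group) and a target partition (e.g. the patient group),
#' lists per source module the target modules receiving members, and
#' matches each source module to its maximal-overlap target module (ties
#' broken toward the larger target module, then the lower label). Jaccard
#' overlap of the match is reported alongside.
#'
#' @param p_source,p_target `module_partition`s on the same atlas/N.
#' @return a `reorganization_map`: list with `crosstab` (matrix source x
#'   target), `flows` (data.frame source, target, n, region_ids), `match`
#'   (data.frame source, target, overlap, jaccard).
#' @export
compare_partitions <- function(p_source, p_target) {
  stopifnot(inherits(p_source, "module_partition"),
            inherits(p_target, "module_partition"))
  cs <- p_source$assignment
  ct <- p_target$assignment
  if (length(cs) != length(ct)) {
    stop("partitions cover different node counts (", length(cs), " vs ",
         length(ct), ")")
  }
  ns <- max(cs); nt <- max(ct)
  crosstab <- matrix(0L, ns, nt,
                     dimnames = list(source = seq_len(ns),
                                     target = seq_len(nt)))
  for (i in seq_along(cs)) {
    crosstab[cs[i], ct[i]] <- crosstab[cs[i], ct[i]] + 1L
  }
  flows <- do.call(rbind, lapply(seq_len(ns), function(s) {
    tg <- sort(unique(ct[cs == s]))
    do.call(rbind, lapply(tg, function(t) {
      ids <- which(cs == s & ct == t)
      data.frame(source = s, target = t, n = length(ids),
                 region_ids = paste(ids, collapse = ","))
    }))
  }))
  tgt_sizes <- tabulate(ct, nt)
  match_df <- do.call(rbind, lapply(seq_len(ns), function(s) {
    counts <- crosstab[s, ]
    best <- max(counts)
    cand <- which(counts == best)
    if (length(cand) > 1) {
      cand <- cand[order(-tgt_sizes[cand], cand)]
    }
    t <- cand[1]
    inter <- crosstab[s, t]
    uni <- sum(cs == s) + tgt_sizes[t] - inter
    data.frame(source = s, target = t, overlap = inter,
               jaccard = inter / uni)
  }))
  structure(list(crosstab = crosstab, flows = flows, match = match_df),
            class = "reorganization_map")
}

#' @export
print.reorganization_map <- function(x, ...) {
  cat("<reorganization_map> ", nrow(x$crosstab), " source modules -> ",
      ncol(x$crosstab), " target modules\n", sep = "")
  print(x$crosstab)
  invisible(x)
}

#' Homotopic pairs split across modules
#'
#' For each homotopic pair of the atlas (optionally restricted to a named
#' subset), reports the module label of each member under the given
#' partition and whether the pair is split (members in different modules).
#'
#' @param p a `module_partition` over the atlas regions.
#' @param atlas a `region_atlas`.
#' @param subset `"all"` (default) or a named subset of the atlas; only
#'   pairs with both members in the subset are examined.
#' @return a `homotopic_split_report`: list with `pairs` (data.frame left,
#'   right, module_left, module_right, split), `n_pairs`, `n_split`, and
#'   per-subset counts in `subset_counts`.
#' @export
homotopic_splits <- function(p, atlas, subset = "all") {
  stopifnot(inherits(p, "module_partition"),
            inherits(atlas, "region_atlas"))
  if (length(p$assignment) != atlas$n_regions) {
    stop("partition covers ", length(p$assignment),
         " nodes but atlas has ", atlas$n_regions)
  }
  pairs <- if (identical(subset, "all")) homotopic_pairs(atlas)
           else homotopic_pairs(atlas, subset)
  li <- match(pairs$left, atlas$region_id)
  ri <- match(pairs$right, atlas$region_id)
  ml <- p$assignment[li]
  mr <- p$assignment[ri]
  df <- data.frame(left = pairs$left, right = pairs$right,
                   module_left = ml, module_right = mr,
                   split = ml != mr)
  subset_counts <- lapply(atlas$named_subsets, function(ids) {
    sel <- df$left %in% ids & df$right %in% ids
    c(n_pairs = sum(sel), n_split = sum(df$split[sel]))
  })
  structure(list(pairs = df, n_pairs = nrow(df), n_split = sum(df$split),
                 subset_counts = subset_counts),
            class = "homotopic_split_report")
}

#' @export
print.homotopic_split_report <- function(x, ...) {
  cat("<homotopic_split_report> ", x$n_split, " of ", x$n_pairs,
      " homotopic pairs split\n", sep = "")
  invisible(x)
}

#' Normalized mutual information between two partitions
#'
#' NMI(X, Y) = 2 I(X; Y) / (H(X) + H(Y)), computed from the contingency
#' table of module labels; 1 for identical partitions (up to relabeling),
#' 0 for independent ones. Both partitions trivial (one module each)
#' returns 1 by convention.
#'
#' @param a,b integer label vectors or `module_partition`s.
#' @return NMI in [0, 1].
#' @export
partition_nmi <- function(a, b) {
  if (inherits(a, "module_partition")) a <- a$assignment
  if (inherits(b, "module_partition")) b <- b$assignment
  stopifnot(length(a) == length(b))
  n <- length(a)
  tab <- table(a, b)
  pj <- rowSums(tab) / n
  pk <- colSums(tab) / n
  hx <- -sum(ifelse(pj > 0, pj * log(pj), 0))
  hy <- -sum(ifelse(pk > 0, pk * log(pk), 0))
  if (hx + hy == 0) return(1)
  pjk <- tab / n
  expected <- outer(pj, pk)
  nz <- pjk > 0
  mi <- sum(pjk[nz] * log(pjk[nz] / expected[nz]))
  2 * mi / (hx + hy)
}
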