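#' Per-subject functional connectivity matrix
#'
#' Zero-lag Pearson correlation between every pair of region time courses
#' (CC_ij). The derived edge-distance view is d_ij = 1 - CC_ij.
#'
#' @param ts a `subject_timeseries`.
#' @return a `connectivity_matrix`: list with `subject_id`, `group`, `cc`
#'   (N x N symmetric, unit diagonal).
#' @export
subject_connectivity <- function(ts) {
  stopifnot(inherits(ts, "subject_timeseries"))
  v <- apply(ts$data, 2, stats::var)
  if (any(v == 0)) {
    stop("zero-variance time course in region(s): ",
         paste(colnames(ts$data)[v == 0], collapse = ", "))
  }
  cc <- stats::cor(ts$data)
  cc <- (cc + t(cc)) / 2
  diag(cc) <- 1
  structure(list(subject_id = ts$subject_id, group = ts$group, cc = cc),
            class = "connectivity_matrix")
}

#' Edge-distance view of a connectivity matrix
#'
#' @param cm a `connectivity_matrix`.
#' @return N x N matrix d_ij = 1 - CC_ij (zero diagonal).
#' @export
connectivity_distance <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  1 - cm$cc
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", x$subject_id, ": ", nrow(x$cc), " x ",
      ncol(x$cc), "\n", sep = "")
  invisible(x)
}

#' Group network: entrywise mean over standard deviation, positive-masked
#'
#' For each edge, a_ij = mean_k(CC_kij) / sd_k(CC_kij) over the subjects of
#' one group, with the population (1/n) standard deviation by default.
#' Edges whose mean correlation is non-positive are set to zero (only
#' positive connectivity enters the group network). Edges with zero
#' standard deviation but positive mean are capped at the largest finite
#' ratio in the matrix, with a warning. The diagonal is zero.
#'
#' @param mats list of `connectivity_matrix` (>= 2 subjects, same N).
#' @param sd_type `"population"` (1/n, default) or `"sample"` (1/(n-1)).
#' @param positive_mask `"group"` (default: mask the group-level mean) or
#'   `"subject"` (zero negative per-subject correlations before pooling).
#' @return a `group_network`: list with `a` (masked ratio), `mean_cc`,
#'   `sd_cc`, `n_subjects`.
#' @export
group_network <- function(mats, sd_type = c("population", "sample"),
                          positive_mask = c("group", "subject")) {
  sd_type <- match.arg(sd_type)
  positive_mask <- match.arg(positive_mask)
  if (length(mats) < 2) {
    stop("group network needs at least 2 subjects (got ", length(mats), ")")
  }
  stopifnot(all(vapply(mats, inherits, TRUE, "connectivity_matrix")))
  n_reg <- nrow(mats[[1]]$cc)
  if (!all(vapply(mats, function(m) nrow(m$cc), 0L) == n_reg)) {
    stop("all connectivity matrices must have the same dimension")
  }
  n <- length(mats)
  ccs <- vapply(mats, function(m) {
    x <- m$cc
    if (positive_mask == "subject") x[x < 0] <- 0
    x
  }, matrix(0, n_reg, n_reg))
  mu <- rowMeans(ccs, dims = 2)
  sd_den <- if (sd_type == "population") n else n - 1
  dev <- ccs - array(mu, dim(ccs))  # mu recycles along the subject axis
  sdm <- sqrt(rowSums(dev^2, dims = 2) / sd_den)
  a <- mu / sdm
  a[mu <= 0] <- 0
  diag(a) <- 0
  if (any(is.infinite(a) | is.nan(a))) {
    finite_max <- max(a[is.finite(a)], 0)
    n_cap <- sum((is.infinite(a) | is.nan(a))[upper.tri(a)])
    a[is.infinite(a) | is.nan(a)] <- finite_max
    diag(a) <- 0
    warning(n_cap, " edge(s) with zero standard deviation capped at ",
            signif(finite_max, 4))
  }
  a <- (a + t(a)) / 2
  dimnames(a) <- dimnames(mats[[1]]$cc)
  mu_out <- mu; diag(mu_out) <- 0
  structure(list(a = a, mean_cc = mu_out, sd_cc = sdm, n_subjects = n),
            class = "group_network")
}

#' @export
print.group_network <- function(x, ...) {
  cat("<group_network> ", nrow(x$a), " regions, ", x$n_subjects,
      " subjects, ", sum(x$a[upper.tri(x$a)] > 0), " positive edges\n",
      sep = "")
  invisible(x)
}

#' Weighted graph container
#'
#' @param w symmetric nonnegative N x N weight matrix; the diagonal is
#'   forced to zero.
#' @param id graph identifier (used in partition provenance).
#' @return a `weighted_graph`: list with `w`, `strength` (k_i), `m`
#'   (total weight, half the matrix sum), `id`.
#' @export
weighted_graph <- function(w, id = "graph") {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) stop("weight matrix must be square")
  if (max(abs(w - t(w))) > 1e-12) stop("weight matrix must be symmetric")
  if (any(w < 0)) stop("weights must be nonnegative (positive-mask first)")
  w <- (w + t(w)) / 2
  diag(w) <- 0
  structure(list(w = w, strength = rowSums(w), m = sum(w) / 2, id = id),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat("<weighted_graph> ", nrow(x$w), " nodes, ",
      sum(x$w[upper.tri(x$w)] > 0), " edges, total weight ",
      signif(x$m, 5), "\n", sep = "")
  invisible(x)
}

#' Coerce pipeline objects to a weighted graph
#'
#' Connectivity matrices are positive-masked (negative correlations have no
#' weighted-graph interpretation here); group networks use their masked
#' ratio matrix.
#'
#' @param x a `weighted_graph`, `group_network`, `connectivity_matrix`, or
#'   plain matrix.
#' @param id graph identifier.
#' @return a `weighted_graph`.
#' @export
as_weighted_graph <- function(x, id = NULL) {
  if (inherits(x, "weighted_graph")) return(x)
  if (inherits(x, "group_network")) {
    return(weighted_graph(x$a, id = if (is.null(id)) "group_network" else id))
  }
  if (inherits(x, "connectivity_matrix")) {
    w <- x$cc
    w[w < 0] <- 0
    return(weighted_graph(w, id = if (is.null(id)) x$subject_id else id))
  }
  weighted_graph(x, id = if (is.null(id)) "graph" else id)
}

#' Keep the ne strongest edges of a graph
#'
#' Retains the `ne` largest strictly positive upper-triangle weights and
#' zeroes the rest; retained weights are unchanged. Ties at the cutoff are
#' broken toward lower (i, j) in lexicographic order, so the result is
#' deterministic and edge sets are nested in `ne`.
#'
#' @param g a `weighted_graph` (or anything [as_weighted_graph()] accepts).
#' @param ne number of edges to keep (1 <= ne <= positive edge count).
#' @return a `weighted_graph` with exactly `ne` edges.
#' @export
threshold_by_edge_count <- function(g, ne) {
  g <- as_weighted_graph(g)
  n <- nrow(g$w)
  ut <- which(upper.tri(g$w), arr.ind = TRUE)
  wts <- g$w[ut]
  pos <- wts > 0
  n_pos <- sum(pos)
  if (ne < 1 || ne > n_pos) {
    stop("ne must be in [1, ", n_pos, "] (strictly positive edges); got ",
         ne)
  }
  # order by decreasing weight, then row, then column: deterministic ties
  ord <- order(-wts[pos], ut[pos, 1], ut[pos, 2])
  keep <- which(pos)[ord[seq_len(ne)]]
  w2 <- matrix(0, n, n)
  w2[ut[keep, , drop = FALSE]] <- wts[keep]
  w2 <- w2 + t(w2)
  dimnames(w2) <- dimnames(g$w)
  weighted_graph(w2, id = paste0(g$id, "_ne", ne))
}
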