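#' Module partition objects
#'
#' @param assignment integer vector: module label per node, labels
#'   1..M contiguous.
#' @param Q modularity of the assignment on its source graph.
#' @param source graph identifier.
#' @return a `module_partition`.
#' @export
module_partition <- function(assignment, Q = NA_real_, source = "graph") {
  assignment <- as.integer(assignment)
  labs <- sort(unique(assignment))
  if (!identical(labs, seq_along(labs))) {
    assignment <- match(assignment, labs)  # force contiguous 1..M
  }
  structure(list(assignment = assignment, Q = Q, source = source,
                 n_modules = max(assignment)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("<module_partition> ", length(x$assignment), " nodes in ",
      x$n_modules, " modules; Q = ", signif(x$Q, 5), " [", x$source, "]\n",
      sep = "")
  invisible(x)
}

#' Weighted modularity Q of a partition
#'
#' Q = (1/2m) * sum_ij [a_ij - k_i k_j / 2m] delta(c_i, c_j), with k the
#' node strength and m the total weight (the weighted generalization of
#' degree and edge count).
#'
#' @param g a `weighted_graph` (or coercible).
#' @param assignment module labels per node (or a `module_partition`).
#' @return Q, a number in [-1, 1).
#' @export
modularity_q <- function(g, assignment) {
  g <- as_weighted_graph(g)
  if (inherits(assignment, "module_partition")) {
    assignment <- assignment$assignment
  }
  assignment <- as.integer(assignment)
  n <- nrow(g$w)
  if (length(assignment) != n || anyNA(assignment)) {
    stop("assignment must label all ", n, " nodes")
  }
  if (g$m <= 0) stop("graph has no weight (m = 0); Q undefined")
  k <- g$strength
  m2 <- 2 * g$m
  q <- 0
  for (c in unique(assignment)) {
    idx <- assignment == c
    q <- q + sum(g$w[idx, idx]) - sum(k[idx])^2 / m2
  }
  q / m2
}

# Modularity matrix B = A - k k^T / 2m of the full graph.
.modularity_matrix <- function(g) {
  g$w - tcrossprod(g$strength) / (2 * g$m)
}

# Leading eigenpair of a symmetric matrix with a deterministic sign
# convention (flip so the sum of entries is positive; first nonzero entry
# positive on an exact tie).
.leading_eig <- function(B) {
  e <- eigen(B, symmetric = TRUE)
  v <- e$vectors[, 1]
  s <- sum(v)
  if (s < 0 || (s == 0 && v[which(v != 0)[1]] < 0)) v <- -v
  list(value = e$values[1], vector = v)
}

# Kernighan-Lin style refinement of a bisection sign vector s on subgraph
# modularity matrix Bg: greedily flip the single node whose flip most
# increases s^T Bg s, until no flip improves. Returns the refined s.
.kl_refine <- function(Bg, s, tol = 1e-10) {
  ng <- length(s)
  Bs <- as.vector(Bg %*% s)
  max_iter <- 4L * ng * ng + 16L
  for (iter in seq_len(max_iter)) {
    gains <- -4 * s * Bs + 4 * diag(Bg)
    i <- which.max(gains)
    if (gains[i] <= tol) break
    s[i] <- -s[i]
    Bs <- Bs + 2 * s[i] * Bg[, i]
  }
  s
}

#' Detect modules by Newman's spectral algorithm
#'
#' Recursive bisection by the sign of the leading eigenvector of the
#' (generalized) modularity matrix B_ij = a_ij - k_i k_j / 2m, with
#' Newman's subgroup correction for the restricted matrix, followed after
#' each bisection by a Kernighan-Lin style single-node-move refinement
#' pass (on by default). A subgroup is indivisible when its leading
#' eigenvalue is <= 1e-10 or the best bisection gains <= 1e-10 modularity.
#' Disconnected components are partitioned independently. Module labels
#' are renumbered 1..M by descending module size (ties: lowest member
#' index first).
#'
#' @param g a `weighted_graph` (or coercible); weights must be
#'   nonnegative.
#' @param refine logical: apply the refinement pass (default TRUE).
#' @param tol indivisibility tolerance.
#' @return a `module_partition` with its Q.
#' @export
detect_modules <- function(g, refine = TRUE, tol = 1e-10) {
  g <- as_weighted_graph(g)
  n <- nrow(g$w)
  if (g$m <= 0) stop("graph has no weight (m = 0)")
  B <- .modularity_matrix(g)
  m2 <- 2 * g$m

  comp <- .components(g$w)
  assignment <- integer(n)
  next_label <- 0L

  divide <- function(nodes) {
    # returns a list of node-index vectors (the modules within `nodes`)
    if (length(nodes) == 1) return(list(nodes))
    Bg <- B[nodes, nodes, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)  # Newman's subgroup correction
    le <- .leading_eig(Bg)
    if (le$value <= tol) return(list(nodes))
    s <- ifelse(le$vector >= -1e-12, 1, -1)
    if (refine) s <- .kl_refine(Bg, s, tol)
    dq <- as.vector(s %*% Bg %*% s) / (2 * m2)
    if (dq <= tol || all(s == s[1])) return(list(nodes))
    c(divide(nodes[s > 0]), divide(nodes[s < 0]))
  }

  for (cp in comp) {
    mods <- if (length(cp) == 1) list(cp) else divide(cp)
    for (md in mods) {
      next_label <- next_label + 1L
      assignment[md] <- next_label
    }
  }

  # renumber by descending size, ties by lowest member index
  sizes <- tabulate(assignment)
  first <- vapply(seq_along(sizes), function(l) which(assignment == l)[1], 0L)
  ord <- order(-sizes, first)
  assignment <- match(assignment, ord)
  module_partition(assignment, Q = modularity_q(g, assignment),
                   source = g$id)
}

# Connected components of a nonnegative weight matrix (edges where w > 0).
.components <- function(w) {
  n <- nrow(w)
  seen <- logical(n)
  out <- list()
  adj <- w > 0
  for (i in seq_len(n)) {
    if (seen[i]) next
    frontier <- i
    seen[i] <- TRUE
    members <- i
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nb] <- TRUE
      members <- c(members, nb)
      frontier <- nb
    }
    out[[length(out) + 1]] <- sort(members)
  }
  out
}

#' Degree-preserving random equivalent of a graph
#'
#' Maslov-Sneppen double-edge swaps on the binarized topology (10 x
#' edge-count attempted swaps), then the original weight multiset is
#' reassigned to the rewired edges in random order. The binary degree
#' sequence and the total weight are preserved exactly.
#'
#' @param g a `weighted_graph` (>= 2 edges).
#' @param seed integer seed (reproducible).
#' @param swaps_per_edge attempted swaps per edge (default 10).
#' @return a rewired `weighted_graph`.
#' @export
random_equivalent <- function(g, seed, swaps_per_edge = 10) {
  g <- as_weighted_graph(g)
  n <- nrow(g$w)
  ut <- which(upper.tri(g$w) & g$w > 0, arr.ind = TRUE)
  n_edge <- nrow(ut)
  if (n_edge < 2) stop("need at least 2 edges to rewire")
  set.seed(as.integer(seed))
  ei <- ut[, 1]; ej <- ut[, 2]
  adj <- g$w > 0
  n_attempt <- ceiling(swaps_per_edge * n_edge)
  pick <- matrix(sample.int(n_edge, 2 * n_attempt, replace = TRUE),
                 ncol = 2)
  accepted <- 0L
  for (t in seq_len(n_attempt)) {
    e1 <- pick[t, 1]; e2 <- pick[t, 2]
    if (e1 == e2) next
    a <- ei[e1]; b <- ej[e1]; c <- ei[e2]; d <- ej[e2]
    # propose (a-b, c-d) -> (a-d, c-b)
    if (a == d || c == b || a == c || b == d) next
    if (adj[a, d] || adj[c, b]) next
    adj[a, b] <- adj[b, a] <- FALSE
    adj[c, d] <- adj[d, c] <- FALSE
    adj[a, d] <- adj[d, a] <- TRUE
    adj[c, b] <- adj[b, c] <- TRUE
    ej[e1] <- d; ej[e2] <- b
    if (ei[e1] > ej[e1]) { tmp <- ei[e1]; ei[e1] <- ej[e1]; ej[e1] <- tmp }
    if (ei[e2] > ej[e2]) { tmp <- ei[e2]; ei[e2] <- ej[e2]; ej[e2] <- tmp }
    accepted <- accepted + 1L
  }
  if (accepted == 0L) {
    warning("no legal double-edge swap found; returning weight-reshuffled ",
            "original topology")
  }
  wts <- g$w[ut]
  perm <- sample.int(n_edge)
  w2 <- matrix(0, n, n)
  w2[cbind(ei, ej)] <- wts[perm]
  w2 <- w2 + t(w2)
  dimnames(w2) <- dimnames(g$w)
  weighted_graph(w2, id = paste0(g$id, "_null", seed))
}

#' Q versus edge-count curves with random-network nulls
#'
#' For every subject and every edge count in the grid: sparsify to the ne
#' strongest positive edges, detect modules, record Q, and compare with
#' the mean/sd of Q over `n_null` seeded degree-preserving random
#' equivalents. Per edge count, groups are compared by Welch's two-sample
#' t-test on subject Qs, Bonferroni-corrected across the grid.
#'
#' @param cohorts named list (one entry per group) of lists of
#'   `connectivity_matrix`.
#' @param ne_grid integer vector of edge counts.
#' @param n_null null realizations per subject and edge count (default 100).
#' @param seed master seed for the null streams.
#' @param refine passed to [detect_modules()].
#' @return a `q_curve`: list with `per_subject` (data.frame subject_id,
#'   group, ne, Q, Q_random_mean, Q_random_sd) and `comparison`
#'   (data.frame ne, t, p, p_bonferroni).
#' @export
q_curve <- function(cohorts, ne_grid, n_null = 100, seed = 1L,
                    refine = TRUE) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1,
            !is.null(names(cohorts)))
  ne_grid <- as.integer(ne_grid)
  rows <- list()
  for (gname in names(cohorts)) {
    for (cm in cohorts[[gname]]) {
      wg <- as_weighted_graph(cm)
      for (ne in ne_grid) {
        gt <- threshold_by_edge_count(wg, ne)
        p <- detect_modules(gt, refine = refine)
        qn <- vapply(seq_len(n_null), function(r) {
          null_seed <- .substream_seed(seed, match(gname, names(cohorts)),
                                       r, salt = ne)
          detect_modules(random_equivalent(gt, null_seed),
                         refine = refine)$Q
        }, 0)
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = cm$subject_id, group = gname, ne = ne, Q = p$Q,
          Q_random_mean = mean(qn), Q_random_sd = stats::sd(qn))
      }
    }
  }
  per_subject <- do.call(rbind, rows)
  comparison <- NULL
  if (length(cohorts) == 2) {
    g1 <- names(cohorts)[1]; g2 <- names(cohorts)[2]
    comparison <- do.call(rbind, lapply(ne_grid, function(ne) {
      q1 <- per_subject$Q[per_subject$group == g1 & per_subject$ne == ne]
      q2 <- per_subject$Q[per_subject$group == g2 & per_subject$ne == ne]
      tt <- stats::t.test(q1, q2)  # Welch by default
      data.frame(ne = ne, t = unname(tt$statistic), p = tt$p.value)
    }))
    comparison$p_bonferroni <- pmin(1, comparison$p * length(ne_grid))
  }
  structure(list(per_subject = per_subject, comparison = comparison,
                 n_null = n_null, seed = seed),
            class = "q_curve")
}
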