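# Shared fixtures: tiny atlases, toy graphs, small cohort specs.

# 6-region toy atlas: 2 homotopic pairs (1,2) and (3,4), 2 midline regions.
toy_atlas <- function() {
  region_atlas(
    region_id = 1:6,
    name = c("A_L", "A_R", "B_L", "B_R", "M1", "M2"),
    hemisphere = c("left", "right", "left", "right", "midline", "midline"),
    homotopic_partner = c(2, 1, 4, 3, NA, NA),
    named_subsets = list(both_pairs = 1:4)
  )
}

# Two disconnected cliques of `size` nodes with unit weights.
two_cliques <- function(size = 4) {
  n <- 2 * size
  w <- matrix(0, n, n)
  w[1:size, 1:size] <- 1
  w[(size + 1):n, (size + 1):n] <- 1
  diag(w) <- 0
  weighted_graph(w, id = "two_cliques")
}

# Random weighted graph on n nodes, edge probability p, weights U(0.1, 1).
random_graph <- function(n, p = 0.5) {
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  present <- stats::runif(length(ut)) < p
  if (!any(present)) present[sample(length(present), 1)] <- TRUE
  w[ut[present]] <- stats::runif(sum(present), 0.1, 1)
  w <- w + t(w)
  weighted_graph(w)
}

# Small single-group cohort spec (fast default for unit tests).
small_spec <- function(n_subjects = 4, seed = 1, ...) {
  cohort_spec(groups = "CN", rho_homotopic = c(CN = 0.6),
              gmc_mean = c(CN = 0.55), n_subjects = n_subjects,
              seed = seed, ...)
}

# Connectivity matrix built directly from a given CC matrix.
cm_from_matrix <- function(cc, subject_id = "s1", group = "g") {
  cc <- (cc + t(cc)) / 2
  diag(cc) <- 1
  structure(list(subject_id = subject_id, group = group, cc = cc),
            class = "connectivity_matrix")
}
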