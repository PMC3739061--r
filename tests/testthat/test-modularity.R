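test_that("modularity Q matches closed forms and the naive double loop", {
  g <- two_cliques(4)
  expect_equal(modularity_q(g, rep(1, 8)), 0)                # one module
  expect_equal(modularity_q(g, rep(1:2, each = 4)), 0.5)     # the cliques
  # two nodes, one edge of any weight, singleton modules -> -0.5
  for (w in c(0.3, 1, 7)) {
    g2 <- weighted_graph(matrix(c(0, w, w, 0), 2, 2))
    expect_equal(modularity_q(g2, 1:2), -0.5)
  }
  # random graphs: grouped-sum implementation == naive double loop
  set.seed(5)
  for (r in 1:10) {
    gr <- random_graph(7)
    p <- sample(1:3, 7, replace = TRUE)
    expect_equal(modularity_q(gr, p), naive_q(gr$w, p), tolerance = 1e-12)
  }
  expect_error(modularity_q(weighted_graph(matrix(0, 3, 3)), rep(1, 3)),
               "m = 0")
})

test_that("Q is invariant under relabeling and node permutation", {
  set.seed(6)
  for (r in 1:5) {
    g <- random_graph(10)
    p <- sample(1:4, 10, replace = TRUE)
    relab <- match(p, sample(unique(p)))
    expect_equal(modularity_q(g, relab), modularity_q(g, p))
    perm <- sample(10)
    expect_equal(modularity_q(weighted_graph(g$w[perm, perm]), p[perm]),
                 modularity_q(g, p))
  }
})

test_that("detect_modules recovers disconnected cliques exactly", {
  g <- two_cliques(5)
  p <- detect_modules(g)
  expect_equal(p$n_modules, 2)
  expect_equal(p$Q, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(p$assignment[1:5])), 1)
  expect_equal(length(unique(p$assignment[6:10])), 1)
  # stored Q is reproducible from (graph, assignment)
  expect_equal(modularity_q(g, p$assignment), p$Q, tolerance = 1e-12)
  # rejects negative weights
  wneg <- g$w; wneg[1, 2] <- wneg[2, 1] <- -0.5
  expect_error(detect_modules(wneg), "nonnegative")
})

test_that("detected Q is near the exhaustive optimum on small graphs", {
  # reduced version of the 50-graph acceptance oracle (full run in
  # test-acceptance.R); also checks Q >= 0 (never worse than one module)
  set.seed(8)
  for (r in 1:10) {
    g <- random_graph(sample(4:7, 1))
    det <- detect_modules(g)
    opt <- best_partition_q(g)
    expect_gte(det$Q + 1e-12, 0)
    expect_gte(det$Q, 0.95 * opt - 1e-12)
  }
})

test_that("refinement never lowers Q", {
  set.seed(9)
  for (r in 1:10) {
    g <- random_graph(12, 0.4)
    expect_gte(detect_modules(g, refine = TRUE)$Q,
               detect_modules(g, refine = FALSE)$Q - 1e-12)
  }
})

test_that("random_equivalent preserves degrees and total weight", {
  set.seed(10)
  g <- random_graph(20, 0.3)
  null <- random_equivalent(g, seed = 123)
  expect_equal(rowSums(null$w > 0), rowSums(g$w > 0))  # binary degrees
  expect_equal(null$m, g$m, tolerance = 1e-12)         # weight multiset
  expect_equal(sort(null$w[upper.tri(null$w) & null$w > 0]),
               sort(g$w[upper.tri(g$w) & g$w > 0]))
  # seeded: reproducible, different seeds differ
  expect_identical(random_equivalent(g, seed = 123)$w, null$w)
  expect_false(identical(random_equivalent(g, seed = 124)$w, null$w))
  # a graph with no legal swap: star topology -> warning, weights reshuffled
  w_star <- matrix(0, 4, 4); w_star[1, 2:4] <- c(0.2, 0.5, 0.9)
  w_star <- w_star + t(w_star)
  expect_warning(ns <- random_equivalent(weighted_graph(w_star), seed = 1),
                 "no legal")
  expect_equal(rowSums(ns$w > 0), rowSums(w_star > 0))
})

test_that("planted-modular graphs beat their nulls in Q", {
  spec <- small_spec(n_subjects = 2, seed = 21)
  coh <- suppressMessages(simulate_cohort(spec))
  g <- threshold_by_edge_count(
    as_weighted_graph(subject_connectivity(coh$subjects[[1]])), 500)
  q_obs <- detect_modules(g)$Q
  q_null <- vapply(1:5, function(s) {
    detect_modules(random_equivalent(g, seed = s))$Q
  }, 0)
  expect_gt(q_obs, mean(q_null))
})

test_that("q_curve records per-subject nulls and Bonferroni-corrects", {
  spec <- cohort_spec(n_subjects = 3, T_len = 100, seed = 31)
  coh <- suppressMessages(simulate_cohort(spec))
  mats <- lapply(coh$subjects, subject_connectivity)
  gl <- vapply(mats, `[[`, "", "group")
  qc <- q_curve(split(mats, gl)[c("CN", "AD")], ne_grid = c(300, 600),
                n_null = 2, seed = 1)
  expect_equal(nrow(qc$per_subject), 6 * 2)  # one row per (subject, ne)
  expect_true(all(qc$comparison$p_bonferroni >= qc$comparison$p))
  expect_equal(qc$comparison$p_bonferroni,
               pmin(1, qc$comparison$p * 2))
  # grid of length 1: corrected p equals raw p
  qc1 <- q_curve(split(mats, gl)[c("CN", "AD")], ne_grid = 400,
                 n_null = 2, seed = 1)
  expect_equal(qc1$comparison$p_bonferroni, qc1$comparison$p)
})

test_that("identical-spec groups show no corrected Q difference", {
  # type-I control, reduced: 3 fixed-seed replicates, small cohorts
  clean <- vapply(1:3, function(r) {
    sa <- cohort_spec(groups = c("g1", "g2"), n_subjects = 4, T_len = 120,
                      rho_homotopic = c(g1 = 0.6, g2 = 0.6),
                      gmc_mean = c(g1 = 0.5, g2 = 0.5), seed = 500 + r)
    coh <- simulate_cohort(sa)
    mats <- lapply(coh$subjects, subject_connectivity)
    gl <- vapply(mats, `[[`, "", "group")
    qc <- q_curve(split(mats, gl), ne_grid = c(300, 600, 900), n_null = 1,
                  seed = r)
    all(qc$comparison$p_bonferroni > 0.05)
  }, TRUE)
  expect_gte(sum(clean), 2)
})
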