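#' Index A: mean homotopic (interhemispheric) connectivity
#'
#' The arithmetic mean of the raw correlation CC(ROI_L(i), ROI_R(i)) over
#' the homotopic pairs of a designated region set (default the 8 insula
#' module pairs). Negative correlations are not masked.
#'
#' @param cm a `connectivity_matrix`.
#' @param atlas a `region_atlas`.
#' @param pairs subset name (default `"insula_module_pairs"`) or region-id
#'   vector; pairs with both members in the set are used.
#' @return index A, a number in [-1, 1].
#' @export
index_a <- function(cm, atlas, pairs = "insula_module_pairs") {
  stopifnot(inherits(cm, "connectivity_matrix"),
            inherits(atlas, "region_atlas"))
  pr <- homotopic_pairs(atlas, pairs)
  if (nrow(pr) < 1) stop("no homotopic pairs in the requested set")
  li <- match(pr$left, atlas$region_id)
  ri <- match(pr$right, atlas$region_id)
  mean(cm$cc[cbind(li, ri)])
}

#' Index B: mean intrahemispheric connectivity among unilateral members
#'
#' Default mode (`"mean_pairs"`): the mean raw correlation over all
#' unordered distinct within-hemisphere region pairs of the set, left and
#' right pooled (2 * n(n-1)/2 terms, self-pairs excluded) — a bounded,
#' interpretable index. Literal mode reproduces the printed normalization:
#' the two full n x n within-hemisphere sums (including self-correlation
#' terms) divided by the number of pairs n, which can exceed 1.
#'
#' @param cm a `connectivity_matrix`.
#' @param atlas a `region_atlas`.
#' @param pairs subset name or region-id vector (needs >= 2 pairs).
#' @param mode `"mean_pairs"` (default) or `"literal"`.
#' @return index B.
#' @export
index_b <- function(cm, atlas, pairs = "insula_module_pairs",
                    mode = c("mean_pairs", "literal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cm, "connectivity_matrix"),
            inherits(atlas, "region_atlas"))
  pr <- homotopic_pairs(atlas, pairs)
  n <- nrow(pr)
  if (n < 2) stop("index B needs at least 2 pairs (got ", n, ")")
  li <- match(pr$left, atlas$region_id)
  ri <- match(pr$right, atlas$region_id)
  if (mode == "literal") {
    (sum(cm$cc[li, li]) + sum(cm$cc[ri, ri])) / n
  } else {
    offd <- function(idx) {
      s <- cm$cc[idx, idx]
      s[upper.tri(s)]
    }
    mean(c(offd(li), offd(ri)))
  }
}

#' Module-averaged gray matter concentration per subject
#'
#' @param gmc_table data.frame with columns subject_id, group, region_id,
#'   gmc (long format, as produced by [simulate_cohort()] or read from
#'   `gmc.tsv`).
#' @param atlas a `region_atlas`.
#' @param regions subset name (default `"insula_module_pairs"`, i.e. all
#'   16 insula-module regions) or region-id vector.
#' @return data.frame subject_id, group, gmc_module_mean.
#' @export
module_gmc <- function(gmc_table, atlas, regions = "insula_module_pairs") {
  stopifnot(is.data.frame(gmc_table),
            all(c("subject_id", "group", "region_id", "gmc") %in%
                  names(gmc_table)))
  ids <- atlas_subset(atlas, regions)
  subjects <- unique(gmc_table$subject_id)
  rows <- lapply(subjects, function(s) {
    sub <- gmc_table[gmc_table$subject_id == s, ]
    missing <- setdiff(ids, sub$region_id)
    if (length(missing)) {
      stop("subject ", s, " lacks GMC for region(s): ",
           paste(missing, collapse = ", "))
    }
    vals <- sub$gmc[match(ids, sub$region_id)]
    if (anyNA(vals)) {
      stop("subject ", s, " has missing GMC value(s) in the region set")
    }
    data.frame(subject_id = s, group = sub$group[1],
               gmc_module_mean = mean(vals))
  })
  do.call(rbind, rows)
}

#' Per-subject biomarker table
#'
#' Computes index A, index B and module-averaged GMC for every subject of
#' one or more cohorts.
#'
#' @param mats list of `connectivity_matrix` (with group labels set).
#' @param atlas a `region_atlas`.
#' @param gmc_table optional long-format GMC table (see [module_gmc()]).
#' @param pairs subset name for the indices (default insula module pairs).
#' @param index_b_mode passed to [index_b()].
#' @return data.frame subject_id, group, index_A, index_B
#'   (+ gmc_module_mean when a GMC table is given).
#' @export
biomarker_table <- function(mats, atlas, gmc_table = NULL,
                            pairs = "insula_module_pairs",
                            index_b_mode = "mean_pairs") {
  bt <- do.call(rbind, lapply(mats, function(cm) {
    data.frame(subject_id = cm$subject_id, group = cm$group,
               index_A = index_a(cm, atlas, pairs),
               index_B = index_b(cm, atlas, pairs, mode = index_b_mode))
  }))
  rownames(bt) <- NULL
  if (!is.null(gmc_table)) {
    g <- module_gmc(gmc_table, atlas, pairs)
    bt$gmc_module_mean <- g$gmc_module_mean[match(bt$subject_id,
                                                  g$subject_id)]
    if (anyNA(bt$gmc_module_mean)) {
      stop("GMC table lacks subject(s): ",
           paste(bt$subject_id[is.na(bt$gmc_module_mean)], collapse = ", "))
    }
  }
  bt
}

#' Residualize index A on gray matter concentration
#'
#' Ordinary least squares of index A on (intercept, module GMC) fitted on
#' the pooled sample; the residuals carry the connectivity signal with the
#' GMC-explained variance controlled out. With zero GMC variance the
#' residuals degrade to centered index A, with a warning.
#'
#' @param bt a biomarker table with columns index_A and gmc_module_mean.
#' @return `bt` with an added `residual_index_A` column (zero mean over
#'   the fitted sample).
#' @export
control_gmc <- function(bt) {
  stopifnot(is.data.frame(bt),
            all(c("index_A", "gmc_module_mean") %in% names(bt)))
  if (nrow(bt) < 3) stop("need at least 3 subjects to residualize")
  if (stats::var(bt$gmc_module_mean) == 0) {
    warning("GMC has zero variance; residuals are centered index A")
    bt$residual_index_A <- bt$index_A - mean(bt$index_A)
    return(bt)
  }
  fit <- stats::lm(index_A ~ gmc_module_mean, data = bt)
  bt$residual_index_A <- stats::resid(fit)
  bt
}

#' Two-group comparison of a biomarker
#'
#' Welch's two-sample t-test plus group means/SDs and Cohen's d with the
#' pooled standard deviation.
#'
#' @param bt a biomarker table.
#' @param measure column name to compare (e.g. `"index_A"`).
#' @param groups character vector of the two group labels; default the
#'   first two present.
#' @return list with `t`, `p`, `df`, `mean`, `sd`, `n` (per group), and
#'   `cohens_d`.
#' @export
group_stats <- function(bt, measure = "index_A", groups = NULL) {
  stopifnot(measure %in% names(bt))
  if (is.null(groups)) groups <- unique(bt$group)[1:2]
  if (length(groups) != 2) stop("exactly two groups required")
  x <- bt[[measure]][bt$group == groups[1]]
  y <- bt[[measure]][bt$group == groups[2]]
  if (length(x) < 2 || length(y) < 2) {
    stop("need >= 2 subjects per group (got ", length(x), ", ", length(y),
         ")")
  }
  tt <- stats::t.test(x, y)  # Welch
  sp <- sqrt(((length(x) - 1) * stats::var(x) +
                (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
  list(measure = measure, groups = groups,
       t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       mean = stats::setNames(c(mean(x), mean(y)), groups),
       sd = stats::setNames(c(stats::sd(x), stats::sd(y)), groups),
       n = stats::setNames(c(length(x), length(y)), groups),
       cohens_d = if (sp > 0) (mean(x) - mean(y)) / sp else 0)
}

#' ROC curve and AUC for one- or two-feature classification
#'
#' For a single feature the ROC is built directly from the feature values;
#' for several features a logistic score is fitted in-sample (no held-out
#' split) and the ROC is built from the fitted scores. The AUC is computed
#' by the rank (concordance) method with ties counted one half, and the
#' orientation is flipped when needed so that AUC >= 0.5 on the fitted
#' sample (recorded in `orientation`). In-sample ROC estimates are
#' optimistic; interpret accordingly.
#'
#' @param bt a biomarker table.
#' @param features character vector of column names (subset of index_A,
#'   index_B, gmc_module_mean, residual_index_A).
#' @param groups the two group labels: first = negative/reference class,
#'   second = positive/case class.
#' @param seed seed recorded with the result (the fit itself is
#'   deterministic).
#' @return a `classification_result`: list with `features`, `roc`
#'   (data.frame fpr, tpr, threshold), `auc`, `weights` (for combined
#'   features), `orientation`, `sens_spec` (per threshold), `seed`.
#' @export
classify <- function(bt, features = c("index_A", "gmc_module_mean"),
                     groups = NULL, seed = 1L) {
  stopifnot(all(features %in% names(bt)))
  if (is.null(groups)) groups <- unique(bt$group)[1:2]
  if (length(groups) != 2) stop("exactly two groups required")
  sel <- bt$group %in% groups
  bt <- bt[sel, , drop = FALSE]
  y <- as.integer(bt$group == groups[2])
  if (sum(y) < 2 || sum(1 - y) < 2) stop("need >= 2 subjects per group")
  weights <- NULL
  if (length(features) == 1) {
    score <- bt[[features]]
  } else {
    X <- as.matrix(bt[, features, drop = FALSE])
    fit <- suppressWarnings(
      stats::glm(y ~ X, family = stats::binomial()))
    if (!fit$converged || any(abs(stats::coef(fit)[-1]) > 1e3,
                              na.rm = TRUE)) {
      message("logistic fit degenerate (likely complete separation); ",
              "scores reduce to a rank ordering")
    }
    co <- stats::coef(fit)
    co[is.na(co)] <- 0
    weights <- stats::setNames(co, c("(Intercept)", features))
    score <- as.vector(co[1] + X %*% co[-1])
  }
  auc <- .rank_auc(score, y)
  orientation <- 1
  if (auc < 0.5) {
    score <- -score
    auc <- .rank_auc(score, y)
    orientation <- -1
  }
  roc <- .roc_curve(score, y)
  structure(list(features = features, groups = groups, roc = roc,
                 auc = auc, weights = weights, orientation = orientation,
                 seed = as.integer(seed)),
            class = "classification_result")
}

# AUC by the rank / concordance (Mann-Whitney) method, ties counted 1/2.
.rank_auc <- function(score, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(score, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Step ROC over all distinct thresholds, from (0,0) to (1,1).
.roc_curve <- function(score, y) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; yy <- y[ord]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  tp <- cumsum(yy); fp <- cumsum(1 - yy)
  # collapse tied scores: one point per distinct threshold
  last <- c(s[-1] != s[-length(s)], TRUE)
  data.frame(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp[last] / n0),
    tpr = c(0, tp[last] / n1),
    sensitivity = c(0, tp[last] / n1),
    specificity = c(1, 1 - fp[last] / n0))
}

#' Trapezoidal area under a step ROC curve
#'
#' Companion check for the rank-method AUC; the two agree to numerical
#' precision.
#'
#' @param roc data.frame with `fpr`, `tpr` as produced by [classify()].
#' @return the trapezoidal area.
#' @export
roc_trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}
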