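#' Synthetic cohort specification
#'
#' Describes the stated world the generator samples from: a block-modular
#' region covariance (within-module correlation `rho_within`, between
#' `rho_between`), elevated or suppressed homotopic correlation for a
#' designated pair set per group, Gaussian observation noise, and
#' group-shifted gray-matter-concentration (GMC) means. Defaults emulate
#' the study cohorts: 30 subjects per group, 175 time points, 116 regions,
#' a 4-module plan whose first module is the 16-region insula set, strong
#' homotopic coupling in controls (0.6) and weakened coupling (0.2) in the
#' patient group on those pairs, and GMC lowered in patients.
#'
#' @param atlas a `region_atlas` (default [aal116_atlas()]).
#' @param groups character vector of group labels, default `c("CN", "AD")`.
#' @param n_subjects subjects per group (recycled), default 30.
#' @param T_len time points per subject, default 175.
#' @param module_plan integer vector (one module label per region) or NULL
#'   for the default 4-module plan (insula pair set + 3 roughly equal
#'   blocks of the remaining regions).
#' @param rho_within within-module correlation target, default 0.6.
#' @param rho_between between-module correlation target, default 0.1.
#' @param rho_homotopic named numeric: per-group homotopic correlation for
#'   the affected pairs, default `c(CN = 0.6, AD = 0.2)`.
#' @param affected_pairs subset name (in the atlas) of the pairs carrying
#'   the group contrast, default `"insula_module_pairs"`.
#' @param gmc_mean named numeric: per-group GMC mean for affected regions,
#'   default `c(CN = 0.55, AD = 0.45)`; unaffected regions use the mean of
#'   the stated values.
#' @param gmc_sd GMC spread, default 0.05.
#' @param noise_sd independent observation noise s.d., default 0.1 (small
#'   so that observed correlations track the stated targets; jitter
#'   attenuates correlations by 1/(1+noise_sd^2)).
#' @param seed master seed; per-subject substreams are derived so existing
#'   subjects do not reshuffle when a cohort is extended.
#' @return a `cohort_spec` object (validated; covariance targets must be
#'   repairable to positive semi-definite, see [build_target_covariance()]).
#' @export
cohort_spec <- function(atlas = aal116_atlas(),
                        groups = c("CN", "AD"),
                        n_subjects = 30L,
                        T_len = 175L,
                        module_plan = NULL,
                        rho_within = 0.6,
                        rho_between = 0.1,
                        rho_homotopic = c(CN = 0.6, AD = 0.2),
                        affected_pairs = "insula_module_pairs",
                        gmc_mean = c(CN = 0.55, AD = 0.45),
                        gmc_sd = 0.05,
                        noise_sd = 0.1,
                        seed = 20130809L) {
  stopifnot(inherits(atlas, "region_atlas"))
  groups <- as.character(groups)
  n_subjects <- rep_len(as.integer(n_subjects), length(groups))
  if (is.null(module_plan)) module_plan <- .default_module_plan(atlas)
  module_plan <- as.integer(module_plan)
  if (length(module_plan) != atlas$n_regions || anyNA(module_plan)) {
    stop("module_plan must assign every region exactly once")
  }
  rhos <- c(rho_within, rho_between, unname(rho_homotopic))
  if (any(abs(rhos) >= 1)) stop("correlation targets must satisfy |rho| < 1")
  missing_g <- setdiff(groups, names(rho_homotopic))
  if (length(missing_g)) {
    stop("rho_homotopic lacks group(s): ", paste(missing_g, collapse = ", "))
  }
  if (length(setdiff(groups, names(gmc_mean)))) {
    stop("gmc_mean lacks group(s): ",
         paste(setdiff(groups, names(gmc_mean)), collapse = ", "))
  }
  # validate affected subset exists
  atlas_subset(atlas, affected_pairs)
  spec <- structure(
    list(atlas = atlas, groups = groups, n_subjects = n_subjects,
         T_len = as.integer(T_len), module_plan = module_plan,
         rho_within = rho_within, rho_between = rho_between,
         rho_homotopic = rho_homotopic, affected_pairs = affected_pairs,
         gmc_mean = gmc_mean, gmc_sd = gmc_sd, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
  # every group's target must be (repairably) PSD; errors out otherwise
  for (g in groups) build_target_covariance(spec, g)
  spec
}

# Default planted partition: module 1 = the affected pair set (the insula
# module), remaining regions split into 3 contiguous blocks.
.default_module_plan <- function(atlas,
                                 affected = "insula_module_pairs") {
  plan <- integer(atlas$n_regions)
  ins <- match(atlas_subset(atlas, affected), atlas$region_id)
  plan[ins] <- 1L
  rest <- which(plan == 0L)
  plan[rest] <- 1L + as.integer(cut(seq_along(rest), breaks = 3,
                                    labels = FALSE))
  plan
}

#' Target region correlation matrix for one group
#'
#' Unit diagonal; `rho_within` inside planted modules, `rho_between`
#' across, overridden by the group's homotopic correlation on the affected
#' pairs. If the construction is indefinite it is projected to the nearest
#' positive semi-definite matrix by clipping negative eigenvalues at zero
#' and re-normalizing to unit diagonal; an adjustment larger than 0.05 in
#' any entry is an error (the requested contrasts are inconsistent).
#'
#' @param spec a `cohort_spec`.
#' @param group group label.
#' @return list with `sigma` (the N x N correlation matrix) and
#'   `max_adjustment` (largest absolute entry change from the PSD repair).
#' @export
build_target_covariance <- function(spec, group) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!group %in% spec$groups) stop("unknown group: ", group)
  atlas <- spec$atlas
  n <- atlas$n_regions
  plan <- spec$module_plan
  same <- outer(plan, plan, "==")
  sigma <- ifelse(same, spec$rho_within, spec$rho_between)
  pairs <- homotopic_pairs(atlas, spec$affected_pairs)
  li <- match(pairs$left, atlas$region_id)
  ri <- match(pairs$right, atlas$region_id)
  rho_h <- spec$rho_homotopic[[group]]
  sigma[cbind(li, ri)] <- rho_h
  sigma[cbind(ri, li)] <- rho_h
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    vals <- pmax(ev$values, 0)
    repaired <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(repaired))
    repaired <- repaired / tcrossprod(d)
    adj <- max(abs(repaired - sigma))
    if (adj > 0.05) {
      stop("correlation targets are irreparably indefinite ",
           "(max adjustment ", signif(adj, 3),
           " > 0.05); use weaker contrasts")
    }
    message("PSD repair applied to target covariance (max adjustment ",
            signif(adj, 3), ")")
    sigma <- (repaired + t(repaired)) / 2
    diag(sigma) <- 1
    max_adj <- adj
  } else {
    max_adj <- 0
  }
  list(sigma = sigma, max_adjustment = max_adj)
}

# Deterministic per-subject substream seed below 2^31, derived from the
# master seed, the group index and the subject index. Adding subjects or
# groups never reshuffles existing ones.
.substream_seed <- function(master, group_idx, subj_idx, salt = 0L) {
  s <- (as.double(master) * 2654435761 + group_idx * 40503 +
          subj_idx * 97 + salt * 1299709) %% 2147483647
  as.integer(s)
}

#' Simulate a multi-subject cohort
#'
#' Each subject's T x N matrix is T independent draws from a zero-mean
#' multivariate normal with the group's target correlation, plus
#' independent Gaussian observation noise of s.d. `noise_sd`. GMC values
#' are drawn per subject and region from
#' N(gmc_mean[group or affected region], gmc_sd); only the affected pair
#' regions carry the group shift, all others share the midpoint mean.
#' Fully reproducible: subject k of group g depends only on
#' (seed, g, k).
#'
#' @param spec a `cohort_spec`.
#' @return list with `subjects` (list of `subject_timeseries`), `gmc`
#'   (data.frame subject_id, group, region_id, gmc) and `groups`
#'   (data.frame subject_id, group).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  atlas <- spec$atlas
  n_reg <- atlas$n_regions
  if (spec$T_len < n_reg) {
    message("T (", spec$T_len, ") < number of regions (", n_reg,
            "): sample covariance will be rank-deficient (expected for ",
            "fMRI-like data)")
  }
  affected_idx <- match(atlas_subset(atlas, spec$affected_pairs),
                        atlas$region_id)
  base_gmc <- mean(spec$gmc_mean[spec$groups])
  subjects <- list()
  gmc_rows <- list()
  for (gi in seq_along(spec$groups)) {
    g <- spec$groups[gi]
    # symmetric square root: robust to the (PSD but singular) repaired case
    ev <- eigen(build_target_covariance(spec, g)$sigma, symmetric = TRUE)
    sqrt_R <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
    mu <- rep(base_gmc, n_reg)
    mu[affected_idx] <- spec$gmc_mean[[g]]
    for (k in seq_len(spec$n_subjects[gi])) {
      sid <- sprintf("%s_%02d", g, k)
      set.seed(.substream_seed(spec$seed, gi, k))
      z <- matrix(stats::rnorm(spec$T_len * n_reg), spec$T_len, n_reg)
      x <- z %*% sqrt_R +
        spec$noise_sd * matrix(stats::rnorm(spec$T_len * n_reg),
                               spec$T_len, n_reg)
      subjects[[sid]] <- subject_timeseries(sid, x, atlas, group = g)
      gmc_rows[[sid]] <- data.frame(
        subject_id = sid, group = g, region_id = atlas$region_id,
        gmc = stats::rnorm(n_reg, mu, spec$gmc_sd))
    }
  }
  gmc <- do.call(rbind, c(gmc_rows, list(make.row.names = FALSE)))
  groups <- data.frame(
    subject_id = vapply(subjects, `[[`, "", "subject_id"),
    group = vapply(subjects, `[[`, "", "group"),
    row.names = NULL)
  list(subjects = subjects, gmc = gmc, groups = groups)
}

#' Write a simulated cohort to a directory
#'
#' One TSV per subject (`ts_<subject_id>.tsv`), a `gmc.tsv` long-format
#' table and a `groups.tsv` label file.
#'
#' @param cohort result of [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (s in cohort$subjects) {
    write_timeseries(s, file.path(out_dir,
                                  paste0("ts_", s$subject_id, ".tsv")))
  }
  utils::write.table(cohort$gmc, file.path(out_dir, "gmc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$groups, file.path(out_dir, "groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
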