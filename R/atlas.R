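#' Region atlas objects
#'
#' A `region_atlas` describes the parcellation every other stage of the
#' pipeline speaks: region identities (1-based ids, as in the AAL
#' convention), hemisphere labels, homotopic (left-right mirror) pairing,
#' and named region subsets such as the 8 homotopic pairs of the insula
#' module. All interfaces use 1-based region ids.
#'
#' @param region_id integer vector of 1-based region ids (unique).
#' @param name character vector of region labels.
#' @param hemisphere character vector, each one of `"left"`, `"right"`,
#'   `"midline"`.
#' @param homotopic_partner integer vector: partner region id, or `NA` for
#'   midline regions.
#' @param named_subsets named list mapping subset name to integer vector of
#'   region ids.
#' @return A `region_atlas` object (list with the validated fields plus
#'   `n_regions`).
#' @export
region_atlas <- function(region_id, name, hemisphere, homotopic_partner,
                         named_subsets = list()) {
  region_id <- as.integer(region_id)
  n <- length(region_id)
  if (anyDuplicated(region_id)) {
    stop("duplicate region ids: ",
         paste(unique(region_id[duplicated(region_id)]), collapse = ", "))
  }
  if (length(name) != n || length(hemisphere) != n ||
      length(homotopic_partner) != n) {
    stop("atlas columns must all have length ", n)
  }
  hemisphere <- as.character(hemisphere)
  bad <- setdiff(unique(hemisphere), c("left", "right", "midline"))
  if (length(bad)) stop("invalid hemisphere label: ", paste(bad, collapse = ", "))
  homotopic_partner <- as.integer(homotopic_partner)

  idx <- match(homotopic_partner, region_id)  # position of partner, NA ok
  for (k in seq_len(n)) {
    p <- homotopic_partner[k]
    if (hemisphere[k] == "midline") {
      if (!is.na(p)) {
        stop("midline region ", region_id[k], " must not have a partner")
      }
      next
    }
    if (is.na(p)) {
      stop("non-midline region ", region_id[k], " has no homotopic partner")
    }
    if (is.na(idx[k])) {
      stop("region ", region_id[k], " names unknown partner ", p)
    }
    back <- homotopic_partner[idx[k]]
    if (is.na(back) || back != region_id[k]) {
      stop("asymmetric homotopic pairing: ", region_id[k], " -> ", p,
           " but ", p, " -> ", ifelse(is.na(back), "none", back))
    }
    hemis <- sort(c(hemisphere[k], hemisphere[idx[k]]))
    if (!identical(hemis, c("left", "right"))) {
      stop("pair (", region_id[k], ", ", p,
           ") must contain one left and one right region")
    }
  }

  named_subsets <- lapply(named_subsets, as.integer)
  for (nm in names(named_subsets)) {
    missing <- setdiff(named_subsets[[nm]], region_id)
    if (length(missing)) {
      stop("subset '", nm, "' names unknown regions: ",
           paste(missing, collapse = ", "))
    }
  }

  structure(
    list(n_regions = n, region_id = region_id, name = as.character(name),
         hemisphere = hemisphere, homotopic_partner = homotopic_partner,
         named_subsets = named_subsets),
    class = "region_atlas"
  )
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("<region_atlas> ", x$n_regions, " regions, ",
      nrow(homotopic_pairs(x)), " homotopic pairs, ",
      sum(x$hemisphere == "midline"), " midline regions\n", sep = "")
  if (length(x$named_subsets)) {
    cat("  subsets:", paste(names(x$named_subsets), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Homotopic pairs of an atlas
#'
#' @param atlas a `region_atlas`.
#' @param subset optional subset name; restricts to pairs with both members
#'   in the named subset.
#' @return data.frame with columns `left`, `right` (region ids), one row
#'   per pair.
#' @export
homotopic_pairs <- function(atlas, subset = NULL) {
  stopifnot(inherits(atlas, "region_atlas"))
  keep <- atlas$hemisphere == "left" & !is.na(atlas$homotopic_partner)
  left <- atlas$region_id[keep]
  right <- atlas$homotopic_partner[keep]
  if (!is.null(subset)) {
    ids <- atlas_subset(atlas, subset)
    sel <- left %in% ids & right %in% ids
    left <- left[sel]; right <- right[sel]
  }
  data.frame(left = left, right = right)
}

#' Look up a named region subset
#'
#' @param atlas a `region_atlas`.
#' @param subset subset name, or an integer vector of region ids which is
#'   validated and passed through.
#' @return integer vector of region ids.
#' @export
atlas_subset <- function(atlas, subset) {
  stopifnot(inherits(atlas, "region_atlas"))
  if (is.numeric(subset)) {
    ids <- as.integer(subset)
    missing <- setdiff(ids, atlas$region_id)
    if (length(missing)) {
      stop("unknown region ids: ", paste(missing, collapse = ", "))
    }
    return(ids)
  }
  if (!subset %in% names(atlas$named_subsets)) {
    stop("unknown subset '", subset, "'; available: ",
         paste(names(atlas$named_subsets), collapse = ", "))
  }
  atlas$named_subsets[[subset]]
}

# Region ids (odd left / even right) of the 8 homotopic pairs making up the
# insula module: inferior frontal operculum, area triangularis, insula,
# putamen, globus pallidus, transverse temporal (Heschl), superior temporal,
# superior temporal pole.
.insula_module_left <- c(11L, 13L, 29L, 73L, 75L, 79L, 81L, 83L)

.aal116_names <- c(
  "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
  "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
  "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
  "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
  "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
  "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
  "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
  "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
  "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
  "Pallidum", "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
  "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf", "Cerebelum_Crus1",
  "Cerebelum_Crus2", "Cerebelum_3", "Cerebelum_4_5", "Cerebelum_6",
  "Cerebelum_7b", "Cerebelum_8", "Cerebelum_9", "Cerebelum_10")

.aal116_vermis <- c("Vermis_1_2", "Vermis_3", "Vermis_4_5", "Vermis_6",
                    "Vermis_7", "Vermis_8", "Vermis_9", "Vermis_10")

#' The bundled 116-region AAL atlas
#'
#' Follows the conventional AAL ordering: ids 1-108 alternate left (odd)
#' and right (even) hemisphere with consecutive odd/even ids homotopic,
#' ids 109-116 are midline (cerebellar vermis) regions. Ships the
#' `"insula_module_pairs"` subset: the 16 regions (8 homotopic pairs)
#' of the insula module.
#'
#' @return a `region_atlas` with 116 regions, 54 pairs, 8 midline regions.
#' @export
aal116_atlas <- function() {
  ids <- 1:116
  name <- c(rbind(paste0(.aal116_names, "_L"), paste0(.aal116_names, "_R")),
            .aal116_vermis)
  hemi <- c(rep(c("left", "right"), 54), rep("midline", 8))
  partner <- c(rbind(seq(2, 108, 2), seq(1, 107, 2)), rep(NA_integer_, 8))
  region_atlas(ids, name, hemi, partner,
               named_subsets = list(
                 insula_module_pairs = sort(c(.insula_module_left,
                                              .insula_module_left + 1L))))
}

#' Read a region atlas from a TSV file
#'
#' The file must have a header with columns `region_id`, `name`,
#' `hemisphere`, `homotopic_partner` (empty or NA partner for midline
#' regions). Subset definitions are not part of the file format and are
#' supplied via `named_subsets`.
#'
#' @param path TSV file path.
#' @param named_subsets named list of region-id vectors (optional).
#' @return a validated `region_atlas`.
#' @export
read_atlas <- function(path, named_subsets = list()) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("region_id", "name", "hemisphere", "homotopic_partner")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("atlas file lacks columns: ", paste(missing, collapse = ", "))
  }
  region_atlas(df$region_id, df$name, df$hemisphere,
               suppressWarnings(as.integer(df$homotopic_partner)),
               named_subsets = named_subsets)
}

#' Write a region atlas to TSV
#'
#' @param atlas a `region_atlas`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "region_atlas"))
  df <- data.frame(region_id = atlas$region_id, name = atlas$name,
                   hemisphere = atlas$hemisphere,
                   homotopic_partner = atlas$homotopic_partner)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
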