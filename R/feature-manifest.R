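# The feature manifest: the authoritative enumeration of every single-cell
# feature the extractor emits, in output order. Names follow
#   <channel>.<compartment>.<family>.<stat>
# with channel "none" for purely geometric families and an ordered channel
# pair (e.g. "junction_actin") for colocalization.

vp_intensity_stats <- c("integrated", "mean", "median", "sd", "mad", "min",
                        "max", "q01", "q05", "q10", "q25", "q75", "q90",
                        "q95", "q99", "iqr", "cv", "skewness", "kurtosis",
                        "entropy", "mass_displacement")
vp_shape_stats <- c("area", "perimeter", "radius_mean", "radius_sd",
                    "radius_min", "radius_max", "equiv_diameter",
                    "form_factor")
vp_moment_stats <- c("eccentricity", "major_axis", "minor_axis",
                     "orientation", "mu20", "mu11", "mu02")
vp_texture_stats <- c("asm", "contrast", "correlation", "variance",
                      "homogeneity", "sum_average", "sum_variance",
                      "sum_entropy", "entropy", "diff_variance",
                      "diff_entropy", "imc1", "imc2")
vp_distribution_stats <- c("frac_ring1", "frac_ring2", "frac_ring3",
                           "frac_ring4", "radial_mean", "radial_cv")
vp_coloc_stats <- c("pearson", "manders_m1", "manders_m2", "overlap")

vp_intensity_compartments <- c("cell", "nucleus", "cytoplasm", "membrane",
                               "cytoring")
vp_texture_compartments <- c("cell", "nucleus", "cytoplasm")
vp_coloc_pairs <- list(c("junction", "actin"), c("junction", "mito"),
                       c("actin", "mito"))

#' Enumerate the single-cell feature manifest
#'
#' Returns one row per feature column produced by [extract_site()], in
#' output order, with its channel, compartment, family and statistic. The
#' manifest is generated from the same constants the extractor uses, so the
#' two cannot drift apart; its length (>= 800 features) is asserted in the
#' test suite.
#'
#' @param texture_distances co-occurrence distances in pixels.
#' @return a data frame with columns `name`, `channel`, `compartment`,
#'   `family`, `stat`.
#' @export
feature_manifest <- function(texture_distances = c(1L, 3L)) {
  key <- paste(texture_distances, collapse = ",")
  cached <- .manifest_cache[[key]]
  if (!is.null(cached)) return(cached)
  rows <- list()
  add <- function(channel, compartment, family, stat) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = paste(channel, compartment, family, stat, sep = "."),
      channel = channel, compartment = compartment, family = family,
      stat = stat, stringsAsFactors = FALSE)
  }
  for (comp in c("cell", "nucleus")) {
    for (s in vp_shape_stats) add("none", comp, "shape", s)
  }
  add("none", "nucleus", "shape", "area_ratio")
  for (comp in c("cell", "nucleus")) {
    for (s in vp_moment_stats) add("none", comp, "moment", s)
  }
  for (ch in vp_channels) {
    for (comp in vp_intensity_compartments) {
      for (s in vp_intensity_stats) add(ch, comp, "intensity", s)
    }
  }
  for (ch in vp_channels) {
    for (comp in vp_texture_compartments) {
      for (d in texture_distances) {
        for (s in vp_texture_stats) {
          add(ch, comp, "texture", sprintf("%s.d%d", s, d))
        }
      }
    }
  }
  for (ch in vp_channels) {
    for (s in vp_distribution_stats) add(ch, "cell", "distribution", s)
  }
  for (pair in vp_coloc_pairs) {
    ch <- paste(pair, collapse = "_")
    for (comp in vp_texture_compartments) {
      for (s in vp_coloc_stats) add(ch, comp, "colocalization", s)
    }
  }
  for (other in c("junction", "actin", "mito")) {
    ch <- paste("nuclei", other, sep = "_")
    for (s in vp_coloc_stats) add(ch, "nucleus", "colocalization", s)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  .manifest_cache[[key]] <- out
  out
}

.manifest_cache <- new.env(parent = emptyenv())

# metadata columns preceding the feature block in every feature table
vp_meta_cols <- c("plate", "well", "site", "sample_id", "group", "replicate",
                  "label", "centroid_x", "centroid_y")

#' Feature columns of a feature table
#'
#' @param table a feature table as returned by [extract_site()] or
#'   [extract_plate_features()].
#' @return character vector of feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(colnames(table), c(vp_meta_cols, "imputed_any"))
}
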