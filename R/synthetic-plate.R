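#' Plate design for a synthetic assay run
#'
#' Describes how samples, wells and imaging sites are laid out across plates.
#' Every sample belongs to one group, occupies `replicate_wells_per_sample`
#' adjacent wells on a single plate, and each well is imaged at
#' `sites_per_well` non-overlapping sites. Samples of each group are
#' distributed across plates round-robin so that every plate carries a
#' balanced group mix.
#'
#' @param plates character vector of plate ids.
#' @param samples_per_group named integer vector: group label -> number of
#'   samples.
#' @param replicate_wells_per_sample replicate wells exposed per sample
#'   (default 3, the assay's standard layout).
#' @param sites_per_well imaged sites per well (default 8).
#' @param plate_effect named numeric vector of per-plate multiplicative
#'   intensity factors (default 1 for every plate).
#' @param image_size side length of each site image, pixels.
#' @return a `plate_design` object.
#' @export
plate_design <- function(plates,
                         samples_per_group,
                         replicate_wells_per_sample = 3L,
                         sites_per_well = 8L,
                         plate_effect = NULL,
                         image_size = 192L) {
  stopifnot(length(plates) >= 1L, !anyDuplicated(plates))
  if (is.null(names(samples_per_group)) || any(samples_per_group < 1)) {
    stop("`samples_per_group` must be a named vector of positive counts")
  }
  if (!is_count(sites_per_well)) stop("`sites_per_well` must be >= 1")
  if (!is_count(replicate_wells_per_sample)) {
    stop("`replicate_wells_per_sample` must be >= 1")
  }
  if (is.null(plate_effect)) {
    plate_effect <- stats::setNames(rep(1, length(plates)), plates)
  }
  if (!all(plates %in% names(plate_effect))) {
    stop("`plate_effect` must name every plate")
  }
  structure(list(plates = as.character(plates),
                 samples_per_group = samples_per_group,
                 replicate_wells_per_sample = as.integer(replicate_wells_per_sample),
                 sites_per_well = as.integer(sites_per_well),
                 plate_effect = plate_effect[plates],
                 image_size = as.integer(image_size)),
            class = "plate_design")
}

#' Expand a plate design into a per-image layout table
#'
#' @param design a [plate_design()].
#' @return a data frame with one row per image site (not per channel):
#'   columns `plate`, `well`, `site`, `sample_id`, `group`, `replicate`.
#' @export
plate_layout <- function(design) {
  stopifnot(inherits(design, "plate_design"))
  groups <- names(design$samples_per_group)
  samples <- data.frame(
    sample_id = unlist(lapply(groups, function(g)
      sprintf("%s_%02d", g, seq_len(design$samples_per_group[[g]])))),
    group = rep(groups, design$samples_per_group),
    stringsAsFactors = FALSE)
  # round-robin over plates, interleaving groups so plates stay balanced
  samples <- samples[order(stats::ave(seq_len(nrow(samples)), samples$group,
                                      FUN = seq_along), samples$group), ]
  samples$plate <- design$plates[(seq_len(nrow(samples)) - 1L) %%
                                   length(design$plates) + 1L]
  rows <- list()
  for (p in design$plates) {
    sp <- samples[samples$plate == p, , drop = FALSE]
    wi <- 0L
    for (k in seq_len(nrow(sp))) {
      for (r in seq_len(design$replicate_wells_per_sample)) {
        wi <- wi + 1L
        well <- sprintf("%s%02d", LETTERS[(wi - 1L) %/% 12L + 1L],
                        (wi - 1L) %% 12L + 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          plate = p, well = well, site = seq_len(design$sites_per_well),
          sample_id = sp$sample_id[k], group = sp$group[k], replicate = r,
          stringsAsFactors = FALSE)
      }
    }
  }
  layout <- do.call(rbind, rows)
  rownames(layout) <- NULL
  layout
}

#' Generate a full synthetic plate set
#'
#' Renders every site of the design with the phenotype parameters of its
#' group, applies the per-plate intensity effect, and returns images, the
#' layout table, and the per-site ground truth.
#'
#' @param design a [plate_design()].
#' @param group_params named list: group label -> [phenotype_params()].
#' @param seed master integer seed; per-site seeds are derived from it.
#' @return a list with `sites` (list of `image_site`), `layout` (data frame,
#'   one row per site), and `truth` (list of `ground_truth`, aligned with
#'   `sites`).
#' @export
generate_plate_set <- function(design, group_params, seed) {
  layout <- plate_layout(design)
  missing <- setdiff(unique(layout$group), names(group_params))
  if (length(missing)) {
    stop("missing phenotype parameters for group(s): ",
         paste(missing, collapse = ", "))
  }
  sites <- vector("list", nrow(layout))
  truth <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    gs <- generate_layout_site(design, group_params, seed, layout, i)
    sites[[i]] <- gs$site
    truth[[i]] <- gs$truth
  }
  list(sites = sites, layout = layout, truth = truth)
}

# single-site worker shared by generate_plate_set() and the streaming
# pipeline in extract_plate_features(); row `i` indexes `layout`
generate_layout_site <- function(design, group_params, seed, layout, i) {
  generate_site(group_params[[layout$group[i]]],
                seed = derive_seed(seed, i),
                size = design$image_size,
                plate = layout$plate[i], well = layout$well[i],
                site = layout$site[i],
                intensity_scale = design$plate_effect[[layout$plate[i]]])
}
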