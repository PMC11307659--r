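# End-to-end assay pipeline over synthetic plate sets, plus the canned
# study designs used throughout the documentation and tests.

#' Standard synthetic assay design and parameters
#'
#' `standard_assay_design()` and `standard_assay_params()` define the
#' package's reference dataset: 2 plates with a multiplicative batch
#' effect, 3 phenotype groups (quiescent, activated, severe) of 2 samples
#' each, 3 replicate wells per sample and 8 sites per well (144 sites,
#' about 5,000 cells at 35 cells per 160-px site). The group phenotypes
#' encode a graded endothelial activation: stress-fiber gain, junction
#' roughening, elongation, and — dominating the severe group —
#' mitochondrial fragmentation. Mild vignetting and a small artifact rate
#' exercise the QC and illumination-correction stages.
#'
#' @return a [plate_design()] / named list of [phenotype_params()].
#' @export
standard_assay_design <- function() {
  plate_design(plates = c("P1", "P2"),
               samples_per_group = c(quiescent = 2L, activated = 2L,
                                     severe = 2L),
               replicate_wells_per_sample = 3L,
               sites_per_well = 8L,
               plate_effect = c(P1 = 1.0, P2 = 1.15),
               image_size = 160L)
}

#' @rdname standard_assay_design
#' @export
standard_assay_params <- function() {
  base <- list(cell_density = 35, channel_snr = 8, vignette_amplitude = 0.25,
               artifact_rate = 0.02)
  list(
    quiescent = do.call(phenotype_params, c(base, list(
      elongation = 1.10, stress_fiber_level = 0.10,
      junction_irregularity = 1.0, mito_fragmentation = 0.15))),
    activated = do.call(phenotype_params, c(base, list(
      elongation = 1.45, stress_fiber_level = 0.55,
      junction_irregularity = 2.5, mito_fragmentation = 0.35))),
    severe = do.call(phenotype_params, c(base, list(
      elongation = 1.60, stress_fiber_level = 0.75,
      junction_irregularity = 3.5, mito_fragmentation = 0.80))))
}

#' Synthetic dose-response (stimulant) experiment
#'
#' One plate, three conditions with 5 replicate wells and 8 sites each:
#' an unstimulated monolayer and two strongly perturbed phenotypes
#' emulating high-dose cytokine and endotoxin responses (large, documented
#' phenotype offsets). Used for validating the classification pipeline on
#' well-level fingerprints.
#'
#' @return a [plate_design()] / named list of [phenotype_params()].
#' @export
stimulant_design <- function() {
  plate_design(plates = "P1",
               samples_per_group = c(unstimulated = 1L, tnf_high = 1L,
                                     lps_high = 1L),
               replicate_wells_per_sample = 5L,
               sites_per_well = 8L,
               image_size = 160L)
}

#' @rdname stimulant_design
#' @export
stimulant_params <- function() {
  base <- list(cell_density = 30, channel_snr = 8, vignette_amplitude = 0.2)
  list(
    unstimulated = do.call(phenotype_params, c(base, list(
      elongation = 1.10, stress_fiber_level = 0.10,
      junction_irregularity = 1.0, mito_fragmentation = 0.15))),
    tnf_high = do.call(phenotype_params, c(base, list(
      elongation = 1.80, stress_fiber_level = 0.80,
      junction_irregularity = 3.0, mito_fragmentation = 0.30))),
    lps_high = do.call(phenotype_params, c(base, list(
      elongation = 1.15, stress_fiber_level = 0.90,
      junction_irregularity = 4.0, mito_fragmentation = 0.70))))
}

#' Extract the single-cell feature table for a whole synthetic plate set
#'
#' Walks the design site by site: a first pass generates the images,
#' computes QC records and estimates per-plate/channel illumination fields
#' from a subsample of sites; the second pass corrects each passing site,
#' segments it and extracts its features. With `cache_images = FALSE`
#' sites are regenerated deterministically in the second pass instead of
#' being held in memory. Missing values are imputed by per-plate medians.
#'
#' @param design a [plate_design()].
#' @param group_params named list of [phenotype_params()] per group.
#' @param seed master seed for the generator.
#' @param qc discard sites failing [flag_outliers()]?
#' @param illumination estimate and apply illumination correction?
#' @param seg_params a [segmentation_params()].
#' @param n_illum_sites sites per plate used for field estimation.
#' @param cache_images keep the generated images of the first pass in
#'   memory instead of regenerating them (faster; disable for very large
#'   designs).
#' @param verbose print progress.
#' @return a list: `features` (imputed feature table with layout metadata),
#'   `qc` (flagged records), `illumination` (fields per plate/channel),
#'   `layout`.
#' @export
extract_plate_features <- function(design, group_params, seed,
                                   qc = TRUE, illumination = TRUE,
                                   seg_params = segmentation_params(),
                                   n_illum_sites = 16L, cache_images = TRUE,
                                   verbose = FALSE) {
  layout <- plate_layout(design)
  missing <- setdiff(unique(layout$group), names(group_params))
  if (length(missing)) {
    stop("missing phenotype parameters for group(s): ",
         paste(missing, collapse = ", "))
  }
  qcrecs <- vector("list", nrow(layout))
  illum_imgs <- list()
  illum_pick <- integer(0)
  if (illumination) {
    illum_pick <- unlist(lapply(unique(layout$plate), function(p) {
      rows <- which(layout$plate == p)
      rows[unique(round(seq(1, length(rows),
                            length.out = min(n_illum_sites, length(rows)))))]
    }))
  }
  cached <- if (cache_images) vector("list", nrow(layout)) else NULL
  for (i in seq_len(nrow(layout))) {
    gs <- generate_layout_site(design, group_params, seed, layout, i)
    if (cache_images) cached[[i]] <- gs$site
    if (qc) {
      qcrecs[[i]] <- do.call(rbind, lapply(vp_channels, function(ch) {
        compute_qc(gs$site$channels[[ch]], plate = layout$plate[i],
                   well = layout$well[i], site = layout$site[i], channel = ch)
      }))
    }
    if (i %in% illum_pick) {
      p <- layout$plate[i]
      for (ch in vp_channels) {
        illum_imgs[[p]][[ch]] <- c(illum_imgs[[p]][[ch]] %||% list(),
                                   list(gs$site$channels[[ch]]))
      }
    }
  }
  qcrecs <- if (qc) flag_outliers(do.call(rbind, qcrecs)) else NULL
  fields <- NULL
  if (illumination) {
    fields <- lapply(illum_imgs, function(by_ch) {
      lapply(by_ch, estimate_illumination)
    })
  }
  keep <- seq_len(nrow(layout))
  if (qc) {
    sitekey <- paste(qcrecs$plate, qcrecs$well, qcrecs$site, sep = ":")
    ok_sites <- unique(sitekey[qcrecs$pass])
    keep <- which(paste(layout$plate, layout$well, layout$site,
                        sep = ":") %in% ok_sites)
  }
  tables <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    site_i <- if (cache_images) cached[[i]] else
      generate_layout_site(design, group_params, seed, layout, i)$site
    chans <- site_i$channels
    if (illumination) {
      fl <- fields[[layout$plate[i]]]
      chans <- lapply(vp_channels, function(ch) {
        correct_illumination(chans[[ch]], fl[[ch]])
      })
      names(chans) <- vp_channels
      site_i$channels <- chans
    }
    nuc <- segment_nuclei(chans$nuclei, seg_params)
    seg <- segment_cells(nuc, chans$junction, seg_params)
    tables[[j]] <- extract_site(site_i, seg)
    if (verbose && j %% 20 == 0) {
      message(sprintf("  extracted %d/%d sites", j, length(keep)))
    }
  }
  feats <- do.call(rbind, tables)
  feats <- merge(layout, feats, by = c("plate", "well", "site"), sort = FALSE)
  feats <- feats[order(feats$plate, feats$well, feats$site, feats$label), ]
  rownames(feats) <- NULL
  feats <- impute_missing(feats)
  list(features = feats, qc = qcrecs, illumination = fields, layout = layout)
}

#' Run the full profiling pipeline on a synthetic assay
#'
#' Generation -> QC -> illumination correction -> segmentation -> feature
#' extraction -> per-plate z-scoring -> factor model -> aggregation to
#' fingerprints.
#'
#' @inheritParams extract_plate_features
#' @param level aggregation level for fingerprints (see
#'   [aggregate_fingerprints()]).
#' @param variance_target passed to [fit_factor_model()].
#' @param k_max passed to [fit_factor_model()].
#' @return a list: `fingerprints`, `model`, `scores`, `features`
#'   (normalized), `qc`, `labels` (per-fingerprint group), plus the
#'   `layout`.
#' @export
profile_assay <- function(design, group_params, seed,
                          level = c("well", "condition", "sample"),
                          variance_target = 0.80, k_max = 60L,
                          qc = TRUE, illumination = TRUE,
                          seg_params = segmentation_params(),
                          verbose = FALSE) {
  level <- match.arg(level)
  ex <- extract_plate_features(design, group_params, seed, qc = qc,
                               illumination = illumination,
                               seg_params = seg_params, verbose = verbose)
  norm <- normalize_per_plate(ex$features)
  model <- fit_factor_model(norm, variance_target = variance_target,
                            k_max = k_max, seed = seed)
  scores <- transform_factors(norm, model)
  fp <- aggregate_fingerprints(scores, norm, level = level)
  labels <- entity_labels(norm, fp, level)
  list(fingerprints = fp, model = model, scores = scores, features = norm,
       qc = ex$qc, labels = labels, layout = ex$layout)
}

# group label of each fingerprint entity
entity_labels <- function(metadata, fingerprints, level) {
  key <- switch(level,
                well = paste(metadata$plate, metadata$well, sep = ":"),
                condition = as.character(metadata$group),
                sample = as.character(metadata$sample_id))
  map <- tapply(as.character(metadata$group), key, function(g) g[1])
  unname(map[fingerprints$entity])
}
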