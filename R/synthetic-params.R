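#' Phenotype parameters for the synthetic monolayer generator
#'
#' Bundles the knobs that encode an endothelial activation phenotype in the
#' generated images: how many cells populate a site, how elongated they are,
#' what fraction carries prominent F-actin stress fibers, how rough the
#' adherens-junction borders are, how fragmented the mitochondrial network
#' is, and the imaging nuisances (signal-to-noise, vignetting, artifacts).
#'
#' @param cell_density target number of cells per site (count, >= 1).
#' @param elongation mean cell aspect ratio (dimensionless, >= 1); 1 gives
#'   isotropic cobblestone cells.
#' @param stress_fiber_level fraction of cells rendered with linear F-actin
#'   stress fibers, in \[0, 1\].
#' @param junction_irregularity border roughness amplitude in pixels (>= 0);
#'   0 gives clean polygonal borders.
#' @param mito_fragmentation fraction of the mitochondrial signal rendered as
#'   small puncta instead of elongated networks, in \[0, 1\].
#' @param channel_snr per-channel signal-to-noise ratio; a single number or a
#'   named vector over `nuclei`, `junction`, `actin`, `mito`.
#' @param vignette_amplitude relative corner darkening in \[0, 1).
#' @param artifact_rate probability that a generated site carries a quality
#'   artifact, in \[0, 1\].
#' @param artifact_kinds which artifact kinds may be drawn; subset of
#'   `"blur"`, `"blank"`, `"saturation"`, `"debris"`.
#' @return an object of class `phenotype_params`.
#' @seealso [generate_site()], [generate_plate_set()]
#' @export
phenotype_params <- function(cell_density = 50,
                             elongation = 1.15,
                             stress_fiber_level = 0.1,
                             junction_irregularity = 1.5,
                             mito_fragmentation = 0.2,
                             channel_snr = 8,
                             vignette_amplitude = 0,
                             artifact_rate = 0,
                             artifact_kinds = c("blur", "blank",
                                                "saturation", "debris")) {
  if (!is_count(cell_density)) {
    stop_field("cell_density", "must be a single number >= 1")
  }
  if (!is.numeric(elongation) || length(elongation) != 1L || elongation < 1) {
    stop_field("elongation", "must be a single number >= 1")
  }
  for (f in c("stress_fiber_level", "mito_fragmentation", "artifact_rate")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop_field(f, "must be a fraction in [0, 1]")
    }
  }
  if (!is.numeric(junction_irregularity) || length(junction_irregularity) != 1L ||
      junction_irregularity < 0) {
    stop_field("junction_irregularity", "must be a single number >= 0")
  }
  if (!is.numeric(vignette_amplitude) || length(vignette_amplitude) != 1L ||
      vignette_amplitude < 0 || vignette_amplitude >= 1) {
    stop_field("vignette_amplitude", "must lie in [0, 1)")
  }
  if (length(channel_snr) == 1L && is.null(names(channel_snr))) {
    channel_snr <- stats::setNames(rep(channel_snr, 4L), vp_channels)
  }
  if (is.null(names(channel_snr)) || !all(vp_channels %in% names(channel_snr))) {
    stop_field("channel_snr", "must be a scalar or named over all 4 channels")
  }
  if (any(!is.finite(channel_snr)) || any(channel_snr <= 0)) {
    stop_field("channel_snr", "must be positive and finite")
  }
  artifact_kinds <- match.arg(artifact_kinds,
                              c("blur", "blank", "saturation", "debris"),
                              several.ok = TRUE)
  structure(list(cell_density = cell_density,
                 elongation = elongation,
                 stress_fiber_level = stress_fiber_level,
                 junction_irregularity = junction_irregularity,
                 mito_fragmentation = mito_fragmentation,
                 channel_snr = channel_snr[vp_channels],
                 vignette_amplitude = vignette_amplitude,
                 artifact_rate = artifact_rate,
                 artifact_kinds = artifact_kinds),
            class = "phenotype_params")
}

#' @export
print.phenotype_params <- function(x, ...) {
  cat("Phenotype parameters for the synthetic monolayer generator\n")
  cat(sprintf("  cells/site %g | elongation %.2f | stress fibers %.2f\n",
              x$cell_density, x$elongation, x$stress_fiber_level))
  cat(sprintf("  junction irregularity %.2f px | mito fragmentation %.2f\n",
              x$junction_irregularity, x$mito_fragmentation))
  cat(sprintf("  SNR %s | vignette %.2f | artifact rate %.2f\n",
              paste(sprintf("%s=%g", names(x$channel_snr), x$channel_snr),
                    collapse = " "),
              x$vignette_amplitude, x$artifact_rate))
  invisible(x)
}
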