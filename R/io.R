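# Disk formats: single-channel 16-bit TIFF images named
# {plate}_{well}_s{site}_{channel}.tif, 16-bit label TIFFs for masks,
# and a plain CSV layout table.

#' Write a site's channel images as 16-bit TIFFs
#'
#' @param site an `image_site`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_site_images <- function(site, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in names(site$channels)) {
    path <- file.path(dir, sprintf("%s_%s_s%d_%s.tif", site$plate, site$well,
                                   site$site, ch))
    tiff::writeTIFF(clamp(site$channels[[ch]]), path, bits.per.sample = 16L)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a site's channel images back from TIFFs
#'
#' @param dir directory written by [write_site_images()].
#' @param plate,well,site identity of the site to read.
#' @return an `image_site`.
#' @export
read_site_images <- function(dir, plate, well, site) {
  channels <- lapply(vp_channels, function(ch) {
    path <- file.path(dir, sprintf("%s_%s_s%d_%s.tif", plate, well,
                                   as.integer(site), ch))
    if (!file.exists(path)) stop("missing image: ", path)
    m <- tiff::readTIFF(path)
    matrix(as.numeric(m), nrow(m), ncol(m))
  })
  names(channels) <- vp_channels
  structure(list(channels = channels, plate = plate, well = well,
                 site = as.integer(site)),
            class = "image_site")
}

#' Write / read an integer label mask as a 16-bit TIFF
#'
#' Labels up to 65535 round-trip exactly.
#'
#' @param mask integer label matrix.
#' @param path file path.
#' @return invisibly, the path / the label matrix.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(max(mask) <= 65535L)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(as.numeric(m) * 65535)), nrow(m), ncol(m))
}

#' Write / read the plate layout table as CSV
#'
#' @param layout layout data frame (see [plate_layout()]).
#' @param path file path.
#' @return invisibly the path / the layout data frame.
#' @export
write_layout <- function(layout, path) {
  utils::write.csv(layout, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Materialize a synthetic plate set on disk
#'
#' Writes every site's channel TIFFs, the ground-truth label masks, and the
#' layout CSV.
#'
#' @param design a [plate_design()].
#' @param group_params named list of [phenotype_params()].
#' @param seed master seed.
#' @param dir output directory.
#' @return invisibly, the layout data frame.
#' @export
write_plate_set <- function(design, group_params, seed, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layout <- plate_layout(design)
  for (i in seq_len(nrow(layout))) {
    gs <- generate_layout_site(design, group_params, seed, layout, i)
    write_site_images(gs$site, dir)
    base <- sprintf("%s_%s_s%d", layout$plate[i], layout$well[i],
                    layout$site[i])
    write_label_mask(gs$truth$nuclei_mask,
                     file.path(dir, paste0(base, "_nuclei_mask.tif")))
    write_label_mask(gs$truth$cell_mask,
                     file.path(dir, paste0(base, "_cell_mask.tif")))
  }
  write_layout(layout, file.path(dir, "layout.csv"))
  invisible(layout)
}
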