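#' Segmentation parameters
#'
#' @param local_threshold_window odd window width (pixels) of the local-mean
#'   threshold used for nuclei detection.
#' @param local_threshold_offset intensity offset above the local mean (on
#'   the \[0,1\] scale) a pixel must exceed to count as nuclear foreground;
#'   the default is 2 percent of the dynamic range.
#' @param min_nucleus_area smallest accepted nucleus, pixels.
#' @param propagation_regularization lambda >= 0 trading junction-intensity
#'   guidance against Euclidean distance during cell propagation; larger
#'   values make the partition more purely geometric.
#' @param border_policy `"keep"` (default) or `"drop_border_cells"`.
#' @param nucleus_smoothing Gaussian sigma applied to the nuclei channel
#'   before thresholding.
#' @param watershed_tolerance minimum object depth passed to the watershed
#'   that splits touching nuclei.
#' @return a `segmentation_params` object.
#' @export
segmentation_params <- function(local_threshold_window = 51L,
                                local_threshold_offset = 0.02,
                                min_nucleus_area = 30L,
                                propagation_regularization = 0.02,
                                border_policy = c("keep", "drop_border_cells"),
                                nucleus_smoothing = 1.5,
                                watershed_tolerance = 1) {
  if (local_threshold_window < 3L || local_threshold_window %% 2L == 0L) {
    stop("`local_threshold_window` must be odd and >= 3")
  }
  if (min_nucleus_area < 1L) stop("`min_nucleus_area` must be >= 1")
  if (propagation_regularization < 0) {
    stop("`propagation_regularization` must be >= 0")
  }
  structure(list(local_threshold_window = as.integer(local_threshold_window),
                 local_threshold_offset = local_threshold_offset,
                 min_nucleus_area = as.integer(min_nucleus_area),
                 propagation_regularization = propagation_regularization,
                 border_policy = match.arg(border_policy),
                 nucleus_smoothing = nucleus_smoothing,
                 watershed_tolerance = watershed_tolerance),
            class = "segmentation_params")
}

#' Segment nuclei by local thresholding and watershed
#'
#' Nuclear foreground is what exceeds the local window mean by
#' `local_threshold_offset` after mild Gaussian smoothing; touching nuclei
#' are split by a watershed on the negated distance transform of the
#' foreground; regions below `min_nucleus_area` are discarded as debris.
#'
#' @param dapi_image illumination-corrected nuclei-channel matrix on \[0,1\].
#' @param params a [segmentation_params()].
#' @return an integer label matrix (0 = background, consecutive labels).
#' @export
segment_nuclei <- function(dapi_image, params = segmentation_params()) {
  stopifnot(is.matrix(dapi_image), length(dapi_image) > 0)
  sm <- gsmooth(dapi_image, params$nucleus_smoothing)
  w <- (params$local_threshold_window - 1L) %/% 2L
  fg <- EBImage::thresh(EBImage::Image(sm), w = w, h = w,
                        offset = params$local_threshold_offset)
  fg <- as_mat(fg)
  if (!any(fg > 0)) return(matrix(0L, nrow(dapi_image), ncol(dapi_image)))
  dm <- EBImage::distmap(EBImage::Image(fg))
  lab <- EBImage::watershed(dm, tolerance = params$watershed_tolerance)
  lab <- matrix(as.integer(as_mat(lab)), nrow(dapi_image))
  relabel_consecutive(drop_small_labels(lab, params$min_nucleus_area))
}

#' Delineate cells by nuclei-seeded image-weighted Voronoi propagation
#'
#' Each pixel is assigned to the nucleus reachable at minimal cost, where
#' moving across junction-intensity changes is penalized and straight-line
#' distance is charged at rate `propagation_regularization`. Bright
#' VE-cadherin borders therefore stop the propagation, and for a uniform
#' junction image the partition converges to the geometric Voronoi diagram
#' of the seeds.
#'
#' @param nuclei_mask integer label matrix of seeds (from
#'   [segment_nuclei()]).
#' @param junction_image junction-channel matrix, same shape.
#' @param params a [segmentation_params()].
#' @return a `segmentation_result`: list with `nuclei_mask`, `cell_mask`
#'   (matched labels), and `sizes` (per-label nucleus/cell pixel counts).
#' @export
segment_cells <- function(nuclei_mask, junction_image,
                          params = segmentation_params()) {
  stopifnot(is.matrix(nuclei_mask))
  if (!all(dim(nuclei_mask) == dim(junction_image))) {
    stop("`nuclei_mask` and `junction_image` shapes differ")
  }
  if (!any(nuclei_mask > 0)) {
    return(new_segmentation_result(nuclei_mask * 0L, nuclei_mask * 0L))
  }
  cells <- .propagate_cpp(junction_image,
                          matrix(as.integer(nuclei_mask), nrow(nuclei_mask)),
                          params$propagation_regularization)
  res <- new_segmentation_result(matrix(as.integer(nuclei_mask),
                                        nrow(nuclei_mask)), cells)
  if (params$border_policy == "drop_border_cells") {
    res <- filter_cells(res, drop_border_cells = TRUE)
  }
  res
}

new_segmentation_result <- function(nuclei_mask, cell_mask) {
  labs <- sort(setdiff(unique(as.vector(cell_mask)), 0L))
  sizes <- data.frame(
    label = labs,
    nucleus_px = tabulate(nuclei_mask, nbins = max(labs, 0L))[labs],
    cell_px = tabulate(cell_mask, nbins = max(labs, 0L))[labs])
  structure(list(nuclei_mask = nuclei_mask, cell_mask = cell_mask,
                 sizes = sizes),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation_result: %d cells on a %dx%d raster\n",
              nrow(x$sizes), nrow(x$cell_mask), ncol(x$cell_mask)))
  invisible(x)
}

#' Filter segmented cells by size and border rules
#'
#' Labels failing any rule are removed jointly from the nucleus and cell
#' masks and the survivors are relabelled consecutively (in increasing
#' original-label order).
#'
#' @param result a `segmentation_result`.
#' @param min_nucleus_area,min_cell_area,max_cell_area size rules in pixels
#'   (NULL disables a rule).
#' @param drop_border_cells drop cells touching the image frame.
#' @return a filtered `segmentation_result`.
#' @export
filter_cells <- function(result, min_nucleus_area = NULL,
                         min_cell_area = NULL, max_cell_area = NULL,
                         drop_border_cells = FALSE) {
  stopifnot(inherits(result, "segmentation_result"))
  keep <- result$sizes$label
  if (!is.null(min_nucleus_area)) {
    keep <- intersect(keep,
                      result$sizes$label[result$sizes$nucleus_px >= min_nucleus_area])
  }
  if (!is.null(min_cell_area)) {
    keep <- intersect(keep,
                      result$sizes$label[result$sizes$cell_px >= min_cell_area])
  }
  if (!is.null(max_cell_area)) {
    keep <- intersect(keep,
                      result$sizes$label[result$sizes$cell_px <= max_cell_area])
  }
  if (drop_border_cells) {
    cm <- result$cell_mask
    border <- unique(c(cm[1, ], cm[nrow(cm), ], cm[, 1], cm[, ncol(cm)]))
    keep <- setdiff(keep, border)
  }
  nmax <- max(result$sizes$label, 1L)
  map <- integer(nmax + 1L)  # index by label + 1
  map[sort(keep) + 1L] <- seq_along(keep)
  new_segmentation_result(
    matrix(map[result$nuclei_mask + 1L], nrow(result$nuclei_mask)),
    matrix(map[result$cell_mask + 1L], nrow(result$cell_mask)))
}

drop_small_labels <- function(mask, min_area) {
  if (max(mask) == 0L) return(mask)
  sz <- tabulate(mask, nbins = max(mask))
  bad <- which(sz > 0 & sz < min_area)
  if (length(bad)) mask[mask %in% bad] <- 0L
  mask
}

relabel_consecutive <- function(mask) {
  labs <- sort(setdiff(unique(as.vector(mask)), 0L))
  if (!length(labs)) return(mask)
  map <- integer(max(labs) + 1L)
  map[labs + 1L] <- seq_along(labs)
  matrix(map[mask + 1L], nrow(mask))
}
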