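# Retrospective illumination / vignetting correction.
#
# The gain field of a plate+channel is estimated from the images
# themselves by an iterative robust per-pixel scheme: start from the
# smoothed per-pixel median across images, flat-field every image with the
# current estimate, mask pixels that deviate from the per-pixel median of
# the flat-fielded stack (foreground rejection), re-estimate from the
# unmasked pixels, apply the smoothness constraint and renormalize to
# mean 1.

#' Estimate a multiplicative illumination field
#'
#' The smoothness constraint is, by default, a low-order polynomial surface
#' fit (the classic parametric model for retrospective shading correction):
#' Gaussian blurring of the per-pixel estimate systematically flattens a
#' sloped field near the image border, which caps how well a strong
#' vignette can be removed, while a polynomial surface represents radial
#' vignettes essentially exactly. A Gaussian smoother remains available via
#' `smoothing = "gaussian"`.
#'
#' @param images list of same-shaped matrices from one plate and channel
#'   (>= 10 recommended so the per-pixel median suppresses foreground).
#' @param iterations maximum number of refinement iterations.
#' @param smoothing `"polynomial"` (default) or `"gaussian"`.
#' @param degree polynomial surface degree (total degree, default 2,
#'   matching the essentially quadratic profile of a radial vignette).
#' @param smoothing_sigma Gaussian sigma when `smoothing = "gaussian"`;
#'   default image width / 8.
#' @param mask_threshold relative deviation above which a pixel is treated
#'   as foreground and excluded from the re-estimate.
#' @param tol stop early when the field's maximum absolute change falls
#'   below this.
#' @return an `illumination_field`: positive matrix with spatial mean 1.
#' @export
estimate_illumination <- function(images, iterations = 5L,
                                  smoothing = c("polynomial", "gaussian"),
                                  degree = 2L, smoothing_sigma = NULL,
                                  mask_threshold = 0.3, tol = 1e-3) {
  stopifnot(is.list(images), length(images) >= 2L)
  smoothing <- match.arg(smoothing)
  d <- dim(images[[1]])
  if (!all(vapply(images, function(m) all(dim(m) == d), TRUE))) {
    stop("all images must share the same shape")
  }
  if (is.null(smoothing_sigma)) smoothing_sigma <- d[2] / 8
  smooth_fun <- if (smoothing == "polynomial") {
    basis <- poly_basis(d, degree)
    function(m) poly_surface(m, basis)
  } else {
    function(m) gsmooth(m, smoothing_sigma)
  }
  stack <- vapply(images, as.vector, numeric(prod(d)))
  med <- apply(stack, 1, stats::median)
  field <- normalize_field(smooth_fun(matrix(med, d[1], d[2])))
  for (it in seq_len(iterations)) {
    fv <- as.vector(field)
    flat <- stack / fv
    mflat <- apply(flat, 1, stats::median)
    scale <- stats::median(mflat) + 1e-12
    keep <- abs(flat - mflat) / scale <= mask_threshold
    num <- rowSums(stack * keep)
    den <- rowSums(keep)
    est <- ifelse(den > 0, num / den, med)
    new_field <- normalize_field(smooth_fun(matrix(est, d[1], d[2])))
    delta <- max(abs(new_field - field))
    field <- new_field
    if (delta < tol) break
  }
  structure(field, class = c("illumination_field", class(field)))
}

# orthogonal polynomial design over the pixel grid, built once per shape
poly_basis <- function(d, degree) {
  x <- rep(seq_len(d[2]), each = d[1]) / d[2] * 2 - 1
  y <- rep(seq_len(d[1]), times = d[2]) / d[1] * 2 - 1
  terms <- list()
  for (i in 0:degree) {
    for (j in 0:(degree - i)) {
      terms[[length(terms) + 1L]] <- x^i * y^j
    }
  }
  X <- do.call(cbind, terms)
  qr(X)
}

poly_surface <- function(m, basis) {
  fit <- qr.fitted(basis, as.vector(m))
  matrix(fit, nrow(m), ncol(m))
}

normalize_field <- function(field) {
  field <- pmax(field, 1e-6)
  field / mean(field)
}

#' Correct an image for uneven illumination
#'
#' Divides by the estimated gain field and clips at zero. Because the field
#' has spatial mean 1, plate-wide mean intensity is conserved up to the
#' field's spatial structure.
#'
#' @param image numeric matrix.
#' @param field an [estimate_illumination()] result (or any positive matrix
#'   of the same shape).
#' @return corrected image.
#' @export
correct_illumination <- function(image, field) {
  if (!all(dim(image) == dim(field))) {
    stop("image and illumination field shapes differ")
  }
  if (any(field <= 0)) stop("illumination field must be strictly positive")
  pmax(image / unclass(field), 0)
}
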