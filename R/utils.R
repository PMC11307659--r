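# Internal helpers shared across modules.
#
# Raster convention used everywhere in this package: images are numeric R
# matrices indexed [row, col] with the origin at the top-left; x = column,
# y = row. Label masks are integer matrices with 0 = background and positive
# consecutive labels. Intensities live on [0, 1]; files on disk are 16-bit.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @useDynLib vasoprofile, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

vp_channels <- c("nuclei", "junction", "actin", "mito")

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

#' Derive a child seed from a master seed
#'
#' Deterministic mixing keeps every per-site stream reproducible from a single
#' integer while staying within R's 32-bit integer range.
#' @param seed master integer seed.
#' @param i stream index (site counter, repeat counter, ...).
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 104729) %% 2147483587)
}

# shift a matrix by (dr, dc), padding with `fill`
shift_mat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# boundary pixels of a label mask: any 4-neighbour carries a different label
# (image frame does not count as boundary unless `frame = TRUE`)
label_boundary <- function(mask, frame = FALSE) {
  b <- (shift_mat(mask, 1, 0, fill = NA) != mask) |
    (shift_mat(mask, -1, 0, fill = NA) != mask) |
    (shift_mat(mask, 0, 1, fill = NA) != mask) |
    (shift_mat(mask, 0, -1, fill = NA) != mask)
  b[is.na(b)] <- frame
  b & (mask > 0)
}

# strip the EBImage Image class, keeping dimensions (EBImage stores data
# x-major; all uses here are symmetric in x/y so no transpose is needed)
as_mat <- function(img) {
  d <- EBImage::imageData(img)
  matrix(as.vector(d), nrow(d), ncol(d))
}

# smooth a matrix with an isotropic Gaussian. Normalized convolution
# (zero-padded Gaussian divided by the smoothed indicator) keeps local
# means unbiased at the image border; the kernel is capped at the image
# size so very large sigmas stay legal.
gsmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- 2L * ceiling(3 * sigma) + 1L
  rmax <- min(dim(m))
  if (rmax %% 2L == 0L) rmax <- rmax - 1L
  r <- min(r, rmax)
  num <- as_mat(EBImage::gblur(EBImage::Image(m), sigma = sigma,
                               radius = r, boundary = 0))
  den <- as_mat(EBImage::gblur(EBImage::Image(matrix(1, nrow(m), ncol(m))),
                               sigma = sigma, radius = r, boundary = 0))
  num / pmax(den, 1e-12)
}

clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1
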