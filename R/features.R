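# Single-cell morphological feature extraction.
#
# All per-family operations work on label masks and return one row per
# label, so fixtures with a single hand-built region exercise the same code
# path as full sites. Feature values depend only on region content, never on
# absolute image position.

# ---- shape and moments ------------------------------------------------------

#' Shape and moment features per segmented cell
#'
#' Geometry of the cell and nucleus regions: pixel area, 4-connected border
#' perimeter (edge count), boundary radii about the centroid, equivalent
#' diameter, form factor, and the normalized central moments up to order 2
#' with the derived ellipse parameters (eccentricity, axis lengths,
#' orientation), plus the nucleus/cell area ratio. A degenerate one-pixel
#' region yields perimeter 4 and eccentricity 0.
#'
#' @param cell_mask,nuclei_mask matched integer label masks.
#' @return a data frame with `label` and one column per feature, named as in
#'   [feature_manifest()].
#' @export
shape_moment_features <- function(cell_mask, nuclei_mask) {
  labs <- sort(setdiff(unique(as.vector(cell_mask)), 0L))
  blocks <- list(label = labs)
  shp <- list(cell = shape_stats_by_label(cell_mask, labs),
              nucleus = shape_stats_by_label(nuclei_mask, labs))
  for (comp in c("cell", "nucleus")) {
    m <- shp[[comp]]$shape
    colnames(m) <- paste("none", comp, "shape", vp_shape_stats, sep = ".")
    blocks[[comp]] <- m
  }
  ratio <- shp$nucleus$shape[, "area"] / pmax(shp$cell$shape[, "area"], 1)
  blocks$ratio <- matrix(ratio, ncol = 1,
                         dimnames = list(NULL, "none.nucleus.shape.area_ratio"))
  for (comp in c("cell", "nucleus")) {
    m <- shp[[comp]]$moment
    colnames(m) <- paste("none", comp, "moment", vp_moment_stats, sep = ".")
    blocks[[paste0("m_", comp)]] <- m
  }
  feat <- do.call(cbind, blocks[-1])
  out <- data.frame(label = blocks$label, feat, check.names = FALSE)
  rownames(out) <- NULL
  out
}

shape_stats_by_label <- function(mask, labs) {
  n <- length(labs)
  shape <- matrix(NA_real_, n, length(vp_shape_stats),
                  dimnames = list(NULL, vp_shape_stats))
  moment <- matrix(NA_real_, n, length(vp_moment_stats),
                   dimnames = list(NULL, vp_moment_stats))
  if (!n) return(list(shape = shape, moment = moment))
  nmax <- max(labs)
  area <- tabulate(mask, nbins = nmax)[labs]
  # perimeter: count of 4-edges from region pixels to anything else
  # (other labels, background, or the image frame)
  perim_acc <- integer(nmax)
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- shift_mat(mask, sh[1], sh[2], fill = 0L)
    edge <- mask > 0L & nb != mask
    if (any(edge)) {
      t <- tabulate(mask[edge], nbins = nmax)
      perim_acc <- perim_acc + t
    }
  }
  perim <- perim_acc[labs]
  idx <- which(mask > 0L)
  l <- mask[idx]
  y <- ((idx - 1L) %% nrow(mask)) + 1L
  x <- ((idx - 1L) %/% nrow(mask)) + 1L
  cx <- as.vector(rowsum(x, l)[, 1] / tabulate(l, nmax)[sort(unique(l))])
  names(cx) <- sort(unique(l))
  cy <- as.vector(rowsum(y, l)[, 1] / tabulate(l, nmax)[sort(unique(l))])
  names(cy) <- sort(unique(l))
  cxv <- cx[as.character(l)]; cyv <- cy[as.character(l)]
  dx <- x - cxv; dy <- y - cyv
  mu20 <- rowsum(dx^2, l)[, 1] / tabulate(l, nmax)[sort(unique(l))]
  mu02 <- rowsum(dy^2, l)[, 1] / tabulate(l, nmax)[sort(unique(l))]
  mu11 <- rowsum(dx * dy, l)[, 1] / tabulate(l, nmax)[sort(unique(l))]
  bnd <- label_boundary(mask, frame = TRUE)
  for (k in seq_len(n)) {
    lb <- labs[k]
    key <- as.character(lb)
    if (!key %in% names(cx)) next
    bidx <- which(bnd & mask == lb)
    by <- ((bidx - 1L) %% nrow(mask)) + 1L
    bx <- ((bidx - 1L) %/% nrow(mask)) + 1L
    r <- sqrt((bx - cx[key])^2 + (by - cy[key])^2)
    m20 <- mu20[key]; m02 <- mu02[key]; m11 <- mu11[key]
    tr <- m20 + m02
    det <- m20 * m02 - m11^2
    l1 <- tr / 2 + sqrt(pmax(tr^2 / 4 - det, 0))
    l2 <- tr / 2 - sqrt(pmax(tr^2 / 4 - det, 0))
    shape[k, ] <- c(area[k], perim[k], mean(r),
                    sqrt(mean((r - mean(r))^2)), min(r), max(r),
                    2 * sqrt(area[k] / pi),
                    4 * pi * area[k] / max(perim[k], 1)^2)
    moment[k, ] <- c(if (l1 > 1e-12) sqrt(1 - pmin(l2 / l1, 1)) else 0,
                     4 * sqrt(pmax(l1, 0)), 4 * sqrt(pmax(l2, 0)),
                     0.5 * atan2(2 * m11, m20 - m02),
                     m20, m11, m02)
  }
  list(shape = shape, moment = moment)
}

# ---- intensity --------------------------------------------------------------

#' Intensity features per labelled region
#'
#' Integrated and order statistics of the channel intensity within each
#' region, its histogram entropy (32 bins within the region's range), and
#' the mass displacement (distance between the geometric and the
#' intensity-weighted centroid).
#'
#' @param image channel matrix.
#' @param mask integer label mask of the same shape.
#' @return a data frame with `label` plus the statistics named as in
#'   `vp_intensity_stats`.
#' @export
intensity_features <- function(image, mask) {
  stopifnot(all(dim(image) == dim(mask)))
  labs <- sort(setdiff(unique(as.vector(mask)), 0L))
  m <- intensity_stats_by_label(image, mask, labs)
  out <- data.frame(label = labs, m, check.names = FALSE)
  rownames(out) <- NULL
  out
}

intensity_stats_by_label <- function(image, mask, labs) {
  ns <- length(vp_intensity_stats)
  out <- matrix(NA_real_, length(labs), ns,
                dimnames = list(NULL, vp_intensity_stats))
  if (!length(labs)) return(out)
  idx <- which(mask > 0L)
  l <- mask[idx]
  v <- image[idx]
  y <- ((idx - 1L) %% nrow(mask)) + 1L
  x <- ((idx - 1L) %/% nrow(mask)) + 1L
  sp <- split(seq_along(l), l)
  for (k in seq_along(labs)) {
    key <- as.character(labs[k])
    if (!key %in% names(sp)) next
    ii <- sp[[key]]
    vv <- v[ii]
    n <- length(vv)
    m <- mean(vv)
    sdev <- stats::sd(vv)           # sample sd; NA for n = 1
    if (is.na(sdev)) sdev <- 0
    spop <- sqrt(mean((vv - m)^2))  # population sd for shape statistics
    q <- stats::quantile(vv, c(.01, .05, .10, .25, .75, .90, .95, .99),
                         names = FALSE, type = 7)
    skew <- if (spop > 1e-12) mean((vv - m)^3) / spop^3 else 0
    kurt <- if (spop > 1e-12) mean((vv - m)^4) / spop^4 - 3 else 0
    cv <- if (abs(m) > 1e-12) spop / m else NA_real_
    rng <- range(vv)
    ent <- 0
    if (diff(rng) > 0) {
      h <- tabulate(pmin(32L, 1L + floor((vv - rng[1]) / diff(rng) * 32)), 32L)
      p <- h[h > 0] / n
      ent <- -sum(p * log(p))
    }
    tot <- sum(vv)
    md <- if (tot > 1e-12) {
      sqrt((sum(x[ii] * vv) / tot - mean(x[ii]))^2 +
             (sum(y[ii] * vv) / tot - mean(y[ii]))^2)
    } else 0
    out[k, ] <- c(tot, m, stats::median(vv), sdev, stats::mad(vv),
                  rng[1], rng[2], q, q[4 + 1] - q[4], cv, skew, kurt, ent, md)
  }
  out
}

# ---- texture ----------------------------------------------------------------

#' Gray-level co-occurrence texture features per labelled region
#'
#' 13 Haralick statistics averaged over the four principal directions, at
#' the given pixel distances, on intensities quantized to `levels`
#' equal-width bins between each region's own min and max. Regions smaller
#' than `min_area` pixels get missing values (imputed downstream).
#'
#' @param image channel matrix.
#' @param mask integer label mask.
#' @param levels number of gray levels (default 64).
#' @param distances co-occurrence offsets in pixels (default 1 and 3).
#' @param min_area minimum region size in pixels (default 25).
#' @return a data frame with `label` plus `<stat>.d<distance>` columns.
#' @export
texture_features <- function(image, mask, levels = 64L,
                             distances = c(1L, 3L), min_area = 25L) {
  stopifnot(all(dim(image) == dim(mask)))
  labs <- sort(setdiff(unique(as.vector(mask)), 0L))
  nmax <- if (length(labs)) max(labs) else 0L
  blocks <- list()
  for (d in distances) {
    m <- .glcm_features_cpp(image, matrix(as.integer(mask), nrow(mask)),
                            nmax, as.integer(levels), as.integer(d))
    m <- m[labs, , drop = FALSE]
    colnames(m) <- sprintf("%s.d%d", vp_texture_stats, d)
    blocks[[as.character(d)]] <- m
  }
  m <- do.call(cbind, blocks)
  if (length(labs)) {
    small <- tabulate(mask, nbins = nmax)[labs] < min_area
    m[small, ] <- NA_real_
  }
  out <- data.frame(label = labs, m, check.names = FALSE)
  rownames(out) <- NULL
  out
}

# ---- radial distribution ----------------------------------------------------

#' Radial intensity distribution per cell
#'
#' Scales each cell pixel's position to a normalized radius
#' rho = r / (r + d_border), where r is the distance to the nucleus centroid
#' and d_border the distance to the nearest cell border, and reports the
#' intensity fraction falling in 4 equal-width rings (ring 1 at the nucleus
#' centroid, ring 4 at the border) plus the intensity-weighted mean and
#' coefficient of variation of rho. Fractions sum to 1. Cells with zero
#' total intensity fall back to the ring *area* fractions and are flagged in
#' the `zero_intensity` attribute.
#'
#' @param image channel matrix.
#' @param cell_mask integer label mask.
#' @param nucleus_centroids data frame with `label`, `x`, `y` (e.g. nucleus
#'   centroids from the matched nuclei mask).
#' @return a data frame with `label` plus the 6 distribution statistics.
#' @export
distribution_features <- function(image, cell_mask, nucleus_centroids) {
  stopifnot(all(dim(image) == dim(cell_mask)))
  labs <- sort(setdiff(unique(as.vector(cell_mask)), 0L))
  out <- matrix(NA_real_, length(labs), 6,
                dimnames = list(NULL, vp_distribution_stats))
  zero <- logical(length(labs))
  if (length(labs)) {
    nmax <- max(labs)
    cx <- rep(NA_real_, nmax); cy <- rep(NA_real_, nmax)
    cx[nucleus_centroids$label] <- nucleus_centroids$x
    cy[nucleus_centroids$label] <- nucleus_centroids$y
    bnd <- label_boundary(cell_mask, frame = TRUE)
    dborder <- as_mat(EBImage::distmap(EBImage::Image(1 - bnd * 1)))
    idx <- which(cell_mask > 0L)
    l <- cell_mask[idx]
    y <- ((idx - 1L) %% nrow(cell_mask)) + 1L
    x <- ((idx - 1L) %/% nrow(cell_mask)) + 1L
    r <- sqrt((x - cx[l])^2 + (y - cy[l])^2)
    rho <- r / (r + dborder[idx])
    rho[r == 0] <- 0
    ring <- pmin(4L, 1L + as.integer(floor(rho * 4)))
    w <- image[idx]
    sp <- split(seq_along(l), l)
    for (k in seq_along(labs)) {
      ii <- sp[[as.character(labs[k])]]
      if (is.null(ii) || anyNA(rho[ii])) next  # no nucleus centroid -> NA row
      wk <- w[ii]
      tot <- sum(wk)
      if (tot <= 1e-12) { zero[k] <- TRUE; wk <- rep(1, length(ii)); tot <- length(ii) }
      fr <- vapply(1:4, function(g) sum(wk[ring[ii] == g]) / tot, 0)
      rm <- sum(wk * rho[ii]) / tot
      r2 <- sum(wk * rho[ii]^2) / tot
      cvr <- if (rm > 1e-12) sqrt(pmax(r2 - rm^2, 0)) / rm else NA_real_
      out[k, ] <- c(fr, rm, cvr)
    }
  }
  res <- data.frame(label = labs, out, check.names = FALSE)
  rownames(res) <- NULL
  attr(res, "zero_intensity") <- labs[zero]
  res
}

# ---- colocalization ---------------------------------------------------------

#' Colocalization features per labelled region
#'
#' Pearson correlation, thresholded Manders M1/M2 with per-cell Otsu
#' thresholds, and the overlap coefficient between two channels within each
#' region. Pearson is missing when either channel has zero variance in the
#' region. M1 is the fraction of above-threshold channel-A intensity found
#' where B is also above its threshold (and symmetrically for M2), so two
#' identical channels give M1 = M2 = 1 and channels with disjoint
#' above-threshold support give 0.
#'
#' @param a,b channel matrices (ordered pair).
#' @param mask integer label mask.
#' @return a data frame with `label`, `pearson`, `manders_m1`, `manders_m2`,
#'   `overlap`.
#' @export
colocalization_features <- function(a, b, mask) {
  stopifnot(all(dim(a) == dim(mask)), all(dim(b) == dim(mask)))
  labs <- sort(setdiff(unique(as.vector(mask)), 0L))
  out <- matrix(NA_real_, length(labs), 4,
                dimnames = list(NULL, vp_coloc_stats))
  if (length(labs)) {
    idx <- which(mask > 0L)
    l <- mask[idx]
    va <- a[idx]; vb <- b[idx]
    sp <- split(seq_along(l), l)
    for (k in seq_along(labs)) {
      ii <- sp[[as.character(labs[k])]]
      if (is.null(ii)) next
      x <- va[ii]; y <- vb[ii]
      pear <- if (stats::sd(x) > 0 && stats::sd(y) > 0) {
        stats::cor(x, y)
      } else NA_real_
      ta <- otsu_threshold(x); tb <- otsu_threshold(y)
      sa <- sum(x[x > ta]); sb <- sum(y[y > tb])
      m1 <- if (sa > 1e-12) sum(x[x > ta & y > tb]) / sa else NA_real_
      m2 <- if (sb > 1e-12) sum(y[x > ta & y > tb]) / sb else NA_real_
      den <- sqrt(sum(x^2) * sum(y^2))
      ov <- if (den > 1e-12) sum(x * y) / den else NA_real_
      out[k, ] <- c(pear, m1, m2, ov)
    }
  }
  res <- data.frame(label = labs, out, check.names = FALSE)
  rownames(res) <- NULL
  res
}

#' Otsu threshold of an intensity sample
#'
#' Maximizes between-class variance on a 64-bin histogram of the sample;
#' deterministic, used for the per-cell Manders thresholds.
#'
#' @param v numeric vector of intensities.
#' @param nbins histogram bins.
#' @return threshold value (upper edge of the selected bin).
#' @export
otsu_threshold <- function(v, nbins = 64L) {
  r <- range(v)
  if (diff(r) <= 0) return(r[1])
  h <- tabulate(pmin(nbins, 1L + floor((v - r[1]) / diff(r) * nbins)), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mut <- mu[nbins]
  sigma2 <- (mut * omega - mu)^2 / (omega * (1 - omega))
  sigma2[!is.finite(sigma2)] <- 0
  k <- which.max(sigma2)
  r[1] + k / nbins * diff(r)
}

# ---- compartments -----------------------------------------------------------

# pixels whose full 4-neighbourhood (frame counts as outside) keeps the same
# label, iterated `steps` times
erode_labels <- function(mask, steps) {
  for (s in seq_len(steps)) {
    keep <- mask > 0L
    for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      keep <- keep & shift_mat(mask, sh[1], sh[2], fill = 0L) == mask
    }
    mask <- mask * keep
  }
  mask
}

# grow `inner` labels into their own cell (same label in `outer`) by
# 4-neighbour dilation, `steps` times
dilate_within <- function(inner, outer, steps) {
  cur <- inner
  for (s in seq_len(steps)) {
    for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      cand <- shift_mat(cur, sh[1], sh[2], fill = 0L)
      grow <- cur == 0L & cand > 0L & outer == cand
      cur[grow] <- cand[grow]
    }
  }
  cur
}

site_compartments <- function(seg) {
  cellm <- seg$cell_mask
  nucm <- seg$nuclei_mask
  cyto <- cellm * (nucm == 0L)
  membrane <- cellm * (erode_labels(cellm, 2L) == 0L)
  ring <- dilate_within(nucm, cellm, 3L)
  cytoring <- ring * (nucm == 0L)
  list(cell = cellm, nucleus = nucm, cytoplasm = cyto,
       membrane = membrane, cytoring = cytoring)
}

label_centroids <- function(mask) {
  labs <- sort(setdiff(unique(as.vector(mask)), 0L))
  if (!length(labs)) {
    return(data.frame(label = integer(0), x = numeric(0), y = numeric(0)))
  }
  idx <- which(mask > 0L)
  l <- mask[idx]
  y <- ((idx - 1L) %% nrow(mask)) + 1L
  x <- ((idx - 1L) %/% nrow(mask)) + 1L
  n <- rowsum(rep(1, length(l)), l)[, 1]
  data.frame(label = labs,
             x = rowsum(x, l)[, 1] / n,
             y = rowsum(y, l)[, 1] / n)
}

# ---- site-level extraction --------------------------------------------------

#' Extract the full single-cell feature table for one site
#'
#' Runs every feature family over the site's four channels and the
#' compartments derived from the segmentation (cell, nucleus, cytoplasm,
#' 2-px membrane band, 3-px peri-nuclear ring), producing one row per cell
#' with all manifest features in order. Missing values (e.g. texture on
#' sub-minimum regions, Pearson on constant signal) are left as NA here and
#' imputed per plate by [impute_missing()].
#'
#' @param site an `image_site`.
#' @param seg a `segmentation_result` aligned with the site's images.
#' @param texture_levels,texture_distances,min_texture_area see
#'   [texture_features()].
#' @return a data frame: `plate`, `well`, `site`, `label`, `centroid_x`,
#'   `centroid_y`, then all feature columns of [feature_manifest()].
#' @export
extract_site <- function(site, seg, texture_levels = 64L,
                         texture_distances = c(1L, 3L),
                         min_texture_area = 25L) {
  stopifnot(inherits(site, "image_site"), inherits(seg, "segmentation_result"))
  manifest <- feature_manifest(texture_distances)
  comps <- site_compartments(seg)
  labs <- sort(setdiff(unique(as.vector(comps$cell)), 0L))
  cent <- label_centroids(comps$cell)
  nuc_cent <- label_centroids(comps$nucleus)

  blocks <- list()
  sm <- shape_moment_features(comps$cell, comps$nucleus)
  blocks$shape <- as.matrix(sm[, -1, drop = FALSE])
  for (ch in vp_channels) {
    img <- site$channels[[ch]]
    for (comp in vp_intensity_compartments) {
      m <- intensity_stats_by_label(img, comps[[comp]], labs)
      colnames(m) <- paste(ch, comp, "intensity", colnames(m), sep = ".")
      blocks[[paste(ch, comp, "int", sep = ".")]] <- m
    }
  }
  for (ch in vp_channels) {
    img <- site$channels[[ch]]
    for (comp in vp_texture_compartments) {
      tf <- texture_features(img, comps[[comp]], levels = texture_levels,
                             distances = texture_distances,
                             min_area = min_texture_area)
      tf <- align_by_label(tf, labs)
      m <- as.matrix(tf[, -1, drop = FALSE])
      colnames(m) <- paste(ch, comp, "texture", colnames(m), sep = ".")
      blocks[[paste(ch, comp, "tex", sep = ".")]] <- m
    }
  }
  for (ch in vp_channels) {
    df <- distribution_features(site$channels[[ch]], comps$cell, nuc_cent)
    df <- align_by_label(df, labs)
    m <- as.matrix(df[, -1, drop = FALSE])
    colnames(m) <- paste(ch, "cell", "distribution", colnames(m), sep = ".")
    blocks[[paste(ch, "dist", sep = ".")]] <- m
  }
  for (pair in vp_coloc_pairs) {
    chn <- paste(pair, collapse = "_")
    for (comp in vp_texture_compartments) {
      cf <- colocalization_features(site$channels[[pair[1]]],
                                    site$channels[[pair[2]]], comps[[comp]])
      cf <- align_by_label(cf, labs)
      m <- as.matrix(cf[, -1, drop = FALSE])
      colnames(m) <- paste(chn, comp, "colocalization", colnames(m), sep = ".")
      blocks[[paste(chn, comp, sep = ".")]] <- m
    }
  }
  for (other in c("junction", "actin", "mito")) {
    chn <- paste("nuclei", other, sep = "_")
    cf <- colocalization_features(site$channels$nuclei,
                                  site$channels[[other]], comps$nucleus)
    cf <- align_by_label(cf, labs)
    m <- as.matrix(cf[, -1, drop = FALSE])
    colnames(m) <- paste(chn, "nucleus", "colocalization", colnames(m),
                         sep = ".")
    blocks[[chn]] <- m
  }

  feat <- do.call(cbind, blocks)
  stopifnot(identical(colnames(feat), manifest$name))
  meta <- data.frame(plate = rep(site$plate, length(labs)),
                     well = rep(site$well, length(labs)),
                     site = rep(site$site, length(labs)),
                     label = labs,
                     centroid_x = cent$x[match(labs, cent$label)],
                     centroid_y = cent$y[match(labs, cent$label)],
                     stringsAsFactors = FALSE)
  if (!length(labs)) {
    feat <- matrix(numeric(0), 0, nrow(manifest),
                   dimnames = list(NULL, manifest$name))
  }
  out <- cbind(meta, as.data.frame(feat, check.names = FALSE))
  rownames(out) <- NULL
  out
}

align_by_label <- function(df, labs) {
  df[match(labs, df$label), , drop = FALSE]
}

#' Impute missing feature values by per-plate medians
#'
#' Replaces NA feature entries with the median of their column within the
#' same plate (falling back to the global column median, then 0, when a
#' whole plate or column is missing). The companion logical mask of imputed
#' entries is attached as attribute `"imputed"` and summarized in the
#' `imputed_any` column so downstream analyses can exclude affected cells.
#'
#' @param table a feature table.
#' @return the table with complete feature columns.
#' @export
impute_missing <- function(table) {
  fcols <- feature_columns(table)
  x <- as.matrix(table[, fcols, drop = FALSE])
  mask <- is.na(x)
  if (any(mask)) {
    for (p in unique(table$plate)) {
      rows <- which(table$plate == p)
      sub <- x[rows, , drop = FALSE]
      nacols <- which(colSums(is.na(sub)) > 0)
      for (j in nacols) {
        med <- stats::median(sub[, j], na.rm = TRUE)
        if (is.na(med)) med <- stats::median(x[, j], na.rm = TRUE)
        if (is.na(med)) med <- 0
        sub[is.na(sub[, j]), j] <- med
      }
      x[rows, ] <- sub
    }
  }
  table[, fcols] <- x
  table$imputed_any <- rowSums(mask) > 0
  attr(table, "imputed") <- mask
  table
}
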