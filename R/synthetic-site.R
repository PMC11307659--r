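# Seeded synthetic monolayer images with exact ground truth.
#
# Cells are perturbed anisotropic Voronoi polygons around dart-throwing
# (Poisson-disk) nucleus centers, which emulates a confluent cobblestone
# endothelial monolayer and gives exact label masks for free. The junction
# channel draws bright lines on cell borders, the actin channel adds
# stress fibers along the cell axis in a parameterized fraction of cells,
# and the mitochondria channel mixes elongated filaments with puncta
# according to the fragmentation parameter. Intensities are corrupted by
# Poisson shot noise plus Gaussian read noise on a 16-bit-like [0,1] scale,
# under an optional radial vignette.

#' Generate one synthetic imaging site with ground truth
#'
#' @param params a [phenotype_params()] object.
#' @param seed integer seed; the same `(params, seed)` pair reproduces the
#'   site bit for bit.
#' @param size image side length in pixels (square site).
#' @param plate,well,site identity stamped on the result.
#' @param intensity_scale multiplicative factor applied to the noiseless
#'   signal before noise; used by [generate_plate_set()] to inject plate
#'   batch effects.
#' @return a list with elements `site` (an `image_site`: named list
#'   `channels` of \[0,1\] matrices plus identity) and `truth` (a
#'   `ground_truth`: `nuclei_mask`, `cell_mask`, `per_cell` table,
#'   `n_visible_nuclei` (nuclei with any in-frame pixel, including partial
#'   nuclei of cells centered outside the frame), `noiseless` channel
#'   renders, the applied `vignette` field, and the injected `artifact`,
#'   if any).
#' @examples
#' gs <- generate_site(phenotype_params(cell_density = 20), seed = 1, size = 96)
#' range(gs$truth$cell_mask)
#' @export
generate_site <- function(params, seed, size = 192L,
                          plate = "P1", well = "A01", site = 1L,
                          intensity_scale = 1) {
  if (!inherits(params, "phenotype_params")) {
    params <- do.call(phenotype_params, as.list(params))
  }
  stopifnot(is_count(size), size >= 32)
  size <- as.integer(size)
  withr::with_seed(as.integer(seed), {
    # geometry and noiseless rendering happen on a padded canvas that is
    # cropped afterwards, so frame-edge cells have out-of-frame neighbours
    # and edge statistics (junction lines, cortical rims) match the interior
    # -- as in a real cropped monolayer
    # pad by ~1.5 mean cell radii so every frame pixel can be covered by an
    # out-of-frame cell
    pad <- max(8L, round(0.9 * size / sqrt(round(params$cell_density))))
    sizep <- size + 2L * pad
    geom <- draw_monolayer_geometry(params, sizep,
                                    n_target = round(params$cell_density *
                                                       (sizep / size)^2))
    noiseless <- render_channels(params, geom, sizep)
    cropped <- crop_to_frame(geom, noiseless, size, pad)
    geom <- cropped$geom
    noiseless <- cropped$noiseless
    vig <- vignette_field(size, params$vignette_amplitude)
    channels <- vector("list", 4L)
    names(channels) <- vp_channels
    for (ch in vp_channels) {
      channels[[ch]] <- add_camera_noise(clamp(noiseless[[ch]] * intensity_scale) * vig,
                                         snr = params$channel_snr[[ch]])
    }
    artifact <- NULL
    if (stats::runif(1) < params$artifact_rate) {
      kind <- if (length(params$artifact_kinds) == 1L) params$artifact_kinds else
        sample(params$artifact_kinds, 1L)
      ch <- sample(vp_channels, 1L)
      channels[[ch]] <- apply_artifact(channels[[ch]], kind)
      artifact <- list(kind = kind, channel = ch)
    }
    site_obj <- structure(list(channels = channels, plate = plate,
                               well = well, site = as.integer(site)),
                          class = "image_site")
    truth <- structure(list(nuclei_mask = geom$nuclei_mask,
                            cell_mask = geom$cell_mask,
                            per_cell = geom$per_cell,
                            n_visible_nuclei = geom$n_visible_nuclei,
                            noiseless = noiseless,
                            vignette = vig,
                            artifact = artifact),
                       class = "ground_truth")
    list(site = site_obj, truth = truth)
  })
}

#' @export
print.image_site <- function(x, ...) {
  cat(sprintf("image_site %s/%s site %d: %dx%d, channels %s\n",
              x$plate, x$well, x$site,
              nrow(x$channels[[1]]), ncol(x$channels[[1]]),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# ---- geometry ---------------------------------------------------------------

draw_monolayer_geometry <- function(params, size,
                                    n_target = round(params$cell_density)) {
  rmin <- 0.72 * size / sqrt(n_target)
  pts <- matrix(NA_real_, n_target, 2L)
  n <- 0L; tries <- 0L
  while (n < n_target && tries < 500L * n_target) {
    p <- stats::runif(2, 1, size)
    ok <- n == 0L ||
      min((pts[seq_len(n), 1] - p[1])^2 + (pts[seq_len(n), 2] - p[2])^2) >= rmin^2
    if (ok) { n <- n + 1L; pts[n, ] <- p }
    tries <- tries + 1L
  }
  pts <- pts[seq_len(n), , drop = FALSE]

  theta <- stats::runif(n, 0, pi)
  aspect <- pmax(1, params$elongation * exp(stats::rnorm(n, 0, 0.05)))

  # smooth coordinate warp carries the junction irregularity
  xs <- matrix(rep(seq_len(size), each = size), size, size)  # column index
  ys <- matrix(rep(seq_len(size), times = size), size, size) # row index
  if (params$junction_irregularity > 0) {
    wx <- gsmooth(matrix(stats::rnorm(size^2), size, size), sigma = 6)
    wy <- gsmooth(matrix(stats::rnorm(size^2), size, size), sigma = 6)
    wx <- wx / max(stats::sd(wx), 1e-12) * params$junction_irregularity
    wy <- wy / max(stats::sd(wy), 1e-12) * params$junction_irregularity
    xw <- xs + wx; yw <- ys + wy
  } else {
    xw <- xs; yw <- ys
  }

  # anisotropic weighted Voronoi assignment
  d2 <- matrix(Inf, size * size, 1)
  best <- rep(1L, size * size)
  bestd <- rep(Inf, size * size)
  s <- sqrt(aspect)
  for (i in seq_len(n)) {
    dx <- as.vector(xw) - pts[i, 1]
    dy <- as.vector(yw) - pts[i, 2]
    u <- cos(theta[i]) * dx + sin(theta[i]) * dy
    v <- -sin(theta[i]) * dx + cos(theta[i]) * dy
    di <- (u / s[i])^2 + (v * s[i])^2
    upd <- di < bestd
    best[upd] <- i
    bestd[upd] <- di[upd]
  }
  cell_mask <- matrix(best, size, size)
  cell_mask <- repair_connectivity(cell_mask, pts)

  # nuclei: ellipses at the centers, clipped to the owning cell
  nuclei_mask <- matrix(0L, size, size)
  mean_area <- size^2 / n
  rn <- sqrt(0.16 * mean_area / pi)
  sn <- sqrt(sqrt(aspect))     # nuclei are less elongated than cells
  for (i in seq_len(n)) {
    dx <- xs - pts[i, 1]; dy <- ys - pts[i, 2]
    u <- cos(theta[i]) * dx + sin(theta[i]) * dy
    v <- -sin(theta[i]) * dx + cos(theta[i]) * dy
    inside <- ((u / (rn * sn[i]))^2 + (v * sn[i] / rn)^2 <= 1) & cell_mask == i
    if (!any(inside)) {
      # degenerate fallback: 3x3 patch at the in-cell pixel nearest the center
      idx <- which(cell_mask == i)
      if (length(idx) == 0L) next
      rr <- ((idx - 1L) %% size) + 1L; cc <- ((idx - 1L) %/% size) + 1L
      j <- which.min((cc - pts[i, 1])^2 + (rr - pts[i, 2])^2)
      inside <- abs(xs - cc[j]) <= 1 & abs(ys - rr[j]) <= 1 & cell_mask == i
    }
    nuclei_mask[inside] <- i
  }
  nuclei_mask <- keep_largest_component(nuclei_mask)

  # drop cells that lost their nucleus entirely (rare edge effect)
  present <- sort(intersect(unique(as.vector(cell_mask)),
                            unique(as.vector(nuclei_mask))))
  present <- present[present > 0]
  relab <- integer(max(max(cell_mask), 1L)); relab[present] <- seq_along(present)
  drop <- !(cell_mask %in% c(0L, present))
  if (any(drop)) {
    cell_mask[drop] <- 0L
    cell_mask <- fill_orphans(cell_mask)
  }
  relab0 <- c(0L, relab)
  cell_mask[] <- relab0[cell_mask + 1L]
  nuclei_mask[] <- relab0[nuclei_mask + 1L]
  keep <- present

  per_cell <- data.frame(label = seq_along(keep),
                         center_x = pts[keep, 1],
                         center_y = pts[keep, 2],
                         orientation = theta[keep],
                         aspect = aspect[keep],
                         stringsAsFactors = FALSE)
  per_cell$has_stress_fibers <- stats::runif(nrow(per_cell)) < params$stress_fiber_level
  per_cell$mito_fragmentation <- params$mito_fragmentation
  per_cell$cell_area <- tabulate(cell_mask, nbins = nrow(per_cell))
  per_cell$nucleus_area <- tabulate(nuclei_mask, nbins = nrow(per_cell))

  list(cell_mask = cell_mask, nuclei_mask = nuclei_mask, per_cell = per_cell,
       centers = pts[keep, , drop = FALSE], theta = theta[keep],
       aspect = aspect[keep])
}

# crop the padded geometry and renders back to the imaged frame; cells whose
# center falls outside the frame stay visible in the masks (with fresh labels
# after the nucleated ones) but carry no nucleus and no per_cell row
crop_to_frame <- function(geom, noiseless, size, pad) {
  rng <- (pad + 1L):(pad + size)
  cell <- geom$cell_mask[rng, rng]
  nuc <- geom$nuclei_mask[rng, rng]
  # nuclei with any pixel in frame, including partials of cells centered
  # outside: what a detector actually sees
  n_visible <- length(setdiff(unique(as.vector(nuc)), 0L))
  pc <- geom$per_cell
  in_crop <- pc$center_x > pad + 0.5 & pc$center_x <= pad + size + 0.5 &
    pc$center_y > pad + 0.5 & pc$center_y <= pad + size + 0.5
  keepl <- pc$label[in_crop]
  others <- setdiff(sort(unique(cell[cell > 0])), keepl)
  nmax <- max(c(cell, 1L))
  map <- integer(nmax + 1L)
  map[keepl + 1L] <- seq_along(keepl)
  map[others + 1L] <- length(keepl) + seq_along(others)
  cellm <- matrix(map[cell + 1L], size, size)
  mapn <- map
  mapn[others + 1L] <- 0L  # out-of-frame cells carry no nucleus label
  nucm <- matrix(mapn[nuc + 1L], size, size)
  pc <- pc[in_crop, , drop = FALSE]
  pc$label <- seq_len(nrow(pc))
  pc$center_x <- pc$center_x - pad
  pc$center_y <- pc$center_y - pad
  # cropping can cut a warped cell into several in-frame fragments; keep the
  # fragment holding the nucleus (or the largest) and absorb the rest into
  # their neighbours so every labelled region stays connected
  cellm <- repair_connectivity(cellm,
                               as.matrix(rbind(pc[, c("center_x", "center_y")],
                                               orphan_anchor(cellm, nrow(pc)))))
  bad_nuc <- nucm > 0L & nucm != cellm
  if (any(bad_nuc)) nucm[bad_nuc] <- 0L
  nucm <- keep_largest_component(nucm)
  pc$cell_area <- tabulate(cellm, nbins = nrow(pc))[seq_len(nrow(pc))]
  pc$nucleus_area <- tabulate(nucm, nbins = nrow(pc))[seq_len(nrow(pc))]
  rownames(pc) <- NULL
  geom$cell_mask <- cellm
  geom$nuclei_mask <- nucm
  geom$per_cell <- pc
  geom$n_visible_nuclei <- n_visible
  list(geom = geom, noiseless = lapply(noiseless, function(m) m[rng, rng]))
}

# centroid anchors for labels beyond `k0` (cells with no in-frame nucleus)
orphan_anchor <- function(mask, k0) {
  labs <- setdiff(sort(unique(as.vector(mask))), c(0L, seq_len(k0)))
  if (!length(labs)) {
    return(matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("center_x", "center_y"))))
  }
  out <- t(vapply(labs, function(l) {
    idx <- which(mask == l)
    c(mean(((idx - 1L) %/% nrow(mask)) + 1L),
      mean(((idx - 1L) %% nrow(mask)) + 1L))
  }, numeric(2)))
  colnames(out) <- c("center_x", "center_y")
  out
}

# keep, per label, only the connected component containing (or nearest) its
# seed; reassign stray fragments to an adjacent label
repair_connectivity <- function(mask, centers) {
  size <- nrow(mask)
  for (i in seq_len(nrow(centers))) {
    sel <- mask == i
    if (!any(sel)) next
    comp <- EBImage::bwlabel(EBImage::Image(sel * 1))
    comp <- as_mat(comp)
    cx <- round(clamp(centers[i, 1], 1, size))
    cy <- round(clamp(centers[i, 2], 1, size))
    home <- comp[cy, cx]
    if (home == 0) {
      idx <- which(sel)
      rr <- ((idx - 1L) %% size) + 1L; cc <- ((idx - 1L) %/% size) + 1L
      home <- comp[idx[which.min((cc - cx)^2 + (rr - cy)^2)]]
    }
    mask[sel & comp != home] <- 0L
  }
  fill_orphans(mask)
}

# grow labels into 0 pixels from 4-neighbours until none remain
fill_orphans <- function(mask) {
  while (any(mask == 0L)) {
    cand <- list(shift_mat(mask, 1, 0), shift_mat(mask, -1, 0),
                 shift_mat(mask, 0, 1), shift_mat(mask, 0, -1))
    pick <- matrix(0L, nrow(mask), ncol(mask))
    for (cm in cand) pick[pick == 0L & cm > 0L] <- cm[pick == 0L & cm > 0L]
    fill <- mask == 0L & pick > 0L
    if (!any(fill)) break
    mask[fill] <- pick[fill]
  }
  mask
}

keep_largest_component <- function(mask) {
  for (i in setdiff(unique(as.vector(mask)), 0L)) {
    sel <- mask == i
    comp <- as_mat(EBImage::bwlabel(EBImage::Image(sel * 1)))
    if (max(comp) > 1L) {
      sizes <- tabulate(comp[sel], nbins = max(comp))
      mask[sel & comp != which.max(sizes)] <- 0L
    }
  }
  mask
}

# ---- rendering --------------------------------------------------------------

render_channels <- function(params, geom, size) {
  cell <- geom$cell_mask; nuc <- geom$nuclei_mask
  n <- nrow(geom$per_cell)
  xs <- matrix(rep(seq_len(size), each = size), size, size)
  ys <- matrix(rep(seq_len(size), times = size), size, size)
  boundary <- label_boundary(cell)

  # nuclei: radially shaded ellipses
  nuclei <- matrix(0.02, size, size)
  idx <- which(nuc > 0)
  if (length(idx)) {
    lab <- nuc[idx]
    cxs <- geom$per_cell$center_x[lab]; cys <- geom$per_cell$center_y[lab]
    r2 <- (xs[idx] - cxs)^2 + (ys[idx] - cys)^2
    rmax <- stats::ave(r2, lab, FUN = max)
    nuclei[idx] <- 0.55 * (1 - 0.4 * r2 / pmax(rmax, 1)) + 0.03
  }

  # junctions: bright lines on cell borders over a dim cytoplasm base
  jl <- matrix(0, size, size); jl[boundary] <- 0.85
  junction <- clamp(gsmooth(jl, 0.8) + 0.04)

  # actin: cytoplasm base + cortical rim + stress fibers along the cell axis
  actin <- matrix(0.06, size, size) + 0.25 * gsmooth(jl, 0.8) / 0.85 * 0.85
  fib_cells <- which(geom$per_cell$has_stress_fibers)
  for (i in fib_cells) {
    px <- which(cell == i)
    if (!length(px)) next
    dx <- xs[px] - geom$per_cell$center_x[i]
    dy <- ys[px] - geom$per_cell$center_y[i]
    th <- geom$per_cell$orientation[i]
    v <- -sin(th) * dx + cos(th) * dy
    span <- max(abs(v), 2)
    nf <- sample(3:5, 1)
    offs <- stats::runif(nf, -0.8, 0.8) * span
    hit <- rep(FALSE, length(px))
    for (o in offs) hit <- hit | abs(v - o) < 0.9
    actin[px[hit]] <- actin[px[hit]] + 0.4
  }
  actin <- clamp(actin)

  # mitochondria: filaments (networked) vs puncta (fragmented) in cytoplasm
  mito <- matrix(0.02, size, size)
  frag <- params$mito_fragmentation
  for (i in seq_len(n)) {
    px <- which(cell == i & nuc == 0L)
    if (length(px) < 12L) next
    # puncta count and brightness chosen so total mitochondrial signal is
    # roughly conserved across fragmentation levels (fission redistributes
    # mass, it does not remove it)
    n_punct <- round(47 * frag)
    n_fil <- round(4 * (1 - frag))
    rr <- ((px - 1L) %% size) + 1L; cc <- ((px - 1L) %/% size) + 1L
    inside <- matrix(FALSE, size, size); inside[px] <- TRUE
    if (n_fil > 0) {
      # persistent random walks that reflect off the nucleus and cell border,
      # so each filament stays one connected elongated structure
      for (f in seq_len(n_fil)) {
        j <- sample(length(px), 1L)
        x <- cc[j]; y <- rr[j]
        phi <- stats::runif(1, 0, 2 * pi)
        len <- 30 + stats::rpois(1, 12)
        stamped <- 0L
        xp <- round(x); yp <- round(y)
        while (stamped < len) {
          xn <- x + cos(phi); yn <- y + sin(phi)
          xi <- round(xn); yi <- round(yn)
          if (xi < 1 || xi > size || yi < 1 || yi > size || !inside[yi, xi]) {
            phi <- phi + pi / 2 * sample(c(-1, 1), 1) +
              stats::rnorm(1, 0, 0.3)
            len <- len - 1L  # give up eventually in cramped corners
            next
          }
          x <- xn; y <- yn
          # keep the trace 4-connected: bridge diagonal moves
          if (xi != xp && yi != yp && inside[yp, xi]) mito[yp, xi] <- 0.55
          mito[yi, xi] <- 0.55
          xp <- xi; yp <- yi
          stamped <- stamped + 1L
          phi <- phi + stats::rnorm(1, 0, 0.25)
        }
      }
    }
    if (n_punct > 0) {
      j <- sample(length(px), min(n_punct, length(px)))
      for (k in j) {
        y0 <- rr[k]; x0 <- cc[k]
        mito[y0, x0] <- 0.9
        # one extra pixel makes puncta resolvable but still "small"
        y1 <- min(size, y0 + 1L)
        if (inside[y1, x0]) mito[y1, x0] <- 0.9
      }
    }
  }

  list(nuclei = nuclei, junction = junction, actin = actin, mito = mito)
}

vignette_field <- function(size, amplitude) {
  if (amplitude <= 0) return(matrix(1, size, size))
  xs <- matrix(rep(seq_len(size), each = size), size, size)
  ys <- matrix(rep(seq_len(size), times = size), size, size)
  c0 <- (size + 1) / 2
  r2 <- ((xs - c0)^2 + (ys - c0)^2) / (2 * (c0 - 1)^2)  # 1 at the corners
  1 - amplitude * r2
}

# Poisson shot noise + Gaussian read noise; `snr` is the signal-to-noise
# ratio at half scale, so the photon gain is 2*snr^2
add_camera_noise <- function(signal, snr) {
  if (is.na(snr)) return(signal)
  gain <- 2 * snr^2
  shot <- stats::rpois(length(signal), lambda = as.vector(signal) * gain) / gain
  read <- stats::rnorm(length(signal), 0, 0.25 / snr)
  matrix(clamp(shot + read), nrow(signal), ncol(signal))
}

apply_artifact <- function(img, kind) {
  size <- nrow(img)
  switch(kind,
    blur = gsmooth(img, 4),
    blank = matrix(0, size, size),
    saturation = {
      w <- max(8L, round(size / 4))
      r0 <- sample(seq_len(size - w), 1L); c0 <- sample(seq_len(size - w), 1L)
      img[r0:(r0 + w), c0:(c0 + w)] <- 1
      img
    },
    debris = {
      r <- max(6L, round(size / 14))
      cy <- sample(seq_len(size), 1L); cx <- sample(seq_len(size), 1L)
      xs <- matrix(rep(seq_len(size), each = size), size, size)
      ys <- matrix(rep(seq_len(size), times = size), size, size)
      img[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- 1
      img
    },
    stop("unknown artifact kind: ", kind))
}
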