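# Shared fixtures, memoized so expensive synthetic sites are built once per
# test run, plus small brute-force oracles kept independent of the package
# implementation they check.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

clean_params <- function(...) {
  phenotype_params(junction_irregularity = 0, vignette_amplitude = 0,
                   artifact_rate = 0, ...)
}

# a modest default site with segmentation, reused across files
std_site <- function() {
  fixture("std_site", {
    gs <- generate_site(phenotype_params(cell_density = 50, elongation = 1.2,
                                         stress_fiber_level = 0.3),
                        seed = 11, size = 192)
    nuc <- segment_nuclei(gs$site$channels$nuclei)
    seg <- segment_cells(nuc, gs$site$channels$junction)
    list(gs = gs, seg = seg)
  })
}

std_features <- function() {
  fixture("std_features", extract_site(std_site()$gs$site, std_site()$seg))
}

# brute-force 4-connected component sizes by flood fill (independent of any
# image library)
flood_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  sizes <- integer(0)
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      size <- size + 1L
      r <- ((p - 1L) %% nr) + 1L
      c <- ((p - 1L) %/% nr) + 1L
      for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (d[1] >= 1L && d[1] <= nr && d[2] >= 1L && d[2] <= nc) {
          q <- d[1] + (d[2] - 1L) * nr
          if (mask[q] && !seen[q]) { seen[q] <- TRUE; queue <- c(queue, q) }
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# brute-force oriented linear-structure energy: best mean response of a
# 9-px line template over 6 orientations, summed over bright pixels
oriented_energy <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  offs <- -4:4
  best <- matrix(-Inf, nr, nc)
  for (th in seq(0, 150, by = 30) * pi / 180) {
    dy <- round(offs * sin(th)); dx <- round(offs * cos(th))
    acc <- matrix(0, nr, nc)
    for (k in seq_along(offs)) {
      sh <- matrix(0, nr, nc)
      rs <- max(1, 1 + dy[k]):min(nr, nr + dy[k])
      cs <- max(1, 1 + dx[k]):min(nc, nc + dx[k])
      sh[rs, cs] <- img[rs - dy[k], cs - dx[k]]
      acc <- acc + sh
    }
    best <- pmax(best, acc / length(offs))
  }
  sum((best - mean(img))[best > mean(img)]^2)
}

# brute-force symmetric co-occurrence matrix for one direction on a masked
# region, with the package's min-max quantization convention
brute_glcm <- function(img, mask, nlevels, dr, dc) {
  v <- img[mask]
  rng <- range(v)
  q <- matrix(0L, nrow(img), ncol(img))
  if (diff(rng) > 0) {
    lev <- floor((img - rng[1]) / diff(rng) * nlevels)
    lev[lev >= nlevels] <- nlevels - 1L
    q[mask] <- lev[mask]
  }
  G <- matrix(0, nlevels, nlevels)
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nrow(img) || c2 < 1 || c2 > ncol(img)) next
      if (mask[r, c] && mask[r2, c2]) {
        i <- q[r, c] + 1L; j <- q[r2, c2] + 1L
        G[i, j] <- G[i, j] + 1
        G[j, i] <- G[j, i] + 1
      }
    }
  }
  G / sum(G)
}

# type-7 quantile by the explicit order-statistic formula
quantile_oracle <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}
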