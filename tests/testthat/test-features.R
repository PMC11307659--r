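# Single-cell feature extraction, checked against analytic shapes, hand
# enumerations, and brute-force oracles.

test_that("the feature manifest enumerates >= 800 uniquely named features", {
  man <- feature_manifest()
  expect_gte(nrow(man), 800)
  expect_identical(anyDuplicated(man$name), 0L)
  expect_true(all(man$family %in% c("shape", "moment", "intensity", "texture",
                                    "distribution", "colocalization")))
  # geometric families carry no channel
  expect_true(all(man$channel[man$family %in% c("shape", "moment")] == "none"))
  # colocalization names carry an ordered channel pair
  expect_true(all(grepl("_", man$channel[man$family == "colocalization"])))
})

test_that("shape features are exact on an axis-aligned square", {
  m <- matrix(0L, 30, 30); m[5:14, 5:14] <- 1L
  sm <- shape_moment_features(m, m)
  expect_equal(sm[["none.cell.shape.area"]], 100)
  expect_equal(sm[["none.cell.shape.perimeter"]], 40)
  expect_equal(sm[["none.cell.moment.eccentricity"]], 0, tolerance = 1e-9)
  expect_equal(sm[["none.nucleus.shape.area_ratio"]], 1)
})

test_that("a rendered ellipse recovers its 2:1 axis ratio within 5%", {
  xs <- matrix(rep(1:80, each = 80), 80, 80)
  ys <- matrix(rep(1:80, times = 80), 80, 80)
  e <- matrix(0L, 80, 80)
  e[((xs - 40) / 20)^2 + ((ys - 40) / 10)^2 <= 1] <- 1L
  se <- shape_moment_features(e, e)
  ratio <- se[["none.cell.moment.major_axis"]] / se[["none.cell.moment.minor_axis"]]
  expect_equal(ratio, 2, tolerance = 0.05)
  expect_equal(se[["none.cell.moment.orientation"]], 0, tolerance = 0.05)
})

test_that("degenerate one-pixel regions get the documented fallbacks", {
  m <- matrix(0L, 10, 10); m[5, 5] <- 1L
  sm <- shape_moment_features(m, m)
  expect_equal(sm[["none.cell.shape.perimeter"]], 4)
  expect_equal(sm[["none.cell.moment.eccentricity"]], 0)
  expect_equal(sm[["none.cell.shape.area"]], 1)
})

test_that("intensity statistics match a hand-enumerated 9-pixel oracle", {
  img <- matrix(0, 6, 6)
  vals <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9)
  img[2:4, 2:4] <- matrix(vals, 3, 3)
  mask <- matrix(0L, 6, 6); mask[2:4, 2:4] <- 1L
  f <- intensity_features(img, mask)
  expect_equal(f$integrated, sum(vals))
  expect_equal(f$mean, mean(vals))
  expect_equal(f$median, 0.5)
  expect_equal(f$sd, stats::sd(vals))
  expect_equal(f$mad, stats::mad(vals))
  expect_equal(f$min, 0.1)
  expect_equal(f$max, 0.9)
  expect_equal(f$q25, quantile_oracle(vals, 0.25))
  expect_equal(f$q95, quantile_oracle(vals, 0.95))
  expect_equal(f$iqr, quantile_oracle(vals, 0.75) - quantile_oracle(vals, 0.25))
  # mass displacement by hand: columns are x, rows are y (column-major fill)
  w <- img[2:4, 2:4]
  xs <- matrix(rep(2:4, each = 3), 3, 3); ys <- matrix(rep(2:4, 3), 3, 3)
  md <- sqrt((sum(xs * w) / sum(w) - mean(xs))^2 +
               (sum(ys * w) / sum(w) - mean(ys))^2)
  expect_equal(f$mass_displacement, md)
})

test_that("constant regions give sd 0, mass displacement 0, integrated c*A", {
  img <- matrix(0.4, 8, 8)
  mask <- matrix(0L, 8, 8); mask[2:6, 3:7] <- 1L
  f <- intensity_features(img, mask)
  expect_equal(f$integrated, 0.4 * 25)
  expect_equal(f$sd, 0)
  expect_equal(f$mass_displacement, 0)
  expect_equal(f$skewness, 0)
})

test_that("integrated intensity is exactly additive over nucleus + cytoplasm", {
  ft <- std_features()
  for (ch in c("nuclei", "junction", "actin", "mito")) {
    lhs <- ft[[paste0(ch, ".cell.intensity.integrated")]]
    rhs <- ft[[paste0(ch, ".nucleus.intensity.integrated")]] +
      ft[[paste0(ch, ".cytoplasm.intensity.integrated")]]
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("texture of a constant region is the single co-occurrence state", {
  mask <- matrix(0L, 20, 20); mask[3:18, 3:18] <- 1L
  tf <- texture_features(matrix(0.5, 20, 20), mask)
  expect_equal(tf[["asm.d1"]], 1)
  expect_equal(tf[["contrast.d1"]], 0)
  expect_equal(tf[["entropy.d1"]], 0)
  expect_equal(tf[["homogeneity.d1"]], 1)
})

test_that("co-occurrence statistics match a brute-force enumeration", {
  # checkerboard: hand-checkable two-level texture
  size <- 12L
  img <- outer(1:size, 1:size, function(r, c) (r + c) %% 2)
  mask <- matrix(0L, size, size); mask[2:11, 2:11] <- 1L
  tf <- texture_features(img, mask, levels = 64, distances = 1L,
                         min_area = 25L)
  dirs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  stats_by_dir <- lapply(dirs, function(d) {
    G <- brute_glcm(img, mask == 1L, 64, d[1], d[2])
    contrast <- sum(outer(1:64, 1:64, function(i, j) (i - j)^2) * G)
    asm <- sum(G^2)
    p <- G[G > 0]
    c(contrast = contrast, asm = asm, entropy = -sum(p * log(p)))
  })
  avg <- Reduce(`+`, stats_by_dir) / 4
  expect_equal(tf[["contrast.d1"]], avg[["contrast"]], tolerance = 1e-9)
  expect_equal(tf[["asm.d1"]], avg[["asm"]], tolerance = 1e-9)
  expect_equal(tf[["entropy.d1"]], avg[["entropy"]], tolerance = 1e-9)
  # horizontal pairs alternate levels 1 and 64: contrast 63^2, asm 1/2
  expect_equal(sum(outer(1:64, 1:64, function(i, j) (i - j)^2) *
                     brute_glcm(img, mask == 1L, 64, 0, 1)), 63^2)

  # and on an irregular random texture
  withr::with_seed(8, {
    rimg <- matrix(stats::runif(size^2), size, size)
  })
  tf2 <- texture_features(rimg, mask, levels = 16, distances = 1L,
                          min_area = 25L)
  avg2 <- Reduce(`+`, lapply(dirs, function(d) {
    G <- brute_glcm(rimg, mask == 1L, 16, d[1], d[2])
    contrast <- sum(outer(1:16, 1:16, function(i, j) (i - j)^2) * G)
    c(contrast = contrast, asm = sum(G^2))
  })) / 4
  expect_equal(tf2[["contrast.d1"]], avg2[["contrast"]], tolerance = 1e-9)
  expect_equal(tf2[["asm.d1"]], avg2[["asm"]], tolerance = 1e-9)
})

test_that("direction-averaged texture is invariant to 90-degree rotation", {
  withr::with_seed(12, {
    img <- matrix(stats::runif(400), 20, 20)
  })
  mask <- matrix(0L, 20, 20); mask[4:17, 3:16] <- 1L
  rot <- function(m) t(m)[, nrow(m):1]  # 90 degrees counterclockwise
  a <- texture_features(img, mask)
  b <- texture_features(rot(img), rot(mask) * 1L)
  expect_equal(as.numeric(a[-1]), as.numeric(b[-1]), tolerance = 1e-9)
})

test_that("sub-minimum regions yield missing texture values", {
  mask <- matrix(0L, 10, 10); mask[2:4, 2:4] <- 1L
  tf <- texture_features(matrix(stats::runif(100), 10, 10), mask,
                         min_area = 25L)
  expect_true(all(is.na(tf[, -1])))
})

test_that("ring fractions reproduce the pixel-counting oracle for uniform intensity", {
  fx <- std_site()
  seg <- fx$seg
  uni <- matrix(1, nrow(seg$cell_mask), ncol(seg$cell_mask))
  cent <- vasoprofile:::label_centroids(seg$nuclei_mask)
  df <- distribution_features(uni, seg$cell_mask, cent)
  # oracle: recompute ring memberships by explicit pixel counting
  bnd <- vasoprofile:::label_boundary(seg$cell_mask, frame = TRUE)
  db <- vasoprofile:::as_mat(EBImage::distmap(EBImage::Image(1 - bnd * 1)))
  for (k in c(1, nrow(df) %/% 2, nrow(df))) {
    lab <- df$label[k]
    idx <- which(seg$cell_mask == lab)
    y <- ((idx - 1) %% nrow(uni)) + 1
    x <- ((idx - 1) %/% nrow(uni)) + 1
    cx <- cent$x[cent$label == lab]; cy <- cent$y[cent$label == lab]
    r <- sqrt((x - cx)^2 + (y - cy)^2)
    rho <- ifelse(r == 0, 0, r / (r + db[idx]))
    ring <- pmin(4, 1 + floor(rho * 4))
    expect_equal(as.numeric(df[k, paste0("frac_ring", 1:4)]),
                 as.numeric(table(factor(ring, levels = 1:4)) / length(idx)),
                 tolerance = 1e-12)
  }
  expect_equal(rowSums(df[, paste0("frac_ring", 1:4)]), rep(1, nrow(df)),
               tolerance = 1e-9)
})

test_that("intensity concentrated at the border lands entirely in ring 4", {
  mask <- matrix(0L, 20, 20); mask[5:15, 5:15] <- 1L
  img <- matrix(0, 20, 20); img[5, 10] <- 1  # on the region border
  cent <- data.frame(label = 1L, x = 10, y = 10)
  df <- distribution_features(img, mask, cent)
  expect_equal(df$frac_ring4, 1)
})

test_that("ring fractions sum to 1 on random images and flag zero intensity", {
  mask <- matrix(0L, 16, 16); mask[3:14, 3:14] <- 1L
  cent <- data.frame(label = 1L, x = 8, y = 8)
  withr::with_seed(5, {
    for (i in 1:10) {
      df <- distribution_features(matrix(stats::rexp(256), 16, 16), mask, cent)
      expect_equal(sum(df[1, paste0("frac_ring", 1:4)]), 1, tolerance = 1e-9)
    }
  })
  dz <- distribution_features(matrix(0, 16, 16), mask, cent)
  expect_identical(attr(dz, "zero_intensity"), 1L)
  expect_equal(sum(dz[1, paste0("frac_ring", 1:4)]), 1, tolerance = 1e-9)
})

test_that("colocalization of a channel with itself is perfect", {
  withr::with_seed(3, {
    a <- matrix(stats::runif(400), 20, 20)
  })
  mask <- matrix(1L, 20, 20)
  cf <- colocalization_features(a, a, mask)
  expect_equal(cf$pearson, 1)
  expect_equal(cf$overlap, 1)
  expect_equal(cf$manders_m1, 1)
  expect_equal(cf$manders_m2, 1)
})

test_that("independent channels show near-zero correlation", {
  withr::with_seed(21, {
    for (i in 1:5) {
      a <- matrix(stats::runif(1600), 40, 40)
      b <- matrix(stats::runif(1600), 40, 40)
      cf <- colocalization_features(a, b, matrix(1L, 40, 40))
      expect_lt(abs(cf$pearson), 0.1)
    }
  })
})

test_that("disjoint above-threshold supports give zero Manders coefficients", {
  a <- matrix(0.01, 20, 20); a[4:8, 4:8] <- 0.9
  b <- matrix(0.01, 20, 20); b[12:16, 12:16] <- 0.9
  cf <- colocalization_features(a, b, matrix(1L, 20, 20))
  expect_equal(cf$manders_m1, 0)
  expect_equal(cf$manders_m2, 0)
})

test_that("zero-variance channels yield missing Pearson", {
  a <- matrix(0.5, 10, 10)
  b <- matrix(stats::runif(100), 10, 10)
  cf <- colocalization_features(a, b, matrix(1L, 10, 10))
  expect_true(is.na(cf$pearson))
})

test_that("extract_site yields one complete row per cell with the manifest header", {
  ft <- std_features()
  seg <- std_site()$seg
  expect_identical(nrow(ft), nrow(seg$sizes))
  expect_gte(length(feature_columns(ft)), 800)
  expect_identical(feature_columns(ft), feature_manifest()$name)
})

test_that("an empty segmentation yields an empty table with an intact header", {
  blank <- matrix(0L, 64, 64)
  site <- structure(list(channels = stats::setNames(replicate(
    4, matrix(0, 64, 64), simplify = FALSE),
    c("nuclei", "junction", "actin", "mito")),
    plate = "P1", well = "A01", site = 1L), class = "image_site")
  seg <- vasoprofile:::new_segmentation_result(blank, blank)
  ft <- extract_site(site, seg)
  expect_identical(nrow(ft), 0L)
  expect_identical(feature_columns(ft), feature_manifest()$name)
})

test_that("features are invariant to translating the whole site", {
  gs <- generate_site(clean_params(cell_density = 6), seed = 17, size = 96)
  shift_by <- function(m, dr, dc, fill) {
    out <- matrix(fill, 128, 128)
    out[(dr + 1):(dr + 96), (dc + 1):(dc + 96)] <- m
    out
  }
  pad0 <- function(m) shift_by(m, 0, 0, 0)
  mk_site <- function(chans) {
    structure(list(channels = chans, plate = "P1", well = "A01", site = 1L),
              class = "image_site")
  }
  base_seg <- vasoprofile:::new_segmentation_result(
    pad0(gs$truth$nuclei_mask) * 1L, pad0(gs$truth$cell_mask) * 1L)
  ft0 <- extract_site(mk_site(lapply(gs$site$channels, pad0)), base_seg)
  seg2 <- vasoprofile:::new_segmentation_result(
    matrix(as.integer(shift_by(gs$truth$nuclei_mask, 11, 23, 0)), 128),
    matrix(as.integer(shift_by(gs$truth$cell_mask, 11, 23, 0)), 128))
  ft1 <- extract_site(mk_site(lapply(gs$site$channels, shift_by,
                                     dr = 11, dc = 23, fill = 0)), seg2)
  fc <- feature_columns(ft0)
  expect_equal(as.matrix(ft0[, fc]), as.matrix(ft1[, fc]), tolerance = 1e-9)
})

test_that("row order is canonical regardless of label shuffling", {
  ft <- std_features()
  expect_identical(ft$label, sort(ft$label))
  expect_identical(anyDuplicated(ft[, c("site", "label")]), 0L)
})

test_that("per-plate median imputation fills NAs and flags them", {
  ft <- std_features()
  fc <- feature_columns(ft)
  ft2 <- ft
  ft2[1, fc[3]] <- NA
  ft2[5, fc[10]] <- NA
  imp <- impute_missing(ft2)
  expect_false(anyNA(imp[, fc]))
  expect_equal(imp[1, fc[3]],
               stats::median(ft2[ft2$plate == ft2$plate[1], fc[3]],
                             na.rm = TRUE))
  expect_true(imp$imputed_any[1] && imp$imputed_any[5])
  expect_identical(sum(attr(imp, "imputed")), 2L)
})
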