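# Plate normalization, factor-analysis reduction, aggregation and the
# factor composition map.

make_feature_table <- function(x, plate = "P1", well = "A01",
                               sample_id = "s1", group = "g1") {
  colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  data.frame(plate = plate, well = well, site = 1L, sample_id = sample_id,
             group = group, replicate = 1L, label = seq_len(nrow(x)),
             centroid_x = 0, centroid_y = 0, x,
             check.names = FALSE, stringsAsFactors = FALSE)
}

test_that("per-plate z-scoring gives mean 0 / sd 1 within every plate", {
  withr::with_seed(1, {
    x <- matrix(stats::rnorm(200 * 6, mean = 3, sd = 2), 200, 6)
  })
  tab <- make_feature_table(x, plate = rep(c("P1", "P2"), each = 100))
  norm <- normalize_per_plate(tab)
  fc <- feature_columns(norm)
  for (p in c("P1", "P2")) {
    z <- as.matrix(norm[norm$plate == p, fc])
    expect_lt(max(abs(colMeans(z))), 1e-9)
    expect_lt(max(abs(sqrt(colMeans(sweep(z, 2, colMeans(z))^2)) - 1)), 1e-9)
  }
})

test_that("an additive batch shift between plates is removed entirely", {
  withr::with_seed(2, {
    x <- matrix(stats::rnorm(150 * 5), 150, 5)
  })
  tab1 <- make_feature_table(x, plate = "P1")
  tab2 <- make_feature_table(sweep(x, 2, c(5, -3, 0.5, 2, -1), "+"),
                             plate = "P2")
  norm <- normalize_per_plate(rbind(tab1, tab2))
  fc <- feature_columns(norm)
  expect_equal(unname(as.matrix(norm[norm$plate == "P1", fc])),
               unname(as.matrix(norm[norm$plate == "P2", fc])),
               tolerance = 1e-9)
})

test_that("constant columns are zeroed with a warning; single-cell plates error", {
  withr::with_seed(3, {
    x <- cbind(stats::rnorm(50), 7)
  })
  tab <- make_feature_table(x)
  expect_warning(norm <- normalize_per_plate(tab), "zero-variance")
  expect_true(all(norm[[feature_columns(norm)[2]]] == 0))
  expect_error(normalize_per_plate(make_feature_table(matrix(1:2, 1, 2))),
               "fewer than 2 cells")
})

simulate_latent <- function(seed, n = 400, p = 40, k = 5,
                            noise_var = 0.02) {
  withr::with_seed(seed, {
    L <- qr.Q(qr(matrix(stats::rnorm(p * k), p, k)))
    share <- (1 - noise_var) / k
    L <- L * sqrt(share * p)
    # exactly orthonormal factor scores: every factor carries its designed
    # variance share, so the k-selection rule is tested, not sampling noise
    f <- qr.Q(qr(matrix(stats::rnorm(n * k), n, k))) * sqrt(n)
    eps <- matrix(stats::rnorm(n * p, 0, sqrt(noise_var)), n, p)
    x <- f %*% t(L) + eps
    colnames(x) <- sprintf("f%03d", seq_len(p))
    list(x = x, L = L)
  })
}

test_that("the factor-count rule recovers a 5-factor latent model across seeds", {
  for (seed in 1:10) {
    sim <- simulate_latent(seed)
    model <- fit_factor_model(sim$x, variance_target = 0.80, k_max = 20)
    expect_identical(model$k, 5L)
    # principal angles between fitted and true loading subspaces < 10 degrees
    q1 <- qr.Q(qr(model$loadings))
    q2 <- qr.Q(qr(sim$L))
    angles <- acos(pmin(svd(crossprod(q1, q2))$d, 1)) * 180 / pi
    expect_lt(max(angles), 10)
  }
})

test_that("an unreachable variance target falls back to k_max with a warning", {
  withr::with_seed(4, {
    x <- matrix(stats::rnorm(100 * 30), 100, 30)
  })
  colnames(x) <- sprintf("f%02d", 1:30)
  expect_warning(model <- fit_factor_model(x, variance_target = 0.999,
                                           k_max = 5), "k_max")
  expect_identical(model$k, 5L)
  expect_lt(model$explained_variance_fraction, 0.999)
  expect_error(fit_factor_model(x, variance_target = 1.5), "variance_target")
})

test_that("explained variance follows the stated sum-of-squared-loadings formula", {
  sim <- simulate_latent(3)
  model <- fit_factor_model(sim$x, variance_target = 0.8)
  xc <- sweep(sim$x, 2, colMeans(sim$x))
  total <- sum(diag(crossprod(xc) / nrow(xc)))
  expect_equal(model$explained_variance_fraction,
               sum(model$loadings^2) / total, tolerance = 1e-9)
  expect_gte(model$explained_variance_fraction, 0.80)
})

test_that("scores are the regression of the data onto the loadings", {
  # tiny closed-form case, solved independently with solve()
  withr::with_seed(5, {
    x <- matrix(stats::rnorm(60), 10, 6)
  })
  colnames(x) <- sprintf("f%d", 1:6)
  model <- suppressWarnings(fit_factor_model(x, variance_target = 0.7,
                                             k_max = 2))
  s <- transform_factors(x, model)
  xc <- sweep(x, 2, colMeans(x))
  L <- model$loadings
  oracle <- t(solve(t(L) %*% L, t(L) %*% t(xc)))
  expect_equal(unname(s), unname(oracle), tolerance = 1e-9)
  expect_lt(max(abs(colMeans(s))), 1e-6)
  # duplicated rows score identically
  s2 <- transform_factors(x[c(1, 1), ], model)
  expect_equal(s2[1, ], s2[2, ])
  expect_error(transform_factors(x[, 1:3], model), "lacks model feature")
})

test_that("aggregation is the cell-weighted mean, pooled across wells per sample", {
  withr::with_seed(6, {
    s1 <- matrix(stats::rnorm(8), 4, 2)
    s2 <- matrix(stats::rnorm(6), 3, 2)
  })
  scores <- rbind(s1, s2)
  colnames(scores) <- c("factor_01", "factor_02")
  meta <- data.frame(plate = "P1", well = rep(c("A01", "A02"), c(4, 3)),
                     sample_id = "s1", group = "g")
  fp_well <- aggregate_fingerprints(scores, meta, "well")
  expect_identical(nrow(fp_well), 2L)
  expect_equal(as.numeric(fp_well[1, c("factor_01", "factor_02")]),
               colMeans(s1))
  fp_sample <- aggregate_fingerprints(scores, meta, "sample")
  expect_identical(fp_sample$n_cells, 7L)
  expect_equal(as.numeric(fp_sample[1, c("factor_01", "factor_02")]),
               (4 * colMeans(s1) + 3 * colMeans(s2)) / 7)
  # identical cells yield the common vector
  same <- matrix(1:2, 5, 2, byrow = TRUE)
  colnames(same) <- c("factor_01", "factor_02")
  fp <- aggregate_fingerprints(same, meta[1:5, ], "condition")
  expect_equal(as.numeric(fp[1, c("factor_01", "factor_02")]), c(1, 2))
})

test_that("the stimulant layout yields 5 well fingerprints per condition", {
  layout <- plate_layout(stimulant_design())
  withr::with_seed(7, {
    scores <- matrix(stats::rnorm(nrow(layout) * 3), ncol = 3)
  })
  colnames(scores) <- sprintf("factor_%02d", 1:3)
  fp <- aggregate_fingerprints(scores, layout, "well")
  lab <- vasoprofile:::entity_labels(layout, fp, "well")
  expect_identical(as.vector(table(lab)), rep(5L, 3))
})

test_that("fingerprint scaling is exact, idempotent and affine-invariant", {
  withr::with_seed(8, {
    x <- matrix(stats::rnorm(40), 10, 4)
  })
  colnames(x) <- sprintf("factor_%02d", 1:4)
  fp <- data.frame(entity = letters[1:10], level = "well", n_cells = 1, x,
                   check.names = FALSE)
  sc <- scale_fingerprints(fp)
  fac <- sprintf("factor_%02d", 1:4)
  expect_lt(max(abs(colMeans(as.matrix(sc[, fac])))), 1e-9)
  sc2 <- scale_fingerprints(sc)
  expect_equal(as.matrix(sc[, fac]), as.matrix(sc2[, fac]), tolerance = 1e-9)
  fp_aff <- fp
  fp_aff[, fac] <- sweep(sweep(as.matrix(fp[, fac]), 2, c(2, 0.5, 3, 10), "*"),
                         2, c(1, -5, 0, 2), "+")
  sc3 <- scale_fingerprints(fp_aff)
  expect_equal(as.matrix(sc[, fac]), as.matrix(sc3[, fac]), tolerance = 1e-9)
  expect_error(scale_fingerprints(fp[1, ]), "at least 2")
})

test_that("aggregation commutes with the affine factor transform", {
  sim <- simulate_latent(9, n = 120, p = 20, k = 3)
  model <- fit_factor_model(sim$x, variance_target = 0.8)
  scores <- transform_factors(sim$x, model)
  grp <- rep(c("a", "b", "c"), each = 40)
  meta <- data.frame(plate = "P1", well = grp, sample_id = grp, group = grp)
  agg_scores <- aggregate_fingerprints(scores, meta, "well")
  mean_x <- rowsum(sim$x, grp) / 40
  fac <- sprintf("factor_%02d", seq_len(model$k))
  expect_equal(unname(as.matrix(agg_scores[, fac])),
               unname(transform_factors(mean_x, model)), tolerance = 1e-9)
})

test_that("factor composition aggregates squared loadings and sums to 1", {
  man <- feature_manifest()
  feats <- c("mito.cell.intensity.mean", "mito.cell.intensity.sd",
             "actin.cell.texture.contrast.d1")
  L <- matrix(c(2, 1, 0,
                0, 0, 3), nrow = 3,
              dimnames = list(feats, NULL))
  model <- structure(list(loadings = L, k = 2L), class = "factor_model")
  comp <- factor_composition(model, man)
  expect_equal(sum(comp), 1, tolerance = 1e-9)
  # hand enumeration: mito:intensity mass = (4 + 1)/14, actin:texture = 9/14
  expect_equal(comp["factor_01", "mito:intensity"], 5 / 14)
  expect_equal(comp["factor_02", "actin:texture"], 9 / 14)
  expect_true(all(comp >= 0))

  bad <- structure(list(loadings = matrix(1, 1, 1,
                                          dimnames = list("nope", NULL))),
                   class = "factor_model")
  expect_error(factor_composition(bad, man), "not in manifest")
})

test_that("composition of random models is normalized for any loading sign", {
  man <- feature_manifest()
  withr::with_seed(10, {
    feats <- sample(man$name, 30)
    L <- matrix(stats::rnorm(30 * 4), 30, 4, dimnames = list(feats, NULL))
  })
  comp <- factor_composition(structure(list(loadings = L),
                                       class = "factor_model"), man)
  expect_equal(sum(comp), 1, tolerance = 1e-9)
  expect_true(all(comp >= 0))
})

test_that("the factor pipeline is deterministic for a fixed seed", {
  sim <- simulate_latent(11, n = 100, p = 15, k = 3)
  m1 <- fit_factor_model(sim$x, seed = 42)
  m2 <- fit_factor_model(sim$x, seed = 42)
  expect_identical(m1$loadings, m2$loadings)
  expect_identical(m1$k, m2$k)
})
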