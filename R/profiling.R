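# From single-cell features to morphological fingerprints:
# per-plate z-scoring -> factor-analysis reduction -> per-entity averaging
# -> rescaling -> factor composition maps.

#' Z-score features within each plate
#'
#' Centers and scales every feature column to mean 0 and unit variance
#' within each plate separately (population sd, ddof = 0), which removes
#' additive and multiplicative plate batch effects before the plates are
#' combined. Columns with zero variance within a plate are set to 0 there
#' and reported via a warning.
#'
#' @param table a feature table with a `plate` column.
#' @return the table with normalized feature columns; the per-plate means
#'   and sds are attached as attribute `"norm_stats"`.
#' @export
normalize_per_plate <- function(table) {
  fcols <- feature_columns(table)
  plates <- unique(table$plate)
  stats_list <- list()
  zero_cols <- character(0)
  for (p in plates) {
    rows <- which(table$plate == p)
    if (length(rows) < 2L) {
      stop("plate ", p, " has fewer than 2 cells; cannot z-score")
    }
    x <- as.matrix(table[rows, fcols, drop = FALSE])
    mu <- colMeans(x)
    sdv <- sqrt(colMeans(sweep(x, 2, mu)^2))  # population sd
    z <- sweep(x, 2, mu)
    ok <- sdv > 1e-12
    z[, ok] <- sweep(z[, ok, drop = FALSE], 2, sdv[ok], "/")
    z[, !ok] <- 0
    zero_cols <- union(zero_cols, fcols[!ok])
    table[rows, fcols] <- z
    stats_list[[p]] <- list(mean = mu, sd = sdv)
  }
  if (length(zero_cols)) {
    warning(length(zero_cols), " zero-variance feature column(s) set to 0 ",
            "within at least one plate")
  }
  attr(table, "norm_stats") <- stats_list
  attr(table, "zero_variance_cols") <- zero_cols
  table
}

#' Fit a factor model to normalized single-cell features
#'
#' Reduces the feature matrix to k latent factors by principal-axis
#' extraction: loadings are eigenvectors of the feature covariance scaled by
#' the square roots of their eigenvalues, and k is the smallest number of
#' factors whose explained-variance fraction — defined throughout this
#' package as (sum of squared loadings) / (total variance of the normalized
#' data) — reaches `variance_target`. If no k up to `k_max` reaches the
#' target, `k_max` is used with a warning. The fit is deterministic; `seed`
#' is recorded for provenance only.
#'
#' @param table a normalized feature table (see [normalize_per_plate()]) or
#'   a plain numeric matrix of cells x features.
#' @param variance_target fraction of total variance to capture, in (0, 1\];
#'   default 0.80.
#' @param k_max upper bound on the factor count.
#' @param seed recorded in the model.
#' @param rotation `"none"` (default) or `"varimax"`; rotation is orthogonal
#'   and leaves the explained-variance fraction unchanged.
#' @return a `factor_model` with the loading matrix (features x k), the
#'   per-feature noise variances, the explained-variance fraction, and the
#'   per-plate normalization statistics when available.
#' @export
fit_factor_model <- function(table, variance_target = 0.80, k_max = 60L,
                             seed = NULL, rotation = c("none", "varimax")) {
  rotation <- match.arg(rotation)
  if (!is.numeric(variance_target) || length(variance_target) != 1L ||
      variance_target <= 0 || variance_target > 1) {
    stop("`variance_target` must lie in (0, 1]")
  }
  x <- if (is.matrix(table)) table else
    as.matrix(table[, feature_columns(table), drop = FALSE])
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 cells to fit a factor model")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  S <- crossprod(xc) / n
  total_var <- sum(diag(S))
  eig <- eigen(S, symmetric = TRUE)
  evals <- pmax(eig$values, 0)
  k_max <- min(as.integer(k_max), ncol(x), n - 1L)
  ev_frac <- cumsum(evals[seq_len(k_max)]) / total_var
  k <- which(ev_frac >= variance_target)[1]
  if (is.na(k)) {
    k <- k_max
    warning(sprintf(
      "variance target %.2f not reached with k_max = %d factors (%.3f); using k_max",
      variance_target, k_max, ev_frac[k_max]))
  }
  L <- eig$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(evals[seq_len(k)]),
                                                        k, k)
  if (rotation == "varimax" && k > 1L) {
    L <- stats::varimax(L)$loadings
    L <- matrix(as.numeric(L), nrow(L), ncol(L))
  }
  # deterministic sign convention: largest-magnitude element positive
  for (j in seq_len(k)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  rownames(L) <- colnames(x)
  structure(list(loadings = L,
                 k = k,
                 feature_means = mu,
                 noise_variance = pmax(diag(S) - rowSums(L^2), 0),
                 explained_variance_fraction = sum(L^2) / total_var,
                 total_variance = total_var,
                 rotation = rotation,
                 norm_stats = attr(table, "norm_stats"),
                 seed = seed),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf(
    "factor_model: %d factors over %d features, %.1f%% of total variance%s\n",
    x$k, nrow(x$loadings), 100 * x$explained_variance_fraction,
    if (x$rotation == "varimax") " (varimax)" else ""))
  invisible(x)
}

#' Project cells into factor space
#'
#' Scores are the least-squares regression of the (normalized, centered)
#' feature rows onto the loading matrix; over the fitting data their column
#' means are 0.
#'
#' @param table a normalized feature table or matrix with the model's
#'   feature columns.
#' @param model a [fit_factor_model()] result.
#' @return a numeric matrix of cells x k factor scores.
#' @export
transform_factors <- function(table, model) {
  feats <- rownames(model$loadings)
  cols <- colnames(table)
  if (!is.null(cols)) {
    missing <- setdiff(feats, cols)
    if (length(missing)) {
      stop("table lacks model feature column(s): ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
    }
  }
  x <- if (is.matrix(table)) {
    if (is.null(cols)) table else table[, feats, drop = FALSE]
  } else {
    as.matrix(table[, feats, drop = FALSE])
  }
  xc <- sweep(x, 2, model$feature_means)
  L <- model$loadings
  scores <- xc %*% L %*% solve(crossprod(L))
  colnames(scores) <- sprintf("factor_%02d", seq_len(ncol(scores)))
  scores
}

#' @export
predict.factor_model <- function(object, newdata, ...) {
  transform_factors(newdata, object)
}

#' Aggregate single-cell factor scores into fingerprints
#'
#' One fingerprint per entity: the arithmetic mean of all its cells' factor
#' scores. At `level = "sample"` cells are pooled across the sample's
#' replicate wells (cell-weighted, not mean-of-well-means); `"well"` keeps
#' each well separate and `"condition"` pools by group label.
#'
#' @param scores matrix of factor scores (cells x k).
#' @param metadata data frame aligned with `scores`, carrying `plate`,
#'   `well`, `sample_id`, `group`.
#' @param level `"well"`, `"condition"`, or `"sample"`.
#' @return a data frame: `entity`, `level`, `n_cells`, then the k factor
#'   columns.
#' @export
aggregate_fingerprints <- function(scores, metadata,
                                   level = c("well", "condition", "sample")) {
  level <- match.arg(level)
  stopifnot(nrow(scores) == nrow(metadata))
  key <- switch(level,
                well = paste(metadata$plate, metadata$well, sep = ":"),
                condition = as.character(metadata$group),
                sample = as.character(metadata$sample_id))
  if (anyNA(key)) stop("metadata lacks the grouping column for level ", level)
  n <- rowsum(rep(1L, nrow(scores)), key)
  m <- rowsum(scores, key) / as.vector(n)
  out <- data.frame(entity = rownames(m), level = level,
                    n_cells = as.vector(n), m,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Scale fingerprints to zero mean and unit variance
#'
#' Column-wise standardization across entities (population sd), applied
#' before any supervised analysis. Idempotent, and invariant to affine
#' transformations of the input columns.
#'
#' @param fingerprints a fingerprint data frame from
#'   [aggregate_fingerprints()] or a plain matrix.
#' @return same shape as the input, scaled.
#' @export
scale_fingerprints <- function(fingerprints) {
  fac <- fingerprint_cols(fingerprints)
  x <- as.matrix(fingerprints[, fac, drop = FALSE])
  if (nrow(x) < 2L) stop("need at least 2 entities to scale fingerprints")
  sc <- scaler_fit(x)
  fingerprints[, fac] <- scaler_apply(x, sc)
  fingerprints
}

fingerprint_cols <- function(fingerprints) {
  if (is.matrix(fingerprints)) return(colnames(fingerprints))
  grep("^factor_", colnames(fingerprints), value = TRUE)
}

scaler_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- sqrt(colMeans(sweep(x, 2, mu)^2))
  list(mean = mu, sd = pmax(sdv, 1e-12))
}

scaler_apply <- function(x, sc) {
  sweep(sweep(x, 2, sc$mean), 2, sc$sd, "/")
}

#' Factor composition by channel and feature family
#'
#' Attributes each factor to the (channel, family) feature groups by summing
#' squared loadings, normalized by the grand total over all factors and
#' groups, yielding a nonnegative matrix summing to 1 that shows which
#' cellular readouts each factor draws on.
#'
#' @param model a `factor_model` whose loading rows are manifest feature
#'   names.
#' @param manifest the feature manifest (defaults to [feature_manifest()]).
#' @return a `factor_composition` matrix, factors x groups.
#' @export
factor_composition <- function(model, manifest = feature_manifest()) {
  feats <- rownames(model$loadings)
  idx <- match(feats, manifest$name)
  if (anyNA(idx)) {
    stop("feature name(s) not in manifest: ",
         paste(utils::head(feats[is.na(idx)], 5), collapse = ", "))
  }
  group <- paste(manifest$channel[idx], manifest$family[idx], sep = ":")
  L2 <- model$loadings^2
  comp <- t(rowsum(L2, group))  # factors x groups
  comp <- comp / sum(comp)
  rownames(comp) <- sprintf("factor_%02d", seq_len(nrow(comp)))
  structure(comp, class = c("factor_composition", class(comp)))
}

#' Plot a factor composition map
#'
#' @param x a `factor_composition`.
#' @param ... passed to [graphics::image()].
#' @export
plot.factor_composition <- function(x, ...) {
  m <- t(unclass(x))
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  xlab = "", ylab = "", axes = FALSE,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  graphics::axis(1, seq_len(nrow(m)), rownames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(ncol(m)), colnames(m), las = 1, cex.axis = 0.7)
  invisible(x)
}
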