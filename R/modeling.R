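# Supervised stratification of fingerprints: PCA overview, linear
# discriminant analysis with shrinkage, PLS regression, and repeated
# hold-out cross-validation with leak-free scaling (the scaler and the
# model only ever see training rows).

#' Cross-validation scheme
#'
#' @param holdout_fraction fraction of entities left out per repeat
#'   (0 < f < 0.5; the assay's standard settings are 0.10 and 0.20).
#' @param n_repeats number of random splits.
#' @param seed integer seed; fixes every split.
#' @param stratified stratify splits by class (classification only).
#' @return a `cv_scheme`.
#' @export
cv_scheme <- function(holdout_fraction = 0.2, n_repeats = 25L, seed = 1L,
                      stratified = TRUE) {
  if (!is.numeric(holdout_fraction) || holdout_fraction <= 0 ||
      holdout_fraction >= 0.5) {
    stop("`holdout_fraction` must lie in (0, 0.5)")
  }
  if (!is_count(n_repeats)) stop("`n_repeats` must be >= 1")
  structure(list(holdout_fraction = holdout_fraction,
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "cv_scheme")
}

as_fingerprint_matrix <- function(fingerprints) {
  fac <- fingerprint_cols(fingerprints)
  x <- as.matrix(if (is.matrix(fingerprints)) fingerprints
                 else fingerprints[, fac, drop = FALSE])
  if (is.null(colnames(x))) colnames(x) <- sprintf("factor_%02d", seq_len(ncol(x)))
  x
}

#' Principal-component overview of fingerprints
#'
#' @param fingerprints fingerprint data frame or matrix (>= 3 entities).
#' @return a list with `scores`, `variance_fraction` (non-increasing, sums
#'   to <= 1 over the returned components), and the `rotation` matrix.
#' @export
pca_overview <- function(fingerprints) {
  x <- as_fingerprint_matrix(fingerprints)
  if (nrow(x) < 3L) stop("need at least 3 entities for a PCA overview")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  list(scores = pr$x,
       variance_fraction = pr$sdev^2 / sum(pr$sdev^2),
       rotation = pr$rotation)
}

#' Fit a linear discriminant model to fingerprints
#'
#' Fisher LDA on the factor scores: discriminant axes maximize
#' between-class over within-class scatter, at most (classes - 1) of them.
#' The pooled within-class covariance is shrunk toward a scaled identity
#' when ill-conditioned (`shrinkage = "auto"`, the smallest shrinkage that
#' makes it well-conditioned); the shrinkage actually used is reported. The
#' per-factor coefficient vectors (`scalings`) are exported for biplot
#' overlays.
#'
#' @param fingerprints fingerprint data frame or matrix.
#' @param labels class label per entity (>= 2 classes, each >= 2 entities).
#' @param shrinkage `"auto"`, `"none"`, or a number in \[0, 1\].
#' @return an `lda_report`: scalings, entity scores, class means (in
#'   discriminant space), priors, training confusion matrix (row-normalized)
#'   and accuracy.
#' @export
fit_lda <- function(fingerprints, labels, shrinkage = "auto") {
  x <- as_fingerprint_matrix(fingerprints)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  if (any(table(labels) < 2L)) stop("every class needs at least 2 entities")
  fit <- lda_core(x, labels, shrinkage)
  scores <- sweep(x, 2, fit$grand_mean) %*% fit$scalings
  pred <- lda_assign(scores, fit)
  conf <- confusion_matrix(labels, pred, levels(labels))
  structure(c(fit, list(
    scores = scores,
    labels = labels,
    predicted = pred,
    confusion = conf$normalized,
    confusion_counts = conf$counts,
    accuracy = mean(pred == labels),
    per_class_accuracy = diag(conf$normalized))),
    class = "lda_report")
}

lda_core <- function(x, labels, shrinkage = "auto") {
  classes <- levels(labels)
  n <- nrow(x); k <- ncol(x); C <- length(classes)
  means <- rowsum(x, labels) / as.vector(table(labels))
  grand <- colMeans(x)
  Sw <- matrix(0, k, k)
  for (cl in classes) {
    xc <- sweep(x[labels == cl, , drop = FALSE], 2, means[cl, ])
    Sw <- Sw + crossprod(xc)
  }
  Sw <- Sw / max(n - C, 1)
  Sb <- matrix(0, k, k)
  for (cl in classes) {
    d <- means[cl, ] - grand
    Sb <- Sb + sum(labels == cl) * tcrossprod(d)
  }
  Sb <- Sb / n
  gamma_used <- 0
  if (identical(shrinkage, "none")) {
    gammas <- 0
  } else if (is.numeric(shrinkage)) {
    gammas <- shrinkage
  } else {
    gammas <- c(0, 1e-4, 1e-2, 0.1, 0.5)
  }
  tr <- mean(diag(Sw))
  R <- NULL
  for (g in gammas) {
    Sreg <- (1 - g) * Sw + g * tr * diag(k)
    R <- tryCatch(chol(Sreg), error = function(e) NULL)
    if (!is.null(R) && rcond(Sreg) > 1e-10) { gamma_used <- g; break }
    R <- NULL
  }
  if (is.null(R)) {
    gamma_used <- 1
    R <- chol(tr * diag(k) + 1e-12 * diag(k))
  }
  Rinv <- backsolve(R, diag(k))
  M <- crossprod(Rinv, Sb %*% Rinv)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  r <- min(C - 1L, k)
  W <- Rinv %*% eg$vectors[, seq_len(r), drop = FALSE]
  for (j in seq_len(r)) {  # deterministic sign convention
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  rownames(W) <- colnames(x)
  colnames(W) <- sprintf("LD%d", seq_len(r))
  list(scalings = W,
       eigenvalues = pmax(eg$values[seq_len(r)], 0),
       grand_mean = grand,
       class_means = sweep(means, 2, grand) %*% W,
       priors = as.vector(table(labels)) / n,
       classes = classes,
       shrinkage = gamma_used)
}

lda_assign <- function(scores, fit) {
  # nearest class mean in the (within-class whitened) discriminant space,
  # with a log-prior term
  d2 <- sapply(seq_along(fit$classes), function(ci) {
    rowSums(sweep(scores, 2, fit$class_means[ci, ])^2)
  })
  d2 <- matrix(d2, nrow = nrow(scores))
  obj <- sweep(-0.5 * d2, 2, log(fit$priors), "+")
  factor(fit$classes[max.col(obj, ties.method = "first")],
         levels = fit$classes)
}

#' @export
print.lda_report <- function(x, ...) {
  cat(sprintf("lda_report: %d classes, %d discriminant axes, accuracy %.3f",
              length(x$classes), ncol(x$scalings), x$accuracy))
  if (x$shrinkage > 0) cat(sprintf(" (shrinkage %.2g)", x$shrinkage))
  cat("\n")
  invisible(x)
}

#' @export
predict.lda_report <- function(object, newdata, ...) {
  x <- as_fingerprint_matrix(newdata)
  scores <- sweep(x, 2, object$grand_mean) %*% object$scalings
  lda_assign(scores, object)
}

#' Plot discriminant scores
#'
#' @param x an `lda_report`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lda_report <- function(x, ...) {
  s <- x$scores
  if (ncol(s) == 1L) s <- cbind(s, 0)
  graphics::plot(s[, 1], s[, 2], col = as.integer(x$labels), pch = 19,
                 xlab = "LD1", ylab = "LD2", ...)
  graphics::legend("topright", legend = levels(x$labels),
                   col = seq_len(nlevels(x$labels)), pch = 19, cex = 0.8)
  invisible(x)
}

confusion_matrix <- function(true, pred, classes) {
  counts <- table(factor(true, levels = classes),
                  factor(pred, levels = classes))
  norm <- counts / pmax(rowSums(counts), 1)
  list(counts = unclass(counts), normalized = unclass(norm))
}

# stratified (or plain) holdout split; returns test indices
holdout_split <- function(labels, fraction, stratified) {
  n <- length(labels)
  if (stratified && !is.null(labels)) {
    unlist(lapply(split(seq_len(n), labels), function(ii) {
      sample(ii, max(1L, round(fraction * length(ii))))
    }), use.names = FALSE)
  } else {
    sample(n, max(1L, round(fraction * n)))
  }
}

#' Repeated hold-out cross-validation of an LDA classifier
#'
#' For each repeat, a fraction of entities is held out, the standard scaler
#' and the LDA are fitted on the remaining entities only, and the held-out
#' entities are scaled and classified with the fitted objects. Confusion
#' counts are aggregated over repeats and row-normalized per true class, so
#' the diagonal reads as the fraction of entities of each class predicted
#' correctly.
#'
#' @param fingerprints unscaled fingerprint data frame or matrix.
#' @param labels class label per entity.
#' @param scheme a [cv_scheme()].
#' @return a `cv_classifier_report`: normalized `confusion`, raw
#'   `confusion_counts`, `accuracy`, `per_class_accuracy`, and the
#'   per-repeat predictions.
#' @export
cross_validate_classifier <- function(fingerprints, labels, scheme = cv_scheme()) {
  stopifnot(inherits(scheme, "cv_scheme"))
  x <- as_fingerprint_matrix(fingerprints)
  labels <- factor(labels)
  classes <- levels(labels)
  if (any(table(labels) < 2L)) {
    stop("every class needs at least 2 entities for stratified hold-out")
  }
  preds <- list()
  withr::with_seed(scheme$seed, {
    for (rep in seq_len(scheme$n_repeats)) {
      test <- holdout_split(labels, scheme$holdout_fraction, scheme$stratified)
      train <- setdiff(seq_len(nrow(x)), test)
      if (length(unique(labels[train])) < length(classes)) {
        stop("a class is absent from the training split; use stratified ",
             "splits or more entities")
      }
      sc <- scaler_fit(x[train, , drop = FALSE])
      fit <- fit_lda(scaler_apply(x[train, , drop = FALSE], sc), labels[train])
      pred <- predict(fit, scaler_apply(x[test, , drop = FALSE], sc))
      preds[[rep]] <- data.frame(repeat_id = rep, index = test,
                                 true = labels[test],
                                 predicted = factor(pred, levels = classes))
    }
  })
  preds <- do.call(rbind, preds)
  conf <- confusion_matrix(preds$true, preds$predicted, classes)
  structure(list(confusion = conf$normalized,
                 confusion_counts = conf$counts,
                 accuracy = mean(preds$predicted == preds$true),
                 per_class_accuracy = diag(conf$normalized),
                 predictions = preds,
                 scheme = scheme),
            class = "cv_classifier_report")
}

#' @export
print.cv_classifier_report <- function(x, ...) {
  cat(sprintf(
    "cv_classifier_report: %d repeats, %.0f%% held out, overall accuracy %.3f\n",
    x$scheme$n_repeats, 100 * x$scheme$holdout_fraction, x$accuracy))
  print(round(x$confusion, 3))
  invisible(x)
}

#' Repeated hold-out cross-validation of a PLS regressor
#'
#' Same leak-free protocol as [cross_validate_classifier()], with a partial
#' least squares regression of a numeric response on the fingerprints. The
#' number of PLS components is chosen per repeat by an inner 5-fold
#' cross-validation on the training entities (up to `max_components`);
#' out-of-fold performance is summarized as R-squared = 1 - SSres/SStot on
#' the held-out entities, reported per repeat with mean and sd.
#'
#' @param fingerprints unscaled fingerprint data frame or matrix.
#' @param y numeric response per entity (e.g. a clinical severity score).
#' @param scheme a [cv_scheme()] (`stratified` is ignored).
#' @param max_components upper bound on PLS components (default 5).
#' @return a `cv_regressor_report` with `r2` (per repeat), `r2_mean`,
#'   `r2_sd`, and predicted-vs-true values.
#' @export
cross_validate_regressor <- function(fingerprints, y, scheme = cv_scheme(),
                                     max_components = 5L) {
  stopifnot(inherits(scheme, "cv_scheme"))
  x <- as_fingerprint_matrix(fingerprints)
  if (!is.numeric(y) || anyNA(y)) stop("`y` must be numeric and complete")
  if (stats::sd(y) == 0) stop("`y` is constant; nothing to regress")
  r2 <- numeric(scheme$n_repeats)
  preds <- list()
  withr::with_seed(scheme$seed, {
    for (rep in seq_len(scheme$n_repeats)) {
      test <- sample(nrow(x), max(1L, round(scheme$holdout_fraction * nrow(x))))
      train <- setdiff(seq_len(nrow(x)), test)
      sc <- scaler_fit(x[train, , drop = FALSE])
      xtr <- scaler_apply(x[train, , drop = FALSE], sc)
      xte <- scaler_apply(x[test, , drop = FALSE], sc)
      ncomp <- choose_pls_ncomp(xtr, y[train], max_components)
      fit <- mixOmics::pls(xtr, y[train], ncomp = ncomp, mode = "regression",
                           scale = FALSE)
      yhat <- as.vector(stats::predict(fit, newdata = xte)$predict[, 1, ncomp])
      ss_res <- sum((y[test] - yhat)^2)
      ss_tot <- sum((y[test] - mean(y[test]))^2)
      r2[rep] <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
      preds[[rep]] <- data.frame(repeat_id = rep, index = test,
                                 true = y[test], predicted = yhat)
    }
  })
  preds <- do.call(rbind, preds)
  structure(list(r2 = r2,
                 r2_mean = mean(r2, na.rm = TRUE),
                 r2_sd = stats::sd(r2[!is.na(r2)]),
                 predictions = preds,
                 scheme = scheme),
            class = "cv_regressor_report")
}

#' @export
print.cv_regressor_report <- function(x, ...) {
  cat(sprintf("cv_regressor_report: out-of-fold R^2 = %.2f +/- %.2f (%d repeats)\n",
              x$r2_mean, x$r2_sd, length(x$r2)))
  invisible(x)
}

# inner 5-fold selection of the PLS component count on training data only
choose_pls_ncomp <- function(x, y, max_components) {
  n <- nrow(x)
  cmax <- max(1L, min(as.integer(max_components), ncol(x), n - 3L))
  if (cmax == 1L) return(1L)
  folds <- sample(rep(seq_len(5L), length.out = n))
  press <- numeric(cmax)
  for (f in seq_len(5L)) {
    tr <- folds != f; te <- !tr
    if (sum(tr) < cmax + 2L || sum(te) == 0L) next
    fit <- mixOmics::pls(x[tr, , drop = FALSE], y[tr], ncomp = cmax,
                         mode = "regression", scale = FALSE)
    ph <- stats::predict(fit, newdata = x[te, , drop = FALSE])$predict
    for (k in seq_len(cmax)) {
      press[k] <- press[k] + sum((y[te] - ph[, 1, k])^2)
    }
  }
  which.min(press)
}

#' Biplot data: entity scores plus factor coefficient vectors
#'
#' Scales the LDA coefficient vectors uniformly so they fit the score
#' range; the scale factor is recorded and directions (hence angles between
#' vectors) are preserved exactly.
#'
#' @param report an `lda_report`.
#' @return a list with `scores` (entities x axes), `vectors` (factors x
#'   axes, scaled), and `scale_factor`.
#' @export
biplot_data <- function(report) {
  stopifnot(inherits(report, "lda_report"))
  coefs <- report$scalings
  mx <- max(abs(coefs))
  sf <- if (mx > 0) max(abs(report$scores)) / mx else 0
  list(scores = report$scores, vectors = coefs * sf, scale_factor = sf)
}
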