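#' PCA of the neuron-by-feature matrix
#'
#' Principal component analysis of the population feature space. Columns are
#' z-scored by default (so loadings are comparable across features with
#' different units), rows containing non-finite values are excluded with a
#' report, zero-variance features are dropped with a warning, and component
#' signs follow a deterministic convention: the largest-magnitude loading in
#' each component is positive.
#'
#' @param features numeric matrix or data.frame of neurons x features (a
#'   `neuron_id` column, if present, is used for row labels and excluded
#'   from the decomposition). Needs >= 2 rows and >= 2 usable features.
#' @param standardize z-score the columns first (default `TRUE`); otherwise
#'   columns are only centred and the decomposition is of the covariance
#'   matrix.
#' @return object of class `"field_pca"`: `scores` (neurons x components),
#'   `loadings` (features x components, orthonormal columns),
#'   `explained_variance_ratio` (sums to 1), `sdev`, `feature_means`,
#'   `feature_sds`, `dropped_features`, `excluded_rows` (indices of rows
#'   removed for non-finite values), `n_components_90` (components needed
#'   for 90% cumulative variance).
#' @export
pca_features <- function(features, standardize = TRUE) {
  df <- as.data.frame(features)
  ids <- if ("neuron_id" %in% names(df)) df$neuron_id else seq_len(nrow(df))
  df <- df[, setdiff(names(df), "neuron_id"), drop = FALSE]
  X <- as.matrix(df)
  if (!is.numeric(X)) stop("features must be numeric")
  if (nrow(X) < 2L || ncol(X) < 2L) stop("need >= 2 neurons and >= 2 features")

  complete <- apply(X, 1L, function(r) all(is.finite(r)))
  excluded <- which(!complete)
  X <- X[complete, , drop = FALSE]
  ids <- ids[complete]
  if (nrow(X) < 2L) stop("fewer than 2 complete rows")

  sds <- apply(X, 2L, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped) > 0L) {
    warning("dropping zero-variance feature(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(X) < 2L) stop("fewer than 2 usable features")

  pc <- stats::prcomp(X, center = TRUE, scale. = standardize)
  # deterministic sign: largest-|loading| entry of each component positive
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2L, flip, `*`)
  pc$x <- sweep(pc$x, 2L, flip, `*`)

  var_ratio <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(scores = structure(pc$x, dimnames = list(ids, colnames(pc$x))),
         loadings = pc$rotation,
         explained_variance_ratio = var_ratio,
         sdev = pc$sdev,
         feature_means = pc$center,
         feature_sds = if (standardize) pc$scale else
           stats::setNames(rep(1, ncol(X)), colnames(X)),
         standardized = standardize,
         dropped_features = dropped,
         excluded_rows = excluded,
         n_components_90 = which(cumsum(var_ratio) >= 0.9)[1]),
    class = "field_pca"
  )
}

#' @export
print.field_pca <- function(x, ...) {
  k <- length(x$explained_variance_ratio)
  cat(sprintf("<field_pca> %d neurons x %d features, %d components\n",
              nrow(x$scores), nrow(x$loadings), k))
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("PC%d %.1f%%", seq_len(min(k, 4L)),
                            100 * x$explained_variance_ratio[seq_len(min(k, 4L))]),
                    collapse = ", ")))
  cat(sprintf("  components for 90%% variance: %d\n", x$n_components_90))
  if (length(x$excluded_rows))
    cat(sprintf("  %d row(s) excluded for non-finite features\n",
                length(x$excluded_rows)))
  invisible(x)
}

#' Alignment between a tuning metric and a feature direction in PC space
#'
#' Projects a per-neuron metric (SI or F) into the leading PC plane by
#' regressing it on the first `k` scores, then measures the cosine between
#' that metric-gradient direction and the loading direction of a chosen
#' feature. Positive values mean the metric increases along the feature's
#' direction in the biplot.
#'
#' @param pca a `"field_pca"`.
#' @param metric numeric vector over the neurons that entered the PCA (rows
#'   excluded by [pca_features()] must be excluded here too).
#' @param feature name of a feature (row of `pca$loadings`).
#' @param k number of leading components defining the plane (default 2).
#' @return cosine similarity in [-1, 1].
#' @export
metric_alignment <- function(pca, metric, feature, k = 2L) {
  stopifnot(inherits(pca, "field_pca"))
  if (!feature %in% rownames(pca$loadings))
    stop("unknown feature: ", feature)
  if (length(metric) != nrow(pca$scores))
    stop("metric length must match the PCA's retained rows")
  S <- pca$scores[, seq_len(k), drop = FALSE]
  grad <- stats::coef(stats::lm(metric ~ S))[-1]
  load <- pca$loadings[feature, seq_len(k)]
  sum(grad * load) / sqrt(sum(grad^2) * sum(load^2))
}

#' Biplot of a feature-space PCA
#'
#' Scores on the first two components, optionally coloured by a metric, with
#' feature-loading arrows overlaid.
#'
#' @param x a `"field_pca"`.
#' @param color optional numeric vector (e.g. SI or F per retained neuron)
#'   mapped to a colour ramp.
#' @param arrow_scale multiplier for the loading arrows.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.field_pca <- function(x, color = NULL, arrow_scale = NULL, ...) {
  s <- x$scores[, 1:2, drop = FALSE]
  col <- "grey40"
  if (!is.null(color)) {
    pal <- grDevices::hcl.colors(64, "viridis")
    idx <- cut(rank(color), 64, labels = FALSE)
    col <- pal[idx]
  }
  graphics::plot(s, col = col, pch = 16, cex = 0.6,
                 xlab = sprintf("PC1 (%.1f%%)",
                                100 * x$explained_variance_ratio[1]),
                 ylab = sprintf("PC2 (%.1f%%)",
                                100 * x$explained_variance_ratio[2]), ...)
  if (is.null(arrow_scale))
    arrow_scale <- 0.8 * max(abs(s)) / max(abs(x$loadings[, 1:2]))
  L <- x$loadings[, 1:2] * arrow_scale
  graphics::arrows(0, 0, L[, 1], L[, 2], length = 0.08, col = "red3")
  graphics::text(L * 1.08, labels = rownames(L), col = "red3", cex = 0.8)
  invisible(x)
}
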