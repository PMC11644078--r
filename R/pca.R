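#' Principal component analysis of a metabolite table
#'
#' SVD of the column-centered abundance matrix. Deterministic up to sign;
#' the sign of each component is fixed so that its largest-magnitude loading
#' is positive. Explained-variance fractions are relative to the total
#' variance of the centered matrix.
#'
#' @param table A scaled-stage, fully observed [metab_table()], or a plain
#'   numeric matrix (samples x variables).
#' @param n_components Number of components to keep.
#' @return An object of class `metab_pca`: list with `scores`
#'   (samples x components), `loadings` (variables x components, orthonormal
#'   columns), `explained_fraction`, `center`.
#' @export
fit_pca <- function(table, n_components = 2) {
  X <- if (inherits(table, "metab_table")) {
    require_stage(table, "scaled", "fit_pca")
    if (anyNA(table$values)) stopf("fit_pca() requires a fully observed table; impute first")
    table$values
  } else as.matrix(table)
  if (n_components > min(dim(X))) {
    stopf("n_components (%d) exceeds min(samples, variables) = %d",
          n_components, min(dim(X)))
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr, "-")
  sv <- svd(Xc)
  total <- sum(sv$d^2)
  k <- n_components
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(X)
  rownames(loadings) <- colnames(X)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings,
                 explained_fraction = sv$d[seq_len(k)]^2 / total,
                 center = ctr),
            class = "metab_pca")
}

#' @export
print.metab_pca <- function(x, ...) {
  cat(sprintf("PCA: %d components, explained %s\n", ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_fraction), collapse = " / ")))
  invisible(x)
}

#' Confidence ellipse of a 2-D score cloud
#'
#' Gaussian confidence region from the group mean and covariance: the
#' squared Mahalanobis radius equals the chi-square(2) quantile at `level`
#' (for the conventional 90% ellipse, 4.605). A singular covariance gives a
#' degenerate, flagged ellipse.
#'
#' @param scores Two-column matrix of group scores (>= 3 rows).
#' @param level Coverage probability.
#' @return List with `center`, `axes` (semi-axis lengths, decreasing),
#'   `angle` (radians, orientation of the major axis), `degenerate` flag.
#' @export
confidence_ellipse <- function(scores, level = 0.90) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2) stopf("scores must have exactly 2 columns")
  if (nrow(scores) < 3) stopf("need at least 3 points for a covariance ellipse")
  ctr <- colMeans(scores)
  if (level <= 0) {
    return(list(center = ctr, axes = c(0, 0), angle = 0, degenerate = TRUE))
  }
  S <- stats::cov(scores)
  e <- eigen(S, symmetric = TRUE)
  r2 <- stats::qchisq(level, df = 2)
  degen <- any(e$values <= .Machine$double.eps * max(e$values, 1))
  axes <- sqrt(pmax(e$values, 0) * r2)
  angle <- atan2(e$vectors[2, 1], e$vectors[1, 1])
  list(center = ctr, axes = axes, angle = angle, degenerate = degen)
}

#' Hierarchical clustering of profiles by Pearson distance and Ward linkage
#'
#' Agglomerates metabolite mean profiles with distance `1 - Pearson r` and
#' Ward's method. Rows are sorted by name before clustering so the result is
#' invariant to input order; constant profiles (undefined correlation) are
#' put at the maximum distance 2 from everything and flagged.
#'
#' @param profiles A `mean_profiles` matrix (metabolites x timepoints), or
#'   any numeric matrix with >= 2 rows.
#' @return List with `tree` (an `hclust`), `order` (leaf names in dendrogram
#'   order), `flagged` (names of constant profiles).
#' @export
ward_correlation_cluster <- function(profiles) {
  X <- unclass(profiles)
  if (nrow(X) < 2) stopf("need at least 2 profiles")
  X <- X[order(rownames(X)), , drop = FALSE]
  sds <- apply(X, 1, stats::sd)
  flagged <- rownames(X)[sds == 0]
  r <- suppressWarnings(stats::cor(t(X)))
  d <- 1 - r
  d[is.na(d)] <- 2
  diag(d) <- 0
  tree <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  list(tree = tree, order = tree$labels[tree$order], flagged = flagged)
}
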