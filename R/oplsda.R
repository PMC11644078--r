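#' Orthogonal PLS discriminant analysis of a two-group day contrast
#'
#' Fits a single-response OPLS-DA model (NIPALS-style PLS1 with orthogonal
#' signal correction): class-orthogonal X-variation is removed iteratively,
#' then one predictive component is fitted on the filtered matrix. The model
#' splits total X-variance into the predictive fraction (`r2x_pred`, the
#' share of variance associated with class separation), one fraction per
#' orthogonal component, and a residual; the three sum to one.
#'
#' The predictive loading is oriented so that the second day-set of the
#' contrast (the "later" group) has positive mean predictive score; a
#' positive loading therefore means the metabolite is higher in group B.
#'
#' @param table A scaled-stage, fully observed [metab_table()].
#' @param contrast List of two integer day vectors, `list(A, B)`; the groups
#'   must be disjoint and each contain at least 3 samples.
#' @param n_ortho Number of orthogonal components, or `"auto"` to keep
#'   adding components (up to 5) while each explains at least 1% of the
#'   X-variance.
#' @return An object of class `oplsda`: scores/loadings/weights of the
#'   predictive component (`t_pred`, `p_pred`, `w_pred`), orthogonal
#'   scores/loadings (`t_ortho`, `p_ortho`), variance fractions (`r2x_pred`,
#'   `r2x_ortho`, `r2x_residual`), per-metabolite `vip`, the contrast, the
#'   response `y` and the sample ids used.
#' @export
fit_oplsda <- function(table, contrast, n_ortho = 1) {
  require_stage(table, "scaled", "fit_oplsda")
  if (anyNA(table$values)) stopf("fit_oplsda() requires a fully observed table; impute first")
  if (!is.list(contrast) || length(contrast) != 2) {
    stopf("contrast must be a list of two day vectors")
  }
  A <- contrast[[1]]; B <- contrast[[2]]
  if (length(intersect(A, B))) stopf("contrast day-sets must be disjoint")
  day <- table$samples$day
  missing_days <- setdiff(c(A, B), day)
  if (length(missing_days)) stopf("day(s) absent from data: %s",
                                  paste(missing_days, collapse = ", "))
  idx <- day %in% c(A, B)
  y <- ifelse(day[idx] %in% A, -1, 1)
  if (sum(y == -1) < 3 || sum(y == 1) < 3) stopf("both groups need at least 3 samples")
  if (stats::sd(y) == 0) stopf("zero-variance response")
  auto <- identical(n_ortho, "auto")
  max_ortho <- if (auto) 5L else as.integer(n_ortho)
  if (!auto && nrow(table$values[idx, , drop = FALSE]) < max_ortho + 1) {
    stopf("fewer samples than n_ortho + 1")
  }

  X0 <- table$values[idx, , drop = FALSE]
  ctr <- colMeans(X0)
  X <- sweep(X0, 2, ctr, "-")
  yc <- y - mean(y)
  tss <- sum(X^2)

  t_ortho <- NULL; p_ortho <- NULL; w_ortho <- NULL; r2x_ortho <- numeric(0)
  n_kept <- 0L
  repeat {
    if (n_kept >= max_ortho) break
    w <- drop(crossprod(X, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- drop(X %*% w)
    p <- drop(crossprod(X, t)) / sum(t^2)
    w_o <- p - sum(w * p) * w
    nwo <- sqrt(sum(w_o^2))
    if (nwo < 1e-10) break          # no y-orthogonal structure left
    w_o <- w_o / nwo
    t_o <- drop(X %*% w_o)
    if (sum(t_o^2) < 1e-12) break
    p_o <- drop(crossprod(X, t_o)) / sum(t_o^2)
    r2 <- sum(t_o^2) * sum(p_o^2) / tss
    if (auto && r2 < 0.01) break    # component explains <1% of X-variance
    X <- X - tcrossprod(t_o, p_o)
    t_ortho <- cbind(t_ortho, t_o); p_ortho <- cbind(p_ortho, p_o)
    w_ortho <- cbind(w_ortho, w_o)
    r2x_ortho <- c(r2x_ortho, r2)
    n_kept <- n_kept + 1L
  }

  w <- drop(crossprod(X, yc))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stopf("no class-predictive variation left after filtering")
  w <- w / nw
  t_pred <- drop(X %*% w)
  p_pred <- drop(crossprod(X, t_pred)) / sum(t_pred^2)
  # orient: group B (second day-set) positive
  if (mean(t_pred[y == 1]) < 0) {
    w <- -w; t_pred <- -t_pred; p_pred <- -p_pred
  }
  r2x_pred <- sum(t_pred^2) * sum(p_pred^2) / tss
  resid <- X - tcrossprod(t_pred, p_pred)
  J <- ncol(X0)
  vip <- sqrt(J * w^2 / sum(w^2))
  names(vip) <- names(p_pred) <- names(w) <- colnames(X0)

  structure(list(
    contrast = list(A = A, B = B),
    t_pred = stats::setNames(t_pred, rownames(X0)),
    p_pred = p_pred, w_pred = w,
    t_ortho = t_ortho, p_ortho = p_ortho, w_ortho = w_ortho,
    n_ortho = n_kept,
    r2x_pred = r2x_pred, r2x_ortho = r2x_ortho,
    r2x_residual = sum(resid^2) / tss,
    vip = vip, y = stats::setNames(y, rownames(X0)),
    center = ctr
  ), class = "oplsda")
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf("OPLS-DA: days {%s} vs {%s}, %d orthogonal component(s)\n",
              paste(x$contrast$A, collapse = ","),
              paste(x$contrast$B, collapse = ","), x$n_ortho))
  cat(sprintf("  predictive X-variance: %.1f%%; orthogonal: %s; residual: %.1f%%\n",
              100 * x$r2x_pred,
              if (length(x$r2x_ortho)) paste(sprintf("%.1f%%", 100 * x$r2x_ortho), collapse = " + ") else "none",
              100 * x$r2x_residual))
  cat(sprintf("  metabolites with VIP > 1: %d of %d\n",
              sum(x$vip > 1), length(x$vip)))
  invisible(x)
}

#' @export
summary.oplsda <- function(object, ...) {
  df <- data.frame(
    metabolite = names(object$p_pred),
    loading = unname(object$p_pred),
    vip = unname(object$vip),
    band = vip_band(object$vip),
    direction = ifelse(object$p_pred >= 0, "up_in_B", "up_in_A"),
    stringsAsFactors = FALSE
  )
  df[order(-df$vip), ]
}

#' @export
coef.oplsda <- function(object, ...) object$p_pred

#' Project new samples onto a fitted OPLS-DA model
#'
#' Applies the model's centering, removes the orthogonal components and
#' returns the predictive score and the predicted group (sign of the score:
#' positive = group B).
#'
#' @param object A fitted `oplsda` model.
#' @param newdata Numeric matrix (samples x metabolites, same columns as the
#'   training table) or a scaled-stage [metab_table()].
#' @param ... Unused.
#' @return `data.frame` with `t_pred` and `group`.
#' @export
predict.oplsda <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "metab_table")) newdata$values else as.matrix(newdata)
  if (!is.null(colnames(X))) {
    X <- X[, names(object$w_pred), drop = FALSE]
  } else if (ncol(X) != length(object$w_pred)) {
    stopf("newdata has %d columns; model expects %d", ncol(X), length(object$w_pred))
  }
  X <- sweep(X, 2, object$center, "-")
  if (object$n_ortho > 0) {
    for (j in seq_len(object$n_ortho)) {
      t_o <- drop(X %*% object$w_ortho[, j])
      X <- X - tcrossprod(t_o, object$p_ortho[, j])
    }
  }
  t_new <- drop(X %*% object$w_pred)
  data.frame(t_pred = t_new,
             group = ifelse(t_new >= 0, "B", "A"),
             row.names = rownames(X))
}

#' @export
plot.oplsda <- function(x, ...) {
  t_o <- if (!is.null(x$t_ortho)) x$t_ortho[, 1] else stats::rnorm(length(x$t_pred), 0, 1e-6)
  graphics::plot(x$t_pred, t_o, col = ifelse(x$y > 0, "firebrick", "steelblue"),
                 pch = 19, xlab = "predictive score",
                 ylab = "orthogonal score 1", ...)
  graphics::abline(v = 0, lty = 2, col = "grey")
  invisible(x)
}

vip_band <- function(vip) {
  ifelse(vip > 1, "strong", ifelse(vip > 0.9, "weak", "none"))
}

#' Variable-importance-in-projection scores
#'
#' For a single-predictive-component OPLS model the VIP of metabolite j is
#' `sqrt(J * w_j^2 / sum(w^2))` with `w` the predictive weights and `J` the
#' number of metabolites, so the mean squared VIP is exactly 1 and VIP > 1
#' flags influential metabolites.
#'
#' @param model A fitted `oplsda` model.
#' @return Named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "oplsda"))
  model$vip
}

#' Univariate two-group tests per metabolite
#'
#' Two-sided Mann-Whitney (exact when the implementation allows) or Welch t
#' test per metabolite between the two day-sets, with Benjamini-Hochberg
#' adjustment across metabolites. Significance stars follow the conventional
#' bands on adjusted p: `***` < 0.001, `**` < 0.01, `*` < 0.05, `.` < 0.1.
#' All-tied metabolites are reported with p = 1 and flagged.
#'
#' @param table A scaled-stage [metab_table()] (missing values tolerated and
#'   dropped per test).
#' @param contrast List of two day vectors, as in [fit_oplsda()].
#' @param test `"MWW"` (Mann-Whitney-Wilcoxon) or `"t"` (Welch).
#' @return `data.frame` with columns `metabolite`, `statistic`, `p_raw`,
#'   `p_adj`, `stars`, `flagged`.
#' @export
univariate_tests <- function(table, contrast, test = c("MWW", "t")) {
  require_stage(table, "scaled", "univariate_tests")
  test <- match.arg(test)
  A <- contrast[[1]]; B <- contrast[[2]]
  if (length(intersect(A, B))) stopf("contrast day-sets must be disjoint")
  day <- table$samples$day
  ia <- day %in% A; ib <- day %in% B
  if (sum(ia) < 3 || sum(ib) < 3) stopf("both groups need at least 3 samples")
  res <- lapply(colnames(table$values), function(m) {
    xa <- table$values[ia, m]; xb <- table$values[ib, m]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(unique(c(xa, xb))) == 1L) {
      return(data.frame(metabolite = m, statistic = NA_real_, p_raw = 1,
                        flagged = TRUE))
    }
    if (test == "MWW") {
      ht <- suppressWarnings(stats::wilcox.test(xa, xb, exact = NULL))
      data.frame(metabolite = m, statistic = unname(ht$statistic),
                 p_raw = ht$p.value, flagged = FALSE)
    } else {
      ht <- stats::t.test(xa, xb)
      data.frame(metabolite = m, statistic = unname(ht$statistic),
                 p_raw = ht$p.value, flagged = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  out$stars <- stats::symnum(out$p_adj, corr = FALSE, na = FALSE,
                             cutpoints = c(0, 0.001, 0.01, 0.05, 0.1, 1),
                             symbols = c("***", "**", "*", ".", ""))
  out$stars <- as.character(out$stars)
  out[c("metabolite", "statistic", "p_raw", "p_adj", "stars", "flagged")]
}

#' Differential-accumulation calls combining VIP and univariate testing
#'
#' Joins the OPLS-DA loading/VIP view with the univariate p-values into one
#' call per metabolite: direction (up in A or B, from the sign of the
#' predictive loading), VIP band (`strong` for VIP > 1, `weak` for
#' 0.9 < VIP <= 1, else `none`), raw and adjusted p.
#'
#' @param model A fitted `oplsda`.
#' @param table The scaled table the model was fitted on.
#' @param test Test passed to [univariate_tests()].
#' @return `data.frame`, one row per metabolite, sorted by decreasing VIP.
#' @export
differential_calls <- function(model, table, test = c("MWW", "t")) {
  test <- match.arg(test)
  ut <- univariate_tests(table, list(model$contrast$A, model$contrast$B), test)
  df <- data.frame(
    metabolite = names(model$p_pred),
    direction = ifelse(model$p_pred >= 0, "up_in_B", "up_in_A"),
    loading = unname(model$p_pred),
    vip = unname(model$vip),
    vip_band = vip_band(model$vip),
    stringsAsFactors = FALSE
  )
  df <- merge(df, ut[c("metabolite", "p_raw", "p_adj", "stars", "flagged")],
              by = "metabolite", sort = FALSE)
  df$test <- test
  df[order(-df$vip), ]
}
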