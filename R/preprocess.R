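#' Sample-median normalization
#'
#' Divides each sample's abundances by that sample's median over observed
#' metabolites, then multiplies by the grand median of all sample medians so
#' the overall scale of the data is preserved. This removes per-sample
#' loading/injection differences, the first step of the preprocessing chain.
#'
#' @param table A raw-stage [metab_table()].
#' @return A `metab_table` at stage `normalized`.
#' @export
median_normalize <- function(table) {
  require_stage(table, "raw", "median_normalize")
  meds <- apply(table$values, 1, stats::median, na.rm = TRUE)
  if (anyNA(meds)) {
    stopf("sample(s) with no observed values: %s",
          paste(table$samples$sample_id[is.na(meds)], collapse = ", "))
  }
  if (any(meds == 0)) {
    stopf("sample median is zero for: %s",
          paste(table$samples$sample_id[meds == 0], collapse = ", "))
  }
  grand <- stats::median(meds)
  table$values <- table$values / meds * grand
  table$stage <- "normalized"
  table
}

#' Natural-log transform
#'
#' Element-wise natural logarithm. Zeros are floored beforehand to half the
#' smallest positive observed value of the same metabolite (the conventional
#' half-minimum floor for below-detection values); negative values are an
#' error.
#'
#' @param table A normalized-stage [metab_table()].
#' @return A `metab_table` at stage `logged`.
#' @export
log_transform <- function(table) {
  require_stage(table, "normalized", "log_transform")
  v <- table$values
  if (any(v[!is.na(v)] < 0)) stopf("negative values cannot be log-transformed")
  has_zero <- apply(v, 2, function(col) any(!is.na(col) & col == 0))
  for (j in which(has_zero)) {
    pos <- v[, j][!is.na(v[, j]) & v[, j] > 0]
    if (!length(pos)) stopf("metabolite '%s' is all-zero; cannot floor for log",
                            colnames(v)[j])
    v[!is.na(v[, j]) & v[, j] == 0, j] <- min(pos) / 2
  }
  table$values <- log(v)
  table$stage <- "logged"
  table
}

#' Autoscaling (per-metabolite standardization)
#'
#' Centers each metabolite column to mean zero and scales it to unit sample
#' standard deviation over observed values. Constant columns cannot be scaled;
#' they are set to all-zero and recorded in `flags$constant_metabolites`.
#'
#' @param table A logged-stage [metab_table()].
#' @return A `metab_table` at stage `scaled`.
#' @export
autoscale <- function(table) {
  require_stage(table, "logged", "autoscale")
  v <- table$values
  mu <- colMeans(v, na.rm = TRUE)
  sdv <- apply(v, 2, stats::sd, na.rm = TRUE)
  const <- is.na(sdv) | sdv == 0
  sdv[const] <- 1
  v <- sweep(sweep(v, 2, mu, "-"), 2, sdv, "/")
  if (any(const)) {
    v[, const] <- ifelse(is.na(v[, const]), NA_real_, 0)
    table$flags$constant_metabolites <-
      union(table$flags$constant_metabolites, colnames(v)[const])
  }
  table$values <- v
  table$stage <- "scaled"
  table$scaling <- list(center = mu, sd = sdv)
  table
}

#' Map a scaled table back to the normalized (positive) scale
#'
#' Inverts autoscaling and the log transform using the centering/scaling
#' recorded by [autoscale()], recovering positive normalized abundances.
#' Observed cells reproduce their pre-log values exactly; imputed cells get
#' the back-transformed imputed value, which makes the positive-scale
#' variant of downstream analyses (e.g. the Canberra fingerprint) available
#' after imputation.
#'
#' @param table A scaled-stage [metab_table()] produced by [autoscale()]
#'   (optionally after [knn_impute()]).
#' @return A `metab_table` at stage `normalized`.
#' @export
unscale_to_normalized <- function(table) {
  require_stage(table, "scaled", "unscale_to_normalized")
  if (is.null(table$scaling)) {
    stopf("table lacks recorded scaling parameters; was it produced by autoscale()?")
  }
  v <- sweep(sweep(table$values, 2, table$scaling$sd, "*"),
             2, table$scaling$center, "+")
  table$values <- exp(v)
  table$stage <- "normalized"
  table$scaling <- NULL
  table
}

#' K-nearest-neighbour imputation of missing cells
#'
#' Each missing cell is replaced by the mean of the `k` nearest metabolite
#' rows, where distance is Euclidean over the samples on which both rows are
#' observed (normalized by the number of shared samples so rows with
#' different missingness are comparable). Only metabolites with no missing
#' values are neighbour candidates. Originally observed values are never
#' altered; a metabolite missing everywhere is left missing and reported.
#'
#' @param table A scaled-stage [metab_table()].
#' @param k Number of neighbours (default 10, capped at the number of
#'   complete metabolite rows).
#' @return A `metab_table` with missing cells imputed.
#' @export
knn_impute <- function(table, k = 10) {
  require_stage(table, "scaled", "knn_impute")
  v <- table$values
  if (!anyNA(v)) return(table)
  X <- t(v)                      # metabolites x samples
  complete <- rowSums(is.na(X)) == 0
  n_complete <- sum(complete)
  if (k >= n_complete && k > 0 && n_complete > 0) {
    k <- n_complete              # cap at available complete rows
  }
  if (n_complete == 0) stopf("no complete metabolite rows available for imputation")
  if (k < 1) stopf("k must be at least 1")
  comp_idx <- which(complete)
  Xc <- X[comp_idx, , drop = FALSE]
  all_missing <- rowSums(!is.na(X)) == 0
  if (any(all_missing)) {
    warnf("metabolite(s) fully missing, left unimputed: %s",
          paste(rownames(X)[all_missing], collapse = ", "))
  }
  for (i in which(rowSums(is.na(X)) > 0 & !all_missing)) {
    obs <- !is.na(X[i, ])
    diffs <- sweep(Xc[, obs, drop = FALSE], 2, X[i, obs], "-")
    d2 <- rowMeans(diffs^2)      # mean over co-observed samples
    cand <- comp_idx[comp_idx != i]
    dd <- d2[comp_idx != i]
    if (!length(cand)) next
    kk <- min(k, length(cand))
    nn <- cand[order(dd, cand)[seq_len(kk)]]
    miss_s <- which(is.na(X[i, ]))
    X[i, miss_s] <- colMeans(X[nn, miss_s, drop = FALSE])
  }
  table$values <- t(X)
  table
}

#' Replicate-mean temporal profiles
#'
#' Collapses replicates to a metabolites-by-timepoints matrix of means, the
#' input to correlation mapping and hierarchical clustering of profiles.
#'
#' @param table A scaled-stage, fully observed [metab_table()].
#' @return A numeric matrix (metabolites x days) with class `mean_profiles`
#'   and an attribute `days` giving the ordered time points.
#' @export
aggregate_means <- function(table) {
  require_stage(table, "scaled", "aggregate_means")
  if (anyNA(table$values)) stopf("aggregate_means() requires a fully observed table; impute first")
  days <- sort(unique(table$samples$day))
  out <- vapply(days, function(d) {
    colMeans(table$values[table$samples$day == d, , drop = FALSE])
  }, numeric(ncol(table$values)))
  out <- matrix(out, nrow = ncol(table$values),
                dimnames = list(colnames(table$values), as.character(days)))
  attr(out, "days") <- days
  class(out) <- c("mean_profiles", class(out))
  out
}

#' Per-day ratio of two metabolites
#'
#' Biochemical ratio index (e.g. stigmasterol / beta-sitosterol as a membrane
#' activity marker), computed on normalized (pre-log) abundances: the
#' per-sample ratio is averaged within each day, with its replicate SD. Days
#' where the denominator's mean is zero are reported as undefined (`NA`).
#'
#' @param table A normalized-stage [metab_table()].
#' @param numerator,denominator Metabolite names.
#' @return `data.frame` with columns `day`, `ratio`, `sd`.
#' @export
ratio_index <- function(table, numerator, denominator) {
  require_stage(table, "normalized", "ratio_index")
  for (m in c(numerator, denominator)) {
    if (!m %in% colnames(table$values)) stopf("metabolite '%s' not present", m)
  }
  days <- sort(unique(table$samples$day))
  num <- table$values[, numerator]
  den <- table$values[, denominator]
  res <- lapply(days, function(d) {
    idx <- table$samples$day == d
    dmean <- mean(den[idx], na.rm = TRUE)
    if (is.na(dmean) || dmean == 0) {
      return(data.frame(day = d, ratio = NA_real_, sd = NA_real_))
    }
    r <- num[idx] / den[idx]
    data.frame(day = d, ratio = mean(r, na.rm = TRUE),
               sd = stats::sd(r[!is.na(r)]))
  })
  do.call(rbind, res)
}
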