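# Shared fixture builders for the test suite. All fixtures are constructed
# in code; no data files are read from disk except ones a test writes itself.

# A minimal metab_table from a plain matrix: one day per row-group unless
# days/replicates are given explicitly.
make_table <- function(values, days = NULL, replicates = NULL, stage = "raw",
                       classes = NULL) {
  values <- as.matrix(values)
  n <- nrow(values); m <- ncol(values)
  if (is.null(days)) days <- rep(1L, n)
  if (is.null(replicates)) {
    replicates <- stats::ave(seq_len(n), days, FUN = seq_along)
  }
  if (is.null(colnames(values))) colnames(values) <- paste0("m", seq_len(m))
  if (is.null(classes)) classes <- rep("other", m)
  metab_table(
    values,
    samples = data.frame(
      sample_id = sprintf("s%02d", seq_len(n)),
      day = as.integer(days), replicate = as.integer(replicates)),
    metabolites = data.frame(name = colnames(values), class = classes,
                             id_level = rep("identified", m)),
    stage = stage
  )
}

# Full preprocessing chain on a raw table.
preprocess_chain <- function(table, k = 10) {
  knn_impute(autoscale(log_transform(median_normalize(table))), k = k)
}

# Data matrix with an exact prescribed sample covariance (n = 4 rows).
# Columns of `cov_chol` decomposition are realized through two orthogonal
# mean-zero score vectors.
matrix_with_cov <- function(sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  t1 <- c(-3, -1, 1, 3); t2 <- c(1, -1, -1, 1)
  scores <- cbind(t1 / stats::sd(t1), t2 / stats::sd(t2))
  scores %*% diag(sqrt(e$values)) %*% t(e$vectors)
}

# Two-group data (samples x metabolites) with a y-aligned component on v1
# and a y-orthogonal component on v2, with exact Frobenius variance shares.
structured_two_group <- function(n_per_group = 10, n_met = 30,
                                 share_pred = 0.6, seed = 42) {
  with_seed(seed, {
    n <- 2 * n_per_group
    y <- rep(c(-1, 1), each = n_per_group)
    z <- rep(c(1, -1), times = n_per_group)   # orthogonal to y, mean 0
    v <- qr.Q(qr(matrix(stats::rnorm(n_met * 2), ncol = 2)))
    X1 <- tcrossprod(y, v[, 1])
    X2 <- tcrossprod(z, v[, 2])
    X <- X1 * sqrt(share_pred) + X2 * sqrt(1 - share_pred)
    list(X = X, y = y,
         days = ifelse(y < 0, 1L, 2L))
  })
}

with_seed <- metabatch:::with_seed
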