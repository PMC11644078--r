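#' Canberra distance between two vectors
#'
#' `sum_i |u_i - v_i| / (|u_i| + |v_i|)`, with coordinates where both
#' entries are zero contributing 0 (the common convention for the undefined
#' 0/0 term). The distance is scale-sensitive and emphasizes proportional
#' differences near zero; in this package it is applied to replicate vectors
#' of standardized abundances, where values may be negative and the
#' absolute-value form above is used as-is.
#'
#' @param u,v Numeric vectors of equal length (>= 2).
#' @return Non-negative numeric scalar; 0 iff `u` and `v` are identical.
#' @export
#' @examples
#' canberra(c(1, 2), c(3, 4)) # 1/2 + 1/3
canberra <- function(u, v) {
  if (length(u) != length(v)) stopf("vectors differ in length")
  if (length(u) < 2) stopf("vectors must have length >= 2")
  den <- abs(u) + abs(v)
  num <- abs(u - v)
  sum(ifelse(den == 0, 0, num / den))
}

#' Per-time-point Canberra distances between metabolite pairs
#'
#' For each sampling day and each unordered metabolite pair, the Canberra
#' distance between the two metabolites' replicate vectors at that day.
#' The result is the replicate-level variability fingerprint: a matrix with
#' one row per day and one column per pair (`M*(M-1)/2` columns,
#' lexicographic by metabolite index, named `"metA|metB"`).
#'
#' @param table A fully observed [metab_table()] at stage `scaled` (the
#'   standardized fingerprint) or `normalized` (the positive-value variant);
#'   the stage used is recorded in the `space` attribute.
#' @return Numeric matrix (days x pairs) of class `fingerprint_matrix`, with
#'   attributes `days`, `pairs` and `space`.
#' @export
pair_distance_matrix <- function(table) {
  stopifnot(inherits(table, "metab_table"))
  if (!table$stage %in% c("scaled", "normalized")) {
    stopf("pair_distance_matrix() requires a scaled or normalized table")
  }
  if (anyNA(table$values)) stopf("table must be fully observed; impute first")
  days <- sort(unique(table$samples$day))
  reps_per_day <- vapply(days, function(d) sum(table$samples$day == d), integer(1))
  usable <- reps_per_day >= 2
  if (!all(usable)) {
    warnf("day(s) with fewer than 2 replicates skipped: %s",
          paste(days[!usable], collapse = ", "))
    days <- days[usable]
  }
  if (!length(days)) stopf("no day with at least 2 replicates")
  M <- ncol(table$values)
  mets <- colnames(table$values)
  ut <- upper.tri(matrix(0, M, M))
  pair_i <- row(ut)[ut]; pair_j <- col(ut)[ut]
  ord <- order(pair_i, pair_j)           # lexicographic by metabolite index
  pair_i <- pair_i[ord]; pair_j <- pair_j[ord]
  fp <- matrix(NA_real_, nrow = length(days), ncol = length(pair_i),
               dimnames = list(as.character(days),
                               paste(mets[pair_i], mets[pair_j], sep = "|")))
  for (d in seq_along(days)) {
    rows <- which(table$samples$day == days[d])
    acc <- matrix(0, M, M)
    for (r in rows) {
      x <- table$values[r, ]
      num <- abs(outer(x, x, "-"))
      den <- outer(abs(x), abs(x), "+")
      term <- ifelse(den == 0, 0, num / den)
      acc <- acc + term
    }
    fp[d, ] <- acc[cbind(pair_i, pair_j)]
  }
  attr(fp, "days") <- days
  attr(fp, "pairs") <- data.frame(first = mets[pair_i], second = mets[pair_j],
                                  stringsAsFactors = FALSE)
  attr(fp, "space") <- table$stage
  class(fp) <- c("fingerprint_matrix", class(fp))
  fp
}

#' Cluster time points in pair-distance space
#'
#' Computes pairwise Canberra distances between the rows of the fingerprint
#' matrix (each row is one day's vector of metabolite-pair distances) and
#' clusters the days hierarchically.
#'
#' @param fp A [pair_distance_matrix()] result.
#' @param linkage Agglomeration method for [stats::hclust()]; default
#'   `"average"`.
#' @return List with `tree` (`hclust` over days), `metric`, `linkage`,
#'   `leaf_order` and the day-by-day `distances` matrix.
#' @export
cluster_timepoints <- function(fp, linkage = "average") {
  X <- unclass(fp)
  D <- nrow(X)
  if (D < 2) stopf("need at least 2 time points")
  dm <- matrix(0, D, D, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(D - 1)) {
    for (j in (i + 1):D) {
      dm[i, j] <- dm[j, i] <- canberra(X[i, ], X[j, ])
    }
  }
  tree <- stats::hclust(stats::as.dist(dm), method = linkage)
  list(tree = tree, metric = "canberra", linkage = linkage,
       leaf_order = tree$labels[tree$order], distances = dm)
}

#' Write a fingerprint matrix and time-point tree to disk
#'
#' The matrix goes to a wide TSV (row = day, column = `"metA|metB"`), the
#' dendrogram to Newick.
#'
#' @param fp A [pair_distance_matrix()] result.
#' @param clustering Optional [cluster_timepoints()] result.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the vector of written paths.
#' @export
write_fingerprint <- function(fp, clustering = NULL, dir, prefix = "fingerprint") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(matrix = file.path(dir, paste0(prefix, "_pairs.tsv")))
  df <- data.frame(day = rownames(unclass(fp)), unclass(fp),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, paths["matrix"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(clustering)) {
    paths["tree"] <- file.path(dir, paste0(prefix, "_days.nwk"))
    phy <- ape::as.phylo(clustering$tree)
    ape::write.tree(phy, paths["tree"])
  }
  invisible(paths)
}
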