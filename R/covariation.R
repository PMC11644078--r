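#' Correlation matrix of mean temporal profiles
#'
#' Pearson or Spearman correlation between metabolite mean profiles across
#' time points. Constant profiles have undefined correlation; their entries
#' are set to 0 and the profiles flagged.
#'
#' @param profiles A `mean_profiles` matrix (metabolites x timepoints) from
#'   [aggregate_means()], or any numeric matrix with >= 3 columns.
#' @param method `"pearson"` or `"spearman"`.
#' @return Symmetric correlation matrix with unit diagonal; attributes
#'   `method` and `flagged` (constant profiles).
#' @export
correlation_matrix <- function(profiles, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  X <- unclass(profiles)
  attr(X, "days") <- NULL
  if (ncol(X) < 3) stopf("need at least 3 timepoints")
  r <- suppressWarnings(stats::cor(t(X), method = method))
  flagged <- rownames(X)[apply(X, 1, stats::sd) == 0]
  r[is.na(r)] <- 0
  diag(r) <- 1
  attr(r, "method") <- method
  attr(r, "flagged") <- flagged
  r
}

#' Threshold a correlation matrix into a signed network
#'
#' Keeps an undirected edge for every metabolite pair with `|r|` above the
#' threshold, retaining the correlation value and its sign.
#'
#' @param corr Correlation matrix from [correlation_matrix()].
#' @param threshold Absolute-correlation cutoff in (0, 1); default 0.85.
#' @return An object of class `corr_network`: list with `nodes`, `corr`,
#'   `edges` (`data.frame` source/target/r/sign), `threshold`, `method`;
#'   `layout` and `clusters` are filled by [layout_signed()] and
#'   [cluster_nodes()].
#' @export
build_network <- function(corr, threshold = 0.85) {
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be inside (0, 1)")
  nodes <- rownames(corr)
  ut <- which(upper.tri(corr) & abs(corr) > threshold, arr.ind = TRUE)
  edges <- data.frame(
    source = nodes[ut[, 1]],
    target = nodes[ut[, 2]],
    r = corr[ut],
    sign = ifelse(corr[ut] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, corr = corr, edges = edges,
                 threshold = threshold, method = attr(corr, "method"),
                 layout = NULL, clusters = NULL),
            class = "corr_network")
}

#' @export
print.corr_network <- function(x, ...) {
  cat(sprintf("corr_network: %d nodes, %d edges (|r| > %.2f, %s; %d negative)\n",
              length(x$nodes), nrow(x$edges), x$threshold,
              x$method %||% "?", sum(x$edges$sign == "negative")))
  if (!is.null(x$clusters)) {
    cat(sprintf("  clusters: %s\n", paste(table(x$clusters), collapse = ", ")))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signed force-directed layout
#'
#' Places nodes in the plane so that positively correlated metabolites are
#' pulled together (attraction proportional to the edge correlation,
#' normalized by node degree so that hubs do not collapse the embedding)
#' while all node pairs repel, with extra repulsion along negative edges;
#' a cooling schedule caps per-iteration displacement. Positions are initialized from the two leading eigenvectors of
#' the correlation matrix (a spectral sketch of the block structure) plus a
#' small seeded jitter, which makes the optimization start near a sensible
#' embedding and keeps the result deterministic for a given seed.
#' Coordinates are centered at the origin.
#'
#' @param network A [build_network()] result.
#' @param seed Integer seed for the initial-placement jitter.
#' @param iterations Number of force iterations.
#' @return The network with `layout` filled (nodes x 2 coordinate matrix).
#' @export
layout_signed <- function(network, seed = 1, iterations = 300) {
  stopifnot(inherits(network, "corr_network"))
  n <- length(network$nodes)
  if (n < 2) stopf("need at least 2 nodes")
  # signed adjacency: positive weights attract, negative add repulsion
  A <- matrix(0, n, n, dimnames = list(network$nodes, network$nodes))
  if (nrow(network$edges)) {
    si <- match(network$edges$source, network$nodes)
    ti <- match(network$edges$target, network$nodes)
    A[cbind(si, ti)] <- network$edges$r
    A[cbind(ti, si)] <- network$edges$r
  }
  Apos <- pmax(A, 0)
  Aneg <- pmax(-A, 0)
  deg <- pmax(rowSums(Apos), 1)        # weighted positive degree
  k <- sqrt(1 / n)                     # ideal pairwise spacing (unit area)
  # spectral initialization + seeded jitter
  ev <- eigen(network$corr, symmetric = TRUE)
  init <- ev$vectors[, 1:2, drop = FALSE] %*% diag(sqrt(pmax(ev$values[1:2], 0)), 2, 2)
  init <- init / max(1e-12, max(abs(init)))
  pos <- init + with_seed(seed, matrix(stats::rnorm(2 * n, sd = 0.02), ncol = 2))
  temp <- 0.1
  cool <- temp / iterations
  for (it in seq_len(iterations)) {
    dx <- outer(pos[, 1], pos[, 1], "-")
    dy <- outer(pos[, 2], pos[, 2], "-")
    d2 <- dx^2 + dy^2
    d2[d2 < 1e-8] <- 1e-8
    d <- sqrt(d2)
    # repulsion k^2/d for all pairs, tripled along negative edges
    rep_c <- k^2 / d2 * (1 + 3 * Aneg)
    # constant-magnitude attraction proportional to r, normalized by the
    # node's positive degree so that hubs do not collapse the embedding
    att_c <- (Apos / deg) / d
    coef <- rep_c - att_c
    fx <- rowSums(coef * dx)
    fy <- rowSums(coef * dy)
    fn <- sqrt(fx^2 + fy^2)
    fn[fn < 1e-12] <- 1e-12
    step <- pmin(fn, temp)
    pos[, 1] <- pos[, 1] + fx / fn * step
    pos[, 2] <- pos[, 2] + fy / fn * step
    temp <- temp - cool
    if (temp <= 0) temp <- 1e-4
  }
  pos <- sweep(pos, 2, colMeans(pos), "-")
  dimnames(pos) <- list(network$nodes, c("x", "y"))
  network$layout <- pos
  network
}

#' K-means clustering of network nodes in layout coordinates
#'
#' Clusters the 2-D layout coordinates with k-means (best of `n_init`
#' restarts by within-cluster sum of squares). Labels are renumbered by
#' decreasing cluster size (ties by smallest member index) so the labeling
#' is deterministic.
#'
#' @param network A network with layout (see [layout_signed()]).
#' @param k Number of clusters (>= 2, <= node count); default 4.
#' @param seed Integer seed.
#' @param n_init Number of k-means restarts.
#' @return The network with `clusters` filled (named integer vector).
#' @export
cluster_nodes <- function(network, k = 4, seed = 1, n_init = 50) {
  stopifnot(inherits(network, "corr_network"))
  if (is.null(network$layout)) stopf("layout not computed; call layout_signed() first")
  n <- length(network$nodes)
  if (k < 2) stopf("k must be at least 2")
  if (k > n) stopf("k exceeds node count")
  km <- with_seed(seed, {
    if (k == n) {
      list(cluster = seq_len(n))
    } else {
      stats::kmeans(network$layout, centers = k, nstart = n_init,
                    iter.max = 100)
    }
  })
  labels <- km$cluster
  size <- table(labels)
  first <- vapply(names(size), function(l) min(which(labels == l)), integer(1))
  new_order <- names(size)[order(-size, first)]
  relabel <- stats::setNames(seq_along(new_order), new_order)
  network$clusters <- stats::setNames(unname(relabel[as.character(labels)]),
                                      network$nodes)
  network
}

#' Per-cluster median dynamics and class composition
#'
#' For each cluster, the per-day median and inter-quartile band of the
#' member profiles and a tally of chemical classes.
#'
#' @param labels Named integer cluster labels covering all profile rows.
#' @param profiles A `mean_profiles` matrix.
#' @param annotation Named character vector metabolite -> class (or a
#'   `data.frame` with `name` and `class` columns).
#' @return List of per-cluster lists with `cluster`, `n`, `days`, `median`,
#'   `q25`, `q75`, `composition`.
#' @export
cluster_dynamics <- function(labels, profiles, annotation) {
  X <- unclass(profiles)
  if (!all(rownames(X) %in% names(labels))) {
    stopf("labels do not cover all metabolites")
  }
  if (is.data.frame(annotation)) {
    annotation <- stats::setNames(annotation$class, annotation$name)
  }
  days <- attr(profiles, "days") %||% as.numeric(colnames(X))
  lapply(sort(unique(labels)), function(cl) {
    members <- names(labels)[labels == cl]
    sub <- X[members, , drop = FALSE]
    list(cluster = cl,
         n = length(members),
         days = days,
         median = apply(sub, 2, stats::median),
         q25 = apply(sub, 2, stats::quantile, probs = 0.25, names = FALSE),
         q75 = apply(sub, 2, stats::quantile, probs = 0.75, names = FALSE),
         composition = table(annotation[members], useNA = "ifany"))
  })
}

#' Inside- versus outside-pathway correlation contrast
#'
#' Partitions all unordered metabolite pairs by pathway membership: pairs
#' sharing at least one pathway ("inside"), annotated pairs sharing none
#' ("outside"), pairs with an unannotated member (kept only in "all").
#' Reports the three correlation distributions, per-pathway within-pair
#' values, medians, and the median shift `median(inside) - median(outside)`
#' summarizing how much pathway co-membership pushes correlations up.
#'
#' @param corr Correlation matrix (Spearman recommended for this contrast).
#' @param annotation A [pathway_annotation()].
#' @return An object of class `pair_contrast`: list with `all`, `inside`,
#'   `outside`, `per_pathway`, `summary`.
#' @export
pathway_pair_correlations <- function(corr, annotation) {
  stopifnot(inherits(annotation, "pathway_annotation"))
  nodes <- rownames(corr)
  # membership matrix: metabolites x pathways
  memb <- vapply(annotation$sets, function(s) nodes %in% s,
                 logical(length(nodes)))
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = length(nodes))
  annotated <- rowSums(memb) > 0
  if (sum(annotated) < 2) stopf("no annotated metabolite pair available")
  shared <- tcrossprod(memb * 1)        # pairs sharing >= 1 pathway
  ut <- upper.tri(corr)
  all_pairs <- corr[ut]
  ann_pair <- outer(annotated, annotated, "&")
  inside_mask <- ut & ann_pair & shared > 0
  outside_mask <- ut & ann_pair & shared == 0
  if (!any(inside_mask | outside_mask)) stopf("no annotated metabolite pair available")
  per_pathway <- lapply(names(annotation$sets), function(pid) {
    m <- which(nodes %in% annotation$sets[[pid]])
    if (length(m) < 2) return(numeric(0))
    sub <- corr[m, m]
    sub[upper.tri(sub)]
  })
  names(per_pathway) <- names(annotation$sets)
  inside <- corr[inside_mask]
  outside <- corr[outside_mask]
  structure(list(
    all = all_pairs, inside = inside, outside = outside,
    per_pathway = per_pathway,
    summary = list(
      median_all = stats::median(all_pairs),
      median_inside = stats::median(inside),
      median_outside = stats::median(outside),
      median_shift = stats::median(inside) - stats::median(outside),
      n_inside = length(inside), n_outside = length(outside)
    )
  ), class = "pair_contrast")
}

#' @export
print.pair_contrast <- function(x, ...) {
  s <- x$summary
  cat(sprintf("pair_contrast: %d inside / %d outside pairs\n", s$n_inside, s$n_outside))
  cat(sprintf("  medians: all %.3f, inside %.3f, outside %.3f (shift %+.3f)\n",
              s$median_all, s$median_inside, s$median_outside, s$median_shift))
  invisible(x)
}

#' Export a correlation network
#'
#' Writes the network as GraphML (via igraph) plus edge-list, layout and
#' cluster TSV files.
#'
#' @param network A `corr_network`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the vector of written paths.
#' @export
write_network <- function(network, dir, prefix = "network") {
  stopifnot(inherits(network, "corr_network"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(edges = file.path(dir, paste0(prefix, "_edges.tsv")),
             graphml = file.path(dir, paste0(prefix, ".graphml")))
  utils::write.table(network$edges, paths["edges"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = data.frame(name = network$nodes))
  if (!is.null(network$clusters)) {
    igraph::V(g)$cluster <- unname(network$clusters[network$nodes])
  }
  if (!is.null(network$layout)) {
    igraph::V(g)$x <- network$layout[, 1]
    igraph::V(g)$y <- network$layout[, 2]
    paths["layout"] <- file.path(dir, paste0(prefix, "_layout.tsv"))
    utils::write.table(
      data.frame(metabolite = network$nodes, x = network$layout[, 1],
                 y = network$layout[, 2],
                 cluster = if (is.null(network$clusters)) NA else unname(network$clusters)),
      paths["layout"], sep = "\t", row.names = FALSE, quote = FALSE)
  }
  igraph::write_graph(g, paths["graphml"], format = "graphml")
  invisible(paths)
}
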