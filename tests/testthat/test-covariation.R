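test_that("correlation matrices match closed-form values", {
  x <- c(1, 2, 3)
  prof <- rbind(a = x, b = 2 * x, c = c(10, 30, 20), d = rev(x))
  cp <- correlation_matrix(prof, "pearson")
  cs <- correlation_matrix(prof, "spearman")
  expect_equal(cp["a", "b"], 1)
  expect_equal(cs["a", "b"], 1)
  expect_equal(cs["a", "c"], 0.5)       # ranks (1,2,3) vs (1,3,2)
  expect_equal(cp["a", "d"], -1)
  expect_true(isSymmetric(cp))
  expect_equal(unname(diag(cp)), rep(1, 4))
  expect_error(correlation_matrix(prof[, 1:2, drop = FALSE]), "3 timepoints")
  # constant profile: entries zeroed and flagged
  pc <- correlation_matrix(rbind(a = x, k = c(5, 5, 5)))
  expect_identical(attr(pc, "flagged"), "k")
  expect_equal(pc["a", "k"], 0)
})

test_that("network thresholding keeps signed super-threshold pairs", {
  cm <- matrix(c(1, 0.99, -0.99,
                 0.99, 1, 0.10,
                 -0.99, 0.10, 1), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  net <- build_network(cm, threshold = 0.85)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$sign, c("positive", "negative"))
  expect_error(build_network(cm, threshold = 1.2), "threshold")
  expect_error(build_network(cm, threshold = 0), "threshold")
  # duplicated metabolite keeps exactly one twin edge with r = 1
  x <- c(1, 5, 2, 4, 3)
  set.seed(1)
  prof <- rbind(a = x, a2 = x, z = rnorm(5))
  net2 <- build_network(correlation_matrix(prof), 0.85)
  twin <- net2$edges[net2$edges$source == "a" & net2$edges$target == "a2", ]
  expect_equal(nrow(twin), 1)
  expect_equal(twin$r, 1)
  # edge count equals super-threshold off-diagonal pairs / 2
  expect_equal(nrow(net2$edges),
               sum(abs(correlation_matrix(prof)) > 0.85 &
                     upper.tri(net2$corr)))
})

test_that("signed layout contracts positive pairs and is reproducible", {
  cm_pos <- matrix(c(1, 0.99, 0.99, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  cm_neg <- matrix(c(1, -0.99, -0.99, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  pos_net <- layout_signed(build_network(cm_pos, 0.85), seed = 1, iterations = 150)
  neg_net <- layout_signed(build_network(cm_neg, 0.85), seed = 1, iterations = 150)
  d_pos <- dist(pos_net$layout)[1]
  d_neg <- dist(neg_net$layout)[1]
  expect_lt(d_pos, d_neg)
  again <- layout_signed(build_network(cm_pos, 0.85), seed = 1, iterations = 150)
  expect_identical(pos_net$layout, again$layout)
  # coordinates centered at the origin
  expect_equal(unname(colMeans(pos_net$layout)), c(0, 0), tolerance = 1e-9)
})

test_that("planted two-block structure stays separated in the layout", {
  ok <- 0
  for (seed in 1:20) {
    blocks <- rep(1:2, each = 10)
    cm <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.95, -0.9))
    diag(cm) <- 1
    # seeded wiggle so the instance is not perfectly symmetric
    noise <- with_seed(seed, matrix(runif(400, -0.02, 0.02), 20))
    cm <- (cm + (noise + t(noise)) / 2)
    diag(cm) <- 1
    dimnames(cm) <- list(paste0("n", 1:20), paste0("n", 1:20))
    net <- layout_signed(build_network(cm, 0.85), seed = seed, iterations = 200)
    d <- as.matrix(dist(net$layout))
    within <- mean(d[outer(blocks, blocks, "==") & upper.tri(d)])
    between <- mean(d[outer(blocks, blocks, "!=") & upper.tri(d)])
    if (within < between) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("k-means node clustering is exact on separated blobs", {
  cm <- diag(6); dimnames(cm) <- list(paste0("n", 1:6), paste0("n", 1:6))
  net <- build_network(cm + 0.001 - diag(0.001, 6), 0.5)
  net$layout <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1),
                      c(5, 5), c(5.1, 5), c(5, 5.1))
  dimnames(net$layout) <- list(net$nodes, c("x", "y"))
  out <- cluster_nodes(net, k = 2, seed = 1, n_init = 10)
  expect_equal(unname(out$clusters), c(1, 1, 1, 2, 2, 2))
  # k = node count: singleton clusters
  out2 <- cluster_nodes(net, k = 6, seed = 1)
  expect_equal(sort(unname(out2$clusters)), 1:6)
  expect_error(cluster_nodes(net, k = 1), "k must be")
  expect_error(cluster_nodes(net, k = 7), "exceeds")
})

test_that("cluster dynamics summarize medians, IQR and composition", {
  prof <- rbind(m1 = c(0, 1), m2 = c(0, 3), m3 = c(9, 9))
  attr(prof, "days") <- c(1, 2)
  class(prof) <- c("mean_profiles", class(prof))
  labels <- c(m1 = 1L, m2 = 1L, m3 = 2L)
  ann <- c(m1 = "sugars", m2 = "other", m3 = "sugars")
  dyn <- cluster_dynamics(labels, prof, ann)
  expect_equal(unname(dyn[[1]]$median), c(0, 2))
  expect_equal(dyn[[1]]$n, 2)
  expect_equal(sum(dyn[[1]]$composition), 2)
  expect_equal(sum(dyn[[2]]$composition), 1)
  # singleton cluster: median is the profile, zero IQR
  expect_equal(unname(dyn[[2]]$median), c(9, 9))
  expect_equal(unname(dyn[[2]]$q75 - dyn[[2]]$q25), c(0, 0))
})

test_that("inside/outside pair partition enumerates correctly", {
  cm <- diag(4)
  cm[upper.tri(cm)] <- c(0.5, 0.2, 0.3, 0.1, 0.6, 0.4)
  cm <- cm + t(cm) - diag(4)
  dimnames(cm) <- list(paste0("m", 1:4), paste0("m", 1:4))
  ann <- pathway_annotation(list(P1 = c("m1", "m2"), P2 = c("m3", "m4")))
  pc <- pathway_pair_correlations(cm, ann)
  expect_length(pc$inside, 2)
  expect_length(pc$outside, 4)
  expect_length(pc$all, 6)
  expect_setequal(pc$inside, c(cm["m1", "m2"], cm["m3", "m4"]))
  # one pathway covering everything: outside empty
  pc2 <- pathway_pair_correlations(cm, pathway_annotation(list(P = paste0("m", 1:4))))
  expect_length(pc2$inside, 6)
  expect_length(pc2$outside, 0)
  # unannotated members excluded from the partition but present in 'all'
  ann3 <- pathway_annotation(list(P1 = c("m1", "m2")))
  pc3 <- pathway_pair_correlations(cm, ann3)
  expect_length(pc3$inside, 1)
  expect_length(pc3$outside, 0)
  expect_equal(length(pc3$inside) + length(pc3$outside) + 5, length(pc3$all))
  expect_error(pathway_pair_correlations(cm, pathway_annotation(list(Q = "zz"))),
               "no annotated")
})

test_that("archetype clusters are recovered through the network pipeline", {
  ds <- simulate_metabolome(sim_config(n_metabolites = 150, seed = 14))
  tab <- preprocess_chain(ds$table)
  net <- build_network(correlation_matrix(aggregate_means(tab)), 0.85)
  net <- cluster_nodes(layout_signed(net, seed = 14, iterations = 300),
                       k = 4, seed = 14)
  ari <- adjusted_rand_index(ds$truth_clusters[net$nodes], net$clusters)
  expect_gte(ari, 0.8)
  # internal ARI agrees with the mclust reference implementation
  expect_equal(ari,
               mclust::adjustedRandIndex(ds$truth_clusters[net$nodes],
                                         net$clusters),
               tolerance = 1e-12)
})

test_that("network export writes edge list, layout and GraphML", {
  ds <- simulate_metabolome(sim_config(n_metabolites = 30, seed = 2))
  tab <- preprocess_chain(ds$table)
  net <- build_network(correlation_matrix(aggregate_means(tab)), 0.85)
  net <- cluster_nodes(layout_signed(net, seed = 1, iterations = 50), k = 2, seed = 1)
  dir <- tempfile("net")
  paths <- write_network(net, dir)
  expect_true(all(file.exists(paths)))
  g <- igraph::read_graph(paths["graphml"], format = "graphml")
  expect_equal(igraph::gorder(g), 30)
  expect_equal(igraph::gsize(g), nrow(net$edges))
})
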