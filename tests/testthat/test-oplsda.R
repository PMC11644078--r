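scaled_from_matrix <- function(X, days) {
  make_table(X, days = days, stage = "scaled")
}

test_that("with no orthogonal structure the predictive axis is the class axis", {
  s <- structured_two_group(share_pred = 1, n_met = 20, seed = 1)
  tab <- scaled_from_matrix(s$X + matrix(rnorm(length(s$X), 0, 1e-8),
                                         nrow(s$X)), s$days)
  m <- fit_oplsda(tab, list(1, 2), n_ortho = 1)
  v1 <- svd(s$X)$v[, 1]
  cosine <- abs(sum(m$p_pred * v1) / sqrt(sum(m$p_pred^2) * sum(v1^2)))
  expect_gt(cosine, 0.999)
  expect_lte(m$n_ortho, 1)
  expect_gt(m$r2x_pred, 0.99)
})

test_that("constructed variance shares are recovered as r2x_pred", {
  s <- structured_two_group(share_pred = 0.6, n_met = 30, seed = 42)
  m <- fit_oplsda(scaled_from_matrix(s$X, s$days), list(1, 2), n_ortho = 1)
  expect_equal(m$r2x_pred, 0.60, tolerance = 0.02)
  expect_equal(sum(m$r2x_ortho) + m$r2x_residual, 0.40, tolerance = 0.02)
})

test_that("OPLS components satisfy orthogonality and variance bookkeeping", {
  for (seed in 1:5) {
    ds <- simulate_metabolome(sim_config(n_metabolites = 50, seed = seed,
                                         missing_rate = 0))
    tab <- preprocess_chain(ds$table)
    m <- fit_oplsda(tab, list(c(1, 2), c(4, 7)), n_ortho = 2)
    if (m$n_ortho > 0) {
      for (j in seq_len(m$n_ortho)) {
        expect_lt(abs(cor(m$t_ortho[, j], m$y)), 1e-9)
        expect_lt(abs(sum(m$t_pred * m$t_ortho[, j])), 1e-6)
      }
    }
    expect_equal(m$r2x_pred + sum(m$r2x_ortho) + m$r2x_residual, 1,
                 tolerance = 1e-9)
    expect_gte(m$r2x_pred, 0); expect_lte(m$r2x_pred, 1)
    # sign convention: later day-set has positive mean predictive score
    expect_gt(mean(m$t_pred[m$y == 1]), 0)
    # VIP normalization
    expect_equal(mean(m$vip^2), 1, tolerance = 1e-9)
  }
})

test_that("VIP follows its closed form", {
  # equal weights: all VIPs are 1
  s <- structured_two_group(share_pred = 1, n_met = 8, seed = 2)
  m <- fit_oplsda(scaled_from_matrix(s$X, s$days), list(1, 2), n_ortho = 0)
  w <- m$w_pred
  expect_equal(unname(m$vip), unname(sqrt(length(w) * w^2 / sum(w^2))),
               tolerance = 1e-12)
  # direct J=2 example: weights (1, 0) -> VIPs (sqrt(2), 0)
  X <- cbind(m1 = c(-1, -1, -1, 1, 1, 1) * 2, m2 = rep(0, 6))
  tab <- scaled_from_matrix(X, rep(1:2, each = 3))
  m2 <- fit_oplsda(tab, list(1, 2), n_ortho = 0)
  expect_equal(unname(m2$vip), c(sqrt(2), 0), tolerance = 1e-12)
  expect_identical(vip_scores(m2), m2$vip)
})

test_that("VIP selection recovers planted two-group signal", {
  hits <- total <- 0
  for (seed in 1:20) {
    with_seed(seed + 100, {
      n <- 10; J <- 100
      X <- matrix(rnorm(2 * n * J), 2 * n, J)
      shifted <- sample(J, J %/% 10)
      X[(n + 1):(2 * n), shifted] <- X[(n + 1):(2 * n), shifted] + 2
      tab <- scaled_from_matrix(scale(X), rep(1:2, each = n))
      m <- fit_oplsda(tab, list(1, 2), n_ortho = 1)
      hits <- hits + sum(m$vip[shifted] > 1)
      total <- total + length(shifted)
    })
  }
  expect_gte(hits / total, 0.9)
})

test_that("model guards reject degenerate inputs", {
  s <- structured_two_group(n_per_group = 3, n_met = 10, seed = 3)
  tab <- scaled_from_matrix(s$X, s$days)
  expect_error(fit_oplsda(tab, list(1, 1)), "disjoint")
  expect_error(fit_oplsda(tab, list(1, 3)), "absent")
  expect_error(fit_oplsda(tab, list(1, 2), n_ortho = 10), "n_ortho")
  two <- make_table(matrix(rnorm(8), 4), days = c(1, 1, 2, 2), stage = "scaled")
  expect_error(fit_oplsda(two, list(1, 2)), "at least 3")
})

test_that("predict projects new samples onto the trained axis", {
  s <- structured_two_group(share_pred = 0.8, n_met = 20, seed = 5)
  tab <- scaled_from_matrix(s$X, s$days)
  m <- fit_oplsda(tab, list(1, 2), n_ortho = 1)
  pr <- predict(m, s$X)
  expect_identical(unname(pr$group[s$y == 1]),
                   rep("B", sum(s$y == 1)))
  expect_identical(unname(pr$group[s$y == -1]),
                   rep("A", sum(s$y == -1)))
})

test_that("univariate tests reproduce exact references and BH behaviour", {
  # exact two-sided MWW for {1,2,3} vs {4,5,6}: U = 0, p = 0.1
  vals <- cbind(m1 = c(1, 2, 3, 4, 5, 6), m2 = c(2, 2, 2, 2, 2, 2))
  tab <- make_table(vals, days = rep(1:2, each = 3), stage = "scaled")
  ut <- univariate_tests(tab, list(1, 2), test = "MWW")
  expect_equal(ut$p_raw[ut$metabolite == "m1"], 0.1)
  # all-tied metabolite reported with p = 1 and flagged
  expect_equal(ut$p_raw[ut$metabolite == "m2"], 1)
  expect_true(ut$flagged[ut$metabolite == "m2"])
  # identical groups under the t test: t = 0, p = 1
  vals2 <- cbind(m1 = c(1, 2, 3, 1, 2, 3))
  tt <- univariate_tests(make_table(vals2, days = rep(1:2, each = 3),
                                    stage = "scaled"),
                         list(1, 2), test = "t")
  expect_equal(tt$statistic[1], 0)
  expect_equal(tt$p_raw[1], 1)
  # BH keeps p_adj >= p_raw and hits the boundary when all p are equal
  p <- rep(0.03, 7)
  expect_equal(p.adjust(p, "BH"), p)
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(6 * 25), 6, 25)
    res <- univariate_tests(make_table(X, days = rep(1:2, each = 3),
                                       stage = "scaled"), list(1, 2), "t")
    expect_true(all(res$p_adj >= res$p_raw - 1e-12))
    ord <- order(res$p_raw)
    expect_true(all(diff(res$p_adj[ord]) >= -1e-12))
  }
})

test_that("differential calls combine VIP bands with adjusted p-values", {
  ds <- simulate_metabolome(sim_config(n_metabolites = 40, seed = 6,
                                       missing_rate = 0))
  tab <- preprocess_chain(ds$table)
  m <- fit_oplsda(tab, list(7, 14), n_ortho = 1)
  dc <- differential_calls(m, tab, test = "MWW")
  expect_equal(nrow(dc), 40)
  expect_true(all(dc$vip_band[dc$vip > 1] == "strong"))
  expect_true(all(dc$vip_band[dc$vip <= 0.9] == "none"))
  expect_true(all(dc$p_adj >= dc$p_raw - 1e-12))
  expect_identical(dc$direction[dc$loading >= 0][1], "up_in_B")
})
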