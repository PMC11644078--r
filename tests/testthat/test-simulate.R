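test_that("medium trajectory satisfies batch-culture milestones", {
  med <- simulate_medium()
  s0 <- med$sucrose[med$time == 0]
  expect_equal(s0, 30)
  r2 <- med$sucrose[med$time == 2] / s0
  expect_gte(r2, 0.4)
  expect_lte(r2, 0.6)
  expect_lt(med$sucrose[med$time == 7] / s0, 0.10)
  expect_lt(med$sucrose[med$time == 10], 0.5)
  # hexose rises then falls close to zero at culture death
  expect_gt(max(med$hexose), 10)
  expect_lt(med$hexose[med$time == 26], 1)
  peak <- which.max(med$hexose)
  expect_true(all(diff(med$hexose[seq_len(peak)]) >= 0) ||
                med$hexose[peak] > med$hexose[1])
  expect_true(all(diff(med$hexose[peak:nrow(med)]) <= 1e-9))
  # pH dips to ~5.1 then rises to ~6.3
  expect_gte(med$pH[med$time == 2], 5.0)
  expect_lte(med$pH[med$time == 2], 5.2)
  expect_gte(med$pH[med$time == 26], 6.2)
  expect_lte(med$pH[med$time == 26], 6.4)
  # sucrose non-increasing, all pools non-negative
  expect_true(all(diff(med$sucrose) <= 1e-9))
  expect_true(all(med$sucrose >= 0 & med$hexose >= 0 & med$biomass_dry >= 0))
})

test_that("medium model honours the no-flux identity and rejects bad input", {
  p <- medium_params()
  p$uptake_sucrose <- 0; p$hydrolysis <- 0; p$uptake_hexose <- 0
  med <- simulate_medium(p)
  expect_true(all(med$sucrose == 30))
  expect_true(all(med$hexose == 0))
  expect_true(all(med$biomass_dry == med$biomass_dry[1]))
  p2 <- medium_params(); p2$hydrolysis <- -1
  expect_error(simulate_medium(p2), "negative rate")
})

test_that("metabolome generator is deterministic and shaped as configured", {
  cfg <- sim_config(n_metabolites = 60, seed = 7)
  d1 <- simulate_metabolome(cfg)
  d2 <- simulate_metabolome(cfg)
  expect_identical(d1$table$values, d2$table$values)
  expect_identical(d1$truth_clusters, d2$truth_clusters)
  expect_identical(d1$truth_pathways$sets, d2$truth_pathways$sets)

  tab <- d1$table
  expect_equal(nrow(tab$values), 10 * 5)
  expect_equal(ncol(tab$values), 60)
  expect_setequal(unique(tab$samples$day), cfg$sampling_days)
  expect_true(all(d1$truth_clusters %in% 1:4))
  expect_length(d1$truth_clusters, 60)
  expect_true(all(tab$values[!is.na(tab$values)] > 0))
})

test_that("noiseless coupled pathway members have perfectly correlated profiles", {
  cfg <- sim_config(n_metabolites = 40, noise_sd = 0, within_pathway_coupling = 1,
                    amplitude_range = c(1.3, 1.3),
                    perturbation_sd = 0.3, time_jitter_sd = 0,
                    replicate_coupling_early = 0, replicate_coupling_late = 0,
                    missing_rate = 0, pathway_count = 4,
                    pathway_size_range = c(5, 5), seed = 3)
  ds <- simulate_metabolome(cfg)
  prof <- ds$truth_profiles
  for (pid in names(ds$truth_pathways$sets)) {
    members <- ds$truth_pathways$sets[[pid]]
    cl <- ds$truth_clusters[members]
    for (a in unique(cl)) {
      same <- members[cl == a]
      if (length(same) >= 2) {
        cc <- stats::cor(t(prof[same, , drop = FALSE]))
        expect_true(all(cc > 1 - 1e-9))
      }
    }
  }
})

test_that("k-means on true mean profiles recovers the archetype partition", {
  ds <- simulate_metabolome(sim_config(n_metabolites = 200, seed = 11))
  prof <- t(scale(t(ds$truth_profiles)))
  km <- with_seed(1, stats::kmeans(prof, centers = 4, nstart = 25))
  expect_gte(adjusted_rand_index(ds$truth_clusters, km$cluster), 0.9)
})

test_that("class composition biases archetype membership as planted", {
  ds <- simulate_metabolome(sim_config(n_metabolites = 360, seed = 5))
  cls <- ds$table$metabolites$class
  cl <- ds$truth_clusters
  frac_in <- function(classes, arch) {
    idx <- cls %in% classes
    mean(cl[idx] == arch)
  }
  expect_gt(frac_in(c("amino_acids", "sterols"), 1), 0.5)
  expect_gt(frac_in("sugars", 3), 0.45)
  expect_gt(frac_in(c("free_fatty_acids", "carboxylates"), 2), 0.4)
})

test_that("missingness injection hits the requested rate and keeps groups observed", {
  ds <- simulate_metabolome(sim_config(n_metabolites = 360, missing_rate = 0, seed = 2))
  tab0 <- ds$table
  expect_identical(inject_missingness(tab0, 0, seed = 1)$values, tab0$values)
  tab <- inject_missingness(tab0, 0.05, seed = 9)
  frac <- mean(is.na(tab$values))
  expect_gte(frac, 0.04)
  expect_lte(frac, 0.06)
  # no (metabolite, day) group fully missing
  for (d in unique(tab$samples$day)) {
    idx <- tab$samples$day == d
    expect_true(all(colSums(!is.na(tab$values[idx, , drop = FALSE])) >= 1))
  }
  expect_error(inject_missingness(tab0, 1), "rate")
})

test_that("invalid generator configurations are rejected", {
  expect_error(sim_config(archetype_assignment = c(`1` = 0.5, `2` = 0.2,
                                                   `3` = 0.2, `4` = 0.2)),
               "sum to 1")
  expect_error(sim_config(class_composition = c(a = 0.5, b = 0.4)), "sum to 1")
  expect_error(sim_config(sampling_days = c(1, 3, 2)), "increasing")
  expect_error(sim_config(n_replicates = 1), "n_replicates")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
})

test_that("written dataset round-trips through the text formats", {
  dir <- tempfile("ds")
  ds <- simulate_metabolome(sim_config(n_metabolites = 20, seed = 4,
                                       pathway_count = 3, missing_rate = 0.02))
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  back <- read_feature_table(paths["table"], paths["annotation"])
  expect_equal(back$values, ds$table$values)
  expect_identical(back$samples, ds$table$samples)
  expect_identical(back$metabolites, ds$table$metabolites)
  pw <- read_gmt(paths["pathways"])
  expect_identical(lapply(pw$sets, sort), lapply(ds$truth_pathways$sets, sort))
})
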