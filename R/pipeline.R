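#' Default contrast schedule
#'
#' The sequential day-pair comparisons walked by the analysis: subculturing
#' vs lag (21,23 vs 1,2), lag vs proliferation (1,2 vs 4,7), then each
#' adjacent later stage (7 vs 14, 14 vs 18, 18 vs 21, 21 vs 23, 23 vs 26).
#'
#' @return List of `list(A=, B=)` day-set pairs.
#' @export
default_contrasts <- function() {
  list(
    list(A = c(21, 23), B = c(1, 2)),
    list(A = c(1, 2), B = c(4, 7)),
    list(A = 7, B = 14),
    list(A = 14, B = 18),
    list(A = 18, B = 21),
    list(A = 21, B = 23),
    list(A = 23, B = 26)
  )
}

pipeline_defaults <- function() {
  list(
    seed = 1,
    outdir = NULL,
    simulation = NULL,
    input = NULL,
    preprocessing = list(knn_k = 10),
    contrasts = default_contrasts(),
    oplsda = list(n_ortho = 1),
    msea = list(n_perm = 500, weight = 1, min_size = 3),
    network = list(method = "pearson", threshold = 0.85, k = 4,
                   layout_iterations = 300, n_init = 50,
                   contrast_method = "spearman"),
    fingerprint = list(linkage = "average", space = "scaled")
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), materializes all defaults, and
#' performs structural validation, collecting every problem into one
#' aggregated error message.
#'
#' @param config Path to a YAML file, or a named list of options.
#' @return A validated configuration list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stopf("config must be a list or a YAML file path")
  def <- pipeline_defaults()
  unknown <- setdiff(names(config), names(def))
  cfg <- utils::modifyList(def, config[intersect(names(config), names(def))])
  # modifyList merges by name and so skips unnamed lists: take the contrast
  # schedule verbatim when the user supplies one
  if (!is.null(config$contrasts)) cfg$contrasts <- config$contrasts
  errors <- character(0)
  if (length(unknown)) {
    errors <- c(errors, sprintf("unknown field(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    errors <- c(errors, "seed: must be a single integer")
  }
  if (is.null(cfg$simulation) && is.null(cfg$input)) {
    cfg$simulation <- list()     # default: simulate with generator defaults
  }
  if (!is.null(cfg$input)) {
    for (f in c("table", "annotation")) {
      if (is.null(cfg$input[[f]])) {
        errors <- c(errors, sprintf("input: field '%s' is required", f))
      }
    }
  }
  if (!is.null(cfg$simulation)) {
    ok <- tryCatch({
      cfg$sim_config <- do.call(sim_config,
                                utils::modifyList(cfg$simulation,
                                                  list(seed = as.integer(cfg$seed))))
      TRUE
    }, error = function(e) e$message)
    if (!isTRUE(ok)) errors <- c(errors, paste0("simulation: ", ok))
  }
  if (!is.numeric(cfg$msea$n_perm) || cfg$msea$n_perm < 100) {
    errors <- c(errors, "msea.n_perm: must be a number >= 100")
  }
  if (cfg$msea$min_size < 1) errors <- c(errors, "msea.min_size: must be >= 1")
  if (cfg$network$threshold <= 0 || cfg$network$threshold >= 1) {
    errors <- c(errors, "network.threshold: must be inside (0, 1)")
  }
  if (!cfg$network$method %in% c("pearson", "spearman")) {
    errors <- c(errors, "network.method: must be 'pearson' or 'spearman'")
  }
  if (cfg$network$k < 2) errors <- c(errors, "network.k: must be >= 2")
  if (cfg$preprocessing$knn_k < 1) errors <- c(errors, "preprocessing.knn_k: must be >= 1")
  for (i in seq_along(cfg$contrasts)) {
    cc <- cfg$contrasts[[i]]
    if (is.null(cc$A) || is.null(cc$B)) {
      errors <- c(errors, sprintf("contrasts[%d]: needs day-sets 'A' and 'B'", i))
    } else if (length(intersect(cc$A, cc$B))) {
      errors <- c(errors, sprintf("contrasts[%d]: day-sets overlap (%s)", i,
                                  paste(intersect(cc$A, cc$B), collapse = ", ")))
    }
  }
  if (!cfg$fingerprint$space %in% c("scaled", "normalized")) {
    errors <- c(errors, "fingerprint.space: must be 'scaled' or 'normalized'")
  }
  if (length(errors)) {
    stopf("invalid pipeline configuration:\n  - %s", paste(errors, collapse = "\n  - "))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest, preprocessing, PCA, the sequential OPLS-DA
#' contrast schedule with differential calls and metabolite-set enrichment,
#' the correlation-network map with k-means clusters and dynamics, the
#' inside/outside-pathway contrast, and the Canberra fingerprint of time
#' points. Writes every intermediate artifact to `outdir` (if set) and a
#' machine-readable JSON report. Deterministic given the config seed.
#'
#' @param config A [validate_config()] result, a config list, or a YAML
#'   path.
#' @param quiet Suppress stage messages.
#' @return The report (a nested list, invisibly also written as JSON).
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  say <- function(fmt, ...) if (!quiet) message(sprintf(paste0("[metabatch] ", fmt), ...))
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  # --- data ---------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$input)) {
    dat <- run_stage("ingest", {
      tab <- read_feature_table(config$input$table, config$input$annotation)
      pw <- if (!is.null(config$input$pathways)) read_gmt(config$input$pathways) else NULL
      list(table = tab, pathways = pw)
    })
    say("ingested %d samples x %d metabolites", nrow(dat$table$values), ncol(dat$table$values))
  } else {
    dat <- run_stage("simulate", {
      ds <- simulate_metabolome(config$sim_config)
      list(table = ds$table, pathways = ds$truth_pathways, medium = ds$medium,
           truth = ds$truth_clusters)
    })
    truth <- dat$truth
    say("simulated %d samples x %d metabolites", nrow(dat$table$values), ncol(dat$table$values))
  }
  if (!is.null(config$input$overrides) && !is.null(dat$pathways)) {
    dat$pathways <- run_stage("pathway_overrides",
                              apply_pathway_overrides(dat$pathways, config$input$overrides))
  }

  # contrasts must reference days present in the data, before any computation
  data_days <- sort(unique(dat$table$samples$day))
  for (i in seq_along(config$contrasts)) {
    cc <- config$contrasts[[i]]
    absent <- setdiff(c(cc$A, cc$B), data_days)
    if (length(absent)) {
      stopf("contrasts[%d] references day(s) absent from the data: %s",
            i, paste(absent, collapse = ", "))
    }
  }

  # --- preprocessing ------------------------------------------------------
  normalized <- run_stage("preprocess", median_normalize(dat$table))
  scaled <- run_stage("preprocess", {
    knn_impute(autoscale(log_transform(normalized)), k = config$preprocessing$knn_k)
  })
  say("preprocessed (stage %s, %d missing after imputation)",
      scaled$stage, sum(is.na(scaled$values)))

  # --- PCA ----------------------------------------------------------------
  pca <- run_stage("pca", fit_pca(scaled, n_components = 2))
  ellipses <- run_stage("pca", {
    lapply(data_days, function(d) {
      sc <- pca$scores[scaled$samples$day == d, , drop = FALSE]
      if (nrow(sc) >= 3) confidence_ellipse(sc, 0.90) else NULL
    })
  })
  say("PCA: PC1 %.1f%%, PC2 %.1f%%", 100 * pca$explained_fraction[1],
      100 * pca$explained_fraction[2])

  # --- contrasts: OPLS-DA + calls + MSEA ----------------------------------
  contrast_reports <- list()
  for (i in seq_along(config$contrasts)) {
    cc <- config$contrasts[[i]]
    label <- sprintf("%svs%s", paste(cc$A, collapse = "_"), paste(cc$B, collapse = "_"))
    model <- run_stage(paste0("oplsda:", label),
                       fit_oplsda(scaled, list(cc$A, cc$B),
                                  n_ortho = config$oplsda$n_ortho))
    calls <- run_stage(paste0("tests:", label), differential_calls(model, scaled))
    enr <- run_stage(paste0("msea:", label), {
      msea(ranked_list(model$p_pred), dat$pathways,
           n_perm = config$msea$n_perm, min_size = config$msea$min_size,
           weight = config$msea$weight, seed = config$seed + i)
    })
    if (!is.null(outdir)) {
      utils::write.table(calls, file.path(outdir, sprintf("calls_%s.tsv", label)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(enr, file.path(outdir, sprintf("msea_%s.tsv", label)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    contrast_reports[[label]] <- list(
      A = cc$A, B = cc$B,
      r2x_pred = model$r2x_pred,
      r2x_ortho = model$r2x_ortho,
      n_ortho = model$n_ortho,
      n_vip_strong = sum(calls$vip_band == "strong"),
      n_vip_weak = sum(calls$vip_band == "weak"),
      n_signif_adj05 = sum(calls$p_adj < 0.05),
      top_enriched = utils::head(enr$pathway_id, 3)
    )
    say("contrast %s: r2x_pred %.1f%%, %d VIP>1", label,
        100 * model$r2x_pred, sum(calls$vip_band == "strong"))
  }

  # --- covariation map ----------------------------------------------------
  profiles <- run_stage("profiles", aggregate_means(scaled))
  net <- run_stage("network", {
    cm <- correlation_matrix(profiles, method = config$network$method)
    n <- build_network(cm, threshold = config$network$threshold)
    n <- layout_signed(n, seed = config$seed,
                       iterations = config$network$layout_iterations)
    cluster_nodes(n, k = config$network$k, seed = config$seed,
                  n_init = config$network$n_init)
  })
  dynamics <- run_stage("network", {
    cluster_dynamics(net$clusters, profiles,
                     stats::setNames(scaled$metabolites$class,
                                     scaled$metabolites$name))
  })
  contrast_pairs <- NULL
  if (!is.null(dat$pathways)) {
    contrast_pairs <- run_stage("pair_contrast", {
      sm <- correlation_matrix(profiles, method = config$network$contrast_method)
      pathway_pair_correlations(sm, dat$pathways)
    })
  }
  if (!is.null(outdir)) {
    write_network(net, outdir)
    utils::write.table(
      data.frame(metabolite = names(net$clusters), cluster = unname(net$clusters)),
      file.path(outdir, "clusters.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  }
  say("network: %d edges, clusters of sizes %s", nrow(net$edges),
      paste(table(net$clusters), collapse = "/"))

  # --- fingerprint --------------------------------------------------------
  fp_table <- if (config$fingerprint$space == "scaled") {
    scaled
  } else unscale_to_normalized(scaled)
  fp <- run_stage("fingerprint", pair_distance_matrix(fp_table))
  tp <- run_stage("fingerprint", cluster_timepoints(fp, linkage = config$fingerprint$linkage))
  if (!is.null(outdir)) write_fingerprint(fp, tp, outdir)
  say("fingerprint: %d pair columns, leaf order %s", ncol(unclass(fp)),
      paste(tp$leaf_order, collapse = " "))

  # --- report -------------------------------------------------------------
  report <- list(
    version = as.character(utils::packageVersion("metabatch")),
    seed = config$seed,
    n_samples = nrow(scaled$values),
    n_metabolites = ncol(scaled$values),
    days = data_days,
    pca = list(explained_fraction = pca$explained_fraction),
    contrasts = contrast_reports,
    network = list(
      method = config$network$method,
      threshold = config$network$threshold,
      n_edges = nrow(net$edges),
      n_negative_edges = sum(net$edges$sign == "negative"),
      cluster_sizes = as.list(table(net$clusters))
    ),
    pair_contrast = if (!is.null(contrast_pairs)) contrast_pairs$summary else NULL,
    fingerprint = list(space = attr(fp, "space"),
                       linkage = config$fingerprint$linkage,
                       leaf_order = tp$leaf_order),
    truth_ari = if (!is.null(truth)) {
      adjusted_rand_index(truth[names(net$clusters)], net$clusters)
    } else NULL
  )
  if (!is.null(outdir)) {
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
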