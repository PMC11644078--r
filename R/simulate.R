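#' Configuration for the synthetic batch-culture metabolome generator
#'
#' Defaults mirror the study design the pipeline targets: ten sampling days
#' spanning lag, proliferation, elongation, stationary and death phases, five
#' biological replicates, and about 360 metabolites in annotated chemical
#' classes. Four temporal archetypes are planted (1: early-high declining,
#' 2: humps at start / elongation / end, 3: monotone rising, 4: transient
#' mid-culture peak) and metabolites sharing a pathway covary at strength
#' `within_pathway_coupling`.
#'
#' @param n_metabolites Number of metabolites.
#' @param class_composition Named proportions over chemical classes; must sum
#'   to 1.
#' @param sampling_days Strictly increasing integer days after inoculation.
#' @param n_replicates Biological replicates per day (>= 2).
#' @param archetype_assignment Named proportions over archetypes "1".."4";
#'   must sum to 1. Used as base assignment probabilities, biased by class
#'   (amino acids/sterols toward archetype 1, sugars toward 3,
#'   FFAs/carboxylates toward 2).
#' @param pathway_count Number of planted pathways.
#' @param pathway_size_range Integer pair, min/max members per pathway.
#' @param within_pathway_coupling Correlation in `[0, 1]` of the shared
#'   profile perturbation among members of one pathway.
#' @param noise_sd Log-scale standard deviation of multiplicative replicate
#'   noise. Scalar, or a length-2 vector giving the early-phase and
#'   late-phase SDs (freshly subcultured flasks are more heterogeneous than
#'   aged, converged cultures); the default plants distinct phase noise
#'   regimes around a mean level of about 25% CV.
#' @param missing_rate Proportion of cells masked as missing, in `[0, 1)`.
#' @param amplitude_range Range of the archetype amplitude (log scale).
#' @param perturbation_sd Log-scale SD of the per-profile perturbation that
#'   the pathway coupling acts on.
#' @param time_jitter_sd SD (days) of the metabolite-specific shift of its
#'   archetype curve along the day axis, de-synchronizing zero crossings
#'   within an archetype.
#' @param replicate_coupling_early,replicate_coupling_late Fraction in
#'   `[0, 1)` of the replicate noise variance carried by a flask-level
#'   factor shared by all metabolites of one biological replicate (with a
#'   fixed +/-1 loading sign per metabolite, so sample-median normalization
#'   does not cancel it). The lag/proliferation days (up to
#'   `phase_boundary`) and the later phases get different coupling
#'   strengths, planting the phase-specific replicate-covariation regimes
#'   that the Canberra fingerprint detects.
#' @param phase_boundary Last day counted as the early (lag/proliferation)
#'   regime.
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_metabolites = 360,
                       class_composition = c(amino_acids = 0.075,
                                             sugars = 0.165,
                                             carboxylates = 0.085,
                                             free_fatty_acids = 0.035,
                                             sterols = 0.030,
                                             glycosides = 0.085,
                                             other = 0.525),
                       sampling_days = c(1, 2, 3, 4, 7, 14, 18, 21, 23, 26),
                       n_replicates = 5,
                       archetype_assignment = c(`1` = 0.35, `2` = 0.25,
                                                `3` = 0.30, `4` = 0.10),
                       pathway_count = 25,
                       pathway_size_range = c(5, 15),
                       within_pathway_coupling = 0.6,
                       noise_sd = c(0.35, 0.15),
                       missing_rate = 0.02,
                       amplitude_range = c(1.0, 1.8),
                       perturbation_sd = 0.35,
                       time_jitter_sd = 1.0,
                       replicate_coupling_early = 0.8,
                       replicate_coupling_late = 0.1,
                       phase_boundary = 7,
                       seed = 1) {
  if (abs(sum(class_composition) - 1) > 1e-9) stopf("class proportions must sum to 1")
  if (abs(sum(archetype_assignment) - 1) > 1e-9) stopf("archetype fractions must sum to 1")
  if (!all(sort(names(archetype_assignment)) == as.character(1:4))) {
    stopf("archetype_assignment must be named '1'..'4'")
  }
  if (is.unsorted(sampling_days, strictly = TRUE)) stopf("sampling_days must be strictly increasing")
  if (n_replicates < 2) stopf("n_replicates must be >= 2")
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate must be in [0, 1)")
  if (within_pathway_coupling < 0 || within_pathway_coupling > 1) {
    stopf("within_pathway_coupling must be in [0, 1]")
  }
  if (any(noise_sd < 0)) stopf("noise_sd must be non-negative")
  if (!length(noise_sd) %in% c(1L, 2L)) stopf("noise_sd must have length 1 or 2")
  if (length(noise_sd) == 1L) noise_sd <- c(noise_sd, noise_sd)
  for (rc in c(replicate_coupling_early, replicate_coupling_late)) {
    if (rc < 0 || rc >= 1) stopf("replicate coupling must be in [0, 1)")
  }
  structure(list(
    n_metabolites = n_metabolites,
    class_composition = class_composition,
    sampling_days = as.integer(sampling_days),
    n_replicates = as.integer(n_replicates),
    archetype_assignment = archetype_assignment,
    pathway_count = pathway_count,
    pathway_size_range = as.integer(pathway_size_range),
    within_pathway_coupling = within_pathway_coupling,
    noise_sd = noise_sd,
    missing_rate = missing_rate,
    amplitude_range = amplitude_range,
    perturbation_sd = perturbation_sd,
    time_jitter_sd = time_jitter_sd,
    replicate_coupling_early = replicate_coupling_early,
    replicate_coupling_late = replicate_coupling_late,
    phase_boundary = phase_boundary,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default medium-kinetics parameters
#'
#' Daily-step model of the incubation medium: direct sucrose uptake
#' (Monod in sucrose, proportional to biomass), extracellular hydrolysis of
#' sucrose to hexose (first order, with a 1.053 g/g water-gain factor), and
#' hexose uptake feeding logistic dry-biomass growth. The defaults are
#' calibrated once to the culture milestones: medium sucrose roughly halves
#' in the first two days, falls below 10% of its initial level by day 7 and
#' is exhausted around day 10; hexoses rise and then fall to near zero at
#' culture death; pH dips to about 5.1 by day 2 and rises to about 6.3 at
#' day 26.
#'
#' @return Named list of rate constants and initial conditions.
#' @export
medium_params <- function() {
  list(
    sucrose_0 = 30,       # g/L, initial medium sucrose
    biomass_0 = 0.6,      # mg/mL dry biomass at inoculation
    biomass_max = 11.3,   # mg/mL, logistic ceiling of dry biomass
    uptake_sucrose = 0.78,  # g/L per (mg/mL x day), Monod Vmax of direct uptake
    km_sucrose = 4,       # g/L
    hydrolysis = 0.24,    # 1/day, extracellular invertase activity
    uptake_hexose = 0.30, # g/L per (mg/mL x day)
    km_hexose = 8,        # g/L
    yield = 0.75,         # mg/mL dry biomass per g/L sugar taken up
    hydrolysis_gain = 1.053,  # g hexose per g sucrose (water gain)
    ph_start = 5.8, ph_min = 5.1, ph_end = 6.3,
    ph_dip_day = 2, ph_rise_rate = 0.2
  )
}

#' Simulate the incubation-medium trajectory
#'
#' Discrete daily Euler stepping of the three-flux sugar model described in
#' [medium_params()], plus a phenomenological pH curve (linear dip to
#' `ph_min` over the first `ph_dip_day` days, then saturating rise to
#' `ph_end`). Pools are clipped at zero with a warning if a step overshoots.
#' Fresh biomass is derived from dry biomass through the dry-mass fraction,
#' which rises to about 7% in the first two weeks and falls to about 3% at
#' culture death.
#'
#' @param params Parameter list as from [medium_params()]; rate constants
#'   must be non-negative.
#' @param horizon Number of days to simulate (default 26).
#' @return `data.frame` with columns `time`, `sucrose`, `hexose`,
#'   `biomass_dry`, `biomass_fresh`, `pH`; one row per day from 0 to
#'   `horizon`.
#' @export
simulate_medium <- function(params = medium_params(), horizon = 26) {
  defaults <- medium_params()
  params <- utils::modifyList(defaults, params[intersect(names(params), names(defaults))])
  rates <- c("uptake_sucrose", "km_sucrose", "hydrolysis", "uptake_hexose",
             "km_hexose", "yield", "hydrolysis_gain")
  bad <- vapply(params[rates], function(x) x < 0, logical(1))
  if (any(bad)) stopf("negative rate parameter(s): %s", paste(rates[bad], collapse = ", "))
  S <- params$sucrose_0; H <- 0; B <- params$biomass_0
  n <- as.integer(horizon)
  out <- matrix(NA_real_, nrow = n + 1, ncol = 4,
                dimnames = list(NULL, c("time", "sucrose", "hexose", "biomass_dry")))
  out[1, ] <- c(0, S, H, B)
  clipped <- FALSE
  for (i in seq_len(n)) {
    uS <- params$uptake_sucrose * B * S / (params$km_sucrose + S)
    hyd <- params$hydrolysis * S
    uH <- params$uptake_hexose * B * H / (params$km_hexose + H)
    # outflow cannot exceed the pool within one daily step: scale fluxes so
    # the pool empties exactly instead of overshooting
    if (uS + hyd > S && uS + hyd > 0) {
      f <- S / (uS + hyd); uS <- uS * f; hyd <- hyd * f
    }
    if (uH > H + params$hydrolysis_gain * hyd) {
      uH <- H + params$hydrolysis_gain * hyd
    }
    S_new <- S - (uS + hyd)
    H_new <- H + params$hydrolysis_gain * hyd - uH
    B_new <- B + params$yield * (uS + uH) * (1 - B / params$biomass_max)
    if (S_new < 0 || H_new < 0 || B_new < 0) clipped <- TRUE
    S <- max(0, S_new); H <- max(0, H_new); B <- max(0, B_new)
    out[i + 1, ] <- c(i, S, H, B)
  }
  if (clipped) warnf("a daily step produced a negative pool; clipped at 0")
  t <- out[, "time"]
  ph <- ifelse(
    t <= params$ph_dip_day,
    params$ph_start - (params$ph_start - params$ph_min) * t / params$ph_dip_day,
    params$ph_end - (params$ph_end - params$ph_min) *
      exp(-params$ph_rise_rate * (t - params$ph_dip_day))
  )
  # dry-mass fraction: ~5.5% at inoculation, ~7% at two weeks, ~3% at death
  frac <- ifelse(t <= 14, 0.055 + (0.07 - 0.055) * t / 14,
                 0.07 - (0.07 - 0.03) * (t - 14) / 12)
  data.frame(time = t, sucrose = out[, "sucrose"], hexose = out[, "hexose"],
             biomass_dry = out[, "biomass_dry"],
             biomass_fresh = out[, "biomass_dry"] / frac, pH = ph)
}

# The four planted temporal archetypes, evaluated on the day axis and
# standardized across the sampling days so amplitudes are comparable.
# 1: early-high declining; 2: humps at start, elongation and end;
# 3: monotone rising; 4: transient mid-culture peak (days 7-14).
# `shift` displaces the curve along the day axis (metabolite-specific
# temporal jitter), so that sign crossings are not synchronized across
# metabolites of one archetype.
archetype_curves <- function(days, shift = 0) {
  d <- days - shift
  raw <- cbind(
    `1` = 1 / (1 + exp((d - 7.5) / 2.2)),
    `2` = 0.9 * exp(-((d - 1.5) / 1.8)^2) +
          0.7 * exp(-((d - 19.5) / 3.0)^2) +
          0.9 * exp(-((d - 25.5) / 2.5)^2),
    `3` = 1 / (1 + exp(-(d - 11.5) / 3)),
    `4` = exp(-((d - 9) / 2.5)^2)
  )
  apply(raw, 2, function(x) (x - mean(x)) / stats::sd(x))
}

# class -> archetype assignment probabilities: amino acids and sterols are
# enriched in archetype 1, sugars in 3, FFAs and carboxylates in 2; the
# remaining classes follow the configured base proportions.
class_archetype_probs <- function(cls, base) {
  switch(cls,
    amino_acids = ,
    sterols = c(0.70, 0.10, 0.10, 0.10),
    sugars = c(0.10, 0.15, 0.65, 0.10),
    free_fatty_acids = ,
    carboxylates = c(0.10, 0.60, 0.20, 0.10),
    base
  )
}

#' Simulate a batch-culture metabolome with known ground truth
#'
#' Generates raw (positive) peak-area-like abundances whose log-scale mean
#' trajectories follow one of four planted temporal archetypes, scaled by a
#' metabolite-specific amplitude, plus a smooth profile perturbation that
#' members of the same pathway share at strength
#' `within_pathway_coupling`. Replicates multiply the mean by log-normal
#' noise. Chemical classes are assigned with archetype bias (amino acids and
#' sterols accumulate early, sugars late, FFAs/carboxylates follow the
#' multi-hump shape), and sporadic missingness can be injected afterwards
#' with [inject_missingness()].
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_dataset`: a list with elements
#'   `table` (raw-stage [metab_table()]), `truth_clusters` (named integer
#'   archetype per metabolite), `truth_pathways` ([pathway_annotation()]),
#'   `truth_profiles` (noiseless log-scale mean trajectories, metabolites x
#'   days), `medium` (trajectory from [simulate_medium()]) and `config`.
#' @export
simulate_metabolome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    M <- config$n_metabolites
    days <- config$sampling_days
    reps <- config$n_replicates

    classes <- sample(names(config$class_composition), M, replace = TRUE,
                      prob = config$class_composition)
    base <- config$archetype_assignment[as.character(1:4)]
    cluster <- vapply(classes, function(cl) {
      sample.int(4, 1, prob = class_archetype_probs(cl, base))
    }, integer(1))
    names(cluster) <- NULL

    met_names <- sprintf("met_%03d", seq_len(M))
    id_level <- sample(c("identified", "class-annotated", "unknown"), M,
                       replace = TRUE, prob = c(0.3, 0.25, 0.45))
    names(cluster) <- met_names

    # disjoint pathways sampled independently of archetype
    sizes <- sample(seq(config$pathway_size_range[1], config$pathway_size_range[2]),
                    config$pathway_count, replace = TRUE)
    sizes <- pmin(sizes, M)
    pool <- sample(met_names)
    sets <- list()
    pos <- 1
    for (p in seq_len(config$pathway_count)) {
      if (pos + sizes[p] - 1 > length(pool)) break
      sets[[sprintf("pw_%02d", p)]] <- sort(pool[pos:(pos + sizes[p] - 1)])
      pos <- pos + sizes[p]
    }
    pathways <- pathway_annotation(sets)
    pw_of <- stats::setNames(rep(NA_character_, M), met_names)
    for (pid in names(sets)) pw_of[sets[[pid]]] <- pid

    # log-scale mean trajectories
    amp <- stats::runif(M, config$amplitude_range[1], config$amplitude_range[2])
    mu0 <- stats::rnorm(M, log(1e4), 1)
    cpl <- config$within_pathway_coupling
    pw_pert <- lapply(sets, function(s) stats::rnorm(length(days)))
    D <- length(days)
    shift <- stats::rnorm(M, 0, config$time_jitter_sd)
    log_mean <- matrix(NA_real_, nrow = M, ncol = D)
    for (j in seq_len(M)) {
      arch_j <- archetype_curves(days, shift = shift[j])
      own <- stats::rnorm(D)
      shared <- if (!is.na(pw_of[j])) pw_pert[[pw_of[j]]] else stats::rnorm(D)
      pert <- sqrt(cpl) * shared + sqrt(1 - cpl) * own
      log_mean[j, ] <- mu0[j] + amp[j] * arch_j[, cluster[j]] +
        config$perturbation_sd * pert
    }

    # replicate values: mean x log-normal noise, with a flask-level factor
    # shared within each biological replicate; the coupling strength
    # differs between the early and late culture phases
    loading <- sample(c(-1, 1), M, replace = TRUE)
    n_samples <- D * reps
    values <- matrix(NA_real_, nrow = n_samples, ncol = M)
    sample_id <- character(n_samples)
    day_v <- integer(n_samples); rep_v <- integer(n_samples)
    row <- 1
    for (d in seq_len(D)) {
      early <- days[d] <= config$phase_boundary
      rc <- if (early) config$replicate_coupling_early else config$replicate_coupling_late
      sd_d <- if (early) config$noise_sd[1] else config$noise_sd[2]
      for (r in seq_len(reps)) {
        flask <- stats::rnorm(1)
        eps <- sd_d *
          (sqrt(rc) * loading * flask + sqrt(1 - rc) * stats::rnorm(M))
        values[row, ] <- exp(log_mean[, d] + eps)
        sample_id[row] <- sprintf("d%02d_r%d", days[d], r)
        day_v[row] <- days[d]; rep_v[row] <- r
        row <- row + 1
      }
    }

    table <- metab_table(
      values,
      samples = data.frame(sample_id = sample_id, day = day_v,
                           replicate = rep_v, stringsAsFactors = FALSE),
      metabolites = data.frame(name = met_names, class = classes,
                               id_level = id_level, stringsAsFactors = FALSE),
      stage = "raw"
    )
    if (config$missing_rate > 0) {
      table <- inject_missingness(table, config$missing_rate,
                                  seed = config$seed + 1L)
    }
    dimnames(log_mean) <- list(met_names, as.character(days))
    structure(list(table = table, truth_clusters = cluster,
                   truth_pathways = pathways,
                   truth_profiles = log_mean,
                   medium = simulate_medium(horizon = max(days)),
                   config = config),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d metabolites, %d days x %d replicates, %d pathways\n",
              x$config$n_metabolites, length(x$config$sampling_days),
              x$config$n_replicates, length(x$truth_pathways$sets)))
  cat(sprintf("  archetype sizes: %s\n",
              paste(table(x$truth_clusters), collapse = ", ")))
  invisible(x)
}

#' Inject sporadic missing values
#'
#' Masks cells missing uniformly at random at the given rate, but never all
#' replicates of one (metabolite, day) group, so the imputation precondition
#' (at least one observed replicate) always holds.
#'
#' @param table A [metab_table()].
#' @param rate Proportion of cells to mask, in `[0, 1)`.
#' @param seed Integer seed.
#' @return The table with missing cells.
#' @export
inject_missingness <- function(table, rate, seed = 1) {
  stopifnot(inherits(table, "metab_table"))
  if (rate < 0 || rate >= 1) stopf("rate must be in [0, 1)")
  if (rate == 0) return(table)
  with_seed(seed, {
    v <- table$values
    n <- length(v)
    mask <- matrix(stats::runif(n) < rate, nrow = nrow(v))
    # guarantee each (metabolite, day) group keeps >= 1 observed replicate
    for (d in unique(table$samples$day)) {
      idx <- which(table$samples$day == d)
      full <- which(colSums(mask[idx, , drop = FALSE]) == length(idx))
      for (j in full) {
        keep <- sample(idx, 1)
        mask[keep, j] <- FALSE
      }
    }
    v[mask] <- NA_real_
    table$values <- v
    table
  })
}

#' Write a synthetic dataset to disk
#'
#' Emits the abundance table as CSV (`sample_id, day, replicate`, then one
#' column per metabolite), the annotation as TSV
#' (`metabolite, class, id_level`), the pathways as GMT-like TSV and the
#' ground truth (archetype labels, medium trajectory, configuration scalars)
#' as JSON.
#'
#' @param dataset A `synthetic_dataset` from [simulate_metabolome()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    table = file.path(dir, "abundance.csv"),
    annotation = file.path(dir, "annotation.tsv"),
    pathways = file.path(dir, "pathways.gmt.tsv"),
    truth = file.path(dir, "truth.json"),
    medium = file.path(dir, "medium.tsv")
  )
  write_feature_table(dataset$table, paths["table"], paths["annotation"])
  write_gmt(dataset$truth_pathways, paths["pathways"])
  jsonlite::write_json(
    list(truth_clusters = as.list(dataset$truth_clusters),
         seed = dataset$config$seed,
         n_metabolites = dataset$config$n_metabolites,
         sampling_days = dataset$config$sampling_days,
         n_replicates = dataset$config$n_replicates),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  utils::write.table(dataset$medium, paths["medium"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(paths)
}
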