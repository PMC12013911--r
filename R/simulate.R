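#' Specify a synthetic multi-laboratory experiment
#'
#' A `simulation_config` fully determines one synthetic multi-lab dataset:
#' the design (labs, units, repeated observations), the data-generating
#' process on the model/link scale (baseline `alpha`, treatment effect
#' `beta`, lab-level intercept and slope heterogeneity, unit-level and
#' observation-level random effects), and the observation process
#' (availability thinning, response ceiling). The same config plus the same
#' seed always reproduces the same table, and each lab draws from its own
#' seed substream so adding a lab leaves existing labs' data untouched.
#'
#' Three archetypes mirror the structure of three insect behavioral
#' experiments:
#' \describe{
#'   \item{`gaussian_two_group`}{one continuous response per individual
#'     (e.g., post-contact immobility duration of sawfly larvae under a
#'     starvation treatment), generated on a transformed scale and reported
#'     raw, truncated at a ceiling (600 s, or 144 cm for distance moved).}
#'   \item{`binary_repeated_choice`}{repeated binary substrate choices per
#'     individual (e.g., grasshopper color morphs choosing green vs brown
#'     patches), with individual random intercepts and heavy missingness
#'     (only a fraction of observations are scorable).}
#'   \item{`dish_proportion`}{per-dish counts of individuals (out of a
#'     group of 3) found in one of two flour types at 14 time points, with
#'     dish random intercepts, observation-level overdispersion, and
#'     treatment-specific availability (e.g., only adult beetles on their
#'     feet are scorable).}
#' }
#'
#' @param archetype One of `"gaussian_two_group"`, `"binary_repeated_choice"`,
#'   `"dish_proportion"`.
#' @param n_labs Number of laboratories (>= 1).
#' @param units_per_group_per_lab Individuals (or dishes) per treatment group
#'   per lab.
#' @param alpha Baseline (reference-level) mean on the model scale
#'   (transformed scale for gaussian, log-odds otherwise).
#' @param beta Treatment effect on the model scale (non-reference minus
#'   reference).
#' @param lab_intercept_sd SD of lab-level intercept shifts.
#' @param lab_slope_sd SD of lab-specific treatment-effect deviations; this
#'   drives the treatment-by-laboratory interaction. 0 means perfectly
#'   transferable effects.
#' @param unit_re_sd SD of individual/dish random intercepts (non-gaussian
#'   archetypes).
#' @param olre_sd SD of observation-level random effects (`dish_proportion`
#'   only); injects overdispersion.
#' @param residual_sd Gaussian residual SD on the transformed scale
#'   (`gaussian_two_group` only; must be > 0).
#' @param n_timepoints Repeated observations per unit (50 for the binary
#'   choice design: 10 days x 5 daily measurements; 14 for the dish design).
#' @param availability_prob Probability that an observation is scorable.
#'   Either a single value or a length-2 vector (reference level first) for
#'   treatment-specific availability.
#' @param response_ceiling Truncation bound on the raw response scale
#'   (gaussian archetype; e.g., 600 s or 144 cm).
#' @param transform Analysis-scale transform used to map the gaussian
#'   generative scale back to the raw scale.
#' @param group_size Individuals per dish (`dish_proportion` only).
#' @param treatment_levels Length-2 character vector, reference level first.
#' @param outcome_id Label attached to every generated row.
#' @param seed Integer RNG seed.
#' @return An object of class `simulation_config`.
#' @seealso [simulate_experiment()], [default_scenario()]
#' @export
simulation_config <- function(archetype = c("gaussian_two_group",
                                            "binary_repeated_choice",
                                            "dish_proportion"),
                              n_labs = 3L,
                              units_per_group_per_lab = 30L,
                              alpha = 0,
                              beta = 0,
                              lab_intercept_sd = 0,
                              lab_slope_sd = 0,
                              unit_re_sd = 0,
                              olre_sd = 0,
                              residual_sd = 1,
                              n_timepoints = 1L,
                              availability_prob = 1,
                              response_ceiling = Inf,
                              transform = c("log1p", "sqrt", "none"),
                              group_size = 3L,
                              treatment_levels = c("control", "treated"),
                              outcome_id = NULL,
                              seed = 1L) {
  archetype <- match.arg(archetype)
  transform <- match.arg(transform)
  if (is.null(outcome_id)) {
    outcome_id <- switch(archetype,
      gaussian_two_group     = "gaussian_response",
      binary_repeated_choice = "binary_choice",
      dish_proportion        = "dish_proportion")
  }
  cfg <- structure(
    list(archetype = archetype,
         n_labs = as.integer(n_labs),
         units_per_group_per_lab = as.integer(units_per_group_per_lab),
         alpha = alpha, beta = beta,
         lab_intercept_sd = lab_intercept_sd,
         lab_slope_sd = lab_slope_sd,
         unit_re_sd = unit_re_sd,
         olre_sd = olre_sd,
         residual_sd = residual_sd,
         n_timepoints = as.integer(n_timepoints),
         availability_prob = availability_prob,
         response_ceiling = response_ceiling,
         transform = transform,
         group_size = as.integer(group_size),
         treatment_levels = treatment_levels,
         outcome_id = outcome_id,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  sds <- c(lab_intercept_sd = cfg$lab_intercept_sd,
           lab_slope_sd = cfg$lab_slope_sd,
           unit_re_sd = cfg$unit_re_sd, olre_sd = cfg$olre_sd)
  if (any(sds < 0)) {
    stop("random-effect SDs must be >= 0: ",
         paste(names(sds)[sds < 0], collapse = ", "))
  }
  if (cfg$n_labs < 1L || cfg$units_per_group_per_lab < 1L) {
    stop("n_labs and units_per_group_per_lab must be >= 1")
  }
  if (cfg$n_timepoints < 1L) stop("n_timepoints must be >= 1")
  if (cfg$group_size < 1L) stop("group_size must be >= 1")
  if (any(cfg$availability_prob <= 0) || any(cfg$availability_prob > 1)) {
    stop("availability_prob must be in (0, 1]")
  }
  if (!length(cfg$availability_prob) %in% c(1L, 2L)) {
    stop("availability_prob must have length 1 or 2 (reference level first)")
  }
  if (length(cfg$treatment_levels) != 2L ||
      anyDuplicated(cfg$treatment_levels)) {
    stop("treatment_levels must be two distinct labels (reference first)")
  }
  if (cfg$archetype == "gaussian_two_group") {
    if (cfg$residual_sd <= 0) stop("residual_sd must be > 0")
    if (cfg$response_ceiling < 0) stop("response_ceiling must be >= 0")
  }
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation config (", x$archetype, ")\n", sep = "")
  cat("  design: ", x$n_labs, " labs x ", x$units_per_group_per_lab,
      " units/group", sep = "")
  if (x$n_timepoints > 1L) cat(" x ", x$n_timepoints, " timepoints", sep = "")
  cat("\n  effects: alpha ", x$alpha, ", beta ", x$beta,
      ", lab intercept SD ", x$lab_intercept_sd,
      ", lab slope SD ", x$lab_slope_sd, "\n", sep = "")
  cat("  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

# Per-lab seed substream: a fixed affine hash of (global seed, lab index),
# kept below 2^31 so it is a valid R integer seed.
lab_seed <- function(seed, lab_index) {
  as.integer((as.numeric(seed) * 48271 + lab_index * 16807) %% 2147483647)
}

lab_labels <- function(n) sprintf("lab_%02d", seq_len(n))

#' Default simulation scenarios for the three experiment archetypes
#'
#' Returns a [simulation_config()] whose parameters emulate the published
#' three-laboratory insect study designs: 3 labs; 30 individuals per
#' treatment group per lab for the two-group continuous design; roughly 31
#' individuals per morph per lab observed 50 times with 15.1% scorability
#' for the binary choice design; and 18 dishes of 3 individuals per life
#' stage per lab over 14 time points with 33.4% adult availability for the
#' dish design. Treatment effects default to the pooled effect sizes of the
#' corresponding study outcomes; between-lab heterogeneity defaults to zero
#' (perfectly transferable effects).
#'
#' @param archetype Archetype name; see [simulation_config()].
#' @param seed RNG seed stored in the config.
#' @return A `simulation_config`.
#' @export
default_scenario <- function(archetype = c("gaussian_two_group",
                                           "binary_repeated_choice",
                                           "dish_proportion"),
                             seed = 1L) {
  archetype <- match.arg(archetype)
  switch(archetype,
    gaussian_two_group = simulation_config(
      archetype, n_labs = 3L, units_per_group_per_lab = 30L,
      alpha = 3.9, beta = -1.67, lab_intercept_sd = 0.35, lab_slope_sd = 0,
      residual_sd = 1.2, response_ceiling = 600, transform = "log1p",
      treatment_levels = c("control", "starved"),
      outcome_id = "pci_duration", seed = seed),
    binary_repeated_choice = simulation_config(
      archetype, n_labs = 3L, units_per_group_per_lab = 31L,
      alpha = 0, beta = 0.15, lab_intercept_sd = 0.25, lab_slope_sd = 0,
      unit_re_sd = 1, n_timepoints = 50L, availability_prob = 0.151,
      treatment_levels = c("brown", "green"),
      outcome_id = "substrate_choice", seed = seed),
    dish_proportion = simulation_config(
      archetype, n_labs = 3L, units_per_group_per_lab = 18L,
      alpha = -0.13, beta = -0.41, lab_intercept_sd = 0.25, lab_slope_sd = 0,
      unit_re_sd = 0.5, olre_sd = 0.5, n_timepoints = 14L,
      availability_prob = c(0.9, 0.334), group_size = 3L,
      treatment_levels = c("larvae", "adult"),
      outcome_id = "niche_choice", seed = seed)
  )
}

#' Simulate a multi-laboratory dataset
#'
#' Dispatches on the archetype of `config` to one of
#' [simulate_gaussian_experiment()], [simulate_binary_choice_experiment()],
#' or [simulate_dish_proportion_experiment()].
#'
#' @param config A [simulation_config()].
#' @return A long-format observation `data.frame` (one row per scored
#'   observation) with columns `lab_id`, `outcome_id`, `unit_id`,
#'   `treatment`, `timepoint`, `scorable`, and either `response` or
#'   `successes`/`trials`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  switch(config$archetype,
    gaussian_two_group     = simulate_gaussian_experiment(config),
    binary_repeated_choice = simulate_binary_choice_experiment(config),
    dish_proportion        = simulate_dish_proportion_experiment(config)
  )
}

# Draw a lab's intercept/slope pair inside its own substream.
draw_lab_effects <- function(cfg, j) {
  set.seed(lab_seed(cfg$seed, j))
  list(
    intercept = cfg$alpha + rnorm(1L, 0, cfg$lab_intercept_sd),
    slope     = cfg$beta  + rnorm(1L, 0, cfg$lab_slope_sd)
  )
}

avail_for_level <- function(cfg) {
  p <- cfg$availability_prob
  if (length(p) == 1L) p <- c(p, p)
  stats::setNames(p, cfg$treatment_levels)
}

#' Simulate a two-group continuous-response experiment
#'
#' One continuous observation per individual. The response is generated on
#' the analysis (transformed) scale as
#' `y' = alpha_j + beta_j * x + N(0, residual_sd^2)`, where `alpha_j` and
#' `beta_j` are the lab's intercept and slope draws, then back-transformed
#' to the raw scale and truncated to `[0, response_ceiling]` (truncated
#' values are retained, not flagged).
#'
#' @inheritParams simulate_experiment
#' @return Observation `data.frame` with a raw-scale `response` column; one
#'   row per individual.
#' @export
simulate_gaussian_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"),
            config$archetype == "gaussian_two_group")
  if (is.finite(config$response_ceiling) && config$response_ceiling < 0) {
    stop("response_ceiling must be non-negative on the raw scale")
  }
  n_u <- config$units_per_group_per_lab
  rows <- lapply(seq_len(config$n_labs), function(j) {
    eff <- draw_lab_effects(config, j)
    x <- rep(c(0, 1), each = n_u)
    lin <- eff$intercept + eff$slope * x +
      rnorm(2L * n_u, 0, config$residual_sd)
    raw <- pmin(inverse_transform_response(lin, config$transform),
                config$response_ceiling)
    data.frame(
      lab_id = lab_labels(config$n_labs)[j],
      outcome_id = config$outcome_id,
      unit_id = sprintf("%s_ind_%03d", lab_labels(config$n_labs)[j],
                        seq_len(2L * n_u)),
      treatment = config$treatment_levels[x + 1L],
      timepoint = 1L,
      response = raw,
      scorable = TRUE,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a repeated binary-choice experiment
#'
#' Each individual makes `n_timepoints` binary choices with
#' `logit P(response = 1) = alpha_j + beta_j * x + u_unit`,
#' `u_unit ~ N(0, unit_re_sd^2)`. Each observation is independently
#' scorable with probability `availability_prob`; unscorable rows keep an
#' `NA` response and `scorable = FALSE` (the individual was, e.g., not
#' sitting on the cage floor).
#'
#' @inheritParams simulate_experiment
#' @return Observation `data.frame` with a binary `response` column; one
#'   row per individual x timepoint.
#' @export
simulate_binary_choice_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"),
            config$archetype == "binary_repeated_choice")
  n_u <- config$units_per_group_per_lab
  n_t <- config$n_timepoints
  avail <- avail_for_level(config)
  rows <- lapply(seq_len(config$n_labs), function(j) {
    eff <- draw_lab_effects(config, j)
    lab <- lab_labels(config$n_labs)[j]
    x <- rep(c(0, 1), each = n_u)
    u <- rnorm(2L * n_u, 0, config$unit_re_sd)
    per_unit <- lapply(seq_len(2L * n_u), function(i) {
      p <- stats::plogis(eff$intercept + eff$slope * x[i] + u[i])
      scorable <- runif(n_t) < avail[[config$treatment_levels[x[i] + 1L]]]
      resp <- ifelse(scorable, rbinom(n_t, 1L, p), NA_integer_)
      data.frame(
        lab_id = lab,
        outcome_id = config$outcome_id,
        unit_id = sprintf("%s_ind_%03d", lab, i),
        treatment = config$treatment_levels[x[i] + 1L],
        timepoint = seq_len(n_t),
        response = resp,
        scorable = scorable,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, per_unit)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a per-dish proportion experiment
#'
#' Each dish holds `group_size` individuals observed at `n_timepoints` time
#' points. At each time point the number of scorable individuals is
#' `trials ~ Binomial(group_size, availability_prob[treatment])` (e.g.,
#' adult beetles on their feet), and
#' `successes ~ Binomial(trials, plogis(alpha_j + beta_j x + u_dish + e_obs))`
#' with dish random intercepts `u_dish ~ N(0, unit_re_sd^2)` and a fresh
#' observation-level effect `e_obs ~ N(0, olre_sd^2)` per row, which
#' injects overdispersion relative to the binomial.
#'
#' @inheritParams simulate_experiment
#' @return Observation `data.frame` with `successes` and `trials` columns;
#'   one row per dish x timepoint. Rows with `trials = 0` have
#'   `scorable = FALSE`.
#' @export
simulate_dish_proportion_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"),
            config$archetype == "dish_proportion")
  n_u <- config$units_per_group_per_lab
  n_t <- config$n_timepoints
  avail <- avail_for_level(config)
  rows <- lapply(seq_len(config$n_labs), function(j) {
    eff <- draw_lab_effects(config, j)
    lab <- lab_labels(config$n_labs)[j]
    x <- rep(c(0, 1), each = n_u)
    u <- rnorm(2L * n_u, 0, config$unit_re_sd)
    per_dish <- lapply(seq_len(2L * n_u), function(i) {
      lev <- config$treatment_levels[x[i] + 1L]
      trials <- rbinom(n_t, config$group_size, avail[[lev]])
      e_obs <- rnorm(n_t, 0, config$olre_sd)
      p <- stats::plogis(eff$intercept + eff$slope * x[i] + u[i] + e_obs)
      succ <- rbinom(n_t, trials, p)
      data.frame(
        lab_id = lab,
        outcome_id = config$outcome_id,
        unit_id = sprintf("%s_dish_%03d", lab, i),
        treatment = lev,
        timepoint = seq_len(n_t),
        successes = succ,
        trials = trials,
        scorable = trials > 0L,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, per_dish)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a simulation scenario from a YAML file
#'
#' Every [simulation_config()] field must be present explicitly (no silent
#' defaults), so a scenario file is a complete record of the data-generating
#' process. Bundled examples live in
#' `system.file("extdata", "scenarios", package = "labrepro")`.
#'
#' @param path Path to a YAML scenario file.
#' @return A `simulation_config`.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  required <- c("archetype", "n_labs", "units_per_group_per_lab", "alpha",
                "beta", "lab_intercept_sd", "lab_slope_sd", "unit_re_sd",
                "olre_sd", "residual_sd", "n_timepoints", "availability_prob",
                "response_ceiling", "transform", "group_size",
                "treatment_levels", "outcome_id", "seed")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("scenario file ", path, " is missing fields: ",
         paste(missing, collapse = ", "))
  }
  if (identical(raw$response_ceiling, "Inf")) raw$response_ceiling <- Inf
  do.call(simulation_config, raw[required])
}
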