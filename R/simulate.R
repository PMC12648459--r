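#' Configure a synthetic multi-stressor experiment database
#'
#' Builds and validates the configuration object consumed by
#' [generate_database()].  The defaults describe the kind of database the
#' analysis pipeline is designed for: 51 small factorial freshwater
#' experiments, each with a control, all single-stressor arms and the
#' combined-stressor arms implied by its stressor richness, reporting
#' taxon richness (>= 4 taxa), Shannon diversity and one ecosystem-function
#' response per arm.
#'
#' @param n_studies Number of studies (default 51).
#' @param stressor_richness_weights Probabilities that a study manipulates
#'   1, 2 or 3 stressors.  Must sum to 1.
#' @param n_replicates Replicates per experimental arm.
#' @param species_pool Size of the simulated species pool (>= 4 taxa).
#' @param control_cv Coefficient of variation of replicate-level function
#'   responses.  `0` switches the realisation to a deterministic mode where
#'   arm summaries equal their exact expectations with zero SD.
#' @param tau2_study Between-study variance of true log effects on the
#'   function response.
#' @param single_effect_dist List with elements `richness` and `function_`,
#'   each `c(mean, sd)` of true single-stressor log response ratios.
#' @param interaction_delta Additive deviation (log scale) of joint-arm
#'   function responses from the multiplicative null; 0 is the exact null.
#' @param bef_slope_base True slope of LRR function on LRR richness at one
#'   stressor.
#' @param bef_slope_per_stressor True increment of that slope per added
#'   stressor.
#' @param moderator_levels List with `organism_group`, `function_type`,
#'   `stressor_category` label sets; defaults to the full vocabulary.
#' @param exercise_exclusions If `TRUE`, a small fraction of treatment arms
#'   is injected with zero richness or negative function means so the
#'   effect-size exclusion path can be exercised.  Default off.
#' @param n_time_points Post-exposure time points reported per observation
#'   (default 1); values > 1 exercise the time-aggregation step.
#' @param seed Integer seed; all stochastic operations derive from it.
#'
#' @return A validated list of class `bef_sim_config`.
#' @seealso [generate_database()], [spike_interactions()]
#' @export
#' @examples
#' cfg <- sim_config(n_studies = 10, seed = 1)
#' db <- generate_database(cfg)
#' dplyr::count(db$observations, n_stressors)
sim_config <- function(n_studies = 51,
                       stressor_richness_weights = c(0.3, 0.4, 0.3),
                       n_replicates = 4,
                       species_pool = 12,
                       control_cv = 0.3,
                       tau2_study = 0.1,
                       single_effect_dist = list(
                         richness = c(mean = -0.3, sd = 0.4),
                         function_ = c(mean = -0.2, sd = 0.8)
                       ),
                       interaction_delta = 0,
                       bef_slope_base = 0.5,
                       bef_slope_per_stressor = 0.3,
                       moderator_levels = NULL,
                       exercise_exclusions = FALSE,
                       n_time_points = 1,
                       seed = 1L) {
  cfg <- list(
    n_studies = n_studies,
    stressor_richness_weights = stressor_richness_weights,
    n_replicates = n_replicates,
    species_pool = species_pool,
    control_cv = control_cv,
    tau2_study = tau2_study,
    single_effect_dist = single_effect_dist,
    interaction_delta = interaction_delta,
    bef_slope_base = bef_slope_base,
    bef_slope_per_stressor = bef_slope_per_stressor,
    moderator_levels = moderator_levels %||% list(
      organism_group = .befstress_groups,
      function_type = .befstress_functions,
      stressor_category = .befstress_stressor_categories
    ),
    exercise_exclusions = isTRUE(exercise_exclusions),
    n_time_points = n_time_points,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stop_field <- function(field, msg) {
    abort(sprintf("invalid simulation config: `%s` %s", field, msg),
          class = "befstress_config_error")
  }
  count_fields <- c("n_studies", "n_replicates", "n_time_points")
  for (f in count_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != round(v))
      stop_field(f, "must be a single count >= 1")
  }
  if (!is.numeric(cfg$species_pool) || cfg$species_pool < 4 ||
      cfg$species_pool != round(cfg$species_pool))
    stop_field("species_pool", "must be an integer >= 4 (communities with at least 4 taxa)")
  w <- cfg$stressor_richness_weights
  if (!is.numeric(w) || length(w) != 3 || any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop_field("stressor_richness_weights", "must be 3 non-negative probabilities summing to 1")
  if (!is.numeric(cfg$control_cv) || cfg$control_cv < 0)
    stop_field("control_cv", "must be >= 0")
  if (!is.numeric(cfg$tau2_study) || cfg$tau2_study < 0)
    stop_field("tau2_study", "must be >= 0")
  sed <- cfg$single_effect_dist
  if (!is.list(sed) || !all(c("richness", "function_") %in% names(sed)) ||
      any(vapply(sed[c("richness", "function_")],
                 function(x) length(x) != 2 || any(!is.finite(x)) || x[2] < 0,
                 logical(1))))
    stop_field("single_effect_dist", "must hold c(mean, sd >= 0) for richness and function_")
  if (!is.numeric(cfg$interaction_delta) || !is.finite(cfg$interaction_delta))
    stop_field("interaction_delta", "must be a finite number")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed))
    stop_field("seed", "must be a single integer")
  structure(cfg, class = "bef_sim_config")
}

#' Read a simulation configuration from a JSON file
#'
#' @param path Path to a JSON object whose keys match [sim_config()]
#'   arguments.
#' @return A validated `bef_sim_config`.
#' @export
sim_config_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$single_effect_dist))
    raw$single_effect_dist <- lapply(raw$single_effect_dist, unlist)
  do.call(sim_config, raw)
}

# Enumerate the treatment arms implied by a study's stressor richness:
# every single stressor, every pair, and (for three stressors) the triple.
arm_sets <- function(ns) {
  ids <- LETTERS[seq_len(ns)]
  sets <- as.list(ids)
  if (ns >= 2) {
    pairs <- utils::combn(ids, 2, simplify = FALSE)
    sets <- c(sets, pairs)
  }
  if (ns >= 3) sets <- c(sets, list(ids))
  sets
}

# MDR sign convention shared with the null-model module: flip when both
# single-stressor effects are declines.
mdr_sign <- function(lrr_a, lrr_b) ifelse(lrr_a < 0 & lrr_b < 0, -1, 1)

#' Generate a synthetic multi-stressor database with known ground truth
#'
#' Simulates the latent truth (study effects, per-arm true log response
#' ratios, interaction structure) and realises it as arm-level summary
#' statistics in the harmonised observation schema.  Joint-arm true LRRs
#' equal the sum of their single-stressor LRRs (the multiplicative null on
#' the log scale); the function response additionally receives
#' `interaction_delta` and the stressor-number-dependent BEF slope
#' increment.  Identical configurations give identical output.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `observations` (harmonised observation
#'   tibble, one row per study x arm x time point) and `truth` (one row per
#'   arm with the true LRRs and interaction class).
#' @export
generate_database <- function(config) {
  config <- validate_sim_config(unclass(config))
  truth <- simulate_truth(config)
  list(
    observations = realise_observations(truth, config),
    truth = truth
  )
}

# Latent ground truth: one row per study x treatment arm.
simulate_truth <- function(config) {
  set.seed(config$seed)
  mu_r <- config$single_effect_dist$richness[[1]]
  sd_r <- config$single_effect_dist$richness[[2]]
  mu_f <- config$single_effect_dist$function_[[1]]
  sd_f <- config$single_effect_dist$function_[[2]]
  b0 <- config$bef_slope_base
  b1 <- config$bef_slope_per_stressor
  # marginal mean of single-stressor function LRRs stays at mu_f
  mu_f_adj <- mu_f - b0 * mu_r

  studies <- purrr::map(seq_len(config$n_studies), function(j) {
    ns <- sample(1:3, 1, prob = config$stressor_richness_weights)
    pair <- .befstress_attribution[sample(nrow(.befstress_attribution), 1), ]
    cats <- sample(config$moderator_levels$stressor_category, ns, replace = TRUE)
    u_j <- rnorm(1, 0, sqrt(config$tau2_study))
    baseline_function <- rlnorm(1, log(100), 0.5)

    single_tr <- rnorm(ns, mu_r, sd_r)
    single_ef <- u_j + mu_f_adj + b0 * single_tr + rnorm(ns, 0, sd_f)
    names(single_tr) <- names(single_ef) <- LETTERS[seq_len(ns)]

    arms <- arm_sets(ns)
    purrr::map(arms, function(set) {
      k <- length(set)
      tr <- sum(single_tr[set])
      if (k == 1) {
        ef <- single_ef[[set]]
      } else {
        # multiplicative null on the single-stressor function effects, plus
        # the configured null deviation and the per-stressor slope increment
        ef <- sum(single_ef[set]) +
          config$interaction_delta + b1 * (k - 1) * tr
      }
      tibble(
        study_id = sprintf("S%03d", j),
        arm_id = paste(set, collapse = "+"),
        n_stressors = k,
        stressor_ids = paste(set, collapse = ","),
        stressor_categories = paste(sort(unique(cats[match(set, LETTERS)])),
                                    collapse = "+"),
        organism_group = pair$organism_group,
        function_type = pair$function_type,
        study_intercept = u_j,
        baseline_function = baseline_function,
        true_lrr_richness = tr,
        true_lrr_function = ef,
        true_lrr_shannon = 0.9 * tr,
        true_interaction_class = if (k == 1 || config$interaction_delta == 0) {
          "additive"
        } else {
          classify_mdr(exp(mdr_sign(single_ef[[set[1]]], single_ef[[set[2]]]) *
                             config$interaction_delta))
        }
      )
    }) |> bind_rows()
  })
  bind_rows(studies)
}

#' Impose known non-additive interactions on a truth table
#'
#' Shifts the function-response truth of the stated fractions of
#' two-stressor joint arms away from the multiplicative null, so that data
#' realised from the modified table carry a known proportion of antagonistic
#' and synergistic interactions.  The shift direction follows the same
#' sign-flip convention the MDR classifier uses, so in the noise-free limit
#' the classifier recovers the spiked labels exactly.
#'
#' @param truth Truth table from [generate_database()].
#' @param fraction_antagonistic,fraction_synergistic Fractions of
#'   two-stressor joint arms to spike (each >= 0, sum <= 1).
#' @param magnitude Log-scale shift; values > `log(2)` place spiked arms
#'   outside the additive MDR band.
#' @param seed Integer seed for selecting which arms are spiked.
#' @return The modified truth table; pass it to [realise_observations()].
#' @export
spike_interactions <- function(truth, fraction_antagonistic,
                               fraction_synergistic, magnitude = log(4),
                               seed = 1L) {
  fa <- fraction_antagonistic
  fs <- fraction_synergistic
  if (!is.numeric(fa) || !is.numeric(fs) || fa < 0 || fs < 0 || fa + fs > 1)
    abort("spike fractions must be >= 0 and sum to at most 1",
          class = "befstress_config_error")
  if (fa == 0 && fs == 0) return(truth)
  if (magnitude <= 0) abort("`magnitude` must be > 0",
                            class = "befstress_config_error")

  joint_idx <- which(truth$n_stressors == 2)
  n_joint <- length(joint_idx)
  n_ant <- round(fa * n_joint)
  n_syn <- round(fs * n_joint)
  set.seed(seed)
  chosen <- sample(joint_idx, n_ant + n_syn)
  ant <- chosen[seq_len(n_ant)]
  syn <- chosen[setdiff(seq_along(chosen), seq_len(n_ant))]

  singles <- truth |>
    filter(.data$n_stressors == 1) |>
    select("study_id", "arm_id", single_ef = "true_lrr_function")
  shift_one <- function(i, direction) {
    parts <- strsplit(truth$stressor_ids[i], ",", fixed = TRUE)[[1]]
    ef <- singles$single_ef[singles$study_id == truth$study_id[i] &
                              singles$arm_id %in% parts]
    s <- mdr_sign(ef[1], ef[2])
    pred <- sum(ef)
    truth$true_lrr_function[i] <<- pred + direction * s * magnitude
    truth$true_interaction_class[i] <<-
      if (direction > 0) "synergistic" else "antagonistic"
  }
  for (i in ant) shift_one(i, -1)
  for (i in syn) shift_one(i, +1)
  truth
}

#' Realise arm-level summary statistics from a truth table
#'
#' Draws replicate-level responses around each arm's true values and
#' summarises them as (mean, sd, n) per response variable: function and
#' Shannon replicates are lognormal with coefficient of variation
#' `control_cv`; richness replicates are binomial thinnings of the species
#' pool.  With `control_cv = 0` the summaries are the exact expectations
#' with zero SD (a deterministic mode used for noise-free checks).
#' Controls are drawn once per study and shared across that study's arms.
#'
#' @param truth Truth table, possibly modified by [spike_interactions()].
#' @param config The [sim_config()] used to generate it.
#' @return A harmonised observation tibble (one row per study x arm x time
#'   point), ready for [harmonise_observations()] or, with one time point,
#'   directly for [add_effect_sizes()].
#' @export
realise_observations <- function(truth, config) {
  config <- validate_sim_config(unclass(config))
  set.seed(config$seed + 1L)
  nrep <- config$n_replicates
  cv <- config$control_cv
  pool <- config$species_pool
  p0 <- 0.9                     # control-arm per-taxon persistence
  sigma <- if (cv > 0) sqrt(log(1 + cv^2)) else 0

  draw_lognormal <- function(mean_target) {
    if (cv == 0) return(c(mean = mean_target, sd = 0, n = nrep))
    x <- rlnorm(nrep, log(mean_target) - sigma^2 / 2, sigma)
    c(mean = mean(x), sd = sd(x), n = nrep)
  }
  draw_richness <- function(lrr) {
    # deterministic mode reports the idealised (uncapped) expectation so
    # that joint arms reproduce the multiplicative null exactly
    if (cv == 0) return(c(mean = pool * p0 * exp(lrr), sd = 0, n = nrep))
    x <- rbinom(nrep, pool, min(1, p0 * exp(lrr)))
    c(mean = mean(x), sd = sd(x), n = nrep)
  }

  shannon_base <- 0.85 * log(pool)

  rows <- truth |>
    group_by(.data$study_id) |>
    dplyr::group_split() |>
    purrr::map(function(st) {
      purrr::map(seq_len(config$n_time_points), function(tp) {
        ctrl_rich <- draw_richness(0)
        ctrl_fun <- draw_lognormal(st$baseline_function[1])
        ctrl_sha <- draw_lognormal(shannon_base)
        purrr::pmap(st, function(study_id, arm_id, n_stressors, stressor_ids,
                                 stressor_categories, organism_group,
                                 function_type, baseline_function,
                                 true_lrr_richness, true_lrr_function,
                                 true_lrr_shannon, ...) {
          tr <- draw_richness(true_lrr_richness)
          fn <- draw_lognormal(baseline_function * exp(true_lrr_function))
          sh <- draw_lognormal(shannon_base * exp(true_lrr_shannon))
          tibble(
            study_id = study_id,
            observation_id = paste0(study_id, ":", arm_id),
            arm_id = arm_id,
            organism_group = organism_group,
            function_type = function_type,
            stressor_ids = stressor_ids,
            stressor_categories = stressor_categories,
            stressor_combination = stressor_categories,
            n_stressors = n_stressors,
            stressor_level = 1,
            phase = "post",
            time_point = tp,
            richness_mean_c = ctrl_rich[["mean"]],
            richness_sd_c = ctrl_rich[["sd"]],
            richness_n_c = ctrl_rich[["n"]],
            richness_mean_t = tr[["mean"]],
            richness_sd_t = tr[["sd"]],
            richness_n_t = tr[["n"]],
            shannon_mean_c = ctrl_sha[["mean"]],
            shannon_sd_c = ctrl_sha[["sd"]],
            shannon_n_c = ctrl_sha[["n"]],
            shannon_mean_t = sh[["mean"]],
            shannon_sd_t = sh[["sd"]],
            shannon_n_t = sh[["n"]],
            function_mean_c = ctrl_fun[["mean"]],
            function_sd_c = ctrl_fun[["sd"]],
            function_n_c = ctrl_fun[["n"]],
            function_mean_t = fn[["mean"]],
            function_sd_t = fn[["sd"]],
            function_n_t = fn[["n"]]
          )
        }) |> bind_rows()
      }) |> bind_rows()
    }) |>
    bind_rows() |>
    ungroup()

  if (config$exercise_exclusions) {
    n <- nrow(rows)
    zero_idx <- which(runif(n) < 0.02)
    neg_idx <- which(runif(n) < 0.01)
    rows$richness_mean_t[zero_idx] <- 0
    rows$function_mean_t[neg_idx] <- -abs(rows$function_mean_t[neg_idx])
  }
  rows
}

#' Write a synthetic database to CSV
#'
#' Writes `observations.csv` (harmonised schema; see the schema file shipped
#' at `system.file("extdata", "observation_schema.json")`) and `truth.csv`
#' into a directory.
#'
#' @param db List from [generate_database()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_database <- function(db, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(db$observations, file.path(dir, "observations.csv"),
                   row.names = FALSE)
  utils::write.csv(db$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
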