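#' Run the full multi-stressor BEF analysis pipeline
#'
#' Single entry point for synthetic or supplied data.  Executes
#' harmonisation, effect-size computation, the collinearity screen, the
#' backward-selected nested BEF mixed model with influence and
#' leave-one-study-out diagnostics, the multiplicative-null MDR
#' classification with moderator models and cross-response correlation,
#' and the three-level meta-analysis diagnostics — and collects the
#' headline quantities in a report.  Identical input and seed give an
#' identical report.
#'
#' @param input Either a data frame in the harmonised observation schema or
#'   a [sim_config()]; in the latter case a synthetic database is generated
#'   first.
#' @param time_mode Time aggregation mode, see [aggregate_time()].
#' @param covariate Diversity covariate, `"richness"` (default) or
#'   `"shannon"`.
#' @param alpha Significance level for selection and reporting (default
#'   0.05).
#' @param mdr_form MDR form, see [mdr()].
#' @param noise_fraction Noise band width (default 0.25).
#' @param cooks_threshold Influence cutoff (default 0.5).
#' @param weights Mixed-model weighting, see [fit_bef_lmm()].
#' @param run_loso Run leave-one-study-out cross-validation (default
#'   `TRUE`; one refit per study).
#' @param strict Attribution checking, see [validate_observations()].
#' @return An object of class `bef_report` (a list; see Details) with the
#'   harmonised data, effect sizes, all module results and a `headline`
#'   summary suitable for JSON export.
#' @export
run_bef_pipeline <- function(input,
                             time_mode = c("mean", "max_richness_deviation"),
                             covariate = c("richness", "shannon"),
                             alpha = 0.05,
                             mdr_form = c("ratio-of-ratios", "plain-ratio"),
                             noise_fraction = 0.25,
                             cooks_threshold = 0.5,
                             weights = NULL,
                             run_loso = TRUE,
                             strict = TRUE) {
  time_mode <- match.arg(time_mode)
  covariate <- match.arg(covariate)
  mdr_form <- match.arg(mdr_form)

  truth <- NULL
  if (inherits(input, "bef_sim_config")) {
    db <- generate_database(input)
    observations <- db$observations
    truth <- db$truth
  } else {
    observations <- as_tibble(input)
  }

  harmonised <- harmonise_observations(observations, mode = time_mode,
                                       strict = strict)
  effects <- add_effect_sizes(harmonised)
  exclusions <- exclusion_report(effects)
  screen <- cramers_v_screen(effects)

  md <- bef_model_data(effects, covariate = covariate)
  selection <- backward_select(md$data, terms = md$terms,
                               covariate_col = md$covariate_col,
                               alpha = alpha, weights = weights)
  fit <- selection$fit
  influence <- cooks_distance_by_study(fit, threshold = cooks_threshold)
  refit_influential <- if (any(influence$influential) &&
                           fit$n_groups - sum(influence$influential) >= 3) {
    tryCatch(
      refit_without_studies(fit, influence$study_id[influence$influential]),
      error = function(e) {
        warn(paste0("refit without influential studies failed: ",
                    conditionMessage(e)))
        NULL
      }
    )
  }
  loso <- if (run_loso && fit$n_groups >= 3) loso_cv(fit)
  slopes <- marginal_effects_grid(fit)

  nullm <- classify_interactions(effects, noise_fraction = noise_fraction,
                                 form = mdr_form)
  mdr_mods <- if (nrow(nullm$results) > 0)
    mdr_moderator_models(nullm$results, alpha = alpha)
  mdr_cor <- if (nrow(nullm$results) > 0) mdr_correlation(nullm$results)

  bias <- purrr::map(
    setNames(c("richness", "function"), c("richness", "function")),
    function(r) meta_bias_diagnostics(effects, response = r)
  )

  interaction_term <- paste0(md$covariate_col, ":ns")
  headline <- list(
    n_obs = fit$n_obs,
    n_groups = fit$n_groups,
    r2_marginal = fit$r2_marginal,
    r2_conditional = fit$r2_conditional,
    retained_terms = selection$terms,
    interaction_retained = interaction_term %in% selection$terms,
    covariate_slope = unname(lme4::fixef(fit$fit)[md$covariate_col]),
    interaction_slope = unname(lme4::fixef(fit$fit)[interaction_term]),
    mdr_proportions = nullm$proportions,
    mdr_correlation = mdr_cor,
    i2 = purrr::map(bias, function(b)
      c(between = b$fit$i2_between, within = b$fit$i2_within)),
    Q = purrr::map(bias, function(b) c(Q = b$fit$Q, df = b$fit$df)),
    egger_p = purrr::map_dbl(bias, function(b) b$egger$p),
    exclusion_fraction = exclusions$fraction_values,
    n_influential = sum(influence$influential)
  )

  structure(list(
    observations = harmonised,
    effects = effects,
    truth = truth,
    exclusions = exclusions,
    cramers_v = screen,
    selection = selection,
    fit = fit,
    influence = influence,
    refit_without_influential = refit_influential,
    loso = loso,
    marginal_effects = slopes,
    null_model = nullm,
    mdr_moderators = mdr_mods,
    mdr_correlation = mdr_cor,
    meta_bias = bias,
    headline = headline,
    manifest = list(
      covariate = covariate, time_mode = time_mode, alpha = alpha,
      mdr_form = mdr_form, noise_fraction = noise_fraction,
      cooks_threshold = cooks_threshold,
      befstress_version = as.character(utils::packageVersion("befstress")),
      r_version = R.version.string
    )
  ), class = "bef_report")
}

#' @export
print.bef_report <- function(x, ...) {
  h <- x$headline
  cat("Multi-stressor BEF pipeline report\n")
  cat(sprintf("  BEF model: n = %d, %d groups; marginal R2 = %.2f, conditional R2 = %.2f\n",
              h$n_obs, h$n_groups, h$r2_marginal, h$r2_conditional))
  cat(sprintf("  diversity slope = %.3f; slope x stressor-number %s (%.3f)\n",
              h$covariate_slope,
              if (h$interaction_retained) "retained" else "not retained",
              h$interaction_slope %||% NA_real_))
  if (nrow(h$mdr_proportions) > 0) {
    pr <- h$mdr_proportions
    for (r in unique(pr$response)) {
      sub <- pr[pr$response == r, ]
      cat(sprintf("  MDR (%s): %s\n", r,
                  paste(sprintf("%s %.0f%%", sub$classification,
                                100 * sub$proportion), collapse = ", ")))
    }
  }
  if (!is.null(h$mdr_correlation))
    cat(sprintf("  MDR correlation: r = %.3f (p = %.2f, n = %d)\n",
                h$mdr_correlation$r, h$mdr_correlation$p,
                h$mdr_correlation$n))
  for (r in names(h$i2))
    cat(sprintf("  %s: I2 between = %.0f%%, within = %.0f%%, Q = %.0f (df %d), Egger p = %.2f\n",
                r, h$i2[[r]][["between"]], h$i2[[r]][["within"]],
                h$Q[[r]][["Q"]], h$Q[[r]][["df"]], h$egger_p[[r]]))
  cat(sprintf("  excluded effect-size values: %.1f%%\n",
              100 * h$exclusion_fraction))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (headline quantities and manifest) plus the main
#' tables (`effects.csv`, `mdr_results.csv`, `selection_trail.csv`,
#' `influence.csv`, `marginal_effects.csv`) into a directory.
#'
#' @param report A `bef_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "bef_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  headline <- report$headline
  headline$mdr_proportions <- as.data.frame(headline$mdr_proportions)
  jsonlite::write_json(
    list(headline = headline, manifest = report$manifest),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  utils::write.csv(report$effects, file.path(dir, "effects.csv"),
                   row.names = FALSE)
  utils::write.csv(report$null_model$results,
                   file.path(dir, "mdr_results.csv"), row.names = FALSE)
  utils::write.csv(report$selection$trail,
                   file.path(dir, "selection_trail.csv"), row.names = FALSE)
  utils::write.csv(report$influence, file.path(dir, "influence.csv"),
                   row.names = FALSE)
  utils::write.csv(report$marginal_effects,
                   file.path(dir, "marginal_effects.csv"), row.names = FALSE)
  invisible(dir)
}
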