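#' Global coefficient of variation of control arms
#'
#' Average over the dataset's control arms of `sd / mean` for one response
#' variable.  It defines the width of the noise band used by
#' [noise_filter()]: effects indistinguishable from control-level sampling
#' variability.  Computed per response variable, never pooled across
#' responses.
#'
#' @param observations Harmonised observation table.
#' @param response `"richness"` or `"function"`.
#' @return A single non-negative number.
#' @export
global_control_cv <- function(observations, response = c("richness", "function")) {
  response <- match.arg(response)
  ctrl <- observations |>
    dplyr::distinct(.data$study_id,
                    mean_c = .data[[paste0(response, "_mean_c")]],
                    sd_c = .data[[paste0(response, "_sd_c")]]) |>
    filter(.data$mean_c > 0, is.finite(.data$sd_c))
  mean(ctrl$sd_c / ctrl$mean_c)
}

#' Enumerate analysable stressor pairs
#'
#' For each study, every joint arm of exactly two stressors whose both
#' single-stressor arms are present becomes one analysable pair.  Joint
#' arms with three or more stressors are omitted (a three-way null has no
#' agreed classification boundaries), as are joint arms lacking a
#' single-stressor counterpart; both omissions are logged with a reason.
#'
#' @param effects Effect-size table from [add_effect_sizes()].
#' @param response `"richness"` or `"function"` — which LRR column to carry.
#' @return A tibble with one row per study x pair: `lrr_a`, `lrr_b` (single
#'   stressors), `lrr_obs` (joint arm) plus moderators.  The omission log is
#'   attached as attribute `"omitted"`.
#' @export
enumerate_pairs <- function(effects, response = c("richness", "function")) {
  response <- match.arg(response)
  tag <- switch(response, richness = "tr", `function` = "ef")
  lrr_col <- paste0("lrr_", tag)

  omitted <- list()
  singles <- effects |>
    filter(.data$n_stressors == 1) |>
    select("study_id", "function_type", single_id = "stressor_ids",
           single_lrr = all_of(lrr_col))

  joints <- filter(effects, .data$n_stressors >= 2)
  too_many <- filter(joints, .data$n_stressors > 2)
  if (nrow(too_many) > 0)
    omitted$three_or_more <- select(too_many, "study_id", "observation_id")

  pairs <- joints |>
    filter(.data$n_stressors == 2) |>
    tidyr::separate_wider_delim("stressor_ids", ",",
                                names = c("stressor_i", "stressor_j"),
                                cols_remove = FALSE) |>
    left_join(singles |> dplyr::rename(lrr_a = "single_lrr"),
              by = c("study_id", "function_type",
                     "stressor_i" = "single_id")) |>
    left_join(singles |> dplyr::rename(lrr_b = "single_lrr"),
              by = c("study_id", "function_type",
                     "stressor_j" = "single_id")) |>
    dplyr::rename(lrr_obs = all_of(lrr_col))

  unpaired <- pairs |>
    filter(!stats::complete.cases(.data$lrr_a, .data$lrr_b, .data$lrr_obs))
  if (nrow(unpaired) > 0) {
    omitted$unpaired <- select(unpaired, "study_id", "observation_id")
    inform(sprintf("%d joint arm(s) skipped: unpaired or excluded LRRs",
                   nrow(unpaired)))
  }
  out <- pairs |>
    filter(stats::complete.cases(.data$lrr_a, .data$lrr_b, .data$lrr_obs)) |>
    mutate(response = .env$response) |>
    select("study_id", "observation_id", "response",
           "stressor_i", "stressor_j", "organism_group", "function_type",
           dplyr::any_of("stressor_combination"),
           "lrr_a", "lrr_b", "lrr_obs")
  attr(out, "omitted") <- omitted
  out
}

#' Noise filter for stressor pairs
#'
#' A pair is excluded when both single-stressor LRRs are indistinguishable
#' from sampling noise around the control *and* point in opposite
#' directions — such cases would need a different definition of synergism
#' and antagonism, and small ratios of near-zero numbers produce artefactual
#' MDRs.  "Indistinguishable from noise" means within
#' `theta = log(1 + noise_fraction * global_cv)` of zero on the log-ratio
#' scale (the band of plus/minus `noise_fraction` of the global control CV,
#' mapped onto the ratio scale).
#'
#' @param lrr_a,lrr_b Single-stressor log response ratios (vectorised).
#' @param global_cv Global control coefficient of variation for the same
#'   response (see [global_control_cv()]).
#' @param noise_fraction Fraction of the global CV treated as noise
#'   (default 0.25).
#' @return Logical vector: `TRUE` where the pair is noise-excluded.
#' @export
noise_filter <- function(lrr_a, lrr_b, global_cv, noise_fraction = 0.25) {
  if (!is.numeric(global_cv) || length(global_cv) != 1 || global_cv <= 0)
    abort("`global_cv` must be a single positive number",
          class = "befstress_config_error")
  theta <- log(1 + noise_fraction * global_cv)
  sign(lrr_a) != sign(lrr_b) & abs(lrr_a) <= theta & abs(lrr_b) <= theta
}

classify_mdr <- function(mdr) {
  dplyr::case_when(
    mdr > 2 ~ "synergistic",
    mdr < 0.5 ~ "antagonistic",
    .default = "additive"
  )
}

#' Model deviation ratio for a stressor pair
#'
#' Under the multiplicative null model the joint response ratio is the
#' product of the single-stressor response ratios, i.e. the joint LRR is the
#' sum `lrr_a + lrr_b`.  The model deviation ratio (MDR) compares the
#' observed joint effect with that prediction as a ratio of response
#' ratios, `mdr = exp(s * (lrr_obs - lrr_pred))`, where the sign `s` is
#' flipped to `-1` when both single stressors act negatively — so that a
#' joint decline stronger than predicted always registers as `mdr > 1`
#' (without the flip the synergism/antagonism boundaries would be reversed
#' for shared declines).  `mdr > 2` is classified as synergism, `mdr < 0.5`
#' as antagonism, and the boundary values themselves as additive.
#'
#' The `"plain-ratio"` form `lrr_obs / lrr_pred` (with the same sign flip)
#' is available for sensitivity analysis; note that there the flip cancels
#' between numerator and denominator.
#'
#' @param lrr_a,lrr_b Single-stressor LRRs (vectorised).
#' @param lrr_obs Joint-arm LRR.
#' @param form `"ratio-of-ratios"` (default) or `"plain-ratio"`.
#' @return A tibble with `lrr_pred`, `sign_flipped`, `mdr`,
#'   `classification`.
#' @export
#' @examples
#' mdr(lrr_a = -0.5, lrr_b = -0.7, lrr_obs = -1.2)  # exact null: mdr = 1
mdr <- function(lrr_a, lrr_b, lrr_obs,
                form = c("ratio-of-ratios", "plain-ratio")) {
  form <- match.arg(form)
  if (any(!is.finite(lrr_a) | !is.finite(lrr_b) | !is.finite(lrr_obs)))
    abort(paste0("non-finite LRR at row(s): ",
                 paste(which(!is.finite(lrr_a) | !is.finite(lrr_b) |
                               !is.finite(lrr_obs)), collapse = ", ")),
          class = "befstress_computation_error")
  s <- mdr_sign(lrr_a, lrr_b)
  lrr_pred <- lrr_a + lrr_b
  value <- if (form == "ratio-of-ratios") {
    exp(s * lrr_obs - s * lrr_pred)
  } else {
    (s * lrr_obs) / (s * lrr_pred)
  }
  tibble(
    lrr_pred = lrr_pred,
    sign_flipped = s < 0,
    mdr = value,
    classification = classify_mdr(value)
  )
}

#' Classify all stressor-pair interactions in a dataset
#'
#' Runs the full null-model chain for both responses: enumerate analysable
#' pairs, apply the noise filter, compute MDRs, classify, and summarise the
#' proportions of additive / antagonistic / synergistic interactions over
#' the non-excluded pairs.
#'
#' @param effects Effect-size table from [add_effect_sizes()].
#' @param noise_fraction Noise band width as a fraction of the global
#'   control CV (default 0.25).
#' @param form MDR form, see [mdr()].
#' @return A list with `results` (one row per pair x response, including
#'   noise-excluded rows flagged `noise_excluded`) and `proportions`
#'   (tibble of class shares by response).
#' @export
classify_interactions <- function(effects, noise_fraction = 0.25,
                                  form = c("ratio-of-ratios", "plain-ratio")) {
  form <- match.arg(form)
  results <- purrr::map(c("richness", "function"), function(resp) {
    pairs <- enumerate_pairs(effects, response = resp)
    if (nrow(pairs) == 0) return(pairs)
    gcv <- global_control_cv(effects, response = resp)
    pairs$noise_excluded <- if (is.finite(gcv) && gcv > 0) {
      noise_filter(pairs$lrr_a, pairs$lrr_b, gcv, noise_fraction)
    } else {
      FALSE
    }
    res <- mdr(pairs$lrr_a, pairs$lrr_b, pairs$lrr_obs, form = form)
    out <- dplyr::bind_cols(pairs, res)
    out$mdr[out$noise_excluded] <- NA_real_
    out$classification[out$noise_excluded] <- NA_character_
    out
  }) |> bind_rows()

  if (nrow(results) == 0) {
    warn("no analysable stressor pairs in input")
    return(list(results = results, proportions = tibble()))
  }
  proportions <- results |>
    filter(!.data$noise_excluded) |>
    group_by(.data$response, .data$classification) |>
    summarise(n = n(), .groups = "drop_last") |>
    mutate(proportion = .data$n / sum(.data$n)) |>
    ungroup() |>
    tidyr::complete(response = unique(results$response),
                    classification = c("additive", "antagonistic",
                                       "synergistic"),
                    fill = list(n = 0L, proportion = 0)) |>
    arrange(.data$response, .data$classification)
  list(results = results, proportions = proportions)
}

#' Mixed moderator models for model deviation ratios
#'
#' Asks whether deviation from the multiplicative null depends on the
#' study-level moderators: for each response, fits a linear mixed model of
#' `log(mdr)` (symmetric around additivity at 0) on organism group,
#' stressor combination and ecosystem-function type with a random study
#' intercept, and reports per-term likelihood-ratio p-values.  Moderators
#' with fewer than two observed levels are dropped with a message.
#'
#' @param mdr_results `results` table from [classify_interactions()].
#' @param alpha Significance level carried into the report (default 0.05).
#' @return A tibble with one row per response x moderator term:
#'   `statistic` (LR chi-square), `df`, `p.value`, `n`, `n_studies`,
#'   `singular` flag.
#' @export
mdr_moderator_models <- function(mdr_results, alpha = 0.05) {
  moderators <- c("organism_group", "stressor_combination", "function_type")
  purrr::map(unique(mdr_results$response), function(resp) {
    dat <- mdr_results |>
      filter(.data$response == .env$resp, !.data$noise_excluded,
             is.finite(.data$mdr), .data$mdr > 0) |>
      mutate(log_mdr = log(.data$mdr))
    usable <- moderators[purrr::map_int(moderators, function(m) {
      if (!m %in% names(dat)) return(0L)
      dplyr::n_distinct(dat[[m]])
    }) >= 2]
    dropped <- setdiff(intersect(moderators, names(dat)), usable)
    if (length(dropped) > 0)
      inform(paste0("moderator(s) with < 2 levels dropped: ",
                    paste(dropped, collapse = ", ")))
    if (length(usable) == 0 || nrow(dat) < 5) return(NULL)
    ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
    full_fml <- stats::reformulate(c(usable, "(1 | study_id)"),
                                   response = "log_mdr")
    fit <- lme4::lmer(full_fml, data = dat, REML = FALSE, control = ctrl)
    singular <- lme4::isSingular(fit)
    purrr::map(usable, function(term) {
      reduced <- stats::reformulate(c(setdiff(usable, term), "(1 | study_id)"),
                                    response = "log_mdr")
      red_fit <- lme4::lmer(reduced, data = dat, REML = FALSE, control = ctrl)
      lrt <- anova(red_fit, fit)
      tibble(
        response = resp, term = term,
        statistic = lrt$Chisq[2], df = lrt$Df[2], p.value = lrt$`Pr(>Chisq)`[2],
        n = nrow(dat), n_studies = dplyr::n_distinct(dat$study_id),
        significant = lrt$`Pr(>Chisq)`[2] <= alpha,
        singular = singular
      )
    }) |> bind_rows()
  }) |> bind_rows()
}

#' Correlation between richness and function model deviation ratios
#'
#' Matches pairs by study and stressor pair across the two responses and
#' computes the Pearson correlation of their MDRs, to ask whether deviation
#' from the null in biodiversity predicts deviation in function.
#'
#' @param mdr_results `results` table from [classify_interactions()].
#' @return A list with `r`, `p`, `n`; `NA` with a warning when fewer than 3
#'   matched pairs exist.
#' @export
mdr_correlation <- function(mdr_results) {
  wide <- mdr_results |>
    filter(!.data$noise_excluded, is.finite(.data$mdr)) |>
    select("study_id", "stressor_i", "stressor_j", "response", "mdr") |>
    tidyr::pivot_wider(names_from = "response", values_from = "mdr")
  if (!all(c("richness", "function") %in% names(wide))) {
    warn("both responses are needed for the MDR correlation")
    return(list(r = NA_real_, p = NA_real_, n = 0L))
  }
  wide <- filter(wide, stats::complete.cases(.data$richness,
                                             .data$`function`))
  if (nrow(wide) < 3) {
    warn("fewer than 3 matched pairs; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = nrow(wide)))
  }
  ct <- cor.test(wide$richness, wide$`function`, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(wide))
}
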