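#' Raw log response ratio with delta-method sampling variance
#'
#' The effect-size currency of the pipeline: `lrr = log(mean_t / mean_c)`,
#' with first-order delta-method sampling variance
#' `sd_t^2/(n_t mean_t^2) + sd_c^2/(n_c mean_c^2)`.  Non-positive arm means
#' do not raise an error; the affected value is flagged excluded (reason
#' `"nonpositive_mean"`) so that one bad arm never drops a study.
#'
#' @param mean_t,sd_t,n_t Treatment-arm summary statistics (vectorised).
#' @param mean_c,sd_c,n_c Control-arm summary statistics.
#' @return A tibble with columns `lrr`, `variance`, `corrected`, `excluded`,
#'   `exclusion_reason`.
#' @seealso [lrr_corrected()] for the small-sample bias-corrected form.
#' @export
#' @examples
#' lrr_raw(mean_t = 2, sd_t = 0.4, n_t = 3, mean_c = 1, sd_c = 0.3, n_c = 3)
lrr_raw <- function(mean_t, sd_t, n_t, mean_c, sd_c, n_c) {
  ok <- is.finite(mean_t) & is.finite(mean_c) & mean_t > 0 & mean_c > 0
  ok[is.na(ok)] <- FALSE
  lrr <- variance <- rep(NA_real_, length(ok))
  lrr[ok] <- log(mean_t[ok] / mean_c[ok])
  variance[ok] <- sd_t[ok]^2 / (n_t[ok] * mean_t[ok]^2) +
    sd_c[ok]^2 / (n_c[ok] * mean_c[ok]^2)
  tibble(
    lrr = lrr,
    variance = variance,
    corrected = FALSE,
    excluded = !ok,
    exclusion_reason = ifelse(ok, "none", "nonpositive_mean")
  )
}

#' Small-sample bias-corrected log response ratio
#'
#' With few replicates the raw LRR systematically over- or under-estimates
#' the true log ratio whenever the arm coefficients of variation differ,
#' because `E[log(m)] < log(E[m])` by an amount that depends on the sampling
#' variance of each arm mean.  This applies the second-order delta-method
#' ("all cases") correction to both the point estimate,
#' \deqn{\mathrm{LRR} = \log(m_T/m_C)
#'   + \tfrac12\left[\frac{s_T^2}{n_T m_T^2} - \frac{s_C^2}{n_C m_C^2}\right],}
#' and the sampling variance,
#' \deqn{v = \frac{s_T^2}{n_T m_T^2} + \frac{s_C^2}{n_C m_C^2}
#'   + \tfrac12\left[\frac{s_T^4}{n_T^2 m_T^4}
#'   + \frac{s_C^4}{n_C^2 m_C^4}\right].}
#' When either arm has fewer than two replicates the correction has no
#' variance information to work with and the raw form is returned with a
#' warning.
#'
#' @inheritParams lrr_raw
#' @return A tibble as in [lrr_raw()] with `corrected = TRUE` where the
#'   correction was applied.
#' @export
lrr_corrected <- function(mean_t, sd_t, n_t, mean_c, sd_c, n_c) {
  out <- lrr_raw(mean_t, sd_t, n_t, mean_c, sd_c, n_c)
  can_correct <- !out$excluded & n_t >= 2 & n_c >= 2
  if (any(!out$excluded & !can_correct))
    warn("arms with n < 2: falling back to the raw LRR for those values")
  ct <- sd_t^2 / (n_t * mean_t^2)
  cc <- sd_c^2 / (n_c * mean_c^2)
  out$lrr <- ifelse(can_correct, out$lrr + 0.5 * (ct - cc), out$lrr)
  out$variance <- ifelse(
    can_correct,
    out$variance + 0.5 * (ct^2 + cc^2),
    out$variance
  )
  out$corrected <- can_correct
  out
}

# Specific exclusion reasons per response variable: zero richness and
# negative production are the two ways non-positive means arise in practice.
specific_reason <- function(reason, response, mean_t, mean_c) {
  dplyr::case_when(
    reason == "none" ~ "none",
    response == "richness" ~ "zero_richness",
    response %in% c("function", "shannon") &
      (mean_t < 0 | mean_c < 0) ~ "negative_production",
    .default = "nonpositive_mean"
  )
}

#' Compute effect sizes for every response in an observation table
#'
#' Adds bias-corrected (default) or raw log response ratios and sampling
#' variances for taxon richness (`lrr_tr`, `var_tr`), Shannon diversity
#' (`lrr_sd`, `var_sd`; only if Shannon columns are present) and the
#' ecosystem-function response (`lrr_ef`, `var_ef`), together with
#' per-response exclusion flags (`excluded_tr` etc.).  Excluded values are
#' `NA`; the rows (and studies) stay in the table.
#'
#' @param observations Harmonised observation table (see
#'   [harmonise_observations()]).
#' @param correction Apply the small-sample correction (default `TRUE`).
#' @return The input tibble with effect-size columns appended.
#' @export
add_effect_sizes <- function(observations, correction = TRUE) {
  observations <- as_tibble(observations)
  fn <- if (correction) lrr_corrected else lrr_raw
  responses <- c(tr = "richness", sd = "shannon", ef = "function")
  for (tag in names(responses)) {
    resp <- responses[[tag]]
    if (!paste0(resp, "_mean_t") %in% names(observations)) next
    es <- fn(
      mean_t = observations[[paste0(resp, "_mean_t")]],
      sd_t = observations[[paste0(resp, "_sd_t")]],
      n_t = observations[[paste0(resp, "_n_t")]],
      mean_c = observations[[paste0(resp, "_mean_c")]],
      sd_c = observations[[paste0(resp, "_sd_c")]],
      n_c = observations[[paste0(resp, "_n_c")]]
    )
    observations[[paste0("lrr_", tag)]] <- es$lrr
    observations[[paste0("var_", tag)]] <- es$variance
    observations[[paste0("excluded_", tag)]] <- es$excluded
    observations[[paste0("reason_", tag)]] <- specific_reason(
      es$exclusion_reason, resp,
      observations[[paste0(resp, "_mean_t")]],
      observations[[paste0(resp, "_mean_c")]]
    )
  }
  observations
}

#' Summarise effect-size exclusions
#'
#' Reports how many values could not be converted to log response ratios
#' (zero or negative means) and the excluded fraction, counted both over
#' individual values and over observation rows with at least one exclusion.
#'
#' @param effects Output of [add_effect_sizes()].
#' @return A list with `by_reason` (tibble of reason counts),
#'   `fraction_values`, and `fraction_rows`.
#' @export
exclusion_report <- function(effects) {
  flag_cols <- grep("^excluded_", names(effects), value = TRUE)
  reason_cols <- grep("^reason_", names(effects), value = TRUE)
  flags <- as.matrix(effects[flag_cols])
  reasons <- unlist(effects[reason_cols], use.names = FALSE)
  by_reason <- tibble(reason = reasons) |>
    filter(.data$reason != "none") |>
    dplyr::count(.data$reason, name = "n_values")
  list(
    by_reason = by_reason,
    n_values = length(flags),
    fraction_values = mean(flags, na.rm = TRUE),
    fraction_rows = mean(rowSums(flags, na.rm = TRUE) > 0)
  )
}
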