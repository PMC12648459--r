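# Columns every harmonised observation table must carry.  Arm summaries are
# stored wide: <response>_{mean,sd,n}_{c,t} for control and treatment.
.obs_required_cols <- c(
  "study_id", "observation_id", "organism_group", "function_type",
  "stressor_ids", "n_stressors",
  "richness_mean_c", "richness_sd_c", "richness_n_c",
  "richness_mean_t", "richness_sd_t", "richness_n_t",
  "function_mean_c", "function_sd_c", "function_n_c",
  "function_mean_t", "function_sd_t", "function_n_t"
)

#' Validate a harmonised observation table
#'
#' Checks the schema (required columns, replicate counts >= 1, SDs >= 0),
#' that moderator labels come from the known vocabulary, and that every
#' organism-group / function-type pair is one the function can be attributed
#' to a priori (see [attribution_table()]).  Unknown labels are rejected
#' rather than coerced: silently relabelled moderators would corrupt the
#' nested moderator models downstream.
#'
#' @param observations A data frame in the harmonised schema.
#' @param strict If `TRUE` (default) attribution violations abort; otherwise
#'   they are reported as warnings and the offending rows flagged.
#' @return The validated tibble (invisibly unchanged apart from coercion to
#'   tibble).
#' @export
validate_observations <- function(observations, strict = TRUE) {
  observations <- as_tibble(observations)
  missing <- setdiff(.obs_required_cols, names(observations))
  if (length(missing) > 0)
    abort(paste0("observation table lacks required columns: ",
                 paste(missing, collapse = ", ")),
          class = "befstress_schema_error")

  bad_group <- setdiff(unique(observations$organism_group), .befstress_groups)
  bad_fun <- setdiff(unique(observations$function_type), .befstress_functions)
  if (length(bad_group) || length(bad_fun))
    abort(paste0("unknown moderator labels: ",
                 paste(c(bad_group, bad_fun), collapse = ", ")),
          class = "befstress_schema_error")

  for (resp in c("richness", "function")) {
    n_c <- observations[[paste0(resp, "_n_c")]]
    n_t <- observations[[paste0(resp, "_n_t")]]
    if (any(c(n_c, n_t) < 1, na.rm = TRUE))
      abort(sprintf("replicate counts for %s must be >= 1", resp),
            class = "befstress_schema_error")
    sds <- c(observations[[paste0(resp, "_sd_c")]],
             observations[[paste0(resp, "_sd_t")]])
    if (any(sds < 0, na.rm = TRUE))
      abort(sprintf("negative SD for %s", resp),
            class = "befstress_schema_error")
  }

  violations <- observations |>
    anti_join(.befstress_attribution,
              by = c("organism_group", "function_type"))
  if (nrow(violations) > 0) {
    msg <- sprintf(
      "%d observation(s) pair an organism group with a function it cannot be attributed to (e.g. %s / %s)",
      nrow(violations), violations$organism_group[1], violations$function_type[1]
    )
    if (strict) abort(msg, class = "befstress_attribution_error") else warn(msg)
  }
  observations
}

#' Drop measurements taken before stressor exposure
#'
#' Removes rows whose `phase` is not `"post"`; only responses measured under
#' exposure enter the analysis.  The number of dropped rows is reported.
#'
#' @param observations Observation table with a `phase` column
#'   (`"pre"`/`"post"`).  Tables without a `phase` column are returned
#'   unchanged (all rows assumed post-exposure).
#' @return The filtered tibble.
#' @export
drop_pre_exposure <- function(observations) {
  observations <- as_tibble(observations)
  if (!"phase" %in% names(observations) || nrow(observations) == 0)
    return(observations)
  kept <- filter(observations, .data$phase == "post")
  n_dropped <- nrow(observations) - nrow(kept)
  if (n_dropped > 0)
    inform(sprintf("dropped %d pre-exposure row(s)", n_dropped))
  kept
}

# Root-mean-square pooling of per-time-point SDs.  The aggregation rule for
# SDs under mean-over-time is a package choice (conservative, symmetric in
# the time points); it is isolated here so alternatives can be swapped.
pool_sd_rms <- function(sd) sqrt(mean(sd^2))

#' Aggregate repeated measurements over post-exposure time points
#'
#' Collapses each study x observation to a single row.  `mode = "mean"`
#' averages arm means over time points (SDs pooled as root-mean-square,
#' replicate counts as the per-time-point value); `mode =
#' "max_richness_deviation"` keeps the single time point where treatment
#' taxon richness deviated most from the control (largest absolute richness
#' log response ratio), the sensitivity alternative to the mean.
#'
#' @param observations Observation table (post-exposure rows only).
#' @param mode `"mean"` (default) or `"max_richness_deviation"`.
#' @return One row per study x observation; idempotent.
#' @export
aggregate_time <- function(observations,
                           mode = c("mean", "max_richness_deviation")) {
  mode <- match.arg(mode)
  observations <- as_tibble(observations)
  if (nrow(observations) == 0) return(observations)
  if (!"time_point" %in% names(observations)) return(observations)

  summary_cols <- grep("^(richness|shannon|function)_(mean|sd|n)_(c|t)$",
                       names(observations), value = TRUE)
  key_cols <- setdiff(names(observations), c(summary_cols, "time_point"))

  if (mode == "mean") {
    out <- observations |>
      group_by(across(all_of(key_cols))) |>
      summarise(
        across(all_of(grep("_mean_", summary_cols, value = TRUE)),
               ~ mean(.x)),
        across(all_of(grep("_sd_", summary_cols, value = TRUE)),
               ~ pool_sd_rms(.x)),
        across(all_of(grep("_n_", summary_cols, value = TRUE)),
               ~ .x[1]),
        .groups = "drop"
      )
  } else {
    out <- observations |>
      mutate(
        .abs_lrr_tr = dplyr::if_else(
          .data$richness_mean_t > 0 & .data$richness_mean_c > 0,
          abs(log(.data$richness_mean_t / .data$richness_mean_c)),
          -Inf
        )
      ) |>
      group_by(across(all_of(key_cols))) |>
      arrange(dplyr::desc(.data$.abs_lrr_tr), .data$time_point,
              .by_group = TRUE) |>
      dplyr::slice(1) |>
      ungroup() |>
      select(-".abs_lrr_tr")
  }
  out |>
    mutate(time_point = NA_integer_) |>
    select(all_of(names(observations))) |>
    arrange(.data$study_id, .data$observation_id)
}

#' Keep only the highest level of each stressor within a study
#'
#' Most factorial stressor experiments report several intensity levels per
#' stressor; the analysis uses only the strongest one.  For every
#' study x stressor the maximal reported level is found, and an arm is
#' retained only if each of its stressors sits at that stressor's maximal
#' level.  Ties (duplicate arms at the maximal level) are broken by first
#' occurrence with a warning.
#'
#' @param observations Observation table with either a scalar
#'   `stressor_level` column or a `stressor_levels` comma-list aligned with
#'   `stressor_ids`.
#' @return The filtered tibble.
#' @export
select_highest_level <- function(observations) {
  observations <- as_tibble(observations)
  if (nrow(observations) == 0) return(observations)
  has_list <- "stressor_levels" %in% names(observations)
  if (!has_list && !"stressor_level" %in% names(observations))
    abort("no `stressor_level` or `stressor_levels` column",
          class = "befstress_schema_error")

  parsed <- purrr::map2(
    strsplit(observations$stressor_ids, ",", fixed = TRUE),
    if (has_list) strsplit(as.character(observations$stressor_levels), ",",
                           fixed = TRUE)
    else as.list(as.character(observations$stressor_level)),
    function(ids, lev) setNames(as.numeric(rep_len(lev, length(ids))), ids)
  )

  # maximal level per study x stressor
  level_map <- tibble(
    study_id = rep(observations$study_id, lengths(parsed)),
    stressor = unlist(lapply(parsed, names)),
    level = unlist(parsed)
  ) |>
    group_by(.data$study_id, .data$stressor) |>
    summarise(max_level = max(.data$level), .groups = "drop")

  keep <- purrr::map_lgl(seq_len(nrow(observations)), function(i) {
    lv <- parsed[[i]]
    mx <- level_map$max_level[match(
      paste(observations$study_id[i], names(lv)),
      paste(level_map$study_id, level_map$stressor)
    )]
    all(lv >= mx)
  })
  out <- observations[keep, , drop = FALSE]

  dup_key <- paste(out$study_id, out$stressor_ids,
                   if ("time_point" %in% names(out)) out$time_point else "",
                   if ("function_type" %in% names(out)) out$function_type else "")
  if (anyDuplicated(dup_key)) {
    warn("ties at the maximal stressor level; keeping first occurrence")
    out <- out[!duplicated(dup_key), , drop = FALSE]
  }
  out
}

#' Run the full harmonisation chain
#'
#' Convenience wrapper: validate, drop pre-exposure rows, keep the highest
#' stressor level, aggregate over time points.
#'
#' @inheritParams validate_observations
#' @inheritParams aggregate_time
#' @return Analysis-ready observation tibble, one row per
#'   study x observation.
#' @export
harmonise_observations <- function(observations,
                                   mode = c("mean", "max_richness_deviation"),
                                   strict = TRUE) {
  observations |>
    validate_observations(strict = strict) |>
    drop_pre_exposure() |>
    select_highest_level() |>
    aggregate_time(mode = match.arg(mode))
}
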