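test_that("pre-exposure rows are dropped and post-exposure kept", {
  obs <- dplyr::bind_rows(
    make_obs_row(arm = "A", phase = "pre", time_point = 0L),
    make_obs_row(arm = "A", phase = "pre", time_point = 0L),
    make_obs_row(arm = "A", phase = "post", time_point = 1L),
    make_obs_row(arm = "A", phase = "post", time_point = 2L),
    make_obs_row(arm = "A", phase = "post", time_point = 3L)
  )
  expect_message(out <- drop_pre_exposure(obs), "2 pre-exposure")
  expect_equal(nrow(out), 3)
  expect_true(all(out$phase == "post"))
  # all-post input is untouched; empty input passes through
  all_post <- make_obs_row(phase = "post")
  expect_identical(drop_pre_exposure(all_post), all_post)
  expect_equal(nrow(drop_pre_exposure(all_post[0, ])), 0)
})

test_that("mean aggregation averages means and pools SDs as RMS", {
  obs <- dplyr::bind_rows(
    make_obs_row(time_point = 1L, richness_t = c(9, 1, 4),
                 function_t = c(90, 6, 4)),
    make_obs_row(time_point = 2L, richness_t = c(6, 2, 4),
                 function_t = c(60, 8, 4)),
    make_obs_row(time_point = 3L, richness_t = c(3, 2, 4),
                 function_t = c(30, 10, 4))
  )
  out <- aggregate_time(obs, mode = "mean")
  expect_equal(nrow(out), 1)
  expect_equal(out$richness_mean_t, mean(c(9, 6, 3)))
  expect_equal(out$function_mean_t, mean(c(90, 60, 30)))
  expect_equal(out$richness_sd_t, sqrt(mean(c(1, 2, 2)^2)))
  expect_equal(out$function_sd_t, sqrt(mean(c(6, 8, 10)^2)))
})

test_that("max-richness-deviation keeps the most deviating time point", {
  obs <- dplyr::bind_rows(
    make_obs_row(time_point = 1L, richness_t = c(8, 1, 4)),
    make_obs_row(time_point = 2L, richness_t = c(4, 1, 4))
  )
  out <- aggregate_time(obs, mode = "max_richness_deviation")
  expect_equal(nrow(out), 1)
  expect_equal(out$richness_mean_t, 4)
})

test_that("single-time-point records pass through either mode unchanged", {
  obs <- make_obs_row()
  for (mode in c("mean", "max_richness_deviation")) {
    out <- aggregate_time(obs, mode = mode)
    expect_equal(nrow(out), 1)
    expect_equal(out$richness_mean_t, obs$richness_mean_t)
    expect_equal(out$function_sd_t, obs$function_sd_t)
  }
})

test_that("time aggregation is idempotent", {
  obs <- realise_observations(small_db()$truth,
                              sim_config(n_studies = 25, seed = 42,
                                         n_time_points = 3))
  once <- aggregate_time(obs, mode = "mean")
  twice <- aggregate_time(once, mode = "mean")
  expect_equal(twice, once)
})

test_that("only the highest level of each stressor is retained", {
  obs <- dplyr::bind_rows(
    make_obs_row(arm = "A1", stressor_ids = "A", stressor_level = 1),
    make_obs_row(arm = "A2", stressor_ids = "A", stressor_level = 2),
    make_obs_row(arm = "A3", stressor_ids = "A", stressor_level = 3)
  )
  out <- select_highest_level(obs)
  expect_equal(out$arm_id, "A3")

  # a single treatment level beside the control is untouched
  single <- make_obs_row(stressor_level = 1)
  expect_equal(nrow(select_highest_level(single)), 1)
})

test_that("joint arms are kept only when every stressor is at its maximum", {
  obs <- dplyr::bind_rows(
    make_obs_row(arm = "A1", stressor_ids = "A", stressor_level = 1),
    make_obs_row(arm = "A2", stressor_ids = "A", stressor_level = 2),
    make_obs_row(arm = "B1", stressor_ids = "B", stressor_level = 1),
    make_obs_row(arm = "A2xB1", stressor_ids = "A,B", n_stressors = 2L) |>
      dplyr::mutate(stressor_level = NULL, stressor_levels = "2,1")
  )
  obs$stressor_levels[1:3] <- as.character(obs$stressor_level[1:3])
  obs$stressor_level <- NULL
  out <- select_highest_level(obs)
  expect_setequal(out$arm_id, c("A2", "B1", "A2xB1"))
})

test_that("a missing level column is a schema error", {
  obs <- make_obs_row()
  obs$stressor_level <- NULL
  expect_error(select_highest_level(obs), class = "befstress_schema_error")
})

test_that("attribution violations are rejected in strict mode, warned otherwise", {
  bad <- make_obs_row(organism_group = "zooplankton",
                      function_type = "photosynthesis")
  expect_error(validate_observations(bad, strict = TRUE),
               class = "befstress_attribution_error")
  expect_warning(validate_observations(bad, strict = FALSE), "attributed")
  expect_error(validate_observations(
    make_obs_row(organism_group = "fish")), "unknown moderator",
    class = "befstress_schema_error")
})

test_that("harmonisation never increases the number of rows", {
  obs <- realise_observations(small_db()$truth,
                              sim_config(n_studies = 25, seed = 42,
                                         n_time_points = 2))
  out <- quiet(harmonise_observations(obs))
  expect_lte(nrow(out), nrow(obs))
  # and the attribution constraint holds on the output
  expect_silent(validate_observations(out))
})
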