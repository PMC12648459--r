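# Hand-built observation rows in the harmonised schema, for fixtures whose
# expected behaviour is computed by hand.
make_obs_row <- function(study = "S1", arm = "A", organism_group = "algae",
                         function_type = "photosynthesis",
                         stressor_ids = arm, n_stressors = 1L,
                         stressor_level = 1, phase = "post", time_point = 1L,
                         richness_c = c(10, 1, 4), richness_t = c(8, 1, 4),
                         function_c = c(100, 10, 4), function_t = c(80, 8, 4),
                         stressor_combination = "habitat") {
  tibble::tibble(
    study_id = study,
    observation_id = paste0(study, ":", arm),
    arm_id = arm,
    organism_group = organism_group,
    function_type = function_type,
    stressor_ids = stressor_ids,
    stressor_categories = stressor_combination,
    stressor_combination = stressor_combination,
    n_stressors = as.integer(n_stressors),
    stressor_level = stressor_level,
    phase = phase,
    time_point = as.integer(time_point),
    richness_mean_c = richness_c[1], richness_sd_c = richness_c[2],
    richness_n_c = richness_c[3],
    richness_mean_t = richness_t[1], richness_sd_t = richness_t[2],
    richness_n_t = richness_t[3],
    function_mean_c = function_c[1], function_sd_c = function_c[2],
    function_n_c = function_c[3],
    function_mean_t = function_t[1], function_sd_t = function_t[2],
    function_n_t = function_t[3]
  )
}

# A minimal noise-free study with singles A, B and the joint A+B whose
# function response sits exactly on the multiplicative null.
make_null_study <- function(study = "S1", lrr_a = -0.4, lrr_b = -0.2,
                            delta = 0) {
  f0 <- 100
  dplyr::bind_rows(
    make_obs_row(study, "A", stressor_ids = "A",
                 function_t = c(f0 * exp(lrr_a), 5, 4)),
    make_obs_row(study, "B", stressor_ids = "B",
                 function_t = c(f0 * exp(lrr_b), 5, 4),
                 stressor_combination = "nutrients"),
    make_obs_row(study, "A+B", stressor_ids = "A,B", n_stressors = 2L,
                 function_t = c(f0 * exp(lrr_a + lrr_b + delta), 5, 4),
                 stressor_combination = "habitat+nutrients")
  )
}

# Shared small synthetic database (computed once per test run).
small_db <- local({
  value <- NULL
  function() {
    if (is.null(value))
      value <<- generate_database(sim_config(n_studies = 25, seed = 42))
    value
  }
})

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
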