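test_that("Cramer's V hits its limits", {
  expect_equal(cramers_v(rep(c("a", "b"), each = 10),
                         rep(c("x", "y"), each = 10)), 1)
  set.seed(4)
  x <- sample(letters[1:3], 4000, replace = TRUE)
  y <- sample(LETTERS[1:3], 4000, replace = TRUE)
  expect_lt(cramers_v(x, y), 0.05)
  expect_warning(v <- cramers_v(rep("a", 10), rep(c("x", "y"), 5)),
                 "degenerate")
  expect_true(is.na(v))
})

test_that("the collinearity screen reports flagged pairs without dropping", {
  d <- tibble::tibble(
    organism_group = rep(c("algae", "macroinvertebrates"), each = 20),
    function_type = rep(c("photosynthesis", "leaf decomposition"), each = 20),
    stressor_combination = rep(c("habitat", "nutrients"), 20)
  )
  out <- cramers_v_screen(d)
  row <- out[out$var1 == "organism_group" & out$var2 == "function_type", ]
  expect_equal(row$v, 1)
  expect_true(row$flagged)
  expect_equal(nrow(out), 3)
})

test_that("marginality restricts removable terms", {
  terms <- bef_full_terms("lrr_tr")
  rem <- befstress:::removable_terms(terms)
  expect_false("lrr_tr" %in% rem)
  expect_false("ns" %in% rem)
  expect_false("ns:stressor_combination" %in% rem)
  expect_true("lrr_tr:ns:stressor_combination" %in% rem)
  expect_true("lrr_tr:function_type:organism_group" %in% rem)
  # once the three-way terms are gone, their parents become removable
  rem2 <- befstress:::removable_terms(setdiff(terms, c(
    "lrr_tr:ns:stressor_combination",
    "lrr_tr:function_type:organism_group")))
  expect_true("ns:stressor_combination" %in% rem2)
  expect_true("lrr_tr:ns" %in% rem2)
})

test_that("zero between-study variance gives equal marginal and conditional R2", {
  # response simulated directly from the fitted model with tau2 = 0
  set.seed(17)
  dat <- tibble::tibble(
    study_id = rep(sprintf("S%02d", 1:40), each = 3),
    lrr_tr = rnorm(120, -0.3, 0.4),
    ns = rep(sample(1:3, 40, replace = TRUE), each = 3)
  )
  dat$lrr_ef <- 0.2 + 0.5 * dat$lrr_tr + rnorm(120, 0, 0.5)
  fit <- quiet(fit_bef_lmm(dat, terms = c("lrr_tr", "ns", "lrr_tr:ns")))
  expect_lt(fit$tau2, 0.02)
  expect_equal(fit$r2_marginal, fit$r2_conditional, tolerance = 0.02)
  expect_true(fit$r2_marginal >= 0 && fit$r2_conditional <= 1)
  expect_lte(fit$n_groups, fit$n_obs)
})

test_that("an intercept-only model has zero marginal R2", {
  eff <- add_effect_sizes(small_db()$observations)
  md <- bef_model_data(eff)
  fit <- quiet(fit_bef_lmm(md$data, terms = character(0)))
  expect_equal(fit$r2_marginal, 0, tolerance = 1e-10)
})

test_that("backward selection is deterministic and respects marginality", {
  eff <- add_effect_sizes(small_db()$observations)
  md <- bef_model_data(eff)
  a <- quiet(backward_select(md$data, terms = md$terms))
  b <- quiet(backward_select(md$data, terms = md$terms))
  expect_identical(a$trail, b$trail)
  expect_identical(a$terms, b$terms)
  # every intermediate step kept marginality: replay the trail
  terms <- md$terms
  for (t in a$trail$term) {
    expect_true(t %in% befstress:::removable_terms(terms))
    terms <- setdiff(terms, t)
  }
})

test_that("single-level moderators are dropped with a warning, not a crash", {
  eff <- add_effect_sizes(small_db()$observations)
  eff$function_type <- "photosynthesis"
  eff$organism_group <- "algae"
  w <- capture_warnings(md <- bef_model_data(eff))
  expect_true(any(grepl("function_type", w)))
  expect_false(any(grepl("function_type", md$terms)))
  fit <- quiet(fit_bef_lmm(md$data, terms = md$terms))
  expect_s3_class(fit, "bef_lmm")
})

test_that("an inflated study gets the maximal Cook's distance", {
  cfg <- sim_config(n_studies = 12, tau2_study = 0.05, seed = 23)
  eff <- add_effect_sizes(generate_database(cfg)$observations)
  md <- bef_model_data(eff)
  dat <- md$data
  # a study-level constant shift would be absorbed by the random intercept;
  # corrupt the within-study slope of the highest-leverage study instead
  lev <- tapply(dat$lrr_tr^2, dat$study_id, sum)
  target <- names(which.max(lev))
  bad <- dat$study_id == target
  dat$lrr_ef[bad] <- dat$lrr_ef[bad] - 10 * dat$lrr_tr[bad]
  fit <- quiet(fit_bef_lmm(dat, terms = c("lrr_tr", "ns")))
  cd <- quiet(cooks_distance_by_study(fit))
  expect_equal(cd$study_id[which.max(cd$cooks_d)], target)
  expect_true(cd$influential[cd$study_id == target])
})

test_that("balanced duplicated studies have similar small Cook's distances", {
  one <- make_null_study("S1", -0.4, -0.2)
  obs <- purrr::map(1:6, function(i) {
    s <- one
    s$study_id <- paste0("S", i)
    s$observation_id <- paste0(s$study_id, ":", s$arm_id)
    s
  }) |> dplyr::bind_rows()
  eff <- add_effect_sizes(obs)
  fit <- quiet(fit_bef_lmm(bef_model_data(eff)$data, terms = "lrr_tr"))
  cd <- quiet(cooks_distance_by_study(fit))
  expect_lt(max(cd$cooks_d), 0.5)
  expect_lt(diff(range(cd$cooks_d)), 1e-6)
})

test_that("leave-one-study-out produces one refit per study", {
  cfg <- sim_config(n_studies = 3, seed = 29)
  eff <- add_effect_sizes(generate_database(cfg)$observations)
  fit <- quiet(fit_bef_lmm(bef_model_data(eff)$data,
                           terms = c("lrr_tr", "ns")))
  cv <- quiet(loso_cv(fit))
  expect_length(unique(cv$coefficients$held_out), 3)
  expect_true(all(c("sign_stability", "min", "max") %in%
                    names(cv$summary)))
})

test_that("the marginal-effects grid predicts over diversity x stressor number", {
  eff <- add_effect_sizes(small_db()$observations)
  md <- bef_model_data(eff)
  fit <- quiet(fit_bef_lmm(md$data, terms = c("lrr_tr", "ns", "lrr_tr:ns")))
  grid <- marginal_effects_grid(fit)
  expect_true(all(is.finite(grid$predicted)))
  expect_setequal(unique(grid$ns), intersect(1:3, unique(md$data$ns)))
  # slope within each ns level is constant for the linear model
  s1 <- grid[grid$ns == 1, ]
  slope <- unname(lme4::fixef(fit$fit)["lrr_tr"] +
                    lme4::fixef(fit$fit)["lrr_tr:ns"])
  expect_equal(unname(diff(s1$predicted) / diff(s1$lrr_tr)),
               rep(slope, nrow(s1) - 1))
})

test_that("inverse-variance weighting is accepted and changes the fit", {
  eff <- add_effect_sizes(small_db()$observations)
  md <- bef_model_data(eff)
  fw <- quiet(fit_bef_lmm(md$data, terms = c("lrr_tr", "ns"),
                          weights = "inverse-variance"))
  fu <- quiet(fit_bef_lmm(md$data, terms = c("lrr_tr", "ns")))
  expect_s3_class(fw, "bef_lmm")
  expect_false(isTRUE(all.equal(tidy(fw)$estimate, tidy(fu)$estimate)))
})
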