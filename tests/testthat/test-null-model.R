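test_that("MDR matches hand-evaluated cases", {
  # exact multiplicative null
  out <- mdr(-0.5, -0.7, -1.2)
  expect_equal(out$mdr, 1)
  expect_equal(out$classification, "additive")
  expect_true(out$sign_flipped)
  # stronger-than-predicted joint increase
  out <- mdr(0.3, 0.4, 0.7 + log(2.5))
  expect_equal(out$mdr, 2.5)
  expect_equal(out$classification, "synergistic")
  # shared decline weaker than predicted: flip makes it antagonistic
  out <- mdr(-0.5, -0.5, -1.0 + log(2.5))
  expect_equal(out$mdr, 1 / 2.5)
  expect_equal(out$classification, "antagonistic")
})

test_that("boundary MDR values classify as additive", {
  expect_equal(mdr(0, 0, log(2))$mdr, 2)
  expect_equal(mdr(0, 0, log(2))$classification, "additive")
  expect_equal(mdr(0, 0, -log(2))$classification, "additive")
  expect_equal(mdr(0, 0, log(2) + 1e-9)$classification, "synergistic")
  expect_equal(mdr(0, 0, -log(2) - 1e-9)$classification, "antagonistic")
})

test_that("MDR is invariant to swapping the single stressors", {
  set.seed(2)
  a <- rnorm(200); b <- rnorm(200); o <- rnorm(200)
  expect_equal(mdr(a, b, o)$mdr, mdr(b, a, o)$mdr)
})

test_that("a stronger-than-predicted joint effect gives MDR > 1 for shared signs", {
  grid <- expand.grid(a = c(-1, -0.3, 0.3, 1), b = c(-0.8, -0.2, 0.2, 0.8),
                      d = c(0.1, 0.5, 1))
  grid <- grid[sign(grid$a) == sign(grid$b), ]
  # "stronger" = further from zero in the shared direction
  obs <- grid$a + grid$b + sign(grid$a) * grid$d
  expect_true(all(mdr(grid$a, grid$b, obs)$mdr > 1))
})

test_that("non-finite inputs raise a computation error naming the row", {
  expect_error(mdr(c(0.1, NA), c(0.2, 0.2), c(0.3, 0.3)), "2",
               class = "befstress_computation_error")
})

test_that("the plain-ratio form is available and differs as documented", {
  out <- mdr(0.3, 0.4, 1.4, form = "plain-ratio")
  expect_equal(out$mdr, 1.4 / 0.7)
})

test_that("the noise filter excludes only small opposite-sign pairs", {
  theta <- log(1 + 0.25 * 0.4)   # ~0.0953
  expect_true(noise_filter(0.01, -0.01, 0.4))
  expect_false(noise_filter(0.01, 0.01, 0.4))
  expect_false(noise_filter(0.2, -0.01, 0.4))
  expect_true(noise_filter(theta - 1e-9, -(theta - 1e-9), 0.4))
  expect_false(noise_filter(theta + 1e-9, -(theta - 1e-9), 0.4))
  expect_error(noise_filter(0.1, 0.1, 0), class = "befstress_config_error")
})

test_that("a tuned fixture yields the designed number of noise exclusions", {
  gcv <- 0.4
  theta <- log(1 + 0.25 * gcv)
  set.seed(3)
  n <- 100
  a <- runif(n, theta * 1.5, 1)   # default: clearly outside the band
  b <- runif(n, theta * 1.5, 1)
  idx <- 1:12                     # 12 pairs inside the band, opposite signs
  a[idx] <- runif(12, 0, theta * 0.9)
  b[idx] <- -runif(12, 0, theta * 0.9)
  expect_equal(sum(noise_filter(a, b, gcv)), 12)
})

test_that("pair enumeration keeps pairs, skips triples and unpaired arms", {
  db <- generate_database(sim_config(n_studies = 30, seed = 8))
  eff <- add_effect_sizes(db$observations)
  pairs <- quiet(enumerate_pairs(eff, response = "function"))
  n_pairs_expected <- sum(eff$n_stressors == 2)
  expect_equal(nrow(pairs), n_pairs_expected)
  # triples logged as omitted
  omitted <- attr(pairs, "omitted")
  expect_equal(nrow(omitted$three_or_more), sum(eff$n_stressors == 3))

  # one study, single stressors only -> no pairs
  singles_only <- add_effect_sizes(dplyr::bind_rows(
    make_obs_row(arm = "A"), make_obs_row(arm = "B")
  ))
  expect_equal(nrow(enumerate_pairs(singles_only, "function")), 0)

  # joint arm lacking its single-stressor counterpart is skipped
  unpaired <- add_effect_sizes(dplyr::bind_rows(
    make_obs_row(arm = "A"),
    make_obs_row(arm = "A+B", stressor_ids = "A,B", n_stressors = 2L)
  ))
  expect_message(out <- enumerate_pairs(unpaired, "function"), "unpaired")
  expect_equal(nrow(out), 0)
})

test_that("noise-free data under the exact null classify 100% additive", {
  obs <- dplyr::bind_rows(
    make_null_study("S1", -0.4, -0.2),
    make_null_study("S2", 0.3, -0.5),
    make_null_study("S3", 0.6, 0.2)
  )
  eff <- add_effect_sizes(obs)
  cls <- classify_interactions(eff)
  fn <- cls$proportions[cls$proportions$response == "function", ]
  expect_equal(fn$proportion[fn$classification == "additive"], 1)
})

test_that("classification proportions are computed over non-excluded pairs", {
  obs <- dplyr::bind_rows(
    make_null_study("S1", -0.4, -0.2, delta = 0),
    make_null_study("S2", 0.5, 0.4, delta = log(3)),    # synergistic
    make_null_study("S3", -0.5, -0.4, delta = 0.9)      # antagonistic (flip)
  )
  eff <- add_effect_sizes(obs)
  cls <- classify_interactions(eff)
  fn <- cls$results[cls$results$response == "function", ]
  expect_equal(fn$classification[fn$study_id == "S2"], "synergistic")
  expect_equal(fn$classification[fn$study_id == "S3"], "antagonistic")
})

test_that("the MDR correlation matches cor.test and handles tiny n", {
  db <- generate_database(sim_config(n_studies = 40, seed = 12))
  eff <- add_effect_sizes(db$observations)
  cls <- quiet(classify_interactions(eff))
  out <- mdr_correlation(cls$results)
  expect_gte(out$n, 3)
  expect_lte(abs(out$r), 1)
  # identical vectors give r = 1
  fake <- cls$results
  fn <- fake$response == "function"
  rich <- fake$response == "richness"
  fake$mdr[fn] <- fake$mdr[rich][match(
    paste(fake$study_id, fake$stressor_i, fake$stressor_j)[fn],
    paste(fake$study_id, fake$stressor_i, fake$stressor_j)[rich])]
  out2 <- mdr_correlation(fake)
  expect_equal(out2$r, 1)
  # too few matched pairs is flagged undefined
  expect_warning(out3 <- mdr_correlation(cls$results[1:2, ]))
  expect_true(is.na(out3$r))
})

test_that("MDR moderator models report p-values per term and response", {
  db <- generate_database(sim_config(n_studies = 40, seed = 12))
  eff <- add_effect_sizes(db$observations)
  cls <- quiet(classify_interactions(eff))
  mods <- quiet(mdr_moderator_models(cls$results))
  expect_true(all(mods$p.value >= 0 & mods$p.value <= 1))
  expect_true(all(mods$term %in% c("organism_group", "stressor_combination",
                                   "function_type")))
  expect_setequal(unique(mods$response), c("richness", "function"))
})
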