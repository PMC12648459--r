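#' Cramér's V association between two categorical variables
#'
#' `V = sqrt(chi2 / (n * (min(r, c) - 1)))` from the contingency table,
#' without continuity correction.  Used to pre-screen moderator pairs for
#' collinearity before mixed-model fitting.
#'
#' @param x,y Vectors coercible to factors, same length.
#' @return A number in `[0, 1]`; `NA` with a warning for degenerate tables
#'   (fewer than two levels on either margin).
#' @export
#' @examples
#' cramers_v(c("a", "a", "b", "b"), c("x", "x", "y", "y"))  # 1
cramers_v <- function(x, y) {
  tab <- table(x, y)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    warn("degenerate contingency table: Cramer's V undefined")
    return(NA_real_)
  }
  chi2 <- suppressWarnings(chisq.test(tab, correct = FALSE))$statistic
  unname(sqrt(chi2 / (sum(tab) * (min(dim(tab)) - 1))))
}

#' Collinearity pre-screen over moderator pairs
#'
#' Computes Cramér's V for every pair of the given categorical moderators
#' and flags pairs above the threshold.  Flagged pairs are *reported*, not
#' dropped: nested factor pairs (e.g. organism group within function type)
#' legitimately exceed the threshold by construction, so action is left to
#' the analyst.
#'
#' @param data Data frame holding the moderators.
#' @param vars Character vector of moderator column names.
#' @param threshold Flagging threshold (default 0.7).
#' @return A tibble with `var1`, `var2`, `v`, `flagged`.
#' @export
cramers_v_screen <- function(data,
                             vars = c("organism_group", "function_type",
                                      "stressor_combination"),
                             threshold = 0.7) {
  vars <- intersect(vars, names(data))
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  purrr::map(pairs, function(p) {
    tibble(var1 = p[1], var2 = p[2],
           v = cramers_v(data[[p[1]]], data[[p[2]]]))
  }) |>
    bind_rows() |>
    mutate(flagged = !is.na(.data$v) & .data$v > threshold)
}

# Full fixed-effect term list of the BEF moderator model:
# LRR_EF ~ LRR_div + NS/SC + EF/TG + LRR_div x (NS + EF + NS/SC + EF/TG),
# with NS continuous, SC nested in NS and TG nested in EF.
bef_full_terms <- function(covariate_col) {
  c(covariate_col,
    "ns",
    "function_type",
    "ns:stressor_combination",
    "function_type:organism_group",
    paste0(covariate_col, ":ns"),
    paste0(covariate_col, ":function_type"),
    paste0(covariate_col, ":ns:stressor_combination"),
    paste0(covariate_col, ":function_type:organism_group"))
}

term_vars <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

# A term is removable under marginality iff no other retained term's
# variable set strictly contains its own.
removable_terms <- function(terms) {
  sets <- lapply(terms, term_vars)
  keep <- vapply(seq_along(terms), function(i) {
    !any(vapply(seq_along(terms), function(j) {
      j != i && all(sets[[i]] %in% sets[[j]])
    }, logical(1)))
  }, logical(1))
  terms[keep]
}

#' Assemble the model frame for the BEF mixed model
#'
#' Selects complete, non-excluded rows, renames the chosen diversity
#' covariate, coerces moderators to factors, and drops single-level
#' moderators (with their terms) rather than crashing on degenerate
#' designs.
#'
#' @param effects Effect-size table from [add_effect_sizes()].
#' @param covariate `"richness"` (default) or `"shannon"` — which diversity
#'   LRR moderates ecosystem function.
#' @return A list with `data`, `terms` (usable fixed-effect terms) and
#'   `covariate_col`.
#' @export
bef_model_data <- function(effects, covariate = c("richness", "shannon")) {
  covariate <- match.arg(covariate)
  cov_col <- switch(covariate, richness = "lrr_tr", shannon = "lrr_sd")
  if (!cov_col %in% names(effects))
    abort(sprintf("effect-size column `%s` not found", cov_col),
          class = "befstress_schema_error")
  dat <- effects |>
    mutate(ns = as.numeric(.data$n_stressors)) |>
    filter(is.finite(.data$lrr_ef), is.finite(.data[[cov_col]])) |>
    mutate(across(all_of(intersect(
      c("organism_group", "function_type", "stressor_combination"),
      names(effects))), factor))

  terms <- bef_full_terms(cov_col)
  for (f in c("organism_group", "function_type", "stressor_combination")) {
    if (!f %in% names(dat) || dplyr::n_distinct(dat[[f]]) < 2) {
      dropped <- terms[vapply(terms, function(t) f %in% term_vars(t),
                              logical(1))]
      if (length(dropped) > 0)
        warn(sprintf("moderator `%s` has < 2 levels; dropping term(s): %s",
                     f, paste(dropped, collapse = ", ")))
      terms <- setdiff(terms, dropped)
    }
  }
  list(data = dat, terms = terms, covariate_col = cov_col)
}

bef_formula <- function(terms) {
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  as.formula(paste("lrr_ef ~", rhs, "+ (1 | study_id)"))
}

#' Fit the BEF linear mixed-effects model
#'
#' Fits `lrr_ef` on the given fixed-effect terms with a random study
#' intercept, by REML (for reporting and Satterthwaite term tests) with an
#' ML refit attached (for deviance-based comparisons).  Optionally weighted
#' by inverse sampling variance of the function-response LRR.
#'
#' @param data Model frame from [bef_model_data()] (its `data` element), or
#'   any data frame with the required columns.
#' @param terms Character vector of fixed-effect terms (default: the full
#'   nested moderator structure for the richness covariate).
#' @param covariate_col Name of the diversity covariate column.
#' @param weights `NULL` (unweighted, the default) or
#'   `"inverse-variance"` to weight rows by `1 / var_ef`.
#' @param alpha Significance level used by selection and reporting.
#' @return An object of class `bef_lmm`: list with the REML `fit`, the `ml`
#'   refit, `terms`, `data`, and fit statistics (`n_obs`, `n_groups`,
#'   `r2_marginal`, `r2_conditional`, `tau2`, `sigma2`, `singular`).
#' @export
fit_bef_lmm <- function(data, terms = bef_full_terms("lrr_tr"),
                        covariate_col = "lrr_tr", weights = NULL,
                        alpha = 0.05) {
  fml <- bef_formula(terms)
  # predict()/model.frame() re-evaluate `w` later in the formula environment
  environment(fml) <- environment()
  w <- if (identical(weights, "inverse-variance")) {
    if (!"var_ef" %in% names(data))
      abort("inverse-variance weighting needs a `var_ef` column",
            class = "befstress_schema_error")
    1 / data$var_ef
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  fit <- lmerTest::lmer(fml, data = data, REML = TRUE, weights = w,
                        control = ctrl)
  ml <- lme4::lmer(fml, data = data, REML = FALSE, weights = w,
                   control = ctrl)
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[vc$grp == "study_id"]
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  r2 <- r2_nakagawa_components(fit, tau2, sigma2)
  structure(list(
    fit = fit, ml = ml, terms = terms, covariate_col = covariate_col,
    data = data, weights = weights, alpha = alpha,
    n_obs = stats::nobs(fit),
    n_groups = lme4::ngrps(fit)[["study_id"]],
    tau2 = tau2, sigma2 = sigma2,
    r2_marginal = r2[["r2_marginal"]],
    r2_conditional = r2[["r2_conditional"]],
    singular = lme4::isSingular(fit)
  ), class = "bef_lmm")
}

#' @export
print.bef_lmm <- function(x, ...) {
  cat("BEF linear mixed-effects model\n")
  cat(sprintf("  fixed terms: %s\n", paste(x$terms, collapse = " + ")))
  cat(sprintf("  n = %d observations, %d study groups\n", x$n_obs, x$n_groups))
  cat(sprintf("  tau2 (study) = %.4f, sigma2 = %.4f\n", x$tau2, x$sigma2))
  cat(sprintf("  marginal R2 = %.3f, conditional R2 = %.3f\n",
              x$r2_marginal, x$r2_conditional))
  if (x$singular) cat("  (singular random-effect fit)\n")
  invisible(x)
}

r2_nakagawa_components <- function(fit, tau2, sigma2) {
  var_fixed <- var(stats::predict(fit, re.form = NA))
  denom <- var_fixed + tau2 + sigma2
  c(r2_marginal = var_fixed / denom,
    r2_conditional = (var_fixed + tau2) / denom)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-partition R²: the marginal form is the share of total variance
#' (fixed + random + residual) explained by the fixed effects alone,
#' `var(X b) / (var(X b) + tau2 + sigma2)`; the conditional form adds the
#' random study intercept variance to the numerator.
#'
#' @param object A `bef_lmm` fit.
#' @return Named numeric vector `c(r2_marginal, r2_conditional)`.
#' @export
r2_nakagawa <- function(object) {
  stopifnot(inherits(object, "bef_lmm"))
  c(r2_marginal = object$r2_marginal, r2_conditional = object$r2_conditional)
}

# Likelihood-ratio p-value for removing `term` from the ML fit.
# Same variables up to order: "a:b" and "b:a" name the same term.
same_term <- function(a, b) {
  va <- sort(term_vars(a))
  vapply(b, function(x) identical(va, sort(term_vars(x))), logical(1))
}

#' Per-term significance tests for removable terms
#'
#' Tests each fixed-effect term that may be removed without violating
#' marginality (i.e. not contained in a retained higher-order term), using
#' type-II F tests with Satterthwaite denominator degrees of freedom on the
#' REML fit.  The F approximation keeps the tests calibrated at the modest
#' per-study sample sizes typical of this design, where large-sample
#' chi-square likelihood-ratio tests are anticonservative.  Terms whose
#' design columns are entirely aliased (rank deficiency) contribute nothing
#' and are reported with p = 1.
#'
#' @param object A `bef_lmm` fit.
#' @return A tibble with `term`, `statistic` (F), `df`, `den_df`,
#'   `p.value`.
#' @export
term_pvalues <- function(object) {
  stopifnot(inherits(object, "bef_lmm"))
  cand <- removable_terms(object$terms)
  if (length(cand) == 0)
    return(tibble(term = character(), statistic = double(), df = double(),
                  den_df = double(), p.value = double()))
  a <- suppressWarnings(suppressMessages(
    stats::anova(object$fit, type = 2, ddf = "Satterthwaite")))
  rows <- rownames(a)
  purrr::map(cand, function(t) {
    i <- which(same_term(t, rows))
    if (length(i) == 0 || is.na(a[i, "Pr(>F)"]))
      return(tibble(term = t, statistic = 0, df = 0, den_df = NA_real_,
                    p.value = 1))
    tibble(term = t, statistic = a[i, "F value"], df = a[i, "NumDF"],
           den_df = a[i, "DenDF"], p.value = a[i, "Pr(>F)"])
  }) |> bind_rows()
}

#' Backward selection with marginality constraints
#'
#' Starting from the full nested moderator model, iteratively removes the
#' least significant removable term whose [term_pvalues()] p-value exceeds
#' `alpha`.  A term is removable only if no retained higher-order term
#' contains it, so main effects of retained interactions and nesting
#' parents of retained nested terms are never dropped.  Ties are broken by
#' the larger p-value, then by later position in the term list.  The
#' procedure is deterministic; every removal is logged.
#'
#' @param data Model frame (the `data` element of [bef_model_data()]).
#' @param terms Starting term list (default: full structure for `lrr_tr`).
#' @param covariate_col Diversity covariate column name.
#' @param alpha Removal threshold on the LRT p-value (default 0.05).
#' @param weights As in [fit_bef_lmm()].
#' @return A list of class `bef_selection`: `fit` (final REML `bef_lmm`),
#'   `terms`, and `trail` (tibble of dropped terms in order with their
#'   p-values).
#' @export
backward_select <- function(data, terms = bef_full_terms("lrr_tr"),
                            covariate_col = "lrr_tr", alpha = 0.05,
                            weights = NULL) {
  trail <- list()
  current <- terms
  repeat {
    fit <- fit_bef_lmm(data, current, covariate_col, weights = weights,
                       alpha = alpha)
    pv <- term_pvalues(fit)
    drop_cand <- pv |> filter(.data$p.value > alpha)
    if (nrow(drop_cand) == 0) break
    drop_cand <- drop_cand |>
      mutate(pos = match(.data$term, current)) |>
      arrange(dplyr::desc(.data$p.value), dplyr::desc(.data$pos))
    dropped <- drop_cand$term[1]
    trail[[length(trail) + 1]] <- tibble(
      step = length(trail) + 1L, term = dropped,
      p.value = drop_cand$p.value[1]
    )
    current <- setdiff(current, dropped)
  }
  structure(list(
    fit = fit, terms = current,
    trail = if (length(trail)) bind_rows(trail) else
      tibble(step = integer(), term = character(), p.value = double())
  ), class = "bef_selection")
}

#' @export
print.bef_selection <- function(x, ...) {
  cat("Backward-selected BEF model\n")
  if (nrow(x$trail) > 0) {
    cat("  dropped:", paste(sprintf("%s (p=%.3f)", x$trail$term,
                                    x$trail$p.value), collapse = ", "), "\n")
  } else cat("  no terms dropped\n")
  cat("  retained:", paste(x$terms, collapse = " + "), "\n")
  print(x$fit)
  invisible(x)
}

# Refit a bef_lmm on a subset of studies, keeping the term structure.
refit_without_studies <- function(object, studies) {
  dat <- filter(object$data, !.data$study_id %in% studies)
  fit_bef_lmm(dat, object$terms, object$covariate_col,
              weights = object$weights, alpha = object$alpha)
}

#' Study-level Cook's distance by exact deletion refits
#'
#' For each study j the model is refit without it and
#' `D_j = (b - b_(-j))' V(b)^{-1} (b - b_(-j)) / p` computed on the
#' coefficients shared between the two fits (levels can vanish with a
#' study; such studies are flagged).  Studies with `D` above the threshold
#' are conventionally treated as disproportionately influential.
#'
#' @param object A `bef_lmm` fit.
#' @param threshold Influence threshold (default 0.5).
#' @return A tibble with `study_id`, `cooks_d`, `n_obs`, `influential`,
#'   `flagged` (refit problem).  Attribute `"threshold"` records the cutoff.
#' @export
cooks_distance_by_study <- function(object, threshold = 0.5) {
  stopifnot(inherits(object, "bef_lmm"))
  beta <- lme4::fixef(object$fit)
  V <- as.matrix(vcov(object$fit))
  p <- length(beta)
  studies <- unique(object$data$study_id)
  out <- purrr::map(studies, function(s) {
    res <- tryCatch({
      ref <- refit_without_studies(object, s)
      beta_j <- lme4::fixef(ref$fit)
      common <- intersect(names(beta), names(beta_j))
      d <- beta[common] - beta_j[common]
      Vi <- V[common, common, drop = FALSE]
      list(d = drop(t(d) %*% solve(Vi, d)) / p,
           flagged = length(common) < p)
    }, error = function(e) list(d = NA_real_, flagged = TRUE))
    tibble(study_id = s,
           cooks_d = res$d,
           n_obs = sum(object$data$study_id == s),
           influential = !is.na(res$d) & res$d > threshold,
           flagged = res$flagged)
  }) |> bind_rows()
  attr(out, "threshold") <- threshold
  out
}

#' Leave-one-study-out cross-validation
#'
#' Refits the model once per held-out study and summarises the stability of
#' the diversity-covariate slope and the covariate-by-stressor-number
#' interaction: sign agreement with the full fit and the range of held-out
#' estimates.
#'
#' @param object A `bef_lmm` fit.
#' @return A list with `coefficients` (long tibble: held-out study x term
#'   x estimate/SE) and `summary` (per key term: sign stability fraction,
#'   min/max estimate).
#' @export
loso_cv <- function(object) {
  stopifnot(inherits(object, "bef_lmm"))
  studies <- unique(object$data$study_id)
  if (length(studies) < 3)
    abort("leave-one-study-out needs at least 3 studies",
          class = "befstress_config_error")
  coefs <- purrr::map(studies, function(s) {
    ref <- refit_without_studies(object, s)
    est <- lme4::fixef(ref$fit)
    se <- sqrt(diag(as.matrix(vcov(ref$fit))))
    tibble(held_out = s, term = names(est), estimate = unname(est),
           std.error = unname(se))
  }) |> bind_rows()

  full <- lme4::fixef(object$fit)
  key <- intersect(c(object$covariate_col,
                     paste0(object$covariate_col, ":ns")),
                   names(full))
  summary <- purrr::map(key, function(k) {
    est <- coefs$estimate[coefs$term == k]
    tibble(term = k, full_estimate = unname(full[k]),
           sign_stability = mean(sign(est) == sign(full[k])),
           min = min(est), max = max(est))
  }) |> bind_rows()
  list(coefficients = coefs, summary = summary)
}

#' Predicted BEF relationship over a diversity-by-stressor-number grid
#'
#' The marginal-effect quantity behind the headline figure: predicted
#' function LRR over a grid of diversity LRR values at 1-3 stressors,
#' holding categorical moderators at their most frequent level (chosen per
#' stressor number for the nested stressor combination) and using fixed
#' effects only.
#'
#' @param object A `bef_lmm` fit.
#' @param lrr_values Grid of diversity-covariate values (default: 25 points
#'   over the observed range).
#' @param ns_values Stressor numbers to predict at (default `1:3`).
#' @return A tibble with `ns`, the covariate grid, and `predicted`.
#' @export
marginal_effects_grid <- function(object, lrr_values = NULL,
                                  ns_values = 1:3) {
  stopifnot(inherits(object, "bef_lmm"))
  dat <- object$data
  cov_col <- object$covariate_col
  lrr_values <- lrr_values %||%
    seq(min(dat[[cov_col]]), max(dat[[cov_col]]), length.out = 25)
  ns_values <- intersect(ns_values, unique(dat$ns))

  modal <- function(x) names(sort(table(x), decreasing = TRUE))[1]
  grid <- purrr::map(ns_values, function(k) {
    sub <- filter(dat, .data$ns == k)
    g <- tidyr::expand_grid(ns = k, value = lrr_values)
    for (f in c("organism_group", "function_type", "stressor_combination")) {
      if (f %in% names(dat))
        g[[f]] <- factor(modal(sub[[f]]), levels = levels(dat[[f]]))
    }
    g
  }) |> bind_rows()
  grid[[cov_col]] <- grid$value
  grid$predicted <- stats::predict(object$fit, newdata = grid, re.form = NA)
  select(grid, "ns", all_of(cov_col), "predicted",
         dplyr::any_of(c("organism_group", "function_type",
                         "stressor_combination")))
}
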