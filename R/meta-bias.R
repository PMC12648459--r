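#' Three-level random-effects meta-analysis
#'
#' Fits `y_ij = mu + u_j + w_ij + e_ij` by REML, with a between-study
#' component `u_j`, a within-study component `w_ij` (multiple effect sizes
#' per study) and known sampling variances `Var(e_ij) = v_ij`.  The
#' heterogeneity statistic Q is the weighted residual sum of squares about
#' the fixed-effect pooled mean with weights `1 / v_ij` (df = k - 1).
#'
#' @param effects Numeric vector of (bias-corrected) log response ratios.
#' @param variances Their sampling variances (> 0; rows with missing or
#'   non-positive variance are excluded with a message).
#' @param study_ids Study grouping vector.
#' @param force_within_zero Constrain the within-study component to zero,
#'   which collapses the model to the classical two-level random-effects
#'   model (used for equivalence checks).
#' @return An object of class `bef_three_level`: pooled effect `mu` and
#'   `se`, `tau2_between`, `tau2_within`, `Q`, `df`, `p_q`, multilevel
#'   `i2_between` / `i2_within` (percent), `k`, `n_studies`, `n_dropped`,
#'   and the underlying `metafor::rma.mv` fit as `$fit`.
#' @export
fit_three_level <- function(effects, variances, study_ids,
                            force_within_zero = FALSE) {
  ok <- is.finite(effects) & is.finite(variances) & variances > 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    inform(sprintf("%d effect(s) without a positive sampling variance excluded",
                   n_dropped))
  y <- effects[ok]; v <- variances[ok]; sid <- as.character(study_ids[ok])
  if (dplyr::n_distinct(sid) < 2)
    abort("three-level model needs at least 2 studies",
          class = "befstress_config_error")
  dat <- tibble(y = y, v = v, study = sid, es = seq_along(y))
  sigma2 <- if (force_within_zero) c(NA, 0) else c(NA, NA)
  fit <- tryCatch(
    metafor::rma.mv(y, v, random = ~ 1 | study / es, data = dat,
                    sigma2 = sigma2, method = "REML"),
    error = function(e) {
      warn(paste0("REML fit failed (", conditionMessage(e),
                  "); retrying with optim"))
      metafor::rma.mv(y, v, random = ~ 1 | study / es, data = dat,
                      sigma2 = sigma2, method = "REML",
                      control = list(optimizer = "optim"))
    }
  )
  tau2_between <- fit$sigma2[1]
  tau2_within <- fit$sigma2[2]
  i2 <- i2_multilevel(tau2_between, tau2_within, v)
  structure(list(
    mu = unname(fit$beta[1, 1]), se = fit$se,
    tau2_between = tau2_between, tau2_within = tau2_within,
    Q = unname(fit$QE), df = fit$k - 1, p_q = fit$QEp,
    i2_between = i2[["i2_between"]], i2_within = i2[["i2_within"]],
    k = fit$k, n_studies = dplyr::n_distinct(sid), n_dropped = n_dropped,
    method = "REML", fit = fit
  ), class = "bef_three_level")
}

#' @export
print.bef_three_level <- function(x, ...) {
  cat("Three-level random-effects meta-analysis (REML)\n")
  cat(sprintf("  pooled effect: %.4f (SE %.4f), k = %d effects, %d studies\n",
              x$mu, x$se, x$k, x$n_studies))
  cat(sprintf("  tau2 between = %.4f, within = %.4f\n",
              x$tau2_between, x$tau2_within))
  cat(sprintf("  I2 between = %.1f%%, within = %.1f%%\n",
              x$i2_between, x$i2_within))
  cat(sprintf("  Q = %.1f (df = %d), p %s\n", x$Q, x$df,
              format.pval(x$p_q, eps = 1e-4)))
  invisible(x)
}

#' Multilevel I-squared
#'
#' Partitions total effect-size variability into between-study,
#' within-study and sampling-error shares.  The sampling-error term is the
#' typical sampling variance
#' `v_typ = (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))` with `w = 1 / v`, and
#' each level's I² is `100 * tau2_level / (tau2_between + tau2_within +
#' v_typ)`; the two levels therefore sum to at most 100.
#'
#' @param tau2_between,tau2_within Variance components (or a
#'   `bef_three_level` object as first argument).
#' @param variances Known sampling variances of the effects.
#' @return Named numeric `c(i2_between, i2_within)` in percent.
#' @export
i2_multilevel <- function(tau2_between, tau2_within = NULL, variances = NULL) {
  if (inherits(tau2_between, "bef_three_level")) {
    obj <- tau2_between
    return(i2_multilevel(obj$tau2_between, obj$tau2_within, obj$fit$vi))
  }
  w <- 1 / variances
  k <- length(w)
  v_typ <- (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))
  denom <- tau2_between + tau2_within + v_typ
  c(i2_between = 100 * tau2_between / denom,
    i2_within = 100 * tau2_within / denom)
}

#' Egger's regression test for funnel asymmetry
#'
#' Tests whether effect sizes are associated with their own precision —
#' the signature of small-study / publication bias.  The default
#' `"multilevel"` form adds the sampling standard error as a moderator to
#' the three-level model and reports its coefficient; the `"classical"`
#' form is the conventional two-level weighted regression, available for
#' cross-checking.  Fewer than 10 effects trigger a warning (the test has
#' little power there) but the statistic is still computed; effects without
#' a positive sampling variance are excluded with a message.
#'
#' @inheritParams fit_three_level
#' @param method `"multilevel"` (default) or `"classical"`.
#' @return A list with `estimate` (SE-moderator slope), `se`, `p`,
#'   `method`, and `funnel` — a tibble of (effect, se) pairs with the
#'   pooled effect for reference lines.
#' @export
eggers_test <- function(effects, variances, study_ids,
                        method = c("multilevel", "classical")) {
  method <- match.arg(method)
  ok <- is.finite(effects) & is.finite(variances) & variances > 0
  if (sum(ok) < 3)
    abort("Egger's test needs at least 3 effects with positive sampling variance",
          class = "befstress_config_error")
  if (any(!ok))
    inform(sprintf(
      "%d effect(s) without a positive sampling variance excluded from Egger's test",
      sum(!ok)))
  y <- effects[ok]; v <- variances[ok]; sid <- as.character(study_ids[ok])
  if (length(y) < 10)
    warn("fewer than 10 effects: Egger's test has little power")
  sei <- sqrt(v)
  dat <- tibble(y = y, v = v, sei = sei, study = sid, es = seq_along(y))
  fit <- if (method == "multilevel") {
    metafor::rma.mv(y, v, mods = ~ sei, random = ~ 1 | study / es,
                    data = dat, method = "REML")
  } else {
    metafor::rma(y, v, mods = ~ sei, data = dat, method = "REML")
  }
  pooled <- fit_three_level(y, v, sid)
  list(
    estimate = unname(fit$beta["sei", 1]),
    se = fit$se[2],
    p = fit$pval[2],
    method = method,
    funnel = tibble(effect = y, se = sei, study_id = sid,
                    pooled_effect = pooled$mu)
  )
}

#' Run all meta-analytic diagnostics for one response
#'
#' Three-level fit, multilevel I², Q, funnel data and Egger's test for the
#' chosen response's effect sizes.
#'
#' @param effects Effect-size table from [add_effect_sizes()].
#' @param response `"richness"` or `"function"`.
#' @param egger_method Passed to [eggers_test()].
#' @return A list with `fit` (`bef_three_level`) and `egger`.
#' @export
meta_bias_diagnostics <- function(effects, response = c("richness", "function"),
                                  egger_method = "multilevel") {
  response <- match.arg(response)
  tag <- switch(response, richness = "tr", `function` = "ef")
  y <- effects[[paste0("lrr_", tag)]]
  v <- effects[[paste0("var_", tag)]]
  list(
    response = response,
    fit = fit_three_level(y, v, effects$study_id),
    egger = eggers_test(y, v, effects$study_id, method = egger_method)
  )
}
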