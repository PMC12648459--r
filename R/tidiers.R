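#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a BEF mixed-model fit
#'
#' @param x A `bef_lmm` object.
#' @param ... Unused.
#' @return One row per fixed-effect coefficient: `term`, `estimate`,
#'   `std.error`, `statistic` (t), `df` (Satterthwaite) and `p.value`
#'   where available.
#' @export
tidy.bef_lmm <- function(x, ...) {
  cf <- coef(summary(x$fit))
  out <- tibble(term = rownames(cf), estimate = unname(cf[, "Estimate"]),
                std.error = unname(cf[, "Std. Error"]))
  if ("df" %in% colnames(cf)) {
    out$statistic <- unname(cf[, "t value"])
    out$df <- unname(cf[, "df"])
    out$p.value <- unname(cf[, "Pr(>|t|)"])
  } else {
    out$statistic <- out$estimate / out$std.error
  }
  out
}

#' Model-level summary of a BEF mixed-model fit
#'
#' @param x A `bef_lmm` object.
#' @param ... Unused.
#' @return A one-row tibble with sample sizes, variance components,
#'   R-squareds and log-likelihoods.
#' @export
glance.bef_lmm <- function(x, ...) {
  tibble(
    n_obs = x$n_obs, n_groups = x$n_groups,
    tau2_study = x$tau2, sigma2 = x$sigma2,
    r2_marginal = x$r2_marginal, r2_conditional = x$r2_conditional,
    logLik_reml = as.numeric(logLik(x$fit)),
    logLik_ml = as.numeric(logLik(x$ml)),
    singular = x$singular
  )
}

#' Tidy a backward-selection result
#'
#' @param x A `bef_selection` object.
#' @param ... Unused.
#' @return The selection trail: one row per dropped term in drop order.
#' @export
tidy.bef_selection <- function(x, ...) x$trail

#' @rdname tidy.bef_selection
#' @export
glance.bef_selection <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n_terms_retained = length(x$terms),
           n_terms_dropped = nrow(x$trail)),
    glance(x$fit)
  )
}

#' Tidy a three-level meta-analysis fit
#'
#' @param x A `bef_three_level` object.
#' @param ... Unused.
#' @return Rows for the pooled effect and the two variance components.
#' @export
tidy.bef_three_level <- function(x, ...) {
  tibble(
    term = c("pooled_effect", "tau2_between", "tau2_within"),
    estimate = c(x$mu, x$tau2_between, x$tau2_within),
    std.error = c(x$se, NA_real_, NA_real_)
  )
}

#' @rdname tidy.bef_three_level
#' @export
glance.bef_three_level <- function(x, ...) {
  tibble(k = x$k, n_studies = x$n_studies, Q = x$Q, df = x$df, p_q = x$p_q,
         i2_between = x$i2_between, i2_within = x$i2_within)
}
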