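#' Funnel-plot data from a fitted meta-regression
#'
#' Returns, for every row used in the fit, the fixed-effect (marginal)
#' residual `zr_i - x_i' beta` and the precision `1 / sqrt(v_z)`.  Plotting
#' residuals from the full meta-regression rather than raw effects removes
#' heterogeneity due to moderators and phylogeny that could otherwise mimic
#' funnel asymmetry.  Conditional residuals (subtracting the best linear
#' unbiased predictions of the random effects as well) are available with
#' `conditional = TRUE`.
#'
#' @param fit A `"zr_fit"`.
#' @param conditional Subtract BLUPs of the random effects too.
#' @return A tibble with `estimate_id`, `residual`, `precision`, `zr`, `v_z`.
#' @export
funnel_points <- function(fit, conditional = FALSE) {
  d <- fit$design
  resid <- unname(d$y - drop(d$X %*% fit$beta))
  if (conditional) {
    # BLUP of the combined random effect: G V^-1 r with G the random-effect
    # part of the marginal covariance
    V <- marginal_covariance(fit$sigma2[fit$random], d$study, d$estimate, d$v,
                             row_corr = fit$row_corr, species = d$species)
    G <- V - diag(d$v, length(d$v))
    blup <- drop(G %*% solve(V, resid))
    resid <- resid - blup
  }
  tibble::tibble(
    estimate_id = d$estimate,
    residual = resid,
    precision = 1 / sqrt(d$v),
    zr = d$y,
    v_z = d$v
  )
}

# Shared machinery for the two continuous-moderator bias tests: fits the
# multilevel model with a single continuous moderator and returns its slope.
bias_slope_test <- function(effects, column, kind, random, phylo_corr,
                            method, references) {
  fit <- fit_zr(effects, moderators = column, random = random,
                phylo_corr = phylo_corr, method = method,
                references = references)
  co <- tidy(fit)
  row <- co[co$term == column, ]
  structure(list(
    slope = row$estimate, se = row$std_error, z = row$statistic,
    p_value = row$p_value, moderator_kind = kind, random = random,
    method = fit$method, fit = fit
  ), class = "zr_bias_test")
}

#' @export
print.zr_bias_test <- function(x, ...) {
  cat(sprintf("%s bias test: slope = %.4g (SE %.3g), z = %.3f, p = %.4g\n",
              x$moderator_kind, x$slope, x$se, x$z, x$p_value))
  invisible(x)
}

#' @export
tidy.zr_bias_test <- function(x, ...) {
  tibble::tibble(moderator_kind = x$moderator_kind, slope = x$slope,
                 se = x$se, z = x$z, p_value = x$p_value)
}

#' Modified Egger's regression test for publication bias
#'
#' Fits the multilevel model with the sampling variance `v_z` as the only
#' moderator (same random structure as the corresponding main model) and
#' tests its slope with a Wald z test.  A positive slope indicates that
#' less precise effects are systematically larger — the small-study signature
#' of publication bias.  `moderator = "se"` uses the standard error instead
#' of the variance, for sensitivity analysis.
#'
#' @param effects Tibble of standardised effects.
#' @param random,phylo_corr,references Passed to [fit_zr()].
#' @param method Estimation method; defaults to ML, as for the moderated
#'   main models.
#' @param moderator `"sampling_variance"` (default) or `"se"`.
#' @return A `"zr_bias_test"` with `slope`, `se`, `z`, `p_value` and the
#'   underlying fit.
#' @export
eggers_test <- function(effects, random = c("study", "estimate"),
                        phylo_corr = NULL, references = NULL, method = "ML",
                        moderator = c("sampling_variance", "se")) {
  moderator <- match.arg(moderator)
  if (nrow(effects) < 3 || length(unique(effects$v_z)) < 2) {
    tm_abort("Egger's test needs >= 3 effects with distinct sampling variances.",
             "tm_error_schema")
  }
  effects <- dplyr::mutate(
    effects,
    .bias_mod = if (moderator == "sampling_variance") .data$v_z else sqrt(.data$v_z)
  )
  bias_slope_test(effects, ".bias_mod", moderator, random, phylo_corr,
                  method, references)
}

#' Time-lag bias test
#'
#' Fits the multilevel model with mean-centred publication year as the only
#' moderator and tests its slope: a systematic drift of reported effect sizes
#' over time (effects typically shrinking as a field matures) shows up as a
#' nonzero slope.  Centring the year only shifts the intercept, never the
#' slope.
#'
#' @inheritParams eggers_test
#' @return A `"zr_bias_test"`.
#' @export
timelag_test <- function(effects, random = c("study", "estimate"),
                         phylo_corr = NULL, references = NULL, method = "ML") {
  if (length(unique(effects$year)) < 2) {
    tm_abort("Time-lag test needs >= 2 distinct publication years.",
             "tm_error_schema")
  }
  effects <- dplyr::mutate(effects,
                           .year_c = .data$year - mean(.data$year))
  bias_slope_test(effects, ".year_c", "centred_year", random, phylo_corr,
                  method, references)
}
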