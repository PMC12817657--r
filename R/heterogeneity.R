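#' Typical sampling-error variance
#'
#' Summarises the per-effect sampling variances into the "typical"
#' within-study variance used in the I-squared denominator:
#' `sigma2_m = (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))` with weights
#' `w_j = 1 / v_j` and `k` the number of effect sizes.  For equal sampling
#' variances the expression collapses exactly to the common variance.
#'
#' @param v Numeric vector of sampling variances (all > 0, length >= 2).
#' @return The typical sampling variance (scalar).
#' @examples
#' typical_sampling_variance(c(1, 4)) # 2.5
#' typical_sampling_variance(rep(0.02, 10)) # 0.02
#' @export
typical_sampling_variance <- function(v) {
  if (length(v) < 2) tm_abort("Need at least 2 sampling variances.", "tm_error_schema")
  if (any(v <= 0)) tm_abort("Sampling variances must be positive.", "tm_error_domain")
  w <- 1 / v
  k <- length(v)
  (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))
}

#' I-squared heterogeneity decomposition of a fitted model
#'
#' Decomposes the total variance of a multilevel meta-analytic model into its
#' components.  The total variance is `sigma2_t = sigma2_study +
#' sigma2_estimate + sigma2_species + sigma2_phylo + sigma2_m` where
#' `sigma2_m` is the typical sampling variance of the effects used in the
#' fit.  Total heterogeneity is `I2_total = (sigma2_t - sigma2_m) / sigma2_t`,
#' each component's share is `sigma2_component / sigma2_t`, and the residual
#' share `sigma2_m / sigma2_t` completes the decomposition
#' (`I2_total + I2_residual = 1`).
#'
#' @param fit A converged `"zr_fit"`.
#' @return An object of class `"zr_heterogeneity"`: a list with `sigma2_m`,
#'   `sigma2_t`, `i2_total`, `i2_residual`, `i2_by_component` (named vector
#'   over the fit's random terms), `weights`, and `k`; `as_tibble()`/`tidy()`
#'   give a long-format table.
#' @examples
#' sim <- simulate_dataset(sim_config(n_studies = 10, seed = 1))
#' het <- heterogeneity(fit_zr(sim$effects))
#' het$i2_total
#' @export
heterogeneity <- function(fit) {
  stopifnot(inherits(fit, "zr_fit"))
  v <- fit$design$v
  sigma2_m <- typical_sampling_variance(v)
  comps <- fit$sigma2[fit$random]
  sigma2_t <- sum(comps) + sigma2_m
  if (sigma2_t <= 0) tm_abort("Total variance is zero.", "tm_error_domain")
  structure(list(
    sigma2_m = sigma2_m,
    sigma2_t = sigma2_t,
    i2_total = sum(comps) / sigma2_t,
    i2_residual = sigma2_m / sigma2_t,
    i2_by_component = comps / sigma2_t,
    weights = 1 / v,
    k = length(v)
  ), class = "zr_heterogeneity")
}

#' @export
print.zr_heterogeneity <- function(x, ...) {
  cat(sprintf("I2 total: %.3f  (residual %.3f), sigma2_m = %.5f, k = %d\n",
              x$i2_total, x$i2_residual, x$sigma2_m, x$k))
  cat("Component shares:\n")
  print(round(x$i2_by_component, 4))
  invisible(x)
}

#' @export
tidy.zr_heterogeneity <- function(x, ...) {
  tibble::tibble(
    component = c(names(x$i2_by_component), "residual", "total"),
    sigma2 = c(x$i2_by_component * x$sigma2_t, x$sigma2_m, x$sigma2_t),
    i2 = c(x$i2_by_component, x$i2_residual, x$i2_total)
  )
}

#' Marginal R-squared of a moderator
#'
#' Quantifies the share of total variance explained by one moderator.  In the
#' default `"single"` strategy a model containing only that moderator (with
#' the same random structure and estimation method) is fitted and
#' `R2 = var(X beta) / (var(X beta) + sum(sigma2) + sigma2_m)`, where
#' `var(X beta)` is the variance of the fixed-effect fitted values.  The
#' `"leave_one_out"` strategy instead reports the drop in marginal R-squared
#' when the term is removed from the full model.  A companion variant that
#' omits `sigma2_m` from the denominator is returned alongside for
#' comparability with tools that define R-squared without the sampling
#' variance.
#'
#' @param effects Tibble of standardised effects.
#' @param moderator Term to evaluate: a moderator name or an interaction
#'   `"a:b"`.
#' @param random,phylo_corr,references,method As in [fit_zr()] (method
#'   defaults to ML, the convention for moderated models).
#' @param strategy `"single"` (default) or `"leave_one_out"`.
#' @param full_moderators,full_interactions For `"leave_one_out"`, the full
#'   model's terms.
#' @return A one-row tibble with `moderator`, `r2_marginal` (denominator
#'   includes `sigma2_m`), and `r2_no_sampling` (denominator without it).
#' @export
marginal_r2 <- function(effects, moderator, random = c("study", "estimate"),
                        phylo_corr = NULL, references = NULL, method = "ML",
                        strategy = c("single", "leave_one_out"),
                        full_moderators = NULL, full_interactions = NULL) {
  strategy <- match.arg(strategy)
  r2_of_fit <- function(fit) {
    fitted_fix <- drop(fit$design$X %*% fit$beta)
    var_fix <- var(fitted_fix)
    s2 <- sum(fit$sigma2[fit$random])
    s2m <- typical_sampling_variance(fit$design$v)
    c(with = var_fix / (var_fix + s2 + s2m),
      without = var_fix / (var_fix + s2))
  }
  split_term <- function(term) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (length(parts) > 1) {
      list(moderators = parts, interactions = term)
    } else {
      list(moderators = parts, interactions = NULL)
    }
  }
  if (strategy == "single") {
    tm <- split_term(moderator)
    fit <- fit_zr(effects, moderators = tm$moderators,
                  interactions = tm$interactions, random = random,
                  phylo_corr = phylo_corr, method = method,
                  references = references)
    r2 <- r2_of_fit(fit)
  } else {
    full <- fit_zr(effects, moderators = full_moderators,
                   interactions = full_interactions, random = random,
                   phylo_corr = phylo_corr, method = method,
                   references = references)
    reduced <- fit_zr(
      effects,
      moderators = setdiff(full_moderators, split_term(moderator)$moderators),
      interactions = setdiff(full_interactions %||% character(0), moderator),
      random = random, phylo_corr = phylo_corr, method = method,
      references = references
    )
    r2 <- pmax(r2_of_fit(full) - r2_of_fit(reduced), 0)
  }
  tibble::tibble(moderator = moderator,
                 r2_marginal = unname(r2["with"]),
                 r2_no_sampling = unname(r2["without"]))
}
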