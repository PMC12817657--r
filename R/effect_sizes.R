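#' Standard error from a reported 95% confidence interval
#'
#' Recovers the standard error of an estimate from its upper 95% confidence
#' bound as `(ci_upper - estimate) / 1.96`, the standard normal-interval
#' back-calculation used when primary studies report confidence intervals
#' instead of standard errors.
#'
#' @param estimate Numeric vector of point estimates.
#' @param ci_upper Numeric vector of upper 95% confidence bounds.
#' @return Numeric vector of standard errors (strictly positive).
#' @examples
#' se_from_ci(0.095, 0.124) # ~0.015
#' @export
se_from_ci <- function(estimate, ci_upper) {
  if (any(!is.finite(estimate)) || any(!is.finite(ci_upper))) {
    tm_abort("`estimate` and `ci_upper` must be finite.", "tm_error_domain")
  }
  if (any(ci_upper <= estimate)) {
    tm_abort(
      "Upper confidence bound must exceed the estimate (inverted or degenerate interval).",
      "tm_error_interval"
    )
  }
  (ci_upper - estimate) / 1.96
}

#' Correlation coefficient from a regression t statistic
#'
#' Converts a t statistic and its residual degrees of freedom into a
#' correlation coefficient, `r = t / sqrt(t^2 + df)`.  The function is odd in
#' `t` and its magnitude is strictly below 1 for finite `t`.
#'
#' @param t_value Numeric vector of t statistics.
#' @param df Integer vector of residual degrees of freedom (>= 1).
#' @return Numeric vector of correlations in (-1, 1).
#' @examples
#' t_to_r(2, 96) # 0.2
#' @export
t_to_r <- function(t_value, df) {
  if (any(!is.finite(df)) || any(df < 1)) {
    tm_abort("Degrees of freedom must be >= 1.", "tm_error_domain")
  }
  t_value / sqrt(t_value^2 + df)
}

#' Small-sample bias adjustment of a correlation coefficient
#'
#' Adjusts an observed correlation toward the population correlation using the
#' approximate correction `rho = r + r (1 - r^2) / (2 (n - 4))`, which inflates
#' the skewed sampling distribution of `r` back toward its population value.
#' The denominator reading `2(n - 4)` follows the Olkin-Pratt-style
#' approximation; the alternative literal reading `2n - 4` is available via
#' `reading`.
#'
#' Because the correction can overshoot for extreme `r` and very small `n`,
#' any adjusted value with magnitude >= 1 is clamped to `+/-(1 - 1e-10)` with a
#' warning.
#'
#' @param r Numeric vector of correlations, |r| < 1.
#' @param n Integer vector of sample sizes.  Must be > 4 under the default
#'   reading (the denominator vanishes at n = 4); set `small_n = "passthrough"`
#'   to return `rho = r` unadjusted (with a warning) for such rows.
#' @param reading Which algebraic reading of the denominator to use:
#'   `"2(n-4)"` (default) or `"2n-4"`.
#' @param small_n `"error"` (default) or `"passthrough"` for n <= 4 under the
#'   default reading.
#' @return Numeric vector of adjusted correlations in (-1, 1).
#' @examples
#' r_to_rho(0.5, 54) # 0.50375
#' @export
r_to_rho <- function(r, n, reading = c("2(n-4)", "2n-4"),
                     small_n = c("error", "passthrough")) {
  reading <- match.arg(reading)
  small_n <- match.arg(small_n)
  if (any(abs(r) >= 1)) {
    tm_abort("Correlations must satisfy |r| < 1.", "tm_error_domain")
  }
  denom <- if (reading == "2(n-4)") 2 * (n - 4) else 2 * n - 4
  bad <- denom <= 0
  if (any(bad)) {
    if (small_n == "error") {
      tm_abort(
        sprintf(
          "Sample size too small for the correlation adjustment (n = %s): denominator %s is nonpositive.",
          paste(n[bad], collapse = ", "), reading
        ),
        "tm_error_small_n"
      )
    }
    tm_warn(sprintf(
      "%d row(s) with n <= 4: correlation adjustment skipped (rho = r).",
      sum(bad)
    ), "tm_warning_small_n")
  }
  rho <- r + r * (1 - r^2) / denom
  rho[bad] <- r[bad]
  over <- abs(rho) >= 1
  if (any(over)) {
    tm_warn(sprintf(
      "%d adjusted correlation(s) reached |rho| >= 1 and were clamped to 1 - 1e-10.",
      sum(over)
    ), "tm_warning_clamped")
    rho[over] <- sign(rho[over]) * (1 - 1e-10)
  }
  rho
}

#' Fisher's z transformation
#'
#' Transforms a correlation to the variance-stabilised Fisher's z scale,
#' `zr = 0.5 * log((1 + rho) / (1 - rho)) = atanh(rho)`.
#'
#' @param rho Numeric vector of correlations, |rho| < 1.
#' @return Numeric vector of Fisher's z values.
#' @examples
#' rho_to_zr(0.5)
#' tanh(rho_to_zr(0.5)) # 0.5, round trip
#' @export
rho_to_zr <- function(rho) {
  if (any(abs(rho) >= 1)) {
    tm_abort("Fisher's z requires |rho| < 1.", "tm_error_domain")
  }
  0.5 * log((1 + rho) / (1 - rho))
}

#' Sampling variance of Fisher's z
#'
#' The known sampling variance of a Fisher's z-transformed correlation based on
#' a sample of size `n`: `v_z = 1 / (n - 3)`.
#'
#' @param n Integer vector of sample sizes, n >= 4.
#' @return Numeric vector of sampling variances.
#' @examples
#' zr_sampling_variance(103) # 0.01
#' @export
zr_sampling_variance <- function(n) {
  if (any(!is.finite(n)) || any(n <= 3)) {
    tm_abort("Sampling variance 1/(n - 3) requires n >= 4.", "tm_error_domain")
  }
  1 / (n - 3)
}

#' Standardise extracted study statistics to Fisher's-z effect sizes
#'
#' Converts each row of an extraction table into a Fisher's z effect size with
#' its sampling variance, retaining every intermediate (t, r, rho) so the
#' conversion is auditable row by row.  Dispatch follows `statistic_kind`:
#'
#' * `"slope_t"` — a regression slope with a t statistic (or with a standard
#'   error, from which `t = value / se`); converted via [t_to_r()].  Requires
#'   `df`.
#' * `"slope_ci"`, `"estimate_ci"` — an estimate with a 95% CI; the standard
#'   error is recovered with [se_from_ci()], then `t = value / se` and
#'   [t_to_r()].  Requires `df`.
#' * `"correlation"` — a reported correlation coefficient, used directly.
#'
#' All paths then apply [r_to_rho()], [rho_to_zr()] and
#' [zr_sampling_variance()] using the row's `n`.
#'
#' @param data A data frame with columns `study_id`, `estimate_id`, `species`,
#'   `statistic_kind`, `value`, `n`, and (as needed per kind) `se`, `ci_upper`,
#'   `t_value`, `df`; `year` and any moderator columns are carried through.
#' @param reading,small_n Passed to [r_to_rho()].
#' @return A tibble with one row per estimate and columns `study_id`,
#'   `estimate_id`, `species`, `r`, `rho`, `zr`, `v_z`, `precision`
#'   (`1/sqrt(v_z)`), `year`, plus all moderator columns.
#' @examples
#' tbl <- tibble::tibble(
#'   study_id = "s1", estimate_id = "e1", species = "Homo sapiens",
#'   statistic_kind = "slope_t", value = NA, se = NA, ci_upper = NA,
#'   t_value = 2, df = 96, n = 100, year = 2020
#' )
#' standardize_effects(tbl)
#' @export
standardize_effects <- function(data, reading = c("2(n-4)", "2n-4"),
                                small_n = c("error", "passthrough")) {
  reading <- match.arg(reading)
  small_n <- match.arg(small_n)
  required <- c("study_id", "estimate_id", "species", "statistic_kind", "value", "n")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    tm_abort(
      paste0("Missing required column(s): ", paste(missing_cols, collapse = ", ")),
      "tm_error_schema"
    )
  }
  for (col in c("se", "ci_upper", "t_value", "df", "year")) {
    if (!col %in% names(data)) data[[col]] <- NA_real_
  }
  if (anyDuplicated(data$estimate_id)) {
    tm_abort("`estimate_id` must be unique.", "tm_error_schema")
  }
  if (any(!is.finite(data$n))) {
    tm_abort("`n` is required for every estimate.", "tm_error_schema")
  }

  kinds <- c("slope_t", "slope_ci", "correlation", "estimate_ci")
  unknown <- setdiff(unique(data$statistic_kind), kinds)
  if (length(unknown)) {
    tm_abort(
      paste0("Unknown statistic_kind: ", paste(unknown, collapse = ", ")),
      "tm_error_schema"
    )
  }

  row_r <- function(kind, value, se, ci_upper, t_value, df, n, estimate_id) {
    tryCatch({
      if (kind == "correlation") {
        if (!is.finite(value)) tm_abort("missing correlation value", "tm_error_schema")
        return(value)
      }
      if (kind %in% c("slope_ci", "estimate_ci")) {
        if (!is.finite(ci_upper)) tm_abort("missing ci_upper", "tm_error_schema")
        se <- se_from_ci(value, ci_upper)
      }
      t <- if (kind == "slope_t" && is.finite(t_value)) t_value else {
        if (!is.finite(se) || se <= 0) tm_abort("missing se or t_value for slope", "tm_error_schema")
        value / se
      }
      if (!is.finite(df) || df < 1) {
        tm_abort("missing or invalid df for slope path", "tm_error_schema")
      }
      t_to_r(t, df)
    }, telometa_error = function(e) {
      tm_abort(
        sprintf("estimate %s: %s", estimate_id, conditionMessage(e)),
        class(e)[1]
      )
    })
  }

  r <- purrr::pmap_dbl(
    list(
      data$statistic_kind, as.numeric(data$value), as.numeric(data$se),
      as.numeric(data$ci_upper), as.numeric(data$t_value), as.numeric(data$df),
      as.numeric(data$n), as.character(data$estimate_id)
    ),
    row_r
  )

  rho <- r_to_rho(r, data$n, reading = reading, small_n = small_n)
  zr <- rho_to_zr(rho)
  v_z <- zr_sampling_variance(data$n)

  extra <- setdiff(
    names(data),
    c("statistic_kind", "value", "se", "ci_upper", "t_value", "df")
  )
  out <- dplyr::as_tibble(data[extra])
  out$r <- r
  out$rho <- rho
  out$zr <- zr
  out$v_z <- v_z
  out$precision <- 1 / sqrt(v_z)
  front <- c("study_id", "estimate_id", "species", "r", "rho", "zr", "v_z",
             "precision", "year")
  dplyr::relocate(out, dplyr::all_of(front))
}
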