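#' Contour-enhanced funnel plot
#'
#' Plots precision (1/SE) against fixed-effect residuals of the fitted
#' meta-regression, with shaded pseudo-confidence contours at 90/95/99%:
#' at precision `p` a residual drawn purely from sampling error lies inside
#' `+/- z_alpha / p` with the stated probability.  Points piling up outside
#' one flank of the contours suggest publication bias.
#'
#' @param x A `"zr_fit"` or a tibble from [funnel_points()].
#' @param contours Two-sided coverage levels for the shaded contours.
#' @return A ggplot object.
#' @export
plot_funnel <- function(x, contours = c(0.90, 0.95, 0.99)) {
  pts <- if (inherits(x, "zr_fit")) funnel_points(x) else x
  prec <- seq(min(pts$precision) * 0.8, max(pts$precision) * 1.05,
              length.out = 200)
  bands <- purrr::map_dfr(sort(contours, decreasing = TRUE), function(cv) {
    z <- qnorm(1 - (1 - cv) / 2)
    tibble::tibble(precision = prec, lo = -z / prec, hi = z / prec,
                   level = sprintf("%d%%", round(100 * cv)))
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$residual, y = .data$precision)) +
    ggplot2::geom_ribbon(
      data = bands,
      ggplot2::aes(y = .data$precision, xmin = .data$lo, xmax = .data$hi,
                   fill = .data$level),
      orientation = "y", alpha = 0.35, inherit.aes = FALSE
    ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_fill_grey(start = 0.85, end = 0.55, name = "Pseudo-CI") +
    ggplot2::labs(x = "Residual Zr", y = "Precision (1/SE)") +
    ggplot2::theme_minimal()
}

#' Forest plot of per-study aggregated effects
#'
#' @param effects Tibble of standardised effects (aggregated internally with
#'   [forest_data()]) or an already-aggregated tibble with `zr`, `conf_low`,
#'   `conf_high`.
#' @return A ggplot object with one row per study.
#' @export
plot_forest <- function(effects) {
  agg <- if (all(c("conf_low", "conf_high") %in% names(effects))) {
    effects
  } else {
    forest_data(effects)
  }
  agg$study_id <- stats::reorder(agg$study_id, agg$zr)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$zr, y = .data$study_id)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      height = 0.2, colour = "grey40"
    ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$k), colour = "#2c7fb8") +
    ggplot2::scale_size_continuous(range = c(1.5, 4), name = "k effects") +
    ggplot2::labs(x = "Fisher's z (study inverse-variance mean, 95% CI)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Orchard-style moderator plot
#'
#' For one categorical moderator of a fitted model, shows the estimated
#' marginal mean per level with its 95% confidence interval (thick) and 95%
#' prediction interval (thin, adding the summed random-effect variances), on
#' top of the raw effects scaled by precision.
#'
#' @param fit A `"zr_fit"`.
#' @param term A categorical moderator of the fit.
#' @return A ggplot object.
#' @export
plot_orchard <- function(fit, term) {
  if (!term %in% names(fit$design$xlev)) {
    tm_abort(sprintf("`%s` is not a categorical moderator of the fit.", term),
             "tm_error_schema")
  }
  grid <- expand.grid(fit$design$xlev, stringsAsFactors = FALSE)
  for (m in setdiff(fit$moderators, names(fit$design$xlev))) {
    grid[[m]] <- mean(fit$design$data[[m]])
  }
  Xg <- model.matrix(delete.response(fit$design$terms), grid,
                     xlev = fit$design$xlev)[, names(fit$beta), drop = FALSE]
  lv <- fit$design$xlev[[term]]
  s2_sum <- sum(fit$sigma2[fit$random])
  emm <- purrr::map_dfr(lv, function(l) {
    rows <- grid[[term]] == l
    cvec <- colMeans(Xg[rows, , drop = FALSE])
    est <- sum(cvec * fit$beta)
    se <- sqrt(drop(t(cvec) %*% fit$beta_cov %*% cvec))
    tibble::tibble(level = l, estimate = est, se = se,
                   conf_low = est - 1.96 * se, conf_high = est + 1.96 * se,
                   pred_low = est - 1.96 * sqrt(se^2 + s2_sum),
                   pred_high = est + 1.96 * sqrt(se^2 + s2_sum))
  })
  raw <- fit$design$data
  raw$level <- as.character(raw[[term]])
  ggplot2::ggplot(emm, ggplot2::aes(y = .data$level)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_jitter(
      data = raw,
      ggplot2::aes(x = .data$zr, y = .data$level, size = 1 / sqrt(.data$v_z)),
      height = 0.15, alpha = 0.25, colour = "#41ab5d"
    ) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$pred_low, xmax = .data$pred_high),
      height = 0, linewidth = 0.4
    ) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      height = 0, linewidth = 1.4
    ) +
    ggplot2::geom_point(ggplot2::aes(x = .data$estimate), size = 3) +
    ggplot2::scale_size_continuous(range = c(0.5, 4), name = "Precision") +
    ggplot2::labs(x = "Fisher's z", y = term) +
    ggplot2::theme_minimal()
}

#' Coefficient plot of a fitted meta-regression
#'
#' @param object A `"zr_fit"`.
#' @param ... Unused.
#' @return A ggplot object of coefficients with 95% Wald intervals.
#' @export
autoplot.zr_fit <- function(object, ...) {
  co <- tidy(object)
  co$term <- stats::reorder(co$term, co$estimate)
  ggplot2::ggplot(co, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      height = 0.15
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Estimate (Zr)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
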