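#' Read an effect-size extraction table
#'
#' Reads a delimited extraction table (CSV by default), normalises Unicode
#' minus signs to ASCII, optionally renames columns via `col_map`, and
#' validates the schema: required columns present, unique estimate IDs,
#' integer sample sizes of at least 4 (the Fisher's-z sampling variance
#' 1/(n-3) and the correlation adjustment both need it), known statistic
#' kinds, and reported correlations inside (-1, 1).  All violations are
#' collected and reported together, naming the offending rows and columns.
#'
#' @param path File path of the delimited table.
#' @param col_map Optional named character vector `c(our_name = "file_name")`
#'   renaming file columns onto the package schema.
#' @param delim Field delimiter (default `","`).
#' @param vocab Optional named list of allowed level vocabularies per
#'   moderator column; unknown levels become validation errors.
#' @return A tibble of raw estimates ready for [standardize_effects()].
#' @export
read_effects <- function(path, col_map = NULL, delim = ",", vocab = NULL) {
  if (!file.exists(path)) tm_abort(paste0("File not found: ", path), "tm_error_io")
  data <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  data <- dplyr::mutate(data, dplyr::across(dplyr::where(is.character),
                                            normalise_minus))
  # re-parse character columns that were numeric but for the Unicode minus
  for (col in names(data)) {
    if (is.character(data[[col]])) {
      num <- suppressWarnings(as.numeric(data[[col]]))
      all_parse <- all(is.na(data[[col]]) | !is.na(num))
      if (all_parse && !all(is.na(num))) data[[col]] <- num
    }
  }
  if (!is.null(col_map)) {
    for (ours in names(col_map)) {
      theirs <- col_map[[ours]]
      if (!theirs %in% names(data)) {
        tm_abort(sprintf("Mapped column `%s` absent from file.", theirs),
                 "tm_error_schema")
      }
      names(data)[names(data) == theirs] <- ours
    }
  }

  problems <- character(0)
  note <- function(...) problems <<- c(problems, sprintf(...))
  required <- c("study_id", "estimate_id", "species", "statistic_kind",
                "value", "n", "year")
  for (col in setdiff(required, names(data))) {
    note("missing required column `%s`", col)
  }
  if (!length(problems)) {
    if (anyDuplicated(data$estimate_id)) {
      note("duplicate estimate_id: %s",
           paste(unique(data$estimate_id[duplicated(data$estimate_id)]),
                 collapse = ", "))
    }
    bad_n <- which(!is.finite(data$n) | data$n < 4 | data$n != round(data$n))
    for (i in bad_n) {
      note("row %d: n = %s violates the sampling-variance constraint n >= 4 (v_z = 1/(n-3))",
           i, format(data$n[i]))
    }
    kinds <- c("slope_t", "slope_ci", "correlation", "estimate_ci")
    bad_kind <- which(!data$statistic_kind %in% kinds)
    for (i in bad_kind) {
      note("row %d: unknown statistic_kind `%s`", i, data$statistic_kind[i])
    }
    is_corr <- data$statistic_kind == "correlation"
    bad_r <- which(is_corr & (!is.finite(data$value) | abs(data$value) >= 1))
    for (i in bad_r) note("row %d: correlation outside (-1, 1)", i)
    for (col in names(vocab)) {
      if (!col %in% names(data)) next
      bad <- which(!is.na(data[[col]]) & !data[[col]] %in% vocab[[col]])
      for (i in bad) {
        note("row %d, column `%s`: unknown level `%s`", i, col, data[[col]][i])
      }
    }
  }
  if (length(problems)) {
    tm_abort(paste0("Dataset validation failed:\n",
                    paste0("  - ", problems, collapse = "\n")),
             "tm_error_schema")
  }
  inform(sprintf("Read %d estimates from %d studies.", nrow(data),
                 length(unique(data$study_id))))
  dplyr::as_tibble(data)
}

#' Write a table of effects as delimited text
#'
#' @param effects A tibble (raw or standardised effects).
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_effects <- function(effects, path, delim = ",") {
  readr::write_delim(effects, path, delim = delim)
  invisible(path)
}

#' Run the full meta-analytic pipeline on one data subset
#'
#' Chains the analysis stages the way the human and non-human subsets of a
#' parental-age meta-analysis are modelled: standardisation (if raw
#' statistics are supplied), an intercept-only multilevel model (REML), a
#' moderated model (ML), heterogeneity decomposition, variance-component
#' likelihood-ratio tests and profile CIs, the omnibus moderator test,
#' post-hoc contrasts, per-moderator marginal R-squared, and the Egger and
#' time-lag bias diagnostics.  Phylogeny is dropped automatically for
#' single-species subsets.
#'
#' @param data Raw estimates (with `statistic_kind`) or already-standardised
#'   effects (with `zr` and `v_z`).
#' @param tree Optional `"phylo"` tree (required for multi-species data if
#'   `random` includes `"phylo"`).
#' @param moderators,interactions,references Fixed-effect specification for
#'   the moderated model.
#' @param random Random terms for all models; `"phylo"` is removed when only
#'   one species is present.
#' @param contrast_terms List of terms passed to [pairwise_contrasts()].
#' @param vc_ci Compute profile-likelihood CIs for the variance components.
#' @param output_dir If non-`NULL`, writes delimited tables and a JSON report
#'   there.
#' @return A list of class `"zr_report"` with elements `effects`,
#'   `fit_intercept`, `fit_moderated`, `heterogeneity`, `vc_tests`, `vc_ci`,
#'   `omnibus`, `contrasts`, `r2`, `egger`, `timelag`, `funnel`, `forest`.
#' @export
run_analysis <- function(data, tree = NULL, moderators = NULL,
                         interactions = NULL, references = NULL,
                         random = c("study", "estimate", "phylo"),
                         contrast_terms = NULL, vc_ci = FALSE,
                         output_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      tm_abort(sprintf("[stage %s] %s", name, conditionMessage(e)),
               "tm_error_stage")
    })
  }
  effects <- if ("zr" %in% names(data)) {
    dplyr::as_tibble(data)
  } else {
    stage("standardize", standardize_effects(data))
  }

  n_species <- length(unique(effects$species))
  if (n_species < 2) random <- setdiff(random, "phylo")
  phylo_corr <- NULL
  if ("phylo" %in% random) {
    if (is.null(tree)) {
      tm_abort("[stage config] A tree is required for a multi-species subset with a phylogenetic random effect.",
               "tm_error_stage")
    }
    phylo_corr <- stage("phylogeny",
                        phylo_correlation(tree, unique(effects$species)))
  }

  fit1 <- stage("fit_intercept",
                fit_zr(effects, random = random, phylo_corr = phylo_corr,
                       method = "REML"))
  fit2 <- if (length(moderators %||% character(0))) {
    stage("fit_moderated",
          fit_zr(effects, moderators = moderators, interactions = interactions,
                 references = references, random = random,
                 phylo_corr = phylo_corr, method = "ML"))
  } else {
    NULL
  }

  het <- stage("heterogeneity", heterogeneity(fit1))
  vc_tests <- stage("lrt", purrr::map_dfr(fit1$random, ~lrt_vc(fit1, .x)))
  vc_cis <- if (vc_ci) stage("vc_ci", vc_profile_ci(fit1)) else NULL
  omnibus <- if (!is.null(fit2)) stage("omnibus", omnibus_test(fit2)) else NULL
  contrasts <- if (!is.null(fit2) && length(contrast_terms)) {
    stage("posthoc",
          purrr::map(contrast_terms, ~pairwise_contrasts(fit2, .x)))
  } else {
    NULL
  }
  r2 <- if (!is.null(fit2)) {
    stage("r2", purrr::map_dfr(
      c(moderators, interactions),
      ~marginal_r2(effects, .x, random = random, phylo_corr = phylo_corr,
                   references = references)
    ))
  } else {
    NULL
  }
  bias_fit <- fit2 %||% fit1
  egger <- stage("egger", eggers_test(effects, random = random,
                                      phylo_corr = phylo_corr))
  timelag <- stage("timelag", timelag_test(effects, random = random,
                                           phylo_corr = phylo_corr))
  funnel <- stage("funnel", funnel_points(bias_fit))
  forest <- stage("forest", forest_data(effects))

  report <- structure(list(
    effects = effects, fit_intercept = fit1, fit_moderated = fit2,
    heterogeneity = het, vc_tests = vc_tests, vc_ci = vc_cis,
    omnibus = omnibus, contrasts = contrasts, r2 = r2,
    egger = egger, timelag = timelag, funnel = funnel, forest = forest
  ), class = "zr_report")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_effects(effects, file.path(output_dir, "effects.csv"))
    write_effects(tidy(fit1), file.path(output_dir, "intercept_model.csv"))
    if (!is.null(fit2)) {
      write_effects(tidy(fit2), file.path(output_dir, "moderated_model.csv"))
    }
    write_effects(tidy(het), file.path(output_dir, "heterogeneity.csv"))
    write_effects(funnel, file.path(output_dir, "funnel.csv"))
    write_effects(forest, file.path(output_dir, "forest.csv"))
    json <- list(
      intercept = as.list(glance(fit1)),
      heterogeneity = list(i2_total = het$i2_total,
                           i2_residual = het$i2_residual,
                           i2_by_component = as.list(het$i2_by_component)),
      omnibus = if (!is.null(omnibus)) as.list(omnibus),
      egger = as.list(tidy(egger)),
      timelag = as.list(tidy(timelag)),
      r2 = if (!is.null(r2)) r2,
      versions = list(telometa = as.character(utils::packageVersion("telometa")),
                      r = R.version.string)
    )
    jsonlite::write_json(json, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Per-study aggregated effects for a forest plot
#'
#' Aggregates each study's effects with a fixed-effect inverse-variance mean:
#' `zbar = sum(zr/v) / sum(1/v)` with variance `1 / sum(1/v)`, plus a 95%
#' Wald interval.
#'
#' @param effects Tibble of standardised effects.
#' @return A tibble with one row per study: `study_id`, `k`, `zr`, `se`,
#'   `conf_low`, `conf_high`.
#' @export
forest_data <- function(effects) {
  effects |>
    dplyr::group_by(.data$study_id) |>
    dplyr::summarise(
      k = dplyr::n(),
      zr = sum(.data$zr / .data$v_z) / sum(1 / .data$v_z),
      se = sqrt(1 / sum(1 / .data$v_z)),
      .groups = "drop"
    ) |>
    dplyr::mutate(conf_low = .data$zr - 1.96 * .data$se,
                  conf_high = .data$zr + 1.96 * .data$se)
}

#' Reproduce the deposited-dataset analysis
#'
#' Runs the full pipeline on a local copy of a deposited extraction table
#' (and Newick tree for the non-human subset) and returns the headline
#' numbers: subset intercepts with CIs, I-squared decomposition, omnibus
#' statistic, key coefficients, laboratory-method R-squared, and the Egger
#' and time-lag slopes.  The species column value given by `human_label`
#' defines the human subset; all other species form the non-human subset.
#'
#' @param csv_path Path to the deposited effect-size table.
#' @param tree_path Path to the Newick tree for the non-human species.
#' @param col_map,vocab Passed to [read_effects()].
#' @param moderators,interactions,references Moderated-model specification.
#' @param human_label Species label identifying human rows.
#' @return A list with `human` and `nonhuman` `"zr_report"`s plus a
#'   `headline` tibble of named numbers.
#' @export
reproduce_deposited <- function(csv_path, tree_path = NULL, col_map = NULL,
                                vocab = NULL, moderators = NULL,
                                interactions = NULL, references = NULL,
                                human_label = "Homo sapiens") {
  raw <- read_effects(csv_path, col_map = col_map, vocab = vocab)
  std <- if ("zr" %in% names(raw)) raw else standardize_effects(raw)
  human <- dplyr::filter(std, .data$species == human_label)
  nonhuman <- dplyr::filter(std, .data$species != human_label)
  tree <- if (!is.null(tree_path)) parse_newick(tree_path) else NULL
  rep_h <- run_analysis(human, moderators = moderators,
                        interactions = interactions, references = references,
                        random = c("study", "estimate"))
  rep_nh <- run_analysis(nonhuman, tree = tree, moderators = moderators,
                         references = references,
                         random = c("study", "estimate", "phylo"))
  headline <- tibble::tibble(
    quantity = c("zr_mean", "zr_sd", "zr_min", "zr_max",
                 "human_intercept", "nonhuman_intercept",
                 "human_i2_total", "human_i2_study",
                 "nonhuman_i2_phylo",
                 "human_egger_slope", "human_timelag_slope"),
    value = c(mean(std$zr), sd(std$zr), min(std$zr), max(std$zr),
              rep_h$fit_intercept$beta[["(Intercept)"]],
              rep_nh$fit_intercept$beta[["(Intercept)"]],
              rep_h$heterogeneity$i2_total,
              rep_h$heterogeneity$i2_by_component[["study"]],
              rep_nh$heterogeneity$i2_by_component[["phylo"]],
              rep_h$egger$slope, rep_h$timelag$slope)
  )
  list(human = rep_h, nonhuman = rep_nh, headline = headline)
}
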