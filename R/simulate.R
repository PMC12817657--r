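#' Configuration for the synthetic-data generator
#'
#' Bundles the true parameters and design sizes under which
#' [simulate_dataset()] draws Fisher's-z effect sizes.  Defaults reproduce
#' the scale and variance structure of a vertebrate parental-age
#' meta-analysis: 42 studies contributing one to six estimates each (about
#' 148 effects in expectation), 13 species with one species per study,
#' study-level variance 0.004, estimate-level (residual) variance 0.002,
#' phylogenetic variance 0.022, and per-estimate sample sizes drawn
#' log-uniformly between 10 and 1000 to mimic the heavy right tail of real
#' sample sizes.
#'
#' @param n_studies Number of studies.
#' @param estimates_per_study Integer vector of possible estimates per study
#'   (drawn uniformly), or a single integer.
#' @param n_species Number of species.
#' @param species_assignment `"per_study"` (each study gets one species,
#'   species recycled across studies) or `"single"` (every row the same
#'   species, mirroring a human-only subset).
#' @param n_range Inclusive range for per-estimate sample sizes (min >= 5).
#' @param beta Named vector of true fixed effects.  `"intercept"` is the
#'   grand mean; other entries are written `"moderator=level"` and add to
#'   rows with that level.
#' @param sigma2_study,sigma2_estimate,sigma2_phylo True variance components.
#' @param tree A `"phylo"` tree whose tips will name the species, or
#'   `"simulate"` to draw a pure-birth tree.
#' @param moderator_levels Named list: moderator name -> named numeric vector
#'   of level sampling probabilities (must sum to 1).
#' @param year_range Publication-year span (years drawn uniformly).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @return A `"sim_config"` list.
#' @export
sim_config <- function(n_studies = 42,
                       estimates_per_study = 1:6,
                       n_species = 13,
                       species_assignment = c("per_study", "single"),
                       n_range = c(10, 1000),
                       beta = c(intercept = 0.06),
                       sigma2_study = 0.004,
                       sigma2_estimate = 0.002,
                       sigma2_phylo = 0.022,
                       tree = "simulate",
                       moderator_levels = list(
                         parental_sex = c(mother = 0.5, father = 0.5),
                         lab_method = c(qPCR = 0.6, TRF_in_gel = 0.1,
                                        TRF_southern = 0.2, WGS = 0.1)
                       ),
                       year_range = c(2004, 2023),
                       seed = 1L) {
  species_assignment <- match.arg(species_assignment)
  stopifnot(n_studies >= 2, n_species >= 1, length(n_range) == 2,
            n_range[1] >= 5, n_range[2] >= n_range[1],
            sigma2_study >= 0, sigma2_estimate >= 0, sigma2_phylo >= 0)
  if (!"intercept" %in% names(beta)) {
    tm_abort("`beta` must include an `intercept` entry.", "tm_error_schema")
  }
  for (m in names(moderator_levels)) {
    p <- moderator_levels[[m]]
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      tm_abort(sprintf("Probabilities for moderator `%s` must be nonnegative and sum to 1.", m),
               "tm_error_schema")
    }
  }
  # every non-intercept effect must name a known moderator level
  for (nm in setdiff(names(beta), "intercept")) {
    parts <- strsplit(nm, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[1] %in% names(moderator_levels) ||
        !parts[2] %in% names(moderator_levels[[parts[1]]])) {
      tm_abort(sprintf("beta entry `%s` does not match a moderator level.", nm),
               "tm_error_schema")
    }
  }
  structure(list(
    n_studies = n_studies, estimates_per_study = estimates_per_study,
    n_species = n_species, species_assignment = species_assignment,
    n_range = n_range, beta = beta, sigma2_study = sigma2_study,
    sigma2_estimate = sigma2_estimate, sigma2_phylo = sigma2_phylo,
    tree = tree, moderator_levels = moderator_levels,
    year_range = year_range, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate an ultrametric pure-birth phylogeny
#'
#' Draws a pure-birth (Yule) tree and rescales all root-to-tip depths to 1,
#' so the implied correlation matrix is exact under the shared-branch-length
#' normalisation.  Deterministic given the seed.
#'
#' @param n_species Number of tips (>= 2).
#' @param seed Integer seed.
#' @return A `"phylo"` tree with tips `sp01, sp02, ...` and unit depth.
#' @export
simulate_tree <- function(n_species, seed = 1L) {
  if (n_species < 2) tm_abort("Need at least 2 species.", "tm_error_schema")
  tree <- withr::with_seed(as.integer(seed), {
    ape::rphylo(n_species, birth = 1, death = 0)
  })
  depths <- ape::node.depth.edgelength(tree)[seq_len(n_species)]
  tree$edge.length <- tree$edge.length / max(depths)
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tree
}

#' Simulate a meta-analytic dataset of Fisher's-z effects
#'
#' Draws a dataset with the exact statistical structure the multilevel model
#' assumes: `zr = X beta + u_study + a_species + e_estimate + m`, with
#' `u ~ N(0, sigma2_study)` per study, species effects jointly multivariate
#' normal with covariance `sigma2_phylo * C` over the tree correlation `C`,
#' `e ~ N(0, sigma2_estimate)` per row, and sampling error
#' `m ~ N(0, 1/(N-3))` with `N` drawn log-uniformly over the configured
#' range.  Moderator levels are sampled independently per row.  Fully
#' deterministic given `config$seed`; the realised random-effect draws are
#' retained in `truth` for parameter-recovery tests.
#'
#' @param config A [sim_config()].
#' @return A `"zr_sim"` list with `effects` (a tibble in the standardised
#'   schema: `study_id`, `estimate_id`, `species`, `zr`, `v_z`, `n`, `year`,
#'   moderator columns), `tree`, `phylo_corr`, and `truth` (the config plus
#'   realised `u`, `a`, `e`, `m`).
#' @examples
#' sim <- simulate_dataset(sim_config(n_studies = 8, seed = 42))
#' head(sim$effects)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  tree <- if (identical(cf$tree, "simulate")) {
    simulate_tree(max(cf$n_species, 2), seed = cf$seed + 1000L)
  } else {
    cf$tree
  }
  withr::with_seed(cf$seed, {
    species_pool <- tree$tip.label[seq_len(cf$n_species)]
    study_ids <- sprintf("study%02d", seq_len(cf$n_studies))
    study_species <- switch(cf$species_assignment,
      per_study = species_pool[((seq_len(cf$n_studies) - 1) %% cf$n_species) + 1],
      single = rep(species_pool[1], cf$n_studies)
    )
    k_per <- if (length(cf$estimates_per_study) == 1) {
      rep(cf$estimates_per_study, cf$n_studies)
    } else {
      sample(cf$estimates_per_study, cf$n_studies, replace = TRUE)
    }
    n_rows <- sum(k_per)
    row_study <- rep(study_ids, k_per)
    row_species <- rep(study_species, k_per)
    estimate_ids <- sprintf("est%03d", seq_len(n_rows))

    C <- phylo_correlation(tree, species_pool)
    a_species <- if (cf$sigma2_phylo > 0) {
      drop(t(chol(symmetrise(C) + diag(1e-10, nrow(C)))) %*%
             rnorm(length(species_pool))) * sqrt(cf$sigma2_phylo)
    } else {
      rep(0, length(species_pool))
    }
    names(a_species) <- species_pool
    u_study <- setNames(rnorm(cf$n_studies, 0, sqrt(cf$sigma2_study)), study_ids)
    e_row <- rnorm(n_rows, 0, sqrt(cf$sigma2_estimate))

    # log-uniform sample sizes mimic the heavy right tail of real studies
    n_i <- round(exp(runif(n_rows, log(cf$n_range[1]), log(cf$n_range[2]))))
    n_i <- pmin(pmax(n_i, cf$n_range[1]), cf$n_range[2])
    v_z <- 1 / (n_i - 3)
    m_row <- rnorm(n_rows, 0, sqrt(v_z))

    mods <- purrr::map_dfc(cf$moderator_levels, function(p) {
      sample(names(p), n_rows, replace = TRUE, prob = p)
    })
    fixed <- rep(cf$beta[["intercept"]], n_rows)
    for (nm in setdiff(names(cf$beta), "intercept")) {
      parts <- strsplit(nm, "=", fixed = TRUE)[[1]]
      fixed <- fixed + cf$beta[[nm]] * (mods[[parts[1]]] == parts[2])
    }
    zr <- fixed + u_study[row_study] + a_species[row_species] + e_row + m_row

    # publication year is a study-level attribute: one year per study
    study_year <- setNames(
      sample(seq(cf$year_range[1], cf$year_range[2]), cf$n_studies,
             replace = TRUE),
      study_ids
    )
    effects <- tibble::tibble(
      study_id = row_study,
      estimate_id = estimate_ids,
      species = row_species,
      zr = as.numeric(zr),
      v_z = v_z,
      precision = 1 / sqrt(v_z),
      n = n_i,
      year = study_year[row_study]
    )
    effects <- dplyr::bind_cols(effects, mods)

    structure(list(
      effects = effects,
      tree = tree,
      phylo_corr = C,
      truth = list(config = cf, u = u_study, a = a_species, e = e_row,
                   m = m_row, fixed = fixed)
    ), class = "zr_sim")
  })
}

#' Apply a publication-selection filter to a simulated dataset
#'
#' Thins a simulated dataset by independent Bernoulli retention draws,
#' emulating publication bias.  The default rule retains every effect except
#' non-significant negative ones (`zr < 0` and `|zr| / sqrt(v_z) < 1.96`),
#' which are kept only with probability `1 - suppress`.  The truth records
#' which rows were censored.
#'
#' @param sim A `"zr_sim"` from [simulate_dataset()].
#' @param rule Function of `(zr, v_z)` returning a retention probability in
#'   \[0, 1\] per row; `NULL` uses the default suppression rule.
#' @param suppress Suppression probability of the default rule.
#' @param seed Integer seed for the retention draws.
#' @return A `"zr_sim"` with the retained rows; `truth$retained` flags the
#'   original rows.
#' @export
apply_selection <- function(sim, rule = NULL, suppress = 0.8, seed = 1L) {
  stopifnot(inherits(sim, "zr_sim"))
  rule <- rule %||% function(zr, v_z) {
    ifelse(zr < 0 & abs(zr) / sqrt(v_z) < 1.96, 1 - suppress, 1)
  }
  prob <- rule(sim$effects$zr, sim$effects$v_z)
  if (any(prob < 0 | prob > 1)) {
    tm_abort("Selection rule must return probabilities in [0, 1].",
             "tm_error_domain")
  }
  keep <- withr::with_seed(as.integer(seed),
                           runif(nrow(sim$effects)) < prob)
  if (!any(keep)) tm_abort("Selection removed every row.", "tm_error_domain")
  out <- sim
  out$effects <- sim$effects[keep, , drop = FALSE]
  out$truth$retained <- keep
  out
}
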