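#' Build the fixed-effects design for a meta-regression
#'
#' Constructs the design matrix, response, and sampling-variance vector for a
#' multilevel meta-regression of Fisher's-z effects.  Categorical moderators
#' are treatment-coded against declared (or first alphabetical) reference
#' levels; numeric moderators enter linearly; interaction columns are
#' elementwise products of the main-effect indicators.  Rows with missing
#' moderator values are dropped with a message, all-constant moderators are
#' dropped with a warning, and aliased columns are removed deterministically
#' in column order with a named warning.
#'
#' @param effects A tibble of standardised effects (from
#'   [standardize_effects()] or [simulate_dataset()]) with columns `zr`,
#'   `v_z`, `study_id`, `estimate_id`, `species`, and the moderator columns.
#' @param moderators Character vector of moderator column names (may be empty
#'   for an intercept-only model).
#' @param interactions Character vector of interaction terms written as
#'   `"a:b"`; both main effects must be listed in `moderators`.
#' @param references Named list or vector mapping a categorical moderator to
#'   its reference level.
#' @return A list with elements `X` (design matrix), `y` (Zr), `v` (sampling
#'   variances), `study`, `estimate`, `species`, `data` (rows used), `terms`,
#'   `xlev`, `assign`, and `term_labels`.
#' @export
build_design <- function(effects, moderators = NULL, interactions = NULL,
                         references = NULL) {
  stopifnot(all(c("zr", "v_z", "study_id", "estimate_id") %in% names(effects)))
  moderators <- moderators %||% character(0)
  interactions <- interactions %||% character(0)
  missing_mods <- setdiff(moderators, names(effects))
  if (length(missing_mods)) {
    tm_abort(paste0("Moderator column(s) not found: ",
                    paste(missing_mods, collapse = ", ")), "tm_error_schema")
  }
  for (term in interactions) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% moderators)) {
      tm_abort(sprintf("Interaction `%s` references undeclared main effects.", term),
               "tm_error_schema")
    }
  }

  data <- dplyr::as_tibble(effects)
  if (length(moderators)) {
    keep <- complete.cases(data[moderators])
    if (any(!keep)) {
      inform(sprintf("Dropped %d row(s) with missing moderator values.", sum(!keep)))
      data <- data[keep, , drop = FALSE]
    }
  }

  # constant moderators carry no contrast and are removed up front
  constant <- moderators[vapply(moderators, function(m) {
    length(unique(data[[m]])) < 2
  }, logical(1))]
  if (length(constant)) {
    tm_warn(paste0("Dropping constant moderator(s): ",
                   paste(constant, collapse = ", ")), "tm_warning_constant")
    moderators <- setdiff(moderators, constant)
    interactions <- interactions[!vapply(interactions, function(term) {
      any(strsplit(term, ":", fixed = TRUE)[[1]] %in% constant)
    }, logical(1))]
  }

  for (m in moderators) {
    if (!is.numeric(data[[m]])) {
      lev <- sort(unique(as.character(data[[m]])))
      ref <- references[[m]] %||% lev[1]
      if (!ref %in% lev) {
        tm_abort(sprintf("Reference level `%s` absent from moderator `%s`.", ref, m),
                 "tm_error_schema")
      }
      data[[m]] <- factor(data[[m]], levels = c(ref, setdiff(lev, ref)))
    }
  }

  rhs <- c(moderators, interactions)
  form <- if (length(rhs)) {
    as.formula(paste("~", paste(rhs, collapse = " + ")))
  } else {
    ~1
  }
  trm <- terms(form, data = data)
  X <- model.matrix(trm, data = data)
  xlev <- lapply(data[moderators[!vapply(moderators, function(m)
    is.numeric(data[[m]]), logical(1))]], levels)

  # drop aliased columns deterministically, keeping earlier columns
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep_cols <- sort(qrX$pivot[seq_len(qrX$rank)])
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep_cols)]
    tm_warn(paste0("Dropping aliased design column(s): ",
                   paste(dropped, collapse = ", ")), "tm_warning_aliased")
    assign_vec <- attr(X, "assign")[keep_cols]
    X <- X[, keep_cols, drop = FALSE]
    attr(X, "assign") <- assign_vec
  }

  list(
    X = X,
    y = as.numeric(data$zr),
    v = as.numeric(data$v_z),
    study = as.character(data$study_id),
    estimate = as.character(data$estimate_id),
    species = if ("species" %in% names(data)) as.character(data$species) else NULL,
    data = data,
    terms = trm,
    xlev = xlev,
    assign = attr(X, "assign"),
    term_labels = attr(trm, "term.labels")
  )
}

#' Marginal covariance matrix of the multilevel meta-analytic model
#'
#' Assembles `V = sigma2_study * S + sigma2_estimate * E + sigma2_phylo * R +
#' sigma2_species * Sp + diag(v)`, where `S` (`E`, `Sp`) is the indicator
#' matrix of shared study (estimate, species) membership, `R` is the row-level
#' phylogenetic correlation, and `v` the known sampling variances.  With one
#' row per estimate `E` is the identity and the estimate-level component acts
#' as residual heterogeneity.
#'
#' @param sigma2 Named numeric vector with any of `study`, `estimate`,
#'   `phylo`, `species` (absent components are treated as zero).
#' @param study,estimate Character vectors of study and estimate IDs per row.
#' @param species Character vector of species per row (needed for the
#'   `species` component).
#' @param row_corr Row-level phylogenetic correlation matrix (needed for the
#'   `phylo` component), e.g. from [expand_phylo()].
#' @param v Sampling variances per row.
#' @return The n-by-n marginal covariance matrix.
#' @export
marginal_covariance <- function(sigma2, study, estimate, v,
                                row_corr = NULL, species = NULL) {
  n <- length(v)
  stopifnot(length(study) == n, length(estimate) == n)
  s2 <- function(name) if (name %in% names(sigma2)) sigma2[[name]] else 0
  V <- diag(v, n)
  if (s2("study") > 0) {
    V <- V + s2("study") * outer(study, study, "==")
  }
  if (s2("estimate") > 0) {
    V <- V + s2("estimate") * outer(estimate, estimate, "==")
  }
  if (s2("species") > 0) {
    if (is.null(species)) tm_abort("`species` needed for the species component.",
                                   "tm_error_schema")
    V <- V + s2("species") * outer(species, species, "==")
  }
  if (s2("phylo") > 0) {
    if (is.null(row_corr)) tm_abort("`row_corr` needed for the phylo component.",
                                    "tm_error_schema")
    stopifnot(nrow(row_corr) == n)
    ev_min <- min(eigen(symmetrise(row_corr), symmetric = TRUE,
                        only.values = TRUE)$values)
    if (ev_min < -1e-8) {
      tm_abort("Row-level phylogenetic correlation is not positive semi-definite.",
               "tm_error_psd")
    }
    V <- V + s2("phylo") * row_corr
  }
  symmetrise(unname(V))
}

#' Generalised least squares coefficients under a known covariance
#'
#' Computes `beta = (X' V^-1 X)^-1 X' V^-1 y` and its covariance
#' `(X' V^-1 X)^-1` through a Cholesky factorisation of `V` (the inverse of
#' `V` is never formed explicitly).
#'
#' @param V Positive-definite covariance matrix.
#' @param X Design matrix of full column rank.
#' @param y Response vector.
#' @return List with `beta`, `beta_cov`, the Cholesky factor `L` of `V`, the
#'   whitened residual quadratic form `quad = r' V^-1 r`, and
#'   `logdet_xtvix = log|X' V^-1 X|`.
#' @export
gls_beta <- function(V, X, y) {
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) {
    tm_abort("Covariance matrix is not positive definite.", "tm_error_psd")
  }
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  xtvix <- crossprod(Xw)
  ch <- tryCatch(chol(xtvix), error = function(e) NULL)
  if (is.null(ch)) {
    tm_abort(
      paste0("Design is rank deficient after weighting; aliased coefficients: ",
             paste(colnames(X), collapse = ", ")),
      "tm_error_rank"
    )
  }
  beta_cov <- chol2inv(ch)
  beta <- drop(beta_cov %*% crossprod(Xw, yw))
  names(beta) <- colnames(X)
  dimnames(beta_cov) <- list(colnames(X), colnames(X))
  resid_w <- yw - Xw %*% beta
  list(
    beta = beta,
    beta_cov = beta_cov,
    L = L,
    quad = sum(resid_w^2),
    logdet_xtvix = 2 * sum(log(diag(ch)))
  )
}

# Precompute the random-effect structure matrices once per design so the
# optimiser does not rebuild n^2 indicator comparisons at every evaluation.
structure_matrices <- function(design, row_corr = NULL) {
  n <- length(design$y)
  mats <- list(
    study = outer(design$study, design$study, "==") * 1,
    estimate = outer(design$estimate, design$estimate, "==") * 1
  )
  if (!is.null(design$species)) {
    mats$species <- outer(design$species, design$species, "==") * 1
  }
  if (!is.null(row_corr)) mats$phylo <- unname(row_corr)
  mats
}

# Log-likelihood given cached structure matrices.
loglik_cached <- function(sigma2, design, mats, method) {
  n <- length(design$y)
  V <- diag(design$v, n)
  for (nm in names(sigma2)) {
    if (sigma2[[nm]] > 0) V <- V + sigma2[[nm]] * mats[[nm]]
  }
  g <- tryCatch(gls_beta(symmetrise(V), design$X, design$y),
                telometa_error = function(e) NULL)
  if (is.null(g)) {
    return(list(ll = -Inf, gls = NULL))
  }
  n <- length(design$y)
  p <- ncol(design$X)
  logdet_v <- 2 * sum(log(diag(g$L)))
  ll <- -0.5 * (n * log(2 * pi) + logdet_v + g$quad)
  if (method == "REML") {
    # the log|X'X| term makes the restricted likelihood invariant to
    # full-rank reparameterisations of the fixed-effect basis
    ll <- ll + 0.5 * p * log(2 * pi) - 0.5 * g$logdet_xtvix +
      0.5 * determinant(crossprod(design$X), logarithm = TRUE)$modulus[1]
  }
  list(ll = ll, gls = g)
}

# General-purpose wrapper: assembles V through the audited marginal_covariance
# path (with its PSD checks), then evaluates the likelihood.
loglik_components <- function(sigma2, design, row_corr = NULL,
                              method = c("ML", "REML")) {
  method <- match.arg(method)
  mats <- structure_matrices(design, row_corr)
  # validate the phylo structure the same way marginal_covariance does
  if ("phylo" %in% names(sigma2) && isTRUE(sigma2[["phylo"]] > 0) &&
      is.null(row_corr)) {
    tm_abort("`row_corr` needed for the phylo component.", "tm_error_schema")
  }
  loglik_cached(sigma2, design, mats, method)
}

#' Log-likelihood of a multilevel meta-analytic model
#'
#' Evaluates the marginal (ML) or restricted (REML) log-likelihood of the
#' model at fixed variance components, profiling out the fixed effects by
#' generalised least squares.
#'
#' @param sigma2 Named numeric vector of variance components (see
#'   [marginal_covariance()]).
#' @param effects Tibble of standardised effects.
#' @inheritParams build_design
#' @param row_corr Optional row-level phylogenetic correlation matrix.
#' @param method `"ML"` or `"REML"`.
#' @return The log-likelihood (scalar; `-Inf` for a non-positive-definite
#'   covariance).
#' @export
loglik_zr <- function(sigma2, effects, moderators = NULL, interactions = NULL,
                      row_corr = NULL, method = c("ML", "REML"),
                      references = NULL) {
  design <- build_design(effects, moderators, interactions, references)
  loglik_components(sigma2, design, row_corr, match.arg(method))$ll
}

# Method-of-moments initial value for the total heterogeneity variance,
# based on the DerSimonian-Laird Q statistic of the weighted fixed-effect fit.
mom_tau2 <- function(design) {
  w <- 1 / design$v
  g <- gls_beta(diag(design$v, length(design$v)), design$X, design$y)
  Q <- g$quad
  c_dl <- sum(w) - sum(w^2) / sum(w)
  max((Q - (length(design$y) - ncol(design$X))) / c_dl, 1e-4)
}

#' Fit a multilevel random-effects meta-regression of Fisher's-z effects
#'
#' Fits the meta-analytic model `zr_i = x_i' beta + u_study + a_phylo +
#' e_estimate + m_i`, with Gaussian random intercepts for study and estimate,
#' an optional phylogenetically correlated species effect, and known sampling
#' error `m_i ~ N(0, v_z)`.  Variance components are estimated by maximising
#' the ML or REML log-likelihood over `log(sigma2)` (bounded below at 1e-12)
#' with deterministic multiple starting points perturbed from a
#' method-of-moments initialiser; fixed effects are profiled by generalised
#' least squares.
#'
#' By default intercept-only models use REML (lower variance-component bias)
#' and moderated models use ML, matching standard meta-analytic practice; set
#' `method` to override.
#'
#' @inheritParams build_design
#' @param random Character subset of `c("study", "estimate", "phylo",
#'   "species")` naming the random components to estimate.
#' @param phylo_corr Species-level correlation matrix from
#'   [phylo_correlation()]; required iff `"phylo"` is in `random`.
#' @param method `"ML"`, `"REML"`, or `NULL` to choose by the presence of
#'   moderators.
#' @param n_starts Number of deterministic optimiser starts (default 5).
#' @param control Passed to [stats::nlminb()]'s `control` (defaults set a
#'   1e-10 relative tolerance).
#' @return An object of class `"zr_fit"`: a list with coefficient estimates
#'   (`beta`, `beta_cov`), variance components (`sigma2`), log-likelihood and
#'   information criteria, counts, convergence diagnostics, and the design
#'   used.  Methods: [print()], [summary()], [tidy()], [glance()],
#'   [autoplot()], [vc_profile_ci()].
#' @examples
#' sim <- simulate_dataset(sim_config(n_studies = 10, seed = 1))
#' fit <- fit_zr(sim$effects, random = c("study", "estimate"))
#' fit
#' @export
fit_zr <- function(effects, moderators = NULL, interactions = NULL,
                   random = c("study", "estimate"), phylo_corr = NULL,
                   method = NULL, references = NULL, n_starts = 5,
                   control = list()) {
  random <- unique(random)
  bad <- setdiff(random, c("study", "estimate", "phylo", "species"))
  if (length(bad)) {
    tm_abort(paste0("Unknown random term(s): ", paste(bad, collapse = ", ")),
             "tm_error_schema")
  }
  if (nrow(effects) < 2) tm_abort("Need at least 2 effect sizes.", "tm_error_schema")
  method <- method %||%
    if (length(moderators %||% character(0)) +
        length(interactions %||% character(0)) == 0) "REML" else "ML"
  method <- match.arg(method, c("ML", "REML"))

  design <- build_design(effects, moderators, interactions, references)
  row_corr <- NULL
  if ("phylo" %in% random) {
    if (is.null(phylo_corr)) {
      tm_abort("`phylo_corr` is required when `phylo` is a random term.",
               "tm_error_schema")
    }
    row_corr <- expand_phylo(phylo_corr, design$species)
  }

  active <- random
  q <- length(active)
  lower <- log(1e-12)
  upper <- log(100)
  ctrl <- modifyList(list(rel.tol = 1e-10, iter.max = 500, eval.max = 1000),
                     control)

  mats <- structure_matrices(design, row_corr)
  obj <- function(par) {
    s2 <- setNames(exp(par), active)
    -loglik_cached(s2, design, mats, method)$ll
  }

  if (q == 0) {
    # pure fixed-effect (inverse-variance weighted) meta-regression
    best_s2 <- setNames(numeric(0), character(0))
    ll <- loglik_cached(best_s2, design, mats, method)
    conv <- TRUE
    diagnostics <- list(n_starts = 0, grad_norm = 0, codes = integer(0))
  } else {
    tau2 <- mom_tau2(design)
    splits <- list(rep(1 / q, q))
    if (q > 1) {
      for (j in seq_len(q)) {
        s <- rep(0.3 / (q - 1), q); s[j] <- 0.7
        splits <- c(splits, list(s))
      }
    }
    scales <- c(1, 0.1, 10, 0.01, 5)
    starts <- list()
    i <- 1
    while (length(starts) < n_starts) {
      sp <- splits[[(i - 1) %% length(splits) + 1]]
      sc <- scales[(i - 1) %/% length(splits) + 1]
      if (is.na(sc)) sc <- scales[(i - 1) %% length(scales) + 1]
      starts[[i]] <- log(pmax(tau2 * sc * sp, 1e-8))
      i <- i + 1
    }
    fits <- lapply(starts, function(s) {
      tryCatch(nlminb(s, obj, lower = lower, upper = upper, control = ctrl),
               error = function(e) list(objective = Inf, convergence = 1L))
    })
    objs <- vapply(fits, function(f) f$objective, numeric(1))
    best <- fits[[which.min(objs)]]
    # polish from the best candidate for a tight stationary point
    best <- nlminb(best$par, obj, lower = lower, upper = upper,
                   control = modifyList(ctrl, list(rel.tol = 1e-12)))
    par <- best$par
    best_s2 <- setNames(exp(par), active)
    ll <- loglik_cached(best_s2, design, mats, method)

    # projected numerical gradient on the log-variance scale (KKT measure:
    # components at the lower bound with outward-pointing gradient drop out)
    h <- 1e-4
    grad <- vapply(seq_len(q), function(j) {
      e <- numeric(q); e[j] <- h
      (obj(pmin(par + e, upper)) - obj(pmax(par - e, lower))) /
        (min(par[j] + h, upper) - max(par[j] - h, lower))
    }, numeric(1))
    at_lb <- par <= lower + 1e-6
    grad[at_lb & grad > 0] <- 0
    diagnostics <- list(
      n_starts = length(starts),
      objectives = objs,
      codes = vapply(fits, function(f) f$convergence %||% 1L, integer(1)),
      grad_norm = sqrt(sum(grad^2))
    )
    conv <- best$convergence == 0 && diagnostics$grad_norm < 1e-4
  }

  sigma2 <- setNames(numeric(4), c("study", "estimate", "phylo", "species"))
  sigma2[names(best_s2)] <- best_s2
  p <- ncol(design$X)
  n <- length(design$y)
  k_par <- p + q
  n_eff <- if (method == "REML") n - p else n

  fit <- structure(list(
    beta = ll$gls$beta,
    beta_cov = ll$gls$beta_cov,
    sigma2 = sigma2,
    random = active,
    loglik = ll$ll,
    deviance = -2 * ll$ll,
    aic = -2 * ll$ll + 2 * k_par,
    bic = -2 * ll$ll + log(n_eff) * k_par,
    n_obs = n,
    n_studies = length(unique(design$study)),
    n_species = length(unique(design$species %||% character(0))),
    p = p, q = q,
    method = method,
    converged = conv,
    diagnostics = diagnostics,
    design = design,
    row_corr = row_corr,
    phylo_corr = phylo_corr,
    moderators = moderators %||% character(0),
    interactions = interactions %||% character(0),
    references = references
  ), class = "zr_fit")
  fit
}

#' @export
print.zr_fit <- function(x, ...) {
  cat(sprintf(
    "Multilevel meta-analytic model (%s), %d effects / %d studies\n",
    x$method, x$n_obs, x$n_studies
  ))
  cat(sprintf("logLik %.3f  AIC %.2f  BIC %.2f  converged: %s\n",
              x$loglik, x$aic, x$bic, x$converged))
  cat("\nVariance components:\n")
  print(round(x$sigma2[x$random], 6))
  cat("\nCoefficients:\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @export
summary.zr_fit <- function(object, ...) print(object)

#' Tidy coefficient table of a fitted meta-regression
#'
#' @param x A `"zr_fit"` object.
#' @param conf_level Confidence level for Wald normal intervals.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std_error`, `statistic` (Wald
#'   z), `p_value`, `conf_low`, `conf_high`.
#' @export
tidy.zr_fit <- function(x, conf_level = 0.95, ...) {
  se <- sqrt(diag(x$beta_cov))
  z <- x$beta / se
  crit <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std_error = unname(se),
    statistic = unname(z),
    p_value = unname(2 * pnorm(-abs(z))),
    conf_low = unname(x$beta - crit * se),
    conf_high = unname(x$beta + crit * se)
  )
}

#' One-row model summary of a fitted meta-regression
#'
#' @param x A `"zr_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble with fit statistics and variance components.
#' @export
glance.zr_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, n_studies = x$n_studies, n_species = x$n_species,
    method = x$method, log_lik = x$loglik, deviance = x$deviance,
    aic = x$aic, bic = x$bic,
    sigma2_study = x$sigma2[["study"]],
    sigma2_estimate = x$sigma2[["estimate"]],
    sigma2_phylo = x$sigma2[["phylo"]],
    sigma2_species = x$sigma2[["species"]],
    converged = x$converged
  )
}

#' Omnibus Wald test of all non-intercept coefficients
#'
#' Tests whether the moderators jointly explain variation in the effect
#' sizes: `QM = b' Cov(b)^-1 b` over the non-intercept coefficients `b`,
#' referred to a chi-square distribution with as many degrees of freedom as
#' coefficients tested.
#'
#' @param fit A `"zr_fit"` with at least one non-intercept coefficient.
#' @return A tibble with `qm`, `df`, `p_value`.
#' @export
omnibus_test <- function(fit) {
  idx <- which(names(fit$beta) != "(Intercept)")
  if (!length(idx)) {
    tm_abort("Model has no non-intercept coefficients.", "tm_error_schema")
  }
  b <- fit$beta[idx]
  S <- fit$beta_cov[idx, idx, drop = FALSE]
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    tm_abort("Coefficient sub-covariance is singular.", "tm_error_rank")
  }
  qm <- sum(backsolve(ch, b, transpose = TRUE)^2)
  tibble::tibble(qm = qm, df = length(idx),
                 p_value = pchisq(qm, length(idx), lower.tail = FALSE))
}

#' Likelihood-ratio test for a variance component
#'
#' Refits the model with one random component removed (same estimation
#' method and data) and reports `LRT = 2 (logLik_full - logLik_reduced)`
#' against a chi-square with 1 df.  Because the null value sits on the
#' boundary of the parameter space, the plain chi-square reference is
#' conservative; `boundary = TRUE` uses the 50:50 mixture of a point mass at
#' zero and a chi-square(1), which halves the p-value.
#'
#' @param fit A converged `"zr_fit"`.
#' @param component One of the fit's random terms.
#' @param boundary Use the boundary-corrected mixture reference.
#' @return A tibble with `component`, `lrt`, `p_value`, and both fits'
#'   log-likelihoods.
#' @export
lrt_vc <- function(fit, component, boundary = FALSE) {
  if (!component %in% fit$random) {
    tm_abort(sprintf("`%s` is not a random term of this fit.", component),
             "tm_error_schema")
  }
  reduced <- fit_zr(
    fit$design$data,
    moderators = fit$moderators, interactions = fit$interactions,
    random = setdiff(fit$random, component),
    phylo_corr = fit$phylo_corr, method = fit$method,
    references = fit$references
  )
  lrt <- max(2 * (fit$loglik - reduced$loglik), 0)
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  if (boundary) p <- p / 2
  tibble::tibble(component = component, lrt = lrt, p_value = p,
                 loglik_full = fit$loglik, loglik_reduced = reduced$loglik)
}

#' Profile-likelihood confidence interval for a variance component
#'
#' Profiles the log-likelihood over one variance component (re-optimising the
#' others at each value) and inverts the likelihood-ratio statistic at the
#' requested level.  A lower limit of 0 is reported when the profile at zero
#' is inside the confidence region.
#'
#' @param fit A converged `"zr_fit"`.
#' @param component One of the fit's random terms; default all of them.
#' @param level Confidence level.
#' @return A tibble with `component`, `estimate`, `conf_low`, `conf_high`.
#' @export
vc_profile_ci <- function(fit, component = fit$random, level = 0.95) {
  purrr::map_dfr(component, function(comp) {
    others <- setdiff(fit$random, comp)
    crit <- stats::qchisq(level, df = 1) / 2
    target <- fit$loglik - crit
    prof <- function(s2) {
      if (length(others)) {
        # re-optimise the other components with `comp` held fixed
        obj <- function(par) {
          s2v <- setNames(exp(par), others)
          s2v[comp] <- s2
          -loglik_components(s2v, fit$design, fit$row_corr, fit$method)$ll
        }
        start <- log(pmax(fit$sigma2[others], 1e-8))
        opt <- nlminb(start, obj, lower = log(1e-12), upper = log(100),
                      control = list(rel.tol = 1e-9))
        -opt$objective
      } else {
        s2v <- setNames(s2, comp)
        loglik_components(s2v, fit$design, fit$row_corr, fit$method)$ll
      }
    }
    est <- fit$sigma2[[comp]]
    lo <- if (prof(1e-12) >= target) 0 else {
      stats::uniroot(function(ls) prof(exp(ls)) - target,
                     lower = log(1e-12), upper = log(max(est, 1e-10)),
                     tol = 1e-6)$root |> exp()
    }
    hi_bound <- log(100)
    hi <- if (prof(exp(hi_bound)) >= target) Inf else {
      stats::uniroot(function(ls) prof(exp(ls)) - target,
                     lower = log(max(est, 1e-10)), upper = hi_bound,
                     tol = 1e-6)$root |> exp()
    }
    tibble::tibble(component = comp, estimate = est,
                   conf_low = lo, conf_high = hi)
  })
}

#' Post-hoc pairwise contrasts of predicted marginal means
#'
#' Computes predicted marginal means for each level of a moderator (or each
#' combination of two moderators, e.g. parental sex by offspring sex) by
#' averaging model predictions with equal weight over the levels of all other
#' categorical moderators, then tests all pairwise differences with Wald z
#' tests.  Multiplicity adjustment is `"none"` (default) or `"tukey"`
#' (studentised-range adjustment over the set of means).
#'
#' @param fit A `"zr_fit"` with categorical moderators.
#' @param term A moderator name, or a length-2 character vector for an
#'   interaction pair.
#' @param adjust `"none"` or `"tukey"`.
#' @return A tibble with `level_a`, `level_b`, `estimate` (difference of
#'   marginal means, Zr units), `se`, `z`, `p_value`, `p_adjusted`.
#' @export
pairwise_contrasts <- function(fit, term, adjust = c("none", "tukey")) {
  adjust <- match.arg(adjust)
  factors <- names(fit$design$xlev)
  if (!all(term %in% factors)) {
    tm_abort(paste0("Term(s) not categorical moderators of the fit: ",
                    paste(setdiff(term, factors), collapse = ", ")),
             "tm_error_schema")
  }
  grid <- expand.grid(fit$design$xlev, stringsAsFactors = FALSE)
  # continuous moderators are held at their sample mean
  numeric_mods <- setdiff(fit$moderators, factors)
  for (m in numeric_mods) grid[[m]] <- mean(fit$design$data[[m]])
  # drop level combinations never observed (empty cells cannot be predicted
  # for in a way that reflects the data)
  if (length(term) > 1) {
    observed <- unique(fit$design$data[term])
    keycol <- function(d) do.call(paste, c(d[term], sep = "\r"))
    keep <- keycol(grid) %in% keycol(observed)
    if (!all(keep)) {
      dropped <- unique(keycol(grid)[!keep])
      tm_warn(paste0("Excluding empty cell(s): ",
                     paste(gsub("\r", ":", dropped), collapse = ", ")),
              "tm_warning_empty_cell")
      grid <- grid[keep, , drop = FALSE]
    }
  }
  trm <- delete.response(fit$design$terms)
  Xg <- model.matrix(trm, data = grid, xlev = fit$design$xlev)
  Xg <- Xg[, names(fit$beta), drop = FALSE]
  label <- do.call(paste, c(lapply(term, function(t) grid[[t]]), sep = ":"))
  levels_seen <- unique(label)
  L <- t(vapply(levels_seen, function(lv) {
    colMeans(Xg[label == lv, , drop = FALSE])
  }, numeric(ncol(Xg))))
  k <- nrow(L)
  pairs <- utils::combn(k, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    cvec <- L[a, ] - L[b, ]
    est <- sum(cvec * fit$beta)
    se <- sqrt(drop(t(cvec) %*% fit$beta_cov %*% cvec))
    z <- est / se
    tibble::tibble(level_a = levels_seen[a], level_b = levels_seen[b],
                   estimate = est, se = se, z = z,
                   p_value = 2 * pnorm(-abs(z)))
  })
  out$p_adjusted <- if (adjust == "tukey") {
    ptukey(abs(out$z) * sqrt(2), nmeans = k, df = Inf, lower.tail = FALSE)
  } else {
    out$p_value
  }
  out
}

#' Variance inflation factors of a design matrix
#'
#' Computes per-column VIFs (`1 / (1 - R^2_j)` from regressing column `j` on
#' the remaining predictors) and, when a term-assignment vector is available,
#' generalised per-term VIFs via correlation-determinant ratios.  Perfectly
#' collinear predictors yield `Inf`.
#'
#' @param X Design matrix (an intercept column is ignored).
#' @param assign Optional integer vector mapping columns to terms (as from
#'   `attr(model.matrix(...), "assign")`); 0 marks the intercept.
#' @param term_labels Optional term names matching `assign` values.
#' @return A tibble with `term`, `df`, `gvif`, and `gvif_adj`
#'   (`gvif^(1/(2 df))`, comparable across terms of different df).
#' @export
design_vif <- function(X, assign = NULL, term_labels = NULL) {
  icol <- which(colnames(X) %in% "(Intercept)" |
                  apply(X, 2, function(c) all(c == c[1])))
  Xp <- if (length(icol)) X[, -icol, drop = FALSE] else X
  if (ncol(Xp) < 2) {
    tm_abort("Need at least 2 predictor columns for VIF.", "tm_error_schema")
  }
  R <- suppressWarnings(stats::cor(Xp))
  detR <- det(R)
  assign <- if (is.null(assign)) seq_len(ncol(Xp)) else {
    if (length(icol)) assign[-icol] else assign
  }
  terms_idx <- unique(assign)
  purrr::map_dfr(terms_idx, function(t) {
    cols <- which(assign == t)
    gvif <- if (detR <= .Machine$double.eps) Inf else {
      det(R[cols, cols, drop = FALSE]) *
        det(R[-cols, -cols, drop = FALSE]) / detR
    }
    df <- length(cols)
    nm <- if (!is.null(term_labels) && t <= length(term_labels)) {
      term_labels[t]
    } else {
      paste(colnames(Xp)[cols], collapse = "+")
    }
    tibble::tibble(term = nm, df = df, gvif = gvif,
                   gvif_adj = gvif^(1 / (2 * df)))
  })
}

#' @rdname design_vif
#' @param fit A `"zr_fit"` object.
#' @export
model_vif <- function(fit) {
  design_vif(fit$design$X, assign = fit$design$assign,
             term_labels = fit$design$term_labels)
}
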