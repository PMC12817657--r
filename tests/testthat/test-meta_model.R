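test_that("design construction codes moderators against reference levels", {
  eff <- toy_effects(10)
  d0 <- build_design(eff)
  expect_equal(unname(d0$X), matrix(1, 10, 1), ignore_attr = TRUE)

  d1 <- build_design(eff, moderators = "sex",
                     references = list(sex = "mother"))
  expect_identical(colnames(d1$X), c("(Intercept)", "sexfather"))
  expect_equal(unname(d1$X[, 2]), as.numeric(eff$sex == "father"))

  # interaction columns are products of the main-effect indicators
  d2 <- build_design(eff, moderators = c("sex", "method"),
                     interactions = "sex:method",
                     references = list(sex = "mother", method = "qPCR"))
  expect_true("sexfather:methodTRF" %in% colnames(d2$X))
  expect_equal(unname(d2$X[, "sexfather:methodTRF"]),
               unname(d2$X[, "sexfather"] * d2$X[, "methodTRF"]))

  # rows with missing moderators dropped with a message
  eff2 <- eff
  eff2$sex[c(2, 5)] <- NA
  expect_message(d3 <- build_design(eff2, moderators = "sex"), "2 row")
  expect_equal(nrow(d3$X), 8)

  # constant moderators dropped with a warning
  eff3 <- eff
  eff3$sex <- "mother"
  expect_warning(d4 <- build_design(eff3, moderators = "sex"),
                 class = "tm_warning_constant")
  expect_equal(ncol(d4$X), 1)

  # aliased columns dropped by name
  eff4 <- eff
  eff4$sex2 <- eff4$sex
  expect_warning(d5 <- build_design(eff4, moderators = c("sex", "sex2")),
                 class = "tm_warning_aliased")
  expect_equal(qr(d5$X)$rank, ncol(d5$X))
  expect_error(build_design(eff, moderators = "nope"), class = "tm_error_schema")
})

test_that("marginal covariance equals naive indicator-matrix assembly", {
  # direct two-row example
  V2 <- marginal_covariance(c(study = 0.004, estimate = 0.002),
                            study = c("a", "a"), estimate = c("e1", "e2"),
                            v = c(0.01, 0.01))
  expect_equal(V2, matrix(c(0.016, 0.004, 0.004, 0.016), 2), tolerance = 1e-14)

  # zero components collapse to diag(v)
  expect_equal(marginal_covariance(c(study = 0, estimate = 0),
                                   c("a", "b"), c("e1", "e2"), v = c(1, 2)),
               diag(c(1, 2)), tolerance = 1e-14)

  # random instance against a brute-force O(n^2) assembly oracle
  withr::with_seed(11, {
    n <- 23
    study <- sample(letters[1:6], n, replace = TRUE)
    est <- sprintf("e%d", 1:n)
    sp <- sample(c("x", "y", "z"), n, replace = TRUE)
    tr <- simulate_tree(3, seed = 2)
    C <- phylo_correlation(tr)
    rownames(C) <- colnames(C) <- c("x", "y", "z")
    R <- expand_phylo(C, sp)
    v <- runif(n, 0.01, 0.1)
    s2 <- c(study = 0.03, estimate = 0.01, phylo = 0.05, species = 0.02)
    V <- marginal_covariance(s2, study, est, v, row_corr = R, species = sp)
    naive <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      naive[i, j] <- s2["study"] * (study[i] == study[j]) +
        s2["estimate"] * (est[i] == est[j]) +
        s2["phylo"] * R[i, j] +
        s2["species"] * (sp[i] == sp[j]) +
        (i == j) * v[i]
    }
    expect_equal(V, naive, tolerance = 1e-12)
  })
})

test_that("GLS solutions match closed forms and a dense-inverse oracle", {
  X <- matrix(1, 3, 1)
  g <- gls_beta(diag(3), X, c(0.1, 0.2, 0.3))
  expect_equal(unname(g$beta), 0.2, tolerance = 1e-14)

  g2 <- gls_beta(diag(c(1, 1, 4)), X, c(0, 0, 9))
  expect_equal(unname(g2$beta), 1, tolerance = 1e-14)

  withr::with_seed(21, {
    for (rep in 1:5) {
      n <- 8
      A <- matrix(rnorm(n * n), n)
      V <- crossprod(A) + diag(n)
      X <- cbind(1, rnorm(n))
      y <- rnorm(n)
      g3 <- gls_beta(V, X, y)
      Vi <- solve(V)
      beta_or <- solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y
      expect_equal(unname(g3$beta), drop(beta_or), tolerance = 1e-10)
      expect_equal(unname(g3$beta_cov), solve(t(X) %*% Vi %*% X),
                   tolerance = 1e-10)
    }
  })

  expect_error(gls_beta(diag(3), cbind(1, c(1, 1, 1)), 1:3),
               class = "tm_error_rank")
})

test_that("log-likelihood matches independent normal densities and is REML-invariant", {
  # single observation, unit variance, zero response
  eff1 <- tibble::tibble(study_id = "s", estimate_id = "e", species = "x",
                         zr = 0, v_z = 1)
  d1 <- build_design(eff1)
  expect_equal(telometa:::loglik_components(c(study = 0), d1, method = "ML")$ll,
               -0.5 * log(2 * pi), tolerance = 1e-12)

  # all components zero: sum of independent normal log-densities at GLS mean
  eff <- toy_effects(15, seed = 3)
  d <- build_design(eff)
  ll <- telometa:::loglik_components(c(study = 0, estimate = 0), d,
                                     method = "ML")$ll
  g <- gls_beta(diag(eff$v_z), d$X, eff$zr)
  expect_equal(ll, sum(dnorm(eff$zr, mean = g$beta, sd = sqrt(eff$v_z),
                             log = TRUE)),
               tolerance = 1e-10)

  # REML invariance under a full-rank reparameterisation of X
  eff2 <- toy_effects(20, seed = 5)
  d2 <- build_design(eff2, moderators = "sex")
  s2 <- c(study = 0.01, estimate = 0.005)
  ll_orig <- telometa:::loglik_components(s2, d2, method = "REML")$ll
  A <- matrix(c(2, 1, 0.5, 3), 2)
  d2b <- d2
  d2b$X <- d2$X %*% A
  colnames(d2b$X) <- colnames(d2$X)
  ll_rep <- telometa:::loglik_components(s2, d2b, method = "REML")$ll
  expect_equal(ll_orig, ll_rep, tolerance = 1e-8)
})

test_that("fitting agrees with an independent multilevel meta-analysis oracle", {
  skip_if_not_installed("metafor")
  sim <- simulate_dataset(sim_config(n_studies = 20, seed = 13))
  eff <- sim$effects
  eff$phylo <- eff$species
  fit <- fit_zr(eff, random = c("study", "estimate", "phylo"),
                phylo_corr = sim$phylo_corr, method = "REML")
  m <- metafor::rma.mv(zr, v_z,
                       random = list(~1 | study_id, ~1 | estimate_id, ~1 | phylo),
                       R = list(phylo = sim$phylo_corr), data = eff,
                       method = "REML")
  expect_equal(unname(fit$beta), unname(coef(m)), tolerance = 1e-5)
  expect_equal(unname(fit$sigma2[c("study", "estimate", "phylo")]),
               m$sigma2, tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-6)

  fit_ml <- fit_zr(eff, moderators = "parental_sex",
                   random = c("study", "estimate"), method = "ML")
  m_ml <- metafor::rma.mv(zr, v_z, mods = ~parental_sex,
                          random = list(~1 | study_id, ~1 | estimate_id),
                          data = eff, method = "ML")
  expect_equal(unname(fit_ml$beta), unname(coef(m_ml)), tolerance = 1e-5)
  expect_equal(omnibus_test(fit_ml)$qm, m_ml$QM, tolerance = 1e-4)
})

test_that("degenerate random structures reduce to known fits", {
  eff <- toy_effects(16, seed = 7)
  # no random terms: inverse-variance weighted fixed-effect regression
  fit0 <- fit_zr(eff, random = character(0))
  w <- 1 / eff$v_z
  expect_equal(unname(fit0$beta), sum(w * eff$zr) / sum(w), tolerance = 1e-12)
  expect_true(fit0$converged)

  # identity phylo correlation is exchangeable across species: same model as
  # a species-intercept random effect
  sp <- unique(eff$species)
  C_id <- diag(length(sp))
  dimnames(C_id) <- list(sp, sp)
  fit_phylo <- fit_zr(eff, random = c("estimate", "phylo"), phylo_corr = C_id)
  fit_species <- fit_zr(eff, random = c("estimate", "species"))
  expect_equal(fit_phylo$loglik, fit_species$loglik, tolerance = 1e-6)
  expect_equal(unname(fit_phylo$sigma2[["phylo"]]),
               unname(fit_species$sigma2[["species"]]), tolerance = 1e-4)
})

test_that("converged fits sit at a stationary point of the likelihood", {
  for (s in c(2, 9)) {
    sim <- simulate_dataset(sim_config(n_studies = 15, seed = s))
    fit <- fit_zr(sim$effects, random = c("study", "estimate"))
    expect_true(fit$converged)
    expect_lt(fit$diagnostics$grad_norm, 1e-6)
    # information criteria identities
    expect_equal(fit$deviance, -2 * fit$loglik, tolerance = 1e-12)
    expect_equal(fit$aic, -2 * fit$loglik + 2 * (fit$p + fit$q),
                 tolerance = 1e-12)
    # beta covariance is symmetric PSD
    expect_equal(fit$beta_cov, t(fit$beta_cov), tolerance = 1e-12)
    expect_gte(min(eigen(fit$beta_cov, symmetric = TRUE,
                         only.values = TRUE)$values), 0)
  }
})

test_that("omnibus test reduces to the squared z for one coefficient", {
  eff <- toy_effects(20, seed = 31)
  fit <- fit_zr(eff, moderators = "sex", random = c("study", "estimate"),
                method = "ML")
  co <- tidy(fit)
  b <- co$estimate[co$term != "(Intercept)"]
  s <- co$std_error[co$term != "(Intercept)"]
  om <- omnibus_test(fit)
  expect_equal(om$qm, (b / s)^2, tolerance = 1e-10)
  expect_equal(om$df, 1)
  intercept_only <- fit_zr(eff, random = c("study", "estimate"))
  expect_error(omnibus_test(intercept_only), class = "tm_error_schema")
})

test_that("likelihood-ratio test is near zero for an absent component", {
  sim <- simulate_dataset(sim_config(
    n_studies = 25, sigma2_study = 0, sigma2_phylo = 0,
    sigma2_estimate = 0.02, n_species = 1, species_assignment = "single",
    seed = 17
  ))
  fit <- fit_zr(sim$effects, random = c("study", "estimate"))
  out <- lrt_vc(fit, "study")
  expect_gte(out$lrt, 0)
  expect_lt(out$lrt, 4)
  # boundary-corrected reference halves the p-value
  out_b <- lrt_vc(fit, "study", boundary = TRUE)
  expect_equal(out_b$p_value, out$p_value / 2, tolerance = 1e-12)
  expect_error(lrt_vc(fit, "phylo"), class = "tm_error_schema")
})

test_that("pairwise contrasts match treatment coding and a cell-mean oracle", {
  eff <- toy_effects(24, seed = 41)
  fit <- fit_zr(eff, moderators = "sex", random = c("study", "estimate"),
                method = "ML", references = list(sex = "mother"))
  pc <- pairwise_contrasts(fit, "sex")
  expect_equal(nrow(pc), 1)
  # for a 2-level factor the single contrast is the coefficient itself
  expect_equal(abs(pc$estimate), abs(unname(fit$beta["sexfather"])),
               tolerance = 1e-10)
  expect_equal(pc$p_adjusted, pc$p_value)

  # balanced 3-level design, equal variances, no random terms: contrasts are
  # direct differences of group means
  withr::with_seed(43, {
    lev <- rep(c("a", "b", "c"), each = 8)
    effb <- tibble::tibble(
      study_id = sprintf("s%d", 1:24), estimate_id = sprintf("e%d", 1:24),
      species = "x", zr = rnorm(24, ifelse(lev == "b", 0.3, 0), 0.1),
      v_z = rep(0.04, 24), grp = lev
    )
  })
  fitb <- fit_zr(effb, moderators = "grp", random = character(0))
  pcb <- pairwise_contrasts(fitb, "grp")
  means <- tapply(effb$zr, effb$grp, mean)
  for (i in seq_len(nrow(pcb))) {
    expect_equal(pcb$estimate[i],
                 unname(means[pcb$level_a[i]] - means[pcb$level_b[i]]),
                 tolerance = 1e-10)
  }
  # tukey adjustment is never smaller than the raw p
  pcb_t <- pairwise_contrasts(fitb, "grp", adjust = "tukey")
  expect_true(all(pcb_t$p_adjusted >= pcb_t$p_value - 1e-12))
})

test_that("marginal means averaged over other factors match emmeans", {
  skip_if_not_installed("emmeans")
  withr::with_seed(47, {
    n <- 40
    effb <- tibble::tibble(
      study_id = sprintf("s%d", 1:n), estimate_id = sprintf("e%d", 1:n),
      species = "x",
      grp = sample(c("a", "b", "c"), n, replace = TRUE),
      sex = sample(c("m", "f"), n, replace = TRUE),
      v_z = rep(0.04, n)
    )
    effb$zr <- rnorm(n, 0.2 * (effb$grp == "b") + 0.1 * (effb$sex == "m"), 0.1)
  })
  # equal variances and no random terms make the fit an OLS regression, so
  # emmeans on the matching lm is an exact independent oracle
  fitb <- fit_zr(effb, moderators = c("grp", "sex"), random = character(0))
  pc <- pairwise_contrasts(fitb, "grp")
  lmfit <- stats::lm(zr ~ grp + sex, data = effb)
  em <- summary(emmeans::emmeans(lmfit, pairwise ~ grp)$contrasts,
                adjust = "none")
  for (i in seq_len(nrow(em))) {
    pair <- strsplit(as.character(em$contrast[i]), " - ")[[1]]
    row <- pc[pc$level_a == pair[1] & pc$level_b == pair[2], ]
    expect_equal(row$estimate, em$estimate[i], tolerance = 1e-8)
  }
})

test_that("variance inflation factors match a regression oracle", {
  withr::with_seed(53, {
    n <- 60
    x1 <- rnorm(n)
    x2 <- 0.8 * x1 + rnorm(n, 0, 0.5)
    x3 <- rnorm(n)
    X <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2, x3 = x3)
  })
  out <- design_vif(X)
  for (j in 1:3) {
    r2 <- summary(stats::lm(X[, j + 1] ~ X[, -c(1, j + 1)]))$r.squared
    expect_equal(out$gvif[j], 1 / (1 - r2), tolerance = 1e-8)
  }
  # uncorrelated (orthogonal) columns give VIF 1
  Xo <- cbind(`(Intercept)` = 1,
              a = rep(c(1, -1), 6),
              b = rep(c(1, 1, -1, -1), 3),
              c = rep(c(1, -1, -1, 1), 3))
  expect_equal(design_vif(Xo)$gvif, rep(1, 3), tolerance = 1e-10)
  # duplicated column: infinite VIF
  Xd <- cbind(1, x1, x1)
  colnames(Xd) <- c("(Intercept)", "a", "b")
  expect_true(all(is.infinite(design_vif(Xd)$gvif)))
  expect_error(design_vif(cbind(1, x1)), class = "tm_error_schema")
})

test_that("generalised VIF matches car on a factor design", {
  skip_if_not_installed("car")
  withr::with_seed(59, {
    n <- 80
    d <- data.frame(
      g = sample(c("a", "b", "c"), n, replace = TRUE),
      h = sample(c("u", "v"), n, replace = TRUE),
      x = rnorm(n)
    )
    d$y <- rnorm(n)
  })
  lmfit <- stats::lm(y ~ g + h + x, data = d)
  X <- model.matrix(lmfit)
  ours <- design_vif(X, assign = attr(X, "assign"),
                     term_labels = attr(terms(lmfit), "term.labels"))
  theirs <- car::vif(lmfit)
  expect_equal(ours$gvif, unname(theirs[, "GVIF"]), tolerance = 1e-8)
})

test_that("profile-likelihood intervals bracket the estimate and cover zero correctly", {
  sim <- simulate_dataset(sim_config(n_studies = 20, n_species = 1,
                                     species_assignment = "single", seed = 23))
  fit <- fit_zr(sim$effects, random = c("study", "estimate"))
  ci <- vc_profile_ci(fit, "study")
  expect_gte(ci$estimate, ci$conf_low)
  expect_lte(ci$estimate, ci$conf_high)
  expect_gte(ci$conf_low, 0)
})
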