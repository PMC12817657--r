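test_that("CI back-calculation recovers standard errors", {
  expect_equal(se_from_ci(0.095, 0.124), (0.124 - 0.095) / 1.96, tolerance = 1e-12)
  expect_equal(round(se_from_ci(0.095, 0.124), 3), 0.015)
  expect_equal(round(se_from_ci(-0.087, 0.094), 3), 0.092)
  expect_equal(se_from_ci(0, 1.96), 1, tolerance = 1e-12)
  expect_error(se_from_ci(0.5, 0.4), class = "tm_error_interval")
  expect_error(se_from_ci(0.5, 0.5), class = "tm_error_interval")
})

test_that("t-to-r conversion is exact, odd, and bounded", {
  expect_identical(t_to_r(0, 50), 0)
  expect_equal(t_to_r(2, 96), 0.2, tolerance = 1e-12)
  expect_equal(t_to_r(-3, 16), -0.6, tolerance = 1e-12)
  expect_error(t_to_r(1, 0), class = "tm_error_domain")
  # strictly increasing in t at fixed df, magnitude below 1
  t <- seq(-50, 50, length.out = 101)
  r <- t_to_r(t, 7)
  expect_true(all(diff(r) > 0))
  expect_true(all(abs(r) < 1))
})

test_that("population-correlation adjustment follows the adopted reading", {
  expect_identical(r_to_rho(0, 100), 0)
  expect_equal(r_to_rho(0.5, 54), 0.5 + 0.5 * 0.75 / (2 * 50), tolerance = 1e-14)
  expect_equal(r_to_rho(0.5, 54), 0.50375, tolerance = 1e-12)
  expect_equal(r_to_rho(-0.5, 54), -0.50375, tolerance = 1e-12)
  # alternative literal reading of the denominator
  expect_equal(r_to_rho(0.5, 54, reading = "2n-4"),
               0.5 + 0.5 * 0.75 / 104, tolerance = 1e-14)
  expect_error(r_to_rho(0.5, 4), class = "tm_error_small_n")
  expect_error(r_to_rho(1, 50), class = "tm_error_domain")
  expect_warning(out <- r_to_rho(0.5, 4, small_n = "passthrough"),
                 class = "tm_warning_small_n")
  expect_identical(out, 0.5)
  # overshoot is clamped, not fatal (possible for fractional effective n,
  # where the denominator drops below 2)
  expect_warning(cl <- r_to_rho(0.8, 4.5), class = "tm_warning_clamped")
  expect_lt(abs(cl), 1)
})

test_that("Fisher's z is atanh with exact round trip", {
  expect_identical(rho_to_zr(0), 0)
  expect_equal(rho_to_zr(0.5), 0.549306144334055, tolerance = 1e-12)
  expect_equal(rho_to_zr(tanh(1.2)), 1.2, tolerance = 1e-12)
  x <- seq(-0.99, 0.99, by = 0.01)
  expect_equal(tanh(rho_to_zr(x)), x, tolerance = 1e-12)
  expect_error(rho_to_zr(1), class = "tm_error_domain")
})

test_that("sampling variance 1/(n-3) is exact and decreasing in n", {
  expect_identical(zr_sampling_variance(4), 1)
  expect_equal(zr_sampling_variance(103), 0.01, tolerance = 1e-14)
  expect_equal(zr_sampling_variance(148), 1 / 145, tolerance = 1e-14)
  expect_error(zr_sampling_variance(3), class = "tm_error_domain")
  n <- 4:500
  expect_true(all(diff(zr_sampling_variance(n)) < 0))
})

test_that("standardisation dispatches on statistic kind and keeps intermediates", {
  raw <- tiny_raw()
  out <- standardize_effects(raw)
  expect_s3_class(out, "tbl_df")
  expect_named(out, c("study_id", "estimate_id", "species", "r", "rho", "zr",
                      "v_z", "precision", "year", "n", "parental_sex",
                      "lab_method"), ignore.order = TRUE)
  # slope_t row: t = 2, df = 96, n = 100
  r1 <- out[out$estimate_id == "e1", ]
  expect_equal(r1$r, 0.2, tolerance = 1e-12)
  expect_equal(r1$rho, 0.2 + 0.2 * 0.96 / 192, tolerance = 1e-12)
  expect_equal(r1$zr, atanh(r1$rho), tolerance = 1e-12)
  expect_equal(r1$v_z, 1 / 97, tolerance = 1e-14)
  # correlation row enters at r directly
  r2 <- out[out$estimate_id == "e2", ]
  expect_equal(r2$r, 0.3, tolerance = 1e-12)
  expect_equal(r2$v_z, 1 / 47, tolerance = 1e-14)
  # CI rows: se recovered, then t = value/se
  r3 <- out[out$estimate_id == "e3", ]
  expect_equal(r3$r, t_to_r(0.095 / se_from_ci(0.095, 0.124), 40),
               tolerance = 1e-12)
  # invariants
  expect_true(all(out$v_z > 0))
  expect_equal(sign(out$zr), sign(out$r))
  expect_equal(tanh(out$zr), out$rho, tolerance = 1e-12)
})

test_that("zero correlation passes through the whole chain as zero", {
  raw <- tibble::tibble(
    study_id = "s", estimate_id = "e", species = "x",
    statistic_kind = "correlation", value = 0, n = 50, year = 2020
  )
  out <- standardize_effects(raw)
  expect_identical(out$zr, 0)
  expect_equal(out$v_z, 1 / 47, tolerance = 1e-14)
})

test_that("standardisation matches an independent composed-formula oracle", {
  withr::with_seed(99, {
    k <- 1000
    t <- runif(k, -5, 5)
    df <- sample(5:300, k, replace = TRUE)
    n <- sample(10:500, k, replace = TRUE)
  })
  raw <- tibble::tibble(
    study_id = "s", estimate_id = sprintf("e%04d", seq_len(1000)),
    species = "x", statistic_kind = "slope_t", value = NA_real_,
    t_value = t, df = df, n = n, year = 2020
  )
  out <- standardize_effects(raw)
  # single-expression evaluation of the composed formulas
  r <- t / sqrt(t^2 + df)
  expected_zr <- atanh(r + r * (1 - r^2) / (2 * (n - 4)))
  expect_equal(out$zr, expected_zr, tolerance = 1e-12)
  expect_equal(out$v_z, 1 / (n - 3), tolerance = 1e-12)
})

test_that("negating the statistic negates zr exactly", {
  raw <- tiny_raw()
  neg <- raw
  neg$value <- -neg$value
  neg$t_value <- -neg$t_value
  # for CI-based rows the interval flips around the negated estimate; keep the
  # same |se| by mirroring the upper bound
  flip <- neg$statistic_kind %in% c("slope_ci", "estimate_ci")
  neg$ci_upper[flip] <- -raw$value[flip] + (raw$ci_upper[flip] - raw$value[flip])
  expect_equal(standardize_effects(neg)$zr, -standardize_effects(raw)$zr,
               tolerance = 1e-14)
})

test_that("standardisation errors carry the estimate id", {
  raw <- tiny_raw()
  raw$df[1] <- NA
  expect_error(standardize_effects(raw), regexp = "e1")
  raw2 <- tiny_raw()[, setdiff(names(tiny_raw()), "n")]
  expect_error(standardize_effects(raw2), class = "tm_error_schema")
})
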