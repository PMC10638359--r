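test_that("slice aggregation is the median", {
  expect_equal(aggregate_slices(rep(47.3, 80)), 47.3)
  expect_equal(aggregate_slices(c(40, 50, 60)), 50)
  expect_equal(aggregate_slices(c(40, 50, 60, 70)), 55)  # even: midpoint
  expect_error(aggregate_slices(numeric(0)), "empty")
  set.seed(1)
  draws <- rnorm(80, 50, 5)
  expect_lt(abs(aggregate_slices(draws) - 50), 3 * 1.2533 * 5 / sqrt(80))
})

test_that("OLS bias fit solves exact and hand-checkable instances", {
  recs <- data.frame(age = c(20, 50, 80),
                     predicted_brain_age = c(29.2, 50.2, 71.2))
  fit <- fit_bias_model(recs, bias_model_spec("marginal", "OLS"))
  expect_equal(fit$coefficients$intercept, 15.2, tolerance = 1e-10)
  expect_equal(fit$coefficients$slope, 0.7, tolerance = 1e-10)
  expect_equal(fit$coef_count, 2L)

  ident <- data.frame(age = c(30, 40, 77), predicted_brain_age = c(30, 40, 77))
  fit_id <- fit_bias_model(ident, bias_model_spec("marginal", "OLS"))
  expect_equal(fit_id$coefficients$intercept, 0, tolerance = 1e-10)
  expect_equal(fit_id$coefficients$slope, 1, tolerance = 1e-10)
})

test_that("bias fits equal independent normal-equation solutions (n <= 10)", {
  for (s in 1:5) {
    set.seed(100 + s)
    n <- sample(4:10, 1)
    age <- runif(n, 20, 90)
    y <- 10 + 0.8 * age + rnorm(n, 0, 3)
    recs <- data.frame(age = age, predicted_brain_age = y)
    fit <- fit_bias_model(recs, bias_model_spec("marginal", "OLS"))
    X <- cbind(1, age)
    beta <- solve(t(X) %*% X, t(X) %*% y)  # oracle: normal equations
    expect_equal(fit$coefficients$intercept, beta[1], tolerance = 1e-8)
    expect_equal(fit$coefficients$slope, beta[2], tolerance = 1e-8)
  }
})

test_that("per-level and WLS fits match reference least-squares routines", {
  cfg <- small_noisy_config(seed = 44, n = 100)
  co <- generate_predictions(build_cohort(cfg), cfg)
  by_mod <- fit_bias_model(co, bias_model_spec("by_modality", "OLS"))
  for (m in unique(co$modality)) {
    ref <- coef(lm(predicted_brain_age ~ age, co[co$modality == m, ]))
    row <- by_mod$coefficients[by_mod$coefficients$level == m, ]
    expect_equal(c(row$intercept, row$slope), unname(ref), tolerance = 1e-8)
  }
  expect_equal(by_mod$coef_count, 2L * length(unique(co$modality)))

  wls <- fit_bias_model(co, bias_model_spec("marginal", "WLS",
                                            wls_grouping = "modality"))
  w <- 1 / as.numeric(table(co$modality)[co$modality])
  ref_w <- coef(lm(predicted_brain_age ~ age, co, weights = w))
  expect_equal(c(wls$coefficients$intercept, wls$coefficients$slope),
               unname(ref_w), tolerance = 1e-8)
})

test_that("small or degenerate levels are flagged, not silently fitted", {
  recs <- data.frame(age = c(20, 50, 80, 30, 40),
                     predicted_brain_age = c(29, 50, 71, 35, 44),
                     modality = c("A", "A", "A", "B", "B"))
  expect_message(fit <- fit_bias_model(recs,
                                       bias_model_spec("by_modality", "OLS")),
                 "unfittable")
  expect_identical(fit$dropped_levels, "B")
  const <- data.frame(age = rep(50, 5), predicted_brain_age = rnorm(5, 50))
  expect_error(fit_bias_model(const, bias_model_spec("marginal", "OLS")),
               "zero age variance")
})

test_that("inverse correction inverts the bias and handles unseen levels", {
  fit <- structure(list(
    spec = bias_model_spec("marginal", "OLS"),
    coefficients = data.frame(level = "(all)", intercept = 15.2, slope = 0.7,
                              n = 100L),
    dropped_levels = character(), coef_count = 2L),
    class = "bias_model_fit")
  recs <- data.frame(predicted_brain_age = c(15.2, 50.2))
  expect_equal(unname(correct_ages(recs, fit)[1]), 0, ignore_attr = TRUE)
  expect_equal(unname(correct_ages(recs, fit)[2]), 50, tolerance = 1e-12,
               ignore_attr = TRUE)

  fit2 <- structure(list(
    spec = bias_model_spec("by_modality", "OLS"),
    coefficients = data.frame(level = c("A", "B"),
                              intercept = c(10, 20), slope = c(0.5, 0.9),
                              n = c(50L, 50L)),
    dropped_levels = character(), coef_count = 4L),
    class = "bias_model_fit")
  rec_c <- data.frame(predicted_brain_age = 29, modality = "C")
  out <- correct_ages(rec_c, fit2)
  expect_equal(unname(out), (29 - 15) / 0.7, tolerance = 1e-12,
               ignore_attr = TRUE)  # mean coefs
  expect_identical(attr(out, "unseen_levels"), "C")

  fit$coefficients$slope <- 0
  expect_error(correct_ages(recs, fit), "correction error")
})

test_that("analytic identities of the marginal correction hold exactly", {
  cfg <- noiseless_config(seed = 10, n = 50)
  co <- generate_predictions(build_cohort(cfg), cfg)
  fit <- fit_bias_model(co, bias_model_spec("marginal", "OLS"))
  expect_equal(unname(correct_ages(co, fit)), co$age, tolerance = 1e-9,
               ignore_attr = TRUE)

  # noisy case: variance scaling and correlation preservation are affine facts
  cfgn <- small_noisy_config(seed = 11, n = 150)
  con <- generate_predictions(build_cohort(cfgn), cfgn)
  fitn <- fit_bias_model(con, bias_model_spec("marginal", "OLS"))
  corrected <- correct_ages(con, fitn)
  expect_equal(var(corrected),
               var(con$predicted_brain_age) / fitn$coefficients$slope^2,
               tolerance = 1e-12)
  expect_equal(cor(corrected, con$age),
               cor(con$predicted_brain_age, con$age), tolerance = 1e-12)
})

test_that("naive correction returns age plus the OLS residual", {
  cfgn <- small_noisy_config(seed = 13, n = 120)
  con <- generate_predictions(build_cohort(cfgn), cfgn)
  fitn <- fit_bias_model(con, bias_model_spec("marginal", "OLS"))
  naive <- naive_correct(con, fitn)
  resid <- con$predicted_brain_age -
    (fitn$coefficients$intercept + fitn$coefficients$slope * con$age)
  expect_equal(naive, con$age + resid, tolerance = 1e-12)
  # same-sample coefficients: residuals exactly orthogonal to age
  expect_lt(abs(sum(resid * (con$age - mean(con$age)))), 1e-6)
  # a record on the fitted line is returned to its chronological age
  on_line <- data.frame(age = 60,
                        predicted_brain_age = fitn$coefficients$intercept +
                          fitn$coefficients$slope * 60)
  expect_equal(naive_correct(on_line, fitn), 60, tolerance = 1e-10)
  by_mod <- fit_bias_model(con, bias_model_spec("by_modality", "OLS"))
  expect_error(naive_correct(con, by_mod), "marginal")
})

test_that("cross-validated selection prefers simple models and finds real structure", {
  one_rep <- function(seed, heterogeneous) {
    cfg <- if (heterogeneous) het_slopes_config(seed = seed, n = 150) else
      small_noisy_config(seed = seed, n = 150)
    co <- generate_predictions(build_cohort(cfg), cfg)
    folds <- suppressWarnings(
      make_cv_folds(unique(co$participant_id), co,
                    strata = strata_spec(variables = c("sex", "age_bin")),
                    seed = seed))
    cands <- list(bias_model_spec("marginal", "OLS"),
                  bias_model_spec("by_modality", "OLS"),
                  bias_model_spec("by_scanner", "OLS"))
    select_bias_model_cv(co, cands, folds)
  }
  hom <- one_rep(71, heterogeneous = FALSE)
  expect_identical(hom$selected$form, "marginal")
  het <- one_rep(72, heterogeneous = TRUE)
  expect_identical(het$selected$form, "by_modality")
  expect_equal(nrow(hom$table), 3L)
  # single candidate: trivially selected
  cfg <- small_noisy_config(seed = 73, n = 60)
  co <- generate_predictions(build_cohort(cfg), cfg)
  folds <- suppressWarnings(
    make_cv_folds(unique(co$participant_id), co,
                  strata = strata_spec(variables = "sex"), seed = 1))
  only <- select_bias_model_cv(co, list(bias_model_spec("marginal", "OLS")),
                               folds)
  expect_identical(only$selected$form, "marginal")
})

test_that("bias fit JSON round-trips", {
  cfg <- small_noisy_config(seed = 55, n = 80)
  co <- generate_predictions(build_cohort(cfg), cfg)
  fit <- fit_bias_model(co, bias_model_spec("by_modality", "OLS"))
  path <- withr::local_tempfile(fileext = ".json")
  write_bias_fit(fit, path)
  back <- read_bias_fit(path)
  expect_equal(back$coefficients$intercept, fit$coefficients$intercept,
               tolerance = 1e-12)
  expect_identical(back$spec$form, "by_modality")
  expect_equal(correct_ages(co, back), correct_ages(co, fit),
               tolerance = 1e-12)
})

test_that("bias model specs validate their invariants", {
  expect_error(bias_model_spec("marginal", "WLS"), "wls_grouping")
  expect_error(bias_model_spec("marginal", "OLS", wls_grouping = "modality"),
               "only meaningful")
})
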