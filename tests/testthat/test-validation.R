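test_that("the c-statistic equals brute-force pair counting", {
  expect_equal(c_statistic(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(c_statistic(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(c_statistic(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(c_statistic(runif(5), rep(1, 5)),
               class = "pedfl_domain_error")
  set.seed(12)
  for (r in 1:100) {
    n <- sample(10:200, 1)
    pred <- round(runif(n), sample(c(1, 2, 3), 1)) # induce ties
    outcome <- rbinom(n, 1, 0.4)
    if (length(unique(outcome)) < 2) next
    expect_equal(c_statistic(pred, outcome), bf_cstat(pred, outcome))
  }
})

test_that("the R-squared family reproduces the published fit statistics", {
  phi <- 642 / 1672
  # invert the printed Cox-Snell values into Nagelkerke on this prevalence
  ll0 <- 1672 * (phi * log(phi) + (1 - phi) * log(1 - phi))
  r_bmi <- r2_family(loglik_model = ll0 - 1672 / 2 * log(1 - 0.26),
                     n = 1672, event_fraction = phi)
  expect_equal(r_bmi$cox_snell, 0.26, tolerance = 1e-10)
  expect_equal(round(r_bmi$nagelkerke, 2), 0.35)
  r_wc <- r2_family(loglik_model = ll0 - 1672 / 2 * log(1 - 0.25),
                    n = 1672, event_fraction = phi)
  expect_equal(round(r_wc$nagelkerke, 2), 0.34)
  # degenerate and error paths
  r0 <- r2_family(loglik_null = -100, loglik_model = -100, n = 50)
  expect_equal(r0$cox_snell, 0)
  expect_equal(r0$nagelkerke, 0)
  expect_error(r2_family(loglik_null = -10, loglik_model = -11, n = 50),
               "below the null")
})

test_that("information criteria follow their algebraic identities", {
  # at n = 1 the BIC penalty vanishes (ln 1 = 0)
  expect_equal(aic_bic(0, 1, 1), list(aic = 2, bic = 0))
  set.seed(3)
  for (r in 1:10) {
    ll <- -runif(1, 10, 1000); k <- sample(1:12, 1); n <- sample(20:5000, 1)
    ic <- aic_bic(ll, k, n)
    expect_equal(ic$bic - ic$aic, k * (log(n) - 2))
  }
  # the printed BIC - AIC gap of ~48 identifies k = 9 parameters at
  # n = 1672: the published AIC of 1746 implies loglik = -864, whose BIC
  # is then 1728 + 9 ln(1672) = 1794.8, matching the printed 1794
  expect_equal(round(9 * (log(1672) - 2)), 49)
  ic <- aic_bic(-864, 9, 1672)
  expect_equal(ic$aic, 1746)
  expect_equal(round(ic$bic), 1795)
})

test_that("apparent calibration of a training-data MLE is exact", {
  d <- sample_cohort(generator_config(n = 1672, seed = 55))
  fit <- fit_logistic(bmi_design(d), d$fl)
  cal <- calibration_assess(fit$fitted, d$fl, B_ci = 25, seed = 1)
  expect_equal(cal$weak$slope, 1, tolerance = 1e-6)
  expect_equal(cal$weak$intercept, 0, tolerance = 1e-6)
  expect_equal(cal$mean$mean_predicted, cal$mean$observed_rate,
               tolerance = 1e-9)
  expect_true(all(cal$moderate$smoothed_observed >= 0 &
                    cal$moderate$smoothed_observed <= 1))
})

test_that("miscalibrated predictions are diagnosed", {
  set.seed(31)
  n <- 4000
  p_true <- plogis(rnorm(n, -0.5, 1.2))
  y <- rbinom(n, 1, p_true)
  over <- plogis(2 * qlogis(p_true)) # overconfident by a factor 2 on logit
  cal <- calibration_assess(over, y, B_ci = 40, seed = 2)
  expect_equal(cal$weak$slope, 0.5, tolerance = 0.07)
  expect_true(cal$weak$slope_ci[1] < cal$weak$slope &
                cal$weak$slope < cal$weak$slope_ci[2])
  expect_error(calibration_assess(rep(0.38, n), y, B_ci = 5),
               class = "pedfl_domain_error")
  expect_error(calibration_assess(c(0, runif(n - 1)), y, B_ci = 5),
               class = "pedfl_domain_error")
})

test_that("the observed-rate interval matches the published 36-41%", {
  ci <- pedfl:::wilson_ci(642, 1672)
  expect_equal(round(100 * ci[["lower"]]), 36)
  expect_equal(round(100 * ci[["upper"]]), 41)
})

test_that("calibration bootstrap intervals are seed-reproducible", {
  d <- sample_cohort(generator_config(n = 600, seed = 64))
  fit <- fit_logistic(bmi_design(d), d$fl)
  c1 <- calibration_assess(fit$fitted, d$fl, B_ci = 30, seed = 7)
  c2 <- calibration_assess(fit$fitted, d$fl, B_ci = 30, seed = 7)
  expect_identical(c1$weak, c2$weak)
})

test_that("calibration plots export a re-renderable curve", {
  d <- sample_cohort(generator_config(n = 800, seed = 28))
  cal <- calibration_assess(d$risk, d$fl, B_ci = 20, seed = 3)
  csv <- withr::local_tempfile(fileext = ".csv")
  p <- calibration_plot(cal, csv_path = csv)
  expect_s3_class(p, "ggplot")
  back <- utils::read.csv(csv)
  expect_equal(back$smoothed_observed, cal$moderate$smoothed_observed)
  # self-simulated risks are well calibrated over the bulk of the range
  mid <- cal$moderate$grid_risk >= 0.1 & cal$moderate$grid_risk <= 0.7
  expect_lt(max(abs(cal$moderate$smoothed_observed[mid] -
                      cal$moderate$grid_risk[mid])), 0.1)
})

test_that("the performance report assembles all published measures", {
  d <- sample_cohort(generator_config(n = 1672, seed = 70))
  rep <- performance_report(d$risk, d$fl, k = 9, B_ci = 40, seed = 2)
  expect_gt(rep$c_statistic, 0.75)
  expect_true(rep$c_ci[1] < rep$c_statistic & rep$c_statistic < rep$c_ci[2])
  expect_lt(rep$r2$cox_snell, rep$r2$max_cox_snell)
  expect_equal(rep$r2$nagelkerke,
               rep$r2$cox_snell / rep$r2$max_cox_snell)
  expect_equal(rep$bic - rep$aic, 9 * (log(1672) - 2))
})
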