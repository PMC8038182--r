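test_that("fp_transform reproduces the hand-computed transforms", {
  t_alt <- fp_term("alt", c(-2, -1), scale = 100)
  expect_equal(unname(fp_transform(100, t_alt)), cbind(1, 1))
  expect_equal(unname(fp_transform(23, t_alt)),
               cbind((100 / 23)^2, 100 / 23), tolerance = 1e-12)
  expect_equal(unname(fp_transform(23, t_alt))[1, ],
               c(18.9036, 4.34783), tolerance = 1e-4)
  t_homa <- fp_term("homa", c(1, 2), scale = 10)
  expect_equal(unname(fp_transform(2.4, t_homa)), cbind(0.24, 0.0576))
  # power 0 is the natural log; a repeated power adds the log-product term
  expect_equal(unname(fp_transform(exp(2), fp_term("x", 0))), cbind(2))
  rep2 <- fp_transform(5, fp_term("x", c(2, 2)))
  expect_equal(unname(rep2), cbind(25, 25 * log(5)))
  expect_error(fp_transform(c(3, 0), fp_term("x", 1)),
               class = "pedfl_domain_error")
  expect_error(fp_term("x", c(1, 2, 3)))
  expect_error(fp_term("x", 1.7))
})

test_that("the logistic fitter agrees with closed forms", {
  # intercept-only: logit of the event fraction
  y <- rep(c(1, 0), c(13, 27))
  f <- fit_logistic(matrix(1, 40, 1, dimnames = list(NULL, "intercept")), y)
  expect_equal(unname(f$coefficients), qlogis(13 / 40), tolerance = 1e-7)
  # single binary covariate: the log odds ratio of the 2x2 table
  set.seed(2)
  x <- rbinom(400, 1, 0.5)
  y <- rbinom(400, 1, plogis(-0.4 + 0.9 * x))
  f <- fit_logistic(cbind(intercept = 1, x = x), y)
  tab <- table(x, y)
  lor <- log(tab[2, 2] * tab[1, 1] / (tab[2, 1] * tab[1, 2]))
  expect_equal(unname(f$coefficients["x"]), lor, tolerance = 1e-7)
  # log-likelihood matches the binomial formula at the fitted values
  expect_equal(f$loglik,
               sum(y * log(f$fitted) + (1 - y) * log(1 - f$fitted)),
               tolerance = 1e-10)
})

test_that("degenerate designs raise typed errors", {
  set.seed(4)
  x <- rnorm(80)
  y_sep <- as.integer(x > 0.2)
  expect_error(fit_logistic(cbind(intercept = 1, x = x), y_sep),
               class = "pedfl_separation")
  y <- rbinom(80, 1, 0.5)
  expect_error(
    fit_logistic(cbind(intercept = 1, a = x, b = 2 * x), y),
    "rank deficient.*b"
  )
  expect_error(fit_logistic(cbind(1, x), c(y[-1], 2)),
               class = "pedfl_domain_error")
})

test_that("best FP deviances equal an exhaustive independent search", {
  set.seed(10)
  for (n in c(220, 500)) {
    z <- rexp(n) + 0.3
    y <- rbinom(n, 1, plogis(-1 + 0.8 * log(z)))
    d <- data.frame(fl = y, v = z)
    dec <- fsp_select(d, "v", "fl")
    bf <- bf_fp_deviances(d, "v", "fl")
    expect_equal(unname(dec$deviances["fp1"]), bf$fp1, tolerance = 1e-6)
    expect_equal(unname(dec$deviances["fp2"]), bf$fp2, tolerance = 1e-6)
    # deviance hierarchy: null >= linear >= best FP1 >= best FP2
    dv <- dec$deviances
    expect_true(dv["null"] >= dv["linear"] - 1e-8)
    expect_true(dv["linear"] >= dv["fp1"] - 1e-8)
    expect_true(dv["fp1"] >= dv["fp2"] - 1e-8)
  }
})

test_that("the closed test recovers known functional forms", {
  set.seed(14)
  n <- 5000
  x <- rlnorm(n, 3, 0.6)
  y_lin <- rbinom(n, 1, plogis(-2 + 0.08 * x))
  expect_equal(fsp_select(data.frame(fl = y_lin, v = x), "v", "fl")$form,
               "linear")
  # simulate from the published ALT shape: powers (-2, -1) on z = alt/100
  d <- sample_cohort(generator_config(n = n, seed = 15))
  lp <- 1.4 + 0.036 * (d$alt / 100)^-2 - 0.767 * (d$alt / 100)^-1
  d$fl <- rbinom(n, 1, plogis(lp))
  dec <- fsp_select(d, "alt", "fl", scale = 100)
  expect_equal(dec$form, "FP2")
  expect_equal(dec$powers, c(-2, -1))
})

test_that("closed-test type-I error for a null variable is near alpha", {
  set.seed(41)
  n <- 2000
  reps <- 500
  omitted <- logical(reps)
  for (r in seq_len(reps)) {
    d <- data.frame(fl = rbinom(n, 1, 0.38), v = rlnorm(n))
    omitted[r] <- fsp_select(d, "v", "fl")$form == "omitted"
  }
  rate <- 1 - mean(omitted)
  mc2 <- 2 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), mc2 + 0.01)
})

test_that("cycling reduces to single-variable selection and handles
           degenerate inputs", {
  d <- sample_cohort(generator_config(n = 1500, seed = 22))
  one <- mfp_cycle(d, "fl", "alt")
  solo <- fsp_select(d, "alt", "fl", scale = 100)
  expect_equal(one$state$alt$form, solo$form)
  expect_equal(one$state$alt$powers, solo$powers)
  empty <- mfp_cycle(d, "fl", character(0))
  expect_equal(empty$fit$k, 1)
  expect_equal(unname(empty$fit$coefficients), qlogis(mean(d$fl)),
               tolerance = 1e-6)
})

test_that("joint cycling on the calibrated cohort keeps the true drivers", {
  d <- sample_cohort(generator_config(n = 1672, seed = 40))
  m <- mfp_cycle(d, "fl", c("age", "bmi", "alt", "homa", "tg", "ur"))
  expect_true(m$stable)
  expect_equal(m$state$alt$form, "FP2")
  expect_equal(m$state$alt$powers, c(-2, -1))
  expect_false(m$state$bmi$form == "omitted")
  expect_false(m$state$age$form == "omitted")
})

test_that("bootstrap inclusion fractions are reproducible percentages", {
  d <- sample_cohort(generator_config(n = 400, seed = 6))
  b1 <- bootstrap_bif(d, "fl", c("alt", "tg"), B = 1, seed = 5)
  expect_true(all(b1$summary$bif1 %in% c(0, 100)))
  b5a <- bootstrap_bif(d, "fl", c("alt", "tg"), B = 5, seed = 5)
  b5b <- bootstrap_bif(d, "fl", c("alt", "tg"), B = 5, seed = 5)
  expect_identical(b5a$summary, b5b$summary)
  expect_true(all(b5a$summary$bif2 <= b5a$summary$bif1))
  tab <- bif_table(b5a)
  expect_equal(names(tab), c("variable", "BIF-1", "EXP-1", "BIF-2", "EXP-2"))
})

test_that("final fits carry percentile intervals around the estimate", {
  d <- sample_cohort(generator_config(n = 800, seed = 13))
  terms <- list(age = "linear",
                alt = fp_term("alt", c(-2, -1), scale = 100),
                ur = "linear")
  fit <- fit_final(d, "fl", terms, B_ci = 40, seed = 2)
  expect_true(all(fit$ci[, "lower"] <= fit$coefficients))
  expect_true(all(fit$ci[, "upper"] >= fit$coefficients))
  expect_equal(fit$k, 5)
  tiny <- d[1:4, ]
  expect_error(fit_final(tiny, "fl", terms, B_ci = 2, seed = 1),
               "parameters")
})
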