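test_that("copula construction maps Spearman targets to latent scale", {
  m <- default_marginals()[c("ins", "glu")]
  tgt <- matrix(c(1, 0.98, 0.98, 1), 2,
                dimnames = list(c("ins", "glu"), c("ins", "glu")))
  cop <- build_copula(tgt, m)
  expect_equal(cop$latent["ins", "glu"], 2 * sin(0.98 * pi / 6),
               tolerance = 1e-12)
  expect_false(cop$repair$repaired) # 2x2 is always positive definite
  tgt0 <- tgt; tgt0["ins", "glu"] <- tgt0["glu", "ins"] <- 0
  expect_equal(build_copula(tgt0, m)$latent["ins", "glu"], 0)
  tgt1 <- tgt; tgt1["ins", "glu"] <- tgt1["glu", "ins"] <- 1
  expect_error(build_copula(tgt1, m), class = "pedfl_domain_error")
})

test_that("an infeasible target triangle is repaired to positive definite", {
  vars <- c("alt", "tg", "ur")
  m <- default_marginals()[vars]
  tgt <- diag(3)
  dimnames(tgt) <- list(vars, vars)
  tgt["alt", "tg"] <- tgt["tg", "alt"] <- 0.9
  tgt["alt", "ur"] <- tgt["ur", "alt"] <- 0.9
  tgt["tg", "ur"] <- tgt["ur", "tg"] <- -0.9 # jointly impossible
  cop <- build_copula(tgt, m)
  expect_true(cop$repair$repaired)
  expect_gt(cop$repair$max_perturbation, 0)
  expect_gt(min(eigen(cop$latent, symmetric = TRUE)$values), 0)
  expect_equal(diag(cop$latent), rep(1, 3), ignore_attr = TRUE)
})

test_that("the study copula inverts discrete-margin attenuation", {
  cop <- build_copula(default_spearman_targets(), default_marginals())
  expect_false(cop$repair$repaired)
  # the ordinal pubertal stage needs a latent correlation well above its
  # 0.82 Spearman target to survive discretisation
  expect_gt(cop$latent["age", "pub"], 0.88)
  d <- sample_cohort(generator_config(n = 20000, seed = 17), copula = cop)
  expect_equal(cor(d$age, d$pub, method = "spearman"), 0.82,
               tolerance = 0.02)
  expect_equal(cor(d$male, d$alt, method = "spearman"), 0.39,
               tolerance = 0.02)
})

test_that("sampling is bit-reproducible and respects record invariants", {
  cfg <- generator_config(n = 500, seed = 99)
  d1 <- sample_cohort(cfg)
  d2 <- sample_cohort(cfg)
  expect_identical(d1, d2)
  expect_silent(validate_cohort(d1))
  expect_equal(d1$homa, d1$ins * d1$glu / 405)
  expect_equal(d1$map, d1$sbp / 3 + 2 * d1$dbp / 3)
  expect_true(all(d1$age >= 5 & d1$age <= 18))
  # a single subject is a complete valid record
  one <- sample_cohort(generator_config(n = 1, seed = 2))
  expect_equal(nrow(one), 1)
  expect_silent(validate_cohort(one))
  # the generator does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(sample_cohort(generator_config(n = 10, seed = 5)))
  expect_identical(rnorm(1), before)
})

test_that("sampled quartiles converge to the printed anchors", {
  d <- sample_cohort(generator_config(n = 20000, seed = 31))
  marg <- default_marginals()
  for (v in c("age", "bmi", "wc", "alt", "glu", "ins", "tg", "ur", "crp")) {
    q <- quantile(d[[v]], c(0.25, 0.5, 0.75), names = FALSE)
    expect_equal(q, marg[[v]]$anchors, tolerance = 0.03,
                 label = sprintf("quartiles of %s", v))
  }
  # derived MAP reproduces its printed quartiles emergently
  expect_equal(quantile(d$map, c(0.25, 0.5, 0.75), names = FALSE),
               c(87, 93, 97), tolerance = 0.02)
})

test_that("realized rank correlations track the targets at study size", {
  d <- sample_cohort(generator_config(n = 1672, seed = 8))
  tgt <- default_spearman_targets()
  sampled <- setdiff(rownames(tgt), c("sbp", "dbp"))
  rho <- cor(as.matrix(d[sampled]), method = "spearman")
  dev <- abs(rho - tgt[sampled, sampled])
  expect_lt(max(dev[upper.tri(dev)]), 0.08)
})

test_that("outcome simulation closes the loop with the published scores", {
  d <- sample_cohort(generator_config(n = 1672, seed = 4))
  # mean predicted risk tracks the realized prevalence (mean calibration)
  expect_equal(mean(d$risk), mean(d$fl), tolerance = 0.03)
  # prevalence within 2 percentage points of the published 38.4%
  expect_lt(abs(mean(d$fl) - 0.384), 0.02)
  # emergent near-unit correlation between insulin and derived HOMA-IR
  expect_gt(cor(d$ins, d$homa, method = "spearman"), 0.95)
})

test_that("coefficient recovery is unbiased to Monte Carlo precision", {
  rec <- recovery_experiment(generator_config(n = 1672), replicates = 10,
                             seed = 33)
  expect_equal(attr(rec, "n_converged"), 10)
  expect_equal(rec$term[1], "intercept")
  expect_equal(nrow(rec), 9)
  # loose consistency screen at 10 replicates; the acceptance suite runs
  # the full 50-replicate version
  expect_true(all(abs(rec$bias) < 4 * rec$mc_se + 1e-8))
  expect_true(all(rec$rmse >= abs(rec$bias) - 1e-12))
})

test_that("generator overrides and user outcome models are honoured", {
  cfg <- generator_config(n = 4000, seed = 12, male_prop = 0.25,
                          stage_probs = rep(1, 5))
  d <- sample_cohort(cfg)
  expect_equal(mean(d$male), 0.25, tolerance = 0.03)
  expect_equal(unname(table(d$pub)) / 4000, rep(0.2, 5), tolerance = 0.1,
               ignore_attr = TRUE)
  # a user maximum-likelihood fit can drive the outcome simulation
  base <- sample_cohort(generator_config(n = 1200, seed = 3))
  fit <- fit_final(base, "fl",
                   list(age = "linear",
                        alt = fp_term("alt", c(-2, -1), scale = 100)),
                   B_ci = 5, seed = 1)
  d2 <- sample_cohort(generator_config(n = 800, seed = 9,
                                       outcome_model = fit))
  expect_equal(d2$risk, predict(fit, d2))
  expect_true(all(d2$fl %in% c(0, 1)))
  expect_equal(predict(fit, base[1:5, ]),
               plogis(predict(fit, base[1:5, ], type = "link")))
})
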