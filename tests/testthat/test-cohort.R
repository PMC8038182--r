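test_that("derived variables match their closed forms", {
  expect_equal(derive_homa_ir(13, 79), 13 * 79 / 405)
  expect_equal(derive_homa_ir(13, 79), 2.5358, tolerance = 1e-4)
  expect_equal(derive_homa_ir(0, 90), 0)
  expect_equal(derive_homa_ir(9, 74), 1.6444, tolerance = 1e-4)
  expect_equal(derive_map(120, 80), 93.3333, tolerance = 1e-4)
  expect_equal(derive_map(130, 70), 90)
  expect_equal(derive_map(85, 85), 85)
  # property: exact formulas on random positive inputs
  set.seed(1)
  ins <- runif(50, 1, 40); glu <- runif(50, 60, 120)
  expect_equal(derive_homa_ir(ins, glu), ins * glu / 405)
  dbp <- runif(50, 50, 90); sbp <- dbp + runif(50, 5, 60)
  expect_equal(derive_map(sbp, dbp), sbp / 3 + 2 * dbp / 3)
  expect_error(derive_homa_ir(-1, 80), class = "pedfl_domain_error")
  expect_error(derive_homa_ir(10, 0), class = "pedfl_domain_error")
  expect_error(derive_map(80, 120), class = "pedfl_domain_error")
})

test_that("cohort validation enforces the row-level invariants", {
  d <- tiny_cohort()
  expect_silent(validate_cohort(d))
  d_bad <- d; d_bad$alt[2] <- NA
  expect_error(validate_cohort(d_bad), "missing value")
  d_bad <- d; d_bad$alt[1] <- -3
  expect_error(validate_cohort(d_bad), "strictly positive")
  d_bad <- d; d_bad$pub[1] <- 7
  expect_error(validate_cohort(d_bad), "1..5")
  d_bad <- d; d_bad$homa[1] <- d$homa[1] + 0.01
  expect_error(validate_cohort(d_bad), "homa")
  # fl must agree with the ultrasound grade when present
  d2 <- d; d2$fl_grade <- c(0, 2, 0)
  expect_silent(validate_cohort(d2))
  d2$fl_grade <- c(1, 2, 0)
  expect_error(validate_cohort(d2), "fl_grade")
})

test_that("describe_cohort uses median and interpolated quartiles", {
  one <- tiny_cohort()[2, ]
  s <- describe_cohort(one)
  alt_row <- s[s$variable == "alt", ]
  expect_equal(alt_row$median, 42)
  expect_equal(alt_row$p25, alt_row$p75)
  # the chosen quantile rule on 1..5: median 3, quartiles (2, 4)
  d <- tiny_cohort()[rep(1, 5), ]
  d$alt <- 1:5
  d$homa <- derive_homa_ir(d$ins, d$glu)
  s <- describe_cohort(d)
  expect_equal(unlist(s[s$variable == "alt", c("p25", "median", "p75")]),
               c(p25 = 2, median = 3, p75 = 4))
  expect_error(describe_cohort(tiny_cohort()[0, ]))
  # grouped summaries report each sex side by side
  s <- describe_cohort(tiny_cohort(), group_by = "male")
  expect_true(all(c("total", "male_0", "male_1") %in% names(s)))
})

test_that("synthetic cohort summaries sit near the published anchors", {
  d <- sample_cohort(generator_config(n = 1672, seed = 271))
  s <- describe_cohort(d)
  expect_lt(abs(s[s$variable == "alt", "median"] - 23) / 23, 0.10)
  fl_row <- s[s$variable == "fl" & s$level == 1, ]
  expect_lt(abs(fl_row$proportion - 0.384), 0.04)
})

test_that("spearman screening matches a brute-force component search", {
  set.seed(7)
  n <- 300
  base <- rnorm(n)
  d <- data.frame(
    a = base + rnorm(n, sd = 0.4),        # a-b-c form one cluster
    b = base + rnorm(n, sd = 0.4),
    c = base + rnorm(n, sd = 0.9),        # linked through a/b only
    x = rnorm(n), y = rnorm(n),
    z = rexp(n)
  )
  scr <- spearman_screen(d, names(d), threshold = 0.5, priority = c("a", "x"))
  bf <- bf_clusters(scr$spearman, 0.5)
  got <- lapply(scr$clusters, sort)
  expect_setequal(lapply(got, paste, collapse = "+"),
                  lapply(bf, paste, collapse = "+"))
  big <- got[[which(lengths(got) > 1)[1]]]
  expect_true("a" %in% big)
  expect_equal(scr$kept[lengths(scr$clusters) > 1][1], "a")
})

test_that("screening is rank-based and handles antitone and null cases", {
  set.seed(21)
  d <- data.frame(u = rexp(100), v = rnorm(100), w = runif(100))
  d$neg <- -d$u
  scr <- spearman_screen(d, c("u", "neg", "v", "w"), threshold = 0.6,
                         priority = "u")
  expect_equal(scr$spearman["u", "neg"], -1)
  expect_setequal(scr$clusters[[which(lengths(scr$clusters) > 1)]],
                  c("u", "neg"))
  # invariance under strictly monotone transforms
  d2 <- d
  d2$u <- exp(d2$u); d2$v <- qlogis(plogis(d2$v)); d2$w <- d2$w^3
  scr2 <- spearman_screen(d2, c("u", "neg", "v", "w"), threshold = 0.6)
  expect_equal(scr2$spearman, scr$spearman, tolerance = 1e-12)
  # independent columns produce no multi-variable clusters
  set.seed(5)
  ind <- as.data.frame(matrix(rnorm(500 * 4), 500))
  scr3 <- spearman_screen(ind, names(ind), threshold = 0.6)
  expect_true(all(lengths(scr3$clusters) == 1))
  ind$flat <- 1
  expect_error(spearman_screen(ind, names(ind)), "constant")
})

test_that("screening the calibrated cohort flags the published clusters", {
  d <- sample_cohort(generator_config(n = 1672, seed = 11))
  scr <- spearman_screen(d, c("age", "pub", "bmi", "wc", "alt", "ast",
                              "ggt", "ins", "homa", "tg", "ur"),
                         threshold = 0.6,
                         priority = c("age", "bmi", "alt", "homa"))
  expect_equal(scr$spearman["age", "pub"], 0.82, tolerance = 0.05)
  expect_equal(scr$spearman["bmi", "wc"], 0.77, tolerance = 0.05)
  expect_equal(scr$spearman["alt", "ast"], 0.81, tolerance = 0.05)
  expect_gt(scr$spearman["ins", "homa"], 0.95)
  in_one_cluster <- function(a, b) {
    any(vapply(scr$clusters, function(cl) all(c(a, b) %in% cl), logical(1)))
  }
  expect_true(in_one_cluster("age", "pub"))
  expect_true(in_one_cluster("bmi", "wc"))
  expect_true(in_one_cluster("alt", "ast"))
  expect_true(in_one_cluster("ins", "homa"))
})

test_that("cohort CSV round-trips exactly and rejects incomplete files", {
  d <- sample_cohort(generator_config(n = 40, seed = 3))
  d$risk <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(d, path)
  expect_match(readLines(path, n = 1), "synthetic seed=3")
  d2 <- read_cohort(path)
  expect_equal(as.data.frame(d2), as.data.frame(d), ignore_attr = TRUE)
  # a 3-row fixture reads to 3 subjects
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(tiny_cohort(), path3)
  expect_equal(nrow(read_cohort(path3)), 3)
  # blank cell -> error naming the cell; complete data are assumed
  tc <- tiny_cohort(); tc$ins[2] <- NA
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tc, bad, row.names = FALSE)
  expect_error(read_cohort(bad), "row 2, column 'ins'")
  tc <- tiny_cohort(); tc$wc <- NULL
  bad2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tc, bad2, row.names = FALSE)
  expect_error(read_cohort(bad2), "wc")
})

test_that("metabolic component flags follow the supplied cutoffs", {
  d <- tiny_cohort()
  d$sbp <- c(118, 132, 125)
  d$dbp <- c(76, 84, 80)
  cut <- list(wc = 94, glu = 100, hdlc = 40, tg = 150, sbp = 130, dbp = 85)
  f <- metabolic_flags(d, cut)
  expect_equal(f$large_wc, as.integer(d$wc >= 94))
  expect_equal(f$low_hdl, as.integer(d$hdlc < 40))
  expect_equal(f$high_bp, as.integer(d$sbp >= 130 | d$dbp >= 85))
  expect_equal(f$met_syndrome, as.integer(
    f$large_wc == 1 & (f$high_glu + f$low_hdl + f$high_tg + f$high_bp) >= 2
  ))
  # no consensus defaults are baked in: cutoffs are mandatory
  expect_error(metabolic_flags(d, list(wc = 94)), "cutoffs")
})
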