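# shared fixtures and independent oracles, built in code

# a tiny fully valid cohort for I/O and descriptive tests
tiny_cohort <- function() {
  data.frame(
    fl = c(0, 1, 0), male = c(0, 1, 1), age = c(12, 15, 17),
    pub = c(2, 4, 5), bmi = c(31, 38, 34), wc = c(98, 118, 106),
    alt = c(18, 42, 25), ast = c(19, 30, 22), ggt = c(13, 24, 16),
    glu = c(76, 81, 79), ins = c(9, 19, 13),
    homa = c(9, 19, 13) * c(76, 81, 79) / 405,
    hdlc = c(48, 36, 44), ldlc = c(92, 120, 104), tg = c(70, 130, 88),
    map = c(88, 98, 92), ur = c(5.1, 7.0, 6.1), crp = c(0.3, 0.9, 0.4)
  )
}

# brute-force concordance: loop over all case/non-case pairs, ties = 1/2
bf_cstat <- function(pred, outcome) {
  cases <- pred[outcome == 1]
  controls <- pred[outcome == 0]
  tot <- 0
  for (a in cases) {
    for (b in controls) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(cases) * length(controls))
}

# brute-force collinearity clusters: repeated closure over all pairs
bf_clusters <- function(rho, threshold) {
  vars <- rownames(rho)
  groups <- as.list(vars)
  repeat {
    merged <- FALSE
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (j <= i) next
        hit <- any(abs(rho[groups[[i]], groups[[j]], drop = FALSE]) >
                     threshold)
        if (hit) {
          groups[[i]] <- c(groups[[i]], groups[[j]])
          groups[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  lapply(groups, sort)
}

# independent degree-1/degree-2 FP deviance search via stats::glm
bf_fp_deviances <- function(data, variable, outcome, scale = 1) {
  z <- data[[variable]] / scale
  y <- data[[outcome]]
  powers <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)
  tr <- function(p) if (p == 0) log(z) else z^p
  dev <- function(x) {
    suppressWarnings(stats::glm(y ~ x, family = stats::binomial())$deviance)
  }
  d1 <- vapply(powers, function(p) dev(tr(p)), numeric(1))
  d2 <- c()
  for (i in seq_along(powers)) {
    for (j in i:length(powers)) {
      x <- if (i == j) cbind(tr(powers[i]), tr(powers[i]) * log(z)) else
        cbind(tr(powers[i]), tr(powers[j]))
      d2 <- c(d2, dev(x))
    }
  }
  list(fp1 = min(d1), fp2 = min(d2))
}

# design matrix of the published BMI model, assembled from exported pieces
bmi_design <- function(d) {
  cbind(intercept = 1, age = d$age, bmi = d$bmi,
        fp_transform(d$alt, fp_term("alt", c(-2, -1), scale = 100)),
        fp_transform(d$homa, fp_term("homa", c(1, 2), scale = 10)),
        tg = d$tg, ur = d$ur)
}
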