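# Marginal models for the synthetic generator. Each continuous variable is
# summarised in the source tables only by its quartiles, so the marginal is a
# quantile function: piecewise linear in the standard-normal quantile on the
# log scale through the three anchors, with linear (lognormal-type) tail
# extension beyond the outer anchors.

#' Quantile-anchored marginal specification
#'
#' Defines a positive continuous marginal from its printed quartiles. The
#' quantile function is piecewise linear in the standard-normal quantile on
#' the log scale through `(p25, p50, p75)` and extends the adjacent segment's
#' slope into each tail. Tied anchors (values recorded on a coarse grid, e.g.
#' blood pressure on a 5 mm Hg grid) are allowed and produce an atom at the
#' tied value; a flat adjacent segment falls back to the overall p25-p75
#' slope for its tail.
#'
#' @param name Variable name.
#' @param p25,p50,p75 Quartile anchors (weakly increasing, positive).
#' @param lower,upper Support bounds; sampled values are clamped.
#' @return An object of class `fl_marginal`.
#' @export
marginal_spec <- function(name, p25, p50, p75, lower = 0, upper = Inf) {
  stopifnot(p25 > 0, p25 <= p50, p50 <= p75, p25 < p75, lower >= 0)
  structure(
    list(name = name, anchors = c(p25, p50, p75), lower = lower,
         upper = upper, type = "continuous"),
    class = "fl_marginal"
  )
}

# marginal for a 0/1 variable, sampled by thresholding the latent normal
binary_marginal <- function(name, prob) {
  stopifnot(prob > 0, prob < 1)
  structure(list(name = name, prob = prob, type = "binary"),
            class = "fl_marginal")
}

# marginal for an ordinal variable with given level probabilities
ordinal_marginal <- function(name, probs, levels = seq_along(probs)) {
  stopifnot(all(probs > 0), abs(sum(probs) - 1) < 1e-8)
  structure(list(name = name, probs = probs, levels = levels,
                 type = "ordinal"),
            class = "fl_marginal")
}

# evaluate a marginal's quantile function at latent standard-normal values z
marginal_quantile <- function(m, z) {
  switch(m$type,
    continuous = {
      zk <- stats::qnorm(c(0.25, 0.5, 0.75))
      l <- log(m$anchors)
      s12 <- (l[2] - l[1]) / (zk[2] - zk[1])
      s23 <- (l[3] - l[2]) / (zk[3] - zk[2])
      sov <- (l[3] - l[1]) / (zk[3] - zk[1])
      tlo <- if (s12 > 0) s12 else sov
      thi <- if (s23 > 0) s23 else sov
      lq <- ifelse(z < zk[1], l[1] + tlo * (z - zk[1]),
            ifelse(z < zk[2], l[1] + s12 * (z - zk[1]),
            ifelse(z < zk[3], l[2] + s23 * (z - zk[2]),
                              l[3] + thi * (z - zk[3]))))
      pmin(pmax(exp(lq), m$lower), m$upper)
    },
    binary = as.integer(z > stats::qnorm(1 - m$prob)),
    ordinal = m$levels[findInterval(z, stats::qnorm(cumsum(m$probs))[
      -length(m$probs)]) + 1L],
    stop("unknown marginal type")
  )
}

# discrete mid-rank representation used by the Spearman inversion:
# thresholds on the latent scale, mid-rank cdf values, and midrank variance
marginal_midranks <- function(m) {
  probs <- switch(m$type,
    binary = c(1 - m$prob, m$prob),
    ordinal = m$probs,
    return(NULL) # continuous margins handled in closed form
  )
  cum <- cumsum(probs)
  list(tau = stats::qnorm(cum[-length(cum)]),
       fs = c(0, cum[-length(cum)]) + probs / 2,
       v = (1 - sum(probs^3)) / 12)
}

#' Default marginal specifications of the obesity cohort
#'
#' Quartile anchors of the continuous predictors (and latent prevalences of
#' sex and pubertal stage) as printed in the source cohort's descriptive
#' table: 1672 obese children, median age 15 years. Age is clamped to the
#' cohort's stated 5-18 year range. `homa` and `map` carry no marginal: they
#' are always derived from their parent variables.
#'
#' @return Named list of `fl_marginal` objects for `male`, `age`, `pub`,
#'   `bmi`, `wc`, `alt`, `ast`, `ggt`, `glu`, `ins`, `hdlc`, `ldlc`, `tg`,
#'   `sbp`, `dbp`, `ur`, `crp`.
#' @export
default_marginals <- function() {
  list(
    male = binary_marginal("male", 692 / 1672),
    age  = marginal_spec("age", 13, 15, 16, lower = 5, upper = 18),
    pub  = ordinal_marginal("pub", c(194, 144, 213, 373, 748) / 1672),
    bmi  = marginal_spec("bmi", 32, 36, 40),
    wc   = marginal_spec("wc", 101, 111, 122),
    alt  = marginal_spec("alt", 16, 23, 35),
    ast  = marginal_spec("ast", 17, 21, 26),
    ggt  = marginal_spec("ggt", 12, 16, 22),
    glu  = marginal_spec("glu", 74, 79, 83),
    ins  = marginal_spec("ins", 9, 13, 18),
    hdlc = marginal_spec("hdlc", 37, 43, 51),
    ldlc = marginal_spec("ldlc", 85, 102, 122),
    tg   = marginal_spec("tg", 66, 87, 114),
    sbp  = marginal_spec("sbp", 120, 120, 130),
    dbp  = marginal_spec("dbp", 70, 80, 80),
    ur   = marginal_spec("ur", 5.2, 6.0, 6.9),
    crp  = marginal_spec("crp", 0.2, 0.4, 0.7)
  )
}

#' Default Spearman dependence targets of the obesity cohort
#'
#' The published rank-correlation matrix of the candidate predictors. The
#' published table reports mean arterial pressure only; since the generator
#' samples `sbp` and `dbp` and derives `map`, both pressure components take
#' the `map` row of the table, with Spearman(sbp, dbp) = 0.60 (a realistic
#' pediatric value). Rows for the outcome and for derived variables (`homa`,
#' `map`) are intentionally absent: those correlations must emerge from the
#' outcome model and the derivation formulas rather than being imposed.
#'
#' @return A symmetric 17 x 17 matrix of Spearman targets with unit diagonal.
#' @export
default_spearman_targets <- function() {
  vars <- c("male", "age", "pub", "bmi", "wc", "alt", "ast", "ggt", "glu",
            "ins", "hdlc", "ldlc", "tg", "sbp", "dbp", "ur", "crp")
  m <- diag(length(vars))
  dimnames(m) <- list(vars, vars)
  rows <- list(
    age  = c(male = -0.09),
    pub  = c(male = -0.30, age = 0.82),
    bmi  = c(male = 0.01, age = 0.36, pub = 0.31),
    wc   = c(male = 0.23, age = 0.38, pub = 0.28, bmi = 0.77),
    alt  = c(male = 0.39, age = 0.05, pub = -0.09, bmi = 0.21, wc = 0.29),
    ast  = c(male = 0.41, age = -0.12, pub = -0.24, bmi = 0.03, wc = 0.12,
             alt = 0.81),
    ggt  = c(male = 0.35, age = 0.13, pub = 0.01, bmi = 0.30, wc = 0.34,
             alt = 0.61, ast = 0.46),
    glu  = c(male = 0.13, age = -0.13, pub = -0.16, bmi = 0.09, wc = 0.13,
             alt = 0.07, ast = 0.03, ggt = 0.05),
    ins  = c(male = 0.05, age = 0.03, pub = 0.03, bmi = 0.40, wc = 0.37,
             alt = 0.27, ast = 0.13, ggt = 0.34, glu = 0.14),
    hdlc = c(male = -0.17, age = -0.06, pub = -0.02, bmi = -0.22, wc = -0.27,
             alt = -0.17, ast = -0.09, ggt = -0.20, glu = -0.07, ins = -0.25),
    ldlc = c(male = 0.06, age = -0.03, pub = -0.05, bmi = 0.07, wc = 0.08,
             alt = 0.16, ast = 0.15, ggt = 0.27, glu = 0.04, ins = 0.10,
             hdlc = -0.05),
    tg   = c(male = 0.10, age = 0.07, pub = 0.02, bmi = 0.19, wc = 0.21,
             alt = 0.25, ast = 0.17, ggt = 0.31, glu = 0.00, ins = 0.34,
             hdlc = -0.38, ldlc = 0.43),
    sbp  = c(male = 0.14, age = 0.30, pub = 0.22, bmi = 0.41, wc = 0.42,
             alt = 0.19, ast = 0.06, ggt = 0.23, glu = 0.06, ins = 0.25,
             hdlc = -0.10, ldlc = 0.04, tg = 0.13),
    dbp  = c(male = 0.14, age = 0.30, pub = 0.22, bmi = 0.41, wc = 0.42,
             alt = 0.19, ast = 0.06, ggt = 0.23, glu = 0.06, ins = 0.25,
             hdlc = -0.10, ldlc = 0.04, tg = 0.13, sbp = 0.60),
    ur   = c(male = 0.36, age = 0.13, pub = 0.05, bmi = 0.37, wc = 0.42,
             alt = 0.37, ast = 0.28, ggt = 0.38, glu = 0.09, ins = 0.28,
             hdlc = -0.26, ldlc = 0.09, tg = 0.25, sbp = 0.26, dbp = 0.26),
    crp  = c(male = -0.02, age = 0.04, pub = 0.00, bmi = 0.34, wc = 0.22,
             alt = 0.02, ast = -0.04, ggt = 0.16, glu = 0.04, ins = 0.14,
             hdlc = -0.10, ldlc = 0.04, tg = 0.00, sbp = 0.09, dbp = 0.09,
             ur = 0.09)
  )
  for (v in names(rows)) {
    for (u in names(rows[[v]])) {
      m[v, u] <- m[u, v] <- rows[[v]][[u]]
    }
  }
  m
}
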