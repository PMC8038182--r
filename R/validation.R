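# Internal validation: discrimination, likelihood-based fit measures, and
# the three-level (mean / weak / moderate) calibration hierarchy.

#' Harrell's c-statistic
#'
#' Proportion of case/non-case pairs in which the case has the higher
#' predicted risk, ties counted one half; equivalent to the area under the
#' ROC curve, computed via the rank-sum identity.
#'
#' @param pred Predicted risks (or any monotone score).
#' @param outcome Binary 0/1 outcome; both classes must be present.
#' @return Concordance in `[0, 1]`.
#' @export
c_statistic <- function(pred, outcome) {
  stopifnot(length(pred) == length(outcome))
  if (!is_binary01(outcome)) stop_domain("outcome must be coded 0/1")
  n1 <- sum(outcome == 1)
  n0 <- sum(outcome == 0)
  if (n1 == 0L || n0 == 0L) {
    stop_domain("both outcome classes must be present to compute concordance")
  }
  r <- rank(pred) # mid-ranks: ties contribute 1/2
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Likelihood-based R-squared family
#'
#' Cox-Snell `R2 = 1 - exp(2 (ll_null - ll_model) / n)`, its maximum
#' attainable value `1 - exp(2 ll_null / n)` (a function of the event
#' fraction only, since `ll_null = n * (phi log phi + (1-phi) log(1-phi))`),
#' and Nagelkerke's rescaled ratio.
#'
#' @param loglik_null Log-likelihood of the intercept-only model. May be
#'   omitted if `event_fraction` is given.
#' @param loglik_model Log-likelihood of the fitted model.
#' @param n Number of subjects.
#' @param event_fraction Optional outcome prevalence used to reconstruct
#'   `loglik_null`.
#' @return List with `cox_snell`, `max_cox_snell`, `nagelkerke`.
#' @export
r2_family <- function(loglik_null = NULL, loglik_model, n,
                      event_fraction = NULL) {
  if (is.null(loglik_null)) {
    stopifnot(!is.null(event_fraction), event_fraction > 0,
              event_fraction < 1)
    phi <- event_fraction
    loglik_null <- n * (phi * log(phi) + (1 - phi) * log(1 - phi))
  }
  if (loglik_model < loglik_null - 1e-8) {
    stop("model log-likelihood is below the null log-likelihood")
  }
  cs <- 1 - exp(2 * (loglik_null - loglik_model) / n)
  max_cs <- 1 - exp(2 * loglik_null / n)
  list(cox_snell = cs, max_cox_snell = max_cs, nagelkerke = cs / max_cs)
}

#' Akaike and Bayesian information criteria
#'
#' `AIC = -2 loglik + 2 k`; `BIC = -2 loglik + k log n`, with `k` the number
#' of parameters including the intercept.
#'
#' @param loglik Model log-likelihood.
#' @param k Number of parameters (>= 1).
#' @param n Number of subjects (>= 1).
#' @return List with `aic` and `bic`.
#' @export
aic_bic <- function(loglik, k, n) {
  stopifnot(k >= 1, n >= 1)
  list(aic = -2 * loglik + 2 * k, bic = -2 * loglik + k * log(n))
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(k, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = centre - half, upper = centre + half)
}

#' Three-level calibration assessment
#'
#' The mean / weak / moderate calibration hierarchy. Mean calibration
#' compares the average predicted risk with the observed event rate (Wilson
#' interval for the observed rate). Weak calibration refits the outcome on
#' the logit of the predictions: the slope is the coefficient of
#' `logit(pred)`, and the intercept is estimated with the slope fixed at 1
#' by entering `logit(pred)` as an offset; both receive percentile bootstrap
#' confidence intervals over `B_ci` row resamples. Moderate calibration is a
#' locally weighted smoother (span 0.75) of the outcome on the predicted
#' risk, evaluated on an equally spaced 100-point grid and clamped to
#' `[0, 1]`, with a 10-bin histogram of the predicted risks.
#'
#' @param pred Predicted probabilities strictly inside (0, 1).
#' @param outcome Binary 0/1 outcome, both classes present.
#' @param B_ci Bootstrap resamples for the slope/intercept intervals;
#'   default 2000.
#' @param seed Integer seed for the bootstrap.
#' @param level Confidence level; default 0.95.
#' @return Object of class `fl_calibration`: `mean` (observed rate and mean
#'   predicted risk with intervals), `weak` (slope and intercept with
#'   intervals), `moderate` (data.frame `grid_risk`, `smoothed_observed`,
#'   `n_in_bin`), `n`, `B_ci`, `seed`.
#' @export
calibration_assess <- function(pred, outcome, B_ci = 2000, seed = 1,
                               level = 0.95) {
  stopifnot(length(pred) == length(outcome))
  if (any(pred <= 0 | pred >= 1)) {
    stop_domain("predictions must lie strictly inside (0, 1)")
  }
  if (!is_binary01(outcome) || length(unique(outcome)) < 2L) {
    stop_domain("outcome must be 0/1 with both classes present")
  }
  if (stats::sd(pred) == 0) {
    stop_domain("constant predictions: the calibration slope is inestimable")
  }
  n <- length(outcome)
  lp <- logit(pred)
  slope_int <- function(y, l) {
    slope <- fit_logistic(cbind(intercept = 1, logit_pred = l),
                          y)$coefficients[["logit_pred"]]
    intercept <- fit_logistic(matrix(1, length(y), 1,
                                     dimnames = list(NULL, "intercept")),
                              y, offset = l)$coefficients[["intercept"]]
    c(slope = slope, intercept = intercept)
  }
  est <- slope_int(outcome, lp)
  boot <- matrix(NA_real_, B_ci, 2, dimnames = list(NULL, names(est)))
  with_preserved_rng({
    set.seed(seed)
    for (b in seq_len(B_ci)) {
      idx <- sample.int(n, n, replace = TRUE)
      boot[b, ] <- tryCatch(slope_int(outcome[idx], lp[idx]),
                            error = function(e) c(NA_real_, NA_real_))
    }
  })
  ok <- stats::complete.cases(boot)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- apply(boot[ok, , drop = FALSE], 2, stats::quantile, probs = probs)
  # bootstrap interval for the mean predicted risk reuses the same seed
  with_preserved_rng({
    set.seed(seed)
    mp <- numeric(B_ci)
    for (b in seq_len(B_ci)) {
      mp[b] <- mean(pred[sample.int(n, n, replace = TRUE)])
    }
  })
  moderate <- local({
    lo <- stats::loess(outcome ~ pred, span = 0.75,
                       degree = 2, family = "gaussian")
    grid <- seq(min(pred), max(pred), length.out = 100)
    sm <- pmin(pmax(stats::predict(lo, newdata = data.frame(pred = grid)),
                    0), 1)
    breaks <- seq(0, 1, by = 0.1)
    counts <- as.integer(table(cut(pred, breaks, include.lowest = TRUE)))
    bin <- findInterval(grid, breaks, rightmost.closed = TRUE)
    data.frame(grid_risk = grid, smoothed_observed = sm,
               n_in_bin = counts[bin])
  })
  structure(
    list(
      mean = list(
        observed_rate = mean(outcome),
        observed_ci = wilson_ci(sum(outcome), n, level),
        mean_predicted = mean(pred),
        predicted_ci = stats::quantile(mp, probs = probs,
                                       names = FALSE)
      ),
      weak = list(
        slope = unname(est["slope"]),
        slope_ci = unname(qs[, "slope"]),
        intercept = unname(est["intercept"]),
        intercept_ci = unname(qs[, "intercept"])
      ),
      moderate = moderate,
      n = n, B_ci = B_ci, seed = seed, level = level
    ),
    class = "fl_calibration"
  )
}

#' @export
print.fl_calibration <- function(x, ...) {
  cat(sprintf("Calibration (n = %d, B = %d)\n", x$n, x$B_ci))
  cat(sprintf("  mean:  observed %.1f%% (%.1f-%.1f), predicted %.1f%% (%.1f-%.1f)\n",
              100 * x$mean$observed_rate, 100 * x$mean$observed_ci[1],
              100 * x$mean$observed_ci[2], 100 * x$mean$mean_predicted,
              100 * x$mean$predicted_ci[1], 100 * x$mean$predicted_ci[2]))
  cat(sprintf("  weak:  slope %.3f (%.3f-%.3f), intercept %.3f (%.3f-%.3f)\n",
              x$weak$slope, x$weak$slope_ci[1], x$weak$slope_ci[2],
              x$weak$intercept, x$weak$intercept_ci[1],
              x$weak$intercept_ci[2]))
  dev <- max(abs(x$moderate$smoothed_observed - x$moderate$grid_risk))
  cat(sprintf("  moderate: max |smoothed - identity| = %.3f over the grid\n",
              dev))
  invisible(x)
}

#' Calibration plot
#'
#' Draws the moderate-calibration curve against the identity line with a
#' histogram of predicted risks, and optionally writes the image and a CSV
#' of the curve points (columns `grid_risk`, `smoothed_observed`,
#' `n_in_bin`) for bit-exact re-rendering.
#'
#' @param report An `fl_calibration` object.
#' @param path Optional image path (`.png`/`.svg`/`.pdf`, via
#'   [ggplot2::ggsave()]).
#' @param csv_path Optional CSV path for the curve points.
#' @return The ggplot object, invisibly.
#' @export
calibration_plot <- function(report, path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "fl_calibration"))
  curve <- report$moderate
  hist_df <- local({
    # histogram heights recovered from the per-bin counts stored on the curve
    breaks <- seq(0, 1, by = 0.1)
    agg <- unique(data.frame(
      bin = findInterval(curve$grid_risk, breaks, rightmost.closed = TRUE),
      n = curve$n_in_bin))
    data.frame(x = breaks[agg$bin] + 0.05,
               h = 0.15 * agg$n / max(agg$n, 1))
  })
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = grid_risk)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = smoothed_observed),
                       linewidth = 0.8, colour = "#2c6e91") +
    ggplot2::geom_col(data = hist_df,
                      ggplot2::aes(x = x, y = h), width = 0.09,
                      fill = "grey70", alpha = 0.6, inherit.aes = FALSE) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Predicted risk", y = "Observed event rate",
                  title = "Internal calibration") +
    ggplot2::theme_minimal()
  if (!is.null(csv_path)) {
    utils::write.csv(curve, csv_path, row.names = FALSE)
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 5, height = 5, dpi = 150)
  }
  invisible(p)
}

#' Full performance report for a fitted or published model
#'
#' Convenience wrapper computing discrimination (c-statistic with percentile
#' bootstrap interval), the R-squared family, AIC/BIC and the calibration
#' hierarchy for a vector of predicted risks.
#'
#' @param pred Predicted probabilities in (0, 1).
#' @param outcome Binary 0/1 outcome.
#' @param k Number of model parameters including the intercept (for
#'   AIC/BIC).
#' @param B_ci Bootstrap resamples; default 2000.
#' @param seed Integer seed.
#' @return Object of class `fl_performance`: `c_statistic`, `c_ci`,
#'   `r2` (Cox-Snell/max/Nagelkerke), `aic`, `bic`, `calibration`, `n`, `k`.
#' @export
performance_report <- function(pred, outcome, k, B_ci = 2000, seed = 1) {
  n <- length(outcome)
  cstat <- c_statistic(pred, outcome)
  with_preserved_rng({
    set.seed(seed)
    cb <- numeric(B_ci)
    for (b in seq_len(B_ci)) {
      idx <- sample.int(n, n, replace = TRUE)
      cb[b] <- tryCatch(c_statistic(pred[idx], outcome[idx]),
                        error = function(e) NA_real_)
    }
  })
  ll_model <- sum(ifelse(outcome == 1, log(pred), log(1 - pred)))
  phi <- mean(outcome)
  r2 <- r2_family(loglik_model = ll_model, n = n, event_fraction = phi)
  ic <- aic_bic(ll_model, k, n)
  structure(
    list(c_statistic = cstat,
         c_ci = stats::quantile(cb, c(0.025, 0.975), na.rm = TRUE,
                                names = FALSE),
         r2 = r2, aic = ic$aic, bic = ic$bic,
         calibration = calibration_assess(pred, outcome, B_ci = B_ci,
                                          seed = seed),
         n = n, k = k),
    class = "fl_performance"
  )
}

#' @export
print.fl_performance <- function(x, ...) {
  cat(sprintf("Performance (n = %d, k = %d)\n", x$n, x$k))
  cat(sprintf("  c-statistic %.3f (%.3f-%.3f)\n", x$c_statistic,
              x$c_ci[1], x$c_ci[2]))
  cat(sprintf("  Cox-Snell R2 %.3f, Nagelkerke R2 %.3f\n",
              x$r2$cox_snell, x$r2$nagelkerke))
  cat(sprintf("  AIC %.1f, BIC %.1f\n", x$aic, x$bic))
  print(x$calibration)
  invisible(x)
}
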