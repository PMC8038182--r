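# Bootstrap machinery: inclusion fractions over resampled model selection,
# and percentile confidence intervals for a fixed final model.

#' Bootstrap inclusion fractions
#'
#' Runs the full multivariable FP selection ([mfp_cycle()]) on `B`
#' nonparametric bootstrap resamples (rows drawn with replacement, resample
#' size = n) and summarises, per candidate: BIF-1, the percentage of
#' converged resamples retaining the variable in any form; BIF-2, the
#' percentage retaining a second FP term (an FP2 form); and the modal first
#' and second exponents among retaining resamples (ties broken toward the
#' lowest power). Percentages are computed over converged resamples. A
#' variable is flagged for inclusion when BIF-1 >= 66%.
#'
#' @param data Cohort `data.frame`.
#' @param outcome Binary outcome column; default `"fl"`.
#' @param candidates Candidate predictor names.
#' @param B Number of bootstrap resamples; default 1000.
#' @param alpha Closed-test level passed to [mfp_cycle()].
#' @param seed Integer seed; results are bit-reproducible given `seed` and
#'   `B`.
#' @param scales Pre-transformation scales, as in [mfp_cycle()].
#' @param bif_threshold Inclusion threshold in percent; default 66.
#' @return Object of class `fl_bif`: `summary` (data.frame with `variable`,
#'   `bif1`, `exp1`, `bif2`, `exp2`, `included`), `B`, `converged`
#'   (number of converged resamples), `seed`, `bif_threshold`.
#' @export
bootstrap_bif <- function(data, outcome = "fl", candidates, B = 1000,
                          alpha = 0.05, seed = 1,
                          scales = default_fp_scales(),
                          bif_threshold = 66) {
  stopifnot(B >= 1)
  n <- nrow(data)
  retained <- matrix(FALSE, B, length(candidates),
                     dimnames = list(NULL, candidates))
  two_term <- retained
  pow1 <- matrix(NA_real_, B, length(candidates),
                 dimnames = list(NULL, candidates))
  pow2 <- pow1
  ok <- logical(B)
  with_preserved_rng({
    set.seed(seed)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      res <- tryCatch(
        suppressWarnings(mfp_cycle(data[idx, , drop = FALSE], outcome,
                                   candidates, alpha, scales = scales)),
        error = function(e) NULL
      )
      if (is.null(res) || !res$converged) next
      ok[b] <- TRUE
      for (v in candidates) {
        st <- res$state[[v]]
        if (st$form == "omitted") next
        retained[b, v] <- TRUE
        pow1[b, v] <- st$powers[1L]
        if (st$form == "FP2") {
          two_term[b, v] <- TRUE
          pow2[b, v] <- st$powers[2L]
        }
      }
    }
  })
  n_ok <- sum(ok)
  if (n_ok == 0L) stop("no bootstrap resample converged")
  if (B - n_ok > 0.05 * B) {
    warning(sprintf("%d of %d bootstrap resamples did not converge", B - n_ok, B))
  }
  modal_low <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NA_real_)
    tab <- table(x)
    cand <- as.numeric(names(tab)[tab == max(tab)])
    min(cand) # deterministic tie-break: lowest power
  }
  summary <- data.frame(
    variable = candidates,
    bif1 = 100 * colSums(retained[ok, , drop = FALSE]) / n_ok,
    exp1 = vapply(candidates, function(v) modal_low(pow1[ok, v]), numeric(1)),
    bif2 = 100 * colSums(two_term[ok, , drop = FALSE]) / n_ok,
    exp2 = vapply(candidates, function(v) modal_low(pow2[ok, v]), numeric(1)),
    row.names = NULL
  )
  summary$included <- summary$bif1 >= bif_threshold
  structure(
    list(summary = summary, B = B, converged = n_ok, seed = seed,
         bif_threshold = bif_threshold),
    class = "fl_bif"
  )
}

#' @export
print.fl_bif <- function(x, ...) {
  cat(sprintf("Bootstrap inclusion fractions (B = %d, %d converged, threshold %.0f%%)\n",
              x$B, x$converged, x$bif_threshold))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Export a BIF summary as a selection table
#'
#' @param x An `fl_bif` object.
#' @param path Optional CSV path; written with columns variable, BIF-1,
#'   EXP-1, BIF-2, EXP-2.
#' @return The table, invisibly if written.
#' @export
bif_table <- function(x, path = NULL) {
  stopifnot(inherits(x, "fl_bif"))
  tab <- x$summary[c("variable", "bif1", "exp1", "bif2", "exp2")]
  names(tab) <- c("variable", "BIF-1", "EXP-1", "BIF-2", "EXP-2")
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Fit a final model with bootstrap confidence intervals
#'
#' Fits the retained terms by full-data maximum likelihood and attaches
#' percentile 95% confidence intervals from `B_ci` bootstrap refits with the
#' functional form held fixed.
#'
#' @param data Cohort `data.frame`.
#' @param outcome Binary outcome column; default `"fl"`.
#' @param terms Named list describing the model: each element is either the
#'   string `"linear"` or an [fp_term()]; names are the predictor columns.
#' @param B_ci Number of bootstrap resamples for the intervals; default 1000.
#' @param seed Integer seed.
#' @return Object of class `fl_model_fit`: `terms`, `coefficients`
#'   (intercept first), `ci` (2.5/97.5 percentile matrix), `loglik`, `n`,
#'   `k`, `converged`, `boot_failed`, `seed`.
#' @export
fit_final <- function(data, outcome = "fl", terms, B_ci = 1000, seed = 1) {
  stopifnot(length(terms) >= 1, !is.null(names(terms)))
  y <- data[[outcome]]
  design <- function(d) terms_design(terms, d)
  x <- design(data)
  if (nrow(x) <= ncol(x)) {
    stop("more parameters than subjects: the model cannot be identified")
  }
  fit <- fit_logistic(x, y)
  boot <- matrix(NA_real_, B_ci, ncol(x), dimnames = list(NULL, colnames(x)))
  with_preserved_rng({
    set.seed(seed)
    for (b in seq_len(B_ci)) {
      idx <- sample.int(nrow(data), nrow(data), replace = TRUE)
      bf <- tryCatch(fit_logistic(design(data[idx, , drop = FALSE]), y[idx]),
                     pedfl_separation = function(e) NULL,
                     error = function(e) NULL)
      if (!is.null(bf) && bf$converged) boot[b, ] <- bf$coefficients
    }
  })
  ok <- stats::complete.cases(boot)
  ci <- t(apply(boot[ok, , drop = FALSE], 2, stats::quantile,
                probs = c(0.025, 0.975), type = 7))
  colnames(ci) <- c("lower", "upper")
  structure(
    list(terms = terms, coefficients = fit$coefficients, ci = ci,
         loglik = fit$loglik, n = fit$n, k = fit$k,
         converged = fit$converged, boot_failed = B_ci - sum(ok),
         B_ci = B_ci, seed = seed),
    class = "fl_model_fit"
  )
}

#' @export
print.fl_model_fit <- function(x, ...) {
  cat(sprintf("Logistic model (n = %d, k = %d, loglik = %.2f)\n",
              x$n, x$k, x$loglik))
  out <- data.frame(coef = x$coefficients,
                    lower = x$ci[, "lower"], upper = x$ci[, "upper"])
  print(out, digits = 3)
  invisible(x)
}

# intercept + transformed columns for a named term list ("linear" entries
# or fp_term objects), shared by fit_final, predict and the pipeline
terms_design <- function(terms, data) {
  cols <- NULL
  for (v in names(terms)) {
    piece <- if (identical(terms[[v]], "linear")) {
      m <- matrix(data[[v]], ncol = 1)
      colnames(m) <- v
      m
    } else {
      fp_transform(data[[v]], terms[[v]])
    }
    cols <- cbind(cols, piece)
  }
  out <- cbind(intercept = rep(1, nrow(data)), cols)
  colnames(out)[1L] <- "intercept"
  out
}

#' Predict from a fitted final model
#'
#' @param object An `fl_model_fit` from [fit_final()].
#' @param newdata Cohort `data.frame` with the model's predictor columns.
#' @param type `"response"` (probability) or `"link"` (logit).
#' @param ... Unused.
#' @return Numeric vector, one value per row of `newdata`.
#' @export
predict.fl_model_fit <- function(object, newdata,
                                 type = c("response", "link"), ...) {
  type <- match.arg(type)
  eta <- drop(terms_design(object$terms, newdata) %*% object$coefficients)
  if (type == "link") eta else expit(eta)
}

#' Translate a selection state into final-model terms
#'
#' @param mfp An `fl_mfp` object from [mfp_cycle()].
#' @param scales Pre-transformation scales used during selection.
#' @return Named list of `"linear"` / [fp_term()] entries for [fit_final()],
#'   containing the retained candidates only.
#' @export
mfp_terms <- function(mfp, scales = default_fp_scales()) {
  stopifnot(inherits(mfp, "fl_mfp"))
  out <- list()
  for (v in names(mfp$state)) {
    st <- mfp$state[[v]]
    if (st$form == "omitted") next
    sc <- if (v %in% names(scales)) scales[[v]] else 1
    out[[v]] <- if (st$form == "linear" && sc == 1) {
      "linear"
    } else {
      fp_term(v, st$powers, scale = sc)
    }
  }
  out
}
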