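# Function selection procedure: for one predictor, the closed test deciding
# omitted vs linear vs FP1 vs FP2 against chi-square reference
# distributions; and the cycling algorithm applying it to each candidate
# in turn, adjusted for the current forms of the others.

#' Closed-test function selection for one predictor
#'
#' Finds the best one-power (FP1, over the 8 powers) and two-power (FP2,
#' over the 36 pairs including repeats) fractional-polynomial logistic fits
#' of `variable`, adjusted for `adjust`, and applies the closed test:
#' (i) best FP2 against omission on 4 df - if not significant the variable
#' is omitted; (ii) best FP2 against the linear form on 3 df - if not
#' significant the form is linear; (iii) best FP2 against best FP1 on 2 df -
#' FP1 if not significant, otherwise FP2. Binary (0/1) predictors skip the
#' FP family and are tested linear vs omitted on 1 df.
#'
#' @param data Cohort `data.frame`.
#' @param variable Name of the candidate predictor.
#' @param outcome Name of the binary outcome column (default `"fl"`).
#' @param adjust Optional matrix of adjustment columns (no intercept).
#' @param alpha Significance level of each closed-test step; default 0.05.
#' @param scale,shift Pre-transformation scaling of the candidate.
#' @return Object of class `fl_fsp_decision`: `variable`, `form` (one of
#'   `"omitted"`, `"linear"`, `"FP1"`, `"FP2"`), `powers`, `deviances`
#'   (null/linear/fp1/fp2), `p_values` (overall/nonlinear/fp2_vs_fp1),
#'   `converged`.
#' @export
fsp_select <- function(data, variable, outcome = "fl", adjust = NULL,
                       alpha = 0.05, scale = 1, shift = 0) {
  stopifnot(alpha > 0, alpha < 1)
  y <- data[[outcome]]
  x <- data[[variable]]
  cache <- if (is_binary01(x)) NULL else fp_cache(x, scale, shift)
  fsp_select_impl(y, x, cache, variable, adjust, alpha)
}

# internal: y outcome, x raw column, cache NULL for binary predictors
fsp_select_impl <- function(y, x, cache, variable, adjust, alpha) {
  base <- cbind(intercept = rep(1, length(y)), adjust)
  colnames(base)[1L] <- "intercept"
  # A separated sub-fit invalidates the whole decision; a merely
  # non-convergent or singular candidate transform is excluded from the
  # search (its deviance is NA) without poisoning the decision.
  converged <- TRUE
  eta0 <- NULL
  dev_of <- function(extra) {
    fit <- tryCatch(
      fit_logistic(cbind(base, extra), y, check_rank = FALSE,
                   compute_vcov = FALSE, etastart = eta0),
      pedfl_separation = function(e) {
        converged <<- FALSE
        NULL
      },
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) return(NA_real_)
    if (is.null(extra)) eta0 <<- fit$eta # warm start for the larger fits
    fit$deviance
  }
  d_null <- dev_of(NULL)
  if (is.na(d_null)) {
    return(fsp_decision(variable, "omitted", NULL,
                        c(null = NA, linear = NA, fp1 = NA, fp2 = NA),
                        c(overall = NA, nonlinear = NA, fp2_vs_fp1 = NA),
                        FALSE))
  }
  if (is.null(cache)) { # binary predictor: linear vs omitted, 1 df
    d_lin <- dev_of(matrix(x, ncol = 1))
    p <- stats::pchisq(d_null - d_lin, df = 1, lower.tail = FALSE)
    form <- if (!is.na(p) && p < alpha) "linear" else "omitted"
    return(fsp_decision(variable, form, if (form == "linear") 1,
                        c(null = d_null, linear = d_lin, fp1 = NA, fp2 = NA),
                        c(overall = p, nonlinear = NA, fp2_vs_fp1 = NA),
                        converged))
  }
  d_lin <- dev_of(fp_cols_from_cache(cache, 1))
  dev1 <- vapply(fp_powers(),
                 function(p) dev_of(fp_cols_from_cache(cache, p)),
                 numeric(1))
  pairs <- fp_power_pairs()
  dev2 <- vapply(pairs,
                 function(pw) dev_of(fp_cols_from_cache(cache, pw)),
                 numeric(1))
  if (all(is.na(dev1)) || all(is.na(dev2)) || is.na(d_lin)) {
    return(fsp_decision(variable, "omitted", NULL,
                        c(null = d_null, linear = d_lin,
                          fp1 = suppressWarnings(min(dev1, na.rm = TRUE)),
                          fp2 = suppressWarnings(min(dev2, na.rm = TRUE))),
                        c(overall = NA, nonlinear = NA, fp2_vs_fp1 = NA),
                        FALSE))
  }
  best1 <- which.min(dev1)            # ties: first = lowest power
  best2 <- which.min(dev2)
  d_fp1 <- dev1[best1]
  d_fp2 <- dev2[best2]
  devs <- c(null = d_null, linear = d_lin, fp1 = d_fp1, fp2 = d_fp2)
  p_overall <- stats::pchisq(d_null - d_fp2, df = 4, lower.tail = FALSE)
  p_nonlin <- stats::pchisq(d_lin - d_fp2, df = 3, lower.tail = FALSE)
  p_fp2 <- stats::pchisq(d_fp1 - d_fp2, df = 2, lower.tail = FALSE)
  ps <- c(overall = p_overall, nonlinear = p_nonlin, fp2_vs_fp1 = p_fp2)
  if (p_overall >= alpha) {
    fsp_decision(variable, "omitted", NULL, devs, ps, converged)
  } else if (p_nonlin >= alpha) {
    fsp_decision(variable, "linear", 1, devs, ps, converged)
  } else if (p_fp2 >= alpha) {
    fsp_decision(variable, "FP1", fp_powers()[best1], devs, ps, converged)
  } else {
    fsp_decision(variable, "FP2", pairs[[best2]], devs, ps, converged)
  }
}

fsp_decision <- function(variable, form, powers, deviances, p_values,
                         converged) {
  structure(
    list(variable = variable, form = form, powers = powers,
         deviances = deviances, p_values = p_values, converged = converged),
    class = "fl_fsp_decision"
  )
}

#' @export
print.fl_fsp_decision <- function(x, ...) {
  cat(sprintf("%s: %s%s\n", x$variable, x$form,
              if (!is.null(x$powers) && x$form %in% c("FP1", "FP2")) {
                sprintf(" (powers %s)", paste(x$powers, collapse = ", "))
              } else ""))
  invisible(x)
}

# design columns implied by a selection state, excluding `exclude`;
# caches is a named list of fp_cache results (NULL entries for binaries)
state_design <- function(data, state, caches, exclude = NULL) {
  cols <- NULL
  for (v in names(state)) {
    if (v %in% exclude || state[[v]]$form == "omitted") next
    piece <- if (is.null(caches[[v]])) {
      m <- matrix(data[[v]], ncol = 1)
      colnames(m) <- v
      m
    } else {
      m <- fp_cols_from_cache(caches[[v]], state[[v]]$powers)
      colnames(m) <- sprintf("%s^%g%s", v, state[[v]]$powers,
                             c("", "*log")[
                               1 + (duplicated(state[[v]]$powers))])
      m
    }
    cols <- cbind(cols, piece)
  }
  cols
}

#' Multivariable fractional-polynomial cycling
#'
#' Applies [fsp_select()] to each candidate in turn - visited in order of
#' decreasing univariable significance - adjusting for the current
#' functional forms of all other candidates, and iterates until no decision
#' changes or `max_cycles` is reached (the state is then flagged unstable).
#' An empty candidate list yields the intercept-only model.
#'
#' @param data Cohort `data.frame`.
#' @param outcome Binary outcome column name; default `"fl"`.
#' @param candidates Character vector of candidate predictors. Binary (0/1)
#'   candidates bypass the FP family.
#' @param alpha Closed-test significance level; default 0.05.
#' @param max_cycles Maximum number of full cycles; default 5.
#' @param scales Named numeric vector of pre-transformation divisors;
#'   default ALT/100 and HOMA-IR/10, all others 1, matching the published
#'   coefficient scales.
#' @return Object of class `fl_mfp`: `decisions` (list of
#'   `fl_fsp_decision`), `state`, final `fit` (`fl_logit`), `cycles`,
#'   `stable`, `converged`.
#' @export
mfp_cycle <- function(data, outcome = "fl", candidates, alpha = 0.05,
                      max_cycles = 5, scales = default_fp_scales()) {
  y <- data[[outcome]]
  if (!is_binary01(y)) stop_domain("outcome must be coded 0/1")
  if (length(candidates) == 0L) {
    fit <- fit_logistic(matrix(1, nrow(data), 1,
                               dimnames = list(NULL, "intercept")), y)
    return(structure(list(decisions = list(), state = list(), fit = fit,
                          cycles = 0L, stable = TRUE, converged = TRUE),
                     class = "fl_mfp"))
  }
  stopifnot(all(candidates %in% names(data)))
  caches <- lapply(stats::setNames(candidates, candidates), function(v) {
    if (is_binary01(data[[v]])) return(NULL)
    sc <- if (v %in% names(scales)) scales[[v]] else 1
    fp_cache(data[[v]], scale = sc, shift = 0)
  })
  # visit order: decreasing univariable (linear, 1 df) significance
  null_dev <- fit_logistic(matrix(1, nrow(data), 1), y)$deviance
  uni_p <- vapply(candidates, function(v) {
    fit <- tryCatch(
      fit_logistic(cbind(1, data[[v]]), y),
      pedfl_separation = function(e) NULL
    )
    if (is.null(fit)) return(1)
    stats::pchisq(null_dev - fit$deviance, df = 1, lower.tail = FALSE)
  }, numeric(1))
  order_v <- candidates[order(uni_p)]
  state <- lapply(stats::setNames(order_v, order_v),
                  function(v) list(form = "linear", powers = 1))
  decisions <- list()
  cycles <- 0L
  stable <- FALSE
  while (cycles < max_cycles) {
    cycles <- cycles + 1L
    changed <- FALSE
    for (v in order_v) {
      adj <- state_design(data, state, caches, exclude = v)
      dec <- fsp_select_impl(y, data[[v]], caches[[v]], v, adj, alpha)
      if (!identical(state[[v]][c("form", "powers")],
                     list(form = dec$form, powers = dec$powers))) {
        changed <- TRUE
      }
      state[[v]] <- list(form = dec$form, powers = dec$powers)
      decisions[[v]] <- dec
    }
    if (!changed) {
      stable <- TRUE
      break
    }
  }
  if (!stable) {
    warning("selection did not stabilise within max_cycles; returning last state")
  }
  # convergence is judged on the final cycle's decisions and the final fit
  converged <- all(vapply(decisions, `[[`, logical(1), "converged"))
  final_x <- cbind(intercept = rep(1, nrow(data)),
                   state_design(data, state, caches))
  colnames(final_x)[1L] <- "intercept"
  fit <- tryCatch(fit_logistic(final_x, y),
                  pedfl_separation = function(e) NULL)
  if (is.null(fit)) converged <- FALSE
  structure(
    list(decisions = decisions, state = state, fit = fit, cycles = cycles,
         stable = stable, converged = converged),
    class = "fl_mfp"
  )
}

#' Default pre-transformation scales
#'
#' Divisors applied to predictors before fractional-polynomial powering, so
#' that selected models are reported on the published coefficient scale:
#' ALT/100 and HOMA-IR/10, everything else unscaled.
#'
#' @return Named numeric vector.
#' @export
default_fp_scales <- function() c(alt = 100, homa = 10)

#' @export
print.fl_mfp <- function(x, ...) {
  cat(sprintf("FP cycling: %d cycle(s), %s\n", x$cycles,
              ifelse(x$stable, "stable", "UNSTABLE")))
  for (d in x$decisions) print(d)
  invisible(x)
}
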