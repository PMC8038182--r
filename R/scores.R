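# The two published fatty-liver scoring equations, shipped as immutable
# JSON model cards. Each model is intercept + sum(coefficient x transformed
# term), with ALT entering through (ALT/100)^-2 and (ALT/100)^-1 and
# HOMA-IR through (HOMA-IR/10) and (HOMA-IR/10)^2; the remaining predictors
# are linear. The card keeps the printed confidence limits verbatim; three
# upper limits of the WC model are flagged as suspected dropped minus signs
# and are stored as printed rather than silently corrected.

#' Load a published fatty-liver prediction model
#'
#' Returns one of the two published scoring equations as an immutable model
#' card: the BMI-based model (intercept -0.533; age, BMI, ALT FP(-2, -1),
#' HOMA-IR FP(1, 2), triglycerides, uric acid) or the WC-based model
#' (intercept -0.925; waist circumference replacing BMI). Coefficients are
#' exactly the printed values; `ci_flag` marks printed confidence limits
#' whose sign is suspect in the source table.
#'
#' @param id `"bmi"` or `"wc"`.
#' @return Object of class `fl_published_model`.
#' @export
published_model <- function(id = c("bmi", "wc")) {
  id <- match.arg(id)
  key <- paste0("model_", id)
  if (!is.null(.pedfl_cache[[key]])) return(.pedfl_cache[[key]])
  path <- system.file("extdata", paste0(key, ".json"), package = "pedfl",
                      mustWork = TRUE)
  card <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  card$terms <- lapply(card$terms, function(t) {
    t$powers <- as.numeric(t$powers)
    t$coefficients <- as.numeric(t$coefficients)
    t$ci <- lapply(t$ci, as.numeric)
    t
  })
  model <- structure(card, class = "fl_published_model")
  .pedfl_cache[[key]] <- model
  model
}

#' @export
print.fl_published_model <- function(x, ...) {
  cat(x$label, "\n")
  cat(sprintf("  intercept %.3f\n", x$intercept))
  for (t in x$terms) {
    lab <- if (t$type == "fp") {
      paste(sprintf("(%s/%g)^%g", t$variable, t$scale, t$powers),
            collapse = " + ")
    } else {
      t$variable
    }
    cat(sprintf("  %s: %s\n", lab,
                paste(sprintf("%.3f", t$coefficients), collapse = ", ")))
  }
  invisible(x)
}

# fields a model card requires in the scoring data
published_required <- function(model) {
  vapply(model$terms, `[[`, character(1), "variable")
}

#' Flat coefficient vector of a published model
#'
#' The printed coefficients in design order (no intercept), named after the
#' transformed columns (e.g. `alt^-2`, `homa^1`).
#'
#' @param model An `fl_published_model`.
#' @return Named numeric vector.
#' @export
published_coefficients <- function(model) {
  out <- numeric(0)
  for (t in model$terms) {
    nm <- if (length(t$coefficients) == 1L) {
      t$variable
    } else {
      sprintf("%s^%g", t$variable, t$powers)
    }
    out <- c(out, stats::setNames(t$coefficients, nm))
  }
  out
}

# design matrix of the model's transformed terms (no intercept)
published_design <- function(model, data) {
  need <- published_required(model)
  missing_v <- setdiff(need, names(data))
  if (length(missing_v) > 0L) {
    stop(sprintf("model '%s' requires missing column(s): %s",
                 model$id, paste(missing_v, collapse = ", ")))
  }
  cols <- NULL
  for (t in model$terms) {
    piece <- if (t$type == "fp") {
      fp_transform(data[[t$variable]], fp_term(t$variable, t$powers,
                                               scale = t$scale))
    } else {
      m <- matrix(data[[t$variable]], ncol = 1)
      colnames(m) <- t$variable
      m
    }
    cols <- cbind(cols, piece)
  }
  cols
}

#' Linear predictor of a published model
#'
#' `intercept + sum(coefficient * transformed term)` on the logit scale.
#'
#' @param model An `fl_published_model`.
#' @param data Cohort `data.frame` with the model's required columns (`age`,
#'   `alt`, `homa`, `tg`, `ur`, plus `bmi` or `wc`). ALT and HOMA-IR must be
#'   strictly positive.
#' @return Numeric vector of logits, one per row.
#' @export
linear_predictor <- function(model, data) {
  stopifnot(inherits(model, "fl_published_model"))
  x <- published_design(model, data)
  drop(model$intercept + x %*% published_coefficients(model))
}

#' Predicted fatty-liver risk
#'
#' Inverse-logit of [linear_predictor()]; strictly increasing in the linear
#' predictor and always inside (0, 1).
#'
#' @inheritParams linear_predictor
#' @return Numeric vector of probabilities, order-preserving with the rows.
#' @export
predict_risk <- function(model, data) {
  expit(linear_predictor(model, data))
}

#' Score a cohort file
#'
#' Reads a cohort CSV, scores every row with a published model, and writes
#' a CSV with the linear predictor and predicted risk appended.
#'
#' @param model `"bmi"`, `"wc"` or an `fl_published_model`.
#' @param input Path of the cohort CSV.
#' @param output Path of the scored CSV.
#' @return The scored `data.frame`, invisibly.
#' @export
score_cohort <- function(model, input, output) {
  if (is.character(model)) model <- published_model(model)
  d <- read_cohort(input, required = published_required(model))
  d$lp <- linear_predictor(model, d)
  d$risk <- expit(d$lp)
  utils::write.csv(d, output, row.names = FALSE)
  invisible(d)
}
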