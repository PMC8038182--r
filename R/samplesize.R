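# Riley minimum-sample-size criteria for developing a binary-outcome
# prediction model: (1) global shrinkage of predictor effects, (2) bounded
# optimism in apparent Nagelkerke R-squared, (3) precision of the overall
# outcome-risk estimate. The required n is the maximum of the three.

#' Maximum attainable Cox-Snell R-squared
#'
#' For a binary outcome with prevalence `phi`,
#' `max R2 = 1 - exp(2 (phi log phi + (1 - phi) log(1 - phi)))`.
#'
#' @param phi Outcome prevalence in (0, 1).
#' @return The maximum Cox-Snell R-squared, in (0, 1); symmetric in
#'   `phi <-> 1 - phi`.
#' @export
max_cox_snell <- function(phi) {
  if (any(phi <= 0 | phi >= 1)) stop_domain("prevalence must be in (0, 1)")
  1 - exp(2 * (phi * log(phi) + (1 - phi) * log(1 - phi)))
}

#' Riley minimum sample size for a binary-outcome prediction model
#'
#' Three criteria, each rounded up, with the maximum binding:
#' \describe{
#'   \item{n1 (shrinkage)}{`p / ((S - 1) ln(1 - R2/S))` targets a global
#'     shrinkage factor of at least `S` (default 0.9, i.e. expected
#'     shrinkage of predictor effects below 10%).}
#'   \item{n2 (optimism)}{the same expression evaluated at
#'     `S2 = R2 / (R2 + delta_nag * maxR2)`, bounding the difference
#'     between apparent and optimism-adjusted Nagelkerke R-squared by
#'     `delta_nag` (default 0.05).}
#'   \item{n3 (risk precision)}{`(1.96 / delta_phi)^2 phi (1 - phi)`,
#'     estimating the average outcome risk to within `delta_phi`
#'     (default 0.05) absolute.}
#' }
#'
#' @param p Number of candidate model parameters (positive integer;
#'   indicator coding counts each dummy, see [count_parameters()]).
#' @param r2_cs Anticipated Cox-Snell R-squared, in `(0, max_cox_snell(phi))`.
#' @param prevalence Anticipated outcome prevalence in (0, 1).
#' @param shrinkage Target global shrinkage factor S in (0, 1); default 0.9.
#' @param delta_nag Allowed apparent-minus-adjusted Nagelkerke difference;
#'   default 0.05.
#' @param delta_phi Absolute precision of the outcome-risk estimate;
#'   default 0.05.
#' @return Object of class `fl_sample_size`: `n1`, `n2`, `n3`, `n_required`
#'   (their maximum), `max_cox_snell`, `events_per_parameter` (implied at
#'   `n_required`), and the inputs.
#' @examples
#' riley_n(p = 20, r2_cs = 0.11, prevalence = 0.38)
#' @export
riley_n <- function(p, r2_cs, prevalence, shrinkage = 0.9,
                    delta_nag = 0.05, delta_phi = 0.05) {
  stopifnot(p >= 1, shrinkage > 0, shrinkage < 1,
            delta_nag > 0, delta_phi > 0)
  if (prevalence <= 0 || prevalence >= 1) {
    stop_domain("prevalence must be in (0, 1)")
  }
  max_r2 <- max_cox_snell(prevalence)
  if (r2_cs <= 0 || r2_cs >= max_r2) {
    stop_domain("r2_cs must be in (0, max_cox_snell(prevalence))")
  }
  if (r2_cs >= shrinkage) {
    stop_domain("r2_cs must be below the shrinkage factor S")
  }
  n_for_s <- function(s) ceiling(p / ((s - 1) * log(1 - r2_cs / s)))
  n1 <- n_for_s(shrinkage)
  s2 <- r2_cs / (r2_cs + delta_nag * max_r2)
  n2 <- n_for_s(s2)
  n3 <- ceiling((1.96 / delta_phi)^2 * prevalence * (1 - prevalence))
  n_req <- max(n1, n2, n3)
  structure(
    list(n1 = n1, n2 = n2, n3 = n3, n_required = n_req,
         max_cox_snell = max_r2,
         events_per_parameter = n_req * prevalence / p,
         inputs = list(p = p, r2_cs = r2_cs, prevalence = prevalence,
                       shrinkage = shrinkage, delta_nag = delta_nag,
                       delta_phi = delta_phi)),
    class = "fl_sample_size"
  )
}

#' @export
print.fl_sample_size <- function(x, ...) {
  cat("Minimum sample size for model development\n")
  cat(sprintf("  n1 (shrinkage <= %.0f%%):        %d\n",
              100 * (1 - x$inputs$shrinkage), x$n1))
  cat(sprintf("  n2 (Nagelkerke optimism <= %.2f): %d\n",
              x$inputs$delta_nag, x$n2))
  cat(sprintf("  n3 (risk precision %.2f):        %d\n",
              x$inputs$delta_phi, x$n3))
  cat(sprintf("  required n = %d (%.1f events per parameter)\n",
              x$n_required, x$events_per_parameter))
  invisible(x)
}

#' Count effective model parameters
#'
#' Helper documenting the indicator-counting rule: a continuous or binary
#' predictor contributes one parameter; an ordinal or nominal predictor with
#' L levels contributes L - 1 indicator parameters.
#'
#' @param continuous Number of continuous or binary candidate predictors.
#' @param categorical_levels Integer vector of level counts of categorical
#'   candidates (e.g. `5` for the five Tanner stages).
#' @return Total candidate parameter count `p`.
#' @examples
#' count_parameters(16, 5) # 16 single-df predictors + 5-level stage -> 20
#' @export
count_parameters <- function(continuous, categorical_levels = integer(0)) {
  stopifnot(continuous >= 0, all(categorical_levels >= 2))
  as.integer(continuous + sum(categorical_levels - 1L))
}
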