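# Metabolic-syndrome component flags. The defining cutoffs come from the
# International Diabetes Federation pediatric consensus definition and are
# deliberately NOT baked in here: they are age- and sex-specific and must be
# supplied by the analyst from that consensus document.

#' Metabolic-syndrome component flags from user-supplied cutoffs
#'
#' Computes the binary component indicators of a metabolic-syndrome
#' definition: large waist circumference, high glucose, low HDL-cholesterol,
#' high triglycerides, and high blood pressure, plus the syndrome indicator
#' itself (central obesity and at least two other components, the structure
#' of the IDF consensus definition). Every cutoff must be supplied by the
#' caller - per subject if age/sex-specific - because the consensus values
#' are not part of this package.
#'
#' @param cohort Cohort `data.frame` with `wc`, `glu`, `hdlc`, `tg`, and
#'   `sbp`/`dbp` (or `map` alone if no pressure cutoffs are given).
#' @param cutoffs Named list with elements `wc`, `glu`, `hdlc`, `tg`,
#'   `sbp`, `dbp`; each a scalar or a vector with one value per subject.
#'   Flags: `wc` >= cutoff, `glu` >= cutoff, `hdlc` < cutoff (low HDL),
#'   `tg` >= cutoff, and high blood pressure when `sbp` or `dbp` reaches
#'   its cutoff.
#' @return `data.frame` of 0/1 columns `large_wc`, `high_glu`, `low_hdl`,
#'   `high_tg`, `high_bp`, `met_syndrome`.
#' @export
metabolic_flags <- function(cohort, cutoffs) {
  need <- c("wc", "glu", "hdlc", "tg", "sbp", "dbp")
  missing_c <- setdiff(need, names(cutoffs))
  if (length(missing_c) > 0L) {
    stop(sprintf(
      "cutoffs must supply %s (consensus values are the analyst's input)",
      paste(missing_c, collapse = ", ")
    ))
  }
  out <- data.frame(
    large_wc = as.integer(cohort$wc >= cutoffs$wc),
    high_glu = as.integer(cohort$glu >= cutoffs$glu),
    low_hdl = as.integer(cohort$hdlc < cutoffs$hdlc),
    high_tg = as.integer(cohort$tg >= cutoffs$tg),
    high_bp = as.integer(cohort$sbp >= cutoffs$sbp |
                           cohort$dbp >= cutoffs$dbp)
  )
  out$met_syndrome <- as.integer(
    out$large_wc == 1 &
      (out$high_glu + out$low_hdl + out$high_tg + out$high_bp) >= 2
  )
  out
}
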