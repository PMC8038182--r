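# Cohort data model: derived variables, descriptive summaries, Spearman
# collinearity screening and CSV I/O.

# canonical modelling columns of a cohort table, in conventional order
canonical_cohort_vars <- function() {
  c("fl", "male", "age", "pub", "bmi", "wc", "alt", "ast", "ggt", "glu",
    "ins", "homa", "hdlc", "ldlc", "tg", "map", "ur", "crp")
}

# columns treated as discrete in summaries and screening
discrete_cohort_vars <- function() c("fl", "male", "pub", "fl_grade")

#' Homeostasis model assessment of insulin resistance
#'
#' `HOMA-IR = insulin * glucose / 405`, with fasting insulin in uU/mL and
#' fasting glucose in mg/dL.
#'
#' @param insulin Fasting insulin (uU/mL), non-negative.
#' @param glucose Fasting glucose (mg/dL), strictly positive.
#' @return Dimensionless HOMA-IR, same length as the inputs.
#' @examples
#' derive_homa_ir(13, 79)
#' @export
derive_homa_ir <- function(insulin, glucose) {
  if (any(insulin < 0)) stop_domain("insulin must be non-negative")
  if (any(glucose <= 0)) stop_domain("glucose must be strictly positive")
  insulin * glucose / 405
}

#' Mean arterial pressure
#'
#' `MAP = SBP/3 + 2*DBP/3` (mm Hg).
#'
#' @param sbp Systolic blood pressure (mm Hg).
#' @param dbp Diastolic blood pressure (mm Hg); must not exceed `sbp`.
#' @return Mean arterial pressure (mm Hg).
#' @examples
#' derive_map(120, 80)
#' @export
derive_map <- function(sbp, dbp) {
  if (any(dbp <= 0)) stop_domain("blood pressures must be positive")
  if (any(dbp > sbp)) stop_domain("dbp must not exceed sbp")
  sbp / 3 + 2 * dbp / 3
}

#' Validate a cohort table
#'
#' Checks the row-level invariants of a cohort: completeness, positivity of
#' the continuous measurements, Tanner stage in 1-5, binary coding of `fl`
#' and `male`, agreement of `fl` with `fl_grade` when the latter is present,
#' and the derivation identities for `homa` (from `ins`, `glu`) and `map`
#' (from `sbp`, `dbp`) when the parent columns are present.
#'
#' @param cohort A cohort `data.frame`.
#' @param tol Tolerance for the derived-variable identities.
#' @return `cohort`, invisibly, if all invariants hold; otherwise an error.
#' @export
validate_cohort <- function(cohort, tol = 1e-9) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) < 1L) stop("cohort must contain at least one subject")
  if (anyNA(cohort)) {
    bad <- which(is.na(cohort), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "missing value at row %d, column '%s': cohorts are assumed complete",
      bad[1L], names(cohort)[bad[2L]]
    ))
  }
  cont <- setdiff(
    intersect(names(cohort), c(canonical_cohort_vars(), "sbp", "dbp",
                               "weight", "height", "chol")),
    discrete_cohort_vars()
  )
  for (v in cont) {
    if (!is.numeric(cohort[[v]])) stop(sprintf("column '%s' is not numeric", v))
    if (v != "homa" && any(cohort[[v]] <= 0)) {
      stop(sprintf("column '%s' must be strictly positive", v))
    }
    if (v == "homa" && any(cohort[[v]] < 0)) {
      stop("column 'homa' must be non-negative")
    }
  }
  if ("pub" %in% names(cohort) && !all(cohort$pub %in% 1:5)) {
    stop("pubertal stage 'pub' must take values in 1..5")
  }
  for (v in intersect(c("fl", "male"), names(cohort))) {
    if (!is_binary01(cohort[[v]])) stop(sprintf("'%s' must be coded 0/1", v))
  }
  if (all(c("fl", "fl_grade") %in% names(cohort))) {
    if (!all(cohort$fl_grade %in% 0:3)) stop("'fl_grade' must be in 0..3")
    if (!all((cohort$fl == 1) == (cohort$fl_grade >= 1))) {
      stop("'fl' must equal 1 exactly when 'fl_grade' >= 1")
    }
  }
  if (all(c("homa", "ins", "glu") %in% names(cohort))) {
    if (max(abs(cohort$homa - derive_homa_ir(cohort$ins, cohort$glu))) > tol) {
      stop("'homa' does not equal ins*glu/405")
    }
  }
  if (all(c("map", "sbp", "dbp") %in% names(cohort))) {
    if (max(abs(cohort$map - derive_map(cohort$sbp, cohort$dbp))) > tol) {
      stop("'map' does not equal sbp/3 + 2*dbp/3")
    }
  }
  if (all(c("bmi", "weight", "height") %in% names(cohort))) {
    recomputed <- cohort$weight / cohort$height^2
    rel <- abs(recomputed - cohort$bmi) / cohort$bmi
    if (any(rel > 0.01)) {
      warning(sprintf(
        "%d rows have recorded BMI differing >1%% from weight/height^2",
        sum(rel > 0.01)
      ))
    }
  }
  invisible(cohort)
}

#' Descriptive summary of a cohort
#'
#' Continuous variables are summarised as median (25th-75th percentile),
#' discrete ones (`fl`, `male`, `pub`, `fl_grade`) as count (proportion) per
#' level. Quantiles use linear interpolation of order statistics
#' ([stats::quantile()] type 7).
#'
#' @param cohort A cohort `data.frame`.
#' @param group_by Optional name of a binary column; summaries are then
#'   reported for the total cohort and each group side by side.
#' @return A `data.frame` with columns `variable`, `level` (`NA` for
#'   continuous rows), and one formatted summary column per group, plus
#'   numeric `median`/`p25`/`p75` (or `count`/`proportion`) columns for the
#'   total cohort.
#' @export
describe_cohort <- function(cohort, group_by = NULL) {
  validate_cohort(cohort)
  vars <- intersect(c(canonical_cohort_vars(), "sbp", "dbp", "fl_grade"),
                    names(cohort))
  groups <- list(total = rep(TRUE, nrow(cohort)))
  if (!is.null(group_by)) {
    stopifnot(group_by %in% names(cohort), is_binary01(cohort[[group_by]]))
    groups[[paste0(group_by, "_0")]] <- cohort[[group_by]] == 0
    groups[[paste0(group_by, "_1")]] <- cohort[[group_by]] == 1
  }
  rows <- list()
  for (v in vars) {
    x <- cohort[[v]]
    if (v %in% discrete_cohort_vars()) {
      for (lev in sort(unique(x))) {
        row <- data.frame(variable = v, level = lev)
        for (g in names(groups)) {
          n <- sum(groups[[g]])
          k <- sum(x[groups[[g]]] == lev)
          row[[g]] <- sprintf("%d (%.1f%%)", k, 100 * k / n)
        }
        row$count <- sum(x == lev)
        row$proportion <- mean(x == lev)
        rows[[length(rows) + 1L]] <- row
      }
    } else {
      row <- data.frame(variable = v, level = NA_real_)
      for (g in names(groups)) {
        q <- stats::quantile(x[groups[[g]]], c(0.25, 0.5, 0.75),
                             names = FALSE, type = 7)
        row[[g]] <- sprintf("%.4g (%.4g-%.4g)", q[2], q[1], q[3])
      }
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      row$median <- q[2]; row$p25 <- q[1]; row$p75 <- q[3]
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    for (col in c("median", "p25", "p75", "count", "proportion")) {
      if (is.null(r[[col]])) r[[col]] <- NA_real_
    }
    r
  }))
  rownames(out) <- NULL
  out
}

#' Spearman collinearity screening
#'
#' Computes the Spearman rank-correlation matrix of the requested variables
#' (mid-ranks for ties) and groups them into clusters: connected components
#' of the graph whose edges join pairs with `|rho| > threshold`. Within each
#' multi-variable cluster one representative is kept, chosen by the
#' caller-supplied `priority` order (a clinical-availability judgment, not an
#' automatic rule).
#'
#' @param cohort A cohort `data.frame`.
#' @param variables Character vector (>= 2) of columns to screen.
#' @param threshold Absolute rank-correlation above which a pair is
#'   considered collinear; default 0.60.
#' @param priority Optional character vector; within each cluster the first
#'   `priority` member found is kept. Clusters with no prioritised member get
#'   `NA` and must be resolved by the analyst.
#' @return An object of class `fl_screening`: list with `spearman` (the
#'   correlation matrix), `clusters` (list of character vectors, singletons
#'   included), `kept` (one name or `NA` per cluster), `threshold`.
#' @export
spearman_screen <- function(cohort, variables, threshold = 0.60,
                            priority = NULL) {
  stopifnot(length(variables) >= 2L, all(variables %in% names(cohort)),
            threshold > 0, threshold < 1)
  x <- cohort[variables]
  const <- vapply(x, function(col) stats::var(col) == 0, logical(1))
  if (any(const)) {
    stop(sprintf("constant column(s) make rank correlations undefined: %s",
                 paste(variables[const], collapse = ", ")))
  }
  rho <- stats::cor(x, method = "spearman")
  # connected components of the |rho| > threshold graph, via label sweep
  adj <- abs(rho) > threshold
  diag(adj) <- FALSE
  comp <- seq_along(variables)
  repeat {
    changed <- FALSE
    for (i in seq_along(variables)) {
      nb <- which(adj[i, ])
      if (length(nb) > 0L) {
        m <- min(comp[c(i, nb)])
        if (any(comp[c(i, nb)] != m)) {
          comp[c(i, nb)] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  clusters <- lapply(unique(comp), function(k) variables[comp == k])
  kept <- vapply(clusters, function(cl) {
    if (length(cl) == 1L) return(cl)
    hit <- priority[priority %in% cl]
    if (length(hit) > 0L) hit[1L] else NA_character_
  }, character(1))
  structure(
    list(spearman = rho, clusters = clusters, kept = kept,
         threshold = threshold),
    class = "fl_screening"
  )
}

#' @export
print.fl_screening <- function(x, ...) {
  cat(sprintf("Spearman screening (|rho| > %.2f)\n", x$threshold))
  multi <- lengths(x$clusters) > 1L
  if (!any(multi)) {
    cat("  no collinear clusters\n")
  } else {
    for (i in which(multi)) {
      cat(sprintf("  cluster {%s} -> keep %s\n",
                  paste(x$clusters[[i]], collapse = ", "),
                  ifelse(is.na(x$kept[i]), "<unresolved>", x$kept[i])))
    }
  }
  invisible(x)
}

#' Read a cohort from CSV
#'
#' Expects a header of canonical lower-case variable names, decimal point,
#' UTF-8; lines starting with `#` (provenance comments written by
#' [write_cohort()]) are skipped. Missing or non-numeric cells are an error
#' naming the offending row and column, since the modelling workflow assumes
#' complete data.
#'
#' @param path CSV file path.
#' @param required Character vector of columns that must be present; default
#'   the canonical modelling columns.
#' @return A validated cohort `data.frame` with a `provenance` attribute.
#' @export
read_cohort <- function(path, required = canonical_cohort_vars()) {
  raw <- utils::read.csv(path, comment.char = "#", check.names = TRUE,
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop(sprintf("cohort file '%s' lacks required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")))
  }
  for (v in names(raw)) {
    if (!is.numeric(raw[[v]])) {
      suppressWarnings(num <- as.numeric(raw[[v]]))
      bad <- which(is.na(num) & !is.na(raw[[v]]))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric cell at row %d, column '%s'", bad[1L], v))
      }
      raw[[v]] <- num
    }
    if (anyNA(raw[[v]])) {
      stop(sprintf(
        "missing value at row %d, column '%s': complete data are required",
        which(is.na(raw[[v]]))[1L], v
      ))
    }
  }
  attr(raw, "provenance") <- "real"
  validate_cohort(raw)
  raw
}

#' Write a cohort to CSV
#'
#' Writes the table with a leading `#` comment line carrying the provenance
#' tag (real or synthetic) and, for synthetic cohorts, the generator seed.
#'
#' @param cohort A cohort `data.frame`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  prov <- attr(cohort, "provenance") %||% "real"
  seed <- attr(cohort, "seed")
  hdr <- sprintf("# provenance: %s%s", prov,
                 if (is.null(seed)) "" else sprintf(" seed=%d", seed))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(cohort), con, row.names = FALSE)
  invisible(path)
}
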