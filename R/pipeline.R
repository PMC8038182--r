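# Config-driven orchestration of the full development-and-validation
# workflow: describe -> Spearman screening -> bootstrap FP selection per
# anthropometric arm -> final fit with bootstrap CIs -> performance and
# calibration reports, with every artifact written alongside a config
# snapshot.

#' Pipeline configuration
#'
#' @param input Optional path of a cohort CSV; if `NULL`, a synthetic cohort
#'   is generated from `generator`.
#' @param generator A [generator_config()] used when `input` is `NULL`.
#' @param candidates Candidate predictors screened for collinearity before
#'   modelling. Default: the full roster (sex, age, pubertal stage, BMI, WC,
#'   ALT, AST, GGT, glucose, insulin, HOMA-IR, HDL, LDL, triglycerides, MAP,
#'   uric acid, CRP).
#' @param priority Cluster-representative priority (clinical availability):
#'   default age over pubertal stage, ALT over AST/GGT, HOMA-IR over
#'   insulin, BMI/WC handled as separate arms.
#' @param arm `"both"`, `"bmi"` or `"wc"`: which anthropometric arm(s) to
#'   develop.
#' @param B_selection Bootstrap resamples for inclusion fractions (default
#'   1000; the published workflow's value).
#' @param B_ci Bootstrap resamples for coefficient intervals (default 1000).
#' @param B_calibration Bootstrap resamples for calibration intervals
#'   (default 2000).
#' @param alpha Closed-test level (default 0.05).
#' @param seed Integer seed driving every stochastic stage.
#' @param out_dir Output directory (created if missing).
#' @param fast If `TRUE`, all three B values are reduced to 100 for quick
#'   runs; reports always state the B actually used.
#' @return Object of class `fl_pipeline_config`.
#' @export
pipeline_config <- function(input = NULL,
                            generator = generator_config(),
                            candidates = c("male", "age", "pub", "bmi",
                                           "wc", "alt", "ast", "ggt",
                                           "glu", "ins", "homa", "hdlc",
                                           "ldlc", "tg", "map", "ur",
                                           "crp"),
                            priority = c("age", "alt", "homa", "bmi", "wc"),
                            arm = c("both", "bmi", "wc"),
                            B_selection = 1000, B_ci = 1000,
                            B_calibration = 2000, alpha = 0.05, seed = 1,
                            out_dir = tempfile("pedfl_run_"),
                            fast = FALSE) {
  arm <- match.arg(arm)
  if (fast) B_selection <- B_ci <- B_calibration <- 100
  stopifnot(B_selection >= 1, B_ci >= 1, B_calibration >= 1)
  structure(
    list(input = input, generator = generator, candidates = candidates,
         priority = priority, arm = arm, B_selection = B_selection,
         B_ci = B_ci, B_calibration = B_calibration, alpha = alpha,
         seed = as.integer(seed), out_dir = out_dir),
    class = "fl_pipeline_config"
  )
}

#' Run the full development-and-validation pipeline
#'
#' Executes, in order: cohort acquisition (CSV or synthetic), descriptive
#' summary, Spearman collinearity screening (glucose is additionally
#' excluded from multivariable candidacy whenever HOMA-IR is a candidate,
#' since HOMA-IR already contains it), bootstrap FP selection per
#' anthropometric arm, final-model fitting with bootstrap intervals, and
#' the discrimination/fit/calibration report with plots. All artifacts are
#' written under `config$out_dir` together with a config snapshot; any
#' stage failure aborts with the stage name while preserving the partial
#' outputs.
#'
#' @param config An [pipeline_config()] object.
#' @param quiet Suppress stage messages.
#' @return Invisible list: `cohort`, `description`, `screening`, and per
#'   arm `bif`, `model`, `performance`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "fl_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  snapshot <- config
  snapshot$generator <- unclass(snapshot$generator)
  if (inherits(snapshot$generator$outcome_model, "fl_published_model")) {
    snapshot$generator$outcome_model <- snapshot$generator$outcome_model$id
  }
  jsonlite::write_json(unclass(snapshot),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)

  cohort <- stage("cohort", {
    if (is.null(config$input)) {
      say("stage cohort: generating synthetic cohort (n = %d, seed = %d)",
          config$generator$n, config$generator$seed)
      d <- sample_cohort(config$generator)
      write_cohort(d, file.path(config$out_dir, "cohort.csv"))
      d
    } else {
      say("stage cohort: reading %s", config$input)
      read_cohort(config$input)
    }
  })

  description <- stage("describe", {
    say("stage describe: summarising %d subjects", nrow(cohort))
    tab <- describe_cohort(cohort,
                           group_by = if ("male" %in% names(cohort)) "male")
    utils::write.csv(tab, file.path(config$out_dir, "description.csv"),
                     row.names = FALSE)
    tab
  })

  vars <- intersect(config$candidates, names(cohort))
  screening <- if (length(vars) >= 2L) {
    stage("screen", {
      say("stage screen: Spearman screening of %d candidates", length(vars))
      scr <- spearman_screen(cohort, vars, threshold = 0.60,
                             priority = config$priority)
      utils::write.csv(scr$spearman,
                       file.path(config$out_dir, "spearman.csv"))
      scr
    })
  } else {
    NULL
  }

  arms <- if (config$arm == "both") c("bmi", "wc") else config$arm
  kept <- if (is.null(screening)) vars else {
    stats::na.omit(screening$kept)
  }
  if ("homa" %in% kept) kept <- setdiff(kept, "glu")
  out <- list(cohort = cohort, description = description,
              screening = screening, arms = list())
  for (arm in arms) {
    other_arm <- setdiff(c("bmi", "wc"), arm)
    cand <- setdiff(kept, other_arm)
    if (length(config$candidates) > 0L) {
      cand <- union(cand, intersect(arm, names(cohort)))
    }
    cand <- intersect(c(config$candidates, arm), cand) # stable order
    bif <- if (length(cand) > 0L) {
      stage(paste0("bif_", arm), {
        say("stage bif (%s arm): B = %d over %d candidates",
            arm, config$B_selection, length(cand))
        b <- bootstrap_bif(cohort, "fl", cand, B = config$B_selection,
                           alpha = config$alpha, seed = config$seed)
        bif_table(b, file.path(config$out_dir,
                               sprintf("bif_%s.csv", arm)))
        say("  converged resamples: %d / %d", b$converged, b$B)
        b
      })
    } else {
      NULL
    }
    included <- if (is.null(bif)) character(0) else {
      bif$summary$variable[bif$summary$included]
    }
    model <- stage(paste0("model_", arm), {
      if (length(included) == 0L) {
        say("stage model (%s arm): no predictor included; intercept-only", arm)
        NULL
      } else {
        say("stage model (%s arm): final form for {%s}", arm,
            paste(included, collapse = ", "))
        mfp <- suppressWarnings(
          mfp_cycle(cohort, "fl", included, alpha = config$alpha)
        )
        fit_final(cohort, "fl", mfp_terms(mfp), B_ci = config$B_ci,
                  seed = config$seed)
      }
    })
    perf <- stage(paste0("validate_", arm), {
      if (is.null(model)) {
        say("stage validate (%s arm): prevalence-only report", arm)
        list(prevalence = mean(cohort$fl),
             prevalence_ci = wilson_ci(sum(cohort$fl), nrow(cohort)))
      } else {
        say("stage validate (%s arm): B = %d", arm, config$B_calibration)
        pred <- predict(model, cohort)
        rep <- performance_report(pred, cohort$fl, k = model$k,
                                  B_ci = config$B_calibration,
                                  seed = config$seed)
        calibration_plot(rep$calibration,
                         path = file.path(config$out_dir,
                                          sprintf("calibration_%s.png", arm)),
                         csv_path = file.path(config$out_dir,
                                              sprintf("calibration_%s.csv",
                                                      arm)))
        report <- list(
          arm = arm, n = rep$n, k = rep$k,
          B = list(selection = config$B_selection, ci = config$B_ci,
                   calibration = config$B_calibration),
          c_statistic = rep$c_statistic, c_ci = rep$c_ci,
          cox_snell_r2 = rep$r2$cox_snell,
          nagelkerke_r2 = rep$r2$nagelkerke,
          aic = rep$aic, bic = rep$bic,
          coefficients = as.list(model$coefficients),
          ci = apply(model$ci, 1, as.list),
          calibration = list(
            mean = rep$calibration$mean, weak = rep$calibration$weak
          )
        )
        jsonlite::write_json(report,
                             file.path(config$out_dir,
                                       sprintf("model_%s.json", arm)),
                             auto_unbox = TRUE, digits = NA)
        rep
      }
    })
    out$arms[[arm]] <- list(bif = bif, model = model, performance = perf)
  }
  say("pipeline complete: artifacts in %s", config$out_dir)
  invisible(out)
}
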