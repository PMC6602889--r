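#' Subject record
#'
#' Covariates and tracer data for one study participant.
#'
#' @param id subject identifier.
#' @param sex `"M"` or `"F"`.
#' @param age age, years.
#' @param body_weight body weight, kg.
#' @param bmi body mass index, kg/m².
#' @param mean_serum_retinol mean serum retinol over the study, µmol/L.
#' @param liver_weight estimated liver weight, g (optional; `NA` if unknown).
#' @param tracer a [tracer_curve()] of observed fraction-of-dose data, or
#'   `NULL` when only covariates are available.
#' @param group optional group label (e.g. `"US"`, `"CH"`).
#' @param truth optional list of generating ground truth (attached by the
#'   synthetic-data generator).
#' @return Object of class `"subject_record"`.
#' @export
subject_record <- function(id, sex = NA_character_, age = NA_real_,
                           body_weight, bmi = NA_real_, mean_serum_retinol,
                           liver_weight = NA_real_, tracer = NULL,
                           group = NA_character_, truth = NULL) {
  stopifnot(body_weight > 0, mean_serum_retinol > 0)
  if (!is.na(liver_weight)) stopifnot(liver_weight > 0)
  if (!is.null(tracer)) stopifnot(inherits(tracer, "tracer_curve"))
  structure(
    list(id = as.character(id), sex = sex, age = age,
         body_weight = body_weight, bmi = bmi,
         mean_serum_retinol = mean_serum_retinol,
         liver_weight = liver_weight, tracer = tracer, group = group,
         truth = truth),
    class = "subject_record")
}

#' Geometric mean and dispersion of positive values
#'
#' Summarises per-subject outputs the way skewed biological quantities are
#' usually reported: geometric mean with a geometric SD factor. An
#' arithmetic summary is available where that convention applies (e.g.
#' serum retinol concentrations).
#'
#' @param values positive numeric vector (`NA` removed).
#' @param type `"geometric"` (default) or `"arithmetic"`.
#' @return List with `mean`, `dispersion` (geometric SD factor, or SD for
#'   the arithmetic type) and `n`.
#' @export
group_summary <- function(values, type = c("geometric", "arithmetic")) {
  type <- match.arg(type)
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to summarise")
  if (type == "geometric") {
    if (any(values <= 0)) stop("geometric summary requires positive values")
    lv <- log(values)
    list(mean = exp(mean(lv)),
         dispersion = if (length(values) > 1) exp(stats::sd(lv)) else NA_real_,
         n = length(values), type = type)
  } else {
    list(mean = mean(values),
         dispersion = if (length(values) > 1) stats::sd(values) else NA_real_,
         n = length(values), type = type)
  }
}

#' Pointwise geometric-mean tracer curve
#'
#' Composite ("population") curve: the geometric mean fraction of dose
#' across subjects at each shared sampling time.
#'
#' @param subjects list of [subject_record()]s (or of [tracer_curve()]s).
#' @param grid_tol relative tolerance for declaring sampling grids equal.
#' @return A [tracer_curve()].
#' @export
geometric_mean_curve <- function(subjects, grid_tol = 1e-6) {
  curves <- lapply(subjects, function(s) {
    if (inherits(s, "subject_record")) s$tracer else s
  })
  if (!length(curves) || any(vapply(curves, is.null, logical(1)))) {
    stop("every subject needs a tracer curve")
  }
  ref <- curves[[1]]$time_d
  for (ci in seq_along(curves)) {
    tt <- curves[[ci]]$time_d
    if (length(tt) != length(ref) ||
        any(abs(tt - ref) > grid_tol * pmax(ref, 1))) {
      stop("subject ", ci, " is on a different sampling grid")
    }
    if (any(curves[[ci]]$fdp <= 0)) {
      stop("subject ", ci, " has non-positive fdp; geometric mean undefined")
    }
  }
  logs <- vapply(curves, function(cv) log(cv$fdp), numeric(length(ref)))
  tracer_curve(ref, exp(rowMeans(matrix(logs, nrow = length(ref)))))
}

#' Analysis run configuration
#'
#' Constants and settings for [run_group()]: which model treatments to run,
#' the steady-state constants, the intake observation used for the
#' diet-constrained fit, and fitting controls.
#'
#' @param treatments subset of `c("1EV", "2EV", "2EV_DI")`.
#' @param intake dietary vitamin A intake observation for the
#'   diet-constrained treatment, µmol/d; default 2.8 (adult RDA).
#' @param fsd_plasma,fsd_intake fractional SD weights; defaults 0.05 / 0.1.
#' @param absorption_efficiency fixed absorption efficiency; default 0.75.
#' @param liver_fraction fraction of body vitamin A in the liver; default 0.9.
#' @param plasma_volume_per_kg plasma volume per body weight, L/kg;
#'   default 0.0435.
#' @param multi_start multiplicative start factors passed to [fit_model()].
#' @param control optimiser control list passed to [fit_model()].
#' @param late_window_start,min_late_points,detection_floor subject inclusion
#'   rule: a subject's kinetics count as identifiable when at least
#'   `min_late_points` observations at or after `late_window_start` days
#'   exceed `detection_floor` (fraction of dose).
#' @param seed integer seed recorded with the analysis (the pipeline itself
#'   is deterministic; the seed namespaces any downstream randomness).
#' @return List of class `"run_config"`.
#' @export
run_config <- function(treatments = c("1EV", "2EV", "2EV_DI"),
                       intake = 2.8, fsd_plasma = 0.05, fsd_intake = 0.1,
                       absorption_efficiency = 0.75, liver_fraction = 0.9,
                       plasma_volume_per_kg = 0.0435,
                       multi_start = 1, control = list(),
                       late_window_start = 20, min_late_points = 4,
                       detection_floor = 1e-6, seed = 1L) {
  treatments <- match.arg(treatments, several.ok = TRUE)
  stopifnot(length(treatments) >= 1, intake > 0, fsd_plasma > 0,
            fsd_intake > 0, absorption_efficiency > 0,
            absorption_efficiency <= 1, liver_fraction > 0,
            liver_fraction <= 1, plasma_volume_per_kg > 0)
  structure(
    list(treatments = treatments, intake = intake, fsd_plasma = fsd_plasma,
         fsd_intake = fsd_intake,
         absorption_efficiency = absorption_efficiency,
         liver_fraction = liver_fraction,
         plasma_volume_per_kg = plasma_volume_per_kg,
         multi_start = multi_start, control = control,
         late_window_start = late_window_start,
         min_late_points = min_late_points,
         detection_floor = detection_floor, seed = as.integer(seed)),
    class = "run_config")
}

treatment_spec <- function(treatment, config) {
  switch(treatment,
         "1EV" = model_spec("ONE_EV",
                            absorption_efficiency = config$absorption_efficiency),
         "2EV" = model_spec("TWO_EV",
                            absorption_efficiency = config$absorption_efficiency),
         "2EV_DI" = model_spec("TWO_EV", include_diet_constraint = TRUE,
                               absorption_efficiency = config$absorption_efficiency),
         stop("unknown treatment: ", treatment))
}

treatment_obs <- function(treatment, curve, M5, config) {
  if (treatment == "2EV_DI") {
    observation_set(curve, M5, fsd_plasma = config$fsd_plasma,
                    intake = config$intake, fsd_intake = config$fsd_intake)
  } else {
    observation_set(curve, M5, fsd_plasma = config$fsd_plasma)
  }
}

fit_treatment <- function(treatment, curve, M5, config, starts = NULL) {
  spec <- treatment_spec(treatment, config)
  obs <- treatment_obs(treatment, curve, M5, config)
  fit <- fit_model(obs, spec, multi_start = config$multi_start,
                   starts = starts, control = config$control)
  list(treatment = treatment, fit = fit,
       steady = solve_steady_state(fit$params, spec, M5))
}

# two-pool treatments are warm-started from a one-pool fit of the same curve
# (see two_pool_starts); returns the per-treatment starts list
treatment_starts <- function(treatments, curve, M5, config) {
  if (!any(treatments %in% c("2EV", "2EV_DI"))) {
    return(stats::setNames(vector("list", length(treatments)), treatments))
  }
  simple <- fit_model(treatment_obs("1EV", curve, M5, config),
                      treatment_spec("1EV", config),
                      multi_start = config$multi_start,
                      control = config$control)
  warm <- two_pool_starts(simple)
  out <- lapply(treatments, function(tr) {
    if (tr %in% c("2EV", "2EV_DI")) warm else NULL
  })
  stats::setNames(out, treatments)
}

subject_identifiable <- function(subject, config) {
  cv <- subject$tracer
  if (is.null(cv)) return(FALSE)
  sel <- cv$time_d >= config$late_window_start &
    cv$fdp > config$detection_floor
  sum(sel) >= config$min_late_points
}

#' Run the full group analysis
#'
#' Executes both analysis tracks for one group of subjects: (i) the
#' composite track, fitting the pointwise geometric-mean tracer curve with
#' the group geometric-mean plasma pool, and (ii) the per-subject track,
#' fitting each identifiable subject individually and summarising outputs as
#' geometric means. Nested-model F-tests compare the one-pool model against
#' the two-pool model (and, on the intake-augmented observation set, against
#' the diet-constrained two-pool model).
#'
#' @param subjects list of [subject_record()]s with tracer data.
#' @param config a [run_config()].
#' @param label group label for reporting.
#' @param per_subject run the per-subject track (default `TRUE`).
#' @return Object of class `"group_analysis"`.
#' @export
run_group <- function(subjects, config = run_config(), label = "group",
                      per_subject = TRUE) {
  stopifnot(length(subjects) >= 2)
  keep <- vapply(subjects, subject_identifiable, logical(1), config = config)
  excluded <- vapply(subjects[!keep], `[[`, character(1), "id")
  subjects <- subjects[keep]
  if (length(subjects) < 2) stop("fewer than 2 identifiable subjects")

  pools <- vapply(subjects, function(s) {
    plasma_pool_size(s$mean_serum_retinol, s$body_weight,
                     config$plasma_volume_per_kg)
  }, numeric(1))
  M5 <- group_summary(pools)$mean
  lw <- vapply(subjects, `[[`, numeric(1), "liver_weight")
  liver_gm <- if (all(is.na(lw))) NA_real_ else group_summary(lw[!is.na(lw)])$mean

  curve <- geometric_mean_curve(subjects)
  warm <- treatment_starts(config$treatments, curve, M5, config)
  composite <- lapply(config$treatments, function(tr) {
    fit_treatment(tr, curve, M5, config, starts = warm[[tr]])
  })
  names(composite) <- config$treatments
  for (tr in config$treatments) {
    st <- composite[[tr]]$steady
    composite[[tr]]$liver_va <- if (is.na(liver_gm)) NA_real_ else
      liver_va_concentration(st$TBS, liver_gm, config$liver_fraction)
  }

  f_tests <- list()
  if (all(c("1EV", "2EV") %in% config$treatments)) {
    f_tests[["1EV_vs_2EV"]] <-
      f_test(composite[["1EV"]]$fit, composite[["2EV"]]$fit)
  }
  if (all(c("1EV", "2EV_DI") %in% config$treatments)) {
    # refit the simple model on the intake-augmented observation set so the
    # two objectives are comparable
    obs_di <- treatment_obs("2EV_DI", curve, M5, config)
    simple_di <- fit_model(obs_di, treatment_spec("1EV", config),
                           multi_start = config$multi_start,
                           control = config$control)
    f_tests[["1EV_vs_2EV_DI"]] <-
      f_test(simple_di, composite[["2EV_DI"]]$fit)
  }

  subject_results <- NULL
  subject_summaries <- NULL
  if (per_subject) {
    subject_results <- lapply(subjects, function(s) {
      m5 <- plasma_pool_size(s$mean_serum_retinol, s$body_weight,
                             config$plasma_volume_per_kg)
      warm_s <- tryCatch(
        treatment_starts(config$treatments, s$tracer, m5, config),
        error = function(e) {
          stats::setNames(vector("list", length(config$treatments)),
                          config$treatments)
        })
      res <- lapply(config$treatments, function(tr) {
        tryCatch(fit_treatment(tr, s$tracer, m5, config,
                               starts = warm_s[[tr]]),
                 error = function(e) list(treatment = tr,
                                          error = conditionMessage(e)))
      })
      names(res) <- config$treatments
      list(id = s$id, M5 = m5, results = res)
    })
    names(subject_results) <- vapply(subjects, `[[`, character(1), "id")
    subject_summaries <- lapply(config$treatments, function(tr) {
      get_var <- function(v) {
        vapply(subject_results, function(sr) {
          r <- sr$results[[tr]]
          if (!is.null(r$error)) NA_real_ else r$steady[[v]]
        }, numeric(1))
      }
      vals <- lapply(c(TBS = "TBS", DR = "DR", U1 = "U1",
                       days_of_stores = "days_of_stores"), get_var)
      ok <- !is.na(vals$TBS)
      if (!any(ok)) return(NULL)
      lapply(vals, function(v) group_summary(v[ok])$mean)
    })
    names(subject_summaries) <- config$treatments
  }

  structure(
    list(label = label, config = config, n_subjects = length(subjects),
         excluded = excluded, composite_curve = curve, composite_M5 = M5,
         liver_weight_gm = liver_gm, composite = composite,
         f_tests = f_tests, per_subject = subject_results,
         subject_geomeans = subject_summaries),
    class = "group_analysis")
}

#' @export
print.group_analysis <- function(x, digits = 4, ...) {
  cat("Group analysis:", x$label, "(", x$n_subjects, "subjects )\n")
  cat("  composite M(5):", signif(x$composite_M5, digits), "umol;",
      "geometric-mean liver weight:", signif(x$liver_weight_gm, digits), "g\n")
  for (tr in names(x$composite)) {
    st <- x$composite[[tr]]$steady
    cat(sprintf(
      "  %-7s U1=%7.3f  TBS=%8.1f  DR=%6.3f  days=%7.1f  liverVA=%s\n",
      tr, st$U1, st$TBS, st$DR, as.numeric(st$days_of_stores),
      format(signif(x$composite[[tr]]$liver_va, 3))))
  }
  for (nm in names(x$f_tests)) {
    ft <- x$f_tests[[nm]]
    cat(sprintf("  F-test %s: F=%.3f (df %d,%d), p=%.4g\n",
                nm, ft$F, ft$df1, ft$df2, ft$p))
  }
  invisible(x)
}

#' Sensitivity of stores to the assumed intake
#'
#' Refits the diet-constrained model with the intake observation scaled by
#' each multiplier and reports the percent change in total body stores
#' relative to the unscaled run.
#'
#' @param subjects list of [subject_record()]s (a composite fit is used).
#' @param multipliers fractions of the configured intake to evaluate;
#'   default `c(0.5, 1, 1.5)`.
#' @param config a [run_config()] that includes the `"2EV_DI"` treatment.
#' @return `data.frame` with columns `multiplier`, `intake`, `TBS`,
#'   `pct_change_TBS`.
#' @export
intake_sensitivity <- function(subjects, multipliers = c(0.5, 1, 1.5),
                               config = run_config()) {
  if (!"2EV_DI" %in% config$treatments) {
    stop("intake_sensitivity requires the 2EV_DI treatment")
  }
  stopifnot(all(multipliers > 0))
  if (!1 %in% multipliers) multipliers <- c(1, multipliers)
  keep <- vapply(subjects, subject_identifiable, logical(1), config = config)
  subjects <- subjects[keep]
  curve <- geometric_mean_curve(subjects)
  pools <- vapply(subjects, function(s) {
    plasma_pool_size(s$mean_serum_retinol, s$body_weight,
                     config$plasma_volume_per_kg)
  }, numeric(1))
  M5 <- group_summary(pools)$mean
  warm <- treatment_starts("2EV_DI", curve, M5, config)
  tbs <- vapply(multipliers, function(m) {
    cfg <- config
    cfg$intake <- config$intake * m
    fit_treatment("2EV_DI", curve, M5, cfg,
                  starts = warm[["2EV_DI"]])$steady$TBS
  }, numeric(1))
  ref <- tbs[multipliers == 1][1]
  out <- data.frame(multiplier = multipliers,
                    intake = config$intake * multipliers,
                    TBS = tbs,
                    pct_change_TBS = 100 * (tbs - ref) / ref)
  out[order(out$multiplier), , drop = FALSE]
}
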