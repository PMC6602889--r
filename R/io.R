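#' Read a tracer curve from CSV
#'
#' Expects a comma-separated file with header columns `time_d` and `fdp`
#' (times in days, "." decimal). Validation failures name the offending row.
#'
#' @param path file path.
#' @return A [tracer_curve()].
#' @export
read_tracer_csv <- function(path) {
  if (!file.exists(path)) stop("tracer file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_d", "fdp")
  if (!all(need %in% names(df))) {
    stop("tracer CSV must have columns time_d and fdp: ", path)
  }
  for (col in need) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad)) {
      stop("non-numeric ", col, " in ", path, " at data row ", bad[1])
    }
    df[[col]] <- as.numeric(df[[col]])
  }
  dup <- which(duplicated(df$time_d))
  if (length(dup)) {
    stop("duplicated sampling time in ", path, " at data row ", dup[1])
  }
  ooo <- which(diff(df$time_d) <= 0)
  if (length(ooo)) {
    stop("sampling times out of order in ", path, " at data row ", ooo[1] + 1)
  }
  neg <- which(df$fdp < 0)
  if (length(neg)) {
    stop("negative fdp in ", path, " at data row ", neg[1])
  }
  tracer_curve(df$time_d, df$fdp)
}

#' Write a tracer curve to CSV
#' @param curve a [tracer_curve()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_tracer_csv <- function(curve, path) {
  stopifnot(inherits(curve, "tracer_curve"))
  utils::write.csv(as.data.frame(curve)[c("time_d", "fdp")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read subject records from a subjects CSV
#'
#' One row per subject with columns `id`, `group`, `sex`, `age_y`,
#' `body_weight_kg`, `bmi_kg_m2`, `serum_retinol_umol_l`, `liver_weight_g`
#' and, optionally, `tracer_file` (path relative to the CSV's directory).
#'
#' @param path subjects CSV path.
#' @return List of [subject_record()]s.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop("subjects file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "body_weight_kg", "serum_retinol_umol_l")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("subjects CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  getn <- function(col, i, default = NA_real_) {
    if (!col %in% names(df)) return(default)
    v <- suppressWarnings(as.numeric(df[[col]][i]))
    if (!is.na(df[[col]][i]) && is.na(v)) {
      stop("non-numeric ", col, " in ", path, " at data row ", i)
    }
    v
  }
  lapply(seq_len(nrow(df)), function(i) {
    w <- getn("body_weight_kg", i)
    r <- getn("serum_retinol_umol_l", i)
    if (!is.finite(w) || w <= 0) {
      stop("invalid body_weight_kg in ", path, " at data row ", i)
    }
    if (!is.finite(r) || r <= 0) {
      stop("invalid serum_retinol_umol_l in ", path, " at data row ", i)
    }
    tracer <- NULL
    if ("tracer_file" %in% names(df) && nzchar(df$tracer_file[i]) &&
        !is.na(df$tracer_file[i])) {
      tracer <- read_tracer_csv(file.path(dirname(path), df$tracer_file[i]))
    }
    subject_record(
      id = df$id[i],
      sex = if ("sex" %in% names(df)) df$sex[i] else NA_character_,
      age = getn("age_y", i), body_weight = w,
      bmi = getn("bmi_kg_m2", i), mean_serum_retinol = r,
      liver_weight = getn("liver_weight_g", i), tracer = tracer,
      group = if ("group" %in% names(df)) df$group[i] else NA_character_)
  })
}

#' Serialize kinetic parameters and model settings to JSON
#'
#' Flat key layout: `L_2_1`, ..., `DT_3`, `variant`,
#' `absorption_efficiency`.
#'
#' @param params a [kinetic_params()].
#' @param spec a [model_spec()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_params_json <- function(params, spec, path) {
  p <- unclass(as_kinetic_params(params))
  p <- as.list(p[!is.na(p)])
  p$variant <- spec$variant
  p$absorption_efficiency <- spec$absorption_efficiency
  jsonlite::write_json(p, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read kinetic parameters and model settings from JSON
#' @param path JSON path written by [write_params_json()].
#' @return List with `params` ([kinetic_params()]) and `spec`
#'   ([model_spec()]).
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  variant <- if (!is.null(x$variant)) x$variant else "TWO_EV"
  a <- if (!is.null(x$absorption_efficiency)) x$absorption_efficiency else 0.75
  keys <- intersect(names(x), .TWO_EV_PARS)
  params <- as_kinetic_params(unlist(x[keys]))
  list(params = params,
       spec = model_spec(variant, absorption_efficiency = a))
}

#' Write a group-analysis report to a directory
#'
#' Emits `results.json` (the full composite and per-subject summaries), a
#' steady-state summary CSV shaped like the published population table
#' (rows: intake, plasma pool, compartment masses, stores, disposal rate,
#' days of stores, liver vitamin A; one column per model treatment), the
#' composite tracer curve CSV, and a plain-text run log.
#'
#' @param ga a [run_group()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_report <- function(ga, dir) {
  stopifnot(inherits(ga, "group_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(group_analysis_to_list(ga),
                       file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(steady_state_table(ga),
                   file.path(dir, "steady_state_summary.csv"),
                   row.names = FALSE)
  write_tracer_csv(ga$composite_curve, file.path(dir, "composite_curve.csv"))
  log <- c(
    paste("group:", ga$label),
    paste("subjects analysed:", ga$n_subjects),
    if (length(ga$excluded)) paste("excluded:", paste(ga$excluded, collapse = ", ")),
    paste("composite M(5) [umol]:", format(ga$composite_M5)),
    paste("geometric-mean liver weight [g]:", format(ga$liver_weight_gm)),
    vapply(names(ga$f_tests), function(nm) {
      ft <- ga$f_tests[[nm]]
      sprintf("F-test %s: F=%.4f df=(%d,%d) p=%.6g", nm, ft$F, ft$df1,
              ft$df2, ft$p)
    }, character(1)))
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Steady-state summary table of a group analysis
#'
#' @param ga a [run_group()] result.
#' @return `data.frame` with a `quantity` column and one column per
#'   treatment.
#' @export
steady_state_table <- function(ga) {
  rows <- c("dietary_intake_U1_umol_d", "plasma_pool_M5_umol", "M6_umol",
            "M7_umol", "TBS_umol", "DR_umol_d", "days_of_stores_d",
            "liver_vitamin_A_umol_g")
  out <- data.frame(quantity = rows)
  for (tr in names(ga$composite)) {
    st <- ga$composite[[tr]]$steady
    out[[tr]] <- c(st$U1, st$M5, st$M6,
                   if (st$variant == "ONE_EV") NA_real_ else st$M7,
                   st$TBS, st$DR, st$days_of_stores,
                   ga$composite[[tr]]$liver_va)
  }
  out
}

# plain-list view of a group analysis for JSON serialization
group_analysis_to_list <- function(ga) {
  comp <- lapply(ga$composite, function(x) {
    list(treatment = x$treatment,
         params = as.list(unclass(x$fit$params)[
           !is.na(unclass(x$fit$params))]),
         wss = x$fit$wss, n_obs = x$fit$n_obs, n_free = x$fit$n_free,
         converged = x$fit$converged,
         param_fsd = as.list(x$fit$param_fsd),
         steady = x$steady[c("M5", "M6", "M7", "TBS", "DR", "U1",
                             "days_of_stores")],
         liver_va = x$liver_va)
  })
  per <- NULL
  if (!is.null(ga$per_subject)) {
    per <- lapply(ga$per_subject, function(sr) {
      list(id = sr$id, M5 = sr$M5,
           results = lapply(sr$results, function(r) {
             if (!is.null(r$error)) return(list(error = r$error))
             list(wss = r$fit$wss, converged = r$fit$converged,
                  TBS = r$steady$TBS, DR = r$steady$DR, U1 = r$steady$U1,
                  days_of_stores = r$steady$days_of_stores)
           }))
    })
  }
  list(label = ga$label, n_subjects = ga$n_subjects,
       excluded = as.list(ga$excluded),
       composite_M5 = ga$composite_M5,
       liver_weight_gm = ga$liver_weight_gm,
       composite = comp,
       f_tests = ga$f_tests,
       per_subject = per,
       subject_geomeans = ga$subject_geomeans,
       seed = ga$config$seed)
}
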