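#' Synthetic-data generator configuration
#'
#' Describes a simulated study: the generating kinetic parameters, the
#' between-subject variability, the multiplicative measurement noise on the
#' tracer curve, and the covariate template the subjects are drawn from.
#'
#' @param n_subjects number of subjects.
#' @param group_template `"US_LIKE"`, `"CHINESE_LIKE"` or `"CUSTOM"`. The two
#'   named templates centre covariates on the corresponding study group
#'   (body weight ~ 67-68 kg; serum retinol ~ 1.7 vs 1.2 µmol/L) and use
#'   [template_params()] for the generating kinetics.
#' @param true_params generating [kinetic_params()]; defaults to
#'   [template_params()] of the group (required for `"CUSTOM"`).
#' @param variant model variant of the generating kinetics.
#' @param param_gsd between-subject geometric SD factor applied to every
#'   free kinetic parameter; default 1.3. Set to 1 for identical subjects.
#' @param noise_fsd coefficient of variation of the multiplicative
#'   log-normal measurement noise on fdp; default 0.05.
#' @param grid sampling times, days; default the 19-point 3 h-52 d schedule.
#' @param absorption_efficiency fixed absorption efficiency; default 0.75.
#' @param plasma_volume_per_kg used for each subject's plasma pool (L/kg).
#' @param seed integer seed; all generator randomness derives from it.
#' @return List of class `"generator_config"`.
#' @export
generator_config <- function(n_subjects = 7,
                             group_template = c("US_LIKE", "CHINESE_LIKE",
                                                "CUSTOM"),
                             true_params = NULL,
                             variant = "TWO_EV",
                             param_gsd = 1.3, noise_fsd = 0.05,
                             grid = default_sampling_grid(),
                             absorption_efficiency = 0.75,
                             plasma_volume_per_kg = 0.0435,
                             seed = 1L) {
  group_template <- match.arg(group_template)
  stopifnot(n_subjects >= 1, param_gsd >= 1, noise_fsd >= 0,
            all(grid > 0), !is.unsorted(grid, strictly = TRUE))
  if (is.null(true_params)) {
    if (group_template == "CUSTOM") {
      stop("CUSTOM template requires true_params")
    }
    true_params <- template_params(group_template)
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         group_template = group_template,
         true_params = as_kinetic_params(true_params), variant = variant,
         param_gsd = param_gsd, noise_fsd = noise_fsd, grid = grid,
         absorption_efficiency = absorption_efficiency,
         plasma_volume_per_kg = plasma_volume_per_kg,
         seed = as.integer(seed)),
    class = "generator_config")
}

#' Generating kinetic parameters for the study-like templates
#'
#' Two-pool parameter sets whose steady states match the population
#' estimates of the corresponding study group under the diet-constrained
#' model: slow storage turnover (`L_10_6` 0.11%/d for the US-like template,
#' 0.39%/d for the Chinese-like), storage/plasma mass ratios
#' `M6/M5 = 385.2` and `164.4`, and second-pool ratios `M7/M5 = 26` and
#' `8.78`, respectively. Absorptive-chain rates are common to both
#' templates (absorption and processing on the scale of hours, a 0.1-d
#' delay).
#'
#' @param group `"US_LIKE"` or `"CHINESE_LIKE"`.
#' @return A [kinetic_params()] object (two-pool variant).
#' @export
template_params <- function(group = c("US_LIKE", "CHINESE_LIKE")) {
  group <- match.arg(group)
  # Pool 7 turns over on the scale of days (return time well inside the 52-d
  # study window): a second extravascular pool is only statistically
  # resolvable from 52-d data when its kinetics are distinct from the slow
  # storage pool.
  if (group == "US_LIKE") {
    # M6/M5 = 1926/5, M7/M5 = 130/5, DR/M6 = 2.1/1926
    L_10_6 <- 0.0011
    kinetic_params(L_2_1 = 1.5, L_3_2 = 6, DT_3 = 0.1, L_5_4 = 3,
                   L_6_5 = 2, L_5_6 = 2 / (1926 / 5) - L_10_6,
                   L_10_6 = L_10_6,
                   L_7_5 = 2, L_5_7 = 2 / (130 / 5))
  } else {
    # M6/M5 = 564/3.43, M7/M5 = 30.1/3.43, DR/M6 = 2.21/564
    L_10_6 <- 2.21 / 564
    kinetic_params(L_2_1 = 1.5, L_3_2 = 6, DT_3 = 0.1, L_5_4 = 3,
                   L_6_5 = 2, L_5_6 = 2 / (564 / 3.43) - L_10_6,
                   L_10_6 = L_10_6,
                   L_7_5 = 2, L_5_7 = 2 / (30.1 / 3.43))
  }
}

# covariate medians per template (log-normal draws around these)
.covariate_template <- function(group) {
  switch(group,
         US_LIKE = list(weight = 67, weight_gsd = 1.16,
                        retinol = 1.7, retinol_gsd = 1.2,
                        liver = 1323, liver_gsd = 1.09,
                        age_range = c(44, 70)),
         # CUSTOM shares the generic anthropometry of the study population
         CHINESE_LIKE = ,
         CUSTOM = list(weight = 68, weight_gsd = 1.14,
                       retinol = if (group == "CHINESE_LIKE") 1.2 else 1.5,
                       retinol_gsd = 1.2,
                       liver = 1339, liver_gsd = 1.07,
                       age_range = c(50, 60)))
}

# deterministic per-subject seed derived from the config seed
.subject_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + index * 7919) %% 2147483629)
}

#' Generate one synthetic subject
#'
#' Draws covariates log-normally around the template medians, perturbs every
#' free kinetic parameter by a log-normal between-subject deviate
#' (geometric SD `param_gsd`), simulates the subject's true tracer curve,
#' and applies multiplicative log-normal measurement noise with coefficient
#' of variation `noise_fsd` (median-one noise, consistent with
#' geometric-mean composites and fractional-SD weights). The generating
#' parameters and steady-state solution are attached as ground truth.
#'
#' @param cfg a [generator_config()].
#' @param index subject index (drives the per-subject random stream; the
#'   same `cfg` and `index` always produce the identical subject).
#' @return A [subject_record()] whose `truth` field holds `params`,
#'   `steady`, `M5` and the noise-free curve `fdp_true`.
#' @export
generate_subject <- function(cfg, index = 1L) {
  stopifnot(inherits(cfg, "generator_config"))
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.subject_seed(cfg$seed, index))
  tpl <- .covariate_template(cfg$group_template)
  sex <- sample(c("M", "F"), 1L, prob = c(0.4, 0.6))
  age <- round(stats::runif(1, tpl$age_range[1], tpl$age_range[2]))
  weight <- stats::rlnorm(1, log(tpl$weight), log(tpl$weight_gsd))
  retinol <- stats::rlnorm(1, log(tpl$retinol), log(tpl$retinol_gsd))
  liver <- stats::rlnorm(1, log(tpl$liver), log(tpl$liver_gsd))
  height <- stats::rlnorm(1, log(1.65), log(1.04))
  spec <- model_spec(cfg$variant,
                     absorption_efficiency = cfg$absorption_efficiency)

  p <- unclass(cfg$true_params)
  free <- variant_parameters(cfg$variant)
  if (cfg$param_gsd > 1) {
    p[free] <- p[free] * stats::rlnorm(length(free), 0, log(cfg$param_gsd))
  }
  # the sampling schedule is designed so the first draw follows the
  # absorption lag; keep the per-subject delay inside that design
  p[["DT_3"]] <- min(p[["DT_3"]], 0.95 * cfg$grid[1])
  params <- as_kinetic_params(p[free])

  true_curve <- simulate_fdp(params, spec, cfg$grid)
  fdp <- true_curve$fdp
  if (cfg$noise_fsd > 0) {
    sdlog <- sqrt(log(1 + cfg$noise_fsd^2))
    fdp <- fdp * stats::rlnorm(length(fdp), 0, sdlog)
  }
  M5 <- plasma_pool_size(retinol, weight, cfg$plasma_volume_per_kg)
  subject_record(
    id = sprintf("SYN%02d", index), sex = sex, age = age,
    body_weight = weight, bmi = weight / height^2,
    mean_serum_retinol = retinol, liver_weight = liver,
    tracer = tracer_curve(cfg$grid, pmin(fdp, 1)),
    group = cfg$group_template,
    truth = list(params = params,
                 steady = solve_steady_state(params, spec, M5),
                 M5 = M5, fdp_true = true_curve$fdp))
}

#' Generate a synthetic study group
#'
#' @param cfg a [generator_config()].
#' @return List of [subject_record()]s of length `cfg$n_subjects`.
#' @export
generate_group <- function(cfg) {
  lapply(seq_len(cfg$n_subjects), function(i) generate_subject(cfg, i))
}

#' Write a synthetic group to disk in the pipeline's input format
#'
#' Emits one tracer CSV per subject, a subjects CSV referencing them, and a
#' JSON sidecar with each subject's generating ground truth.
#'
#' @param subjects list of [subject_record()]s.
#' @param dir output directory (created if needed).
#' @return Invisibly, the path of the subjects CSV.
#' @export
write_synthetic_group <- function(subjects, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(subjects, function(s) {
    tpath <- file.path(dir, paste0("tracer_", s$id, ".csv"))
    write_tracer_csv(s$tracer, tpath)
    data.frame(id = s$id, group = s$group, sex = s$sex, age_y = s$age,
               body_weight_kg = s$body_weight, bmi_kg_m2 = s$bmi,
               serum_retinol_umol_l = s$mean_serum_retinol,
               liver_weight_g = s$liver_weight,
               tracer_file = basename(tpath))
  })
  spath <- file.path(dir, "subjects.csv")
  utils::write.csv(do.call(rbind, rows), spath, row.names = FALSE)
  truth <- lapply(subjects, function(s) {
    if (is.null(s$truth)) return(NULL)
    list(id = s$id,
         params = as.list(unclass(s$truth$params)),
         M5 = s$truth$M5,
         TBS = s$truth$steady$TBS, DR = s$truth$steady$DR,
         U1 = s$truth$steady$U1)
  })
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(spath)
}
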