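#' Subject characteristics of the reference human tracer study
#'
#' Demographics, study-mean serum retinol concentrations and estimated liver
#' weights for the 13 older adults (7 US, 6 Chinese) of the 52-d oral
#' [²H₈]retinyl acetate tracer study this package's models target. Liver
#' weights were estimated as body surface area (m²) x 772.
#'
#' @return `data.frame` with columns `id`, `group` (`"US"`/`"CH"`), `sex`,
#'   `age_y`, `body_weight_kg`, `bmi_kg_m2`, `serum_retinol_umol_l`,
#'   `liver_weight_g`.
#' @export
study_subjects <- function() {
  utils::read.csv(system.file("extdata", "study_subjects.csv",
                              package = "vakinetics"),
                  stringsAsFactors = FALSE)
}

#' Published population steady-state estimates of the reference study
#'
#' Steady-state model outputs reported for the composite (geometric-mean)
#' data sets of each group under the three treatments: one extravascular
#' pool (`1EV`), two pools (`2EV`), and two pools with the dietary-intake
#' observation in the objective (`2EV_DI`). Used for worked examples and
#' for checking the package's steady-state identities against printed
#' values.
#'
#' @return `data.frame` with columns `group`, `treatment`, `U1_umol_d`,
#'   `M5_umol`, `M6_umol`, `M7_umol`, `TBS_umol`, `DR_umol_d`,
#'   `days_of_stores_d`, `liver_va_umol_g`.
#' @export
study_population_estimates <- function() {
  utils::read.csv(system.file("extdata", "study_population_estimates.csv",
                              package = "vakinetics"),
                  stringsAsFactors = FALSE)
}
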