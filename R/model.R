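#' Compartmental model specification
#'
#' Defines which of the two whole-body vitamin A model topologies is in use
#' and the constants that are fixed by assumption rather than fitted. Both
#' variants share an absorptive chain (compartment 1, the site of tracer and
#' dietary input; compartment 2; a pure delay element, compartment 3; and the
#' hepatic processing compartment 4) feeding the plasma retinol compartment 5.
#' Plasma exchanges with one large, slowly turning-over extravascular storage
#' compartment 6 (the site of irreversible loss) and, in the two-pool variant,
#' with an additional smaller extravascular compartment 7.
#'
#' @param variant `"ONE_EV"` (compartments 1-6) or `"TWO_EV"` (adds
#'   compartment 7).
#' @param include_diet_constraint logical; if `TRUE` the fitting objective is
#'   expected to carry a dietary-intake observation (the "DI" treatment).
#' @param absorption_efficiency fraction of the ingested dose absorbed, in
#'   (0, 1]. Default 0.75. Unabsorbed dose leaves compartment 1 irreversibly
#'   via the implied coefficient `L_10_1 = L_2_1 * (1 - a) / a`.
#' @param adjustable_parameters character vector of parameter names adjusted
#'   during fitting; defaults to the variant's standard adjustable set (see
#'   [default_adjustable()]).
#' @param fixed_parameters named list of parameter values held fixed during
#'   fitting (must be disjoint from `adjustable_parameters`).
#'
#' @return An object of class `"model_spec"`.
#' @seealso [kinetic_params()], [simulate_fdp()], [fit_model()]
#' @export
model_spec <- function(variant = c("TWO_EV", "ONE_EV"),
                       include_diet_constraint = FALSE,
                       absorption_efficiency = 0.75,
                       adjustable_parameters = NULL,
                       fixed_parameters = list()) {
  variant <- match.arg(variant)
  stopifnot(is.logical(include_diet_constraint), length(include_diet_constraint) == 1L)
  if (!is.numeric(absorption_efficiency) || length(absorption_efficiency) != 1L ||
      absorption_efficiency <= 0 || absorption_efficiency > 1) {
    stop("absorption_efficiency must be a single value in (0, 1]")
  }
  if (is.null(adjustable_parameters)) {
    adjustable_parameters <- default_adjustable(variant)
  }
  all_par <- variant_parameters(variant)
  unknown <- setdiff(adjustable_parameters, all_par)
  if (length(unknown)) {
    stop("unknown adjustable parameter(s) for variant ", variant, ": ",
         paste(unknown, collapse = ", "))
  }
  bad_fixed <- setdiff(names(fixed_parameters), all_par)
  if (length(bad_fixed)) {
    stop("unknown fixed parameter(s) for variant ", variant, ": ",
         paste(bad_fixed, collapse = ", "))
  }
  overlap <- intersect(adjustable_parameters, names(fixed_parameters))
  if (length(overlap)) {
    stop("parameters cannot be both adjustable and fixed: ",
         paste(overlap, collapse = ", "))
  }
  structure(
    list(variant = variant,
         include_diet_constraint = include_diet_constraint,
         absorption_efficiency = absorption_efficiency,
         adjustable_parameters = adjustable_parameters,
         fixed_parameters = fixed_parameters),
    class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Vitamin A compartmental model spec\n")
  cat("  variant:               ", x$variant,
      if (x$variant == "ONE_EV") "(compartments 1-6)" else "(compartments 1-7)", "\n")
  cat("  diet constraint:       ", x$include_diet_constraint, "\n")
  cat("  absorption efficiency: ", x$absorption_efficiency, "\n")
  cat("  adjustable:            ", paste(x$adjustable_parameters, collapse = ", "), "\n")
  if (length(x$fixed_parameters)) {
    cat("  fixed:                 ",
        paste(names(x$fixed_parameters), unlist(x$fixed_parameters),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# Parameter bookkeeping ------------------------------------------------------

# Free kinetic parameters per variant. L_10_1 is never free: it is implied by
# L_2_1 and the absorption efficiency.
.ONE_EV_PARS <- c("L_2_1", "L_3_2", "DT_3", "L_5_4", "L_6_5", "L_5_6", "L_10_6")
.TWO_EV_PARS <- c(.ONE_EV_PARS, "L_7_5", "L_5_7")

#' Full parameter list of a model variant
#' @param variant `"ONE_EV"` or `"TWO_EV"`.
#' @return Character vector of parameter names (`"L_I_J"` fractional transfer
#'   coefficients per day, destination I, source J, with `I = 10` the loss to
#'   outside, and the delay time `"DT_3"` in days).
#' @export
variant_parameters <- function(variant = c("TWO_EV", "ONE_EV")) {
  variant <- match.arg(variant)
  if (variant == "ONE_EV") .ONE_EV_PARS else .TWO_EV_PARS
}

#' Default adjustable parameter set of a model variant
#'
#' All free kinetic parameters are adjusted by default; the absorption
#' efficiency (and hence `L_10_1`) is always fixed.
#' @inheritParams variant_parameters
#' @return Character vector of parameter names.
#' @export
default_adjustable <- function(variant = c("TWO_EV", "ONE_EV")) {
  variant_parameters(match.arg(variant))
}

#' Kinetic parameter set
#'
#' Container for the fractional transfer coefficients `L(I,J)` (fraction of
#' vitamin A in compartment J transferred to compartment I per day; `I = 10`
#' denotes irreversible loss to the outside) and the delay time `DT(3)`
#' (days) of the absorption delay element.
#'
#' @param L_2_1,L_3_2,L_5_4,L_6_5,L_5_6,L_10_6 fractional transfer
#'   coefficients, per day; all must be >= 0.
#' @param DT_3 delay time in the absorption delay element, days; >= 0.
#' @param L_7_5,L_5_7 plasma/second-extravascular-pool exchange coefficients;
#'   only meaningful for the `TWO_EV` variant (default `NA`).
#' @return An object of class `"kinetic_params"` (a named numeric vector with
#'   extra validation).
#' @export
kinetic_params <- function(L_2_1, L_3_2, DT_3, L_5_4, L_6_5, L_5_6, L_10_6,
                           L_7_5 = NA_real_, L_5_7 = NA_real_) {
  p <- c(L_2_1 = L_2_1, L_3_2 = L_3_2, DT_3 = DT_3, L_5_4 = L_5_4,
         L_6_5 = L_6_5, L_5_6 = L_5_6, L_10_6 = L_10_6,
         L_7_5 = L_7_5, L_5_7 = L_5_7)
  known <- p[!is.na(p)]
  if (any(!is.finite(known))) stop("kinetic parameters must be finite")
  if (any(known < 0)) stop("kinetic parameters must be non-negative")
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (fractional transfer per day; DT_3 in days)\n")
  print(unclass(x)[!is.na(unclass(x))], ...)
  invisible(x)
}

# Coerce a named numeric vector or list into kinetic_params; missing TWO_EV
# entries stay NA.
as_kinetic_params <- function(x) {
  if (inherits(x, "kinetic_params")) return(x)
  x <- unlist(x)
  need <- .ONE_EV_PARS
  if (!all(need %in% names(x))) {
    stop("missing kinetic parameter(s): ",
         paste(setdiff(need, names(x)), collapse = ", "))
  }
  do.call(kinetic_params, as.list(x[intersect(.TWO_EV_PARS, names(x))]))
}

# Check a parameter set is complete and valid for the variant; returns the
# numeric vector restricted to the variant's parameters.
check_params <- function(params, spec) {
  params <- as_kinetic_params(params)
  need <- variant_parameters(spec$variant)
  p <- unclass(params)[need]
  if (any(is.na(p))) {
    stop("parameter(s) required by variant ", spec$variant, " are missing: ",
         paste(need[is.na(p)], collapse = ", "))
  }
  extra <- setdiff(names(unclass(params))[!is.na(unclass(params))], need)
  if (length(extra)) {
    stop("parameter(s) not allowed for variant ", spec$variant, ": ",
         paste(extra, collapse = ", "))
  }
  p
}

# Loss coefficient from compartment 1 implied by the fixed absorption
# efficiency a: absorbed fraction L21/(L21 + L101) == a.
loss_from_absorption <- function(L_2_1, absorption_efficiency) {
  a <- absorption_efficiency
  L_2_1 * (1 - a) / a
}

#' Assemble the system rate matrix
#'
#' Builds the square first-order rate matrix over the non-delay compartments
#' (1, 2, 4, 5, 6 and, for `TWO_EV`, 7). Off-diagonal entry (i, j) is
#' `L(i,j)`; diagonal entry (j, j) is minus the total fractional outflow of
#' compartment j, including irreversible losses to the outside (compartment
#' "10"): the unabsorbed-dose loss `L_10_1` implied by the absorption
#' efficiency, and `L_10_6` from the storage pool. The delay element
#' (compartment 3) is a pure time shift and is handled separately by the
#' simulator; here the efflux of compartment 2 (`L_3_2`) appears only in the
#' diagonal of compartment 2.
#'
#' @param params a [kinetic_params()] object (or coercible named vector).
#' @param spec a [model_spec()].
#' @return Square numeric matrix with dimnames `c("1","2","4","5","6"[,"7"])`.
#' @export
build_system_matrix <- function(params, spec) {
  p <- check_params(params, spec)
  comps <- if (spec$variant == "ONE_EV") c("1", "2", "4", "5", "6")
           else c("1", "2", "4", "5", "6", "7")
  A <- matrix(0, length(comps), length(comps), dimnames = list(comps, comps))
  L_10_1 <- loss_from_absorption(p[["L_2_1"]], spec$absorption_efficiency)
  A["2", "1"] <- p[["L_2_1"]]
  A["1", "1"] <- -(p[["L_2_1"]] + L_10_1)
  A["2", "2"] <- -p[["L_3_2"]]          # efflux into the delay element
  A["5", "4"] <- p[["L_5_4"]]
  A["4", "4"] <- -p[["L_5_4"]]
  A["6", "5"] <- p[["L_6_5"]]
  A["5", "6"] <- p[["L_5_6"]]
  A["6", "6"] <- -(p[["L_5_6"]] + p[["L_10_6"]])
  out5 <- p[["L_6_5"]]
  if (spec$variant == "TWO_EV") {
    A["7", "5"] <- p[["L_7_5"]]
    A["5", "7"] <- p[["L_5_7"]]
    A["7", "7"] <- -p[["L_5_7"]]
    out5 <- out5 + p[["L_7_5"]]
  }
  A["5", "5"] <- -out5
  A
}
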