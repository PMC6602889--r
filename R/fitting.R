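#' Observation set for model fitting
#'
#' Bundles the observed plasma tracer curve, its fractional-SD weight, the
#' measured plasma retinol pool (fixed during fitting; it anchors the
#' steady-state solution) and, for the diet-constrained fit, a dietary
#' vitamin A intake observation with its own fractional SD.
#'
#' @param tracer observed [tracer_curve()]; all `fdp` must be positive
#'   (fractional weights are undefined at zero).
#' @param plasma_pool_M5 measured plasma retinol pool, µmol (> 0).
#' @param fsd_plasma fractional SD of the plasma tracer data; default 0.05.
#' @param intake optional dietary intake observation, µmol/d; supply to
#'   request the diet-constrained objective.
#' @param fsd_intake fractional SD of the intake observation; default 0.1.
#' @param drop_nonpositive if `TRUE`, drop non-positive `fdp` observations
#'   with a warning instead of failing.
#' @return Object of class `"observation_set"`.
#' @export
observation_set <- function(tracer, plasma_pool_M5, fsd_plasma = 0.05,
                            intake = NULL, fsd_intake = 0.1,
                            drop_nonpositive = FALSE) {
  stopifnot(inherits(tracer, "tracer_curve"))
  if (any(tracer$fdp <= 0)) {
    if (drop_nonpositive) {
      warning("dropping ", sum(tracer$fdp <= 0),
              " non-positive fdp observation(s)")
      tracer <- tracer_curve(tracer$time_d[tracer$fdp > 0],
                             tracer$fdp[tracer$fdp > 0])
    } else {
      stop("observed fdp must be positive (fractional weights undefined); ",
           "set drop_nonpositive = TRUE to drop such points")
    }
  }
  stopifnot(is.numeric(plasma_pool_M5), plasma_pool_M5 > 0, fsd_plasma > 0)
  if (!is.null(intake)) {
    stopifnot(is.numeric(intake), length(intake) == 1L, intake > 0,
              fsd_intake > 0)
  }
  structure(
    list(tracer = tracer, plasma_pool_M5 = plasma_pool_M5,
         fsd_plasma = fsd_plasma, intake = intake, fsd_intake = fsd_intake),
    class = "observation_set")
}

#' Weighted residual vector
#'
#' Residuals on the fractional-SD scale: for each tracer point,
#' `(y - yhat) / (fsd_plasma * y)`; if an intake observation is present, one
#' additional entry `(u - uhat) / (fsd_intake * u)` where `uhat` is the
#' steady-state intake predicted from the current parameters and the fixed
#' plasma pool. The weighted sum of squares minimised by [fit_model()] is
#' the sum of squared entries. Because weights are relative, the objective
#' is invariant to rescaling the dose normalisation.
#'
#' @param obs an [observation_set()].
#' @inheritParams build_system_matrix
#' @return Numeric residual vector (tracer points first, then the intake
#'   entry if present).
#' @export
weighted_residuals <- function(obs, params, spec) {
  stopifnot(inherits(obs, "observation_set"))
  pred <- simulate_fdp(params, spec, obs$tracer$time_d)
  y <- obs$tracer$fdp
  r <- (y - pred$fdp) / (obs$fsd_plasma * y)
  if (!is.null(obs$intake)) {
    uhat <- predicted_intake(params, spec, obs$plasma_pool_M5)
    r <- c(r, (obs$intake - uhat) / (obs$fsd_intake * obs$intake))
  }
  r
}

#' Fit a compartmental model by weighted nonlinear least squares
#'
#' Minimises the weighted sum of squared residuals (see
#' [weighted_residuals()]) over the spec's adjustable parameters using
#' Levenberg-Marquardt least squares on log-transformed parameters (which
#' enforces positivity). Parameter uncertainty is reported as fractional SDs
#' derived from the final Jacobian: the covariance of the log-parameters is
#' `s2 * (J'J)^-1` with `s2 = wss / (n - p)`, and the SD of a log-parameter
#' is, to first order, the fractional SD of the parameter itself.
#'
#' @param obs an [observation_set()].
#' @param spec a [model_spec()]; its `adjustable_parameters` are fitted and
#'   its `fixed_parameters` held constant.
#' @param start starting [kinetic_params()] (or named vector). Defaults to
#'   [default_start()].
#' @param multi_start numeric vector of multiplicative factors; each factor
#'   scales all adjustable starting values for an additional optimisation
#'   run. The best weighted sum of squares wins; ties go to fewer
#'   iterations. Default `1` (single start).
#' @param starts optional list of additional full starting parameter sets
#'   (each coercible to [kinetic_params()]), run alongside the
#'   `multi_start` factors. See [two_pool_starts()] for the warm-start grid
#'   used when extending a one-pool fit.
#' @param control passed to [minpack.lm::nls.lm.control()]; defaults set
#'   `maxiter = 200`, `ftol = 1e-12`, `ptol = 1e-10`.
#' @return Object of class `"fit_result"`: list with `params` (full
#'   [kinetic_params()]), `wss`, `n_obs`, `n_free`, `param_fsd`,
#'   `converged`, `niter`, `start`, `spec` and `trace` (per-start summary).
#' @export
fit_model <- function(obs, spec, start = default_start(spec$variant),
                      multi_start = 1, starts = NULL, control = list()) {
  stopifnot(inherits(obs, "observation_set"), inherits(spec, "model_spec"))
  adj <- spec$adjustable_parameters
  start <- as_kinetic_params(start)
  full0 <- unclass(start)
  for (nm in names(spec$fixed_parameters)) {
    full0[[nm]] <- spec$fixed_parameters[[nm]]
  }
  sv <- full0[adj]
  if (any(is.na(sv) | sv <= 0)) {
    stop("starting values for adjustable parameters must be positive: ",
         paste(adj[is.na(sv) | sv <= 0], collapse = ", "))
  }
  n_obs <- nrow(obs$tracer) + as.integer(!is.null(obs$intake))
  n_free <- length(adj)
  if (n_obs <= n_free) stop("need more observations than free parameters")

  ctl <- utils::modifyList(
    list(maxiter = 200, ftol = 1e-12, ptol = 1e-10, nprint = 0), control)

  assemble <- function(theta) {
    full <- full0
    full[adj] <- exp(theta)
    as_kinetic_params(full[variant_parameters(spec$variant)])
  }
  resid_fn <- function(theta) {
    r <- tryCatch(weighted_residuals(obs, assemble(theta), spec),
                  error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) {
      return(rep(1e6, n_obs))
    }
    r
  }

  start_list <- c(
    lapply(multi_start, function(fac) list(theta0 = log(sv * fac), tag = fac)),
    lapply(seq_along(starts), function(i) {
      alt <- unclass(as_kinetic_params(starts[[i]]))[adj]
      if (any(is.na(alt) | alt <= 0)) {
        stop("starts[[", i, "]] has missing or non-positive adjustable values")
      }
      list(theta0 = log(alt), tag = NA_real_)
    }))
  runs <- lapply(start_list, function(s0) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s0$theta0, fn = resid_fn,
                         control = do.call(minpack.lm::nls.lm.control, ctl)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(fit = fit, factor = s0$tag, wss = fit$deviance, niter = fit$niter)
  })
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) stop("all optimisation starts failed")
  wssv <- vapply(runs, `[[`, numeric(1), "wss")
  itv <- vapply(runs, `[[`, numeric(1), "niter")
  best <- runs[[order(wssv, itv)[1]]]
  fit <- best$fit

  params <- assemble(fit$par)
  wss <- fit$deviance
  converged <- fit$info %in% 1:4
  s2 <- wss / (n_obs - n_free)
  param_fsd <- rep(NA_real_, n_free)
  names(param_fsd) <- adj
  JtJ <- fit$hessian   # nls.lm stores J'J of the final Jacobian
  if (!is.null(JtJ) && rcond(JtJ) > 1e-14) {
    covl <- s2 * solve(JtJ)
    param_fsd[] <- sqrt(pmax(diag(covl), 0))
  }
  structure(
    list(params = params, wss = wss, n_obs = n_obs, n_free = n_free,
         param_fsd = param_fsd, converged = converged, niter = fit$niter,
         message = fit$message, start = sv, spec = spec,
         trace = data.frame(factor = vapply(runs, `[[`, numeric(1), "factor"),
                            wss = wssv, niter = itv)),
    class = "fit_result")
}

#' Default starting values
#'
#' Order-of-magnitude starting values for the adjustable parameters: fast
#' absorption and chylomicron processing (hours), a short hepatic delay,
#' rapid plasma-to-storage exchange and slow storage turnover.
#'
#' @inheritParams variant_parameters
#' @return A [kinetic_params()] object.
#' @export
default_start <- function(variant = c("TWO_EV", "ONE_EV")) {
  variant <- match.arg(variant)
  if (variant == "ONE_EV") {
    kinetic_params(L_2_1 = 1.5, L_3_2 = 6, DT_3 = 0.1, L_5_4 = 3,
                   L_6_5 = 2, L_5_6 = 0.05, L_10_6 = 0.01)
  } else {
    kinetic_params(L_2_1 = 1.5, L_3_2 = 6, DT_3 = 0.1, L_5_4 = 3,
                   L_6_5 = 2, L_5_6 = 0.05, L_10_6 = 0.01,
                   L_7_5 = 0.5, L_5_7 = 0.2)
  }
}

#' Warm starts for extending a one-pool fit to two pools
#'
#' The second extravascular pool is weakly identified, and a cold-started
#' two-pool optimisation often collapses onto the one-pool optimum. The
#' standard remedy is to start the complex model at the simple model's
#' optimum and scan a small grid of pool-7 exchange pairs
#' `(L_7_5, L_5_7)` spanning slow to fast uptake and return.
#'
#' @param simple a one-pool [fit_model()] result (or a [kinetic_params()]
#'   set missing the pool-7 coefficients).
#' @param pairs two-column matrix of `(L_7_5, L_5_7)` values, per day.
#' @return List of [kinetic_params()] starting sets for
#'   `fit_model(..., starts = )`.
#' @export
two_pool_starts <- function(simple,
                            pairs = cbind(L_7_5 = c(0.2, 0.2, 2, 2, 0.5),
                                          L_5_7 = c(0.05, 0.5, 0.1, 1, 5))) {
  base <- if (inherits(simple, "fit_result")) simple$params else
    as_kinetic_params(simple)
  base <- unclass(base)
  apply(pairs, 1, function(pr) {
    base[["L_7_5"]] <- pr[[1]]
    base[["L_5_7"]] <- pr[[2]]
    as_kinetic_params(base)
  }, simplify = FALSE)
}

#' @export
print.fit_result <- function(x, digits = 4, ...) {
  cat("Weighted nonlinear least-squares fit (", x$spec$variant,
      if (!is.null(x$spec$include_diet_constraint) &&
          x$spec$include_diet_constraint) " + diet constraint" else "",
      ")\n", sep = "")
  cat("  wss:", format(signif(x$wss, digits)),
      " n_obs:", x$n_obs, " n_free:", x$n_free,
      " converged:", x$converged, "\n")
  est <- unclass(x$params)[x$spec$adjustable_parameters]
  tab <- data.frame(estimate = signif(est, digits),
                    fsd = signif(x$param_fsd[names(est)], 3))
  print(tab)
  invisible(x)
}

#' Nested-model comparison by F statistic
#'
#' Tests whether the drop in weighted sum of squares achieved by the more
#' complex model is statistically justified:
#' `F = ((wss_s - wss_c) / (p_c - p_s)) / (wss_c / (n - p_c))`, referred to
#' the F distribution with `(p_c - p_s, n - p_c)` degrees of freedom. Both
#' fits must be to the same observation set.
#'
#' @param simple,complex [fit_model()] results; `complex` must have more
#'   free parameters and the same number of observations.
#' @return List with `F`, `p`, `df1`, `df2`.
#' @export
f_test <- function(simple, complex) {
  stopifnot(inherits(simple, "fit_result"), inherits(complex, "fit_result"))
  if (complex$n_obs != simple$n_obs) {
    stop("fits compare different observation sets (n_obs differ)")
  }
  df1 <- complex$n_free - simple$n_free
  df2 <- complex$n_obs - complex$n_free
  if (df1 <= 0 || df2 <= 0) stop("non-nested comparison or no residual df")
  Fstat <- ((simple$wss - complex$wss) / df1) / (complex$wss / df2)
  Fstat <- max(Fstat, 0)   # wss can tick up if the complex fit stalls
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}
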