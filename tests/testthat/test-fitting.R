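test_that("weighted residuals follow the fractional-SD convention", {
  spec <- model_spec("TWO_EV")
  p <- template_params("CHINESE_LIKE")
  curve <- simulate_fdp(p, spec)

  # self-fit: residuals vanish
  obs <- observation_set(curve, plasma_pool_M5 = 3.43)
  expect_equal(max(abs(weighted_residuals(obs, p, spec))), 0, tolerance = 1e-9)

  # intake residual: (u - uhat) / (fsd * u); uhat = M5 * L65 * L106 /
  # ((L56 + L106) * a). Parameters give uhat = 4/3 * M5.
  spec_di <- model_spec("TWO_EV", include_diet_constraint = TRUE)
  pu <- kinetic_params(L_2_1 = 1.5, L_3_2 = 6, DT_3 = 0.1, L_5_4 = 3,
                       L_6_5 = 2, L_5_6 = 0.05, L_10_6 = 0.05,
                       L_7_5 = 0.5, L_5_7 = 0.2)
  cv <- simulate_fdp(pu, spec_di)
  obs_match <- observation_set(cv, plasma_pool_M5 = 2.1, intake = 2.8)
  r <- weighted_residuals(obs_match, pu, spec_di)
  expect_equal(r[length(r)], 0, tolerance = 1e-12)   # uhat = 2.8
  obs_double <- observation_set(cv, plasma_pool_M5 = 4.2, intake = 2.8)
  r2 <- weighted_residuals(obs_double, pu, spec_di)
  expect_equal(r2[length(r2)], -10, tolerance = 1e-12)  # uhat = 5.6

  # non-positive observations are rejected unless explicitly dropped
  bad <- tracer_curve(c(1, 2, 3), c(0.1, 0, 0.05))
  expect_error(observation_set(bad, 3.43), "positive")
  expect_warning(ok <- observation_set(bad, 3.43, drop_nonpositive = TRUE),
                 "dropping")
  expect_equal(nrow(ok$tracer), 2L)
})

test_that("noise-free data are recovered up to the absorptive-chain symmetry", {
  # the plasma curve is invariant under permuting the three absorptive rates
  # {L_2_1 / a, L_3_2, L_5_4}; everything else is identifiable
  spec <- model_spec("TWO_EV", include_diet_constraint = TRUE)
  p <- template_params("US_LIKE")
  curve <- simulate_fdp(p, spec)
  obs <- observation_set(curve, plasma_pool_M5 = 5, intake = 2.8)
  start <- unclass(p)
  start[] <- start * rep(c(2, 0.5), length.out = length(start))
  fit <- fit_model(obs, spec, start = start,
                   control = list(maxiter = 500, ftol = 1e-15, ptol = 1e-13))
  expect_true(fit$converged)
  expect_lt(fit$wss, 1e-6)
  est <- unclass(fit$params)
  tru <- unclass(p)
  ident <- c("DT_3", "L_6_5", "L_5_6", "L_10_6", "L_7_5", "L_5_7")
  expect_equal(est[ident], tru[ident], tolerance = 2e-3)
  a <- spec$absorption_efficiency
  expect_equal(sort(c(est[["L_2_1"]] / a, est[["L_3_2"]], est[["L_5_4"]])),
               sort(c(tru[["L_2_1"]] / a, tru[["L_3_2"]], tru[["L_5_4"]])),
               tolerance = 2e-3)
  # steady-state outputs are unaffected by the symmetry
  st_fit <- solve_steady_state(fit$params, spec, 5)
  st_tru <- solve_steady_state(p, spec, 5)
  expect_equal(st_fit$TBS, st_tru$TBS, tolerance = 5e-3)
})

test_that("correct fractional weighting gives unit reduced weighted SS", {
  # data generated and fitted under the one-pool model: wss / (n - p) ~ 1
  p1 <- fix_one_ev_params()
  red <- vapply(1:12, function(r) {
    cfg <- generator_config(n_subjects = 1, group_template = "CHINESE_LIKE",
                            true_params = p1, variant = "ONE_EV",
                            param_gsd = 1, seed = 900 + r)
    s <- generate_subject(cfg, 1)
    obs <- observation_set(s$tracer, s$truth$M5)
    fit <- fit_model(obs, model_spec("ONE_EV"))
    fit$wss / (fit$n_obs - fit$n_free)
  }, numeric(1))
  expect_gt(mean(red), 0.6)
  expect_lt(mean(red), 1.4)
})

test_that("the F statistic matches hand arithmetic and controls type I error", {
  mk <- function(wss, n_obs, n_free) {
    structure(list(wss = wss, n_obs = n_obs, n_free = n_free),
              class = "fit_result")
  }
  # equal fits: F = 0, p = 1
  ft0 <- f_test(mk(10, 19, 7), mk(10, 19, 9))
  expect_equal(ft0$F, 0)
  expect_equal(ft0$p, 1)
  # wss 20 -> 10, 2 extra parameters, 12 residual df: F = (10/2)/(10/12) = 6
  ft <- f_test(mk(20, 21, 7), mk(10, 21, 9))
  expect_equal(ft$F, 6)
  expect_equal(ft$p, 0.015625, tolerance = 1e-6)
  expect_error(f_test(mk(10, 19, 9), mk(9, 19, 9)), "non-nested")
  expect_error(f_test(mk(10, 19, 7), mk(9, 20, 9)), "different observation")

  # null calibration: one-pool data fitted by both variants. The null sits
  # on the boundary of the two-pool family, so p-values are conservative;
  # the rejection rate at 0.05 must not exceed its nominal level (binomial
  # slack for 25 replicates).
  p1 <- fix_one_ev_params()
  pv <- vapply(1:25, function(r) {
    cfg <- generator_config(n_subjects = 1, group_template = "CHINESE_LIKE",
                            true_params = p1, variant = "ONE_EV",
                            param_gsd = 1, seed = 3000 + r)
    s <- generate_subject(cfg, 1)
    obs <- observation_set(s$tracer, s$truth$M5)
    f1 <- fit_model(obs, model_spec("ONE_EV"))
    f2 <- fit_model(obs, model_spec("TWO_EV"), starts = two_pool_starts(f1))
    f_test(f1, f2)$p
  }, numeric(1))
  expect_lte(mean(pv < 0.05), 0.12)
})

test_that("the diet constraint improves storage-turnover estimation", {
  # replicate noisy single fits with and without the intake observation:
  # the constrained fit estimates L_10_6 (hence TBS and DR) better
  spec_di <- model_spec("TWO_EV", include_diet_constraint = TRUE)
  spec2 <- model_spec("TWO_EV")
  tru <- template_params("US_LIKE")
  err <- t(vapply(1:8, function(r) {
    cfg <- generator_config(n_subjects = 1, param_gsd = 1, seed = 700 + r)
    s <- generate_subject(cfg, 1)
    u_true <- s$truth$steady$U1
    o_di <- observation_set(s$tracer, s$truth$M5, intake = 2.8)
    o_pl <- observation_set(s$tracer, s$truth$M5)
    warm <- two_pool_starts(fit_model(o_pl, model_spec("ONE_EV")))
    f_di <- fit_model(o_di, spec_di, starts = warm)
    f_pl <- fit_model(o_pl, spec2, starts = warm)
    c(di = abs(unclass(f_di$params)[["L_10_6"]] - tru[["L_10_6"]]),
      pl = abs(unclass(f_pl$params)[["L_10_6"]] - tru[["L_10_6"]]))
  }, numeric(2))) / tru[["L_10_6"]]
  expect_lt(median(err[, "di"]), median(err[, "pl"]))
  expect_lt(median(err[, "di"]), 0.5)
})

test_that("a tight intake weight pins the fitted steady-state intake", {
  spec_di <- model_spec("TWO_EV", include_diet_constraint = TRUE)
  cfg <- generator_config(n_subjects = 1, param_gsd = 1, seed = 77)
  s <- generate_subject(cfg, 1)
  warm <- two_pool_starts(
    fit_model(observation_set(s$tracer, s$truth$M5), model_spec("ONE_EV")))
  fits <- lapply(c(0.1, 1e-4), function(fsd) {
    obs <- observation_set(s$tracer, s$truth$M5, intake = 2.8,
                           fsd_intake = fsd)
    fit_model(obs, spec_di, starts = warm)
  })
  u <- vapply(fits, function(f) predicted_intake(f$params, spec_di,
                                                 s$truth$M5), numeric(1))
  expect_lt(abs(u[2] - 2.8), abs(u[1] - 2.8) + 1e-9)
  expect_equal(u[2], 2.8, tolerance = 1e-3)
})
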