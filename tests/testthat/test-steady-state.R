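test_that("steady-state masses satisfy the exchange formulas and flow balance", {
  spec <- model_spec("TWO_EV")
  p <- template_params("US_LIKE")
  st <- solve_steady_state(p, spec, M5 = 5)
  pp <- unclass(p)
  expect_equal(st$M6, 5 * pp[["L_6_5"]] / (pp[["L_5_6"]] + pp[["L_10_6"]]))
  expect_equal(st$M7, 5 * pp[["L_7_5"]] / pp[["L_5_7"]])
  expect_equal(st$TBS, st$M6 + st$M7)
  expect_equal(st$DR, st$M6 * pp[["L_10_6"]])
  expect_equal(st$days_of_stores, st$TBS / st$DR)
  expect_lt(max(abs(steady_state_residual(p, spec, st))), 1e-10)

  # property: DR = a * U1 exactly, and days of stores invariant to M5
  # rescaling, across a random parameter grid
  set.seed(11)
  for (i in 1:20) {
    q <- unclass(p) * stats::rlnorm(9, 0, 0.5)
    a <- stats::runif(1, 0.3, 1)
    sp <- model_spec("TWO_EV", absorption_efficiency = a)
    s1 <- solve_steady_state(q, sp, M5 = 4)
    s2 <- solve_steady_state(q, sp, M5 = 400)
    expect_equal(s1$DR, a * s1$U1, tolerance = 1e-12)
    expect_equal(s1$days_of_stores, s2$days_of_stores, tolerance = 1e-10)
    expect_lt(max(abs(steady_state_residual(q, sp, s1))), 1e-10)
  }

  # no storage pathway: zero mass and disposal, undefined days of stores
  p0 <- unclass(p)
  p0["L_6_5"] <- 0
  st0 <- solve_steady_state(p0, spec, M5 = 5)
  expect_equal(st0$M6, 0)
  expect_equal(st0$DR, 0)
  expect_true(is.na(st0$days_of_stores))

  # division by a zero exchange coefficient is a structural error naming it
  pz <- unclass(p)
  pz["L_5_6"] <- 0
  pz["L_10_6"] <- 0
  expect_error(solve_steady_state(pz, spec, 5), "L_5_6 \\+ L_10_6")
  pz7 <- unclass(p)
  pz7["L_5_7"] <- 0
  expect_error(solve_steady_state(pz7, spec, 5), "L_5_7")
})

test_that("plasma pool, liver weight and liver concentration rules", {
  # subject CH6: 1.58 umol/L, 72.0 kg at 0.0435 L/kg
  expect_equal(plasma_pool_size(1.58, 72.0), 4.9486, tolerance = 1e-4)
  expect_equal(plasma_pool_size(0, 70), 0)
  expect_equal(liver_weight_from_bsa(1.781), 1374.9, tolerance = 1e-4)
  expect_equal(liver_va_concentration(0, 1300), 0)
  expect_equal(liver_va_concentration(1000, 900, liver_fraction = 0.9), 1)
})

test_that("transit, residence and recycling formulas on hand-solvable cases", {
  # storage pool draining only to the outside at 0.5/d: a single passage,
  # so transit = residence per unit entering = 2 d and no plasma recycling
  p <- kinetic_params(L_2_1 = 1.5, L_3_2 = 6, DT_3 = 0.1, L_5_4 = 3,
                      L_6_5 = 2, L_5_6 = 0, L_10_6 = 0.5)
  dk <- derived_kinetics(p, model_spec("ONE_EV"))
  expect_equal(dk$transit_time[["6"]], 2)
  expect_equal(dk$residence_time["6", "6"], 2)
  expect_equal(dk$plasma_recycling_number, 0)

  # plasma/storage exchange: return probability 0.05/0.06, recycling number
  # p/(1-p) = 5, conditional excursion time 1/(0.05+0.01)
  p2 <- kinetic_params(L_2_1 = 1.5, L_3_2 = 6, DT_3 = 0.1, L_5_4 = 3,
                       L_6_5 = 2, L_5_6 = 0.05, L_10_6 = 0.01)
  dk2 <- derived_kinetics(p2, model_spec("ONE_EV"))
  expect_equal(dk2$plasma_recycling_number, 5)
  expect_equal(dk2$plasma_recycling_time, 1 / 0.06)
  expect_equal(dk2$transit_time[["5"]], 0.5)
  expect_equal(dk2$transit_time[["3"]], 0.1)

  # no loss path at all is singular
  pl <- kinetic_params(L_2_1 = 1.5, L_3_2 = 6, DT_3 = 0.1, L_5_4 = 3,
                       L_6_5 = 2, L_5_6 = 0.05, L_10_6 = 0)
  expect_error(derived_kinetics(pl, model_spec("ONE_EV",
                                               absorption_efficiency = 1)),
               "singular")
})

test_that("residence matrix columns integrate to per-route system residence", {
  spec <- model_spec("TWO_EV")
  p <- template_params("CHINESE_LIKE")
  dk <- derived_kinetics(p, spec)
  # independent first-step analysis of mean time to loss from plasma:
  # E5 = transit5 + (l65 E6 + l75 E7)/(l65+l75); E6 = transit6 + p_ret E5;
  # E7 = transit7 + E5
  q <- unclass(p)
  l65 <- q[["L_6_5"]]; l75 <- q[["L_7_5"]]
  l56 <- q[["L_5_6"]]; l106 <- q[["L_10_6"]]; l57 <- q[["L_5_7"]]
  M <- matrix(c(1, -l65 / (l65 + l75), -l75 / (l65 + l75),
                -l56 / (l56 + l106), 1, 0,
                -1, 0, 1), 3, 3, byrow = TRUE)
  rhs <- c(1 / (l65 + l75), 1 / (l56 + l106), 1 / l57)
  E <- solve(M, rhs)
  expect_equal(sum(dk$residence_time[, "5"]), E[1], tolerance = 1e-10)
  # entry at 1: system residence = column sum + absorbed delay time
  expect_equal(dk$system_residence_time,
               sum(dk$residence_time[, "1"]) +
                 spec$absorption_efficiency * unclass(p)[["DT_3"]])
})
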