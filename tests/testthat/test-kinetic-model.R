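test_that("system matrix assembles the declared topology with mass balance", {
  spec2 <- model_spec("TWO_EV")
  p <- kinetic_params(L_2_1 = 1.5, L_3_2 = 6, DT_3 = 0.1, L_5_4 = 3,
                      L_6_5 = 2, L_5_6 = 0.05, L_10_6 = 0.01,
                      L_7_5 = 0.1, L_5_7 = 0.2)
  A <- build_system_matrix(p, spec2)
  expect_equal(dim(A), c(6L, 6L))
  # hand-assembled entries
  expect_equal(A["7", "5"], 0.1)
  expect_equal(A["5", "7"], 0.2)
  expect_equal(A["2", "1"], 1.5)
  expect_equal(A["1", "1"], -(1.5 + 1.5 * 0.25 / 0.75))
  expect_equal(A["5", "5"], -(2 + 0.1))   # pool-7 uptake in the diagonal of 5
  expect_equal(A["6", "6"], -(0.05 + 0.01))
  # columns whose outflow stays inside the matrix sum to minus the loss to
  # the outside (compartment 2 empties into the delay, handled separately)
  cs <- colSums(A)
  expect_equal(cs[["1"]], -1.5 * 0.25 / 0.75)
  expect_equal(cs[["4"]], 0)
  expect_equal(cs[["5"]], 0)
  expect_equal(cs[["6"]], -0.01)
  expect_equal(cs[["7"]], 0)

  # all transfers zero except structural minimum -> zero storage block
  p0 <- kinetic_params(L_2_1 = 0, L_3_2 = 0, DT_3 = 0, L_5_4 = 0,
                       L_6_5 = 0, L_5_6 = 0, L_10_6 = 0)
  A0 <- build_system_matrix(p0, model_spec("ONE_EV"))
  expect_true(all(A0 == 0))

  # pool-7 edges are rejected for the one-pool variant
  expect_error(build_system_matrix(p, model_spec("ONE_EV")),
               "not allowed")
  expect_error(kinetic_params(L_2_1 = -1, L_3_2 = 6, DT_3 = 0.1, L_5_4 = 3,
                              L_6_5 = 2, L_5_6 = 0.05, L_10_6 = 0.01),
               "non-negative")
  expect_error(model_spec("ONE_EV", adjustable_parameters = "L_6_5",
                          fixed_parameters = list(L_6_5 = 2)),
               "both adjustable and fixed")
})

test_that("simulated tracer obeys delay, conservation and zero-transfer limits", {
  times <- default_sampling_grid()
  # no transfers: tracer never reaches plasma
  p0 <- kinetic_params(L_2_1 = 0, L_3_2 = 0, DT_3 = 0, L_5_4 = 0,
                       L_6_5 = 0, L_5_6 = 0, L_10_6 = 0)
  expect_equal(simulate_fdp(p0, model_spec("ONE_EV"), times)$fdp,
               rep(0, length(times)))

  # pure delay blocks arrival before DT_3
  pd <- template_params("US_LIKE")
  pd["DT_3"] <- 2
  cv <- simulate_fdp(pd, model_spec("TWO_EV"), c(0.5, 1, 1.9, 2.5, 5))
  expect_equal(cv$fdp[1:3], c(0, 0, 0))
  expect_gt(cv$fdp[4], 0)

  # with all losses removed, dose is conserved across compartments + delay
  spec_cons <- model_spec("TWO_EV", absorption_efficiency = 1)
  pc <- template_params("US_LIKE")
  pc["L_10_6"] <- 0
  Q <- simulate_compartments(pc, spec_cons, c(0.05, 0.2, 1, 5, 20, 52))
  expect_equal(rowSums(Q), rep(1, 6), tolerance = 1e-8)
})

test_that("forced linear subsystem matches a quadrature oracle to 1e-8", {
  # plasma/storage exchange pair with no loss, driven by a decaying input:
  # independent oracle = adaptive quadrature of the matrix-exponential
  # convolution integral
  A <- matrix(c(-0.7, 0.7, 0.3, -0.3), 2, 2)   # columns: from 5, from 6
  b <- c(1, 0)
  k <- 2.5; cc <- 1.3
  tau <- c(0.3, 1, 2.7, 6, 15)
  got <- vakinetics:::solve_forced_linear(A, b, rate = k, coef = cc, tau = tau)
  oracle <- vapply(tau, function(tt) {
    vapply(1:2, function(i) {
      stats::integrate(function(s) {
        vapply(s, function(si) {
          (as.matrix(Matrix::expm(A * (tt - si))) %*% b)[i] * cc * exp(-k * si)
        }, numeric(1))
      }, 0, tt, rel.tol = 1e-12)$value
    }, numeric(1))
  }, numeric(2))
  expect_equal(got, t(oracle), tolerance = 1e-8)
})

test_that("shifting the delay shifts the downstream response exactly", {
  spec <- model_spec("TWO_EV")
  p1 <- template_params("CHINESE_LIKE")
  p2 <- p1
  p1["DT_3"] <- 0.1
  p2["DT_3"] <- 0.6
  t1 <- c(0.5, 1, 2, 5, 10, 30, 52)
  a <- simulate_fdp(p1, spec, t1)
  b <- simulate_fdp(p2, spec, t1 + 0.5)
  expect_equal(b$fdp, a$fdp, tolerance = 1e-10)
})

test_that("simulator agrees with an independent delay-ODE integrator", {
  skip_if_not_installed("deSolve")
  spec <- model_spec("TWO_EV")
  for (grp in c("US_LIKE", "CHINESE_LIKE")) {
    p <- template_params(grp)
    cv <- simulate_fdp(p, spec)
    ora <- dede_fdp(p, spec, default_sampling_grid())
    expect_lt(max(abs(cv$fdp - ora) / pmax(abs(ora), 1e-12)), 1e-6)
  }
})

test_that("faster storage uptake lowers the late-time plasma curve", {
  spec <- model_spec("TWO_EV")
  late <- vapply(c(0.5, 1, 2, 4, 8), function(l65) {
    p <- template_params("US_LIKE")
    p["L_6_5"] <- l65
    simulate_fdp(p, spec, c(35, 42, 52))$fdp[3]
  }, numeric(1))
  expect_true(all(diff(late) < 0))
})

test_that("terminal slope recovers exponential decay and the slow eigenvalue", {
  tt <- c(1, 3, 6, 10, 15)
  cv <- tracer_curve(tt, 0.5 * exp(-0.1 * tt))
  expect_equal(terminal_slope(cv), -0.1, tolerance = 1e-10)
  flat <- tracer_curve(tt, rep(0.25, 5))
  expect_equal(terminal_slope(flat), 0, tolerance = 1e-12)
  expect_error(terminal_slope(cv, window = c(0, 3.5)), "at least 3 points")
  bad <- tracer_curve(tt, c(0.5, 0.2, 0, 0.1, 0.05))
  expect_error(terminal_slope(bad), "positive")

  # far beyond the study window the log-slope approaches the
  # smallest-magnitude eigenvalue of the downstream system matrix
  spec <- model_spec("TWO_EV")
  p <- template_params("CHINESE_LIKE")
  A <- build_system_matrix(p, spec)[c("4", "5", "6", "7"),
                                    c("4", "5", "6", "7")]
  lam <- max(eigen(A, only.values = TRUE)$values)
  sim <- simulate_fdp(p, spec, seq(100, 150, length.out = 12))
  expect_equal(terminal_slope(sim), lam, tolerance = 0.01)
})

test_that("tracer curve validation rejects malformed inputs", {
  expect_error(tracer_curve(c(1, 2), c(0.1, 0.2, 0.3)), "lengths differ")
  expect_error(tracer_curve(c(2, 1), c(0.1, 0.2)), "strictly increasing")
  expect_error(tracer_curve(c(1, 2), c(-0.1, 0.2)), "\\[0, 1\\]")
  expect_error(simulate_fdp(template_params("US_LIKE"), model_spec("TWO_EV"),
                            c(-1, 2)),
               "non-negative")
})
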