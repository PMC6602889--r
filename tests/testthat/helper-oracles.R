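# Independent oracles used across the test suite.

# Delay-differential-equation oracle for the full tracer system, integrated
# with deSolve::dede at tight tolerance. Returns fdp at `times`.
dede_fdp <- function(params, spec, times) {
  p <- unclass(vakinetics::kinetic_params(
    L_2_1 = params[["L_2_1"]], L_3_2 = params[["L_3_2"]],
    DT_3 = params[["DT_3"]], L_5_4 = params[["L_5_4"]],
    L_6_5 = params[["L_6_5"]], L_5_6 = params[["L_5_6"]],
    L_10_6 = params[["L_10_6"]],
    L_7_5 = if ("L_7_5" %in% names(unclass(params)))
      unclass(params)[["L_7_5"]] else NA_real_,
    L_5_7 = if ("L_5_7" %in% names(unclass(params)))
      unclass(params)[["L_5_7"]] else NA_real_))
  two <- spec$variant == "TWO_EV"
  a <- spec$absorption_efficiency
  k1 <- p[["L_2_1"]] / a
  l75 <- if (two) p[["L_7_5"]] else 0
  l57 <- if (two) p[["L_5_7"]] else 0
  dfun <- function(t, y, parms) {
    q2lag <- if (t > p[["DT_3"]]) deSolve::lagvalue(t - p[["DT_3"]], 2) else 0
    dy <- c(-k1 * y[1],
            p[["L_2_1"]] * y[1] - p[["L_3_2"]] * y[2],
            p[["L_3_2"]] * q2lag - p[["L_5_4"]] * y[3],
            p[["L_5_4"]] * y[3] - (p[["L_6_5"]] + l75) * y[4] +
              p[["L_5_6"]] * y[5] + l57 * y[6],
            p[["L_6_5"]] * y[4] - (p[["L_5_6"]] + p[["L_10_6"]]) * y[5],
            l75 * y[4] - l57 * y[6])
    list(dy)
  }
  sol <- deSolve::dede(c(1, 0, 0, 0, 0, 0), c(0, times), dfun, NULL,
                       rtol = 1e-10, atol = 1e-14)
  sol[-1, 5]
}

# Single-molecule jump-process Monte Carlo over the retained compartments.
# Molecules start in `start`; the 2 -> 4 transition passes through the delay
# (deterministic DT_3 added to the delay clock). Returns mean total time per
# compartment, mean delay time, plasma transit/recycling statistics.
mc_tracer_theory <- function(params, spec, start = "5", n = 1e5, seed = 1) {
  set.seed(seed)
  p <- unclass(params)
  A <- vakinetics::build_system_matrix(params, spec)
  comps <- colnames(A)
  nc <- length(comps)
  i5 <- match("5", comps)
  i2 <- match("2", comps)
  i4 <- match("4", comps)
  rates <- -diag(A)
  # per-source destination cdf (loss = tail mass)
  cdf <- lapply(seq_len(nc), function(j) {
    probs <- A[, j]
    probs[j] <- 0
    if (comps[j] == "2") probs[i4] <- p[["L_3_2"]]
    cumsum(probs)
  })
  state <- rep(match(start, comps), n)
  tot <- numeric(nc)
  delay_total <- 0
  visits5 <- numeric(n)
  time5 <- 0
  exc_time <- numeric(n)
  rec_time_sum <- 0
  rec_count <- 0
  alive <- rep(TRUE, n)
  while (any(alive)) {
    idx <- which(alive)
    st <- state[idx]
    rate <- rates[st]
    dt <- stats::rexp(length(idx), rate)
    add <- tapply(dt, st, sum)
    ii <- as.integer(names(add))
    tot[ii] <- tot[ii] + add
    time5 <- time5 + sum(dt[st == i5])
    ev <- comps[st] %in% c("6", "7")
    exc_time[idx[ev]] <- exc_time[idx[ev]] + dt[ev]
    u <- stats::runif(length(idx)) * rate
    newstate <- integer(length(idx))
    for (j in unique(st)) {
      sel <- st == j
      cj <- cdf[[j]]
      dest <- findInterval(u[sel], cj) + 1L
      dest[u[sel] >= cj[nc]] <- 0L            # irreversible loss
      newstate[sel] <- dest
    }
    via_delay <- st == i2 & newstate == i4
    delay_total <- delay_total + sum(via_delay) * p[["DT_3"]]
    arrive5 <- newstate == i5
    closing <- arrive5 & ev
    rec_time_sum <- rec_time_sum + sum(exc_time[idx[closing]])
    rec_count <- rec_count + sum(closing)
    exc_time[idx[closing]] <- 0
    visits5[idx[arrive5]] <- visits5[idx[arrive5]] + 1
    alive[idx[newstate == 0L]] <- FALSE
    keep <- newstate != 0L
    state[idx[keep]] <- newstate[keep]
  }
  first_visit <- as.integer(start == "5")   # the initial occupancy of plasma
  list(residence = stats::setNames(tot / n, comps),
       delay_time = delay_total / n,
       recycling_number = mean(visits5),
       recycling_time = if (rec_count) rec_time_sum / rec_count else NA_real_,
       plasma_transit = time5 / (sum(visits5) + first_visit * n),
       total_time = sum(tot) / n + delay_total / n)
}
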