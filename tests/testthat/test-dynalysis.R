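test_that("integration converges, respects tolerances and detects
           bistability from initial conditions", {
  sysA <- build_embryonic(embryonic_params(b_syn = 1))
  ss <- steady_states(sysA)
  for (ini in list(c(1, 0.05), c(60, 0.9))) {
    tr <- integrate_system(sysA, init = ini, t_span = c(0, 2000), dt = 1)
    fin <- tr$state[nrow(tr$state), ]
    expect_equal(unname(fin), unname(c(ss$Cdk1, ss$APC)), tolerance = 1e-5)
  }
  # solver-convergence: halving tolerances barely moves the endpoint
  tr1 <- integrate_system(sysA, init = c(5, 0.2), t_span = c(0, 300),
                          dt = 0.5, rtol = 1e-8, atol = 1e-10)
  tr2 <- integrate_system(sysA, init = c(5, 0.2), t_span = c(0, 300),
                          dt = 0.5, rtol = 5e-9, atol = 5e-11)
  f1 <- tr1$state[nrow(tr1$state), ]; f2 <- tr2$state[nrow(tr2$state), ]
  expect_lt(max(abs(f1 - f2) / pmax(abs(f2), 1e-6)), 1e-6)
  # bistable configuration: two basins
  sysB <- build_embryonic(embryonic_params(b_syn = 0.8, alpha_apc = 20))
  lo <- integrate_system(sysB, init = c(0, 0), t_span = c(0, 2000), dt = 1)
  hi <- integrate_system(sysB, init = c(5, 0.95), t_span = c(0, 2000),
                         dt = 1)
  expect_gt(abs(lo$state[nrow(lo$state), "APC"] -
                  hi$state[nrow(hi$state), "APC"]), 0.3)
})

test_that("steady_states finds the bistable triplet with correct
           stability and tiny residuals", {
  sysB <- build_embryonic(embryonic_params(b_syn = 0.8, alpha_apc = 20))
  ss <- steady_states(sysB)
  expect_equal(nrow(ss), 3L)
  expect_equal(sum(ss$stability == "stable"), 2L)
  expect_equal(sum(ss$stability == "unstable"), 1L)
  for (i in seq_len(nrow(ss))) {
    res <- switchcycle:::rhs_at(sysB, as.numeric(ss[i, c("Cdk1", "APC")]))
    expect_lt(max(abs(res)), 1e-9)
  }
})

test_that("continuation reproduces the analytic switch response and the
           ultrasensitive limit has no folds", {
  m5 <- switch_module(K = 20, n = 15, xi = scaling_function("cubic", 5))
  cc <- continuation_curve(m5, input_range = c(0, 60), step_max = 0.02)
  pts <- cc$points
  keep <- pts$output > 1e-3 & pts$output < 1 - 1e-3
  an <- invert_response(pts$output[keep], m5)
  expect_lt(max(abs(pts$input[keep] - an)), 1e-6)
  expect_equal(nrow(cc$folds), 2L)
  fa <- fold_analysis(m5)
  expect_equal(sort(cc$folds$input), sort(fa$folds$input),
               tolerance = 1e-3)
  m0 <- switch_module(K = 20, n = 15)
  cc0 <- continuation_curve(m0, input_range = c(0, 60), step_max = 0.02)
  expect_equal(nrow(cc0$folds), 0L)
})

test_that("oscillation metrics recover known signals and reject damped or
           flat ones", {
  t <- seq(0, 2000, by = 0.5)
  flat <- synthetic_traj(t, Cdk1 = rep(1, length(t)))
  expect_false(oscillation_metrics(flat, var = "Cdk1")$sustained)
  sine <- synthetic_traj(t, Cdk1 = sin(2 * pi * t / 100))
  om <- oscillation_metrics(sine, var = "Cdk1")
  expect_true(om$sustained)
  expect_lt(abs(om$period - 100) / 100, 0.005)
  expect_true(om$regular)
  expect_equal(unname(om$amplitude["Cdk1"]), 2, tolerance = 1e-3)
  expect_equal(om$natural_frequency, 2 * pi / om$period)
  damped <- make_fixture("damped_series", period = 100, decay = 0.05,
                         t_max = 2000, dt = 0.5)
  trd <- synthetic_traj(damped$time, Cdk1 = damped$value)
  expect_false(oscillation_metrics(trd, var = "Cdk1")$sustained)
  saw <- make_fixture("sawtooth_series", period = 120, t_max = 2400, dt = 0.5)
  trs <- synthetic_traj(saw$time, Cdk1 = saw$value)
  oms <- oscillation_metrics(trs, var = "Cdk1")
  expect_true(oms$sustained)
  expect_lt(abs(oms$period - 120) / 120, 0.01)
  expect_error(oscillation_metrics(synthetic_traj(1:10, Cdk1 = 1:10)),
               "too short")
})

test_that("phase segmentation follows the activity-threshold rules and
           partitions the period", {
  t <- 0:99
  tr <- synthetic_traj(t,
                       E2F = c(rep(0.5, 50), rep(0.99, 50)),
                       APC = c(rep(0.5, 25), rep(0.99, 25),
                               rep(0.5, 50)))
  ph <- segment_phases(tr)
  lab <- as.character(ph$labels)
  expect_equal(lab[1], "G1")     # E2F 0.5, APC 0.5
  expect_equal(lab[30], "M")     # APC 0.99 dominates
  expect_equal(lab[60], "SG2")   # E2F 0.99, APC 0.5
  sys <- build_interlinked(somatic_params())
  traj <- integrate_system(sys, t_span = c(0, 6000), dt = 2)
  ph2 <- segment_phases(traj)
  d <- ph2$durations
  expect_true(all(abs(d$G1 + d$SG2 + d$M - d$period) <= 2 * traj$dt))
  expect_error(segment_phases(synthetic_traj(t, Cdk1 = t)), "E2F")
})

test_that("regime classification matches the nullcline-intersection
           oracle across c", {
  # c = 0.5, narrow S-region: single unstable intersection -> oscillations
  lab_osc <- classify_regime(nd_embryonic(0.5, 5))
  expect_equal(as.character(lab_osc), "Osc")
  expect_equal(count_intersections(0.5, 5), 1L)
  # large width, c tuned between the fold products: bistable
  lab_bi <- classify_regime(nd_embryonic(0.4, 20))
  expect_equal(as.character(lab_bi), "Bi")
  expect_equal(count_intersections(0.4, 20), 3L)
  # low / high relative synthesis: single stable state on a branch
  expect_equal(as.character(classify_regime(nd_embryonic(0.05, 5))),
               "MonoLow")
  expect_equal(as.character(classify_regime(nd_embryonic(0.95, 5))),
               "MonoTop")
  expect_equal(count_intersections(0.05, 5), 1L)
  expect_equal(count_intersections(0.95, 5), 1L)
})

test_that("zero delay reduces the DDE to the ODE and delay lengthens the
           cycle", {
  ep0 <- embryonic_params(b_syn = 1, alpha_apc = 5, delay = delay_spec(0))
  sys_dde0 <- build_delayed(ep0)
  sys_ode <- build_embryonic(embryonic_params(b_syn = 1, alpha_apc = 5))
  tr_d <- integrate_system(sys_dde0, init = c(10, 0.1),
                           t_span = c(0, 300), dt = 0.1,
                           rtol = 1e-10, atol = 1e-12)
  tr_o <- integrate_system(sys_ode, init = c(10, 0.1),
                           t_span = c(0, 300), dt = 0.1,
                           rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(tr_d$state - tr_o$state)), 1e-6)
  periods <- vapply(c(0, 5, 15), function(tau) {
    ep <- embryonic_params(b_syn = 1, alpha_apc = 5,
                           delay = delay_spec(tau))
    sys <- if (tau == 0) build_embryonic(ep) else build_delayed(ep)
    tr <- integrate_system(sys, init = c(10, 0.1), t_span = c(0, 1200),
                           dt = 0.25)
    oscillation_metrics(tr, var = "Cdk1")$period
  }, numeric(1L))
  expect_true(all(diff(periods) > 0))
})

test_that("small epsilon trajectories hug the outer branches of the
           S-curve", {
  ep <- embryonic_params(b_syn = 1, alpha_apc = 5, eps_apc_star = 0.001)
  sys <- build_embryonic(ep)
  tr <- integrate_system(sys, t_span = c(0, 400), dt = 0.02)
  keep <- tr$time >= 200
  cdk <- tr$state[keep, "Cdk1"]; apc <- tr$state[keep, "APC"]
  m <- ep$apc_switch
  ok <- apc > 1e-6 & apc < 1 - 1e-12
  dist <- abs(cdk[ok] - invert_response(pmin(pmax(apc[ok], 1e-9),
                                             1 - 1e-9), m)) / m$K
  expect_gte(mean(dist <= 0.02), 0.9)
})

test_that("a second bistable switch amplifies the Cdk1 excursion", {
  tr_iiib <- integrate_system(
    build_embryonic(embryonic_params(b_syn = 1, alpha_apc = 0,
                                     alpha_cdk = 5)),
    t_span = c(0, 800), dt = 0.1)
  tr_ib <- integrate_system(
    build_embryonic(embryonic_params(b_syn = 1, alpha_apc = 5)),
    t_span = c(0, 800), dt = 0.1)
  om3 <- oscillation_metrics(tr_iiib, var = "Cdk1")
  om1 <- oscillation_metrics(tr_ib, var = "Cdk1")
  expect_true(om3$sustained && om1$sustained)
  expect_gt(om3$amplitude[["Cdk1"]], om1$amplitude[["Cdk1"]])
})

test_that("sweep2d records per-cell failures without aborting", {
  build_fn <- function(w, c_) {
    if (w > 1) stop("boom")
    nd_embryonic(c_, width_to_alpha(w))
  }
  g <- sweep2d(build_fn, axis1 = list(name = "width", values = c(0.5, 1.5)),
               axis2 = list(name = "c", values = 0.5),
               t_span = c(0, 80), n_starts = 30)
  expect_equal(nrow(g), 2L)
  expect_equal(g$regime[g$width > 1], "Error")
  expect_true(g$regime[g$width < 1] != "Error")
})
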