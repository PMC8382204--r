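sp <- somatic_params()

test_that("unforced and zero-amplitude forced trajectories coincide", {
  fs0 <- forcing_spec(0, period_h = 24)
  tr_f <- circadian_run(sp, fs0, t_span = c(0, 2000), dt = 2)
  tr_u <- integrate_system(build_interlinked(sp), t_span = c(0, 2000),
                           dt = 2)
  expect_equal(tr_f$state, tr_u$state)
  expect_error(forcing_spec(-1), ">= 0")
})

test_that("locking detector identifies 1:1, 1:2 and rejects
           quasiperiodic signals", {
  fs <- forcing_spec(1, period_h = 24)
  Tf <- fs$period_min
  fx <- make_fixture("periodic_series", period = Tf, t_max = 40 * Tf,
                     dt = 2)
  lk1 <- detect_locking(synthetic_traj(fx$time, Cdk1 = fx$value), fs)
  expect_true(lk1$locked)
  expect_equal(c(lk1$p, lk1$q), c(1L, 1L))
  expect_equal(lk1$cell_period, Tf, tolerance = 0.005)
  # one sharp peak every two forcing periods
  t <- seq(0, 40 * Tf, by = 2)
  tr2 <- synthetic_traj(t, Cdk1 = sin(2 * pi * t / (2 * Tf))^9)
  lk2 <- detect_locking(tr2, fs)
  expect_true(lk2$locked)
  expect_equal(c(lk2$p, lk2$q), c(1L, 2L))
  expect_equal(lk2$cell_period, 2 * Tf, tolerance = 0.005)
  fxq <- make_fixture("quasiperiodic_series", period = Tf, t_max = 40 * Tf,
                      dt = 2)
  lkq <- detect_locking(synthetic_traj(fxq$time, Cdk1 = fxq$value), fs)
  expect_false(lkq$locked)
  expect_error(detect_locking(synthetic_traj(seq(0, 5 * Tf, by = 2),
                                             Cdk1 = numeric(2161)), fs),
               "forcing periods")
})

test_that("locking calls are invariant to the sampling phase", {
  fs <- forcing_spec(1, period_h = 24)
  Tf <- fs$period_min
  t <- seq(0, 45 * Tf, by = 2)
  tr <- synthetic_traj(t, Cdk1 = sin(2 * pi * t / (2 * Tf))^9)
  lk_a <- detect_locking(tr, fs)
  keep <- t >= Tf / 2
  tr_b <- synthetic_traj(t[keep] - Tf / 2,
                         Cdk1 = sin(2 * pi * t[keep] / (2 * Tf))^9)
  lk_b <- detect_locking(tr_b, fs)
  expect_equal(c(lk_a$p, lk_a$q), c(lk_b$p, lk_b$q))
})

test_that("restriction point: commitment survives growth-factor
           withdrawal", {
  b <- switchcycle:::baseline_run(sp, t_span = c(0, 8000), dt = 2)
  w <- c(b$e2f_on[2] + 30, 8000)
  rp <- restriction_point_run(sp, 10, window = w, t_span = c(0, 8000))
  expect_true(rp$completed)
  # a window before any E2F activation is a different experiment
  expect_error(restriction_point_run(sp, 10, window = c(10, 100),
                                     t_span = c(0, 8000)),
               "after the first E2F activation")
  # factor 1 is a no-op: same completion and the same APC/C activation
  # times (the integrator restart at the window edge only shifts the
  # sharp transitions by a fraction of a minute)
  rp1 <- restriction_point_run(sp, 1, window = w, t_span = c(0, 8000))
  expect_true(rp1$completed)
  on_base <- b$apc_on
  on_noop <- switchcycle:::all_crossings(rp1$traj, "APC", 0.95)
  expect_equal(length(on_noop), length(on_base))
  expect_lt(max(abs(on_noop - on_base)), 1)
})

test_that("G1 damage delays E2F activation in proportion to its
           duration", {
  b <- switchcycle:::baseline_run(sp, t_span = c(0, 10000), dt = 2)
  act <- b$e2f_on[3]
  g0 <- dna_damage_g1(sp, 3, window = c(act - 300, act - 300),
                      t_span = c(0, 10000))
  expect_equal(g0$elongation, 0)
  g1 <- dna_damage_g1(sp, 3, window = c(act - 300, act + 200),
                      t_span = c(0, 10000))
  g2 <- dna_damage_g1(sp, 3, window = c(act - 300, act + 600),
                      t_span = c(0, 10000))
  expect_gt(g1$elongation, 0)
  expect_gt(g2$elongation, g1$elongation)
})

test_that("G2 damage raises mitotic CycB; early repair leaves interphase
           duration untouched", {
  b <- switchcycle:::baseline_run(sp, t_span = c(0, 10000), dt = 2)
  cdk_act <- switchcycle:::first_crossing(b$traj, "APC", 0.5,
                                          after = b$e2f_on[2])
  late <- dna_damage_g2(sp, 30, window = c(b$e2f_on[2] + 200,
                                           cdk_act + 150),
                        t_span = c(0, 10000))
  expect_gt(late$mitotic_cycb, late$baseline_mitotic_cycb)
  expect_gt(late$elongation, 0)
  early <- dna_damage_g2(sp, 30, window = c(b$e2f_on[2] + 200,
                                            b$e2f_on[2] + 400),
                         t_span = c(0, 10000))
  expect_lt(abs(early$elongation), 2 * early$traj$dt + 1e-6)
  expect_error(dna_damage_g2(sp, -2, window = c(100, 200)), ">= 0")
})
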