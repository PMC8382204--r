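test_that("system (i-a) steady state matches the scalar nullcline oracle", {
  sys <- build_embryonic(embryonic_params(b_syn = 1))  # c = 0.5
  ss <- steady_states(sys)
  expect_equal(nrow(ss), 1L)
  expect_equal(ss$stability, "stable")
  # nondimensional fixed point solves x * h(x) = c
  h <- function(x) x^15 / (1 + x^15)
  xr <- uniroot(function(x) x * h(x) - 0.5, c(0.1, 5), tol = 1e-14)$root
  expect_equal(ss$Cdk1, xr * 20, tolerance = 1e-8)
  expect_equal(ss$APC, h(xr), tolerance = 1e-8)
})

test_that("the CycB -> Cdk1 switch must multiply by its input", {
  bad <- switch_module(K = 40, n = 15, xi = scaling_function("cubic", 5),
                       multiply_by_input = FALSE)
  expect_error(embryonic_params(b_syn = 1, cdk_switch = bad),
               "multiply_by_input")
})

test_that("nondimensional groups and trajectory equivalence", {
  ep <- embryonic_params(b_syn = 1, alpha_apc = 5, alpha_cdk = 5)
  nd <- nondimensionalize(ep)
  expect_equal(nd$c, 0.5)
  expect_equal(nd$d, 2)
  expect_equal(unname(nd$eps_star), c(0.01, 0.01))
  set.seed(3)
  for (i in 1:10) {
    b_syn <- runif(1, 0.3, 3); b_deg <- runif(1, 0.05, 0.3)
    a <- runif(1, 0, 10)
    ep_i <- embryonic_params(b_syn = b_syn, b_deg = b_deg, alpha_apc = a)
    nd_i <- nondimensionalize(ep_i)
    sysD <- build_embryonic(ep_i)
    init <- c(Cdk1 = runif(1, 0, 30), APC = runif(1, 0, 1))
    tmax <- 40 / b_deg
    trD <- integrate_system(sysD, init = init, t_span = c(0, tmax),
                            dt = tmax / 800, rtol = 1e-10, atol = 1e-12)
    trN <- integrate_system(nd_i$system,
                            init = c(init[1] / 20, init[2]),
                            t_span = c(0, 40), dt = 40 / 800,
                            rtol = 1e-10, atol = 1e-12)
    trDs <- nd_i$to_dimensionless(trD)
    expect_lt(max(abs(trDs$state - trN$state)), 1e-6)
    expect_equal(trDs$time, trN$time, tolerance = 1e-10)
  }
})

test_that("state-dependent delay blends activation into inactivation lag", {
  dl <- delay_spec(4, 10, p = 5)
  expect_equal(switchcycle:::effective_tau(dl, 0.5), 7)  # midpoint average
  expect_equal(switchcycle:::effective_tau(delay_spec(4, 10, p = 50), 0.9),
               10, tolerance = 1e-3)
  expect_equal(switchcycle:::effective_tau(delay_spec(4, 10, p = 50), 0.1),
               4, tolerance = 1e-6)
  expect_error(delay_spec(-1), ">= 0")
})

test_that("interlinked model oscillates through G1 -> S/G2 -> M in order", {
  sys <- build_interlinked(somatic_params())
  traj <- integrate_system(sys, t_span = c(0, 20000), dt = 2)
  om <- oscillation_metrics(traj, var = "APC")
  expect_true(om$sustained)
  ph <- segment_phases(traj)
  expect_gte(nrow(ph$durations), 1L)
  # within each complete cycle all three phases are visited
  expect_true(all(ph$durations$G1 > 0))
  expect_true(all(ph$durations$SG2 > 0))
  expect_true(all(ph$durations$M > 0))
  # phase order within a cycle: G1 before S/G2 before M
  lab <- as.character(ph$labels)
  onset <- which(lab[-1] == "G1" & lab[-length(lab)] == "M") + 1L
  cyc <- lab[onset[1]:(onset[2] - 1L)]
  expect_equal(unique(cyc), c("G1", "SG2", "M"))
})

test_that("no CycD synthesis means no E2F activation from the low state", {
  sys <- build_interlinked(somatic_params(d_syn = 0))
  traj <- integrate_system(sys, t_span = c(0, 4000), dt = 2)
  expect_lt(max(traj$state[, "CycD"]), 1e-6)
  expect_lt(max(traj$state[, "E2F"]), 0.01)
})

test_that("with APC off and no basal offsets, CycD grows at d_syn", {
  p <- somatic_params(delta_d = 0, delta_b = 0)
  sys <- build_interlinked(p)
  d <- switchcycle:::rhs_at(sys, c(CycD = 50, E2F = 0, CycB = 0,
                                   Cdk1 = 0, APC = 0))
  expect_equal(d[1], p$d_syn)
})

test_that("mass-action pools are conserved and APC stays a fraction", {
  mp <- mass_action_params(b_syn = 1, b_deg = 0.1)
  sys <- build_mass_action(mp)
  traj <- integrate_system(sys, t_span = c(0, 400), dt = 0.2)
  cons <- apply(traj$state, 1L, function(y) sys$conserved(y, sys$params))
  for (k in 1:3) {
    tot <- cons[k, ]
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-8)
  }
  expect_gte(min(traj$state[, "APC"]), 0)
  expect_lte(max(traj$state[, "APC"]), 1)
  # initial conditions violating the pool constraints are rejected
  expect_error(integrate_system(sys, init = c(0, 0, 45, 0, 0),
                                t_span = c(0, 1)), "PP2A_tot")
  expect_error(integrate_system(sys, init = c(0, 0, 30, 180, 0),
                                t_span = c(0, 1)), "ENSA_tot")
})

test_that("rate divisor scales the kinetic constants but not turnover", {
  mp <- mass_action_params(b_syn = 1, b_deg = 0.1, rate_divisor = 16.5)
  sys <- build_mass_action(mp)
  expect_equal(sys$params$k_pg, 0.07 / 16.5)
  expect_equal(sys$params$k_cat, 15.85 / 16.5)
  expect_equal(sys$params$b_syn, 1)
  expect_equal(sys$params$b_deg, 0.1)
  # the divided system still oscillates (less separated timescales)
  traj <- integrate_system(sys, t_span = c(0, 3000), dt = 0.5)
  om <- oscillation_metrics(traj, var = "APC")
  expect_true(om$sustained)
})

test_that("clamped-CycB Cdk1 equilibria equal CycB times the switch
           branches", {
  ep3 <- embryonic_params(b_syn = 1, alpha_apc = 0, alpha_cdk = 5,
                          eps_cdk_star = 0.001)
  sys3 <- build_embryonic(ep3)
  cyc0 <- 44  # inside the fold region of the CycB -> Cdk1 switch
  clamped <- clamp_system(sys3, "CycB", cyc0)
  ss <- steady_states(clamped, n_starts = 150)
  sr <- steady_response_values(ep3$cdk_switch, cyc0)
  expect_equal(nrow(sr), 3L)
  got <- sort(ss$Cdk1)
  want <- sort(sr$output * cyc0)
  for (w in want)
    expect_lt(min(abs(got - w)) / cyc0, 1e-6)
})

test_that("schedules: empty is a no-op, overlaps and unknown params are
           rejected, windows apply in place", {
  sys <- build_interlinked(somatic_params())
  empty <- parameter_schedule(data.frame(t_start = numeric(0),
                                         t_end = numeric(0),
                                         param = character(0),
                                         value = numeric(0)))
  tr0 <- integrate_system(sys, t_span = c(0, 400), dt = 1)
  tr1 <- integrate_system(apply_schedule(sys, empty),
                          t_span = c(0, 400), dt = 1)
  expect_equal(tr0$state, tr1$state)
  expect_error(parameter_schedule(data.frame(
    t_start = c(0, 50), t_end = c(100, 150),
    param = "d_syn", value = 1)), "overlapping")
  expect_error(apply_schedule(sys, parameter_schedule(data.frame(
    t_start = 0, t_end = 10, param = "nope", value = 1))), "unknown")
  # multiplying d_syn by 0 freezes CycD growth inside the window only
  sched <- parameter_schedule(data.frame(t_start = 100, t_end = 200,
                                         param = "d_syn", value = 0,
                                         mode = "multiply"))
  tr2 <- integrate_system(apply_schedule(sys, sched),
                          t_span = c(0, 300), dt = 1)
  cycd <- traj_var(tr2, "CycD"); tt <- tr2$time
  # inside the window only basal degradation remains: CycD decays
  slope_in <- diff(cycd[tt >= 120 & tt <= 180])
  slope_out <- diff(cycd[tt >= 220 & tt <= 280])
  expect_lt(max(slope_in), 0)
  expect_gt(min(slope_out), 0)
})
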