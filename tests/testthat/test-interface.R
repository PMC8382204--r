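test_that("configs validate, default and round-trip", {
  cfg <- validate_config(list(system = "interlinked"))
  expect_equal(cfg$params$d_syn, 0.15)
  expect_equal(cfg$params$K_cyc_e2f, 120)
  expect_equal(cfg$params$alpha_cdk, 5)
  expect_true("d_syn" %in% cfg$defaulted)
  expect_error(validate_config(list(system = "warp")), "unknown system")
  expect_error(validate_config(list(system = "ib", nonsense = 1)),
               "unknown config key")
  expect_error(validate_config(list(system = "ib",
                                    params = list(b_deg = -0.1))),
               "out of domain")
  expect_error(validate_config(list(system = "ib",
                                    params = list(zeta = 1))),
               "unknown parameter")
  path <- tempfile(fileext = ".yaml")
  cfg2 <- validate_config(list(system = "ib",
                               params = list(b_syn = 0.8, alpha_apc = 7),
                               seed = 3L))
  save_config(cfg2, path)
  cfg3 <- load_config(path)
  expect_equal(cfg3$system, cfg2$system)
  expect_equal(cfg3$params, cfg2$params)
  sys <- build_from_config(cfg3)
  expect_s3_class(sys, "model_system")
  expect_equal(sys$params$alpha_apc, 7)
  sysm <- build_from_config(validate_config(list(
    system = "mass_action", params = list(b_syn = 1, b_deg = 0.1))))
  expect_equal(sysm$vars, c("Cdk1", "GWLp", "C", "ENSAp", "APC"))
})

test_that("trajectory files round-trip exactly and carry their
           provenance", {
  sys <- build_embryonic(embryonic_params(b_syn = 1, alpha_apc = 5))
  tr <- integrate_system(sys, t_span = c(0, 50), dt = 0.5)
  path <- tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  tr2 <- read_trajectory(path)
  expect_equal(tr2$time, tr$time)
  expect_equal(tr2$state, tr$state)
  hdr <- tr2$header
  expect_true(any(grepl("param b_syn: 1", hdr)))
  expect_true(any(grepl("param alpha_apc: 5", hdr)))
  # missing time column is reported as such
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "1\t2"), bad)
  expect_error(read_trajectory(bad), "time")
})

test_that("response-curve files round-trip with branch labels", {
  m5 <- switch_module(K = 20, n = 15, xi = scaling_function("cubic", 5))
  cc <- continuation_curve(m5, input_range = c(0, 60))
  path <- tempfile(fileext = ".tsv")
  write_response_curve(cc, path)
  cc2 <- read_response_curve(path)
  expect_equal(cc2$points$input, cc$points$input)
  expect_equal(cc2$points$output, cc$points$output)
  expect_equal(sort(unique(cc2$points$branch_id)),
               sort(unique(cc$points$branch_id)))
})

test_that("fixtures are deterministic in their seed and carry ground
           truth", {
  a <- make_fixture("response_curve", noise = 0.02, seed = 5)
  b <- make_fixture("response_curve", noise = 0.02, seed = 5)
  expect_identical(a, b)
  d <- make_fixture("response_curve", noise = 0.02, seed = 6)
  expect_false(identical(a$input, d$input))
  fx <- make_fixture("periodic_series", period = 100)
  om <- oscillation_metrics(synthetic_traj(fx$time, Cdk1 = fx$value),
                            var = "Cdk1")
  expect_equal(om$period, 100, tolerance = 0.005)
  expect_equal(attr(fx, "ground_truth")$period, 100)
  # fixture noise does not touch the global RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(make_fixture("response_curve", noise = 0.05,
                                       seed = 7)); after <- runif(1)
  expect_identical(before, after)
})
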