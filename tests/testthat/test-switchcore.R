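test_that("hill_response matches its closed form and domain contract", {
  for (n in c(1, 2, 15)) expect_equal(hill_response(20, 20, n), 0.5)
  expect_equal(hill_response(0, 20, 15), 0)
  expect_equal(hill_response(40, 20, 15), 32768 / 32769, tolerance = 1e-14)
  x <- seq(0, 100, by = 0.5)
  expect_true(all(diff(hill_response(x, 20, 15)) >= 0))
  expect_error(hill_response(10, -1, 15), "positive")
  expect_error(hill_response(10, 20, 0.5), ">= 1")
  expect_error(hill_response(-1, 20, 15), "non-negative")
})

test_that("invert_response is the exact inverse of the Hill response", {
  m0 <- switch_module(K = 20, n = 15)
  y <- seq(0.1, 0.9, by = 0.1)
  expect_equal(hill_response(invert_response(y, m0), 20, 15), y,
               tolerance = 1e-12)
  expect_equal(invert_response(0.5, m0), 20)
  # xi(r) = 1 makes the midpoint invariant for any cubic bend
  for (a in c(1, 5, 10)) {
    mc <- switch_module(K = 20, n = 15, xi = scaling_function("cubic", a))
    expect_equal(invert_response(0.5, mc), 20, tolerance = 1e-14)
  }
  expect_error(invert_response(1.0, m0), "strictly inside")
  expect_error(invert_response(0, m0), "strictly inside")
  # with a correction factor the inverse still solves the fixed point
  mcr <- switch_module(K = 1, n = 5,
                       xi = scaling_function("piecewise", x_max = 0.36,
                                             x_min = 0.6, xi_max = 1.28,
                                             xi_min = 0.75),
                       correction = 0.95)
  y <- seq(0.05, 0.9, by = 0.05)
  x <- invert_response(y, mcr)
  lhs <- 0.95 * x^5 / ((xi_eval(mcr$xi, y) * 1)^5 + x^5)
  expect_equal(lhs, y, tolerance = 1e-12)
})

test_that("steady_response_values solve the fixed-point equation", {
  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, 0, 15)
    m <- switch_module(K = 20, n = 15, xi = scaling_function("cubic", a))
    inp <- runif(1, 1, 60)
    sols <- steady_response_values(m, inp)
    expect_gte(nrow(sols), 1L)
    for (y in sols$output) {
      res <- inp^15 / ((xi_eval(m$xi, y) * 20)^15 + inp^15) - y
      expect_lt(abs(res), 1e-10)
    }
  }
})

test_that("steady response count and labels follow the S-curve geometry", {
  m0 <- switch_module(K = 20, n = 15)
  expect_equal(steady_response_values(m0, 20)$output, 0.5)
  m5 <- switch_module(K = 20, n = 15, xi = scaling_function("cubic", 5))
  expect_equal(steady_response_values(m5, 0)$output, 0)
  # input strictly between the folds: three coexisting outputs
  sols <- steady_response_values(m5, 20)
  expect_equal(nrow(sols), 3L)
  expect_equal(sols$branch, c("lower", "middle", "upper"))
  expect_true(all(diff(sols$output) > 0))
})

test_that("fold analysis: width grows with the bend and matches the
           dense-grid oracle", {
  m0 <- switch_module(K = 20, n = 15)
  fa0 <- fold_analysis(m0)
  expect_equal(fa0$width, 0)
  expect_false(fa0$bistable)
  widths <- vapply(c(1, 2, 5, 10), function(a) {
    fold_analysis(switch_module(K = 20, n = 15,
                                xi = scaling_function("cubic", a)))$width
  }, numeric(1L))
  expect_true(all(diff(widths) > 0))
  set.seed(7)
  for (i in 1:12) {
    a <- runif(1, 0.5, 18)
    r <- runif(1, 0.35, 0.65)
    n <- sample(5:20, 1)
    m <- try(switch_module(K = 20, n = n,
                           xi = scaling_function("cubic", a, r)),
             silent = TRUE)
    if (inherits(m, "try-error")) next  # positivity guard tripped
    fa <- fold_analysis(m)
    w_oracle <- brute_force_width(m, n = 2e5)
    if (w_oracle > 0)
      expect_lt(abs(fa$width - w_oracle) / w_oracle, 1e-4)
    else expect_equal(fa$width, 0)
  }
})

test_that("width <-> alpha conversion is a consistent inverse pair", {
  w <- c(0.3, 0.8, 1.4)
  a <- width_to_alpha(w)
  expect_equal(alpha_to_width(a), w, tolerance = 1e-5)
  expect_equal(width_to_alpha(0), 0)
  expect_error(width_to_alpha(5), "exceeds the maximum")
})
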