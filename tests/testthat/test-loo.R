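test_that("the univariate fit matches exact lines and a brute-force oracle", {
  x <- c(1, 2, 3, 5, 8)
  f <- fit_univariate(x, 3 * x - 2)
  expect_equal(f$slope, 3); expect_equal(f$intercept, -2)
  expect_equal(f$r_squared, 1); expect_equal(f$sse, 0, tolerance = 1e-20)

  f <- fit_univariate(x, rep(4, 5))
  expect_true(f$degenerate)
  expect_true(is.na(f$r_squared))

  set.seed(8)
  x <- stats::rnorm(20); y <- 1.5 * x + stats::rnorm(20)
  f <- fit_univariate(x, y)
  brute <- stats::optim(c(0, 0),
                        function(b) sum((y - b[1] - b[2] * x)^2),
                        method = "BFGS")$par
  expect_equal(c(f$intercept, f$slope), brute, tolerance = 1e-6)

  expect_error(fit_univariate(rep(1, 5), 1:5), "constant predictor")
  expect_error(fit_univariate(1:3, 1:3), "n >= 4")
})

test_that("hat-matrix PRESS equals explicit leave-one-out refits", {
  set.seed(21)
  x <- stats::rnorm(6); y <- 0.5 * x + stats::rnorm(6)
  loo <- loo_press_q2(x, y)
  expect_equal(loo$press, press_by_refits(x, y), tolerance = 1e-10)
  expect_equal(loo$ss, sum((y - mean(y))^2))
  expect_equal(loo$q2, 1 - loo$press / loo$ss)
})

test_that("collinear data give PRESS 0, Q2 1; degenerate inputs error", {
  x <- c(1, 2, 4, 7, 11)
  loo <- loo_press_q2(x, 2 * x + 3)
  expect_equal(loo$press, 0, tolerance = 1e-18)
  expect_equal(loo$q2, 1)
  expect_error(loo_press_q2(x, rep(1, 5)), "SS = 0")
  expect_error(loo_press_q2(c(0, 0, 0, 1), c(1, 2, 3, 4)), "degenerate")
})

test_that("PRESS >= SSE and Q2 <= R2 on random datasets", {
  set.seed(33)
  for (i in 1:200) {
    n <- sample(5:25, 1)
    x <- stats::rnorm(n)
    y <- stats::runif(1, -2, 2) * x + stats::rnorm(n, sd = stats::runif(1, 0.1, 3))
    fit <- fit_univariate(x, y)
    loo <- loo_press_q2(x, y)
    expect_gte(loo$press, fit$sse)
    expect_lte(loo$q2, fit$r_squared)
    expect_lte(loo$q2, 1)
  }
})

test_that("the asymptotic Q2 correction matches its formula and limits", {
  expect_equal(q2_asymptotic(1, 10), 1)
  expect_equal(q2_asymptotic(1, 10, variant = "adjusted"), 1)
  expect_equal(round(q2_asymptotic(0.8905, 14), 4), 0.8715)
  expect_equal(q2_asymptotic(0.8, 20, variant = "adjusted"),
               1 - 0.2 * 19 / 18)
  # increases toward r2 with n, never exceeding it
  q <- vapply(4:50, function(n) q2_asymptotic(0.8, n), numeric(1))
  expect_true(all(diff(q) > 0))
  expect_true(all(q <= 0.8))
  expect_error(q2_asymptotic(0.8, 2), "n > p \\+ 1")
  expect_error(q2_asymptotic(1.2, 10), "\\[0, 1\\]")
})

test_that("the four-criterion gate applies strict OECD-style logic", {
  # printed validation values of the modeled study: all criteria met
  ref <- dipyrone_reference_validation()
  g <- validation_gate(ref$q2, ref$r2, ref$q2 + ref$q2_asym_minus_q2)
  expect_true(g$crit_q2asym_gap)
  expect_true(g$crit_q2)
  expect_true(g$crit_r2)
  expect_true(g$crit_q2_lt_r2)
  expect_true(g$pass)
  expect_equal(g$q2_minus_r2, -0.0631)

  expect_false(validation_gate(0.5, 0.9, 0.6)$crit_q2)
  expect_false(validation_gate(0.5, 0.9, 0.6)$pass)
  expect_false(validation_gate(0.9, 0.9, 0.95)$crit_q2_lt_r2)  # strict <
  expect_false(validation_gate(0.7, 0.9, 0.7)$crit_q2asym_gap) # strict >
  expect_false(validation_gate(0.7, 0.8, 0.9)$crit_r2)
})

test_that("validate_relationship assembles a self-describing report", {
  set.seed(14)
  xy <- simulate_correlated_xy(14, 0.95)
  rep_ <- validate_relationship(xy$x, xy$y)
  expect_s3_class(rep_, "loo_report")
  expect_equal(rep_$variant, "squared")
  expect_equal(rep_$q2, loo_press_q2(xy$x, xy$y)$q2)
  expect_equal(rep_$q2_asym, q2_asymptotic(rep_$r2, 14))
  expect_lte(rep_$q2, rep_$r2)
  expect_identical(rep_$pass, all(rep_$crit_q2asym_gap, rep_$crit_q2,
                                  rep_$crit_r2, rep_$crit_q2_lt_r2))
  out <- capture.output(print(rep_))
  expect_true(any(grepl("PRESS", out)))
})
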