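test_that("trapezoidal AUEC handles rectangles, zeros and interior knots", {
  expect_equal(trapezoid_auec(c(0, 72), c(10, 10), 0, 72), 720)
  expect_equal(trapezoid_auec(c(0, 72), c(0, 0), 0, 72), 0)
  expect_equal(trapezoid_auec(c(0, 1, 2, 4), c(1, 3, 2, 4), 0, 4), 10.5)
  expect_equal(trapezoid_auec(c(0, 1, 2, 4), c(1, 3, 2, 4), 0, 4),
               dense_linear_integral(c(0, 1, 2, 4), c(1, 3, 2, 4), 0, 4),
               tolerance = 1e-9)
})

test_that("window edges between samples are linearly interpolated", {
  t <- c(0, 2, 4); v <- c(0, 4, 0)
  expect_equal(trapezoid_auec(t, v, 1, 3), 6)  # edges interpolate to 2
  expect_equal(trapezoid_auec(t, v, 1, 3),
               dense_linear_integral(t, v, 1, 3), tolerance = 1e-8)
  expect_error(trapezoid_auec(t, v, -1, 3), "outside sampled range")
  expect_error(trapezoid_auec(t, v, 3, 1), "t0 < t1")
  expect_error(trapezoid_auec(c(0, 0, 1), c(1, 2, 3), 0, 1),
               "strictly increasing")
  expect_error(trapezoid_auec(0, 1, 0, 1), "at least 2")
})

test_that("AUEC matches dense integration and is additive, on random series", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(4:20, 1)
    t <- sort(stats::runif(n, 0, 72))
    v <- stats::rnorm(n, 10, 4)
    t0 <- stats::runif(1, t[1], mean(range(t)))
    t2 <- stats::runif(1, mean(range(t)), t[n])
    t1 <- stats::runif(1, t0, t2)
    full <- trapezoid_auec(t, v, t0, t2)
    expect_equal(full, dense_linear_integral(t, v, t0, t2),
                 tolerance = 1e-6)
    expect_equal(trapezoid_auec(t, v, t0, t1) + trapezoid_auec(t, v, t1, t2),
                 full, tolerance = 1e-9)
  }
})

test_that("the A/B ratio reproduces its definition and sign convention", {
  expect_equal(ab_ratio(720, 360), 0)      # equal time averages
  expect_equal(ab_ratio(4766.87, 2968.43), 0.197, tolerance = 5e-4)
  expect_gt(ab_ratio(100, 100), 0)         # post average 100/72 < 100/36
  expect_lt(ab_ratio(400, 100), 0)         # post average rose
  expect_error(ab_ratio(1, 0), "nonzero")
  expect_error(ab_ratio(1, 1, T_A = 0), "> 0")
  # sign convention: positive iff time-averaged post level fell
  set.seed(7)
  for (i in 1:50) {
    A <- stats::runif(1, 0, 5000); B <- stats::runif(1, 1, 2500)
    expect_identical(ab_ratio(A, B) > 0, A / 72 < B / 36)
  }
})

test_that("paired baseline-vs-effect test matches the hand t statistic", {
  r <- paired_baseline_effect_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0); expect_equal(r$p_value, 1)
  expect_false(r$degenerate)

  b <- c(10, 20, 30, 40); a <- b + c(1, 2, 3, 4)
  r <- paired_baseline_effect_test(a, b)
  expect_equal(round(r$t, 3), 3.873)
  expect_equal(r$df, 3)
  expect_equal(r$p_value, 2 * stats::pt(-abs(2.5 / (stats::sd(1:4) / 2)), 3))

  expect_error(paired_baseline_effect_test(1, 1), "at least 2")
  expect_error(paired_baseline_effect_test(1:3, 1:4), "paired")
  r <- paired_baseline_effect_test(c(2, 3, 4), c(1, 2, 3))  # constant shift
  expect_true(r$degenerate)
  expect_true(is.na(r$p_value))
})

test_that("RSD% is scale invariant and matches hand values", {
  expect_equal(rsd_percent(c(5, 5, 5)), 0)
  expect_equal(rsd_percent(c(8, 10, 12)), 20)
  x <- stats::rlnorm(20)
  expect_equal(rsd_percent(x), rsd_percent(17.3 * x))
  expect_error(rsd_percent(3), "at least 2")
  expect_error(rsd_percent(c(-1, 1)), "zero")
})

test_that("a null-effect noise-free cohort yields zero ratios and flags", {
  cfg <- config_noise_off(config_null_effect(small_config(seed = 5)))
  et <- make_effect_table(simulate_cohort(cfg))
  expect_equal(et$ab_ratio, rep(0, nrow(et)), tolerance = 1e-12)
  expect_equal(et$p_value, rep(1, nrow(et)))
  expect_setequal(attr(et, "warnings"),
                  paste0("DEGENERATE_VARIANCE:", et$parameter))
})

test_that("an instant sustained 30% drop yields an A/B ratio of exactly 0.300", {
  tp <- effect_template("Hb", baseline_mean = 12, baseline_sd = 0,
                        direction = "decrease", fractional_change = 0.30,
                        onset_h = 0, peak_h = 0, shape = "sustained")
  cfg <- cohort_config(list(tp), n_animals = 4, noise_rsd_pct = 0, seed = 1)
  et <- make_effect_table(simulate_cohort(cfg))
  expect_equal(et$ab_ratio, 0.300, tolerance = 1e-12)
  expect_equal(template_ab_ratio(tp, cfg$schedule), 0.300, tolerance = 1e-12)
})

test_that("study-calibrated noise-free cohort reproduces configured extrema", {
  cfg <- config_noise_off(default_study_config(seed = 9))
  et <- make_effect_table(simulate_cohort(cfg))
  hb <- et[et$parameter == "Hb", ]
  expect_equal(hb$dyn_max_mean, 12.35, tolerance = 1e-9)
  expect_equal(hb$dyn_min_mean, 9.14, tolerance = 1e-9)
  ref <- dipyrone_reference_effects()
  for (p in ref$parameter) {
    expect_equal(et$dyn_max_mean[et$parameter == p],
                 ref$dyn_max_mean[ref$parameter == p], tolerance = 1e-9)
    expect_equal(et$dyn_min_mean[et$parameter == p],
                 ref$dyn_min_mean[ref$parameter == p], tolerance = 1e-9)
  }
})

test_that("the table's cohort ratio equals an external recomputation", {
  d <- simulate_cohort(small_config(seed = 31))
  et <- make_effect_table(d)
  for (p in et$parameter) {
    A <- B <- numeric()
    for (a in unique(d$series$animal_id)) {
      s <- get_series(d, a, p)
      base <- s[s$time_h <= 0, ]; post <- s[s$time_h > 0, ]
      B <- c(B, dense_linear_integral(base$time_h, base$value, -36, 0))
      A <- c(A, dense_linear_integral(post$time_h, post$value,
                                      min(post$time_h), 72))
    }
    span <- 72 - min(d$schedule$post_times)
    expect_equal(et$ab_ratio[et$parameter == p],
                 ab_ratio(mean(A), mean(B), T_A = span, T_B = 36),
                 tolerance = 1e-6)
  }
})

test_that("a baseline far outside the dynamic range is flagged", {
  rows <- rbind(
    make_rows("p1", "Hct", c(-36, -24, -12, 0), c(70, 72, 71, 73)),
    make_rows("p1", "Hct", c(1, 2, 24, 72), c(30, 28, 29, 31)),
    make_rows("p2", "Hct", c(-36, -24, -12, 0), c(71, 70, 72, 74)),
    make_rows("p2", "Hct", c(1, 2, 24, 72), c(31, 29, 30, 32)))
  et <- make_effect_table(study_dataset(rows))
  expect_true("BASELINE_OUTSIDE_DYNAMIC_RANGE:Hct" %in% attr(et, "warnings"))
})
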