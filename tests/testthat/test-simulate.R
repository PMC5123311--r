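test_that("a fixed seed gives a bit-identical dataset", {
  d1 <- simulate_cohort(small_config(seed = 123))
  d2 <- simulate_cohort(small_config(seed = 123))
  expect_identical(d1$series, d2$series)
  d3 <- simulate_cohort(small_config(seed = 124))
  expect_false(identical(d1$series$value, d3$series$value))
})

test_that("with noise off every trajectory is exactly the template", {
  cfg <- config_noise_off(small_config(seed = 17))
  d <- simulate_cohort(cfg)
  for (tp in cfg$templates) {
    for (a in unique(d$series$animal_id)) {
      s <- get_series(d, a, tp$parameter)
      expect_equal(s$value,
                   tp$baseline_mean * template_multiplier(tp, s$time_h),
                   tolerance = 1e-12)
    }
  }
})

test_that("template profiles are unit amplitude with correct timing", {
  cfg <- default_study_config()
  tt <- seq(-36, 72, by = 0.05)
  for (tp in cfg$templates) {
    g <- template_profile(tp, tt)
    expect_true(all(g >= 0 & g <= 1))
    expect_true(all(g[tt <= tp$onset_h] == 0))
    expect_equal(template_profile(tp, tp$peak_h), 1)
    if (!is.na(tp$recovery_h)) {
      expect_true(all(g[tt >= tp$recovery_h] == 0))
    } else {
      expect_equal(template_profile(tp, 72),
                   if (tp$shape == "fluctuating") {
                     1 - tp$flutter_amp *
                       sin(pi * (72 - tp$onset_h) / tp$flutter_period_h)^2 *
                       exp(-(72 - tp$onset_h) / tp$flutter_damp_h)
                   } else 1)
    }
  }
})

test_that("positivity invariants survive noise", {
  cfg <- small_config(seed = 77, noise_rsd_pct = 25)
  d <- simulate_cohort(cfg)
  expect_true(all(d$series$value > 0))
})

test_that("pooled post-dose RSD% converges to the configured residual noise", {
  cfg <- config_null_effect(small_config(seed = 41, n_animals = 200,
                                         noise_rsd_pct = 8))
  cfg$templates <- lapply(cfg$templates, function(tp) {
    tp$baseline_sd <- 0
    tp
  })
  et <- make_effect_table(simulate_cohort(cfg))
  expect_true(all(abs(et$rsd_effect_pct - 8) / 8 < 0.15))
  expect_true(all(abs(et$rsd_baseline_pct - 8) / 8 < 0.15))
})

test_that("study-calibrated defaults encode the published effect timings", {
  cfg <- default_study_config()
  plt <- cfg$templates[["Plt"]]
  expect_equal(plt$peak_h, 10)
  expect_equal(plt$recovery_h, 24)
  fib <- cfg$templates[["fibrinogen"]]
  expect_equal(fib$peak_h, 6)
  expect_equal(fib$recovery_h, 24)
  expect_equal(cfg$templates[["Hb"]]$baseline_mean, 12.35)
  expect_equal(cfg$templates[["Hb"]]$baseline_mean *
                 (1 - cfg$templates[["Hb"]]$fractional_change), 9.14)
  expect_equal(cfg$templates[["APTT"]]$onset_h, 6)  # APTT drops after 6 h
  expect_true(is.na(cfg$templates[["RBC"]]$recovery_h))  # no recovery
  expect_equal(cfg$templates[["WBC"]]$recovery_h, 72)    # back to baseline
  expect_equal(cfg$n_animals, 8L)
})

test_that("template validation rejects inconsistent timings", {
  expect_error(effect_template("Hb", 12, 0.5, "decrease", 1.2, 1, 8), "< 1")
  expect_error(effect_template("Hb", 12, 0.5, "decrease", 0.2, 8, 1),
               "onset_h <= peak_h")
  expect_error(effect_template("Hb", 12, 0.5, "decrease", 0.2, 1, 8,
                               recovery_h = 4), "recovery_h")
  expect_error(effect_template("Hb", 12, 0.5, "decrease", 0.2, 1, 8,
                               shape = "transient"), "recovery_h")
  expect_error(cohort_config(list(effect_template("Hb", 12, 0.5, "decrease",
                                                  0.2, 1, 8),
                                  effect_template("Hb", 12, 0.5, "decrease",
                                                  0.2, 1, 8))),
               "one template per parameter")
})

test_that("a configuration round-trips through YAML", {
  cfg <- default_study_config(seed = 99)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_config(cfg, path)
  cfg2 <- read_cohort_config(path)
  d1 <- simulate_cohort(cfg)$series
  d2 <- simulate_cohort(cfg2)$series
  expect_identical(d1[c("animal_id", "parameter", "time_h", "unit")],
                   d2[c("animal_id", "parameter", "time_h", "unit")])
  expect_equal(d1$value, d2$value, tolerance = 1e-9)
})
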