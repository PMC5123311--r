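# shared fixtures: all built in code at test time

# compact three-parameter study: one shape of each kind
small_config <- function(seed = 1, n_animals = 8, noise_rsd_pct = 8) {
  templates <- list(
    effect_template("Hb", baseline_mean = 12, baseline_sd = 0.6,
                    direction = "decrease", fractional_change = 0.25,
                    onset_h = 0.25, peak_h = 12, shape = "sustained"),
    effect_template("WBC", baseline_mean = 15, baseline_sd = 1.5,
                    direction = "increase", fractional_change = 0.6,
                    onset_h = 0.25, peak_h = 8, recovery_h = 72,
                    shape = "fluctuating", flutter_period_h = 7.75),
    effect_template("Plt", baseline_mean = 450, baseline_sd = 40,
                    direction = "increase", fractional_change = 0.3,
                    onset_h = 0.25, peak_h = 10, recovery_h = 24,
                    shape = "transient")
  )
  cohort_config(templates, n_animals = n_animals,
                noise_rsd_pct = noise_rsd_pct, seed = seed)
}

# hand-built long-format rows
make_rows <- function(animal, parameter, times, values) {
  data.frame(animal_id = rep(animal, length(times)), time_h = times,
             parameter = rep(parameter, length(times)), value = values,
             unit = rep(canonical_unit(parameter), length(times)),
             stringsAsFactors = FALSE)
}

# dense numerical integral of the piecewise-linear interpolant;
# independent oracle for trapezoid_auec (pracma::trapz on a fine grid)
dense_linear_integral <- function(times, values, t0, t1, n_grid = 200001) {
  grid <- seq(t0, t1, length.out = n_grid)
  y <- stats::approx(times, values, xout = grid)$y
  pracma::trapz(grid, y)
}

# residual-noise RSD% configured for one parameter
noise_for_test <- function(config, parameter) {
  v <- config$noise_rsd_pct
  if (is.null(names(v))) v[[1]] else unname(v[[parameter]])
}

# explicit leave-one-out refits; independent oracle for the hat-matrix
# shortcut in loo_press_q2
press_by_refits <- function(x, y) {
  n <- length(x)
  sum(vapply(seq_len(n), function(i) {
    fit <- stats::lm(y[-i] ~ x[-i])
    pred <- stats::coef(fit)[1] + stats::coef(fit)[2] * x[i]
    (y[i] - pred)^2
  }, numeric(1)))
}
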