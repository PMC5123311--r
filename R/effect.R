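#' Linear-trapezoidal area under the effect curve over a window
#'
#' Integrates the piecewise-linear interpolant of an observation series,
#' restricted to `[t0, t1]`. Window edges falling between samples are
#' handled by linear interpolation to the edge, so the statistic is exactly
#' additive over abutting windows.
#'
#' @param times Strictly increasing sample times (h).
#' @param values Sample values (same length).
#' @param t0,t1 Window bounds (h), `t0 < t1`, both within the sampled range.
#' @return The area (unit x h).
#' @export
#' @examples
#' trapezoid_auec(c(0, 1, 2, 4), c(1, 3, 2, 4), 0, 4)  # 10.5
trapezoid_auec <- function(times, values, t0, t1) {
  times <- as.numeric(times); values <- as.numeric(values)
  n <- length(times)
  if (n != length(values)) stop("times and values differ in length", call. = FALSE)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (t1 <= t0) stop("window must satisfy t0 < t1", call. = FALSE)
  if (t0 < times[1] || t1 > times[n]) {
    stop("window [", t0, ", ", t1, "] outside sampled range [",
         times[1], ", ", times[n], "]", call. = FALSE)
  }
  interp <- function(t) stats::approx(times, values, xout = t)$y
  inside <- times > t0 & times < t1
  tt <- c(t0, times[inside], t1)
  vv <- c(interp(t0), values[inside], interp(t1))
  sum(diff(tt) * (vv[-length(vv)] + vv[-1]) / 2)
}

#' Baseline-normalized AUEC change ratio (A/B ratio)
#'
#' The fractional change of the time-averaged post-dose level relative to
#' the time-averaged baseline level:
#' `(B/T_B - A/T_A) / (B/T_B)`. Positive when the parameter's time-averaged
#' level fell after dosing, negative when it rose, 0 when unchanged.
#'
#' @param A Post-dose AUEC (unit x h), conventionally over 0-72 h.
#' @param B Baseline AUEC (unit x h), conventionally over -36-0 h.
#' @param T_A,T_B Window durations in hours (defaults 72 and 36).
#' @return Dimensionless ratio.
#' @export
#' @examples
#' ab_ratio(4766.87, 2968.43)  # 0.197: APTT fell ~20% on time average
ab_ratio <- function(A, B, T_A = 72, T_B = 36) {
  if (any(T_A <= 0) || any(T_B <= 0)) stop("window durations must be > 0", call. = FALSE)
  if (any(B == 0)) stop("baseline AUEC B must be nonzero", call. = FALSE)
  (B / T_B - A / T_A) / (B / T_B)
}

#' Paired baseline-vs-effect significance test
#'
#' Two-sided paired Student's t test on the per-animal differences between
#' the time-averaged post-dose level (A/T_A) and the time-averaged baseline
#' level (B/T_B).
#'
#' Identical pairings (all differences zero) return `t = 0, p = 1`; a
#' nonzero shift with zero variance across animals is degenerate (infinite
#' t) and is flagged without a p-value.
#'
#' @param effect_means Per-animal time-averaged post-dose levels.
#' @param baseline_means Per-animal time-averaged baseline levels (paired).
#' @return List with `t`, `df`, `p_value`, `degenerate`.
#' @export
paired_baseline_effect_test <- function(effect_means, baseline_means) {
  n <- length(effect_means)
  if (n != length(baseline_means)) stop("lists must be paired by animal", call. = FALSE)
  if (n < 2) stop("need at least 2 animals", call. = FALSE)
  d <- as.numeric(effect_means) - as.numeric(baseline_means)
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, df = n - 1L, p_value = 1, degenerate = FALSE,
                  zero_variance = TRUE))
    }
    return(list(t = NA_real_, df = n - 1L, p_value = NA_real_,
                degenerate = TRUE, zero_variance = TRUE))
  }
  ht <- stats::t.test(effect_means, baseline_means, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, degenerate = FALSE, zero_variance = FALSE)
}

#' Relative standard deviation in percent
#'
#' `100 * sd(x) / |mean(x)|`, the between-animal variability summary used
#' for baseline and post-dose windows.
#'
#' @param values Numeric vector, `n >= 2`, nonzero mean.
#' @return RSD in percent.
#' @export
rsd_percent <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("mean is zero; RSD% undefined", call. = FALSE)
  100 * stats::sd(values) / abs(m)
}

#' Per-parameter effect summary table
#'
#' Reproduces the study-style summary for each blood parameter: cohort mean
#' and SD of the per-animal post-dose (`A`) and baseline (`B`) AUECs, the
#' A/B change ratio computed from the cohort-mean AUECs, the paired t-test
#' p-value on per-animal time-averaged levels, pooled baseline and
#' post-dose RSD%, and the dynamic post-dose extrema (cohort mean and SD of
#' per-animal maxima and minima).
#'
#' Windows are half-open at the dose: the t = 0 sample is the pre-dose
#' control and belongs to baseline. `B` integrates samples with t <= 0 over
#' \[-36, 0\]; `A` integrates samples with t > 0 over \[first post time, 72\],
#' and time averages divide each AUEC by its actually integrated span.
#'
#' @param dataset A [study_dataset()].
#' @param parameters Parameters to summarise; defaults to all present.
#' @return Data frame of class `effect_table`, one row per parameter, with
#'   attribute `warnings` (machine-readable codes, e.g. a flag when the
#'   time-averaged baseline falls outside the observed dynamic range).
#' @export
make_effect_table <- function(dataset, parameters = NULL) {
  stopifnot(inherits(dataset, "study_dataset"))
  s <- dataset$series
  if (is.null(parameters)) parameters <- sort(unique(s$parameter))
  animals <- sort(unique(s$animal_id))
  warnings <- character()

  rows <- lapply(parameters, function(p) {
    have <- unique(s$animal_id[s$parameter == p])
    if (!all(animals %in% have)) {
      stop("parameter ", p, " missing for animal(s) ",
           paste(setdiff(animals, have), collapse = ", "), call. = FALSE)
    }
    per <- lapply(animals, function(a) {
      obs <- get_series(dataset, a, p)
      base <- obs[obs$time_h <= 0, , drop = FALSE]
      post <- obs[obs$time_h > 0, , drop = FALSE]
      if (nrow(base) < 2 || nrow(post) < 2) {
        stop("animal ", a, ", parameter ", p,
             ": need >= 2 baseline and >= 2 post-dose samples", call. = FALSE)
      }
      T_B <- max(base$time_h) - min(base$time_h)
      T_A <- max(post$time_h) - min(post$time_h)
      B <- trapezoid_auec(base$time_h, base$value, min(base$time_h),
                          max(base$time_h))
      A <- trapezoid_auec(post$time_h, post$value, min(post$time_h),
                          max(post$time_h))
      list(A = A, B = B, T_A = T_A, T_B = T_B,
           a_mean = A / T_A, b_mean = B / T_B,
           dyn_max = max(post$value), dyn_min = min(post$value),
           base_values = base$value, post_values = post$value)
    })
    g <- function(f) vapply(per, `[[`, numeric(1), f)
    A <- g("A"); B <- g("B")
    T_A <- per[[1]]$T_A; T_B <- per[[1]]$T_B
    ab <- ab_ratio(mean(A), mean(B), T_A = T_A, T_B = T_B)
    ht <- paired_baseline_effect_test(g("a_mean"), g("b_mean"))
    if (ht$zero_variance) {
      warnings <<- c(warnings, paste0("DEGENERATE_VARIANCE:", p))
    }
    baseline_avg <- mean(B) / T_B
    dmax <- g("dyn_max"); dmin <- g("dyn_min")
    if (baseline_avg > mean(dmax) * 1.1 || baseline_avg < mean(dmin) * 0.9) {
      warnings <<- c(warnings, paste0("BASELINE_OUTSIDE_DYNAMIC_RANGE:", p))
    }
    data.frame(
      parameter = p,
      dyn_max_mean = mean(dmax), dyn_max_sd = stats::sd(dmax),
      dyn_min_mean = mean(dmin), dyn_min_sd = stats::sd(dmin),
      A_mean = mean(A), A_sd = stats::sd(A),
      B_mean = mean(B), B_sd = stats::sd(B),
      ab_ratio = ab,
      p_value = ht$p_value,
      rsd_baseline_pct = rsd_percent(unlist(lapply(per, `[[`, "base_values"))),
      rsd_effect_pct = rsd_percent(unlist(lapply(per, `[[`, "post_values"))),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "warnings") <- unique(warnings)
  class(out) <- c("effect_table", class(out))
  out
}

#' Write an effect summary table to CSV
#' @param table An `effect_table` from [make_effect_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
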