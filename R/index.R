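#' Composite hemorheological index
#'
#' `PT + (Hb + Hct) / RBC^APTT_ratio`, the bespoke composite that links the
#' coagulation and red-cell panels to metabolite exposure. Inputs are in
#' their canonical units (PT %, Hb g/dL, Hct %, RBC 10^12/L, APTT ratio
#' dimensionless); the index itself is treated as dimensionless.
#'
#' @param PT,Hb,Hct,RBC,APTT_ratio Numeric vectors (recycled).
#' @return Index value(s); errors if `RBC <= 0` or the result is not finite.
#' @export
#' @examples
#' composite_index(PT = 95, Hb = 12.35, Hct = 36.32, RBC = 6.56,
#'                 APTT_ratio = 3.36)
composite_index <- function(PT, Hb, Hct, RBC, APTT_ratio) {
  if (any(RBC <= 0)) stop("RBC must be > 0", call. = FALSE)
  out <- PT + (Hb + Hct) / RBC^APTT_ratio
  if (any(!is.finite(out))) stop("non-finite index value", call. = FALSE)
  out
}

#' MCV + PT index
#'
#' The simple additive index whose relationship to 4MAA concentration is
#' linear up to 48 h post dose.
#'
#' @param MCV,PT Numeric vectors (fL and %).
#' @return `MCV + PT`.
#' @export
mcv_pt_index <- function(MCV, PT) {
  MCV + PT
}

index_constituents <- list(
  composite = c("PT", "Hb", "Hct", "RBC", "APTT_ratio"),
  mcv_pt = c("MCV", "PT")
)

#' Evaluate an index along the time axis
#'
#' @param dataset A [study_dataset()].
#' @param index `"composite"` or `"mcv_pt"`.
#' @param aggregation `"cohort_mean"` (average each constituent parameter
#'   across animals per time point, then evaluate — the default, matching a
#'   one-curve-per-study regression against the metabolite curve) or
#'   `"per_animal"`.
#' @param window Time window `c(t0, t1)` in hours; defaults to the full
#'   post-dose window 0-72 h (times strictly > 0 are used).
#' @return Data frame with `time_h`, `value`, `n_animals` (and `animal_id`
#'   for per-animal aggregation), ordered by time.
#' @export
index_series <- function(dataset, index = c("composite", "mcv_pt"),
                         aggregation = c("cohort_mean", "per_animal"),
                         window = c(0, 72)) {
  stopifnot(inherits(dataset, "study_dataset"))
  index <- match.arg(index)
  aggregation <- match.arg(aggregation)
  need <- index_constituents[[index]]
  s <- dataset$series
  s <- s[s$parameter %in% need & s$time_h > window[1] & s$time_h <= window[2], ]
  if (nrow(s) == 0) stop("no observations in the requested window", call. = FALSE)
  times <- sort(unique(s$time_h))
  animals <- sort(unique(dataset$series$animal_id))

  value_at <- function(sub, time) {
    vals <- lapply(need, function(p) {
      v <- sub$value[sub$parameter == p & sub$time_h == time]
      if (length(v) == 0) {
        stop("constituent parameter ", p, " missing at time ", time,
             call. = FALSE)
      }
      mean(v)
    })
    names(vals) <- need
    if (index == "composite") {
      do.call(composite_index, vals)
    } else {
      do.call(mcv_pt_index, vals)
    }
  }

  if (aggregation == "cohort_mean") {
    out <- data.frame(
      time_h = times,
      value = vapply(times, function(tm) value_at(s, tm), numeric(1)),
      n_animals = length(animals))
  } else {
    out <- do.call(rbind, lapply(animals, function(a) {
      sub <- s[s$animal_id == a, ]
      data.frame(animal_id = a, time_h = times,
                 value = vapply(times, function(tm) value_at(sub, tm),
                                numeric(1)),
                 n_animals = 1L)
    }))
  }
  rownames(out) <- NULL
  out
}

#' Squared Pearson correlation with significance test
#'
#' @param x,y Numeric vectors, equal length `n >= 3`, both non-constant.
#' @return List with `r_squared`, `p_value`, `n`.
#' @export
#' @examples
#' pearson_r2(1:10, 2 * (1:10) + 1)  # r_squared = 1
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r_squared = unname(ct$estimate)^2, p_value = ct$p.value, n = n)
}
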