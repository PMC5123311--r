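#' Canonical hemorheological parameter set
#'
#' The closed set of blood parameters handled by the pipeline, with their
#' canonical reporting units and whether the quantity is constrained to be
#' strictly positive (counts and concentrations).
#'
#' Units follow the conventional hematology reporting units used in the
#' piglet study design this package models: Hb in g/dL, Hct in %, MCV in fL,
#' MCH in pg, RBC in 10^12/L, WBC and Plt in 10^9/L, PT as a percent index,
#' APTT and PFA closure times (CT) in seconds, fibrinogen in g/L, and the
#' APTT ratio dimensionless.
#'
#' @return A data frame with columns `parameter`, `unit`, `positive`.
#' @export
#' @examples
#' hemorheo_parameters()
hemorheo_parameters <- function() {
  data.frame(
    parameter = c("WBC", "RBC", "Hb", "Hct", "MCV", "MCH", "MCHC", "Plt",
                  "PT", "APTT", "APTT_ratio", "fibrinogen", "CT_ADP", "CT_EPI"),
    unit = c("10^9/L", "10^12/L", "g/dL", "%", "fL", "pg", "g/dL", "10^9/L",
             "%", "s", "ratio", "g/L", "s", "s"),
    # strictly-positive constraint applies to counts/concentrations only
    positive = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE,
                 FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Canonical unit for a parameter name
#' @param parameter Character vector of parameter names (closed set).
#' @return Character vector of units; errors on unknown names.
#' @export
canonical_unit <- function(parameter) {
  tab <- hemorheo_parameters()
  i <- match(parameter, tab$parameter)
  if (anyNA(i)) {
    stop("unknown parameter name(s): ",
         paste(unique(parameter[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  tab$unit[i]
}

#' Sampling schedule of a single-dose study
#'
#' Times are hours relative to the dose: baseline samples at t <= 0
#' (spanning -36 h to 0 h, the t = 0 sample being the pre-dose control) and
#' post-dose samples at 0 < t <= 72 h. The post-dose default is the dense
#' early grid typical of single-dose PK/PD sampling.
#'
#' @param baseline_times Numeric vector of baseline sampling times (h),
#'   must span exactly \[-36, 0\] and be strictly increasing.
#' @param post_times Numeric vector of post-dose sampling times (h),
#'   strictly increasing, all > 0, with maximum exactly 72.
#' @return An object of class `sampling_schedule`.
#' @export
#' @examples
#' sampling_schedule()
sampling_schedule <- function(baseline_times = c(-36, -24, -12, 0),
                              post_times = c(0.25, 0.5, 0.75, 1, 2, 4, 6,
                                             8, 10, 12, 24, 48, 72)) {
  baseline_times <- as.numeric(baseline_times)
  post_times <- as.numeric(post_times)
  if (length(baseline_times) < 2 || any(diff(baseline_times) <= 0)) {
    stop("baseline_times must be strictly increasing with >= 2 points",
         call. = FALSE)
  }
  if (length(post_times) < 1 || any(diff(post_times) <= 0)) {
    stop("post_times must be strictly increasing and non-empty",
         call. = FALSE)
  }
  if (min(baseline_times) != -36 || max(baseline_times) != 0) {
    stop("baseline_times must span [-36, 0] exactly", call. = FALSE)
  }
  if (any(post_times <= 0) || max(post_times) != 72) {
    stop("post_times must be > 0 with maximum 72", call. = FALSE)
  }
  structure(list(baseline_times = baseline_times, post_times = post_times),
            class = "sampling_schedule")
}

#' @export
print.sampling_schedule <- function(x, ...) {
  cat("Sampling schedule (hours relative to dose)\n")
  cat("  baseline:", paste(x$baseline_times, collapse = ", "), "\n")
  cat("  post-dose:", paste(x$post_times, collapse = ", "), "\n")
  invisible(x)
}

#' All sampling times of a schedule (baseline then post-dose)
#' @param schedule A [sampling_schedule()].
#' @return Numeric vector of times in hours.
#' @export
schedule_times <- function(schedule) {
  c(schedule$baseline_times, schedule$post_times)
}
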