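#' Construct a study dataset
#'
#' Bundles the long-format observation table with its sampling schedule and
#' optional cohort-mean metabolite profiles. All validation happens here:
#' any violating row aborts construction (no partial datasets).
#'
#' @param series Data frame with columns `animal_id`, `time_h`, `parameter`,
#'   `value`, `unit` (one row per observation).
#' @param schedule A [sampling_schedule()]; if `NULL`, inferred from the
#'   observed times extended by the canonical -36/0/72 endpoints.
#' @param metabolites Optional data frame with columns `analyte`
#'   (`"4MAA"` or `"4AA"`), `time_h`, `concentration` (cohort-mean plasma
#'   concentration; 0 at and before the dose).
#' @param provenance Free-text origin (file path or simulation config echo).
#' @return An object of class `study_dataset`.
#' @export
study_dataset <- function(series, schedule = NULL, metabolites = NULL,
                          provenance = "") {
  required <- c("animal_id", "time_h", "parameter", "value", "unit")
  if (!is.data.frame(series) || !all(required %in% names(series))) {
    stop("series must be a data frame with columns ",
         paste(required, collapse = ","), call. = FALSE)
  }
  series <- series[required]
  series$animal_id <- as.character(series$animal_id)
  series$parameter <- as.character(series$parameter)
  series$unit <- as.character(series$unit)
  series$time_h <- as.numeric(series$time_h)
  series$value <- as.numeric(series$value)

  if (nrow(series) > 0) {
    validate_series_rows(series)
  }
  if (is.null(schedule)) {
    schedule <- infer_schedule(series$time_h)
  }
  stopifnot(inherits(schedule, "sampling_schedule"))
  extra <- setdiff(unique(series$time_h), schedule_times(schedule))
  if (length(extra) > 0) {
    stop("observation times not in the sampling schedule: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (!is.null(metabolites)) {
    metabolites <- validate_metabolites(metabolites)
  }
  series <- series[order(series$animal_id, series$parameter, series$time_h), ,
                   drop = FALSE]
  rownames(series) <- NULL
  structure(list(series = series, schedule = schedule,
                 metabolites = metabolites, provenance = provenance),
            class = "study_dataset")
}

validate_series_rows <- function(series) {
  tab <- hemorheo_parameters()
  bad <- function(mask, what) {
    if (any(mask)) {
      rows <- which(mask)
      stop(what, " at row(s) ", paste(utils::head(rows, 5), collapse = ", "),
           if (sum(mask) > 5) " ..." else "", call. = FALSE)
    }
  }
  bad(!series$parameter %in% tab$parameter, "unknown parameter name")
  bad(!is.finite(series$value), "non-finite or non-numeric value")
  bad(series$unit != canonical_unit(series$parameter), "unit mismatch")
  pos <- tab$positive[match(series$parameter, tab$parameter)]
  bad(pos & series$value <= 0, "non-positive value for a count/concentration")
  key <- paste(series$animal_id, series$parameter, series$time_h, sep = "\r")
  bad(duplicated(key), "duplicate (animal, parameter, time) observation")
  invisible(TRUE)
}

infer_schedule <- function(times) {
  times <- sort(unique(c(times, -36, 0, 72)))
  sampling_schedule(baseline_times = times[times <= 0],
                    post_times = times[times > 0])
}

validate_metabolites <- function(metabolites) {
  required <- c("analyte", "time_h", "concentration")
  if (!is.data.frame(metabolites) || !all(required %in% names(metabolites))) {
    stop("metabolites must have columns ", paste(required, collapse = ","),
         call. = FALSE)
  }
  metabolites <- metabolites[required]
  metabolites$analyte <- as.character(metabolites$analyte)
  if (!all(metabolites$analyte %in% c("4MAA", "4AA"))) {
    stop("analyte must be 4MAA or 4AA", call. = FALSE)
  }
  if (any(metabolites$concentration < 0)) {
    stop("metabolite concentrations must be >= 0", call. = FALSE)
  }
  if (any(metabolites$concentration[metabolites$time_h <= 0] != 0)) {
    stop("metabolite concentration must be 0 at t <= 0 (single dose at t = 0)",
         call. = FALSE)
  }
  metabolites[order(metabolites$analyte, metabolites$time_h), , drop = FALSE]
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("Study dataset:", length(unique(x$series$animal_id)), "animal(s),",
      length(unique(x$series$parameter)), "parameter(s),",
      nrow(x$series), "observations\n")
  if (!is.null(x$metabolites)) {
    cat("  metabolite profiles:",
        paste(unique(x$metabolites$analyte), collapse = ", "), "\n")
  }
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Extract one animal x parameter observation series
#'
#' @param dataset A [study_dataset()].
#' @param animal_id,parameter Identify the series.
#' @return Data frame with columns `time_h`, `value`, ordered by time.
#' @export
get_series <- function(dataset, animal_id, parameter) {
  s <- dataset$series
  s <- s[s$animal_id == animal_id & s$parameter == parameter, , drop = FALSE]
  if (nrow(s) == 0) {
    stop("no series for animal ", animal_id, ", parameter ", parameter,
         call. = FALSE)
  }
  s <- s[order(s$time_h), c("time_h", "value")]
  rownames(s) <- NULL
  s
}

dataset_header <- "animal_id,time_h,parameter,value,unit"

#' Read a study dataset from CSV
#'
#' Expects the exact long-format header
#' `animal_id,time_h,parameter,value,unit` ("." decimal, comma separated).
#' Any invalid row (unknown parameter, wrong unit, non-numeric value,
#' duplicate observation) aborts the read with the offending line number;
#' no partial dataset is ever returned.
#'
#' @param path CSV file path.
#' @param schedule Optional [sampling_schedule()] the times must belong to;
#'   inferred from the data if omitted.
#' @return A [study_dataset()].
#' @export
read_dataset <- function(path, schedule = NULL) {
  first <- readLines(path, n = 1L)
  if (!identical(first, dataset_header)) {
    stop("bad header: expected '", dataset_header, "'", call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    return(study_dataset(
      series = data.frame(animal_id = character(), time_h = numeric(),
                          parameter = character(), value = numeric(),
                          unit = character(), stringsAsFactors = FALSE),
      schedule = schedule %||% sampling_schedule(),
      provenance = path))
  }
  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) {
      stop("non-numeric ", what, " at line(s) ",
           paste(utils::head(line[is.na(v)], 5), collapse = ", "),
           call. = FALSE)
    }
    v
  }
  series <- data.frame(animal_id = raw$animal_id,
                       time_h = num(raw$time_h, "time_h"),
                       parameter = raw$parameter,
                       value = num(raw$value, "value"),
                       unit = raw$unit, stringsAsFactors = FALSE)
  tab <- hemorheo_parameters()
  offend <- function(mask, what) {
    if (any(mask)) {
      stop(what, " at line(s) ",
           paste(utils::head(line[mask], 5), collapse = ", "),
           if (sum(mask) > 5) " ..." else "", call. = FALSE)
    }
  }
  offend(!series$parameter %in% tab$parameter, "unknown parameter name")
  offend(series$unit != canonical_unit(
    ifelse(series$parameter %in% tab$parameter, series$parameter,
           tab$parameter[1])), "unit mismatch")
  key <- paste(series$animal_id, series$parameter, series$time_h, sep = "\r")
  offend(duplicated(key), "duplicate (animal, parameter, time) observation")
  study_dataset(series, schedule = schedule, provenance = path)
}

#' Write a study dataset to CSV
#'
#' Emits the exact `animal_id,time_h,parameter,value,unit` layout, one row
#' per observation, deterministically ordered by (animal, parameter, time).
#' Numbers are written with 15 significant digits so that
#' write -> read -> write is byte-identical and values round-trip well
#' within 1e-9.
#'
#' @param dataset A [study_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "study_dataset"))
  s <- dataset$series
  s <- s[order(s$animal_id, s$parameter, s$time_h), , drop = FALSE]
  lines <- c(dataset_header,
             if (nrow(s) > 0) {
               paste(s$animal_id, sprintf("%.15g", s$time_h), s$parameter,
                     sprintf("%.15g", s$value), s$unit, sep = ",")
             })
  writeLines(lines, path)
  invisible(path)
}

#' Write cohort-mean metabolite profiles to CSV
#'
#' Companion file to the dataset CSV, with columns
#' `analyte,time_h,concentration`.
#'
#' @param dataset A [study_dataset()] with non-`NULL` metabolites.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metabolites <- function(dataset, path) {
  m <- dataset$metabolites
  if (is.null(m)) stop("dataset carries no metabolite profiles", call. = FALSE)
  lines <- c("analyte,time_h,concentration",
             paste(m$analyte, sprintf("%.15g", m$time_h),
                   sprintf("%.15g", m$concentration), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read metabolite profiles written by [write_metabolites()]
#' @param path CSV path.
#' @return Data frame `analyte,time_h,concentration`.
#' @export
read_metabolites <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_metabolites(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
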