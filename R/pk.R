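#' Pharmacokinetic configuration for the metabolite model
#'
#' One-compartment first-order absorption model for 4MAA (the Bateman form)
#' with 4AA as its catenary metabolite. The parent study design prints no
#' PK values, so everything here is configuration; defaults give a 4MAA
#' tmax of about 1.1 h, in the range expected after intramuscular dosing.
#'
#' @param dose_mg_per_kg Dose (default 100 mg/kg, single I.M. dose).
#' @param ka First-order absorption rate constant (1/h).
#' @param ke_4MAA Elimination rate constant of 4MAA (1/h).
#' @param V Apparent volume of distribution (L/kg).
#' @param fm Fraction of 4MAA converted to 4AA (0-1).
#' @param ke_4AA Elimination rate constant of 4AA (1/h).
#' @return An object of class `pk_config`.
#' @export
pk_config <- function(dose_mg_per_kg = 100, ka = 2.0, ke_4MAA = 0.35,
                      V = 1.0, fm = 0.4, ke_4AA = 0.15) {
  if (any(c(ka, ke_4MAA, ke_4AA, V, dose_mg_per_kg) <= 0)) {
    stop("dose, volume and all rate constants must be > 0", call. = FALSE)
  }
  if (fm < 0 || fm > 1) stop("fm must be in [0, 1]", call. = FALSE)
  structure(list(dose_mg_per_kg = dose_mg_per_kg, ka = ka,
                 ke_4MAA = ke_4MAA, V = V, fm = fm, ke_4AA = ke_4AA),
            class = "pk_config")
}

#' Plasma concentration of a dipyrone metabolite
#'
#' Analytic solution of the depot -> 4MAA -> 4AA catenary chain after a
#' single dose at t = 0. 4MAA follows the Bateman (flip-flop safe)
#' absorption/elimination form; 4AA is the tri-exponential catenary
#' metabolite. Concentrations are 0 for t <= 0. The degenerate case
#' ka = ke_4MAA uses the analytic limit `(D ka t / V) exp(-ka t)`;
#' coincident rate pairs in the 4AA branch are resolved by an infinitesimal
#' (1e-9 relative) rate split, which is below any practical resolution.
#'
#' @param t Time(s) in hours (vectorized).
#' @param pk A [pk_config()].
#' @param analyte `"4MAA"` or `"4AA"`.
#' @return Concentration(s), mg/L.
#' @export
#' @examples
#' conc_one_compartment(c(0, 1, 2, 72), pk_config(), "4MAA")
conc_one_compartment <- function(t, pk, analyte = c("4MAA", "4AA")) {
  stopifnot(inherits(pk, "pk_config"))
  analyte <- match.arg(analyte)
  t <- as.numeric(t)
  D <- pk$dose_mg_per_kg; ka <- pk$ka; k1 <- pk$ke_4MAA
  k2 <- pk$ke_4AA; V <- pk$V; fm <- pk$fm
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  if (analyte == "4MAA") {
    if (abs(ka - k1) < 1e-9 * ka) {
      out[pos] <- D * ka * tp * exp(-ka * tp) / V
    } else {
      out[pos] <- D * ka / (V * (ka - k1)) * (exp(-k1 * tp) - exp(-ka * tp))
    }
  } else {
    rates <- split_coincident(c(ka, k1, k2))
    ka <- rates[1]; k1 <- rates[2]; k2 <- rates[3]
    out[pos] <- fm * k1 * ka * D / V * (
      exp(-ka * tp) / ((k1 - ka) * (k2 - ka)) +
      exp(-k1 * tp) / ((ka - k1) * (k2 - k1)) +
      exp(-k2 * tp) / ((ka - k2) * (k1 - k2)))
  }
  out
}

# nudge numerically coincident rate constants apart so the tri-exponential
# catenary solution stays well defined; the perturbation is 1e-9 relative
split_coincident <- function(rates) {
  eps <- 1e-9 * max(rates)
  for (i in 2:length(rates)) {
    while (any(abs(rates[i] - rates[seq_len(i - 1)]) < eps)) {
      rates[i] <- rates[i] + eps
    }
  }
  rates
}

#' Cohort-mean metabolite profiles on a sampling schedule
#'
#' @param schedule A [sampling_schedule()].
#' @param pk A [pk_config()].
#' @return Data frame `analyte,time_h,concentration` for 4MAA and 4AA at
#'   every schedule time (0 at and before the dose).
#' @export
metabolite_profiles <- function(schedule, pk) {
  times <- schedule_times(schedule)
  do.call(rbind, lapply(c("4MAA", "4AA"), function(a) {
    data.frame(analyte = a, time_h = times,
               concentration = conc_one_compartment(times, pk, a),
               stringsAsFactors = FALSE)
  }))
}
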