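#' Published effect summary of the piglet dipyrone study
#'
#' The per-parameter summary published by the original eight-piglet
#' single-dose (100 mg/kg I.M.) dipyrone study that this pipeline models:
#' dynamic-range extrema (cohort mean; SD), post-dose (`A`, 0-72 h) and
#' baseline (`B`, -36-0 h) AUECs (mean; SD), the A/B change ratio, and the
#' paired-test p-value, for the nine parameters with a significant
#' baseline-vs-effect difference. These values are reference inputs: the
#' A/B ratio column is exactly reproduced by [ab_ratio()] applied to the
#' `A_mean`/`B_mean` columns with the standard 72 h / 36 h windows.
#'
#' Note the published Hct row implies a time-averaged baseline
#' (`B/36` = 71.9%) far outside its own printed dynamic range
#' (26.64-36.32%) — physiologically inconsistent as printed, most likely a
#' column transposition at source. The values are kept exactly as
#' published; [make_effect_table()] flags such inconsistencies on computed
#' tables rather than guessing intent.
#'
#' @return Data frame with columns `parameter`, `dyn_max_mean`,
#'   `dyn_max_sd`, `dyn_min_mean`, `dyn_min_sd`, `A_mean`, `A_sd`,
#'   `B_mean`, `B_sd`, `ab_ratio`, `p_value`.
#' @export
#' @examples
#' ref <- dipyrone_reference_effects()
#' all.equal(round(ab_ratio(ref$A_mean, ref$B_mean), 3), ref$ab_ratio)
dipyrone_reference_effects <- function() {
  data.frame(
    parameter = c("APTT", "APTT_ratio", "Hb", "Hct", "MCH", "MCV", "RBC",
                  "WBC", "PT"),
    dyn_max_mean = c(113.59, 3.36, 12.35, 36.32, 19.65, 58.00, 6.56, 24.67, 95.00),
    dyn_max_sd   = c(25.95, 0.77, 0.58, 1.63, 0.88, 2.60, 0.33, 2.14, 6.08),
    dyn_min_mean = c(45.14, 1.33, 9.14, 26.64, 17.58, 51.25, 5.22, 14.71, 77.25),
    dyn_min_sd   = c(11.04, 0.33, 0.49, 1.70, 0.91, 3.53, 0.37, 1.76, 3.67),
    A_mean = c(4766.87, 140.69, 628.56, 1808.43, 1198.07, 3440.34, 362.90,
               1267.83, 5164.33),
    A_sd   = c(542.43, 16.01, 74.74, 213.89, 139.58, 406.96, 42.88, 179.64,
               699.57),
    B_mean = c(2968.43, 86.38, 450.96, 2586.93, 707.33, 2019.75, 229.96,
               476.63, 3207.75),
    B_sd   = c(588.85, 17.14, 20.44, 58.18, 33.62, 113.64, 10.74, 41.72,
               406.96),
    ab_ratio = c(0.197, 0.186, 0.303, 0.650, 0.153, 0.148, 0.211, -0.330,
                 0.195),
    p_value = c(0.0207, 0.0259, 0.0001, 0.0001, 0.0046, 0.0052, 0.0001,
                0.0006, 0.0076),
    stringsAsFactors = FALSE
  )
}

#' Published leave-one-out validation statistics
#'
#' The validation statistics published for the 4MAA vs composite-index
#' relationship in the original study: Q^2, R^2, the Q^2asym - Q^2 gap, SS
#' and PRESS. These are reference inputs for the acceptance gate (they
#' cannot be recomputed without the study's raw per-timepoint data, which
#' was never published); fed to [validation_gate()] they satisfy all four
#' criteria.
#'
#' The study also printed `Q^2 - R^2 = 0.0631` beside the criterion
#' `Q^2 - R^2 < 0`; the difference is signed here (`-0.0631`), consistent
#' with the printed Q^2 and R^2 themselves.
#'
#' @return List with `q2`, `r2`, `q2_asym_minus_q2`, `ss`, `press`, `n`.
#' @export
dipyrone_reference_validation <- function() {
  list(q2 = 0.8274, r2 = 0.8905, q2_asym_minus_q2 = 0.063,
       ss = 1573.36, press = 271.57, n = 14L)
}
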