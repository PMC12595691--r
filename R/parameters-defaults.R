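# Packaged default model parameterisation.
#
# Every row is one named model input with its point value, uncertainty
# (95% CI or SD), the distribution family used in probabilistic sensitivity
# analysis, and the rule used to form its one-way DSA range:
#   dsa = "ci"       -> vary over the reported 95% CI
#   dsa = "pct10"    -> vary value +/- 10% (clamped to [0,1] for probabilities
#                       and utilities)
#   dsa = "explicit" -> vary over stored low..high bounds (discount rate)
#   dsa = "none"     -> held fixed in DSA
# dist = "fixed" means the parameter is not sampled in PSA.
# Relative risks reported with a "beta" label in the source literature are
# sampled lognormally (median = point value, sigma from the log-CI width):
# a beta distribution cannot represent values above 1.

.param_row <- function(name, value, low = NA_real_, high = NA_real_,
                       sd = NA_real_, dist = "fixed", dsa = "none",
                       kind = "probability", section = "transition",
                       units = "") {
  list(name = name, value = value, low = low, high = high, sd = sd,
       dist = dist, dsa = dsa, kind = kind, section = section, units = units)
}

# canonical screening tool registry: internal id, display label, parameter
# name suffix
.tool_registry <- function() {
  data.frame(
    id = c("SARC-F", "MSRA-5", "MSRA-7", "calf_circumference", "finger_ring",
           "ishii", "SARC-CALF", "AWGS2019", "SARCF_or_MSRA5", "SARCF_or_MSRA7"),
    label = c("SARC-F", "MSRA-5", "MSRA-7", "Calf circumference",
              "Finger-ring test", "Ishii test", "SARC-CALF", "AWGS 2019",
              "SARC-F|MSRA-5", "SARC-F|MSRA-7"),
    suffix = c("sarcf", "msra5", "msra7", "calf", "finger_ring", "ishii",
               "sarc_calf", "awgs2019", "sarcf_msra5", "sarcf_msra7"),
    stringsAsFactors = FALSE
  )
}

.default_param_list <- function() {
  r <- .param_row
  p <- list(
    ## --- transition block -------------------------------------------------
    r("sarcopenia_prevalence", 0.12, 0.10, 0.15, dist = "beta", dsa = "ci"),
    r("rr_cvd_fall", 2.17, 1.06, 2.95, dist = "lognormal", dsa = "ci", kind = "rr"),
    r("sarc_incidence_60_69", 0.04, dsa = "pct10"),
    r("sarc_incidence_70_79", 0.12, dsa = "pct10"),
    r("sarc_incidence_80plus", 0.17, dsa = "pct10"),
    r("p_death_background", 0.09, dsa = "pct10"),
    r("fracture_after_fall", 0.26, 0.23, 0.29, dist = "beta", dsa = "ci"),
    r("rr_sarc_cvd", 1.33, 1.04, 1.71, dist = "lognormal", dsa = "ci", kind = "rr"),
    r("rr_sarc_fall", 1.89, 1.33, 2.68, dist = "lognormal", dsa = "ci", kind = "rr"),
    r("rr_sarc_death", 2.00, 1.71, 2.34, dist = "lognormal", dsa = "ci", kind = "rr"),
    r("rr_sarc_fracture", 1.71, 1.44, 2.03, dist = "lognormal", dsa = "ci", kind = "rr"),
    r("sarcopenia_recovery_rate", 0.16, 0.14, 0.18, dist = "beta", dsa = "ci"),
    r("intervention_rr_incidence", 0.45, 0.37, 0.55, dist = "beta", dsa = "ci"),
    r("intervention_rr_recovery", 3.61, 1.05, 13.66, dist = "lognormal",
      dsa = "ci", kind = "rr"),
    r("possible_sarcopenia_prop", 0.40, 0.36, 0.44, dist = "beta", dsa = "ci"),

    ## --- screening tool accuracy -----------------------------------------
    r("sens_msra7", 0.81, 0.72, 0.88, dist = "beta", dsa = "ci", section = "screening_tools"),
    r("sens_sarcf", 0.34, 0.19, 0.53, dist = "beta", dsa = "ci", section = "screening_tools"),
    r("sens_calf", 0.81, 0.77, 0.84, dist = "beta", dsa = "ci", section = "screening_tools"),
    r("sens_msra5", 0.61, 0.54, 0.69, dist = "beta", dsa = "ci", section = "screening_tools"),
    r("sens_ishii", 0.81, 0.78, 0.85, dist = "beta", dsa = "ci", section = "screening_tools"),
    r("sens_finger_ring", 0.71, 0.65, 0.77, dist = "beta", dsa = "ci", section = "screening_tools"),
    r("sens_sarcf_msra5", 0.42, 0.38, 0.47, dist = "beta", dsa = "ci", section = "screening_tools"),
    r("sens_sarcf_msra7", 0.64, 0.57, 0.70, dist = "beta", dsa = "ci", section = "screening_tools"),
    r("sens_sarc_calf", 0.59, 0.57, 0.70, dist = "beta", dsa = "ci", section = "screening_tools"),
    r("sens_awgs2019", 1.00, section = "screening_tools"),
    r("spec_msra7", 0.43, 0.35, 0.52, dist = "beta", dsa = "ci", section = "screening_tools"),
    r("spec_sarcf", 0.90, 0.83, 0.95, dist = "beta", dsa = "ci", section = "screening_tools"),
    r("spec_calf", 0.73, 0.71, 0.76, dist = "beta", dsa = "ci", section = "screening_tools"),
    r("spec_msra5", 0.74, 0.69, 0.79, dist = "beta", dsa = "ci", section = "screening_tools"),
    r("spec_ishii", 0.76, 0.73, 0.79, dist = "beta", dsa = "ci", section = "screening_tools"),
    r("spec_finger_ring", 0.85, 0.82, 0.87, dist = "beta", dsa = "ci", section = "screening_tools"),
    r("spec_sarcf_msra5", 0.98, 0.88, 1.00, dist = "beta", dsa = "ci", section = "screening_tools"),
    r("spec_sarcf_msra7", 1.00, section = "screening_tools"),
    r("spec_sarc_calf", 0.85, 0.75, 0.92, dist = "beta", dsa = "ci", section = "screening_tools"),
    r("spec_awgs2019", 1.00, section = "screening_tools"),

    ## --- costs (2021 USD) -------------------------------------------------
    r("cost_intervention", 1119.05, sd = 119.05, dist = "gamma", dsa = "pct10",
      kind = "cost", section = "costs", units = "USD"),
    r("cost_fracture", 3599.05, sd = 695.07, dist = "gamma", dsa = "pct10",
      kind = "cost", section = "costs", units = "USD"),
    r("cost_cvd_initial", 4149.29, sd = 414.93, dist = "gamma", dsa = "pct10",
      kind = "cost", section = "costs", units = "USD"),
    r("cost_cvd_continuing", 1904.77, sd = 190.48, dist = "gamma", dsa = "pct10",
      kind = "cost", section = "costs", units = "USD"),
    r("cost_msra7", 0.71, sd = 0.07, dist = "gamma", dsa = "pct10",
      kind = "cost", section = "costs", units = "USD"),
    r("cost_sarcf", 0.71, sd = 0.07, dist = "gamma", dsa = "pct10",
      kind = "cost", section = "costs", units = "USD"),
    r("cost_msra5", 0.71, sd = 0.07, dist = "gamma", dsa = "pct10",
      kind = "cost", section = "costs", units = "USD"),
    r("cost_calf", 0.21, sd = 0.02, dist = "gamma", dsa = "pct10",
      kind = "cost", section = "costs", units = "USD"),
    r("cost_ishii", 1.52, sd = 0.15, dist = "gamma", dsa = "pct10",
      kind = "cost", section = "costs", units = "USD"),
    r("cost_finger_ring", 0.21, sd = 0.02, dist = "gamma", dsa = "pct10",
      kind = "cost", section = "costs", units = "USD"),
    r("cost_sarcf_msra5", 1.43, sd = 0.14, dist = "gamma", dsa = "pct10",
      kind = "cost", section = "costs", units = "USD"),
    r("cost_sarcf_msra7", 1.43, sd = 0.14, dist = "gamma", dsa = "pct10",
      kind = "cost", section = "costs", units = "USD"),
    r("cost_sarc_calf", 0.92, sd = 0.09, dist = "gamma", dsa = "pct10",
      kind = "cost", section = "costs", units = "USD"),
    r("cost_handgrip", 1.31, sd = 0.13, dist = "gamma", dsa = "pct10",
      kind = "cost", section = "costs", units = "USD"),
    r("cost_gait", 0.71, sd = 0.07, dist = "gamma", dsa = "pct10",
      kind = "cost", section = "costs", units = "USD"),
    r("cost_dxa", 42.86, sd = 4.29, dist = "gamma", dsa = "pct10",
      kind = "cost", section = "costs", units = "USD"),

    ## --- utilities ---------------------------------------------------------
    r("u_nonsarc", 0.76, sd = 0.08, dist = "beta", dsa = "pct10",
      kind = "utility", section = "utilities"),
    r("u_sarc", 0.68, sd = 0.07, dist = "beta", dsa = "pct10",
      kind = "utility", section = "utilities"),
    r("u_sarc_fracture", 0.51, sd = 0.05, dist = "beta", dsa = "pct10",
      kind = "utility", section = "utilities"),
    r("u_nonsarc_cvd", 0.75, sd = 0.17, dist = "beta", dsa = "pct10",
      kind = "utility", section = "utilities"),
    r("u_sarc_cvd", 0.56, sd = 0.06, dist = "beta", dsa = "pct10",
      kind = "utility", section = "utilities"),
    r("u_sarc_cvd_fracture", 0.42, sd = 0.04, dist = "beta", dsa = "pct10",
      kind = "utility", section = "utilities"),
    # age-banded fracture utilities for non-sarcopenic individuals: printed
    # without uncertainty, so fixed in both PSA and DSA
    r("u_nonsarc_fracture_60_64", 0.57, kind = "utility", section = "utilities"),
    r("u_nonsarc_fracture_65_69", 0.55, kind = "utility", section = "utilities"),
    r("u_nonsarc_fracture_70_74", 0.53, kind = "utility", section = "utilities"),
    r("u_nonsarc_fracture_75_79", 0.52, kind = "utility", section = "utilities"),
    r("u_nonsarc_fracture_80_84", 0.51, kind = "utility", section = "utilities"),
    r("u_nonsarc_fracture_85plus", 0.50, kind = "utility", section = "utilities"),

    ## --- economics ----------------------------------------------------------
    r("discount_rate", 0.03, 0.01, 0.05, dist = "beta", dsa = "explicit",
      section = "economics"),
    r("gdp_per_capita", 12551.49, kind = "cost", section = "economics",
      units = "USD")
  )
  names(p) <- vapply(p, `[[`, "", "name")
  p
}

#' Names of the parameters every configuration must define
#'
#' @return character vector of required parameter names
#' @export
required_parameter_names <- function() {
  names(.default_param_list())
}
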