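# Screening layer: tools, strategies, classification flows and per-cycle
# screening/confirmation costs.

#' Screening tool definitions for a parameter set
#'
#' Returns the ten tools with their current sensitivity, specificity and unit
#' cost. AWGS 2019 is the two-step case-finding pathway: handgrip strength +
#' gait speed applied to every screened person, followed by DXA confirmation
#' for all sarcopenic individuals (step-1 sensitivity treated as perfect so
#' the pathway keeps its overall 1.00/1.00 accuracy) and for the
#' "possible sarcopenia" fraction of non-sarcopenic individuals.
#'
#' @param ps a `sarc_params` object
#' @return data frame with one row per tool: `id`, `label`, `sensitivity`,
#'   `specificity`, `unit_cost`, `two_step`
#' @export
screening_tools <- function(ps) {
  reg <- .tool_registry()
  data.frame(
    id = reg$id, label = reg$label,
    sensitivity = vapply(reg$suffix, function(s) param_value(ps, paste0("sens_", s)), 0),
    specificity = vapply(reg$suffix, function(s) param_value(ps, paste0("spec_", s)), 0),
    unit_cost = vapply(reg$suffix, function(s)
      if (s == "awgs2019") NA_real_ else param_value(ps, paste0("cost_", s)), 0),
    two_step = reg$suffix == "awgs2019",
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' The 21 evaluated strategies
#'
#' The cross product of the ten screening tools with annual and biennial
#' intervals, plus the no-screening comparator.
#'
#' @param ps a `sarc_params` object
#' @return list of strategy objects (`label`, `tool_id`, `interval`), the
#'   comparator first
#' @export
screening_strategies <- function(ps) {
  reg <- .tool_registry()
  out <- list(list(label = "no screening", tool_id = NA_character_, interval = NA_integer_))
  for (iv in c(1L, 2L)) {
    for (i in seq_len(nrow(reg))) {
      out[[length(out) + 1L]] <- list(
        label = sprintf("%s %s", reg$label[i], if (iv == 1L) "annual" else "biennial"),
        tool_id = reg$id[i], interval = iv)
    }
  }
  out
}

#' Decision-tree classification of a screened cohort
#'
#' Splits a screened population with sarcopenic fraction `p` into true
#' positives, false negatives, true negatives and false positives given a
#' tool's sensitivity and specificity.
#'
#' @param p sarcopenic fraction among those screened, in [0, 1]
#' @param sensitivity,specificity tool accuracy, each in [0, 1]
#' @return named numeric vector `c(tp, fn, tn, fp)`, summing to 1
#' @export
#' @examples
#' classify(0.12, sensitivity = 0.34, specificity = 0.90)
classify <- function(p, sensitivity, specificity) {
  stopifnot(p >= 0, p <= 1, sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  c(tp = p * sensitivity,
    fn = p * (1 - sensitivity),
    tn = (1 - p) * specificity,
    fp = (1 - p) * (1 - specificity))
}

#' Accuracy of a parallel (either-positive) test combination
#'
#' Textbook composition: combined sensitivity 1 - (1-s1)(1-s2), combined
#' specificity sp1 * sp2. Provided as a utility; the shipped parallel
#' strategies use empirically measured combined accuracy instead, which a
#' validation study found to be lower than the formula predicts.
#'
#' @param sens1,spec1,sens2,spec2 component accuracies, each in [0, 1]
#' @return named vector `c(sensitivity, specificity)`
#' @export
parallel_combine <- function(sens1, spec1, sens2, spec2) {
  stopifnot(all(c(sens1, spec1, sens2, spec2) >= 0),
            all(c(sens1, spec1, sens2, spec2) <= 1))
  c(sensitivity = 1 - (1 - sens1) * (1 - sens2),
    specificity = spec1 * spec2)
}

#' Is screening due at a given cycle?
#'
#' Screening starts at model entry (cycle 0): annual strategies screen every
#' cycle, biennial strategies on even cycles, the comparator never.
#'
#' @param cycle_index zero-based cycle number
#' @param interval screening interval in years (1 or 2), or `NA` for the
#'   no-screening comparator
#' @return logical
#' @export
screening_due <- function(cycle_index, interval) {
  stopifnot(cycle_index >= 0)
  if (is.na(interval)) return(FALSE)
  cycle_index %% interval == 0
}

#' Screening cost per cohort member for one screening round
#'
#' All living, not-currently-diagnosed members are screened and incur the
#' tool's unit cost; the dead incur nothing. For the two-step AWGS 2019
#' pathway, every screened person incurs the handgrip + gait speed step and
#' DXA is charged to all sarcopenic members plus the possible-sarcopenia
#' fraction of non-sarcopenic members.
#'
#' @param screened_total fraction of the cohort screened (living, undiagnosed)
#' @param screened_sarc the sarcopenic part of `screened_total`
#' @param tool one row of [screening_tools()]
#' @param ps a `sarc_params` object
#' @return cost per entry-cohort member for this round
#' @export
screening_round_cost <- function(screened_total, screened_sarc, tool, ps) {
  if (screened_total <= 0) return(0)
  if (isTRUE(tool$two_step)) {
    step1 <- param_value(ps, "cost_handgrip") + param_value(ps, "cost_gait")
    dxa_frac <- screened_sarc +
      (screened_total - screened_sarc) * param_value(ps, "possible_sarcopenia_prop")
    screened_total * step1 + dxa_frac * param_value(ps, "cost_dxa")
  } else {
    screened_total * tool$unit_cost
  }
}
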