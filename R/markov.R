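# Markov cohort engine.
#
# Nine strata: the four living health states (no sarcopenia, sarcopenia,
# CVD only, sarcopenia + CVD), each split by intervention status (currently
# under intervention from a positive screen), plus absorbing death.
#
# Within-cycle order: screening (if due) -> fall/fracture event overlay and
# utility accrual on the post-screening start-of-cycle occupancy -> state
# transition -> CVD cost accrual (initial cost on this cycle's entrants,
# continuing cost on start-of-cycle CVD occupancy). No half-cycle correction.

# stratum indices
.ST <- list(NS = 1L, S = 2L, C = 3L, SC = 4L,
            NS_I = 5L, S_I = 6L, C_I = 7L, SC_I = 8L, DEAD = 9L)
.N_STRATA <- 9L
.LIVING <- 1:8
.SARC <- c(2L, 4L, 6L, 8L)
.CVD <- c(3L, 4L, 7L, 8L)
.INTERV <- 5:8
.HEALTH <- c("NS", "S", "C", "SC", "NS", "S", "C", "SC", "DEAD")

#' Stratum labels of the cohort engine
#'
#' @return character vector of the nine stratum names: the four living health
#'   states with and without the intervention flag, then death
#' @export
stratum_labels <- function() {
  c("no_sarc", "sarc", "cvd", "sarc_cvd",
    "no_sarc_interv", "sarc_interv", "cvd_interv", "sarc_cvd_interv", "dead")
}

#' Case-fatality rate from mortality and prevalence
#'
#' The age-band fatality rate of a disease is its cause-specific population
#' mortality rate divided by its prevalence, clamped to [0, 1] with a warning
#' when the ratio exceeds 1.
#'
#' @param mortality_rate cause-specific mortality per person-year, >= 0
#' @param prevalence prevalence fraction, > 0
#' @return annual fatality probability in [0, 1]
#' @export
#' @examples
#' fatality_rate(0.02, 0.10)  # 0.2
fatality_rate <- function(mortality_rate, prevalence) {
  if (prevalence <= 0) stop("fatality_rate: prevalence must be positive")
  if (mortality_rate < 0) stop("fatality_rate: mortality must be non-negative")
  r <- mortality_rate / prevalence
  if (r > 1) {
    warning(sprintf("fatality rate %.3f clamped to 1 (mortality %.4f, prevalence %.4f)",
                    r, mortality_rate, prevalence))
    r <- 1
  }
  r
}

#' Annual event probabilities for one stratum at one age
#'
#' Composes the age-band schedules with the relative risks: falls are scaled
#' by 1.89-type sarcopenia RR and the CVD-on-falls RR; the fracture-given-fall
#' proportion is scaled by the sarcopenia fracture RR (the fall RR acts on
#' fall incidence, the fracture RR on the conditional fracture proportion, so
#' no margin is scaled twice); CVD onset is scaled by the sarcopenia CVD RR
#' and is zero once CVD is present. Death combines background mortality
#' (doubled-type RR for sarcopenia), CVD case fatality (CVD states only) and
#' fall fatality applied to fallers, as independent competing components:
#' p = 1 - prod(1 - component).
#'
#' @param age attained age in years
#' @param health one of `"NS"`, `"S"`, `"C"`, `"SC"`
#' @param ps a `sarc_params` object
#' @return list with `p_fall`, `p_fracture`, `p_cvd_onset`, `p_death`
#' @export
annual_event_probs <- function(age, health, ps) {
  sarc <- health %in% c("S", "SC")
  cvd <- health %in% c("C", "SC")
  fall <- schedule_rates(ps$schedules, "fall", age)
  cvd_r <- schedule_rates(ps$schedules, "CVD", age)

  p_fall <- fall[["incidence"]]
  if (sarc) p_fall <- p_fall * param_value(ps, "rr_sarc_fall")
  if (cvd) p_fall <- p_fall * param_value(ps, "rr_cvd_fall")
  p_fall <- min(p_fall, 1)

  p_frac_given_fall <- param_value(ps, "fracture_after_fall")
  if (sarc) p_frac_given_fall <- p_frac_given_fall * param_value(ps, "rr_sarc_fracture")
  p_fracture <- min(p_fall * min(p_frac_given_fall, 1), 1)

  p_cvd_onset <- if (cvd) 0 else {
    x <- cvd_r[["incidence"]]
    if (sarc) x <- x * param_value(ps, "rr_sarc_cvd")
    min(x, 1)
  }

  bg <- param_value(ps, "p_death_background")
  if (sarc) bg <- bg * param_value(ps, "rr_sarc_death")
  bg <- min(bg, 1)
  cvd_fat <- if (cvd) fatality_rate(cvd_r[["mortality"]], cvd_r[["prevalence"]]) else 0
  fall_fat <- fatality_rate(fall[["mortality"]], fall[["prevalence"]])
  p_death <- 1 - (1 - bg) * (1 - cvd_fat) * (1 - p_fall * fall_fat)

  list(p_fall = p_fall, p_fracture = p_fracture,
       p_cvd_onset = p_cvd_onset, p_death = min(p_death, 1))
}

#' Sarcopenia incidence and recovery at one age
#'
#' Incidence comes from the 60-69 / 70-79 / 80+ band rates, multiplied by the
#' intervention incidence ratio while under intervention; recovery is the base
#' recovery rate, multiplied by the intervention recovery ratio (clamped to 1)
#' while under intervention.
#'
#' @param age attained age in years
#' @param intervened logical, currently under intervention
#' @param ps a `sarc_params` object
#' @return named vector `c(p_incidence, p_recovery)`
#' @export
sarcopenia_dynamics <- function(age, intervened, ps) {
  inc <- if (age < 70) param_value(ps, "sarc_incidence_60_69")
         else if (age < 80) param_value(ps, "sarc_incidence_70_79")
         else param_value(ps, "sarc_incidence_80plus")
  rec <- param_value(ps, "sarcopenia_recovery_rate")
  if (intervened) {
    inc <- inc * param_value(ps, "intervention_rr_incidence")
    rec <- rec * param_value(ps, "intervention_rr_recovery")
  }
  c(p_incidence = min(inc, 1), p_recovery = min(rec, 1))
}

#' One-cycle transition matrix over the nine strata
#'
#' Permitted moves: no-sarcopenia <-> sarcopenia, no-sarcopenia -> CVD,
#' sarcopenia -> sarcopenia + CVD, CVD <-> sarcopenia + CVD (sarcopenia onset
#' and recovery with CVD retained), and any living state -> death. CVD is
#' irreversible and death absorbing. Competing sarcopenia/CVD onsets within a
#' cycle are mutually exclusive (each is thinned by the other's complement;
#' the joint event remains in the origin state). The intervention flag is
#' preserved by transitions and only changed by screening.
#'
#' @param age attained age in years
#' @param ps a `sarc_params` object
#' @return 9 x 9 row-stochastic matrix, rows/cols named by [stratum_labels()]
#' @export
build_transition_matrix <- function(age, ps) {
  M <- matrix(0, .N_STRATA, .N_STRATA,
              dimnames = list(stratum_labels(), stratum_labels()))
  for (i in .LIVING) {
    health <- .HEALTH[i]
    intervened <- i %in% .INTERV
    off <- if (intervened) 4L else 0L
    ev <- annual_event_probs(age, health, ps)
    dyn <- sarcopenia_dynamics(age, intervened, ps)
    surv <- 1 - ev$p_death
    M[i, .ST$DEAD] <- ev$p_death
    if (health == "NS") {
      p_s <- dyn[["p_incidence"]] * (1 - ev$p_cvd_onset)
      p_c <- ev$p_cvd_onset * (1 - dyn[["p_incidence"]])
      M[i, .ST$S + off] <- surv * p_s
      M[i, .ST$C + off] <- surv * p_c
      M[i, .ST$NS + off] <- surv * (1 - p_s - p_c)
    } else if (health == "S") {
      p_ns <- dyn[["p_recovery"]] * (1 - ev$p_cvd_onset)
      p_sc <- ev$p_cvd_onset * (1 - dyn[["p_recovery"]])
      M[i, .ST$NS + off] <- surv * p_ns
      M[i, .ST$SC + off] <- surv * p_sc
      M[i, .ST$S + off] <- surv * (1 - p_ns - p_sc)
    } else if (health == "C") {
      M[i, .ST$SC + off] <- surv * dyn[["p_incidence"]]
      M[i, .ST$C + off] <- surv * (1 - dyn[["p_incidence"]])
    } else {  # SC
      M[i, .ST$C + off] <- surv * dyn[["p_recovery"]]
      M[i, .ST$SC + off] <- surv * (1 - dyn[["p_recovery"]])
    }
  }
  M[.ST$DEAD, .ST$DEAD] <- 1
  bad <- abs(rowSums(M) - 1) > 1e-10
  if (any(bad))
    stop(sprintf("transition matrix rows off unity at age %s: %s", age,
                 paste(stratum_labels()[bad], collapse = ", ")))
  M
}

# Precompute everything run_cohort needs that does not depend on the
# strategy: per-cycle transition matrices, per-stratum fall/fracture
# probabilities, state utilities and with-fracture utilities.
build_engine <- function(ps) {
  n <- ps$settings$n_cycles
  ages <- ps$settings$start_age + seq_len(n) - 1L
  u_state <- c(param_value(ps, "u_nonsarc"), param_value(ps, "u_sarc"),
               param_value(ps, "u_nonsarc_cvd"), param_value(ps, "u_sarc_cvd"))
  u_state <- c(u_state, u_state, 0)

  frac_u_band <- function(age) {
    nm <- if (age < 65) "u_nonsarc_fracture_60_64"
          else if (age < 70) "u_nonsarc_fracture_65_69"
          else if (age < 75) "u_nonsarc_fracture_70_74"
          else if (age < 80) "u_nonsarc_fracture_75_79"
          else if (age < 85) "u_nonsarc_fracture_80_84"
          else "u_nonsarc_fracture_85plus"
    param_value(ps, nm)
  }

  mats <- vector("list", n)
  pfall <- pfrac <- ufrac <- matrix(0, n, .N_STRATA)
  for (t in seq_len(n)) {
    age <- ages[t]
    mats[[t]] <- build_transition_matrix(age, ps)
    uf_ns <- frac_u_band(age)
    # no published value for non-sarcopenic CVD with fracture: multiplicative
    # decrement, u_cvd * (age-band fracture utility / non-sarcopenic utility)
    u_ns <- param_value(ps, "u_nonsarc")
    uf_c <- if (u_ns > 0) param_value(ps, "u_nonsarc_cvd") * uf_ns / u_ns else 0
    uf <- c(uf_ns, param_value(ps, "u_sarc_fracture"), uf_c,
            param_value(ps, "u_sarc_cvd_fracture"))
    ufrac[t, ] <- c(uf, uf, 0)
    for (i in .LIVING) {
      ev <- annual_event_probs(age, .HEALTH[i], ps)
      pfall[t, i] <- ev$p_fall
      pfrac[t, i] <- ev$p_fracture
    }
  }
  list(n_cycles = n, ages = ages, matrices = mats, p_fall = pfall,
       p_fracture = pfrac, u_state = u_state, u_fracture = ufrac)
}

#' Run the cohort trace for one strategy
#'
#' Starts the cohort at age 60 with the sarcopenia prevalence in the
#' sarcopenia stratum and the remainder disease-free, none under intervention,
#' and iterates the within-cycle sequence for `n_cycles` years. At each due
#' screening round the intervention flags from the previous round expire, all
#' living members are screened, and screen-positives (true and false) enter
#' the intervened strata, incurring one intervention episode cost per round.
#'
#' The intervention episode triggered by a positive screen lasts one cycle by
#' default (`effect_duration = "one_cycle"`): its incidence and recovery
#' effects apply for the year of the screen and expire before the next cycle,
#' so biennial strategies leave their off-years unprotected. The alternative
#' `"interval"` keeps the flag until the next due screen. The one-cycle
#' episode reproduces the large annual-versus-biennial effectiveness gaps
#' seen in published base cases; interval-long persistence makes biennial
#' screening nearly as effective as annual.
#'
#' @param strategy one element of [screening_strategies()]
#' @param ps a `sarc_params` object
#' @param engine precomputed context from an internal builder; reused across
#'   strategies for speed when supplied
#' @param totals_only if `TRUE`, skip per-cycle bookkeeping and return only
#'   the numbers needed for discounted totals
#' @param effect_duration how long one intervention episode protects:
#'   `"one_cycle"` (default) or `"interval"`
#' @return an object of class `sarc_trace`: per-cycle occupancy, event flows,
#'   undiscounted cost components and utility, plus the strategy label
#' @export
run_cohort <- function(strategy, ps, engine = NULL, totals_only = FALSE,
                       effect_duration = c("one_cycle", "interval")) {
  effect_duration <- match.arg(effect_duration)
  if (is.null(engine)) engine <- build_engine(ps)
  n <- engine$n_cycles
  tools <- screening_tools(ps)
  tool <- if (!is.na(strategy$tool_id)) tools[tools$id == strategy$tool_id, ] else NULL
  c_interv <- param_value(ps, "cost_intervention")
  c_frac <- param_value(ps, "cost_fracture")
  c_cvd0 <- param_value(ps, "cost_cvd_initial")
  c_cvd1 <- param_value(ps, "cost_cvd_continuing")

  occ <- numeric(.N_STRATA)
  prev <- param_value(ps, "sarcopenia_prevalence")
  occ[.ST$S] <- prev
  occ[.ST$NS] <- 1 - prev

  cost_comp <- matrix(0, n, 5, dimnames = list(NULL,
    c("screening", "intervention", "fracture", "cvd_initial", "cvd_continuing")))
  utility <- alive <- falls <- fractures <- cvd_entrants <- numeric(n)
  occupancy <- if (!totals_only) matrix(0, n, .N_STRATA,
                                        dimnames = list(NULL, stratum_labels()))

  for (t in seq_len(n)) {
    cycle0 <- t - 1L
    ## 0. expiry of the previous intervention episode
    if (effect_duration == "one_cycle" ||
        (!is.null(tool) && screening_due(cycle0, strategy$interval))) {
      occ[1:4] <- occ[1:4] + occ[5:8]
      occ[5:8] <- 0
    }
    ## 1. screening round
    if (!is.null(tool) && screening_due(cycle0, strategy$interval)) {
      screened <- sum(occ[1:4])
      if (screened > 0) {
        sarc_frac <- occ[.ST$S] + occ[.ST$SC]
        pos <- c(1 - tool$specificity, tool$sensitivity,
                 1 - tool$specificity, tool$sensitivity)
        moved <- occ[1:4] * pos
        occ[5:8] <- moved
        occ[1:4] <- occ[1:4] - moved
        cost_comp[t, "screening"] <-
          screening_round_cost(screened, sarc_frac, tool, ps)
        cost_comp[t, "intervention"] <- c_interv * sum(moved)
      }
    }

    ## 2. fall/fracture overlay + utility on start-of-cycle occupancy
    frac_flow <- occ * engine$p_fracture[t, ]
    falls[t] <- sum(occ * engine$p_fall[t, ])
    fractures[t] <- sum(frac_flow)
    cost_comp[t, "fracture"] <- c_frac * fractures[t]
    utility[t] <- sum((occ - frac_flow) * engine$u_state) +
      sum(frac_flow * engine$u_fracture[t, ])
    alive[t] <- 1 - occ[.ST$DEAD]
    cost_comp[t, "cvd_continuing"] <- c_cvd1 * sum(occ[.CVD])
    if (!totals_only) occupancy[t, ] <- occ

    ## 3. transition
    M <- engine$matrices[[t]]
    non_cvd <- setdiff(.LIVING, .CVD)
    cvd_in <- sum(occ[non_cvd] * rowSums(M[non_cvd, .CVD, drop = FALSE]))
    occ <- as.numeric(occ %*% M)
    cvd_entrants[t] <- cvd_in
    cost_comp[t, "cvd_initial"] <- c_cvd0 * cvd_in
  }

  structure(list(
    strategy = strategy$label,
    cycles = data.frame(cycle = seq_len(n) - 1L, age = engine$ages,
                        alive = alive, utility = utility,
                        falls = falls, fractures = fractures,
                        cvd_entrants = cvd_entrants, cost_comp,
                        total_cost = rowSums(cost_comp)),
    occupancy = if (!totals_only) occupancy,
    settings = ps$settings
  ), class = "sarc_trace")
}

#' @export
print.sarc_trace <- function(x, ...) {
  cat(sprintf("<sarc_trace> strategy '%s', %d cycles; undiscounted cost %.2f, life-years %.3f\n",
              x$strategy, nrow(x$cycles), sum(x$cycles$total_cost), sum(x$cycles$alive)))
  invisible(x)
}

#' Undiscounted healthy life expectancy of a trace
#'
#' Entry age plus the sum of start-of-cycle living occupancy over all cycles.
#'
#' @param trace a `sarc_trace`
#' @return life expectancy in years
#' @export
healthy_life_expectancy <- function(trace) {
  trace$settings$start_age + sum(trace$cycles$alive)
}

#' Export a cohort trace as a tidy data frame
#'
#' One row per (cycle, stratum) with occupancy, joined with the per-cycle
#' cost components and utility; suitable for writing to CSV.
#'
#' @param trace a `sarc_trace` run without `totals_only`
#' @return data frame in long format
#' @export
trace_to_df <- function(trace) {
  if (is.null(trace$occupancy)) stop("trace was run with totals_only = TRUE")
  n <- nrow(trace$cycles)
  labs <- stratum_labels()
  long <- data.frame(
    strategy = trace$strategy,
    cycle = rep(trace$cycles$cycle, times = length(labs)),
    stratum = rep(labs, each = n),
    occupancy = as.vector(trace$occupancy))
  merge(long, trace$cycles, by = "cycle", sort = TRUE)
}
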