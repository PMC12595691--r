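# Individual-level microsimulation with the same rules as the cohort engine.
# Used as an internal validation oracle: its Monte Carlo means converge to
# the cohort trace's expectations.

#' Individual-level microsimulation oracle
#'
#' Simulates `n_individuals` independent trajectories under exactly the
#' cohort engine's rules (same within-cycle ordering, cost timing and
#' discounting) and returns mean discounted cost and QALYs with Monte Carlo
#' standard errors. Screening classification, DXA referral among the
#' non-sarcopenic, falls, fractures and state transitions are all drawn at
#' the individual level.
#'
#' @param strategy one element of [screening_strategies()]
#' @param ps a `sarc_params` object
#' @param n_individuals number of simulated persons
#' @param seed integer seed
#' @param effect_duration intervention episode duration, as in [run_cohort()]
#' @return list with `mean_cost`, `mean_qaly`, `se_cost`, `se_qaly`, `n`
#' @export
microsim_oracle <- function(strategy, ps, n_individuals = 10000L, seed = 1L,
                            effect_duration = c("one_cycle", "interval")) {
  effect_duration <- match.arg(effect_duration)
  stopifnot(n_individuals >= 1)
  set.seed(as.integer(seed))
  n <- as.integer(n_individuals)
  engine <- build_engine(ps)
  tools <- screening_tools(ps)
  tool <- if (!is.na(strategy$tool_id)) tools[tools$id == strategy$tool_id, ] else NULL
  rate <- param_value(ps, "discount_rate")
  c_interv <- param_value(ps, "cost_intervention")
  c_frac <- param_value(ps, "cost_fracture")
  c_cvd0 <- param_value(ps, "cost_cvd_initial")
  c_cvd1 <- param_value(ps, "cost_cvd_continuing")
  poss <- param_value(ps, "possible_sarcopenia_prop")
  step1 <- param_value(ps, "cost_handgrip") + param_value(ps, "cost_gait")
  c_dxa <- param_value(ps, "cost_dxa")

  # state codes as in the cohort engine: 1 NS, 2 S, 3 C, 4 SC, +4 intervened,
  # 9 dead
  state <- ifelse(stats::runif(n) < param_value(ps, "sarcopenia_prevalence"), 2L, 1L)
  cost <- qaly <- numeric(n)

  for (t in seq_len(engine$n_cycles)) {
    d <- discount_factor(t - 1L, rate)
    alive <- state != 9L

    ## 0. expiry of the previous intervention episode
    if (effect_duration == "one_cycle" ||
        (!is.null(tool) && screening_due(t - 1L, strategy$interval))) {
      state[alive & state > 4L] <- state[alive & state > 4L] - 4L
    }

    ## 1. screening
    if (!is.null(tool) && screening_due(t - 1L, strategy$interval)) {
      scr <- alive
      sarc <- scr & state %in% c(2L, 4L)
      pos <- logical(n)
      pos[sarc] <- stats::runif(sum(sarc)) < tool$sensitivity
      nonsarc <- scr & state %in% c(1L, 3L)
      pos[nonsarc] <- stats::runif(sum(nonsarc)) >= tool$specificity
      if (isTRUE(tool$two_step)) {
        cost[scr] <- cost[scr] + d * step1
        dxa <- sarc | (nonsarc & stats::runif(n) < poss)
        cost[scr & dxa] <- cost[scr & dxa] + d * c_dxa
      } else {
        cost[scr] <- cost[scr] + d * tool$unit_cost
      }
      cost[pos] <- cost[pos] + d * c_interv
      state[pos] <- state[pos] + 4L
    }

    ## 2. falls/fractures + utility on start-of-cycle state
    pfrac <- engine$p_fracture[t, state]
    fractured <- alive & stats::runif(n) < pfrac
    cost[fractured] <- cost[fractured] + d * c_frac
    u <- ifelse(fractured, engine$u_fracture[t, state], engine$u_state[state])
    qaly <- qaly + d * u
    in_cvd <- alive & state %in% c(3L, 4L, 7L, 8L)
    cost[in_cvd] <- cost[in_cvd] + d * c_cvd1

    ## 3. transition
    M <- engine$matrices[[t]]
    cum <- t(apply(M, 1, cumsum))
    r <- stats::runif(n)
    new_state <- state
    for (s in unique(state[alive])) {
      sel <- alive & state == s
      new_state[sel] <- findInterval(r[sel], cum[s, ], left.open = TRUE) + 1L
    }
    entered_cvd <- !(state %in% c(3L, 4L, 7L, 8L)) & new_state %in% c(3L, 4L, 7L, 8L)
    cost[entered_cvd] <- cost[entered_cvd] + d * c_cvd0
    state <- new_state
  }

  list(mean_cost = mean(cost), mean_qaly = mean(qaly),
       se_cost = stats::sd(cost) / sqrt(n), se_qaly = stats::sd(qaly) / sqrt(n),
       n = n)
}
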