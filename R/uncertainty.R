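# One-way deterministic sensitivity analysis (tornado) and probabilistic
# sensitivity analysis with cost-effectiveness acceptability curves.

# incremental NMB of strategy vs comparator under a given parameter set
.incr_nmb <- function(ps, strategy, comparator, wtp) {
  engine <- build_engine(ps)
  rate <- param_value(ps, "discount_rate")
  a <- accumulate(run_cohort(strategy, ps, engine, totals_only = TRUE), rate)
  b <- accumulate(run_cohort(comparator, ps, engine, totals_only = TRUE), rate)
  net_monetary_benefit(a$total_cost, a$total_qaly, wtp) -
    net_monetary_benefit(b$total_cost, b$total_qaly, wtp)
}

.find_strategy <- function(ps, label) {
  strategies <- screening_strategies(ps)
  labels <- vapply(strategies, `[[`, "", "label")
  i <- match(label, labels)
  if (is.na(i))
    stop(sprintf("unknown strategy '%s'; valid: %s", label,
                 paste(labels, collapse = ", ")))
  strategies[[i]]
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' For every parameter with a DSA range rule, reruns the full pipeline with
#' that parameter at its low and at its high bound (all others at base case)
#' and records the incremental net monetary benefit of `strategy` versus
#' `comparator` at willingness-to-pay `wtp`. Rows are sorted by the width of
#' the NMB swing (tornado order); `influence_share` is each swing as a
#' fraction of the sum of swings.
#'
#' @param ps a `sarc_params` object
#' @param strategy strategy label whose net benefit the tornado tracks;
#'   default annual AWGS 2019, the recommended strategy
#' @param comparator comparator label, default no screening
#' @param wtp willingness to pay per QALY; default 3x per-capita GDP
#' @return data frame `parameter`, `low`, `high`, `nmb_low`, `nmb_high`,
#'   `range`, `influence_share`
#' @export
one_way_dsa <- function(ps, strategy = "AWGS 2019 annual",
                        comparator = "no screening",
                        wtp = 3 * ps$settings$gdp_per_capita) {
  strat <- .find_strategy(ps, strategy)
  comp <- .find_strategy(ps, comparator)
  varied <- dsa_parameter_names(ps)
  rows <- lapply(varied, function(nm) {
    rng <- dsa_range(ps$params[[nm]])
    nmb <- vapply(rng, function(v)
      .incr_nmb(set_param_value(ps, nm, v), strat, comp, wtp), 0)
    data.frame(parameter = nm, low = rng[1], high = rng[2],
               nmb_low = nmb[1], nmb_high = nmb[2],
               range = abs(nmb[2] - nmb[1]), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(-df$range, df$parameter), , drop = FALSE]
  total <- sum(df$range)
  df$influence_share <- if (total > 0) df$range / total else 0
  rownames(df) <- NULL
  df
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_draws` joint parameter samples (each via
#' [sample_parameter_set()], one substream per parameter per draw) and runs
#' every strategy under each draw, recording discounted cost and QALYs.
#' Identical `seed` reproduces identical output.
#'
#' @param ps a `sarc_params` object
#' @param n_draws number of Monte Carlo draws (1000 in the reference
#'   analysis)
#' @param seed integer master seed
#' @return data frame `draw`, `strategy`, `cost`, `qaly`
#' @export
run_psa <- function(ps, n_draws = 1000L, seed = 1L) {
  stopifnot(n_draws >= 1)
  strategies <- screening_strategies(ps)
  labels <- vapply(strategies, `[[`, "", "label")
  n_s <- length(strategies)
  cost <- qaly <- matrix(NA_real_, n_draws, n_s)
  for (d in seq_len(n_draws)) {
    draw_seed <- (abs(as.integer(seed)) * 2654435 + d * 40503) %% 2147483647
    psd <- tryCatch(sample_parameter_set(ps, draw_seed),
                    error = function(e) stop(sprintf("PSA draw %d: %s", d,
                                                     conditionMessage(e))))
    engine <- build_engine(psd)
    rate <- param_value(psd, "discount_rate")
    for (k in seq_len(n_s)) {
      tot <- accumulate(run_cohort(strategies[[k]], psd, engine,
                                   totals_only = TRUE), rate)
      cost[d, k] <- tot$total_cost
      qaly[d, k] <- tot$total_qaly
    }
  }
  data.frame(draw = rep(seq_len(n_draws), times = n_s),
             strategy = rep(labels, each = n_draws),
             cost = as.vector(cost), qaly = as.vector(qaly),
             stringsAsFactors = FALSE)
}

#' Cost-effectiveness acceptability curves
#'
#' For every willingness-to-pay value on the grid, the probability that each
#' strategy attains the maximum net monetary benefit across the PSA draws;
#' exact ties split their probability equally. Probabilities over all
#' strategies sum to 1 at every grid point.
#'
#' @param psa output of [run_psa()]
#' @param wtp_grid increasing vector of willingness-to-pay values; the
#'   default 0-40,000 by 200 covers both GDP thresholds
#' @return data frame `wtp`, `strategy`, `probability`
#' @export
ceac <- function(psa, wtp_grid = seq(0, 40000, by = 200)) {
  stopifnot(length(wtp_grid) >= 1, !is.unsorted(wtp_grid))
  labels <- unique(psa$strategy)
  draws <- sort(unique(psa$draw))
  psa <- psa[order(match(psa$strategy, labels), psa$draw), , drop = FALSE]
  cost <- matrix(psa$cost, nrow = length(draws),
                 dimnames = list(NULL, labels))
  qaly <- matrix(psa$qaly, nrow = length(draws),
                 dimnames = list(NULL, labels))
  out <- matrix(0, length(wtp_grid), length(labels),
                dimnames = list(NULL, labels))
  for (g in seq_along(wtp_grid)) {
    nmb <- qaly * wtp_grid[g] - cost
    best <- apply(nmb, 1, max)
    win <- nmb >= best - 1e-9 * pmax(1, abs(best))  # exact-tie tolerance
    out[g, ] <- colSums(win / rowSums(win)) / length(draws)
  }
  data.frame(wtp = rep(wtp_grid, times = length(labels)),
             strategy = rep(labels, each = length(wtp_grid)),
             probability = as.vector(out), stringsAsFactors = FALSE)
}
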