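# Discounted cost/QALY aggregation, ICERs, threshold classification,
# efficiency frontier and net monetary benefit.

#' Discount factor for a cycle
#'
#' `(1 + rate)^(-cycle_index)`; cycle 0 is undiscounted. Costs and QALYs are
#' discounted at the same rate.
#'
#' @param cycle_index zero-based cycle number
#' @param rate annual discount rate, >= 0
#' @return multiplier in (0, 1]
#' @export
discount_factor <- function(cycle_index, rate) {
  stopifnot(rate >= 0)
  (1 + rate)^(-cycle_index)
}

#' Discounted totals of a cohort trace
#'
#' @param trace a `sarc_trace`
#' @param rate annual discount rate; defaults to the trace's parameter-set
#'   discount rate when available
#' @return list with `total_cost` and `total_qaly` per entry-cohort member
#' @export
accumulate <- function(trace, rate) {
  d <- discount_factor(trace$cycles$cycle, rate)
  list(total_cost = sum(d * trace$cycles$total_cost),
       total_qaly = sum(d * trace$cycles$utility))
}

#' Incremental cost-effectiveness ratio
#'
#' Incremental cost divided by incremental effectiveness versus the
#' comparator. Undefined (NA) when the effectiveness difference is zero or
#' negative; callers should report such strategies as dominated rather than
#' as signed ratios.
#'
#' @param cost,qaly strategy totals
#' @param cost0,qaly0 comparator totals
#' @return the ICER, or `NA` when incremental effectiveness <= 0
#' @export
icer <- function(cost, qaly, cost0, qaly0) {
  de <- qaly - qaly0
  if (de <= 0) return(NA_real_)
  (cost - cost0) / de
}

#' Willingness-to-pay threshold classification
#'
#' ICERs below one per-capita GDP are highly cost-effective, below three
#' times GDP cost-effective, otherwise not cost-effective.
#'
#' @param icer_value an ICER (currency per QALY); `NA` allowed
#' @param gdp per-capita GDP used as the threshold unit
#' @return one of `"highly cost-effective"`, `"cost-effective"`,
#'   `"not cost-effective"`, or `NA` for undefined ICERs
#' @export
classify_threshold <- function(icer_value, gdp) {
  stopifnot(gdp > 0)
  if (is.na(icer_value)) return(NA_character_)
  if (icer_value < gdp) "highly cost-effective"
  else if (icer_value < 3 * gdp) "cost-effective"
  else "not cost-effective"
}

#' Net monetary benefit
#'
#' @param cost,qaly strategy totals
#' @param wtp willingness to pay per QALY, >= 0
#' @return `qaly * wtp - cost`
#' @export
net_monetary_benefit <- function(cost, qaly, wtp) {
  stopifnot(wtp >= 0)
  qaly * wtp - cost
}

#' Efficiency frontier on the (QALY, cost) plane
#'
#' Flags the convex, non-dominated lower-right hull: strictly dominated
#' points (some other point with at least the QALYs at no more cost, one
#' strictly better) are removed, then extended dominance is pruned so that
#' sequential ICERs increase along the frontier. Exactly tied points are both
#' retained.
#'
#' @param qaly,cost numeric vectors of per-strategy totals
#' @return logical vector: on the frontier?
#' @export
efficiency_frontier <- function(qaly, cost) {
  stopifnot(length(qaly) == length(cost), length(qaly) >= 2)
  n <- length(qaly)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    dominated <- (qaly >= qaly[i] & cost <= cost[i]) &
      (qaly > qaly[i] | cost < cost[i])
    if (any(dominated)) keep[i] <- FALSE
  }
  idx <- which(keep)
  idx <- idx[order(qaly[idx], cost[idx])]
  # extended dominance: sequential ICERs must be increasing
  repeat {
    if (length(idx) < 3) break
    dq <- diff(qaly[idx]); dc <- diff(cost[idx])
    ratio <- ifelse(dq > 0, dc / dq, Inf)
    drop <- which(diff(ratio) < 0)
    if (!length(drop)) break
    idx <- idx[-(drop[1] + 1L)]
  }
  out <- rep(FALSE, n)
  out[idx] <- TRUE
  # exactly tied points share frontier status
  for (i in which(out)) out[qaly == qaly[i] & cost == cost[i]] <- TRUE
  out
}

#' Base-case cost-effectiveness table for all strategies
#'
#' Runs the cohort for every strategy (the 21 by default) and assembles the
#' standard table: discounted cost and QALYs per person, increments versus no
#' screening, the cost-effectiveness ratio, the ICER versus no screening, the
#' willingness-to-pay classification and the efficiency-frontier flag, sorted
#' by total cost.
#'
#' @param ps a `sarc_params` object
#' @param strategies optional strategy list; defaults to
#'   [screening_strategies()]
#' @return data frame with one row per strategy
#' @export
#' @examples
#' \donttest{
#' tab <- cea_table(default_parameters())
#' tab[which.min(tab$icer), "strategy"]
#' }
cea_table <- function(ps, strategies = NULL) {
  if (is.null(strategies)) strategies <- screening_strategies(ps)
  engine <- build_engine(ps)
  rate <- param_value(ps, "discount_rate")
  gdp <- ps$settings$gdp_per_capita
  tot <- lapply(strategies, function(s)
    accumulate(run_cohort(s, ps, engine, totals_only = TRUE), rate))
  cost <- vapply(tot, `[[`, 0, "total_cost")
  qaly <- vapply(tot, `[[`, 0, "total_qaly")
  labels <- vapply(strategies, `[[`, "", "label")
  i0 <- match("no screening", labels)
  if (is.na(i0)) stop("strategy list must include the no-screening comparator")
  icers <- vapply(seq_along(labels), function(i)
    if (i == i0) NA_real_ else icer(cost[i], qaly[i], cost[i0], qaly[i0]), 0)
  df <- data.frame(
    strategy = labels,
    cost = cost,
    incr_cost = cost - cost[i0],
    qaly = qaly,
    incr_qaly = qaly - qaly[i0],
    ce_ratio = cost / qaly,
    icer = icers,
    threshold_class = vapply(icers, classify_threshold, "", gdp = gdp),
    on_frontier = efficiency_frontier(qaly, cost),
    stringsAsFactors = FALSE)
  df[order(df$cost), , drop = FALSE]
}

#' Frontier coordinates and sequential ICERs
#'
#' The (QALY, cost) pairs of the frontier strategies in increasing QALY
#' order, with the ICER of each frontier step, for plotting the
#' cost-effectiveness plane.
#'
#' @param tab a table from [cea_table()]
#' @return data frame `strategy`, `qaly`, `cost`, `sequential_icer`
#' @export
frontier_table <- function(tab) {
  f <- tab[tab$on_frontier, , drop = FALSE]
  f <- f[order(f$qaly, f$cost), , drop = FALSE]
  seq_icer <- c(NA_real_, diff(f$cost) / diff(f$qaly))
  data.frame(strategy = f$strategy, qaly = f$qaly, cost = f$cost,
             sequential_icer = seq_icer, stringsAsFactors = FALSE)
}

#' Published reference cost-effectiveness table
#'
#' The published base-case table for the same 21 strategies (costs, QALYs,
#' increments, cost-effectiveness ratios and ICERs versus no screening, in
#' 2021 USD). Bundled for arithmetic validation of the ICER/CE operators and
#' for side-by-side comparison in reports; the package does not use it in any
#' computation.
#'
#' @return data frame with columns `strategy`, `cost`, `incr_cost`, `qaly`,
#'   `incr_qaly`, `ce_ratio`, `icer`
#' @export
reference_cea_table <- function() {
  txt <- "strategy;cost;incr_cost;qaly;incr_qaly;ce_ratio;icer
no screening;10411.01;0.00;9.0011;0.0000;1156.64;NA
SARC-F|MSRA-5 biennial;11001.03;590.02;9.2290;0.2279;1192.01;2588.90
SARC-F|MSRA-7 biennial;11064.42;653.41;9.4482;0.4471;1171.06;1461.52
SARC-F biennial;11276.12;865.11;9.2061;0.2050;1224.86;4220.83
SARC-F|MSRA-5 annual;11398.31;987.30;9.3687;0.3677;1216.63;2685.39
SARC-F|MSRA-7 annual;11429.70;1018.70;9.4754;0.4743;1206.25;2147.82
AWGS 2019 biennial;11459.37;1048.36;9.4491;0.4480;1212.75;2340.21
SARC-CALF biennial;11762.51;1351.50;9.3274;0.3263;1261.07;4141.59
Finger-ring test biennial;11865.67;1454.66;9.3750;0.3739;1265.67;3890.64
AWGS 2019 annual;11904.95;1493.95;9.6186;0.6175;1237.70;2419.16
SARC-F annual;11979.69;1568.69;9.3423;0.3412;1282.31;4597.49
MSRA-5 biennial;12312.81;1901.80;9.3584;0.3573;1315.70;5323.03
Ishii test biennial;12395.75;1984.74;9.4302;0.4291;1314.47;4625.16
Calf circumference biennial;12536.44;2125.43;9.4362;0.4351;1328.54;4884.42
SARC-CALF annual;12783.55;2372.54;9.5015;0.5004;1345.42;4740.95
Finger-ring test annual;12905.86;2494.85;9.5553;0.5542;1350.65;4501.77
MSRA-5 annual;13856.56;3445.56;9.5473;0.5462;1451.37;6308.68
Ishii test annual;13881.77;3470.76;9.6221;0.6210;1442.70;5588.97
MSRA-7 biennial;14030.25;3619.24;9.4975;0.4964;1477.25;7290.52
Calf circumference annual;14160.75;3749.75;9.6313;0.6302;1470.29;5950.48
MSRA-7 annual;17147.98;6736.97;9.7257;0.7246;1763.17;9297.93"
  utils::read.table(text = txt, sep = ";", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "NA")
}
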