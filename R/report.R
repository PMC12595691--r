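# Pipeline drivers: run the base case, the tornado DSA and the PSA/CEAC and
# write their canonical CSV outputs plus a reproducibility manifest.

.resolve_params <- function(params) {
  if (inherits(params, "sarc_params")) params
  else if (is.character(params) && length(params) == 1) load_parameters(params)
  else stop("params must be a sarc_params object or a configuration file path")
}

.write_manifest <- function(out_dir, files, seed = NA) {
  info <- data.frame(file = files,
                     md5 = unname(tools::md5sum(file.path(out_dir, files))),
                     stringsAsFactors = FALSE)
  manifest <- c(sprintf("created: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                sprintf("seed: %s", seed),
                sprintf("package_version: %s",
                        as.character(utils::packageVersion("sarcscreen"))),
                sprintf("%s  %s", info$md5, info$file))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(info)
}

#' Run the base-case analysis and write its outputs
#'
#' Writes `cea_table.csv` (one row per strategy, sorted by cost),
#' `frontier.csv` (frontier coordinates and sequential ICERs),
#' `trace_<strategy>.csv` for every strategy, and a manifest with file
#' hashes. Logs the lowest-ICER and highest-QALY strategies.
#'
#' @param params a `sarc_params` object or a configuration file path
#' @param out_dir output directory (created if needed)
#' @param write_traces write the per-strategy cycle traces (default TRUE)
#' @return the CEA table, invisibly
#' @export
run_base_case <- function(params, out_dir, write_traces = TRUE) {
  ps <- .resolve_params(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- cea_table(ps)
  files <- c("cea_table.csv", "frontier.csv")
  utils::write.csv(tab, file.path(out_dir, "cea_table.csv"), row.names = FALSE)
  utils::write.csv(frontier_table(tab), file.path(out_dir, "frontier.csv"),
                   row.names = FALSE)
  if (write_traces) {
    for (s in screening_strategies(ps)) {
      tr <- run_cohort(s, ps)
      f <- sprintf("trace_%s.csv", gsub("[^A-Za-z0-9]+", "_", s$label))
      utils::write.csv(trace_to_df(tr), file.path(out_dir, f), row.names = FALSE)
      files <- c(files, f)
    }
  }
  .write_manifest(out_dir, files)
  best <- tab$strategy[which.min(tab$icer)]
  most_eff <- tab$strategy[which.max(tab$qaly)]
  message(sprintf("lowest ICER: %s; highest QALYs: %s", best, most_eff))
  invisible(tab)
}

#' Run the one-way DSA and write the tornado table
#'
#' @inheritParams run_base_case
#' @param strategy,comparator,wtp passed to [one_way_dsa()]
#' @return the tornado data frame, invisibly
#' @export
run_dsa <- function(params, out_dir, strategy = "AWGS 2019 annual",
                    comparator = "no screening", wtp = NULL) {
  ps <- .resolve_params(params)
  if (is.null(wtp)) wtp <- 3 * ps$settings$gdp_per_capita
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  df <- one_way_dsa(ps, strategy, comparator, wtp)
  utils::write.csv(df, file.path(out_dir, "tornado.csv"), row.names = FALSE)
  .write_manifest(out_dir, "tornado.csv")
  message(sprintf("top tornado rows: %s",
                  paste(utils::head(df$parameter, 3), collapse = ", ")))
  invisible(df)
}

#' Run the PSA, write draws and acceptability curves
#'
#' Writes `psa_draws.csv` and `ceac.csv` and logs, per strategy, the smallest
#' grid willingness-to-pay at which its acceptability first reaches 0.99.
#'
#' @inheritParams run_base_case
#' @param n_draws number of Monte Carlo draws
#' @param seed master seed
#' @param wtp_grid willingness-to-pay grid for the CEAC
#' @return list with elements `psa` and `ceac`, invisibly
#' @export
run_psa_report <- function(params, out_dir, n_draws = 1000L, seed = 1L,
                           wtp_grid = seq(0, 40000, by = 200)) {
  ps <- .resolve_params(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  psa <- run_psa(ps, n_draws, seed)
  cc <- ceac(psa, wtp_grid)
  utils::write.csv(psa, file.path(out_dir, "psa_draws.csv"), row.names = FALSE)
  utils::write.csv(cc, file.path(out_dir, "ceac.csv"), row.names = FALSE)
  .write_manifest(out_dir, c("psa_draws.csv", "ceac.csv"), seed = seed)
  for (s in unique(cc$strategy)) {
    p <- cc[cc$strategy == s, ]
    hit <- p$wtp[p$probability >= 0.99]
    if (length(hit))
      message(sprintf("%s reaches acceptability 0.99 at WTP %s", s, min(hit)))
  }
  invisible(list(psa = psa, ceac = cc))
}
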