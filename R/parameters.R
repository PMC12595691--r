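#' Construct the packaged default parameter set
#'
#' Builds the full model parameterisation: the published input table (point
#' values, uncertainty, distribution families), the model settings (1,000
#' cohort members, 25 one-year cycles starting at age 60, per-capita GDP
#' threshold $12,551.49, 3\% discounting), and age-specific cardiovascular
#' disease and fall rate schedules (synthetic mid-level schedules unless
#' supplied).
#'
#' @param schedules optional age-rate schedule data frame as produced by
#'   [generate_schedules()]; defaults to `generate_schedules(level = "mid")`
#' @return an object of class `sarc_params`
#' @export
#' @examples
#' ps <- default_parameters()
#' param_value(ps, "sarcopenia_prevalence")
default_parameters <- function(schedules = NULL) {
  if (is.null(schedules)) schedules <- generate_schedules(level = "mid")
  ps <- structure(
    list(
      params = .default_param_list(),
      schedules = schedules,
      settings = list(cohort_size = 1000L, n_cycles = 25L, start_age = 60L,
                      gdp_per_capita = 12551.49)
    ),
    class = "sarc_params"
  )
  validate_parameters(ps)
  ps
}

#' @export
print.sarc_params <- function(x, ...) {
  cat(sprintf("<sarc_params> %d parameters, %d schedule bands, cohort %d, %d cycles from age %d\n",
              length(x$params), nrow(x$schedules), x$settings$cohort_size,
              x$settings$n_cycles, x$settings$start_age))
  invisible(x)
}

#' Look up a parameter's current point value
#'
#' @param ps a `sarc_params` object
#' @param name parameter name (see [required_parameter_names()])
#' @return scalar value
#' @export
param_value <- function(ps, name) {
  p <- ps$params[[name]]
  if (is.null(p)) stop(sprintf("unknown parameter '%s'", name))
  p$value
}

# set a point value, returning a modified copy (used by the DSA)
set_param_value <- function(ps, name, value) {
  if (is.null(ps$params[[name]])) stop(sprintf("unknown parameter '%s'", name))
  ps$params[[name]]$value <- value
  ps
}

#' Validate a parameter set
#'
#' Checks completeness against [required_parameter_names()] and the per-row
#' invariants: finite values, probabilities and utilities in [0, 1], costs
#' non-negative, `low <= value <= high` where an interval is given, positive
#' SD where a gamma is requested, and schedule bands covering the modelled
#' ages contiguously.
#'
#' @param ps a `sarc_params` object
#' @return `ps`, invisibly; stops with an informative error otherwise
#' @export
validate_parameters <- function(ps) {
  missing <- setdiff(required_parameter_names(), names(ps$params))
  if (length(missing))
    stop(sprintf("missing required parameters: %s", paste(missing, collapse = ", ")))
  for (p in ps$params) {
    if (!is.finite(p$value))
      stop(sprintf("parameter '%s': value is not finite", p$name))
    if (p$kind %in% c("probability", "utility") && (p$value < 0 || p$value > 1))
      stop(sprintf("parameter '%s': value %s outside [0, 1]", p$name, p$value))
    if (p$kind == "cost" && p$value < 0)
      stop(sprintf("parameter '%s': negative cost", p$name))
    if (!is.na(p$low) && !is.na(p$high) && !(p$low <= p$value && p$value <= p$high))
      stop(sprintf("parameter '%s': value %s outside its interval [%s, %s]",
                   p$name, p$value, p$low, p$high))
    if (p$dist == "gamma" && (is.na(p$sd) || p$sd <= 0))
      stop(sprintf("parameter '%s': gamma distribution requires sd > 0", p$name))
  }
  if (ps$settings$cohort_size < 1) stop("cohort_size must be >= 1")
  if (ps$settings$n_cycles < 1) stop("n_cycles must be >= 1")
  validate_schedules(ps$schedules, ps$settings$start_age,
                     ps$settings$start_age + ps$settings$n_cycles)
  invisible(ps)
}

#' Build the sampling distribution for one parameter
#'
#' Dispatches on the row's distribution family: beta rows with a reported CI
#' are fitted with [beta_from_mean_ci()], beta rows with a reported SD with
#' [beta_from_mean_sd()], gamma rows with [gamma_from_mean_sd()], and
#' relative-risk rows with [lognormal_from_median_ci()]. Fixed rows return
#' `NULL`.
#'
#' @param p a single parameter record from `ps$params`
#' @return a distribution spec list, or `NULL` for fixed parameters
#' @export
param_distribution <- function(p) {
  switch(p$dist,
         fixed = NULL,
         beta = if (!is.na(p$low) && !is.na(p$high))
           beta_from_mean_ci(p$value, p$low, p$high, p$name)
         else beta_from_mean_sd(p$value, p$sd, p$name),
         gamma = gamma_from_mean_sd(p$value, p$sd, p$name),
         lognormal = lognormal_from_median_ci(p$value, p$low, p$high, p$name),
         stop(sprintf("parameter '%s': unknown distribution '%s'", p$name, p$dist)))
}

# deterministic 32-bit hash of a parameter name, for independent substreams
.name_hash <- function(name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

#' Draw one probabilistic-sensitivity-analysis parameter sample
#'
#' Replaces every uncertain parameter by one independent draw from its fitted
#' distribution; fixed parameters (perfect sensitivities/specificities,
#' age-banded incidence rates and fracture utilities, background mortality)
#' are unchanged. Each named parameter uses its own random substream derived
#' from the seed and the parameter name, so adding or removing a parameter
#' does not perturb the draws of the others, and an identical seed reproduces
#' identical draws.
#'
#' @param ps a `sarc_params` object
#' @param seed integer master seed
#' @return a new `sarc_params` with sampled point values
#' @export
sample_parameter_set <- function(ps, seed) {
  seed <- as.integer(seed)
  for (nm in names(ps$params)) {
    p <- ps$params[[nm]]
    spec <- param_distribution(p)
    if (is.null(spec)) next
    sub <- (abs(seed) * 69621 + .name_hash(nm)) %% 2147483647
    old <- .Random.seed_exists()
    set.seed(sub)
    ps$params[[nm]]$value <- dist_draw(spec)
    .restore_seed(old)
  }
  ps
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' One-way deterministic sensitivity range of a parameter
#'
#' Rule `"ci"` returns the reported 95\% CI; `"pct10"` returns value +/- 10\%,
#' clamped to [0, 1] for probabilities and utilities; `"explicit"` returns
#' the stored bounds (the discount rate varies over 0.01-0.05).
#'
#' @param p a single parameter record
#' @return numeric vector `c(low, high)`
#' @export
dsa_range <- function(p) {
  switch(p$dsa,
         none = stop(sprintf("parameter '%s' has no DSA range rule", p$name)),
         ci = {
           if (is.na(p$low) || is.na(p$high))
             stop(sprintf("parameter '%s': DSA rule 'ci' but no CI stored", p$name))
           c(p$low, p$high)
         },
         pct10 = {
           lo <- 0.9 * p$value; hi <- 1.1 * p$value
           if (p$kind %in% c("probability", "utility")) {
             lo <- max(0, lo); hi <- min(1, hi)
           }
           c(lo, hi)
         },
         explicit = c(p$low, p$high),
         stop(sprintf("parameter '%s': unknown DSA rule '%s'", p$name, p$dsa)))
}

# names of parameters varied in the tornado
dsa_parameter_names <- function(ps) {
  names(ps$params)[vapply(ps$params, function(p) p$dsa != "none", logical(1))]
}

## ---- configuration file I/O -------------------------------------------------

#' Load and validate a model configuration file
#'
#' The configuration is YAML with sections `settings`, `transition`,
#' `screening_tools`, `costs`, `utilities`, `economics` and `age_schedules`.
#' Each parameter entry is either a bare number (point value, other fields
#' from the packaged defaults) or a mapping with any of `value`, `low`,
#' `high`, `sd`, `dist`, `dsa`. All names listed by
#' [required_parameter_names()] must be present; `settings` and
#' `age_schedules` are optional and default to the packaged values and the
#' mid-level synthetic schedules.
#'
#' @param path path to a YAML configuration file
#' @return a validated `sarc_params` object
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop(sprintf("configuration file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  defaults <- .default_param_list()
  sections <- c("transition", "screening_tools", "costs", "utilities", "economics")
  supplied <- list()
  for (sec in sections) {
    for (nm in names(cfg[[sec]])) {
      entry <- cfg[[sec]][[nm]]
      if (is.null(defaults[[nm]]))
        stop(sprintf("unknown parameter '%s' in section '%s'", nm, sec))
      p <- defaults[[nm]]
      if (is.numeric(entry) && length(entry) == 1) {
        p$value <- as.numeric(entry)
      } else if (is.list(entry)) {
        for (f in intersect(names(entry), c("value", "low", "high", "sd")))
          p[[f]] <- as.numeric(entry[[f]])
        for (f in intersect(names(entry), c("dist", "dsa")))
          p[[f]] <- as.character(entry[[f]])
      } else {
        stop(sprintf("parameter '%s': entry must be a number or a mapping", nm))
      }
      supplied[[nm]] <- p
    }
  }
  missing <- setdiff(required_parameter_names(), names(supplied))
  if (length(missing))
    stop(sprintf("missing required parameters: %s", paste(missing, collapse = ", ")))

  schedules <- if (!is.null(cfg$age_schedules))
    .schedules_from_config(cfg$age_schedules)
  else generate_schedules(level = "mid")

  settings <- list(cohort_size = 1000L, n_cycles = 25L, start_age = 60L,
                   gdp_per_capita = 12551.49)
  for (f in intersect(names(cfg$settings), names(settings)))
    settings[[f]] <- if (f == "gdp_per_capita") as.numeric(cfg$settings[[f]])
                     else as.integer(cfg$settings[[f]])

  ps <- structure(list(params = supplied[required_parameter_names()],
                       schedules = schedules, settings = settings),
                  class = "sarc_params")
  validate_parameters(ps)
  ps
}

.schedules_from_config <- function(x) {
  rows <- lapply(x, function(b) {
    data.frame(disease = b$disease, age_low = b$age_low, age_high = b$age_high,
               incidence = b$incidence, prevalence = b$prevalence,
               mortality = b$mortality)
  })
  do.call(rbind, rows)
}

#' Write the packaged default configuration to a YAML file
#'
#' Emits every default parameter with its uncertainty, distribution and DSA
#' rule, the model settings, and the mid-level synthetic age schedules, in
#' the schema read by [load_parameters()]. Useful as an editable template.
#'
#' @param path output file path
#' @param ps parameter set to dump; defaults to [default_parameters()]
#' @return `path`, invisibly
#' @export
write_default_config <- function(path, ps = default_parameters()) {
  sec_of <- vapply(ps$params, `[[`, "", "section")
  out <- list(settings = ps$settings)
  for (sec in unique(sec_of)) {
    entries <- lapply(ps$params[sec_of == sec], function(p) {
      e <- list(value = p$value)
      if (!is.na(p$low)) e$low <- p$low
      if (!is.na(p$high)) e$high <- p$high
      if (!is.na(p$sd)) e$sd <- p$sd
      if (p$dist != "fixed") e$dist <- p$dist
      if (p$dsa != "none") e$dsa <- p$dsa
      e
    })
    out[[sec]] <- entries
  }
  out$age_schedules <- lapply(seq_len(nrow(ps$schedules)), function(i)
    as.list(ps$schedules[i, ]))
  yaml::write_yaml(out, path)
  invisible(path)
}
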