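#' Fit a beta distribution to a mean and 95\% interval
#'
#' Fits a beta distribution whose analytic mean equals `mean` exactly and whose
#' 2.5\%/97.5\% quantiles reproduce the reported interval as closely as the
#' beta family allows. The fit starts from the method-of-moments solution with
#' SD = (high - low) / (2 * 1.959964) (normal approximation to the interval)
#' and then refines the concentration a + b by one-dimensional optimisation of
#' the worst quantile-endpoint error, holding the mean fixed. Matching reported
#' interval endpoints rather than a normal-approximated SD is the usual way
#' betas are elicited from published 95\% CIs.
#'
#' @param mean point estimate, strictly inside (0, 1)
#' @param low,high reported 95\% interval, 0 <= low < high <= 1
#' @param name parameter name used in error messages
#' @return a list with elements `family = "beta"`, `shape1`, `shape2`
#' @export
beta_from_mean_ci <- function(mean, low, high, name = "parameter") {
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop(sprintf("beta fit for '%s': mean must be in (0,1), got %s", name, mean))
  if (!is.finite(low) || !is.finite(high) || high <= low)
    stop(sprintf("beta fit for '%s': degenerate interval [%s, %s]", name, low, high))
  if (low < 0 || high > 1)
    stop(sprintf("beta fit for '%s': interval must lie in [0,1]", name))
  sd0 <- (high - low) / (2 * 1.959964)
  if (sd0 * sd0 >= mean * (1 - mean))
    stop(sprintf("beta fit for '%s': implied SD %.4f too large for a beta with mean %.4f",
                 name, sd0, mean))
  nu0 <- mean * (1 - mean) / (sd0 * sd0) - 1  # concentration from moments
  # refine concentration: minimise the worse of the two quantile-endpoint errors
  obj <- function(log_nu) {
    nu <- exp(log_nu)
    q <- stats::qbeta(c(0.025, 0.975), mean * nu, (1 - mean) * nu)
    max(abs(q[1] - low), abs(q[2] - high))
  }
  opt <- stats::optimise(obj, interval = log(nu0) + c(-1.5, 1.5))
  nu <- exp(opt$minimum)
  if (obj(log(nu0)) < opt$objective) nu <- nu0  # never worse than the moment fit
  list(family = "beta", shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Fit a beta distribution to a mean and standard deviation
#'
#' Method-of-moments fit: the analytic mean and SD reproduce the inputs
#' exactly (to floating point).
#'
#' @inheritParams beta_from_mean_ci
#' @param sd standard deviation, with sd^2 < mean * (1 - mean)
#' @return a list with elements `family = "beta"`, `shape1`, `shape2`
#' @export
beta_from_mean_sd <- function(mean, sd, name = "parameter") {
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop(sprintf("beta fit for '%s': mean must be in (0,1)", name))
  if (!is.finite(sd) || sd <= 0 || sd * sd >= mean * (1 - mean))
    stop(sprintf("beta fit for '%s': SD %s invalid for mean %s", name, sd, mean))
  nu <- mean * (1 - mean) / (sd * sd) - 1
  list(family = "beta", shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Fit a gamma distribution to a mean and standard deviation
#'
#' shape = (mean/sd)^2, scale = sd^2/mean, so the analytic mean and SD
#' reproduce the inputs exactly.
#'
#' @param mean positive mean
#' @param sd positive standard deviation
#' @param name parameter name used in error messages
#' @return a list with elements `family = "gamma"`, `shape`, `scale`
#' @export
gamma_from_mean_sd <- function(mean, sd, name = "parameter") {
  if (!is.finite(mean) || mean <= 0 || !is.finite(sd) || sd <= 0)
    stop(sprintf("gamma fit for '%s': mean and SD must be positive", name))
  list(family = "gamma", shape = (mean / sd)^2, scale = sd * sd / mean)
}

#' Fit a lognormal distribution to a median and 95\% interval
#'
#' Used for relative-risk parameters: the median equals the point estimate and
#' sigma is taken from the log-scale interval width (normal approximation on
#' the log scale), the standard treatment of ratio parameters in probabilistic
#' sensitivity analysis.
#'
#' @param median positive point estimate (ratio scale)
#' @param low,high positive reported 95\% interval
#' @param name parameter name used in error messages
#' @return a list with elements `family = "lognormal"`, `meanlog`, `sdlog`
#' @export
lognormal_from_median_ci <- function(median, low, high, name = "parameter") {
  if (!is.finite(median) || median <= 0)
    stop(sprintf("lognormal fit for '%s': median must be positive", name))
  if (!is.finite(low) || !is.finite(high) || low <= 0 || high <= low)
    stop(sprintf("lognormal fit for '%s': degenerate interval [%s, %s]", name, low, high))
  list(family = "lognormal",
       meanlog = log(median),
       sdlog = (log(high) - log(low)) / (2 * 1.959964))
}

#' Analytic mean of a fitted distribution spec
#'
#' @param spec a distribution spec from one of the fitting functions
#' @return the distribution's analytic mean
#' @export
dist_mean <- function(spec) {
  switch(spec$family,
         beta = spec$shape1 / (spec$shape1 + spec$shape2),
         gamma = spec$shape * spec$scale,
         lognormal = exp(spec$meanlog + spec$sdlog^2 / 2),
         stop("unknown distribution family"))
}

#' Analytic standard deviation of a fitted distribution spec
#'
#' @param spec a distribution spec from one of the fitting functions
#' @return the distribution's analytic SD
#' @export
dist_sd <- function(spec) {
  switch(spec$family,
         beta = {
           a <- spec$shape1; b <- spec$shape2
           sqrt(a * b / ((a + b)^2 * (a + b + 1)))
         },
         gamma = sqrt(spec$shape) * spec$scale,
         lognormal = sqrt((exp(spec$sdlog^2) - 1)) * exp(spec$meanlog + spec$sdlog^2 / 2),
         stop("unknown distribution family"))
}

# one random draw from a fitted distribution spec
dist_draw <- function(spec) {
  switch(spec$family,
         beta = stats::rbeta(1, spec$shape1, spec$shape2),
         gamma = stats::rgamma(1, shape = spec$shape, scale = spec$scale),
         lognormal = stats::rlnorm(1, spec$meanlog, spec$sdlog),
         stop("unknown distribution family"))
}
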