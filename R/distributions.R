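# Method-of-moments distribution fitting and sampling for every stochastic
# quantity in the model: negative binomial daily arrivals, truncated
# lognormal durations, categorical procedure mix and physician assignment.

#' Fit a negative binomial to a daily-arrival mean and SD
#'
#' Method of moments: with `v = sd^2`, the size (dispersion) parameter is
#' `r = mean^2 / (v - mean)` and the success probability `p = r / (r + mean)`
#' (equivalently `mean / v`), so that the fitted distribution reproduces the
#' given mean and variance exactly. Overdispersion is required for a proper
#' negative binomial; when `v <= mean` the fit degenerates and a Poisson with
#' the same mean is used instead (`fallback_poisson = TRUE`).
#'
#' @param mean Mean daily count, `> 0`.
#' @param sd Standard deviation of the daily count, `>= 0`.
#' @return An object of class `negbin_params` with fields `r`, `p`,
#'   `fallback_poisson` and `mean`.
#' @examples
#' fit_negative_binomial(2.446, 2.358)  # r ~ 1.921, p ~ 0.440
#' @export
fit_negative_binomial <- function(mean, sd) {
  if (!is.numeric(mean) || length(mean) != 1L || is.na(mean) || mean <= 0) {
    stop("fit_negative_binomial: mean must be a positive number", call. = FALSE)
  }
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0) {
    stop("fit_negative_binomial: sd must be >= 0", call. = FALSE)
  }
  v <- sd^2
  if (v <= mean) {
    return(structure(list(r = NA_real_, p = NA_real_, fallback_poisson = TRUE,
                          mean = mean), class = "negbin_params"))
  }
  r <- mean^2 / (v - mean)
  p <- r / (r + mean)
  structure(list(r = r, p = p, fallback_poisson = FALSE, mean = mean),
            class = "negbin_params")
}

#' Sample one day's arrival count
#'
#' @param params A `negbin_params` from [fit_negative_binomial()].
#' @param n Number of draws (days).
#' @return Integer vector of non-negative counts; Poisson draws when the
#'   fallback flag is set.
#' @export
sample_daily_arrivals <- function(params, n = 1L) {
  stopifnot(inherits(params, "negbin_params"))
  if (params$fallback_poisson) {
    stats::rpois(n, lambda = params$mean)
  } else {
    stats::rnbinom(n, size = params$r, prob = params$p)
  }
}

#' Fit a truncated lognormal to a duration summary
#'
#' Moment match on the natural scale against the *untruncated* lognormal:
#' `sigma_log^2 = log(1 + sd^2/mean^2)` and
#' `mu_log = log(mean) - sigma_log^2 / 2`, after which the distribution is
#' truncated to `[spec$min, spec$max]`. A zero-SD spec denotes a constant
#' duration (`sigma_log = 0`, value `exp(mu_log) = mean`). The summary
#' moments reported for real data are those of already-bounded observations,
#' so the realized (truncated) moments differ slightly from the spec moments;
#' see the methods vignette for the size of this effect.
#'
#' @param spec A [duration_spec()].
#' @return An object of class `lognormal_params` with fields `mu_log`,
#'   `sigma_log`, `lower`, `upper`, `units`.
#' @examples
#' fit_truncated_lognormal(duration_spec(5.050, 2.350, 3, 11, "days"))
#' @export
fit_truncated_lognormal <- function(spec) {
  stopifnot(inherits(spec, "duration_spec"))
  if (spec$mean <= 0) {
    stop("fit_truncated_lognormal: mean must be positive, got ", spec$mean,
         call. = FALSE)
  }
  if (spec$sd == 0) {
    params <- list(mu_log = log(spec$mean), sigma_log = 0,
                   lower = spec$min, upper = spec$max, units = spec$units)
    return(structure(params, class = "lognormal_params"))
  }
  s2 <- log(1 + (spec$sd / spec$mean)^2)
  params <- list(mu_log = log(spec$mean) - s2 / 2, sigma_log = sqrt(s2),
                 lower = spec$min, upper = spec$max, units = spec$units)
  structure(params, class = "lognormal_params")
}

#' Sample from a truncated lognormal
#'
#' Draws by inversion of the truncated CDF: `u ~ U(F(lower), F(upper))`
#' mapped through the lognormal quantile function (distributionally identical
#' to rejection sampling from the untruncated lognormal, but with fixed cost
#' per draw). Constant specs (`sigma_log = 0`) return `exp(mu_log)` exactly.
#'
#' @param params A `lognormal_params` from [fit_truncated_lognormal()].
#' @param n Number of draws.
#' @return Numeric vector in `[params$lower, params$upper]`.
#' @export
sample_truncated <- function(params, n = 1L) {
  stopifnot(inherits(params, "lognormal_params"))
  if (params$sigma_log == 0) {
    # exp(log(m)) can land one ulp outside [lower, upper]; clamp
    v <- min(max(exp(params$mu_log), params$lower), params$upper)
    return(rep(v, n))
  }
  plo <- stats::plnorm(params$lower, params$mu_log, params$sigma_log)
  phi <- stats::plnorm(params$upper, params$mu_log, params$sigma_log)
  if (phi - plo < 1e-12) {
    stop("sample_truncated: truncation interval [", params$lower, ", ",
         params$upper, "] has negligible probability under the fitted ",
         "lognormal; check the duration spec", call. = FALSE)
  }
  u <- stats::runif(n, plo, phi)
  stats::qlnorm(u, params$mu_log, params$sigma_log)
}

# Round half up: 5.5 -> 6, consistent across platforms (base round() halves
# to even).
round_half_up <- function(x) floor(x + 0.5)

#' Sample an integer number of days
#'
#' A truncated-lognormal draw rounded half up to a whole number of days, then
#' clamped to the integer range the bounds allow,
#' `[ceiling(lower), floor(upper)]`.
#'
#' @param params A `lognormal_params` in day units.
#' @param n Number of draws.
#' @return Integer vector of day counts.
#' @export
sample_integer_days <- function(params, n = 1L) {
  x <- round_half_up(sample_truncated(params, n))
  as.integer(pmin(pmax(x, ceiling(params$lower)), floor(params$upper)))
}

#' Sample a pre-operative stay compatible with a realized length of stay
#'
#' The post-operative stay is defined as the difference between the length of
#' stay and the pre-operative stay, so the pre-operative draw must not exceed
#' the realized `los_days`. The pre-op distribution is conditioned on this
#' cap by shrinking its upper truncation bound to
#' `min(upper, los_days + 0.5)` before rounding — distributionally identical
#' to redrawing until the rounded value is `<= los_days`, at fixed cost.
#'
#' @param preop A `lognormal_params` for the pre-operative stay (days).
#' @param los_days Realized integer length of stay, `>= 1`.
#' @return Integer pre-operative days in
#'   `[ceiling(preop$lower), min(floor(preop$upper), los_days)]`; the implied
#'   post-operative stay `los_days - preop` is always `>= 0`.
#' @export
sample_preop_given_los <- function(preop, los_days) {
  stopifnot(inherits(preop, "lognormal_params"))
  if (los_days < 1L) stop("sample_preop_given_los: los_days must be >= 1", call. = FALSE)
  hi <- min(floor(preop$upper), los_days)
  lo <- ceiling(preop$lower)
  if (hi < lo) {
    stop("sample_preop_given_los: no feasible pre-operative stay in [", lo, ", ",
         hi, "] — the pre-op minimum exceeds the realized length of stay; ",
         "check the configuration", call. = FALSE)
  }
  if (preop$sigma_log == 0) {
    v <- round_half_up(exp(preop$mu_log))
    return(as.integer(min(max(v, lo), hi)))
  }
  # Any continuous draw below hi + 0.5 rounds (half-up) to an integer <= hi.
  capped <- preop
  capped$upper <- min(preop$upper, hi + 0.5 - 1e-9)
  x <- round_half_up(sample_truncated(capped, 1L))
  as.integer(min(max(x, lo), hi))
}

#' Draw a procedure class according to the admission mix
#'
#' @param classes List of [procedure_class()] objects with normalized
#'   proportions.
#' @param n Number of draws.
#' @return Integer index/indices into `classes`.
#' @export
draw_procedure_class <- function(classes, n = 1L) {
  if (length(classes) == 0L) stop("draw_procedure_class: empty class list", call. = FALSE)
  probs <- vapply(classes, `[[`, 0, "proportion")
  sample.int(length(classes), size = n, replace = TRUE, prob = probs)
}

#' Assign a procedure to one of the two on-duty physician slots
#'
#' @param weekday Weekday of the procedure.
#' @param alloc The [weekday_allocation()] for that weekday.
#' @param n Number of draws.
#' @return Integer vector of slots (1 or 2); slot 1 with probability
#'   `alloc$p_first`.
#' @export
assign_physician <- function(weekday, alloc, n = 1L) {
  stopifnot(inherits(alloc, "weekday_allocation"))
  if (alloc$weekday != weekday) {
    stop("assign_physician: allocation is for ", alloc$weekday, ", not ", weekday,
         call. = FALSE)
  }
  ifelse(stats::runif(n) < alloc$p_first, 1L, 2L)
}

#' Analytic untruncated moments of a fitted lognormal
#'
#' Diagnostic companion to [fit_truncated_lognormal()]: the mean and SD of
#' the *untruncated* fitted lognormal, which equal the source spec's moments
#' exactly. Comparing them against empirical moments of [sample_truncated()]
#' draws quantifies how much the truncation (and, for stays, integer
#' rounding) shifts the realized distribution away from the reported
#' summary.
#'
#' @param params A `lognormal_params`.
#' @return Named numeric vector with elements `mean` and `sd`.
#' @export
lognormal_moments <- function(params) {
  stopifnot(inherits(params, "lognormal_params"))
  m <- exp(params$mu_log + params$sigma_log^2 / 2)
  s <- m * sqrt(exp(params$sigma_log^2) - 1)
  c(mean = m, sd = s)
}
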