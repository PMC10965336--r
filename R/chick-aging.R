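# Chick aging from body mass via a fitted logistic growth curve.
#
# Chick mass follows a three-parameter logistic in age,
#   mass(age) = A / (1 + exp(-K (age - I))),
# with asymptotic mass A (g), growth rate K (1/day) and inflection age I
# (days), and additive Gaussian measurement error. Inverting the fitted
# curve gives each chick's age from a single mass measurement, and the
# family's hatch day is the observation day minus the mean chick age.

#' Logistic growth parameters
#'
#' @param asymptote_g Asymptotic mass A in grams (> 0).
#' @param growth_rate_per_day Growth rate K per day (> 0).
#' @param inflection_age_days Age I (days) at the inflection, where
#'   mass = A/2.
#' @return Object of class `logistic_params`.
#' @export
logistic_params <- function(asymptote_g, growth_rate_per_day,
                            inflection_age_days) {
  if (!is.numeric(asymptote_g) || asymptote_g <= 0) {
    stop("asymptote_g must be > 0")
  }
  if (!is.numeric(growth_rate_per_day) || growth_rate_per_day <= 0) {
    stop("growth_rate_per_day must be > 0")
  }
  structure(list(asymptote_g = as.numeric(asymptote_g),
                 growth_rate_per_day = as.numeric(growth_rate_per_day),
                 inflection_age_days = as.numeric(inflection_age_days)),
            class = "logistic_params")
}

#' Logistic growth curve
#'
#' @param age_days Age(s) in days.
#' @param params A [logistic_params()].
#' @return Expected mass in grams.
#' @export
logistic_mass <- function(age_days, params) {
  stopifnot(inherits(params, "logistic_params"))
  params$asymptote_g /
    (1 + exp(-params$growth_rate_per_day *
               (age_days - params$inflection_age_days)))
}

#' Fit the logistic growth curve to mass-age measurements
#'
#' Nonlinear least squares (Levenberg-Marquardt) with data-driven starting
#' values: A0 = 1.05 x max mass, I0 = the age whose mass is closest to A0/2,
#' and K0 from the logit slope between the two central age-quantile points.
#' Up to five deterministically jittered restarts are attempted on failure.
#'
#' @param age_days Ages in days (>= 4 points spanning >= 3 distinct ages).
#' @param mass_g Measured masses in grams.
#' @return List with `params` ([logistic_params()]), `residual_sd` (g),
#'   `n`, and the `fit` object.
#' @export
fit_logistic_growth <- function(age_days, mass_g) {
  stopifnot(length(age_days) == length(mass_g))
  ok <- is.finite(age_days) & is.finite(mass_g)
  age_days <- age_days[ok]; mass_g <- mass_g[ok]
  if (length(age_days) < 4L) stop("need at least 4 measurements")
  if (length(unique(age_days)) < 3L) stop("need at least 3 distinct ages")
  if (stats::sd(mass_g) == 0) stop("degenerate data: mass is constant")

  A0 <- 1.05 * max(mass_g)
  I0 <- age_days[which.min(abs(mass_g - A0 / 2))]
  qa <- stats::quantile(age_days, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  m1 <- mass_g[which.min(abs(age_days - qa[1L]))]
  m2 <- mass_g[which.min(abs(age_days - qa[2L]))]
  logit <- function(p) log(p / (1 - p))
  p1 <- min(max(m1 / A0, 1e-3), 1 - 1e-3)
  p2 <- min(max(m2 / A0, 1e-3), 1 - 1e-3)
  K0 <- if (qa[2L] > qa[1L]) (logit(p2) - logit(p1)) / (qa[2L] - qa[1L]) else 0.2
  K0 <- min(max(abs(K0), 0.01), 2)

  dat <- data.frame(age = age_days, mass = mass_g)
  jitters <- rbind(c(1, 1, 0), c(1.2, 0.5, -2), c(0.95, 2, 2),
                   c(1.5, 0.25, 5), c(1.02, 1.5, -5), c(1.1, 0.75, 3))
  fit <- NULL
  for (j in seq_len(nrow(jitters))) {
    start <- list(A = A0 * jitters[j, 1L], K = K0 * jitters[j, 2L],
                  I = I0 + jitters[j, 3L])
    res <- try(minpack.lm::nlsLM(mass ~ A / (1 + exp(-K * (age - I))),
                                 data = dat, start = start,
                                 lower = c(A = 1e-8, K = 1e-8, I = -Inf),
                                 control = minpack.lm::nls.lm.control(maxiter = 200)),
               silent = TRUE)
    if (!inherits(res, "try-error")) {
      fit <- res
      break
    }
  }
  if (is.null(fit)) {
    stop("logistic growth fit did not converge after ", nrow(jitters),
         " starts")
  }
  cf <- stats::coef(fit)
  if (any(!is.finite(cf))) stop("logistic growth fit returned non-finite parameters")
  n <- length(age_days)
  rss <- sum(stats::residuals(fit)^2)
  list(params = logistic_params(cf[["A"]], cf[["K"]], cf[["I"]]),
       residual_sd = sqrt(rss / max(1L, n - 3L)),
       n = n, fit = fit)
}

#' Age of a chick from its mass
#'
#' Exact inverse of the logistic growth curve on its open domain
#' (0, asymptote): age = I - (1/K) log(A/mass - 1).
#'
#' @param mass_g Mass(es) in grams; must satisfy 0 < mass < asymptote.
#' @param params A [logistic_params()].
#' @return Age(s) in days.
#' @export
age_from_mass <- function(mass_g, params) {
  stopifnot(inherits(params, "logistic_params"))
  if (any(mass_g <= 0) || any(mass_g >= params$asymptote_g)) {
    stop("mass must lie strictly between 0 and the asymptote (",
         format(params$asymptote_g), " g) to be invertible")
  }
  params$inflection_age_days -
    log(params$asymptote_g / mass_g - 1) / params$growth_rate_per_day
}

#' Hatch day of an encountered family
#'
#' hatch_doy = observation_doy - mean(age of each invertible chick).
#' Chicks whose mass falls outside the invertible domain (0, asymptote) are
#' skipped with a message; if no chick is invertible, `NA` is returned.
#'
#' @param observation_doy Day-of-year the family was observed.
#' @param chick_masses Masses (g) of the chicks in the brood.
#' @param params A [logistic_params()].
#' @return Estimated hatch day-of-year (numeric, possibly `NA`), with
#'   attributes `n_used` and `n_skipped`.
#' @export
family_hatch_date <- function(observation_doy, chick_masses, params) {
  stopifnot(inherits(params, "logistic_params"), length(observation_doy) == 1L)
  invertible <- chick_masses > 0 & chick_masses < params$asymptote_g
  n_skipped <- sum(!invertible)
  if (n_skipped > 0L) {
    message(n_skipped, " chick(s) with uninvertible mass skipped")
  }
  if (!any(invertible)) {
    out <- NA_real_
  } else {
    ages <- age_from_mass(chick_masses[invertible], params)
    out <- observation_doy - mean(ages)
  }
  attr(out, "n_used") <- sum(invertible)
  attr(out, "n_skipped") <- n_skipped
  out
}
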