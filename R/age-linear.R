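# Medium-term rate projection: per age band, the rate per 100,000 is
# modelled as a straight line in calendar year, fitted by Poisson count
# likelihood with the year centred at the window midpoint. Predicted rates
# are floored at zero, so a steep decline extrapolates to zero and never to
# a negative rate.

#' Fit age-specific linear rate trends
#'
#' For each age band the expected count is
#' `person_years * max(a + b * t, 0) / 100000` with `t` the calendar year
#' centred at the window midpoint, maximised by Fisher scoring from the
#' constant-rate start. Age bands with no events get a zero fit.
#'
#' @param events An [event_table()].
#' @param population A [population_table()].
#' @param window Year range (>= 5 years, default 1998:2007).
#' @param dataset,sex,site Stratum selectors.
#' @param tol,maxit Convergence control.
#' @return An object of class `age_linear` with `intercepts` and `slopes`
#'   per age band (rate per 100,000; slope per year).
#' @export
fit_age_linear <- function(events, population, window = 1998:2007,
                           dataset, sex, site, tol = 1e-10, maxit = 100L) {
  window <- sort(window)
  if (length(window) < 5) {
    stop_canestim("fit_age_linear: at least 5 years of data required")
  }
  ev <- as.data.frame(events)
  ev <- ev[ev$dataset == dataset & ev$sex == sex & ev$site == site &
             ev$year %in% window, , drop = FALSE]
  pop <- as.data.frame(population)
  pop <- pop[pop$dataset == dataset & pop$sex == sex & pop$year %in% window, ,
             drop = FALSE]
  if (!all(window %in% unique(pop$year))) {
    stop_canestim("fit_age_linear: person-years missing for part of the window")
  }
  midpoint <- mean(window)
  intercepts <- numeric(18)
  slopes <- numeric(18)
  converged <- rep(TRUE, 18)
  for (a in 0:17) {
    popa <- pop[pop$age_group == a, , drop = FALSE]
    eva <- ev[ev$age_group == a, , drop = FALSE]
    y <- numeric(length(window))
    if (nrow(eva)) {
      s <- tapply(eva$count, factor(eva$year, levels = window), sum)
      y <- ifelse(is.na(s), 0, as.numeric(s))
    }
    if (all(y == 0)) next                 # degenerate row: zero fit
    pys <- tapply(popa$person_years, factor(popa$year, levels = window), sum)
    if (any(is.na(pys) | pys <= 0)) {
      stop_canestim("fit_age_linear: zero person-years for age band %s",
                    age_band_label(a))
    }
    E <- as.numeric(pys) / 1e5
    t <- window - midpoint
    X <- cbind(1, t)
    start <- c(sum(y) / sum(E), 0)
    fit <- poisson_power_fit(X, y, E, power = 1, start = start,
                             tol = tol, maxit = maxit)
    intercepts[a + 1] <- fit$coefficients[1]
    slopes[a + 1] <- fit$coefficients[2]
    converged[a + 1] <- fit$converged
  }
  if (!all(converged)) {
    stop_canestim("fit_age_linear: no convergence for age band(s) %s (%s, %s)",
                  paste(age_band_label(which(!converged) - 1), collapse = ", "),
                  sex, site)
  }
  structure(list(
    intercepts = stats::setNames(intercepts, age_band_label(0:17)),
    slopes = stats::setNames(slopes, age_band_label(0:17)),
    midpoint = midpoint, window = window,
    dataset = dataset, sex = sex, site = site
  ), class = "age_linear")
}

#' @export
print.age_linear <- function(x, ...) {
  cat(sprintf("Age-specific linear rate trends: %s, %s, %s (%d-%d, midpoint %.1f)\n",
              x$dataset, x$sex, x$site, min(x$window), max(x$window), x$midpoint))
  print(data.frame(age = names(x$intercepts),
                   rate_at_midpoint = round(x$intercepts, 3),
                   slope_per_year = round(x$slopes, 4)),
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.age_linear <- function(object, ...) {
  cbind(intercept = object$intercepts, slope = object$slopes)
}

#' Predict rates from an age-linear fit
#'
#' @param object An `age_linear` fit.
#' @param year Calendar year to predict (the trend is extrapolated linearly
#'   and floored at zero).
#' @param ... Unused.
#' @return A [rate_table()].
#' @export
predict.age_linear <- function(object, year, ...) {
  t <- year - object$midpoint
  rate <- pmax(object$intercepts + object$slopes * t, 0)
  rate_table(data.frame(
    dataset = object$dataset, year = as.integer(year),
    sex = object$sex, site = object$site, age_group = 0:17,
    rate = as.numeric(rate), stringsAsFactors = FALSE))
}
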