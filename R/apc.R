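# Long-term rate projection: an age-period-cohort model on 5-year age by
# 5-year period grids with a power-5 link, in the tradition of Nordic
# incidence-projection software. The linear predictor is
#   eta[a, p] = alpha_a + delta * p + pi_p + gamma_c,   rate = max(eta, 0)^5
# with period index p centred, period effects pi constrained to sum to zero
# with zero slope, and synthetic-cohort effects gamma (c = p - a) under the
# same constraints, so the shared linear trend ("drift") delta is
# identified. Projection continues age effects and drift, attenuating the
# drift over successive future periods ("cut trend"), carries the most
# recent period effect forward and extrapolates unseen cohorts at the last
# estimated cohort's value.

#' Build a 5-year period grid
#'
#' @param counts Age-by-period matrix of event counts (18 rows).
#' @param person_years Matching matrix of person-years (positive).
#' @param periods Character labels of the consecutive 5-year periods.
#' @param end_years Integer vector: the last calendar year of each period.
#' @param dataset,sex,site Metadata carried through to projected rates.
#' @return A `period_grid`.
#' @export
period_grid <- function(counts, person_years, periods, end_years,
                        dataset = "national", sex = "male", site = "all") {
  counts <- as.matrix(counts)
  person_years <- as.matrix(person_years)
  if (!all(dim(counts) == dim(person_years))) {
    stop_canestim("period_grid: counts and person-years matrices must be congruent")
  }
  if (ncol(counts) != length(periods)) {
    stop_canestim("period_grid: one label per period column required")
  }
  if (any(counts < 0) || any(person_years <= 0)) {
    stop_canestim("period_grid: counts must be >= 0 and person-years > 0")
  }
  structure(list(counts = counts, person_years = person_years,
                 periods = periods, end_years = as.integer(end_years),
                 dataset = dataset, sex = sex, site = site),
            class = "period_grid")
}

#' Aggregate annual registry data into 5-year periods
#'
#' Sums counts and person-years within consecutive 5-year bins per age band
#' for one (dataset, sex, site); e.g. 1983-2007 gives five periods and
#' 1998-2007 gives two.
#'
#' @param events An [event_table()].
#' @param population A [population_table()].
#' @param window Integer year range whose length must be divisible by 5.
#' @param dataset,sex,site Stratum selectors.
#' @return A [period_grid()].
#' @export
aggregate_to_periods <- function(events, population, window, dataset, sex, site) {
  window <- sort(window)
  if (length(window) %% 5 != 0) {
    stop_canestim("aggregate_to_periods: window of %d year(s) leaves a partial final 5-year bin",
                  length(window))
  }
  n_per <- length(window) / 5
  bins <- split(window, rep(seq_len(n_per), each = 5))
  ev <- as.data.frame(events)
  ev <- ev[ev$dataset == dataset & ev$sex == sex & ev$site == site &
             ev$year %in% window, , drop = FALSE]
  pop <- as.data.frame(population)
  pop <- pop[pop$dataset == dataset & pop$sex == sex & pop$year %in% window, ,
             drop = FALSE]
  if (!all(window %in% unique(pop$year))) {
    stop_canestim("aggregate_to_periods: person-years missing for part of the window")
  }
  counts <- matrix(0, nrow = 18, ncol = n_per)
  py <- matrix(0, nrow = 18, ncol = n_per)
  for (j in seq_len(n_per)) {
    yrs <- bins[[j]]
    evj <- ev[ev$year %in% yrs, , drop = FALSE]
    if (nrow(evj)) {
      s <- tapply(evj$count, factor(evj$age_group, levels = 0:17), sum)
      counts[, j] <- ifelse(is.na(s), 0, s)
    }
    popj <- pop[pop$year %in% yrs, , drop = FALSE]
    s <- tapply(popj$person_years, factor(popj$age_group, levels = 0:17), sum)
    py[, j] <- ifelse(is.na(s), 0, s)
  }
  if (any(py <= 0)) {
    stop_canestim("aggregate_to_periods: zero person-years in the grid (dataset %s, sex %s)",
                  dataset, sex)
  }
  labels <- vapply(bins, function(y) sprintf("%d-%d", min(y), max(y)), "")
  period_grid(counts, py, labels, vapply(bins, max, 0L),
              dataset = dataset, sex = sex, site = site)
}

# Constraint bases: orthogonal polynomials of degree >= 2 are orthogonal to
# the constant and linear terms on an equally spaced index, which enforces
# sum-to-zero and zero-slope.
detrended_basis <- function(n) {
  if (n < 3) return(matrix(0, n, 0))
  stats::poly(seq_len(n), degree = n - 1)[, -1, drop = FALSE]
}

#' Fit the age-period-cohort power-5 projection model
#'
#' Maximises the Poisson likelihood of expected count
#' `person_years * max(eta, 0)^5 / 100000` by Fisher scoring, starting from
#' the null (age-rates-only) model; the fit is fully deterministic. Age
#' bands with no events anywhere receive a zero rate and are excluded from
#' the optimisation.
#'
#' @param grid A [period_grid()] with at least 3 periods.
#' @param tol Convergence tolerance on the relative deviance change
#'   (default 1e-8).
#' @param maxit Maximum Fisher-scoring iterations (default 100).
#' @return An object of class `apc_power5` with components `age_effects`
#'   (fifth root of rate scale), `drift` (per 5-year period), `drift_se`,
#'   `period_effects`, `cohort_effects`, `deviance`, `converged`, `grid`.
#' @export
fit_apc_power5 <- function(grid, tol = 1e-8, maxit = 100L) {
  stopifnot(inherits(grid, "period_grid"))
  A <- nrow(grid$counts)
  P <- ncol(grid$counts)
  if (P < 3) {
    stop_canestim("fit_apc_power5: at least 3 periods required (%d supplied)", P)
  }
  active <- which(rowSums(grid$counts) > 0)
  if (!length(active)) {
    stop_canestim("fit_apc_power5: no events anywhere in the grid")
  }

  a_idx <- rep(seq_len(A), times = P)
  p_idx <- rep(seq_len(P), each = A)
  keep <- a_idx %in% active
  y <- as.vector(grid$counts)[keep]
  E <- as.vector(grid$person_years)[keep] / 1e5
  a_k <- a_idx[keep]
  p_k <- p_idx[keep]
  coh <- p_k - a_k + A                      # synthetic cohort index
  coh_levels <- sort(unique(coh))
  C <- length(coh_levels)

  X_age <- stats::model.matrix(~ 0 + factor(a_k, levels = active))
  pc <- p_k - (P + 1) / 2
  Qp <- detrended_basis(P)
  X_per <- Qp[p_k, , drop = FALSE]
  Qc <- detrended_basis(C)
  X_coh <- Qc[match(coh, coh_levels), , drop = FALSE]
  X <- cbind(X_age, drift = pc, X_per, X_coh)

  # null-model start: fifth root of the pooled age-specific rate
  rate_a <- vapply(active, function(a) {
    sum(grid$counts[a, ]) / (sum(grid$person_years[a, ]) / 1e5)
  }, 0)
  start <- c(rate_a^(1 / 5), rep(0, 1 + ncol(X_per) + ncol(X_coh)))

  fit <- poisson_power_fit(X, y, E, power = 5, start = start,
                           tol = tol, maxit = maxit)
  if (!fit$converged) {
    stop_canestim("fit_apc_power5: no convergence after %d iterations (deviance %.6g, dataset %s, sex %s, site %s)",
                  fit$iterations, fit$deviance, grid$dataset, grid$sex, grid$site)
  }
  if (fit$floored) {
    warn_canestim("fit_apc_power5: negative linear predictor floored at 0 during fitting (%s, %s)",
                  grid$sex, grid$site)
  }

  beta <- fit$coefficients
  n_age <- length(active)
  age_eff <- numeric(A)
  age_eff[active] <- beta[seq_len(n_age)]
  drift <- unname(beta[n_age + 1])
  u <- beta[n_age + 1 + seq_len(ncol(X_per))]
  v <- beta[n_age + 1 + ncol(X_per) + seq_len(ncol(X_coh))]
  per_eff <- if (ncol(Qp)) as.vector(Qp %*% u) else rep(0, P)
  coh_eff <- if (ncol(Qc)) as.vector(Qc %*% v) else rep(0, C)
  drift_var <- unname(fit$cov[n_age + 1, n_age + 1])

  structure(list(
    age_effects = stats::setNames(age_eff, age_band_label(0:17)),
    drift = drift,
    drift_se = if (is.na(drift_var) || drift_var < 0) NA_real_ else sqrt(drift_var),
    period_effects = stats::setNames(per_eff, grid$periods),
    cohort_effects = stats::setNames(coh_eff, coh_levels),
    active_ages = active,
    deviance = fit$deviance,
    converged = fit$converged,
    iterations = fit$iterations,
    floored = fit$floored,
    grid = grid
  ), class = "apc_power5")
}

#' @export
print.apc_power5 <- function(x, ...) {
  g <- x$grid
  cat(sprintf("Age-period-cohort power-5 fit: %s, %s, %s (%s)\n",
              g$dataset, g$sex, g$site,
              paste(range(g$periods), collapse = " to ")))
  cat(sprintf("  drift: %.5f per 5-year period (se %.5f) on the rate^(1/5) scale\n",
              x$drift, x$drift_se))
  cat(sprintf("  deviance %.4g after %d iterations\n", x$deviance, x$iterations))
  invisible(x)
}

#' @export
coef.apc_power5 <- function(object, ...) {
  c(object$age_effects,
    drift = object$drift,
    stats::setNames(object$period_effects,
                    paste0("period:", names(object$period_effects))),
    stats::setNames(object$cohort_effects,
                    paste0("cohort:", names(object$cohort_effects))))
}

# Linear predictor for observed cells; used by fitted/residuals.
apc_eta <- function(object) {
  g <- object$grid
  A <- nrow(g$counts)
  P <- ncol(g$counts)
  outer(seq_len(A), seq_len(P), function(a, p) {
    coh <- p - a + A
    object$age_effects[a] + object$drift * (p - (P + 1) / 2) +
      object$period_effects[p] +
      object$cohort_effects[match(coh, as.integer(names(object$cohort_effects)))]
  })
}

#' @export
fitted.apc_power5 <- function(object, ...) {
  g <- object$grid
  eta <- apc_eta(object)
  eta[-object$active_ages, ] <- 0
  mu <- g$person_years / 1e5 * pmax(eta, 0)^5
  dimnames(mu) <- list(age_band_label(0:17), g$periods)
  mu
}

#' @export
residuals.apc_power5 <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  r <- object$grid$counts - mu
  if (type == "pearson") r <- r / sqrt(pmax(mu, 1e-300))
  r
}

#' Project fitted rates into future 5-year periods
#'
#' Future rates continue the age effects and the drift, with each successive
#' period's drift increment scaled by the attenuation schedule (the last
#' schedule entry is recycled beyond its length). The most recent period
#' effect is carried forward; cohorts not seen in the data take the last
#' estimated cohort's effect. Rates are floored at zero.
#'
#' @param fit An [fit_apc_power5()] object.
#' @param n_ahead Number of 5-year periods to project (>= 1).
#' @param attenuation Per-period multipliers on the drift increment;
#'   default `c(1, 0.75, 0.5, 0.25)`. Use `rep(1, n)` to disable.
#' @return A [rate_table()] with a `year` column at each projected period's
#'   midpoint year.
#' @export
project_apc <- function(fit, n_ahead = 1L,
                        attenuation = c(1, 0.75, 0.5, 0.25)) {
  stopifnot(inherits(fit, "apc_power5"), n_ahead >= 1)
  g <- fit$grid
  A <- nrow(g$counts)
  P <- ncol(g$counts)
  coh_levels <- as.integer(names(fit$cohort_effects))
  pc_last <- P - (P + 1) / 2
  pi_last <- fit$period_effects[P]
  sched <- function(j) attenuation[min(j, length(attenuation))]
  out <- list()
  for (k in seq_len(n_ahead)) {
    cum_drift <- sum(vapply(seq_len(k), sched, 0))
    a <- seq_len(A)
    coh <- (P + k) - a + A
    gamma <- fit$cohort_effects[pmin(match(coh, coh_levels,
                                           nomatch = length(coh_levels)),
                                     length(coh_levels))]
    gamma[coh > max(coh_levels)] <- fit$cohort_effects[length(coh_levels)]
    gamma[is.na(gamma)] <- fit$cohort_effects[length(coh_levels)]
    eta <- fit$age_effects[a] + fit$drift * (pc_last + cum_drift) +
      pi_last + gamma
    rate <- pmax(eta, 0)^5
    rate[-fit$active_ages] <- 0
    out[[k]] <- data.frame(
      dataset = g$dataset,
      year = g$end_years[P] + 5L * (k - 1L) + 3L,  # period midpoint year
      sex = g$sex, site = g$site, age_group = a - 1L, rate = rate,
      stringsAsFactors = FALSE)
  }
  rate_table(do.call(rbind, out))
}

#' @export
predict.apc_power5 <- function(object, n_ahead = 1L,
                               attenuation = c(1, 0.75, 0.5, 0.25), ...) {
  project_apc(object, n_ahead = n_ahead, attenuation = attenuation)
}
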