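# Estimation methods backed by rate projection. National data are pooled
# from the supplied datasets; every (sex, site) with events in the fit
# window is projected separately. Site-sex combinations whose total count
# in the window falls below `sparse_threshold` are too thin to support a
# trend fit and fall back to recent average rates (method-2 behaviour),
# recorded in the `fallback_sites` attribute of the result.

projection_site_loop <- function(events, population, window, target_year,
                                 datasets, engine, fallback_years,
                                 sparse_threshold) {
  datasets <- datasets %||% unique(as.data.frame(events)$dataset)
  ev <- pool_datasets(events, datasets, "national")
  pop <- pool_population(population, datasets, "national")
  evw <- as.data.frame(ev)
  evw <- evw[evw$year %in% window, , drop = FALSE]
  combos <- unique(evw[c("sex", "site")])
  combos <- combos[order(combos$sex, combos$site), , drop = FALSE]
  rates <- list()
  fallback <- character(0)
  for (i in seq_len(nrow(combos))) {
    sex <- combos$sex[i]
    site <- combos$site[i]
    tot <- sum(evw$count[evw$sex == sex & evw$site == site])
    if (tot < sparse_threshold) {
      r <- pooled_rates(ev, pop, datasets = "national", years = fallback_years,
                        sites = site)
      r <- r[r$sex == sex, , drop = FALSE]
      fallback <- c(fallback, paste(sex, site, sep = ": "))
    } else {
      r <- engine(ev, pop, sex, site)
    }
    r <- as.data.frame(r)
    rates[[i]] <- r[c("sex", "site", "age_group", "rate")]
  }
  list(rates = rate_table(do.call(rbind, rates)), population = pop,
       fallback = fallback)
}

projection_estimate <- function(loop, target_year, method) {
  expected <- apply_rates(loop$rates, loop$population, "national", target_year)
  detail <- as.data.frame(expected)[c("sex", "site", "age_group", "count")]
  names(detail)[names(detail) == "count"] <- "cases"
  est <- estimate_table(method = method, target_year = target_year,
                        detail = detail)
  attr(est, "fallback_sites") <- loop$fallback
  est
}

#' Method 1A: long-term projection of national incidence rates
#'
#' Fits the age-period-cohort power-5 model per sex and site on 5-year
#' periods of the fit window (default 1983-2007), projects to the 5-year
#' period containing the target year with drift attenuation, and applies
#' the projected period rates, read as the annual rates at the period
#' midpoint, to the target-year national population.
#'
#' @param incidence An [event_table()] of recorded incidence.
#' @param population A [population_table()] covering the fit window and the
#'   target year.
#' @param target_year Estimation year (default 2010).
#' @param fit_window Years fitted (default 1983:2007).
#' @param datasets Dataset labels pooled into the nation (default: all).
#' @param attenuation Drift attenuation schedule (see [project_apc()]).
#' @param sparse_threshold Minimum window count below which a (sex, site)
#'   falls back to recent average rates (default 50).
#' @return An [estimate_table()] (method `"1A"`) with age-resolved detail
#'   and a `fallback_sites` attribute.
#' @export
method_1a <- function(incidence, population, target_year = 2010,
                      fit_window = 1983:2007, datasets = NULL,
                      attenuation = c(1, 0.75, 0.5, 0.25),
                      sparse_threshold = 50) {
  window_end <- max(fit_window)
  n_ahead <- ceiling((target_year - window_end) / 5)
  engine <- function(ev, pop, sex, site) {
    grid <- aggregate_to_periods(ev, pop, fit_window, "national", sex, site)
    fit <- fit_apc_power5(grid)
    proj <- project_apc(fit, n_ahead = n_ahead, attenuation = attenuation)
    proj[proj$year == window_end + 5 * (n_ahead - 1) + 3, , drop = FALSE]
  }
  loop <- projection_site_loop(
    incidence, population, fit_window, target_year, datasets, engine,
    fallback_years = (window_end - 4):window_end,
    sparse_threshold = sparse_threshold)
  projection_estimate(loop, target_year, "1A")
}

#' Method 1B: medium-term projection via age-specific linear trends
#'
#' Fits [fit_age_linear()] per sex and site on the window (default
#' 1998-2007), predicts the rate at the target year (floored at zero) and
#' applies it to the target-year national population.
#'
#' @inheritParams method_1a
#' @param fit_window Years fitted (default 1998:2007).
#' @return An [estimate_table()] (method `"1B"`).
#' @export
method_1b <- function(incidence, population, target_year = 2010,
                      fit_window = 1998:2007, datasets = NULL,
                      sparse_threshold = 50) {
  engine <- function(ev, pop, sex, site) {
    fit <- fit_age_linear(ev, pop, fit_window, "national", sex, site)
    predict(fit, year = target_year)
  }
  window_end <- max(fit_window)
  loop <- projection_site_loop(
    incidence, population, fit_window, target_year, datasets, engine,
    fallback_years = (window_end - 4):window_end,
    sparse_threshold = sparse_threshold)
  projection_estimate(loop, target_year, "1B")
}

#' Project national mortality rates to the target period
#'
#' Runs the age-period-cohort power-5 engine on national mortality (default
#' window 1988-2007, projected one 5-year period ahead to 2008-2012, read
#' as annual rates at the 2010 midpoint). This supplies the M input of the
#' mortality-based estimation methods. Sparse sites fall back to
#' window-average mortality rates.
#'
#' @param mortality An [event_table()] of recorded deaths.
#' @param population A [population_table()].
#' @param window Fit window (default 1988:2007).
#' @param target_year Year whose rates are returned (default 2010).
#' @param datasets Dataset labels pooled into the nation (default: all).
#' @param attenuation Drift attenuation schedule.
#' @param sparse_threshold Window count below which a site uses
#'   window-average rates (default 50).
#' @return A [rate_table()] of projected national mortality rates, with an
#'   `expected_deaths` attribute holding the implied target-year
#'   [event_table()] and a `fallback_sites` attribute.
#' @export
project_mortality <- function(mortality, population, window = 1988:2007,
                              target_year = 2010, datasets = NULL,
                              attenuation = c(1, 0.75, 0.5, 0.25),
                              sparse_threshold = 50) {
  window_end <- max(window)
  n_ahead <- ceiling((target_year - window_end) / 5)
  engine <- function(ev, pop, sex, site) {
    grid <- aggregate_to_periods(ev, pop, window, "national", sex, site)
    fit <- fit_apc_power5(grid)
    proj <- project_apc(fit, n_ahead = n_ahead, attenuation = attenuation)
    proj[proj$year == window_end + 5 * (n_ahead - 1) + 3, , drop = FALSE]
  }
  loop <- projection_site_loop(
    mortality, population, window, target_year, datasets, engine,
    fallback_years = window, sparse_threshold = sparse_threshold)
  rates <- loop$rates
  attr(rates, "expected_deaths") <-
    apply_rates(rates, loop$population, "national", target_year,
                kind = "mortality")
  attr(rates, "fallback_sites") <- loop$fallback
  rates
}
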