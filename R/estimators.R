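# Estimation methods 2-9: rate transport from recent national, regional or
# neighbouring-country data; inference from national mortality via
# mortality-to-incidence (M:I) ratios or 5-year relative survival; and
# partition of all-sites rates by site frequencies.

transport_estimate <- function(incidence, population, source_datasets,
                               reference_years, national_datasets,
                               target_year, method) {
  rates <- pooled_rates(incidence, population, datasets = source_datasets,
                        years = reference_years)
  natpop <- pool_population(population, national_datasets, "national")
  expected <- apply_rates(rates, natpop, "national", target_year)
  detail <- as.data.frame(expected)[c("sex", "site", "age_group", "count")]
  names(detail)[names(detail) == "count"] <- "cases"
  estimate_table(method = method, target_year = target_year, detail = detail)
}

#' Method 2: recent national rates applied to the target-year population
#'
#' Average annual age-sex-site rates over the reference period (default
#' 2003-2007) applied to the target-year national person-years.
#'
#' @param incidence An [event_table()].
#' @param population A [population_table()] covering the reference period
#'   and the target year.
#' @param target_year Estimation year (default 2010).
#' @param reference_years Years pooled into the rates (default 2003:2007).
#' @param datasets Dataset labels pooled into the nation (default: all).
#' @return An [estimate_table()] (method `"2"`).
#' @export
method_2 <- function(incidence, population, target_year = 2010,
                     reference_years = 2003:2007, datasets = NULL) {
  datasets <- datasets %||% unique(as.data.frame(incidence)$dataset)
  missing_years <- setdiff(reference_years,
                           unique(as.data.frame(incidence)$year))
  if (length(missing_years)) {
    stop_canestim("method_2: reference year(s) %s absent from incidence data",
                  paste(missing_years, collapse = ", "))
  }
  transport_estimate(incidence, population, datasets, reference_years,
                     datasets, target_year, "2")
}

#' Mortality-to-incidence ratios from proxy registries
#'
#' Per (sex, site, age band), the ratio of pooled deaths to pooled cases
#' over the proxy datasets and the reference period. Sites whose national
#' average annual deaths fall below `pooling_threshold` (default 100) also
#' pool the neighbour datasets before the ratio is taken. Age bands with
#' zero pooled cases -- or zero pooled deaths, for sites with deaths at
#' some age -- are merged with the adjacent younger band, repeatedly,
#' until every merged band has a positive denominator and an informative
#' numerator (a leading run of sparse bands merges upward instead).
#'
#' @param incidence,mortality [event_table()]s covering the proxy (and
#'   neighbour) datasets over the reference period.
#' @param proxy_datasets Dataset labels of the proxy registries.
#' @param neighbour_datasets Labels added to the pool for rare-death sites
#'   (may be empty).
#' @param national_mortality An [event_table()] of national deaths used to
#'   decide rarity (average annual deaths over `reference_years`).
#' @param reference_years Default 2003:2007.
#' @param pooling_threshold Average annual national deaths below which
#'   neighbours are pooled (default 100).
#' @return An `mi_ratio_table`: columns `sex`, `site`, `age_group`,
#'   `cases`, `deaths`, `ratio`, with a `provenance` attribute recording
#'   which sites pooled neighbours.
#' @export
compute_mi_ratios <- function(incidence, mortality, proxy_datasets,
                              neighbour_datasets = character(0),
                              national_mortality = NULL,
                              reference_years = 2003:2007,
                              pooling_threshold = 100) {
  inc <- as.data.frame(incidence)
  mor <- as.data.frame(mortality)
  inc <- inc[inc$year %in% reference_years, , drop = FALSE]
  mor <- mor[mor$year %in% reference_years, , drop = FALSE]

  annual_deaths <- NULL
  if (!is.null(national_mortality)) {
    nm <- as.data.frame(national_mortality)
    nm <- nm[nm$year %in% reference_years, , drop = FALSE]
    annual_deaths <- stats::aggregate(count ~ sex + site, data = nm, FUN = sum)
    annual_deaths$count <- annual_deaths$count / length(reference_years)
  }

  pool_of <- function(sex, site) {
    rare <- FALSE
    if (!is.null(annual_deaths) && length(neighbour_datasets)) {
      i <- which(annual_deaths$sex == sex & annual_deaths$site == site)
      nd <- if (length(i)) annual_deaths$count[i] else 0
      rare <- nd < pooling_threshold
    }
    if (rare) c(proxy_datasets, neighbour_datasets) else proxy_datasets
  }

  combos <- unique(rbind(inc[c("sex", "site")], mor[c("sex", "site")]))
  combos <- combos[order(combos$sex, combos$site), , drop = FALSE]
  out <- list()
  prov <- list()
  for (i in seq_len(nrow(combos))) {
    sex <- combos$sex[i]
    site <- combos$site[i]
    pool <- pool_of(sex, site)
    by_age <- function(df) {
      d <- df[df$sex == sex & df$site == site & df$dataset %in% pool, ,
              drop = FALSE]
      s <- tapply(d$count, factor(d$age_group, levels = 0:17), sum)
      ifelse(is.na(s), 0, as.numeric(s))
    }
    cases <- by_age(inc)
    deaths <- by_age(mor)
    if (sum(cases) == 0) {
      if (sum(deaths) == 0) next   # nothing known about the site; skip
      stop_canestim("compute_mi_ratios: zero pooled incidence at all ages for %s (%s)",
                    site, sex)
    }
    # merge sparse bands into the adjacent younger band (the first band
    # merges upward) until every block has cases, and deaths whenever the
    # site has deaths anywhere: a zero numerator or denominator in a thin
    # band is a sampling artifact, not a real case-fatality of 0 or 1
    blocks <- as.list(1:18)
    total_deaths <- sum(deaths)
    repeat {
      bc <- vapply(blocks, function(ix) sum(cases[ix]), 0)
      bd <- vapply(blocks, function(ix) sum(deaths[ix]), 0)
      bad <- which(bc == 0 | (bd == 0 & total_deaths > 0))
      if (!length(bad) || length(blocks) == 1) break
      i <- bad[1]
      j <- if (i > 1) i - 1 else 2
      blocks[[j]] <- sort(c(blocks[[j]], blocks[[i]]))
      blocks[[i]] <- NULL
    }
    block <- integer(18)
    for (b in seq_along(blocks)) block[blocks[[b]]] <- b
    bc <- tapply(cases, block, sum)
    bd <- tapply(deaths, block, sum)
    ratio <- as.numeric(bd[as.character(block)] / bc[as.character(block)])
    out[[length(out) + 1]] <- data.frame(
      sex = sex, site = site, age_group = 0:17,
      cases = cases, deaths = deaths, ratio = ratio,
      stringsAsFactors = FALSE)
    prov[[length(prov) + 1]] <- data.frame(
      sex = sex, site = site,
      pooled_neighbours = !identical(pool, proxy_datasets),
      datasets = paste(pool, collapse = ";"), stringsAsFactors = FALSE)
  }
  if (!length(out)) stop_canestim("compute_mi_ratios: no sites with data")
  res <- do.call(rbind, out)
  structure(res, provenance = do.call(rbind, prov),
            class = c("mi_ratio_table", "data.frame"))
}

mi_estimate <- function(mortality_rates, mi, population, national_datasets,
                        target_year, method) {
  stopifnot(inherits(mortality_rates, "rate_table"),
            inherits(mi, "mi_ratio_table"))
  r <- as.data.frame(mortality_rates)[c("sex", "site", "age_group", "rate")]
  m <- merge(r, as.data.frame(mi), by = c("sex", "site", "age_group"),
             all.x = TRUE)
  uncovered <- unique(m[m$rate > 0 & is.na(m$ratio), c("sex", "site")])
  if (nrow(uncovered)) {
    stop_canestim("method %s: no M:I ratio for %s",
                  method, paste(uncovered$site, "(", uncovered$sex, ")",
                                collapse = ", "))
  }
  bad <- !is.na(m$ratio) & m$ratio == 0 & m$rate > 0
  if (any(bad)) {
    i <- which(bad)[1]
    stop_canestim("method %s: M:I ratio 0 with nonzero mortality for %s (%s, age band %s)",
                  method, m$site[i], m$sex[i], age_band_label(m$age_group[i]))
  }
  lost <- m$rate == 0 & !is.na(m$cases) & m$cases > 0
  if (any(lost)) {
    warn_canestim("method %s: zero projected mortality in %d age band(s) where the proxy registries record cases; their incidence contributes 0 (known failure mode for rare-death cancers)",
                  method, sum(lost))
  }
  m$rate_inc <- ifelse(m$rate == 0, 0, m$rate / m$ratio)
  inc_rates <- rate_table(data.frame(
    sex = m$sex, site = m$site, age_group = m$age_group, rate = m$rate_inc,
    stringsAsFactors = FALSE))
  natpop <- pool_population(population, national_datasets, "national")
  expected <- apply_rates(inc_rates, natpop, "national", target_year)
  detail <- as.data.frame(expected)[c("sex", "site", "age_group", "count")]
  names(detail)[names(detail) == "count"] <- "cases"
  estimate_table(method = method, target_year = target_year, detail = detail)
}

#' Method 3: national mortality with regional M:I ratios
#'
#' Incidence rate = projected national mortality rate / M:I ratio per
#' stratum; strata with zero projected mortality contribute zero estimated
#' incidence (warned about when the proxy registries do record cases
#' there). The resulting rates are applied to the target-year national
#' population.
#'
#' @param mortality_rates A [rate_table()] of projected national mortality
#'   (see [project_mortality()]).
#' @param mi An `mi_ratio_table` from [compute_mi_ratios()] covering every
#'   (sex, site) with positive mortality.
#' @param population A [population_table()].
#' @param national_datasets Dataset labels pooled into the nation.
#' @param target_year Estimation year (default 2010).
#' @return An [estimate_table()] (method `"3"`).
#' @export
method_3 <- function(mortality_rates, mi, population, national_datasets,
                     target_year = 2010) {
  mi_estimate(mortality_rates, mi, population, national_datasets,
              target_year, "3")
}

#' Method 4: national mortality with neighbour-country M:I ratios
#'
#' Identical contract to [method_3()] with the M:I ratios pooled from
#' neighbouring countries instead of regional registries.
#'
#' @inheritParams method_3
#' @param mi An `mi_ratio_table` built from neighbour datasets.
#' @return An [estimate_table()] (method `"4"`).
#' @export
method_4 <- function(mortality_rates, mi, population, national_datasets,
                     target_year = 2010) {
  mi_estimate(mortality_rates, mi, population, national_datasets,
              target_year, "4")
}

#' Method 5: national mortality with 5-year relative survival
#'
#' Inverts M = I(1 - S): incidence rate = mortality rate / (1 - min(S,
#' s_cap)) per stratum. Survival is applied at sex-site level. Sites with S
#' at or above `s_cap` are capped and flagged as unreliable, since the
#' inversion blows up as S approaches 1.
#'
#' @inheritParams method_3
#' @param survival A [survival_table()] with an entry for every site with
#'   positive mortality.
#' @param s_cap Cap applied to S before inversion (default 0.99).
#' @return An [estimate_table()] (method `"5"`) with an
#'   `unreliable_sites` attribute listing capped sites.
#' @export
method_5 <- function(mortality_rates, survival, population, national_datasets,
                     target_year = 2010, s_cap = 0.99) {
  stopifnot(inherits(mortality_rates, "rate_table"),
            inherits(survival, "survival_table"))
  r <- as.data.frame(mortality_rates)[c("sex", "site", "age_group", "rate")]
  m <- merge(r, as.data.frame(survival), by = c("sex", "site"), all.x = TRUE)
  uncovered <- unique(m[m$rate > 0 & is.na(m$survival_5yr), c("sex", "site")])
  if (nrow(uncovered)) {
    stop_canestim("method 5: no survival entry for %s",
                  paste(uncovered$site, "(", uncovered$sex, ")",
                        collapse = ", "))
  }
  m$survival_5yr[is.na(m$survival_5yr)] <- 0
  capped <- m$survival_5yr > s_cap
  m$rate_inc <- m$rate / (1 - pmin(m$survival_5yr, s_cap))
  inc_rates <- rate_table(m[c("sex", "site", "age_group")] |>
                            cbind(rate = m$rate_inc))
  natpop <- pool_population(population, national_datasets, "national")
  expected <- apply_rates(inc_rates, natpop, "national", target_year)
  detail <- as.data.frame(expected)[c("sex", "site", "age_group", "count")]
  names(detail)[names(detail) == "count"] <- "cases"
  est <- estimate_table(method = "5", target_year = target_year,
                        detail = detail)
  attr(est, "unreliable_sites") <-
    unique(paste(m$sex[capped], m$site[capped], sep = ": "))
  est
}

#' Methods 6 and 7: regional registry rates applied nationally
#'
#' Pooled age-sex-site rates from the proxy regions over the reference
#' period (default 2003-2007) applied to the target-year national
#' population. Method 6 conventionally uses regions away from the capital;
#' method 7 the capital region.
#'
#' @param incidence An [event_table()] covering the proxy regions.
#' @param population A [population_table()] covering the proxy regions and
#'   the nation at the target year.
#' @param proxy_datasets Dataset labels of the proxy region(s).
#' @param national_datasets Dataset labels pooled into the nation.
#' @param target_year Estimation year (default 2010).
#' @param reference_years Default 2003:2007.
#' @return An [estimate_table()] (method `"6"` or `"7"`).
#' @export
method_6 <- function(incidence, population, proxy_datasets, national_datasets,
                     target_year = 2010, reference_years = 2003:2007) {
  transport_estimate(incidence, population, proxy_datasets, reference_years,
                     national_datasets, target_year, "6")
}

#' @rdname method_6
#' @export
method_7 <- function(incidence, population, proxy_datasets, national_datasets,
                     target_year = 2010, reference_years = 2003:2007) {
  transport_estimate(incidence, population, proxy_datasets, reference_years,
                     national_datasets, target_year, "7")
}

#' Site frequency table
#'
#' Per sex, the proportion of all-sites cases by site, pooled over the
#' given datasets and window (default the neighbours over 2009-2011).
#'
#' @param events An [event_table()].
#' @param datasets Dataset labels to pool.
#' @param window Years to pool (default 2009:2011).
#' @return A `frequency_table`: columns `sex`, `site`, `proportion`
#'   (summing to 1 per sex).
#' @export
build_frequency_table <- function(events, datasets = NULL, window = 2009:2011) {
  df <- as.data.frame(events)
  datasets <- datasets %||% unique(df$dataset)
  df <- df[df$dataset %in% datasets & df$year %in% window, , drop = FALSE]
  bysite <- stats::aggregate(count ~ sex + site, data = df, FUN = sum)
  for (s in unique(bysite$sex)) {
    if (sum(bysite$count[bysite$sex == s]) == 0) {
      stop_canestim("build_frequency_table: zero total count for sex %s", s)
    }
  }
  tot <- stats::ave(bysite$count, bysite$sex, FUN = sum)
  bysite$proportion <- bysite$count / tot
  bysite <- bysite[order(bysite$sex, bysite$site), c("sex", "site", "proportion")]
  rownames(bysite) <- NULL
  structure(bysite, class = c("frequency_table", "data.frame"))
}

#' All-sites incidence rates by age and sex
#'
#' Pools every site into a single "all sites" group before computing rates;
#' the input of [method_8()].
#'
#' @inheritParams build_frequency_table
#' @param population A [population_table()].
#' @return A [rate_table()] with `site = "All sites"`.
#' @export
all_sites_rates <- function(events, population, datasets = NULL,
                            window = 2009:2011) {
  df <- as.data.frame(events)
  datasets <- datasets %||% unique(df$dataset)
  df <- df[df$dataset %in% datasets & df$year %in% window, , drop = FALSE]
  df$site <- "All sites"
  ev <- event_table(suppressWarnings(aggregate_counts(df)), event_kind(events))
  pooled_rates(ev, population, datasets = datasets, years = window)
}

#' Method 8: all-sites rates partitioned by site frequencies
#'
#' Applies all-sites age-sex rates to the target-year national population,
#' then splits the expected cases across sites in proportion to the
#' frequency table; by construction the site estimates sum exactly to the
#' all-sites estimate per sex.
#'
#' @param rates A [rate_table()] of all-sites rates by age and sex (see
#'   [all_sites_rates()]).
#' @param frequencies A `frequency_table` from [build_frequency_table()]
#'   covering every sex in `rates`.
#' @param population A [population_table()].
#' @param national_datasets Dataset labels pooled into the nation.
#' @param target_year Estimation year (default 2010).
#' @return An [estimate_table()] (method `"8"`).
#' @export
method_8 <- function(rates, frequencies, population, national_datasets,
                     target_year = 2010) {
  stopifnot(inherits(rates, "rate_table"),
            inherits(frequencies, "frequency_table"))
  missing_sex <- setdiff(unique(rates$sex), unique(frequencies$sex))
  if (length(missing_sex)) {
    stop_canestim("method 8: frequency table missing sex(es): %s",
                  paste(missing_sex, collapse = ", "))
  }
  natpop <- pool_population(population, national_datasets, "national")
  expected <- apply_rates(rates, natpop, "national", target_year)
  allsites <- as.data.frame(expected)
  freq <- as.data.frame(frequencies)
  detail <- merge(allsites[c("sex", "age_group", "count")], freq, by = "sex")
  detail$cases <- detail$count * detail$proportion
  estimate_table(method = "8", target_year = target_year,
                 detail = detail[c("sex", "site", "age_group", "cases")])
}

#' Method 9: pooled neighbour rates applied nationally
#'
#' Neighbour datasets are pooled into one numerator and denominator
#' (person-year weighted), and the resulting age-sex-site rates applied to
#' the target-year national population.
#'
#' @param incidence An [event_table()] covering the neighbour datasets.
#' @param population A [population_table()].
#' @param neighbour_datasets Dataset labels to pool.
#' @param national_datasets Dataset labels pooled into the nation.
#' @param target_year Estimation year (default 2010).
#' @param window Reference years (default 2009:2011).
#' @return An [estimate_table()] (method `"9"`).
#' @export
method_9 <- function(incidence, population, neighbour_datasets,
                     national_datasets, target_year = 2010,
                     window = 2009:2011) {
  transport_estimate(incidence, population, neighbour_datasets, window,
                     national_datasets, target_year, "9")
}

#' Choose an estimation method from data availability
#'
#' Returns the first applicable method in the standard priority order
#' 1, 2, 3, 4, 5, 6/7, 8, 9: full national incidence history beats recent
#' national incidence, which beats national mortality combined with
#' regional M:I ratios, neighbour M:I ratios, then survival; regional
#' registries alone come next, then all-sites-plus-frequency data, then
#' neighbour rates.
#'
#' @param availability A list of logicals:
#'   `national_incidence_history`, `recent_national_incidence`,
#'   `regional_registries`, `national_mortality`, `neighbour_data`,
#'   `survival`, `frequency_data`. Missing entries count as `FALSE`.
#' @return A method label: `"1"`, `"2"`, `"3"`, `"4"`, `"5"`, `"6/7"`,
#'   `"8"` or `"9"`.
#' @export
select_method <- function(availability) {
  has <- function(k) isTRUE(availability[[k]])
  if (has("national_incidence_history")) return("1")
  if (has("recent_national_incidence")) return("2")
  if (has("national_mortality") && has("regional_registries")) return("3")
  if (has("national_mortality") && has("neighbour_data")) return("4")
  if (has("national_mortality") && has("survival")) return("5")
  if (has("regional_registries")) return("6/7")
  if (has("neighbour_data") && has("frequency_data")) return("8")
  if (has("neighbour_data")) return("9")
  stop_canestim("select_method: no estimation method is applicable with the declared data availability")
}
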