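# Rates are the transport currency between estimation methods: counts are
# turned into rates per 100,000 person-years in a source population and
# re-applied to the person-years of the target population.

#' Compute rates per 100,000 person-years
#'
#' @param events An [event_table()].
#' @param population A [population_table()] with positive person-years for
#'   every stratum carrying a nonzero count.
#' @return A [rate_table()] keyed by dataset, year, sex, site, age band.
#' @export
compute_rates <- function(events, population) {
  stopifnot(inherits(events, "event_table"),
            inherits(population, "population_table"))
  df <- merge(as.data.frame(events), as.data.frame(population),
              by = c("dataset", "year", "sex", "age_group"), all.x = TRUE)
  bad <- df$count > 0 & (is.na(df$person_years) | df$person_years <= 0)
  if (any(bad)) {
    i <- which(bad)[1]
    stop_canestim("compute_rates: nonzero count with missing person-years (dataset %s, year %d, %s, %s, age band %s)",
                  df$dataset[i], df$year[i], df$sex[i], df$site[i],
                  age_band_label(df$age_group[i]))
  }
  df$rate <- ifelse(df$count == 0, 0, 100000 * df$count / df$person_years)
  rate_table(df[c("dataset", "year", "sex", "site", "age_group", "rate")])
}

#' Apply rates to a target population
#'
#' Expected cases = rate x person-years / 100,000 per stratum, keeping the
#' age-resolved detail. Any `dataset`/`year` columns on the rate table are
#' ignored; the target stratification comes from `dataset` and `year`.
#'
#' @param rates A [rate_table()] keyed by sex, site, age band.
#' @param population A [population_table()] covering every (sex, age band)
#'   in `rates` for the target dataset and year.
#' @param dataset,year Target population stratum.
#' @param kind Event kind of the result (default `"incidence"`).
#' @return An [event_table()] of expected (real-valued) counts.
#' @export
apply_rates <- function(rates, population, dataset, year,
                        kind = c("incidence", "mortality")) {
  stopifnot(inherits(rates, "rate_table"),
            inherits(population, "population_table"))
  kind <- match.arg(kind)
  pop <- as.data.frame(population)
  pop <- pop[pop$dataset == dataset & pop$year == year, , drop = FALSE]
  r <- as.data.frame(rates)[c("sex", "site", "age_group", "rate")]
  if (anyDuplicated(paste(r$sex, r$site, r$age_group))) {
    stop_canestim("apply_rates: multiple rates per (sex, site, age band); pool the table first")
  }
  df <- merge(r, pop[c("sex", "age_group", "person_years")],
              by = c("sex", "age_group"), all.x = TRUE)
  if (any(is.na(df$person_years))) {
    i <- which(is.na(df$person_years))[1]
    stop_canestim("apply_rates: no person-years for dataset %s, year %s, %s, age band %s",
                  dataset, year, df$sex[i], age_band_label(df$age_group[i]))
  }
  df$count <- df$rate * df$person_years / 100000
  df$dataset <- dataset
  df$year <- as.integer(year)
  event_table(df[c("dataset", "year", "sex", "site", "age_group", "count")],
              kind)
}

#' Pool counts and person-years into average annual rates
#'
#' Sums counts and person-years over the given datasets and years, then
#' forms one rate per (sex, site, age band). Pooling is therefore
#' person-year weighted, not an unweighted mean of per-dataset rates.
#'
#' @param events An [event_table()].
#' @param population A [population_table()].
#' @param datasets Dataset labels to pool (default: all in `events`).
#' @param years Years to pool (default: all in `events`).
#' @param sites Optional site labels to keep (default: all observed; pass
#'   the full catalogue to force zero rates for unobserved sites).
#' @return A [rate_table()] keyed by sex, site, age band.
#' @export
pooled_rates <- function(events, population, datasets = NULL, years = NULL,
                         sites = NULL) {
  stopifnot(inherits(events, "event_table"),
            inherits(population, "population_table"))
  ev <- as.data.frame(events)
  pop <- as.data.frame(population)
  datasets <- datasets %||% unique(ev$dataset)
  years <- years %||% unique(ev$year)
  ev <- ev[ev$dataset %in% datasets & ev$year %in% years, , drop = FALSE]
  pop <- pop[pop$dataset %in% datasets & pop$year %in% years, , drop = FALSE]
  if (!nrow(pop)) stop_canestim("pooled_rates: no person-years for the requested datasets/years")
  sites <- sites %||% sort(unique(ev$site))

  cnt <- stats::aggregate(count ~ sex + site + age_group, data = ev, FUN = sum)
  py <- stats::aggregate(person_years ~ sex + age_group, data = pop, FUN = sum)
  grid <- expand.grid(sex = unique(pop$sex), site = sites, age_group = 0:17,
                      stringsAsFactors = FALSE)
  grid <- grid[!sex_site_conflict(grid$sex, grid$site), , drop = FALSE]
  df <- merge(grid, cnt, by = c("sex", "site", "age_group"), all.x = TRUE)
  df$count[is.na(df$count)] <- 0
  df <- merge(df, py, by = c("sex", "age_group"), all.x = TRUE)
  bad <- df$count > 0 & (is.na(df$person_years) | df$person_years <= 0)
  if (any(bad)) {
    i <- which(bad)[1]
    stop_canestim("pooled_rates: nonzero pooled count with no person-years (%s, %s, age band %s)",
                  df$sex[i], df$site[i], age_band_label(df$age_group[i]))
  }
  df$rate <- ifelse(df$count == 0, 0, 100000 * df$count / df$person_years)
  rate_table(df[c("sex", "site", "age_group", "rate")])
}

#' Gold-standard observed incidence around a target year
#'
#' Per (sex, site), the arithmetic mean of annual recorded cases over the
#' year range; the conventional choice for a 2010 target is the 2009-2011
#' average.
#'
#' @param events An [event_table()] of recorded incidence.
#' @param years Year range to average (default 2009:2011).
#' @param datasets Dataset labels defining the nation (default: all).
#' @param target_year Year the gold standard represents (default: the
#'   midpoint of `years`).
#' @return An [estimate_table()] with method `"observed"`.
#' @export
gold_standard <- function(events, years = 2009:2011, datasets = NULL,
                          target_year = NULL) {
  stopifnot(inherits(events, "event_table"))
  df <- as.data.frame(events)
  datasets <- datasets %||% unique(df$dataset)
  df <- df[df$dataset %in% datasets, , drop = FALSE]
  missing_years <- setdiff(years, unique(df$year))
  if (length(missing_years)) {
    stop_canestim("gold_standard: year(s) %s absent from the registry data",
                  paste(missing_years, collapse = ", "))
  }
  df <- df[df$year %in% years, , drop = FALSE]
  tot <- stats::aggregate(count ~ sex + site, data = df, FUN = sum)
  tot$cases <- tot$count / length(years)
  target_year <- target_year %||% round(mean(years))
  estimate_table(tot[c("sex", "site", "cases")], method = "observed",
                 target_year = target_year)
}

# Sum a set of datasets into a single relabelled dataset (e.g. national
# totals from regional tables).
pool_datasets <- function(events, datasets, label) {
  df <- as.data.frame(events)
  df <- df[df$dataset %in% datasets, , drop = FALSE]
  df$dataset <- label
  event_table(suppressWarnings(aggregate_counts(df)), event_kind(events))
}

pool_population <- function(population, datasets, label) {
  df <- as.data.frame(population)
  df <- df[df$dataset %in% datasets, , drop = FALSE]
  df$dataset <- label
  population_table(stats::aggregate(
    person_years ~ dataset + year + sex + age_group, data = df, FUN = sum))
}
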