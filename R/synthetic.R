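# Synthetic multi-region registry bundles with known ground truth. The
# generator emulates the structure of a Nordic-style registry extract:
# several regions with population shares and rate multipliers, age-specific
# baseline incidence curves with log-linear calendar trends (optionally
# with a changepoint), mortality tied to incidence through 5-year relative
# survival (M = I(1 - S) in expectation, with optional departures that
# emulate documented real-world failure modes), neighbouring countries
# with perturbed rates, and Poisson sampling noise throughout.

#' Scenario configuration for the synthetic registry generator
#'
#' @param regions Data frame with columns `name`, `share` (population
#'   shares summing to 1), `multiplier` (regional rate multipliers) and
#'   `capital` (logical, exactly one TRUE).
#' @param sites Data frame with columns `name`, `sexes`
#'   (`"both"`/`"male"`/`"female"`), `peak_rate` (rate per 100,000 at the
#'   peak age, at the target year), `peak_age` (years), `trend` (annual
#'   log-linear rate trend), `changepoint` (year, or NA), `post_trend`
#'   (annual trend after the changepoint), `survival` (5-year relative
#'   survival in [0, 1)), and optionally `mortality_trend` (extra annual
#'   log-trend on mortality relative to the M = I(1-S) link, default 0,
#'   emulating improving treatment) and `mortality_inflation`
#'   (multiplicative excess mortality, default 1, emulating deaths beyond
#'   5 years of follow-up).
#' @param years Calendar span of the registry (default 1983:2012).
#' @param target_year Year the ground truth refers to (default 2010).
#' @param population_base National person count at the first year
#'   (default 5e6, split across regions by `share`).
#' @param population_growth Annual log-growth of the population
#'   (default 0.005).
#' @param neighbours Data frame with columns `name`, `size` (population
#'   relative to the nation) and `rate_factor` (multiplier on national
#'   baseline rates); may have zero rows.
#' @param survival_lag Years by which the published survival proportion
#'   trails the target year when a `mortality_trend` is active (default
#'   10): a period survival estimate reflects cases diagnosed and followed
#'   up well before the estimation year, so with improving treatment the
#'   true case fatality at the target year is below `1 - S`. With
#'   `mortality_trend = 0` the lag has no effect and the
#'   mortality-equals-incidence-times-(1-S) link holds exactly.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return A `scenario_config`.
#' @export
scenario_config <- function(regions, sites, years = 1983:2012,
                            target_year = 2010, population_base = 5e6,
                            population_growth = 0.005,
                            neighbours = NULL, survival_lag = 10,
                            seed = 1L) {
  if (abs(sum(regions$share) - 1) > 1e-9) {
    stop_canestim("scenario_config: region shares must sum to 1")
  }
  if (sum(regions$capital) != 1) {
    stop_canestim("scenario_config: exactly one region must be the capital")
  }
  if (is.null(sites$mortality_trend)) sites$mortality_trend <- 0
  if (is.null(sites$mortality_inflation)) sites$mortality_inflation <- 1
  if (is.null(sites$changepoint)) sites$changepoint <- NA_real_
  if (is.null(sites$post_trend)) sites$post_trend <- 0
  if (any(sites$survival < 0 | sites$survival >= 1)) {
    stop_canestim("scenario_config: survival must be in [0, 1)")
  }
  if (any(sites$peak_rate <= 0)) {
    stop_canestim("scenario_config: peak rates must be positive")
  }
  if (is.null(neighbours)) {
    neighbours <- data.frame(name = character(0), size = numeric(0),
                             rate_factor = numeric(0))
  }
  structure(list(regions = regions, sites = sites, years = as.integer(years),
                 target_year = as.integer(target_year),
                 population_base = population_base,
                 population_growth = population_growth,
                 neighbours = neighbours, survival_lag = survival_lag,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# Age pyramid: near-flat through mid-life with a logistic roll-off at old
# ages; shares over the 18 bands sum to 1.
age_pyramid_shares <- function() {
  mid <- age_band_midpoint(0:17)
  w <- 1 / (1 + exp((mid - 72) / 8))
  w / sum(w)
}

# Baseline age curve: log rate is quadratic in the age-band midpoint
# around the peak age (fixed curvature scale of 30 years), scaled to
# peak_rate at the peak.
site_age_curve <- function(peak_rate, peak_age, mid = age_band_midpoint(0:17)) {
  peak_rate * exp(-((mid - peak_age) / 30)^2)
}

# Piecewise log-linear calendar factor, normalised to 1 at the target year.
trend_factor <- function(year, trend, changepoint, post_trend, target_year) {
  g <- function(y) {
    if (is.na(changepoint)) return(trend * y)
    ifelse(y <= changepoint, trend * y,
           trend * changepoint + post_trend * (y - changepoint))
  }
  exp(g(year) - g(target_year))
}

#' Generate a synthetic registry bundle with known truth
#'
#' Draws Poisson counts around the configured expected incidence, and
#' mortality with expectation `incidence * (1 - S)` per stratum (modified
#' by the per-site `mortality_trend`/`mortality_inflation` knobs where
#' configured). Deterministic given `config$seed`.
#'
#' @param config A [scenario_config()].
#' @return A list of class `synthetic_registry`: `bundle` (a
#'   [registry_bundle()]), and `truth` with `expected_incidence` /
#'   `expected_mortality` (national expectations per stratum and year) and
#'   `target_incidence` (true expected national cases at the target year
#'   per sex and site).
#' @export
generate_registry <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  shares <- age_pyramid_shares()
  years <- config$years
  y1 <- min(years)
  mid <- age_band_midpoint(0:17)

  datasets <- rbind(
    data.frame(name = config$regions$name,
               size = config$regions$share,
               rate_factor = config$regions$multiplier,
               stringsAsFactors = FALSE),
    data.frame(name = config$neighbours$name,
               size = config$neighbours$size,
               rate_factor = config$neighbours$rate_factor,
               stringsAsFactors = FALSE))

  # person-years: national base * growth * dataset size * pyramid / sexes
  pop_grid <- expand.grid(dataset = datasets$name, year = years,
                          sex = c("male", "female"), age_group = 0:17,
                          stringsAsFactors = FALSE)
  pop_grid <- pop_grid[order(pop_grid$dataset, pop_grid$year, pop_grid$sex,
                             pop_grid$age_group), , drop = FALSE]
  size <- datasets$size[match(pop_grid$dataset, datasets$name)]
  pop_grid$person_years <- config$population_base *
    exp(config$population_growth * (pop_grid$year - y1)) *
    size * shares[pop_grid$age_group + 1] * 0.5
  population <- population_table(pop_grid)

  # expected stratum rates, then counts
  expected_for <- function(ds_names) {
    rows <- list()
    for (i in seq_len(nrow(config$sites))) {
      st <- config$sites[i, ]
      sexes <- switch(st$sexes, both = c("male", "female"), st$sexes)
      base <- site_age_curve(st$peak_rate, st$peak_age, mid)
      for (sx in sexes) {
        g <- expand.grid(dataset = ds_names, year = years, age_group = 0:17,
                         stringsAsFactors = FALSE)
        g$sex <- sx
        g$site <- st$name
        tf <- trend_factor(g$year, st$trend, st$changepoint, st$post_trend,
                           config$target_year)
        rf <- datasets$rate_factor[match(g$dataset, datasets$name)]
        g$rate_inc <- base[g$age_group + 1] * tf * rf
        g$rate_mort <- g$rate_inc * (1 - st$survival) *
          exp(st$mortality_trend *
                (g$year - (config$target_year - config$survival_lag))) *
          st$mortality_inflation
        rows[[length(rows) + 1]] <- g
      }
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$dataset, out$year, out$sex, out$site, out$age_group), ,
               drop = FALSE]
    py <- pop_grid$person_years[match(
      paste(out$dataset, out$year, out$sex, out$age_group),
      paste(pop_grid$dataset, pop_grid$year, pop_grid$sex, pop_grid$age_group))]
    out$exp_inc <- out$rate_inc * py / 1e5
    out$exp_mort <- out$rate_mort * py / 1e5
    out
  }

  all_exp <- expected_for(datasets$name)

  draw <- function(expectation, offset) {
    set.seed(derive_seed(config$seed, offset))
    stats::rpois(length(expectation), expectation)
  }
  inc_counts <- draw(all_exp$exp_inc, 1L)
  mort_counts <- draw(all_exp$exp_mort, 2L)

  mk_events <- function(counts, kind) {
    df <- all_exp[c("dataset", "year", "sex", "site", "age_group")]
    df$count <- counts
    df <- df[df$count > 0, , drop = FALSE]   # sparse: missing stratum = 0
    event_table(df, kind)
  }
  incidence <- mk_events(inc_counts, "incidence")
  mortality <- mk_events(mort_counts, "mortality")

  surv_rows <- list()
  for (i in seq_len(nrow(config$sites))) {
    st <- config$sites[i, ]
    sexes <- switch(st$sexes, both = c("male", "female"), st$sexes)
    surv_rows[[i]] <- data.frame(sex = sexes, site = st$name,
                                 survival_5yr = st$survival,
                                 stringsAsFactors = FALSE)
  }
  survival <- survival_table(do.call(rbind, surv_rows))

  bundle <- registry_bundle(
    incidence = incidence, mortality = mortality, population = population,
    survival = survival,
    national_datasets = config$regions$name,
    capital_dataset = config$regions$name[config$regions$capital],
    neighbour_datasets = config$neighbours$name,
    target_year = config$target_year)

  nat <- all_exp[all_exp$dataset %in% config$regions$name, , drop = FALSE]
  nat_inc <- stats::aggregate(exp_inc ~ year + sex + site + age_group,
                              data = nat, FUN = sum)
  nat_mort <- stats::aggregate(exp_mort ~ year + sex + site + age_group,
                               data = nat, FUN = sum)
  names(nat_inc)[names(nat_inc) == "exp_inc"] <- "expected"
  names(nat_mort)[names(nat_mort) == "exp_mort"] <- "expected"
  tgt <- nat_inc[nat_inc$year == config$target_year, , drop = FALSE]
  target <- stats::aggregate(expected ~ sex + site, data = tgt, FUN = sum)
  names(target)[names(target) == "expected"] <- "cases"

  structure(list(bundle = bundle,
                 truth = list(expected_incidence = nat_inc,
                              expected_mortality = nat_mort,
                              target_incidence = target),
                 config = config),
            class = "synthetic_registry")
}

#' @export
print.synthetic_registry <- function(x, ...) {
  cat("<synthetic_registry>\n")
  print(x$bundle)
  cat(sprintf("  truth: %d (sex, site) target expectations, total %.0f cases\n",
              nrow(x$truth$target_incidence),
              sum(x$truth$target_incidence$cases)))
  invisible(x)
}

nordic_neighbours <- function(rate_factor = 1) {
  data.frame(name = c("nb_denmark", "nb_finland", "nb_iceland", "nb_sweden"),
             size = c(1.1, 1.05, 0.06, 1.85),
             rate_factor = rate_factor,
             stringsAsFactors = FALSE)
}

default_regions <- function(capital_multiplier = 1, other_multiplier = 1) {
  data.frame(
    name = c("southeast", "north", "west", "mid"),
    share = c(0.50, 0.10, 0.25, 0.15),
    multiplier = c(capital_multiplier, rep(other_multiplier, 3)),
    capital = c(TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Preset synthetic scenarios
#'
#' Named study conditions used throughout the test-suite, each isolating a
#' documented behaviour of the estimation methods:
#' \describe{
#'   \item{stable}{No calendar trends, representative regions and
#'     neighbours: every method should land close to the truth.}
#'   \item{screening_bump}{A prostate-like site whose rates rise steeply
#'     and then plateau at a changepoint; long-term projection overshoots
#'     while recent-rate transport stays close.}
#'   \item{rare_death}{A testis-like site with high survival, few deaths
#'     and mortality declining faster than incidence (improving
#'     treatment); mortality-based methods underestimate.}
#'   \item{good_prognosis}{A melanoma/breast-like site with S >= 0.8 and
#'     excess deaths beyond 5 years of follow-up; survival inversion
#'     (method 5) overestimates.}
#'   \item{urban_rural}{Strong regional rate multipliers; regional-proxy
#'     methods inherit the multiplier as bias.}
#' }
#'
#' @param seed Seed stored in each config (default 1).
#' @return Named list of [scenario_config()]s.
#' @export
preset_scenarios <- function(seed = 1L) {
  base_sites <- data.frame(
    name = c("Colon-rectum (C18-21)", "Lung (C33-34)"),
    sexes = c("both", "both"),
    peak_rate = c(260, 160),
    peak_age = c(76, 72),
    trend = c(0, 0), changepoint = NA_real_, post_trend = 0,
    survival = c(0.55, 0.12),
    mortality_trend = 0, mortality_inflation = 1,
    stringsAsFactors = FALSE)
  prostate <- data.frame(
    name = "Prostate (C61)", sexes = "male", peak_rate = 520, peak_age = 72,
    trend = 0, changepoint = NA_real_, post_trend = 0, survival = 0.85,
    mortality_trend = 0, mortality_inflation = 1,
    stringsAsFactors = FALSE)
  breast <- data.frame(
    name = "Breast (C50)", sexes = "female", peak_rate = 280, peak_age = 62,
    trend = 0, changepoint = NA_real_, post_trend = 0, survival = 0.85,
    mortality_trend = 0, mortality_inflation = 1,
    stringsAsFactors = FALSE)

  list(
    stable = scenario_config(
      regions = default_regions(),
      sites = rbind(base_sites, prostate, breast),
      neighbours = nordic_neighbours(),
      seed = seed),
    screening_bump = scenario_config(
      regions = default_regions(),
      sites = rbind(base_sites,
                    within(prostate, { trend <- 0.05; changepoint <- 2003 })),
      neighbours = nordic_neighbours(),
      seed = seed),
    rare_death = scenario_config(
      regions = default_regions(),
      sites = rbind(
        base_sites,
        data.frame(name = "Testis (C62)", sexes = "male", peak_rate = 30,
                   peak_age = 32, trend = 0.02, changepoint = NA_real_,
                   post_trend = 0, survival = 0.95, mortality_trend = -0.08,
                   mortality_inflation = 1, stringsAsFactors = FALSE)),
      neighbours = nordic_neighbours(),
      seed = seed),
    good_prognosis = scenario_config(
      regions = default_regions(),
      sites = rbind(
        base_sites,
        data.frame(name = "Melanoma of skin (C43)", sexes = "both",
                   peak_rate = 28, peak_age = 62, trend = 0,
                   changepoint = NA_real_, post_trend = 0, survival = 0.85,
                   mortality_trend = 0, mortality_inflation = 1.6,
                   stringsAsFactors = FALSE)),
      neighbours = nordic_neighbours(),
      seed = seed),
    urban_rural = scenario_config(
      regions = default_regions(capital_multiplier = 1.5,
                                other_multiplier = 0.75),
      sites = rbind(base_sites, prostate, breast),
      neighbours = nordic_neighbours(),
      seed = seed)
  )
}
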