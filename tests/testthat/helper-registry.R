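# Deterministic fixtures built in code. The "flat" registry has constant
# annual counts and person-years, so every rate-transport method should
# reproduce the recorded counts exactly and self-consistency identities
# hold to machine precision.

flat_events <- function(datasets = "nat", years = 2000:2011,
                        sexes = c("male", "female"),
                        sites = c("Lung (C33-34)", "Stomach (C16)"),
                        kind = "incidence", scale = 1) {
  g <- expand.grid(dataset = datasets, year = years, sex = sexes,
                   site = sites, age_group = 0:17, stringsAsFactors = FALSE)
  g$count <- (20 + 2 * g$age_group) * scale
  event_table(g, kind)
}

flat_population <- function(datasets = "nat", years = 2000:2011, py = 1e5) {
  g <- expand.grid(dataset = datasets, year = years,
                   sex = c("male", "female"), age_group = 0:17,
                   stringsAsFactors = FALSE)
  g$person_years <- py
  population_table(g)
}

random_events <- function(seed, n = 40, datasets = c("a", "b"),
                          years = 2005:2007, kind = "incidence") {
  set.seed(seed)
  g <- expand.grid(dataset = datasets, year = years,
                   sex = c("male", "female"), age_group = 0:17,
                   stringsAsFactors = FALSE)
  g <- g[sample(nrow(g), min(n, nrow(g))), , drop = FALSE]
  n <- nrow(g)
  g$site <- ifelse(g$sex == "male", "Prostate (C61)", "Breast (C50)")
  g$count <- rpois(n, 30)
  event_table(g, kind)
}

# restrict an event table to given sites (methods are site-separable, so
# this is a pure computational shortcut in simulation loops)
keep_sites <- function(ev, sites) {
  d <- as.data.frame(ev)
  event_table(d[d$site %in% sites, , drop = FALSE], attr(ev, "kind"))
}

expect_cases <- function(est, sx, site, expected, tol = 1e-8) {
  d <- as.data.frame(est)
  expect_equal(sum(d$cases[d$sex == sx & d$site == site]), expected,
               tolerance = tol)
}
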