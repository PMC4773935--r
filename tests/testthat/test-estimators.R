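test_that("method 2: identity on constant registries, linearity, brute force", {
  ev <- flat_events("nat", 2003:2010, sites = "Stomach (C16)")
  pop <- flat_population("nat", 2003:2010)
  est <- method_2(ev, pop, target_year = 2010)
  truth <- sum(20 + 2 * (0:17))
  expect_cases(est, "male", "Stomach (C16)", truth, tol = 1e-9)

  # doubled target population -> doubled estimate
  pop2 <- as.data.frame(pop)
  pop2$person_years[pop2$year == 2010] <- 2e5
  est2 <- method_2(ev, population_table(pop2), target_year = 2010)
  expect_cases(est2, "male", "Stomach (C16)", 2 * truth, tol = 1e-9)

  # brute force per stratum on a random registry
  ev3 <- random_events(11, datasets = "nat", years = 2003:2007)
  df3 <- as.data.frame(ev3)
  full <- rbind(df3, data.frame(dataset = "nat", year = 2010,
                                sex = "male", site = "Prostate (C61)",
                                age_group = 0, count = 0))
  est3 <- method_2(event_table(full, "incidence"), flat_population("nat", 2003:2010),
                   target_year = 2010)
  oracle <- stats::aggregate(count ~ sex + site, df3, sum)
  oracle$cases <- oracle$count / 5   # constant person-years cancel
  m <- merge(as.data.frame(est3), oracle, by = c("sex", "site"))
  expect_equal(m$cases.x, m$cases.y, tolerance = 1e-9)
  expect_error(method_2(ev3, pop, reference_years = 2003:2007, target_year = 2010),
               NA)
  expect_error(method_2(flat_events("nat", 2005:2007), pop), "2003")
})

test_that("M:I ratios: definition, age merging, neighbour pooling provenance", {
  mk <- function(counts, kind, dataset = "reg") {
    event_table(data.frame(dataset = dataset, year = 2005, sex = "male",
                           site = "Larynx (C32)", age_group = seq_along(counts) - 1,
                           count = counts), kind)
  }
  inc <- mk(c(100, 50), "incidence")
  mor <- mk(c(40, 10), "mortality")
  mi <- compute_mi_ratios(inc, mor, proxy_datasets = "reg",
                          reference_years = 2005)
  expect_equal(mi$ratio[mi$age_group == 0], 0.4)
  expect_equal(mi$ratio[mi$age_group == 1], 0.2)

  # an age band with 0 cases and 2 deaths merges into the younger band:
  # ratio of the merged block is (40 + 2) / (100 + 0)
  inc2 <- mk(c(100, 0), "incidence")
  mor2 <- mk(c(40, 2), "mortality")
  mi2 <- compute_mi_ratios(inc2, mor2, proxy_datasets = "reg",
                           reference_years = 2005)
  expect_equal(mi2$ratio[mi2$age_group == 0], 42 / 100)
  expect_equal(mi2$ratio[mi2$age_group == 1], 42 / 100)

  # rare-death sites pool the neighbours, recorded in provenance
  nb_inc <- mk(c(400, 200), "incidence", dataset = "nb")
  nb_mor <- mk(c(100, 20), "mortality", dataset = "nb")
  nat_mor <- mk(c(10, 3), "mortality", dataset = "national")
  mi3 <- compute_mi_ratios(
    event_table(rbind(as.data.frame(inc), as.data.frame(nb_inc)), "incidence"),
    event_table(rbind(as.data.frame(mor), as.data.frame(nb_mor)), "mortality"),
    proxy_datasets = "reg", neighbour_datasets = "nb",
    national_mortality = nat_mor, reference_years = 2005,
    pooling_threshold = 100)
  prov <- attr(mi3, "provenance")
  expect_true(prov$pooled_neighbours)
  expect_equal(mi3$ratio[mi3$age_group == 0], (40 + 100) / (100 + 400))

  # zero pooled incidence everywhere with deaths present is an error
  expect_error(
    compute_mi_ratios(mk(c(0, 0), "incidence"), mor, proxy_datasets = "reg",
                      reference_years = 2005),
    "zero pooled incidence")
})

test_that("method 3: self-consistency, inversion arithmetic, ratio-0 error", {
  # M:I ratios computed from the same national data that supplies the
  # mortality reproduce national incidence exactly
  years <- 2003:2010
  inc <- flat_events("nat", years, sites = "Stomach (C16)")
  mor <- flat_events("nat", years, sites = "Stomach (C16)",
                     kind = "mortality", scale = 0.45)
  pop <- flat_population("nat", years)
  mort_rates <- pooled_rates(mor, pop, datasets = "nat", years = 2003:2007)
  mi <- compute_mi_ratios(inc, mor, proxy_datasets = "nat",
                          reference_years = 2003:2007)
  est <- method_3(mort_rates, mi, pop, "nat", target_year = 2010)
  expect_cases(est, "male", "Stomach (C16)", sum(20 + 2 * (0:17)), tol = 1e-9)

  # mortality rate 10, ratio 0.5 -> incidence rate 20
  one_rate <- rate_table(data.frame(sex = "male", site = "Stomach (C16)",
                                    age_group = 10, rate = 10))
  mi_half <- structure(
    data.frame(sex = "male", site = "Stomach (C16)", age_group = 10,
               cases = 100, deaths = 50, ratio = 0.5),
    class = c("mi_ratio_table", "data.frame"))
  est2 <- method_3(one_rate, mi_half, flat_population("nat", 2010), "nat",
                   target_year = 2010)
  expect_cases(est2, "male", "Stomach (C16)", 20 / 1e5 * 1e5, tol = 1e-9)

  mi_zero <- within(mi_half, ratio <- 0)
  class(mi_zero) <- class(mi_half)
  expect_error(method_3(one_rate, mi_zero, flat_population("nat", 2010),
                        "nat", target_year = 2010), "ratio 0")
})

test_that("method 5 inverts M = I(1 - S)", {
  pop <- flat_population("nat", 2010)
  rates <- rate_table(data.frame(sex = "male", site = "Lung (C33-34)",
                                 age_group = c(5, 10), rate = c(10, 30)))
  surv <- survival_table(data.frame(sex = "male", site = "Lung (C33-34)",
                                    survival_5yr = 0.5))
  est <- method_5(rates, surv, pop, "nat", target_year = 2010)
  expect_cases(est, "male", "Lung (C33-34)", (20 + 60) / 1e5 * 1e5, tol = 1e-9)

  # S = 0: incidence equals mortality
  surv0 <- survival_table(data.frame(sex = "male", site = "Lung (C33-34)",
                                     survival_5yr = 0))
  est0 <- method_5(rates, surv0, pop, "nat", target_year = 2010)
  expect_cases(est0, "male", "Lung (C33-34)", 40, tol = 1e-9)

  # generative round trip: mortality built as I(1 - S) recovers I exactly
  years <- 2003:2010
  S <- 0.62
  inc <- flat_events("nat", years, sites = "Melanoma of skin (C43)")
  mor <- flat_events("nat", years, sites = "Melanoma of skin (C43)",
                     kind = "mortality", scale = 1 - S)
  popf <- flat_population("nat", years)
  mort_rates <- pooled_rates(mor, popf, datasets = "nat", years = 2003:2007)
  survS <- survival_table(data.frame(sex = c("male", "female"),
                                     site = "Melanoma of skin (C43)",
                                     survival_5yr = S))
  est3 <- method_5(mort_rates, survS, popf, "nat", target_year = 2010)
  expect_cases(est3, "male", "Melanoma of skin (C43)", sum(20 + 2 * (0:17)),
               tol = 1e-9)

  # S above the cap is capped and flagged
  surv99 <- survival_table(data.frame(sex = "male", site = "Lung (C33-34)",
                                      survival_5yr = 0.999))
  est4 <- method_5(rates, surv99, pop, "nat", target_year = 2010)
  expect_match(attr(est4, "unreliable_sites"), "Lung")
  expect_cases(est4, "male", "Lung (C33-34)", 40 / (1 - 0.99), tol = 1e-9)
  expect_error(survival_table(data.frame(sex = "male", site = "x",
                                         survival_5yr = -0.1)), ">= 0")
})

test_that("methods 6/7: degenerate region equals method 2; rate bias transports", {
  years <- 2003:2010
  ev <- flat_events(c("cap", "rest"), years, sites = "Bladder (C67)")
  pop <- flat_population(c("cap", "rest"), years)
  e2 <- method_2(ev, pop, target_year = 2010, datasets = c("cap", "rest"))
  e6 <- method_6(ev, pop, proxy_datasets = c("cap", "rest"),
                 national_datasets = c("cap", "rest"), target_year = 2010)
  expect_equal(as.data.frame(e6)$cases, as.data.frame(e2)$cases,
               tolerance = 1e-12)

  # proxy rates 1.5x the national rates -> estimates 1.5x
  df <- as.data.frame(ev)
  df$count[df$dataset == "cap"] <- df$count[df$dataset == "cap"] * 1.5
  ev2 <- event_table(df, "incidence")
  e7 <- method_7(ev2, pop, proxy_datasets = "cap",
                 national_datasets = c("cap", "rest"), target_year = 2010)
  base <- method_7(ev, pop, proxy_datasets = "cap",
                   national_datasets = c("cap", "rest"), target_year = 2010)
  expect_equal(as.data.frame(e7)$cases, 1.5 * as.data.frame(base)$cases,
               tolerance = 1e-12)
})

test_that("frequency table normalises per sex", {
  ev <- event_table(data.frame(dataset = "nb", year = 2010, sex = "male",
                               site = c("Lung (C33-34)", "Stomach (C16)"),
                               age_group = 10, count = c(30, 70)), "incidence")
  ft <- build_frequency_table(ev, window = 2010)
  expect_equal(ft$proportion[ft$site == "Lung (C33-34)"], 0.3)
  expect_equal(ft$proportion[ft$site == "Stomach (C16)"], 0.7)

  ev2 <- random_events(13, years = 2009:2011)
  ft2 <- build_frequency_table(ev2)
  sums <- tapply(ft2$proportion, ft2$sex, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-9)
  oracle <- stats::aggregate(count ~ sex + site, as.data.frame(ev2), sum)
  oracle$p <- oracle$count / stats::ave(oracle$count, oracle$sex, FUN = sum)
  m <- merge(as.data.frame(ft2), oracle, by = c("sex", "site"))
  expect_equal(m$proportion, m$p)
  expect_error(build_frequency_table(ev, window = 1999), "no rows|zero total")
})

test_that("method 8 partitions the all-sites total exactly", {
  years <- 2009:2011
  ev <- flat_events("nb", years,
                    sites = c("Lung (C33-34)", "Stomach (C16)",
                              "Bladder (C67)"))
  pop <- flat_population(c("nb", "nat"), unique(c(years, 2010)))
  rates <- all_sites_rates(ev, pop, datasets = "nb", window = years)
  freq <- build_frequency_table(ev, datasets = "nb", window = years)
  e8 <- method_8(rates, freq, pop, "nat", target_year = 2010)
  allsites <- apply_rates(rates, canestim:::pool_population(pop, "nat", "national"),
                          "national", 2010)
  d8 <- as.data.frame(e8)
  expect_equal(sum(d8$cases[d8$sex == "male"]),
               sum(allsites$count[allsites$sex == "male"]))  # exact partition

  # a single site with frequency 1 reduces to method 9
  ev1 <- flat_events("nb", years, sites = "Lung (C33-34)")
  r1 <- all_sites_rates(ev1, pop, datasets = "nb", window = years)
  f1 <- build_frequency_table(ev1, datasets = "nb", window = years)
  e8b <- method_8(r1, f1, pop, "nat", target_year = 2010)
  e9 <- method_9(ev1, pop, neighbour_datasets = "nb",
                 national_datasets = "nat", target_year = 2010,
                 window = years)
  d8b <- as.data.frame(e8b)
  d9 <- as.data.frame(e9)
  expect_equal(sum(d8b$cases[d8b$sex == "male"]),
               sum(d9$cases[d9$sex == "male"]), tolerance = 1e-9)

  # frequency table missing a sex is an error
  fm <- f1[f1$sex == "male", , drop = FALSE]
  class(fm) <- class(f1)
  expect_error(method_8(r1, fm, pop, "nat", target_year = 2010), "female")
})

test_that("method 9 pools neighbours person-year weighted", {
  years <- 2009:2011
  # two neighbours: rates 10 and 20 per 1e5, person-years 1e5 and 3e5
  mk <- function(ds, count, py) {
    list(ev = data.frame(dataset = ds, year = years, sex = "male",
                         site = "Lung (C33-34)", age_group = 10,
                         count = count),
         pop = expand.grid(dataset = ds, year = unique(c(years, 2010)),
                           sex = c("male", "female"), age_group = 0:17,
                           stringsAsFactors = FALSE) |>
           cbind(person_years = py))
  }
  a <- mk("n1", 10, 1e5)
  b <- mk("n2", 60, 3e5)
  nat <- mk("nat", 0, 2e5)
  ev <- event_table(rbind(a$ev, b$ev), "incidence")
  pop <- population_table(rbind(a$pop, b$pop, nat$pop))
  e9 <- method_9(ev, pop, neighbour_datasets = c("n1", "n2"),
                 national_datasets = "nat", target_year = 2010)
  pooled_rate <- 1e5 * (10 + 60) / (1e5 + 3e5)   # 17.5, not mean(10, 20)
  expect_cases(e9, "male", "Lung (C33-34)", pooled_rate / 1e5 * 2e5, tol = 1e-9)

  # neighbours identical to the nation reproduce national counts exactly
  inc <- flat_events(c("nat", "nb"), years, sites = "Lung (C33-34)")
  popf <- flat_population(c("nat", "nb"), unique(c(years, 2010)))
  e9b <- method_9(inc, popf, neighbour_datasets = "nb",
                  national_datasets = "nat", target_year = 2010)
  expect_cases(e9b, "male", "Lung (C33-34)", sum(20 + 2 * (0:17)), tol = 1e-9)

  # rates scaled by k scale the estimate by k
  df <- as.data.frame(inc)
  df$count <- df$count * 3
  e9c <- method_9(event_table(df, "incidence"), popf,
                  neighbour_datasets = "nb", national_datasets = "nat",
                  target_year = 2010)
  expect_cases(e9c, "male", "Lung (C33-34)", 3 * sum(20 + 2 * (0:17)),
               tol = 1e-9)
})

test_that("method selection walks the availability priority order", {
  expect_equal(select_method(list(national_incidence_history = TRUE,
                                  neighbour_data = TRUE)), "1")
  expect_equal(select_method(list(recent_national_incidence = TRUE,
                                  national_mortality = TRUE)), "2")
  expect_equal(select_method(list(regional_registries = TRUE,
                                  national_mortality = TRUE)), "3")
  expect_equal(select_method(list(neighbour_data = TRUE,
                                  national_mortality = TRUE)), "4")
  expect_equal(select_method(list(survival = TRUE,
                                  national_mortality = TRUE)), "5")
  expect_equal(select_method(list(regional_registries = TRUE)), "6/7")
  expect_equal(select_method(list(neighbour_data = TRUE,
                                  frequency_data = TRUE)), "8")
  expect_equal(select_method(list(neighbour_data = TRUE)), "9")
  expect_error(select_method(list()), "no estimation method")
})
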