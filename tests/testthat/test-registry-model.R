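test_that("site catalogue partitions sites by sex", {
  expect_length(site_names("male"), 21)
  expect_length(site_names("female"), 23)
  expect_true("Other and unspecified" %in% site_names("male"))
  expect_false("Breast (C50)" %in% site_names("male"))
  expect_false("Prostate (C61)" %in% site_names("female"))
})

test_that("ICD-10 rubrics map to site groups, C44 excluded", {
  expect_equal(icd10_site_group(c("C18", "C19.2", "c20")),
               rep("Colon-rectum (C18-21)", 3))
  expect_equal(icd10_site_group("C96"), "Non-Hodgkin lymphoma (C82-85, C96)")
  expect_equal(icd10_site_group("C26"), "Other and unspecified")
  expect_true(is.na(icd10_site_group("C44")))
  # group labels pass through unchanged
  expect_equal(icd10_site_group("Lung (C33-34)"), "Lung (C33-34)")
})

test_that("event tables validate strata and enforce sex-site restrictions", {
  df <- data.frame(dataset = "x", year = 2010, sex = "male",
                   site = "Cervix (C53)", age_group = 8, count = 1)
  expect_error(event_table(df, "incidence"), "sex-restricted")
  df$site <- "Prostate (C61)"
  expect_silent(event_table(df, "incidence"))
  df$count <- -1
  expect_error(event_table(df, "incidence"), "non-negative")
})

test_that("registry reader parses, validates and aggregates duplicates", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("dataset,year,sex,site,age_group,count",
               "nor,2010,male,C61,10,1",
               "nor,2010,male,C61,11,2",
               "nor,2010,female,C50,9,3"), f)
  ev <- read_registry_table(f, "incidence")
  expect_s3_class(ev, "event_table")
  expect_equal(nrow(ev), 3)
  expect_equal(sum(ev$count), 6)
  expect_equal(sort(unique(ev$site)), c("Breast (C50)", "Prostate (C61)"))

  # duplicate strata are summed with a warning
  writeLines(c("dataset,year,sex,site,age_group,count",
               "nor,2010,male,C61,10,3",
               "nor,2010,male,C61,10,4"), f)
  expect_warning(ev2 <- read_registry_table(f, "incidence"), "duplicate")
  expect_equal(ev2$count, 7)

  # sex-site conflict names the stratum
  writeLines(c("dataset,year,sex,site,age_group,count",
               "nor,2010,male,C53,8,1"), f)
  expect_error(read_registry_table(f, "incidence"), "C53")

  # missing column is a format error; bad rows are reported by number
  writeLines(c("dataset,year,sex,age_group,count", "nor,2010,male,3,1"), f)
  expect_error(read_registry_table(f, "incidence"), "missing column")
  writeLines(c("dataset,year,sex,site,age_group,count",
               "nor,2010,male,C61,10,1",
               "nor,2010,unknown,C61,10,1"), f)
  expect_error(read_registry_table(f, "incidence"), "row\\(s\\) 2")

  # 19 age bands collapse into 85+
  writeLines(c("dataset,year,sex,site,age_group,count",
               "nor,2010,male,C61,85-89,2",
               "nor,2010,male,C61,90+,3"), f)
  expect_warning(ev3 <- read_registry_table(f, "incidence"), "85\\+")
  expect_equal(ev3$age_group, 17L)
  expect_equal(ev3$count, 5)
})

test_that("group_sites sums within groups, conserves totals, is idempotent", {
  df <- data.frame(dataset = "x", year = 2005, sex = "male",
                   site = c("C18", "C19", "C20"), age_group = 12,
                   count = c(5, 2, 3))
  g <- group_sites(event_table(df, "incidence"))
  expect_equal(nrow(g), 1)
  expect_equal(g$site, "Colon-rectum (C18-21)")
  expect_equal(g$count, 10)
  expect_equal(as.data.frame(group_sites(g)), as.data.frame(g))

  # brute-force oracle over random codes
  set.seed(4)
  codes <- sprintf("C%02d", sample(setdiff(0:97, 44), 50, replace = TRUE))
  df <- data.frame(dataset = "x", year = 2005, sex = "female", site = codes,
                   age_group = sample(0:17, 50, replace = TRUE),
                   count = rpois(50, 8))
  df <- df[!canestim:::sex_site_conflict(df$sex, icd10_site_group(df$site)), ]
  grouped <- group_sites(event_table(suppressWarnings(
    stats::aggregate(count ~ dataset + year + sex + site + age_group,
                     df, sum)), "incidence"))
  oracle <- tapply(df$count, icd10_site_group(df$site), sum)
  got <- tapply(grouped$count, grouped$site, sum)
  expect_equal(sum(grouped$count), sum(df$count))  # exact conservation
  expect_equal(as.numeric(got[names(oracle)]), as.numeric(oracle))
})

test_that("C55 reallocation splits proportionally with fallbacks and conserves totals", {
  mk <- function(c53, c54, c55, dataset = "x", year = 2005, age = 10) {
    data.frame(dataset = dataset, year = year, sex = "female",
               site = c("Cervix (C53)", "Corpus uteri (C54)",
                        "Uterus unspecified (C55)"),
               age_group = age, count = c(c53, c54, c55))
  }
  out <- reallocate_unspecified_uterus(event_table(mk(30, 70, 10), "incidence"))
  expect_equal(out$count[out$site == "Cervix (C53)"], 33)
  expect_equal(out$count[out$site == "Corpus uteri (C54)"], 77)
  expect_false("Uterus unspecified (C55)" %in% out$site)

  # cell empty -> dataset-level proportions (25/75)
  df <- rbind(mk(0, 0, 4, age = 3), mk(25, 75, 0, age = 12))
  out <- reallocate_unspecified_uterus(event_table(df, "incidence"))
  expect_equal(out$count[out$site == "Cervix (C53)" & out$age_group == 3], 1)
  expect_equal(out$count[out$site == "Corpus uteri (C54)" & out$age_group == 3], 3)

  # nothing anywhere -> 50/50 with warning
  expect_warning(
    out <- reallocate_unspecified_uterus(event_table(mk(0, 0, 5), "incidence")),
    "50/50")
  expect_equal(sort(out$count), c(2.5, 2.5))

  # no C55 -> identity
  ev <- event_table(mk(10, 20, 0), "incidence")
  out <- reallocate_unspecified_uterus(ev)
  expect_equal(out$count[out$site != "Uterus unspecified (C55)"], c(10, 20))

  # conservation on random data, per cell
  set.seed(9)
  cells <- expand.grid(dataset = c("a", "b"), year = 2004:2005,
                       age = c(5, 9, 13), stringsAsFactors = FALSE)
  df <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    mk(rpois(1, 10), rpois(1, 30), rpois(1, 3), cells$dataset[i],
       cells$year[i], cells$age[i])
  }))
  ev <- event_table(df, "incidence")
  out <- reallocate_unspecified_uterus(ev)
  before <- stats::aggregate(count ~ dataset + year + age_group,
                             as.data.frame(ev), sum)
  after <- stats::aggregate(count ~ dataset + year + age_group,
                            as.data.frame(out), sum)
  expect_equal(after$count, before$count)
})

test_that("rates: definition, zero counts, round trip and linearity", {
  ev <- event_table(data.frame(dataset = "x", year = 2010, sex = "male",
                               site = "Lung (C33-34)", age_group = c(10, 11),
                               count = c(50, 0)), "incidence")
  pop <- population_table(expand.grid(dataset = "x", year = 2010,
                                      sex = c("male", "female"),
                                      age_group = 0:17,
                                      stringsAsFactors = FALSE) |>
                            cbind(person_years = 1e5))
  r <- compute_rates(ev, pop)
  expect_equal(r$rate, c(50, 0))

  # element-wise brute force on random data
  ev2 <- random_events(21, datasets = "x", years = 2010)
  pop2 <- flat_population("x", 2010, py = 2.5e5)
  r2 <- compute_rates(ev2, pop2)
  m <- merge(as.data.frame(ev2), as.data.frame(r2))
  expect_equal(m$rate, 1e5 * m$count / 2.5e5)

  # round trip: apply(compute(E)) == E
  back <- apply_rates(r2, pop2, "x", 2010)
  m <- merge(as.data.frame(ev2), as.data.frame(back),
             by = c("dataset", "year", "sex", "site", "age_group"))
  expect_equal(m$count.y, m$count.x)

  # linearity in person-years
  pop3 <- flat_population("x", 2010, py = 5e5)
  doubled <- apply_rates(r2, pop3, "x", 2010)
  expect_equal(doubled$count, 2 * back$count)

  # missing person-years for a nonzero count is an error naming the stratum
  popbad <- population_table(data.frame(dataset = "x", year = 2010,
                                        sex = "female", age_group = 0:17,
                                        person_years = 1e5))
  expect_error(compute_rates(ev, popbad), "person-years")
})

test_that("gold standard averages annual counts and is linear", {
  df <- data.frame(dataset = "nor", year = rep(2009:2011, each = 1),
                   sex = "male", site = "Prostate (C61)", age_group = 12,
                   count = c(300, 324, 348))
  ev <- event_table(df, "incidence")
  gs <- gold_standard(ev, 2009:2011)
  expect_equal(gs$cases, 324)
  expect_equal(attr(gs, "method"), "observed")
  expect_error(gold_standard(ev, 2008:2011), "2008")

  # linearity: gold(a*E1 + b*E2) = a*gold(E1) + b*gold(E2)
  e1 <- random_events(31, datasets = "nor", years = 2009:2011)
  e2 <- random_events(32, datasets = "nor", years = 2009:2011)
  comb <- suppressWarnings(event_table(rbind(
    within(as.data.frame(e1), count <- 2 * count),
    within(as.data.frame(e2), count <- 3 * count)), "incidence"))
  g1 <- as.data.frame(gold_standard(e1, 2009:2011))
  g2 <- as.data.frame(gold_standard(e2, 2009:2011))
  gc <- as.data.frame(gold_standard(comb, 2009:2011))
  oracle <- merge(g1, g2, by = c("sex", "site"), all = TRUE)
  oracle[is.na(oracle)] <- 0
  oracle$cases <- 2 * oracle$cases.x + 3 * oracle$cases.y
  m <- merge(gc, oracle[c("sex", "site", "cases")], by = c("sex", "site"))
  expect_equal(m$cases.x, m$cases.y)
})

test_that("readers and writers round-trip tables and bundles", {
  for (seed in c(1, 2, 3)) {
    ev <- random_events(seed)
    f <- tempfile(fileext = ".csv")
    write_registry_table(ev, f)
    back <- read_registry_table(f, "incidence")
    expect_equal(as.data.frame(back), as.data.frame(ev))
  }
  pop <- flat_population()
  f <- tempfile(fileext = ".csv")
  write_population_table(pop, f)
  expect_equal(as.data.frame(read_population_table(f)), as.data.frame(pop))

  surv <- survival_table(data.frame(sex = c("male", "female"),
                                    site = "Lung (C33-34)",
                                    survival_5yr = c(0.12, 0.15)))
  write_survival_table(surv, f)
  expect_equal(as.data.frame(read_survival_table(f)), as.data.frame(surv))

  est <- estimate_table(data.frame(sex = "male", site = "Lung (C33-34)",
                                   cases = 123.4),
                        method = "2", target_year = 2010)
  write_estimate_table(est, f)
  back <- read_estimate_table(f)
  expect_equal(as.data.frame(back), as.data.frame(est))
  expect_equal(attr(back, "method"), "2")

  reg <- generate_registry(preset_scenarios(seed = 5)$stable)
  d <- file.path(tempdir(), "bundle-rt")
  write_registry_bundle(reg$bundle, d)
  back <- read_registry_bundle(d)
  expect_equal(as.data.frame(back$incidence), as.data.frame(reg$bundle$incidence))
  expect_equal(as.data.frame(back$population), as.data.frame(reg$bundle$population))
  expect_equal(back$national_datasets, reg$bundle$national_datasets)
  expect_equal(back$capital_dataset, reg$bundle$capital_dataset)
  expect_equal(back$target_year, reg$bundle$target_year)
})
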