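# End-to-end orchestration: run every estimation method a registry bundle
# supports for its target year, compare each against the recorded gold
# standard, and summarise. Methods whose inputs are absent are skipped with
# a recorded reason, mirroring how the method-selection algorithm walks
# data availability.

years_covered <- function(events, datasets, years) {
  df <- as.data.frame(events)
  all(years %in% unique(df$year[df$dataset %in% datasets]))
}

subset_estimate <- function(est, sex) {
  df <- as.data.frame(est)
  estimate_table(df[df$sex == sex, , drop = FALSE],
                 method = estimate_method(est),
                 target_year = estimate_year(est))
}

# Fill an estimate with zero-case rows so its keys match `keys` exactly
# (a stratum absent from a sparse table means zero cases).
align_estimate <- function(est, keys) {
  df <- as.data.frame(est)
  m <- merge(keys, df, by = c("sex", "site"), all.x = TRUE)
  m$cases[is.na(m$cases)] <- 0
  estimate_table(m[c("sex", "site", "cases")],
                 method = estimate_method(est),
                 target_year = estimate_year(est))
}

digest_file <- function(obj) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  utils::write.csv(as.data.frame(obj), f, row.names = FALSE)
  unname(tools::md5sum(f))
}

#' Run the full estimation-versus-gold-standard evaluation
#'
#' Applies every requested estimation method whose inputs the bundle
#' provides, builds the gold standard from the recorded national incidence
#' around the target year, and compares each estimate per sex and for both
#' sexes combined. Methods with missing prerequisites are skipped with a
#' reason rather than failing the run.
#'
#' @param bundle A [registry_bundle()] (e.g. from [generate_registry()] or
#'   [read_registry_bundle()]).
#' @param methods Method labels to attempt (default all:
#'   `c("1A","1B","2","3","4","5","6","7","8","9")`).
#' @param windows List of fit windows, overridable per method:
#'   `long` (default 1983:2007, method 1A), `medium` (1998:2007, 1B),
#'   `recent` (2003:2007, methods 2-7), `mortality` (1988:2007),
#'   `neighbour` (2009:2011, methods 8-9), `gold` (2009:2011).
#' @param sparse_threshold Passed to the projection engines (default 50).
#' @param exclude_from_range Methods left out of the cross-method range
#'   summary (default `"5"`, whose survival inversion is known to blow up
#'   for good-prognosis cancers).
#' @return A list of class `evaluation_run`: `estimates` (per method),
#'   `gold` (per sex), `reports` (per method and sex), `combined` (per
#'   method, both sexes), `range` (cross-method min/max aggregate
#'   difference), `skipped` (named reasons), `manifest`.
#' @export
run_evaluation <- function(bundle,
                           methods = c("1A", "1B", "2", "3", "4", "5",
                                       "6", "7", "8", "9"),
                           windows = list(),
                           sparse_threshold = 50,
                           exclude_from_range = "5") {
  stopifnot(inherits(bundle, "registry_bundle"))
  w <- utils::modifyList(
    list(long = 1983:2007, medium = 1998:2007, recent = 2003:2007,
         mortality = 1988:2007, neighbour = 2009:2011, gold = 2009:2011),
    windows)
  ty <- bundle$target_year
  nat <- bundle$national_datasets
  cap <- bundle$capital_dataset
  noncap <- setdiff(nat, cap)
  nb <- bundle$neighbour_datasets
  inc <- bundle$incidence
  mort <- bundle$mortality
  pop <- bundle$population

  gold_all <- gold_standard(inc, years = w$gold, datasets = nat,
                            target_year = ty)

  have_mort <- !is.null(mort)
  need_mort_proj <- any(c("3", "4", "5") %in% methods) && have_mort &&
    years_covered(mort, nat, w$mortality)
  mort_rates <- if (need_mort_proj) {
    project_mortality(mort, pop, window = w$mortality, target_year = ty,
                      datasets = nat, sparse_threshold = sparse_threshold)
  } else NULL

  estimates <- list()
  skipped <- list()
  run <- function(label, prereq_ok, why, expr) {
    if (!label %in% methods) return(invisible(NULL))
    if (!prereq_ok) {
      skipped[[label]] <<- why
      return(invisible(NULL))
    }
    estimates[[label]] <<- expr()
    invisible(NULL)
  }

  run("1A", years_covered(inc, nat, w$long),
      "national incidence does not cover the long-term window",
      function() method_1a(inc, pop, target_year = ty, fit_window = w$long,
                           datasets = nat,
                           sparse_threshold = sparse_threshold))
  run("1B", years_covered(inc, nat, w$medium),
      "national incidence does not cover the medium-term window",
      function() method_1b(inc, pop, target_year = ty, fit_window = w$medium,
                           datasets = nat,
                           sparse_threshold = sparse_threshold))
  run("2", years_covered(inc, nat, w$recent),
      "national incidence does not cover the recent window",
      function() method_2(inc, pop, target_year = ty,
                          reference_years = w$recent, datasets = nat))
  run("3", !is.null(mort_rates) && length(noncap) > 0,
      "needs projected national mortality and non-capital regional registries",
      function() {
        mi <- compute_mi_ratios(inc, mort, proxy_datasets = noncap,
                                neighbour_datasets = nb,
                                national_mortality =
                                  pool_datasets(mort, nat, "national"),
                                reference_years = w$recent)
        method_3(mort_rates, mi, pop, nat, target_year = ty)
      })
  run("4", !is.null(mort_rates) && length(nb) > 0,
      "needs projected national mortality and neighbour registries",
      function() {
        mi <- compute_mi_ratios(inc, mort, proxy_datasets = nb,
                                reference_years = w$recent)
        method_4(mort_rates, mi, pop, nat, target_year = ty)
      })
  run("5", !is.null(mort_rates) && !is.null(bundle$survival),
      "needs projected national mortality and a survival table",
      function() method_5(mort_rates, bundle$survival, pop, nat,
                          target_year = ty))
  run("6", length(noncap) > 0 && years_covered(inc, noncap, w$recent),
      "needs non-capital regional registries over the recent window",
      function() method_6(inc, pop, proxy_datasets = noncap,
                          national_datasets = nat, target_year = ty,
                          reference_years = w$recent))
  run("7", !is.null(cap) && years_covered(inc, cap, w$recent),
      "needs the capital-region registry over the recent window",
      function() method_7(inc, pop, proxy_datasets = cap,
                          national_datasets = nat, target_year = ty,
                          reference_years = w$recent))
  run("8", length(nb) > 0 && years_covered(inc, nb, w$neighbour),
      "needs neighbour registries over the neighbour window",
      function() {
        rates <- all_sites_rates(inc, pop, datasets = nb, window = w$neighbour)
        freq <- build_frequency_table(inc, datasets = nb, window = w$neighbour)
        method_8(rates, freq, pop, nat, target_year = ty)
      })
  run("9", length(nb) > 0 && years_covered(inc, nb, w$neighbour),
      "needs neighbour registries over the neighbour window",
      function() method_9(inc, pop, neighbour_datasets = nb,
                          national_datasets = nat, target_year = ty,
                          window = w$neighbour))

  if (!length(estimates)) {
    stop_canestim("run_evaluation: no estimation method is runnable on this bundle")
  }

  keys <- unique(as.data.frame(gold_all)[c("sex", "site")])
  sexes <- sort(unique(keys$sex))
  gold <- lapply(stats::setNames(sexes, sexes),
                 function(sx) subset_estimate(gold_all, sx))
  reports <- list()
  combined <- list()
  for (label in names(estimates)) {
    est <- align_estimate(estimates[[label]], keys)
    per_sex <- lapply(stats::setNames(sexes, sexes), function(sx) {
      compare_estimates(subset_estimate(est, sx), gold[[sx]])
    })
    reports[[label]] <- per_sex
    combined[[label]] <- if (length(sexes) == 2) {
      combine_sexes(per_sex$male, per_sex$female)
    } else per_sex[[1]]
  }
  flat <- unlist(reports, recursive = FALSE)
  range_summary <- method_range_summary(flat,
                                        exclude_methods = exclude_from_range)

  manifest <- list(
    package_version = as.character(utils::packageVersion("canestim")),
    target_year = ty,
    methods_run = names(estimates),
    methods_skipped = skipped,
    windows = w,
    sparse_threshold = sparse_threshold,
    input_digests = c(
      incidence = digest_file(inc),
      mortality = if (have_mort) digest_file(mort) else NA_character_,
      population = digest_file(pop)))

  structure(list(estimates = estimates, gold = gold, reports = reports,
                 combined = combined, range = range_summary,
                 skipped = skipped, manifest = manifest),
            class = "evaluation_run")
}

#' @export
print.evaluation_run <- function(x, ...) {
  cat(sprintf("<evaluation_run: target year %d>\n", x$manifest$target_year))
  for (label in names(x$combined)) {
    r <- x$combined[[label]]
    cat(sprintf("  method %-2s: aggregate %.1f%% (%s cases; under %s / over %s)\n",
                label, r$aggregate_pct, format(r$aggregate_abs),
                format(r$under_total), format(r$over_total)))
  }
  if (length(x$skipped)) {
    cat("  skipped:", paste(names(x$skipped), collapse = ", "), "\n")
  }
  invisible(x)
}
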