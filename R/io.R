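# Delimited-text I/O. Comma is the default separator; tab-separated files
# are detected from the header line. All writers produce files that
# round-trip exactly through the corresponding reader.

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

read_delim_checked <- function(path, required, what) {
  if (!file.exists(path)) stop_canestim("%s: file not found: %s", what, path)
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "", fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_canestim("%s: missing column(s) %s in %s", what,
                  paste(missing_cols, collapse = ", "), path)
  }
  df
}

#' Read a stratified registry event table from a delimited file
#'
#' Expects a long-format file with header columns `dataset`, `year`, `sex`,
#' `site` (group label or raw ICD-10 code), `age_group` (band index 0-17 or
#' label such as `"0-4"`, `"85+"`), `count`. Raw ICD-10 codes are mapped to
#' site groups; non-melanoma skin (C44) and non-cancer codes are dropped
#' with a warning; duplicate strata are summed with a warning.
#'
#' @param path File path (comma- or tab-separated, UTF-8).
#' @param kind `"incidence"` or `"mortality"`.
#' @return An [event_table()].
#' @export
read_registry_table <- function(path, kind = c("incidence", "mortality")) {
  kind <- match.arg(kind)
  df <- read_delim_checked(
    path, c("dataset", "year", "sex", "site", "age_group", "count"),
    "registry table")
  bad_sex <- !df$sex %in% c("male", "female")
  age_idx <- parse_age_group(df$age_group)
  bad_age <- is.na(age_idx) | !(age_idx %in% 0:18)
  if (any(bad_sex) || any(bad_age)) {
    rows <- sort(unique(c(which(bad_sex), which(bad_age))))
    stop_canestim("registry table %s: invalid sex or age_group in data row(s) %s",
                  path, paste(utils::head(rows, 10), collapse = ", "))
  }
  if (any(is.na(suppressWarnings(as.numeric(df$count))) |
          as.numeric(df$count) < 0)) {
    rows <- which(is.na(suppressWarnings(as.numeric(df$count))) |
                    as.numeric(df$count) < 0)
    stop_canestim("registry table %s: negative or non-numeric count in data row(s) %s",
                  path, paste(utils::head(rows, 10), collapse = ", "))
  }
  grp <- icd10_site_group(df$site)
  if (any(is.na(grp))) {
    warn_canestim("registry table: dropping %d row(s) with non-melanoma-skin or non-cancer codes (%s)",
                  sum(is.na(grp)),
                  paste(utils::head(unique(df$site[is.na(grp)]), 5), collapse = ", "))
    df <- df[!is.na(grp), , drop = FALSE]
    grp <- grp[!is.na(grp)]
  }
  df$site <- grp
  event_table(df, kind)
}

#' Read a person-years table
#'
#' Columns: `dataset`, `year`, `sex`, `age_group`, `person_years`.
#' @param path File path.
#' @return A [population_table()].
#' @export
read_population_table <- function(path) {
  df <- read_delim_checked(
    path, c("dataset", "year", "sex", "age_group", "person_years"),
    "population table")
  population_table(df)
}

#' Read a 5-year relative survival table
#'
#' Columns: `sex`, `site`, `survival_5yr`.
#' @param path File path.
#' @return A [survival_table()].
#' @export
read_survival_table <- function(path) {
  df <- read_delim_checked(path, c("sex", "site", "survival_5yr"),
                           "survival table")
  survival_table(df)
}

write_delim_canonical <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, qmethod = "double",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write core tables to delimited files
#'
#' Column order is fixed so repeated writes of the same object are
#' byte-identical; all writers round-trip through the matching reader.
#'
#' @param x Table to write.
#' @param path Output file path (directories are created as needed).
#' @return The path, invisibly.
#' @export
write_registry_table <- function(x, path) {
  stopifnot(inherits(x, "event_table"))
  write_delim_canonical(as.data.frame(x), path)
}

#' @rdname write_registry_table
#' @export
write_population_table <- function(x, path) {
  stopifnot(inherits(x, "population_table"))
  write_delim_canonical(as.data.frame(x), path)
}

#' @rdname write_registry_table
#' @export
write_survival_table <- function(x, path) {
  stopifnot(inherits(x, "survival_table"))
  write_delim_canonical(as.data.frame(x), path)
}

#' Write / read an estimate table
#'
#' Serialized long format with constant `method` and `target_year` columns.
#'
#' @param x An [estimate_table()].
#' @param path File path.
#' @return `write_estimate_table`: the path, invisibly;
#'   `read_estimate_table`: an [estimate_table()].
#' @export
write_estimate_table <- function(x, path) {
  stopifnot(inherits(x, "estimate_table"))
  df <- as.data.frame(x)
  df <- data.frame(method = estimate_method(x), target_year = estimate_year(x),
                   df, stringsAsFactors = FALSE)
  write_delim_canonical(df, path)
}

#' @rdname write_estimate_table
#' @export
read_estimate_table <- function(path) {
  df <- read_delim_checked(path, c("method", "target_year", "sex", "site", "cases"),
                           "estimate table")
  estimate_table(df[c("sex", "site", "cases")],
                 method = df$method[1], target_year = df$target_year[1])
}

#' Bundle the inputs of a full estimation run
#'
#' A registry bundle holds everything the nine estimation methods consume:
#' incidence and mortality event tables covering the national regions and
#' the neighbouring countries, the matching person-years, the survival
#' table, and the roles of each dataset. National totals are always the sum
#' over `national_datasets`.
#'
#' @param incidence,mortality [event_table()]s (mortality may be `NULL`).
#' @param population A [population_table()] covering every dataset.
#' @param survival A [survival_table()] or `NULL`.
#' @param national_datasets Dataset labels making up the target country.
#' @param capital_dataset The single capital region (used by method 7; its
#'   complement backs methods 3 and 6).
#' @param neighbour_datasets Dataset labels of neighbouring countries.
#' @param target_year Year the estimates refer to.
#' @return A `registry_bundle`.
#' @export
registry_bundle <- function(incidence, mortality, population, survival,
                            national_datasets, capital_dataset,
                            neighbour_datasets, target_year) {
  stopifnot(inherits(incidence, "event_table"),
            inherits(population, "population_table"))
  if (!is.null(mortality)) stopifnot(inherits(mortality, "event_table"))
  if (!is.null(survival)) stopifnot(inherits(survival, "survival_table"))
  if (length(capital_dataset) > 1 ||
      (length(capital_dataset) == 1 && !capital_dataset %in% national_datasets)) {
    stop_canestim("registry bundle: capital_dataset must be one of the national datasets")
  }
  structure(list(incidence = incidence, mortality = mortality,
                 population = population, survival = survival,
                 national_datasets = national_datasets,
                 capital_dataset = capital_dataset,
                 neighbour_datasets = neighbour_datasets,
                 target_year = as.integer(target_year)),
            class = "registry_bundle")
}

#' @export
print.registry_bundle <- function(x, ...) {
  cat("<registry_bundle>\n")
  cat(sprintf("  national: %s (capital: %s)\n",
              paste(x$national_datasets, collapse = ", "),
              x$capital_dataset %||% "none"))
  cat(sprintf("  neighbours: %s\n",
              if (length(x$neighbour_datasets)) paste(x$neighbour_datasets, collapse = ", ") else "none"))
  cat(sprintf("  target year: %d; mortality: %s; survival: %s\n",
              x$target_year,
              if (is.null(x$mortality)) "absent" else "present",
              if (is.null(x$survival)) "absent" else "present"))
  invisible(x)
}

#' Write / read a registry bundle as a directory of delimited files
#'
#' Layout: `incidence.csv`, `mortality.csv`, `population.csv`,
#' `survival.csv`, `meta.csv`. Absent components are simply not written.
#'
#' @param bundle A [registry_bundle()].
#' @param dir Directory path.
#' @return `write_registry_bundle`: `dir`, invisibly;
#'   `read_registry_bundle`: a [registry_bundle()].
#' @export
write_registry_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "registry_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_registry_table(bundle$incidence, file.path(dir, "incidence.csv"))
  if (!is.null(bundle$mortality)) {
    write_registry_table(bundle$mortality, file.path(dir, "mortality.csv"))
  }
  write_population_table(bundle$population, file.path(dir, "population.csv"))
  if (!is.null(bundle$survival)) {
    write_survival_table(bundle$survival, file.path(dir, "survival.csv"))
  }
  meta <- data.frame(
    key = c("national_datasets", "capital_dataset", "neighbour_datasets",
            "target_year"),
    value = c(paste(bundle$national_datasets, collapse = ";"),
              bundle$capital_dataset %||% "",
              paste(bundle$neighbour_datasets, collapse = ";"),
              as.character(bundle$target_year)),
    stringsAsFactors = FALSE)
  write_delim_canonical(meta, file.path(dir, "meta.csv"))
  invisible(dir)
}

#' @rdname write_registry_bundle
#' @export
read_registry_bundle <- function(dir) {
  meta <- read_delim_checked(file.path(dir, "meta.csv"), c("key", "value"),
                             "bundle meta")
  get_meta <- function(k) meta$value[match(k, meta$key)]
  split_meta <- function(k) {
    v <- get_meta(k)
    if (is.na(v) || !nzchar(v)) character(0) else strsplit(v, ";", fixed = TRUE)[[1]]
  }
  mort_path <- file.path(dir, "mortality.csv")
  surv_path <- file.path(dir, "survival.csv")
  cap <- get_meta("capital_dataset")
  registry_bundle(
    incidence = read_registry_table(file.path(dir, "incidence.csv"), "incidence"),
    mortality = if (file.exists(mort_path)) read_registry_table(mort_path, "mortality") else NULL,
    population = read_population_table(file.path(dir, "population.csv")),
    survival = if (file.exists(surv_path)) read_survival_table(surv_path) else NULL,
    national_datasets = split_meta("national_datasets"),
    capital_dataset = if (is.na(cap) || !nzchar(cap)) NULL else cap,
    neighbour_datasets = split_meta("neighbour_datasets"),
    target_year = as.integer(get_meta("target_year")))
}
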