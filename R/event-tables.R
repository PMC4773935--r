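# Core stratified-table classes. All are thin data.frame subclasses in long
# format; a missing stratum always means a zero count, never missing data,
# so sparse registry extracts are valid inputs.

AGE_LABELS <- c(paste(seq(0, 80, 5), seq(4, 84, 5), sep = "-"), "85+")

#' Five-year age band labels
#'
#' Age is carried everywhere as an integer band index 0-17 mapping to
#' 0-4, 5-9, ..., 80-84, 85+.
#'
#' @param index Integer vector of band indices (0-17).
#' @return Character labels.
#' @export
age_band_label <- function(index = 0:17) {
  stopifnot(all(index %in% 0:17))
  AGE_LABELS[index + 1]
}

# Midpoint in years of each band (85+ assigned 90) for synthetic age curves.
age_band_midpoint <- function(index) {
  ifelse(index == 17, 90, index * 5 + 2.5)
}

parse_age_group <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  x <- trimws(as.character(x))
  num <- suppressWarnings(as.integer(x))
  lab <- match(x, AGE_LABELS) - 1L
  out <- ifelse(is.na(num), lab, num)
  # 19-band inputs: 85-89 joins 85+; 90+ is flagged (18) for the caller to
  # collapse with a warning
  out[x == "85-89"] <- 17L
  out[x == "90+"] <- 18L
  as.integer(out)
}

canonical_order <- function(df) {
  keys <- intersect(c("dataset", "year", "sex", "site", "age_group"), names(df))
  df[do.call(order, df[keys]), , drop = FALSE]
}

validate_strata <- function(df, what) {
  if (!all(df$sex %in% c("male", "female"))) {
    bad <- unique(df$sex[!df$sex %in% c("male", "female")])
    stop_canestim("%s: invalid sex value(s): %s", what,
                  paste(bad, collapse = ", "))
  }
  if (any(is.na(df$age_group)) || !all(df$age_group %in% 0:17)) {
    stop_canestim("%s: age_group indices must be integers in 0..17", what)
  }
  if ("site" %in% names(df)) {
    bad <- sex_site_conflict(df$sex, df$site)
    if (any(bad)) {
      i <- which(bad)[1]
      stop_canestim(
        "%s: sex-restricted site '%s' appears with sex '%s' (dataset %s, year %s)",
        what, df$site[i], df$sex[i],
        df$dataset[i] %||% "?", df$year[i] %||% "?")
    }
  }
  invisible(df)
}

#' Construct a stratified event-count table
#'
#' The universal input type: incidence or mortality counts keyed by dataset
#' (country or region), calendar year, sex, site group, and 5-year age band.
#'
#' @param records Data frame with columns `dataset`, `year`, `sex`, `site`,
#'   `age_group`, `count`.
#' @param kind `"incidence"` or `"mortality"`.
#' @return An `event_table` (a data frame with a `kind` attribute).
#' @export
event_table <- function(records, kind = c("incidence", "mortality")) {
  kind <- match.arg(kind)
  req <- c("dataset", "year", "sex", "site", "age_group", "count")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop_canestim("event table: missing column(s): %s",
                  paste(missing_cols, collapse = ", "))
  }
  records <- records[req]
  records$dataset <- as.character(records$dataset)
  records$year <- as.integer(records$year)
  records$sex <- as.character(records$sex)
  records$site <- as.character(records$site)
  records$age_group <- parse_age_group(records$age_group)
  records$count <- as.numeric(records$count)
  if (any(records$age_group == 18L, na.rm = TRUE)) {
    warn_canestim("event table: 19 age bands supplied; collapsing 85-89/90+ into 85+")
    records$age_group[records$age_group == 18L] <- 17L
    records <- aggregate_counts(records)
  }
  if (any(is.na(records$count)) || any(records$count < 0)) {
    stop_canestim("event table: counts must be non-negative and non-missing")
  }
  validate_strata(records, "event table")
  key <- do.call(paste, c(records[c("dataset", "year", "sex", "site", "age_group")],
                          sep = "\r"))
  if (anyDuplicated(key)) {
    warn_canestim("event table: duplicate strata found; counts summed")
    records <- aggregate_counts(records)
  }
  records <- canonical_order(records)
  rownames(records) <- NULL
  structure(records, kind = kind,
            class = c("event_table", "data.frame"))
}

aggregate_counts <- function(records) {
  cols <- c("dataset", "year", "sex", "site", "age_group", "count")
  if (!nrow(records)) return(records[cols])
  out <- stats::aggregate(
    count ~ dataset + year + sex + site + age_group,
    data = records, FUN = sum)
  out
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table: %s, %d strata, total %s>\n",
              attr(x, "kind"), nrow(x),
              format(sum(x$count), big.mark = " ")))
  if (nrow(x)) {
    cat(sprintf("  datasets: %s; years %d-%d\n",
                paste(sort(unique(x$dataset)), collapse = ", "),
                min(x$year), max(x$year)))
  }
  invisible(x)
}

event_kind <- function(events) attr(events, "kind") %||% "incidence"

#' Construct a person-years table
#'
#' @param records Data frame with columns `dataset`, `year`, `sex`,
#'   `age_group`, `person_years` (positive).
#' @return A `population_table`.
#' @export
population_table <- function(records) {
  req <- c("dataset", "year", "sex", "age_group", "person_years")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop_canestim("population table: missing column(s): %s",
                  paste(missing_cols, collapse = ", "))
  }
  records <- records[req]
  records$dataset <- as.character(records$dataset)
  records$year <- as.integer(records$year)
  records$sex <- as.character(records$sex)
  records$age_group <- parse_age_group(records$age_group)
  records$person_years <- as.numeric(records$person_years)
  if (any(records$age_group == 18L, na.rm = TRUE)) {
    warn_canestim("population table: collapsing 85-89/90+ into 85+")
    records$age_group[records$age_group == 18L] <- 17L
    records <- stats::aggregate(person_years ~ dataset + year + sex + age_group,
                                data = records, FUN = sum)
  }
  if (any(is.na(records$person_years)) || any(records$person_years <= 0)) {
    stop_canestim("population table: person-years must be positive")
  }
  validate_strata(records, "population table")
  records <- canonical_order(records)
  rownames(records) <- NULL
  structure(records, class = c("population_table", "data.frame"))
}

#' @export
print.population_table <- function(x, ...) {
  cat(sprintf("<population_table: %d strata, %s person-years>\n",
              nrow(x), format(sum(x$person_years), big.mark = " ")))
  invisible(x)
}

#' Construct a rate table (per 100,000 person-years)
#'
#' @param records Data frame with columns `sex`, `site`, `age_group`, `rate`
#'   and optionally `dataset` and/or `year`.
#' @return A `rate_table`.
#' @export
rate_table <- function(records) {
  req <- c("sex", "site", "age_group", "rate")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop_canestim("rate table: missing column(s): %s",
                  paste(missing_cols, collapse = ", "))
  }
  keep <- c(intersect(c("dataset", "year"), names(records)), req)
  records <- records[keep]
  records$age_group <- parse_age_group(records$age_group)
  records$rate <- as.numeric(records$rate)
  if (any(!is.finite(records$rate)) || any(records$rate < 0)) {
    stop_canestim("rate table: rates must be finite and non-negative")
  }
  validate_strata(records, "rate table")
  records <- canonical_order(records)
  rownames(records) <- NULL
  structure(records, class = c("rate_table", "data.frame"))
}

#' Construct a 5-year relative survival table
#'
#' Survival is carried at sex-by-site granularity, the resolution at which
#' registry survival summaries are published. Values may marginally exceed 1
#' (relative survival above that of the general population).
#'
#' @param records Data frame with columns `sex`, `site`, `survival_5yr`.
#' @return A `survival_table`.
#' @export
survival_table <- function(records) {
  req <- c("sex", "site", "survival_5yr")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop_canestim("survival table: missing column(s): %s",
                  paste(missing_cols, collapse = ", "))
  }
  records <- records[req]
  records$survival_5yr <- as.numeric(records$survival_5yr)
  if (any(is.na(records$survival_5yr)) || any(records$survival_5yr < 0)) {
    stop_canestim("survival table: survival proportions must be >= 0")
  }
  records <- records[order(records$sex, records$site), , drop = FALSE]
  rownames(records) <- NULL
  structure(records, class = c("survival_table", "data.frame"))
}

#' Construct an estimate table
#'
#' One estimation method's national case estimates for a target year, by sex
#' and site, optionally carrying age-resolved detail whose totals must match.
#'
#' @param records Data frame with columns `sex`, `site`, `cases`
#'   (non-negative reals; rounding happens only at report time), or `NULL` to
#'   derive totals from `detail`.
#' @param method Method label (`"1A"`, `"1B"`, `"2"` ... `"9"`, or
#'   `"observed"` for a gold standard).
#' @param target_year Calendar year the estimate refers to.
#' @param detail Optional data frame `sex`, `site`, `age_group`, `cases`.
#' @return An `estimate_table`.
#' @export
estimate_table <- function(records = NULL, method, target_year, detail = NULL) {
  if (is.null(records)) {
    if (is.null(detail)) stop_canestim("estimate table: need records or detail")
    records <- stats::aggregate(cases ~ sex + site, data = detail, FUN = sum)
  }
  req <- c("sex", "site", "cases")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop_canestim("estimate table: missing column(s): %s",
                  paste(missing_cols, collapse = ", "))
  }
  records <- records[req]
  records$cases <- as.numeric(records$cases)
  if (any(is.na(records$cases)) || any(records$cases < 0)) {
    stop_canestim("estimate table: cases must be non-negative")
  }
  if (!is.null(detail)) {
    tot <- stats::aggregate(cases ~ sex + site, data = detail, FUN = sum)
    m <- merge(records, tot, by = c("sex", "site"),
               suffixes = c("", ".detail"), all = TRUE)
    if (any(is.na(m$cases)) || any(is.na(m$cases.detail)) ||
        max(abs(m$cases - m$cases.detail)) > 1e-8 * (1 + max(m$cases))) {
      stop_canestim("estimate table: age-resolved detail does not reproduce totals")
    }
  }
  records <- records[order(records$sex, records$site), , drop = FALSE]
  rownames(records) <- NULL
  structure(records, method = as.character(method),
            target_year = as.integer(target_year), detail = detail,
            class = c("estimate_table", "data.frame"))
}

#' @export
print.estimate_table <- function(x, ...) {
  cat(sprintf("<estimate_table: method %s, target year %d>\n",
              attr(x, "method"), attr(x, "target_year")))
  df <- as.data.frame(x)
  df$cases <- round_half_away(df$cases)
  print(df, row.names = FALSE)
  invisible(x)
}

estimate_method <- function(x) attr(x, "method")
estimate_year <- function(x) attr(x, "target_year")
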