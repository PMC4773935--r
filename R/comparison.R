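# Validation arithmetic: per-site differences between an estimate and the
# recorded gold standard, with under- and over-estimation reported
# separately so that opposite-signed site errors cannot cancel in the
# aggregate. The aggregate percentage difference is
# 100 * sum(|diff|) / sum(observed).

#' Compare an estimate against the observed gold standard
#'
#' Estimates are rounded to whole cases (half away from zero) before
#' differencing, matching publication practice; percentage differences are
#' rounded to one decimal. Sites with zero observed cases get an undefined
#' (NA) percentage.
#'
#' @param estimate An [estimate_table()].
#' @param observed An [estimate_table()] of recorded cases (the gold
#'   standard), with the same sex/site keys.
#' @return A `comparison_report`: list with `method`, `sex`, `per_site`
#'   (site, observed, estimated, diff, pct_diff), `under_total` (cases
#'   underestimated, as a positive number), `over_total` (cases
#'   overestimated), `aggregate_abs` (= under + over), `aggregate_pct`.
#' @export
compare_estimates <- function(estimate, observed) {
  stopifnot(inherits(estimate, "estimate_table"),
            inherits(observed, "estimate_table"))
  est <- as.data.frame(estimate)
  obs <- as.data.frame(observed)
  m <- merge(obs, est, by = c("sex", "site"), all = TRUE,
             suffixes = c("_obs", "_est"))
  if (any(is.na(m$cases_obs)) || any(is.na(m$cases_est))) {
    missing_keys <- m[is.na(m$cases_obs) | is.na(m$cases_est), c("sex", "site")]
    stop_canestim("compare_estimates: sex/site keys differ (%s)",
                  paste(missing_keys$site, "(", missing_keys$sex, ")",
                        collapse = ", "))
  }
  m$observed <- round_half_away(m$cases_obs)
  m$estimated <- round_half_away(m$cases_est)
  m$diff <- m$estimated - m$observed
  m$pct_diff <- ifelse(m$observed == 0,
                       ifelse(m$diff == 0, 0, NA_real_),
                       round_half_away(100 * m$diff / m$observed, 1))
  per_site <- m[order(m$sex, m$site),
                c("sex", "site", "observed", "estimated", "diff", "pct_diff")]
  rownames(per_site) <- NULL
  sexes <- unique(per_site$sex)
  new_comparison_report(
    method = estimate_method(estimate),
    sex = if (length(sexes) == 1) sexes else "both",
    per_site = per_site)
}

new_comparison_report <- function(method, sex, per_site) {
  under <- sum(abs(per_site$diff[per_site$diff < 0]))
  over <- sum(per_site$diff[per_site$diff > 0])
  total_obs <- sum(per_site$observed)
  agg_abs <- under + over
  structure(list(
    method = method, sex = sex, per_site = per_site,
    under_total = under, over_total = over,
    aggregate_abs = agg_abs,
    total_observed = total_obs,
    aggregate_pct = if (total_obs > 0) {
      round_half_away(100 * agg_abs / total_obs, 1)
    } else 0
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Comparison with observed cases: method %s (%s)\n",
              x$method, x$sex))
  print(x$per_site, row.names = FALSE)
  cat(sprintf("underestimated: %s cases; overestimated: %s cases\n",
              format(x$under_total), format(x$over_total)))
  cat(sprintf("aggregate difference: %s cases (%.1f%% of %s observed)\n",
              format(x$aggregate_abs), x$aggregate_pct,
              format(x$total_observed)))
  invisible(x)
}

#' Combine per-sex comparison reports
#'
#' Site-wise concatenation of a male and a female report for the same
#' method; totals and the aggregate percentage are recomputed over the
#' union.
#'
#' @param male,female `comparison_report`s with matching `method`.
#' @return A `comparison_report` with `sex = "both"`.
#' @export
combine_sexes <- function(male, female) {
  stopifnot(inherits(male, "comparison_report"),
            inherits(female, "comparison_report"))
  if (!identical(male$method, female$method)) {
    stop_canestim("combine_sexes: reports come from different methods (%s vs %s)",
                  male$method, female$method)
  }
  per_site <- rbind(male$per_site, female$per_site)
  rownames(per_site) <- NULL
  new_comparison_report(male$method, "both", per_site)
}

#' Recompute a report over a subset of sites
#'
#' @param report A `comparison_report`.
#' @param excluded_sites Site labels to drop (e.g. screening-driven sites
#'   such as prostate and breast).
#' @return A `comparison_report` over the remaining sites.
#' @export
exclusion_variant <- function(report, excluded_sites) {
  stopifnot(inherits(report, "comparison_report"))
  keep <- !report$per_site$site %in% excluded_sites
  new_comparison_report(report$method, report$sex,
                        report$per_site[keep, , drop = FALSE])
}

#' Range of aggregate differences across methods
#'
#' The minimum and maximum aggregate percentage difference over a set of
#' reports (typically method-by-sex), each with its companion absolute
#' difference.
#'
#' @param reports List of `comparison_report`s.
#' @param exclude_methods Method labels dropped before summarising (e.g.
#'   `"5"`).
#' @return A list: `min_pct`, `min_abs`, `max_pct`, `max_abs`, and the
#'   identifying `min_method`/`max_method` labels.
#' @export
method_range_summary <- function(reports, exclude_methods = character(0)) {
  keep <- vapply(reports, function(r) !r$method %in% exclude_methods, TRUE)
  reports <- reports[keep]
  if (!length(reports)) stop_canestim("method_range_summary: no reports left")
  pct <- vapply(reports, function(r) r$aggregate_pct, 0)
  abs_ <- vapply(reports, function(r) r$aggregate_abs, 0)
  lab <- vapply(reports, function(r) paste0(r$method, "/", r$sex), "")
  i <- which.min(pct)
  j <- which.max(pct)
  list(min_pct = pct[i], min_abs = abs_[i], min_method = lab[i],
       max_pct = pct[j], max_abs = abs_[j], max_method = lab[j])
}

#' Render comparison reports as publication-style delimited tables
#'
#' Writes one wide table per sex (observed column, then one
#' `estimated (pct)` pair per method in label order) plus a summary file of
#' under/over totals and aggregates. Deterministic: repeated calls on the
#' same reports are byte-identical.
#'
#' @param reports List of `comparison_report`s (one per method per sex).
#' @param dir Output directory.
#' @return Character vector of files written, invisibly.
#' @export
render_tables <- function(reports, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sexes <- sort(unique(vapply(reports, function(r) r$sex, "")))
  method_order <- c("1A", "1B", as.character(2:9))
  files <- character(0)
  for (sx in sexes) {
    rs <- reports[vapply(reports, function(r) r$sex == sx, TRUE)]
    meths <- vapply(rs, function(r) r$method, "")
    rs <- rs[order(match(meths, method_order))]
    base <- rs[[1]]$per_site[c("site", "observed")]
    for (r in rs) {
      stopifnot(identical(r$per_site$site, base$site))
      base[[paste0("method_", r$method)]] <- r$per_site$estimated
      base[[paste0("method_", r$method, "_pct")]] <-
        sprintf("(%.1f)", r$per_site$pct_diff)
    }
    f <- file.path(dir, sprintf("comparison_%s.csv", sx))
    write_delim_canonical(base, f)
    files <- c(files, f)
  }
  summ <- do.call(rbind, lapply(reports, function(r) {
    data.frame(method = r$method, sex = r$sex,
               underestimated = r$under_total, overestimated = r$over_total,
               aggregate_abs = r$aggregate_abs,
               aggregate_pct = r$aggregate_pct,
               total_observed = r$total_observed, stringsAsFactors = FALSE)
  }))
  summ <- summ[order(match(summ$method, method_order), summ$sex), , drop = FALSE]
  f <- file.path(dir, "summary.csv")
  write_delim_canonical(summ, f)
  invisible(c(files, f))
}
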