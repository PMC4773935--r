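#' Group raw ICD-10 coded counts into the site catalogue
#'
#' Sums counts within the fixed site groups (see [site_catalogue()]). Input
#' rows already labelled with group names pass through unchanged, so the
#' operation is idempotent. The total count is conserved exactly, except for
#' non-melanoma skin (C44), which is excluded from the catalogue and dropped
#' with a warning. Labels that are neither catalogue groups nor parseable
#' ICD-10 rubrics are absorbed into "Other and unspecified" with a warning.
#'
#' @param events An [event_table()].
#' @return An [event_table()] with `site` restricted to catalogue groups
#'   (plus the C55 staging group if present).
#' @export
group_sites <- function(events) {
  stopifnot(inherits(events, "event_table"))
  df <- as.data.frame(events)
  grp <- icd10_site_group(df$site)
  rubric <- toupper(sub("\\..*$", "", trimws(df$site)))
  is_c44 <- is.na(grp) & rubric == "C44"
  if (any(is_c44)) {
    warn_canestim("group_sites: dropping %d non-melanoma skin (C44) row(s)",
                  sum(is_c44))
    df <- df[!is_c44, , drop = FALSE]
    grp <- grp[!is_c44]
  }
  if (any(is.na(grp))) {
    warn_canestim("group_sites: %d row(s) with unrecognised site label(s) (%s) absorbed into 'Other and unspecified'",
                  sum(is.na(grp)),
                  paste(utils::head(unique(df$site[is.na(grp)]), 5), collapse = ", "))
    grp[is.na(grp)] <- "Other and unspecified"
  }
  df$site <- grp
  event_table(suppressWarnings(aggregate_counts(df)), event_kind(events))
}

#' Reallocate unspecified uterine cancers (C55) to cervix and corpus
#'
#' Each C55 count is split between cervix (C53) and corpus uteri (C54) in
#' proportion to the counts of those two sites in the same
#' (dataset, year, age band) cell. Where both are zero in the cell, the
#' dataset-level proportions (across all years and ages) are used; where
#' those are also zero the count is split 50/50 with a warning. The total
#' uterine count (C53 + C54 + C55) in each cell is conserved exactly, and
#' counts are real-valued afterwards.
#'
#' @param events An [event_table()] (incidence or mortality).
#' @return An [event_table()] without the C55 staging group.
#' @export
reallocate_unspecified_uterus <- function(events) {
  stopifnot(inherits(events, "event_table"))
  df <- as.data.frame(events)
  if (any(df$site == C55_GROUP & df$sex == "male")) {
    stop_canestim("C55 present in a male stratum")
  }
  is55 <- df$site == C55_GROUP
  if (!any(is55)) {
    return(event_table(df[!is55, , drop = FALSE], event_kind(events)))
  }
  c55 <- df[is55, , drop = FALSE]
  rest <- df[!is55, , drop = FALSE]

  cell_key <- function(d) paste(d$dataset, d$year, d$age_group, sep = "\r")
  lookup <- function(site, keys, by_dataset = FALSE) {
    sub <- rest[rest$site == site & rest$sex == "female", , drop = FALSE]
    if (!nrow(sub)) return(numeric(length(keys)))
    if (by_dataset) {
      agg <- stats::aggregate(count ~ dataset, data = sub, FUN = sum)
      out <- agg$count[match(keys, agg$dataset)]
    } else {
      agg_key <- cell_key(sub)
      agg <- tapply(sub$count, agg_key, sum)
      out <- as.numeric(agg[match(keys, names(agg))])
    }
    ifelse(is.na(out), 0, out)
  }

  keys <- cell_key(c55)
  c53_cell <- lookup("Cervix (C53)", keys)
  c54_cell <- lookup("Corpus uteri (C54)", keys)
  c53_ds <- lookup("Cervix (C53)", c55$dataset, by_dataset = TRUE)
  c54_ds <- lookup("Corpus uteri (C54)", c55$dataset, by_dataset = TRUE)

  cell_tot <- c53_cell + c54_cell
  ds_tot <- c53_ds + c54_ds
  p53 <- ifelse(cell_tot > 0, c53_cell / cell_tot,
                ifelse(ds_tot > 0, c53_ds / ds_tot, 0.5))
  if (any(cell_tot == 0 & ds_tot == 0 & c55$count > 0)) {
    warn_canestim("reallocate_unspecified_uterus: no cervix/corpus counts at any level for %d cell(s); splitting 50/50",
                  sum(cell_tot == 0 & ds_tot == 0 & c55$count > 0))
  }

  add53 <- c55$count * p53
  add54 <- c55$count - add53  # exact conservation by construction
  to53 <- within(c55, { site <- "Cervix (C53)"; count <- add53 })
  to54 <- within(c55, { site <- "Corpus uteri (C54)"; count <- add54 })
  out <- rbind(rest, to53, to54)
  event_table(suppressWarnings(aggregate_counts(out)), event_kind(events))
}
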