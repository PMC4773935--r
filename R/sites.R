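#' Cancer site groups used for national incidence estimation
#'
#' The estimation and validation machinery works on a fixed catalogue of
#' ICD-10 site groups: 19 groups common to both sexes, two male-only groups
#' (prostate C61, testis C62), four female-only groups (breast C50, cervix
#' C53, corpus uteri C54, ovary C56) and a catch-all "Other and unspecified"
#' group, so that 21 male and 23 female groups partition all cancers
#' excluding non-melanoma skin (C44). Unspecified uterus (C55) is carried as
#' a distinct staging group until [reallocate_unspecified_uterus()] splits it
#' between cervix and corpus.
#'
#' @return A data frame with columns `site` (group label) and `sexes`
#'   (`"both"`, `"male"` or `"female"`).
#' @seealso [icd10_site_group()], [site_names()]
#' @export
#' @examples
#' site_catalogue()
site_catalogue <- function() {
  data.frame(
    site = c(
      "Head and neck (C00-14)", "Oesophagus (C15)", "Stomach (C16)",
      "Colon-rectum (C18-21)", "Liver (C22)", "Gallbladder (C23-24)",
      "Pancreas (C25)", "Larynx (C32)", "Lung (C33-34)",
      "Melanoma of skin (C43)", "Breast (C50)", "Cervix (C53)",
      "Corpus uteri (C54)", "Ovary (C56)", "Prostate (C61)", "Testis (C62)",
      "Kidney (C64-66)", "Bladder (C67)", "Brain (C70-72)", "Thyroid (C73)",
      "Hodgkin lymphoma (C81)", "Non-Hodgkin lymphoma (C82-85, C96)",
      "Multiple myeloma (C88, C90)", "Leukaemia (C91-95)",
      "Other and unspecified"
    ),
    sexes = c(
      "both", "both", "both", "both", "both", "both", "both", "both", "both",
      "both", "female", "female", "female", "female", "male", "male",
      "both", "both", "both", "both", "both", "both", "both", "both", "both"
    ),
    stringsAsFactors = FALSE
  )
}

# Staging group for unspecified uterus, valid only before reallocation.
C55_GROUP <- "Uterus unspecified (C55)"

FEMALE_ONLY_SITES <- c("Breast (C50)", "Cervix (C53)", "Corpus uteri (C54)",
                       "Ovary (C56)", C55_GROUP)
MALE_ONLY_SITES <- c("Prostate (C61)", "Testis (C62)")

#' Site group labels valid for a sex
#'
#' @param sex `"male"` or `"female"`.
#' @return Character vector of 21 (male) or 23 (female) group labels.
#' @export
site_names <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  cat <- site_catalogue()
  cat$site[cat$sexes %in% c("both", sex)]
}

#' Map ICD-10 rubric codes to site groups
#'
#' Codes are matched on their three-character rubric (e.g. `"C18.2"` maps via
#' `C18`). Codes within C00-C97 not covered by a named group fall into
#' "Other and unspecified"; non-melanoma skin (C44) maps to `NA` and is
#' excluded from all analyses; C55 maps to its own staging group.
#'
#' @param codes Character vector of ICD-10 codes or existing group labels
#'   (group labels pass through unchanged).
#' @return Character vector of group labels (`NA` for C44 / non-cancer codes).
#' @export
#' @examples
#' icd10_site_group(c("C18", "C20", "C61", "C44"))
icd10_site_group <- function(codes) {
  cat_sites <- site_catalogue()$site
  out <- rep(NA_character_, length(codes))
  known <- codes %in% c(cat_sites, C55_GROUP)
  out[known] <- codes[known]
  todo <- !known
  if (!any(todo)) return(out)

  rubric <- toupper(sub("\\..*$", "", trimws(codes[todo])))
  num <- suppressWarnings(as.integer(sub("^C", "", rubric)))
  ok <- grepl("^C[0-9]{1,2}$", rubric) & !is.na(num)
  grp <- rep(NA_character_, sum(todo))

  in_range <- function(n, lo, hi) !is.na(n) & n >= lo & n <= hi
  grp[ok & in_range(num, 0, 14)] <- "Head and neck (C00-14)"
  grp[ok & num == 15] <- "Oesophagus (C15)"
  grp[ok & num == 16] <- "Stomach (C16)"
  grp[ok & in_range(num, 18, 21)] <- "Colon-rectum (C18-21)"
  grp[ok & num == 22] <- "Liver (C22)"
  grp[ok & in_range(num, 23, 24)] <- "Gallbladder (C23-24)"
  grp[ok & num == 25] <- "Pancreas (C25)"
  grp[ok & num == 32] <- "Larynx (C32)"
  grp[ok & in_range(num, 33, 34)] <- "Lung (C33-34)"
  grp[ok & num == 43] <- "Melanoma of skin (C43)"
  grp[ok & num == 50] <- "Breast (C50)"
  grp[ok & num == 53] <- "Cervix (C53)"
  grp[ok & num == 54] <- "Corpus uteri (C54)"
  grp[ok & num == 55] <- C55_GROUP
  grp[ok & num == 56] <- "Ovary (C56)"
  grp[ok & num == 61] <- "Prostate (C61)"
  grp[ok & num == 62] <- "Testis (C62)"
  grp[ok & in_range(num, 64, 66)] <- "Kidney (C64-66)"
  grp[ok & num == 67] <- "Bladder (C67)"
  grp[ok & in_range(num, 70, 72)] <- "Brain (C70-72)"
  grp[ok & num == 73] <- "Thyroid (C73)"
  grp[ok & num == 81] <- "Hodgkin lymphoma (C81)"
  grp[ok & (in_range(num, 82, 85) | num == 96)] <-
    "Non-Hodgkin lymphoma (C82-85, C96)"
  grp[ok & (num == 88 | num == 90)] <- "Multiple myeloma (C88, C90)"
  grp[ok & in_range(num, 91, 95)] <- "Leukaemia (C91-95)"
  # remaining cancer rubrics -> catch-all, except non-melanoma skin
  rest <- ok & is.na(grp) & in_range(num, 0, 97) & num != 44
  grp[rest] <- "Other and unspecified"

  out[todo] <- grp
  out
}

# Sex/site compatibility; C55 allowed only in females.
sex_site_conflict <- function(sex, site) {
  (sex == "male" & site %in% FEMALE_ONLY_SITES) |
    (sex == "female" & site %in% MALE_ONLY_SITES)
}
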