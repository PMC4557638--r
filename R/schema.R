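#' Cause-of-death classes
#'
#' Fixed index order used everywhere downstream: 1 = non-transport accident
#' (NTA), 2 = suicide (SUI), 3 = homicide (HOM). `EUI` (event of undetermined
#' intent) is the observed class of deaths awaiting reclassification and never
#' receives an index.
#'
#' @format Character vector of the three known-cause labels in index order.
#' @export
CAUSE_LEVELS <- c("NTA", "SUI", "HOM")

#' All observed cause classes (known causes plus undetermined intent)
#' @rdname CAUSE_LEVELS
#' @export
OBSERVED_CAUSE_LEVELS <- c("NTA", "SUI", "HOM", "EUI")

# The ten model covariates, in canonical column order.
COVARIATE_NAMES <- c(
  "identity_known", "age_group", "year", "day_type", "season",
  "region", "urban_rural", "injury_category", "alcohol", "place"
)

#' Death-record schema
#'
#' Declares the level set of every categorical field of a death record.
#' "unknown" and "unspecified" are ordinary levels, never missing markers:
#' ill-defined values carry real diagnostic information and are modelled as
#' such rather than imputed.
#'
#' @param years Integer vector of calendar years covered by the data
#'   (each year is one categorical level).
#' @param regions Character vector of region labels. The default mirrors a
#'   nine-region configuration: eight federal-district-like regions plus the
#'   capital region split out.
#' @return An object of class `eui_schema`: a named list of level vectors,
#'   one per covariate, plus the cause-class levels and the pass-through
#'   (non-covariate) fields.
#' @examples
#' sch <- default_schema()
#' names(sch$levels)
#' @export
default_schema <- function(years = 2000:2011,
                           regions = c("central", "moscow", "northwest",
                                       "south", "northcaucasus", "volga",
                                       "ural", "siberia", "fareast")) {
  stopifnot(length(years) >= 1L, !anyDuplicated(years),
            length(regions) >= 2L, !anyDuplicated(regions))
  levels <- list(
    identity_known  = c("yes", "no"),
    age_group       = c("0-14", "15-24", "25-34", "35-44", "45-54",
                        "55-64", "65+", "unknown"),
    year            = as.character(sort(as.integer(years))),
    day_type        = c("postholiday_monday", "other"),
    season          = c("winter", "summer", "spring_autumn"),
    region          = regions,
    urban_rural     = c("urban", "rural"),
    injury_category = as.character(1:19),
    alcohol         = c("yes", "no"),
    place           = c("home", "residential_institution",
                        "school_public_admin", "sports", "street_highway",
                        "trade_service", "other_specified", "unspecified")
  )
  structure(
    list(
      levels = levels,
      sex_levels = c("male", "female"),
      cause_levels = OBSERVED_CAUSE_LEVELS,
      # carried through I/O for audit but never used as covariates
      passthrough = c("icd_external", "icd_injury",
                      "death_place_type", "certifier")
    ),
    class = "eui_schema"
  )
}

#' @export
print.eui_schema <- function(x, ...) {
  cat("<eui_schema> ", length(x$levels), " covariates\n", sep = "")
  for (v in names(x$levels)) {
    cat(sprintf("  %-16s (%2d) %s\n", v, length(x$levels[[v]]),
                paste(utils::head(x$levels[[v]], 6L), collapse = ", ")))
  }
  invisible(x)
}

#' Validate a microdata data frame against a schema
#'
#' Checks that every categorical field only takes values from its declared
#' level set and that cause_class is consistent with the raw external-cause
#' code where one is present.
#'
#' @param records Data frame of death records.
#' @param schema An `eui_schema`.
#' @return `records`, invisibly, with covariate columns converted to factors
#'   carrying the schema's level order.
#' @export
validate_records <- function(records, schema = default_schema()) {
  stopifnot(is.data.frame(records), inherits(schema, "eui_schema"))
  need <- c("sex", COVARIATE_NAMES, "cause_class")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("microdata is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  check_levels <- function(col, lev) {
    vals <- as.character(records[[col]])
    bad <- which(!(vals %in% lev))
    if (length(bad)) {
      stop(sprintf("invalid level for field '%s' at row %d: '%s'",
                   col, bad[1L], vals[bad[1L]]))
    }
    factor(vals, levels = lev)
  }
  records$sex <- check_levels("sex", schema$sex_levels)
  for (v in COVARIATE_NAMES) {
    records[[v]] <- check_levels(v, schema$levels[[v]])
  }
  records$cause_class <- check_levels("cause_class", schema$cause_levels)

  if ("icd_external" %in% names(records)) {
    has_code <- !is.na(records$icd_external) & nzchar(records$icd_external)
    if (any(has_code)) {
      implied <- vapply(records$icd_external[has_code], classify_cause, "")
      obs <- as.character(records$cause_class[has_code])
      bad <- which(implied != obs)
      if (length(bad)) {
        stop(sprintf(
          "cause_class '%s' inconsistent with external-cause code '%s' (row %d)",
          obs[bad[1L]], records$icd_external[has_code][bad[1L]],
          which(has_code)[bad[1L]]))
      }
    }
  }
  invisible(records)
}
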