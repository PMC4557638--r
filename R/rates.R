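#' European standard population over the model's age bands
#'
#' The classic European standard population (per 100,000), aggregated to
#' the seven known-age bands used by the record schema. The "unknown" age
#' band carries no standard weight: unknown-age deaths are redistributed
#' proportionally before rate computation (see [redistribute_unknown_age()]).
#'
#' @return Object of class `eui_standard_pop`: data frame with `age_group`
#'   and `weight` (proportions summing to 1).
#' @export
european_standard_population <- function() {
  w <- c(`0-14` = 22000, `15-24` = 14000, `25-34` = 14000,
         `35-44` = 14000, `45-54` = 14000, `55-64` = 11000,
         `65+` = 11000)
  structure(
    data.frame(age_group = names(w), weight = as.numeric(w) / sum(w),
               stringsAsFactors = FALSE),
    class = c("eui_standard_pop", "data.frame")
  )
}

#' Build a standard population from explicit weights
#'
#' @param weights Named nonnegative weights by age group; normalized to 1.
#' @return An `eui_standard_pop`.
#' @export
standard_population <- function(weights) {
  stopifnot(!is.null(names(weights)), all(weights >= 0), sum(weights) > 0)
  structure(
    data.frame(age_group = names(weights),
               weight = as.numeric(weights) / sum(weights),
               stringsAsFactors = FALSE),
    class = c("eui_standard_pop", "data.frame")
  )
}

#' Redistribute unknown-age deaths across known age groups
#'
#' Standard vital-statistics practice: deaths with unknown age are shared
#' proportionally to the known-age death counts (within whatever stratum
#' the vector represents). With no known-age deaths the unknown deaths are
#' dropped with a warning.
#'
#' @param deaths Named death counts by age group, possibly including an
#'   `"unknown"` element.
#' @return Named counts over known age groups only.
#' @export
redistribute_unknown_age <- function(deaths) {
  if (!("unknown" %in% names(deaths))) return(deaths)
  u <- deaths[["unknown"]]
  known <- deaths[names(deaths) != "unknown"]
  if (u > 0) {
    if (sum(known) == 0) {
      warning("unknown-age deaths dropped: no known-age deaths to scale")
    } else {
      known <- known + u * known / sum(known)
    }
  }
  known
}

#' Age-standardized death rate (SDR)
#'
#' `SDR = sum_a w_a * (deaths_a / pop_a) * 100000`: age-specific rates
#' weighted by the standard population's age structure, per 100,000.
#'
#' @param deaths Named death counts by age group (an `"unknown"` entry is
#'   redistributed first).
#' @param population Named person denominators by age group.
#' @param standard An `eui_standard_pop` covering the death age groups.
#' @return Rate per 100,000.
#' @examples
#' sdr(c(a = 10, b = 30), c(a = 1e5, b = 1e5),
#'     standard_population(c(a = 0.5, b = 0.5)))  # 20
#' @export
sdr <- function(deaths, population, standard = european_standard_population()) {
  deaths <- redistribute_unknown_age(deaths)
  ages <- standard$age_group
  if (!all(names(deaths) %in% ages)) {
    stop("age groups not covered by the standard population: ",
         paste(setdiff(names(deaths), ages), collapse = ", "))
  }
  d <- stats::setNames(rep(0, length(ages)), ages)
  d[names(deaths)] <- deaths
  p <- population[ages]
  if (anyNA(p) || any(p <= 0 & d > 0)) {
    stop("population denominator missing or zero for an age group with deaths")
  }
  rate_a <- ifelse(d == 0, 0, d / p)
  sum(standard$weight * rate_a) * 1e5
}

#' Official, EUI-contribution and adjusted rate series
#'
#' For each sex, year and cause, computes the SDR of officially registered
#' deaths, the SDR contribution of EUIs reclassified to that cause, the
#' adjusted SDR (their sum), and the proportion of the adjusted rate
#' accounted for by reclassified EUIs.
#'
#' @param official Data frame of officially registered death counts with
#'   columns `sex`, `year`, `cause`, `age_group`, `deaths`.
#' @param eui_contribution Same layout: EUI deaths reclassified to each
#'   cause (may be empty for a zero contribution).
#' @param population Data frame `sex`, `age_group`, `population`
#'   (optionally also `year` for year-specific denominators).
#' @param standard An `eui_standard_pop`.
#' @return Data frame, one row per sex x year x cause, with columns
#'   `official_sdr`, `eui_sdr`, `adjusted_sdr`, `eui_share`.
#' @export
adjusted_series <- function(official, eui_contribution, population,
                            standard = european_standard_population()) {
  need <- c("sex", "year", "cause", "age_group", "deaths")
  stopifnot(all(need %in% names(official)))
  if (nrow(eui_contribution) == 0L) {
    eui_contribution <- official[0L, need]
  }
  stopifnot(all(need %in% names(eui_contribution)))
  keys <- unique(rbind(official[c("sex", "year", "cause")],
                       eui_contribution[c("sex", "year", "cause")]))
  keys <- keys[order(keys$sex, keys$year, keys$cause), , drop = FALSE]

  year_specific <- "year" %in% names(population)
  get_pop <- function(sx, yr) {
    p <- if (year_specific) {
      population[population$sex == sx & population$year == yr, ]
    } else {
      population[population$sex == sx, ]
    }
    if (!nrow(p)) stop("no population denominators for sex ", sx,
                       if (year_specific) paste0(", year ", yr))
    stats::setNames(p$population, p$age_group)
  }
  counts_by_age <- function(df, sx, yr, cs) {
    sub <- df[df$sex == sx & df$year == yr & df$cause == cs, ]
    if (!nrow(sub)) return(numeric(0))
    tapply(sub$deaths, sub$age_group, sum)
  }
  out <- keys
  out$official_sdr <- out$eui_sdr <- NA_real_
  for (r in seq_len(nrow(keys))) {
    sx <- keys$sex[r]; yr <- keys$year[r]; cs <- keys$cause[r]
    pop <- get_pop(sx, yr)
    d_off <- counts_by_age(official, sx, yr, cs)
    d_eui <- counts_by_age(eui_contribution, sx, yr, cs)
    out$official_sdr[r] <- if (length(d_off)) sdr(d_off, pop, standard) else 0
    out$eui_sdr[r] <- if (length(d_eui)) sdr(d_eui, pop, standard) else 0
  }
  out$adjusted_sdr <- out$official_sdr + out$eui_sdr
  out$eui_share <- ifelse(out$adjusted_sdr > 0,
                          out$eui_sdr / out$adjusted_sdr, 0)
  rownames(out) <- NULL
  out
}
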