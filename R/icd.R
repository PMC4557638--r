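#' Classify an ICD-10 external-cause code into a cause class
#'
#' Maps a code from the ICD-10 external-cause chapter (V01--Y98) to one of
#' the analysis classes: `NTA` (non-transport accident, W00--X59), `SUI`
#' (suicide, X60--X84), `HOM` (homicide, X85--Y05 plus Y08, Y09), `EUI`
#' (event of undetermined intent, Y10--Y34), or `"excluded"` for the groups
#' dropped from the analysis: transport accidents (V01--V99) and neglect /
#' maltreatment (Y06--Y07).
#'
#' @param code ICD-10 code string, e.g. `"X70"` or `"X70.1"`; a fourth
#'   character subcode is ignored.
#' @param transport_range Integer vector `c(lo, hi)` of V-code numbers
#'   treated as transport accidents. The source classification says only
#'   "transport accidents"; V01--V99 is the conventional reading and the
#'   default, kept configurable.
#' @return One of `"NTA"`, `"SUI"`, `"HOM"`, `"EUI"`, `"excluded"`.
#' @examples
#' classify_cause("X70")  # suicide
#' classify_cause("Y06")  # excluded (neglect/maltreatment)
#' classify_cause("W00")  # non-transport accident
#' @export
classify_cause <- function(code, transport_range = c(1L, 99L)) {
  code <- toupper(trimws(as.character(code)))
  if (length(code) != 1L || is.na(code) ||
      !grepl("^[A-Z][0-9]{2}([0-9.].*)?$", code)) {
    stop("malformed ICD-10 code: '", code, "'")
  }
  letter <- substr(code, 1L, 1L)
  num <- as.integer(substr(code, 2L, 3L))
  if (letter == "V") {
    if (num >= transport_range[1L] && num <= transport_range[2L]) {
      return("excluded")
    }
    stop("ICD-10 code '", code, "' outside the analysed external-cause groups")
  }
  if (letter == "W") return("NTA")
  if (letter == "X") {
    if (num <= 59L) return("NTA")
    if (num <= 84L) return("SUI")
    return("HOM")                       # X85-X99: assault
  }
  if (letter == "Y") {
    if (num <= 5L) return("HOM")
    if (num <= 7L) return("excluded")   # Y06-Y07 neglect and maltreatment
    if (num <= 9L) return("HOM")        # Y08, Y09
    if (num <= 34L) return("EUI")
    stop("ICD-10 code '", code, "' outside the analysed external-cause groups")
  }
  stop("ICD-10 code '", code, "' is not in the external-cause chapter")
}

# --- nature-of-injury grouping --------------------------------------------

# 19-category national injury grouping and the ICD-10 S/T codes it covers.
# Categories are built as disjoint code sets; coverage of S00-T98 is checked
# once at build time.
injury_rows <- list(
  list(1L,  "Fracture of skull and facial bones", "S02"),
  list(2L,  "Intracranial injury", "S06"),
  list(3L,  "Other injuries to the head", "S00, S01, S03-S05, S07-S09"),
  list(4L,  "Injuries to the neck", "S10-S19"),
  list(5L,  "Open wound of thorax", "S21"),
  list(6L,  "Other injuries to the thorax", "S20, S22-S29"),
  list(7L,  "Injuries to the abdomen, lower back, lumbar spine and pelvis",
        "S30-S39"),
  list(8L,  "Injuries to the limbs", "S40-S99"),
  list(9L,  "Effects of foreign body entering through natural orifice",
        "T15-T19"),
  list(10L, "Burns and corrosions", "T20-T32"),
  list(11L, "Frostbite", "T33-T35"),
  list(12L, "Poisoning by narcotics and psychodysleptics", "T40"),
  list(13L, "Toxic effect of alcohol", "T51"),
  list(14L, "Toxic effect of carbon monoxide", "T58"),
  list(15L, "Other poisoning by drugs and nonmedicinal substances",
        "T36-T39, T41-T50, T52-T57, T59-T65"),
  list(16L, "Hypothermia and other effects of reduced temperature",
        "T68, T69"),
  list(17L, "Asphyxiation", "T71"),
  list(18L, "Lightning, drowning, vibration, electric current and other specified effects",
        "T75"),
  list(19L, "Other injury, poisoning and consequences of external causes",
        "T00-T14, T66, T67, T70, T72-T74, T76-T98")
)

# expand "S03-S05, S07" style spans into 3-character codes
expand_codes <- function(spec) {
  parts <- trimws(strsplit(spec, ",")[[1L]])
  out <- character(0)
  for (p in parts) {
    if (grepl("-", p, fixed = TRUE)) {
      ends <- trimws(strsplit(p, "-", fixed = TRUE)[[1L]])
      l1 <- substr(ends[1L], 1L, 1L); l2 <- substr(ends[2L], 1L, 1L)
      n1 <- as.integer(substr(ends[1L], 2L, 3L))
      n2 <- as.integer(substr(ends[2L], 2L, 3L))
      if (l1 == l2) {
        out <- c(out, sprintf("%s%02d", l1, n1:n2))
      } else {                          # spans an S->T boundary (e.g. S40-S99)
        out <- c(out, sprintf("%s%02d", l1, n1:99L),
                 sprintf("%s%02d", l2, 0L:n2))
      }
    } else {
      out <- c(out, p)
    }
  }
  out
}

build_injury_map <- function() {
  map <- integer(0)
  for (row in injury_rows) {
    codes <- expand_codes(row[[3L]])
    dup <- intersect(names(map), codes)
    if (length(dup)) stop("overlapping injury grouping at ", dup[1L])
    map[codes] <- row[[1L]]
  }
  domain <- c(sprintf("S%02d", 0:99), sprintf("T%02d", 0:98))
  gap <- setdiff(domain, names(map))
  if (length(gap)) stop("injury grouping leaves codes unmapped: ", gap[1L])
  map
}

INJURY_MAP <- build_injury_map()

#' Map an ICD-10 nature-of-injury code to the 19-category grouping
#'
#' Implements the national aggregate injury classification: each S00--T98
#' code maps to exactly one of 19 categories (category 19 is the catch-all
#' "other injury, poisoning and consequences of external causes").
#'
#' @param code ICD-10 S/T code string; a subcode after the first three
#'   characters is ignored.
#' @return Integer category 1--19.
#' @examples
#' classify_injury("S02")  # 1: fracture of skull
#' classify_injury("T51")  # 13: toxic effect of alcohol
#' @export
classify_injury <- function(code) {
  code <- toupper(trimws(as.character(code)))
  if (length(code) != 1L || is.na(code) ||
      !grepl("^[ST][0-9]{2}([0-9.].*)?$", code)) {
    stop("not an ICD-10 nature-of-injury (S/T) code: '", code, "'")
  }
  key <- substr(code, 1L, 3L)
  cat_ <- INJURY_MAP[key]
  if (is.na(cat_)) {
    stop("S/T code '", code, "' is not covered by the injury grouping")
  }
  unname(cat_)
}

#' Injury grouping reference table
#'
#' @return Data frame with columns `category`, `label`, `icd_codes`
#'   describing the 19-category injury grouping.
#' @export
injury_category_table <- function() {
  data.frame(
    category = vapply(injury_rows, `[[`, integer(1), 1L),
    label = vapply(injury_rows, `[[`, character(1), 2L),
    icd_codes = vapply(injury_rows, `[[`, character(1), 3L),
    stringsAsFactors = FALSE
  )
}
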