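#' Read death-record microdata from CSV
#'
#' Reads one-row-per-death microdata, derives `cause_class` from the raw
#' external-cause code when the column is absent, drops records whose cause
#' is outside the analysis (transport accidents V01--V99 and neglect /
#' maltreatment Y06--Y07) with a logged count, and validates every
#' categorical field against the schema.
#'
#' @param path CSV file path (comma-separated, UTF-8, header required).
#' @param schema An `eui_schema` describing the level sets.
#' @return Data frame of validated records; the number of dropped
#'   excluded-cause rows is attached as attribute `"excluded"`.
#' @export
read_microdata <- function(path, schema = default_schema()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!nrow(raw)) stop("no records in ", path)
  if (!("cause_class" %in% names(raw))) {
    if (!("icd_external" %in% names(raw))) {
      stop("microdata must carry either 'cause_class' or 'icd_external'")
    }
    raw$cause_class <- vapply(raw$icd_external, classify_cause, "")
  } else if ("icd_external" %in% names(raw)) {
    # excluded causes may be flagged either way; normalize via the code
    implied <- vapply(raw$icd_external, classify_cause, "")
    excl <- implied == "excluded"
    raw$cause_class[excl] <- "excluded"
  }
  n_excluded <- sum(raw$cause_class == "excluded")
  if (n_excluded > 0L) {
    message("read_microdata: excluded ", n_excluded,
            " record(s) with out-of-scope causes (transport / Y06-Y07)")
    raw <- raw[raw$cause_class != "excluded", , drop = FALSE]
  }
  if ("injury_category" %in% names(raw)) {
    # tolerate a raw S/T code in place of a category number
    not_num <- !grepl("^[0-9]+$", raw$injury_category)
    if (any(not_num)) {
      raw$injury_category[not_num] <-
        as.character(vapply(raw$injury_category[not_num], classify_injury, 0L))
    }
  } else if ("icd_injury" %in% names(raw)) {
    raw$injury_category <-
      as.character(vapply(raw$icd_injury, classify_injury, 0L))
  }
  out <- validate_records(raw, schema)
  attr(out, "excluded") <- n_excluded
  out
}

#' Write microdata to canonical CSV
#'
#' @param records Validated records data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_microdata <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a covariate encoding map
#'
#' Fixes, for every categorical covariate, a reference level and the order
#' of indicator columns, so that identical records always produce identical
#' indicator vectors. By default the reference level of each variable is its
#' most frequent level in the supplied data, which stabilizes estimation;
#' `reference = "first"` uses the schema's first level instead (useful for
#' reproducing an encoding without data).
#'
#' @param records Validated records (used to pick reference levels and,
#'   when `schema` is `NULL`, to read the level sets off their factor
#'   columns).
#' @param schema The `eui_schema`; `NULL` derives levels from `records`.
#' @param reference `"most_frequent"` or `"first"`.
#' @return An object of class `eui_encoding`.
#' @export
build_encoding <- function(records = NULL, schema = NULL,
                           reference = c("most_frequent", "first")) {
  reference <- match.arg(reference)
  if (is.null(schema) && is.null(records)) schema <- default_schema()
  vars <- list()
  for (v in COVARIATE_NAMES) {
    lev <- if (!is.null(schema)) schema$levels[[v]] else {
      if (!is.factor(records[[v]])) {
        stop("cannot derive levels for '", v,
             "': pass a schema or validated records")
      }
      levels(records[[v]])
    }
    ref <- if (reference == "most_frequent" && !is.null(records)) {
      tab <- table(factor(as.character(records[[v]]), levels = lev))
      lev[which.max(tab)]
    } else {
      lev[1L]
    }
    vars[[v]] <- list(levels = lev, reference = ref,
                      indicators = setdiff(lev, ref))
  }
  structure(list(variables = vars), class = "eui_encoding")
}

#' @export
print.eui_encoding <- function(x, ...) {
  k <- 1L + sum(vapply(x$variables, function(v) length(v$indicators), 0L))
  cat("<eui_encoding> ", length(x$variables), " covariates, ",
      k, " design columns (incl. intercept)\n", sep = "")
  invisible(x)
}

#' Encode records as model indicator vectors
#'
#' Dummy (one-hot, reference omitted) expansion of the ten categorical
#' covariates plus an intercept column. Column order and reference levels
#' are fixed by the encoding map, so the design is identical across calls.
#'
#' @param records Data frame of one or more validated records.
#' @param encoding An `eui_encoding` from [build_encoding()].
#' @return Numeric matrix, one row per record; first column `(Intercept)`.
#' @export
encode_covariates <- function(records, encoding) {
  stopifnot(inherits(encoding, "eui_encoding"))
  n <- nrow(records)
  cols <- list(`(Intercept)` = rep(1, n))
  for (v in names(encoding$variables)) {
    spec <- encoding$variables[[v]]
    vals <- as.character(records[[v]])
    bad <- setdiff(unique(vals), spec$levels)
    if (length(bad)) {
      stop("level '", bad[1L], "' of '", v, "' absent from encoding map")
    }
    for (lv in spec$indicators) {
      cols[[paste0(v, ".", lv)]] <- as.numeric(vals == lv)
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- NULL
  mat
}
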